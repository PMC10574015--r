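---
title: "Measuring 7TM receptor activation: basement superposition, RMSF cores, and steered restraint schedules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 7TM receptor activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actimetry)
```

## The model

Class-A GPCR activation is a conformational change of a seven-helix
transmembrane bundle: TM6 swings outward and TM7 shifts toward TM5,
while a stiff core — in CB1 numbering, residues 195–199 of TM3,
243–249 of TM4 and 275–289 of TM5, called the *basement* — remains
essentially fixed between states. The package's central assumption is
that this core is state-independent, which makes it a meaningful
superposition frame: once two conformations are least-squares fitted
on basement Cα atoms, residual displacements elsewhere in the bundle
measure genuine conformational change rather than global rotation or
drift.

The activation indicator is the pooled Cα RMSD (and maximum atom
distance) of residues 351–361 (TM6) and 381–391 (TM7), evaluated in
the basement frame against an active and an inactive reference
structure. We pool the two segments into a single RMSD because the
reference comparisons report one value pair per structure; per-segment
RMSDs are also returned for transparency. Crystal-reference
comparisons place an inactive structure about 3.7/5.4 Å (RMSD/max)
from an active one on this indicator, so the two states are well
separated relative to coordinate noise.

### Classification

References of both states are required. The query is fitted
independently to each reference (per-column comparison, not via a
common frame) and labelled

* `active-like` if `rmsd_active + margin < rmsd_inactive`,
* `inactive-like` in the symmetric case,
* `indeterminate` otherwise, or when the two references are
  indistinguishable on the indicator.

The margin defaults to 0.5 Å. The underlying literature classifies by
inspection; the margin is chosen so that partially activated
conformations (for example 2.2 Å from one reference and 2.0 Å from the
other) are reported as indeterminate rather than force-labelled. It is
a presentation threshold, not a scientific claim, and is exposed as a
parameter.

One ambiguity deserves note: descriptions of the stable TM5 region
vary between 275–289 and a shorter 275–283/286 stretch depending on
context. The package defaults to 275–289 (the stated alignment set for
the reference comparisons); `default_selections(tm5_end = 283)` (or
286) selects the shorter variants.

## Structure handling

PDB parsing and writing go through `bio3d`. Residues are addressed by
*author* numbering throughout, because that is how receptor residues
are cited (e.g. Ser383); insertion codes compare lexicographically.
Alternate locations are resolved to the highest-occupancy conformer by
default (ties broken by lexicographically first altloc) for
determinism; `altloc = "first"` keeps file order instead. HETATM
records are kept separately and never enter protein metrics. Residues
named by a selection but missing from a structure are dropped from the
pairing and reported — never interpolated — so every reported RMSD is
auditable to an explicit atom list. A selection or pairing that
resolves to fewer than three atoms is an error, since a rigid fit is
then underdetermined.

Crystal constructs of receptors are usually fusion proteins; users
should name the receptor chain (all defaults assume a single-chain
receptor numbered in the 100–420 range).

## RMSF and stiff-core detection

RMSF is computed per atom about its *time-mean* position over an
aligned trajectory, `rmsf_i = sqrt(mean_t |r_i(t) − ⟨r_i⟩|²)`; the
mean-structure reference makes the profile invariant under frame
permutation. Alignment is two-pass: frames are fitted to the first
frame, a mean structure is computed, and the original frames are
refitted to that mean.

`detect_stiff_core()` thresholds the profile at a quantile (strict
`<`, so a constant profile yields nothing) and merges surviving
residues into contiguous runs of at least `min_run` (default 4,
because core segments are 5–15 residues long). The quantile should be
set near the *expected stiff fraction* of the chain: the RMSF values of
a two-state chain form two clusters, and a quantile well above the
stiff fraction places the cut inside the mobile cluster, letting
random mobile residues extend or fake runs. In the ground-truth tests
27 of 219 residues (≈ 12%) are planted stiff and the detector is run
at `quantile = 0.13`, which puts the threshold in the gap between
clusters. The default of 0.25 is a reasonable starting point for
exploratory use on real profiles, where the stiff fraction is unknown.

## The steered restraint schedule

The simplified steered-dynamics protocol tethers each pulled atom to a
harmonic restraint `U = k (r − r0)² / 2` and steps the center toward
the destination `r*` over `N` stages:

```
r0^(i+1) = ⟨r⟩^(i) − (⟨r⟩^(i) − r*) / (N − i),   i = 1 … N−1
```

where `⟨r⟩^(i)` is the atom's mean position during stage `i`. The rule
advances `1/(N−i)` of the remaining gap per stage, and at `i = N−1` the
code returns `r*` itself, so the final centers equal the destinations
bitwise. Defaults follow the published protocol: `N = 21`,
`k = 500` kcal/(mol Å²) on pulled atoms, `k = 80` kcal/(mol Å²) on the
retained-core atoms, whose centers stay at their initial coordinates
throughout. When the atoms track their centers (stiff restraint), the
center path is linear and each shift is `d/(N−1)` — about
0.105–0.145 Å per stage for a 2–3 Å pull, matching the magnitude the
protocol was designed around.

The stage mean is taken over the trailing 50% of each stage
(`avg_window = 0.5`); the leading half is treated as the relaxation
transient after the center jump. The source protocol does not state
its averaging window; this is our choice and it is configurable.
Stage length is expressed in integrator steps, keeping the module
agnostic of the backend's time units.

### Work accounting

For a piecewise-constant protocol the thermodynamic work is exactly
the sum of energy jumps at the switching times,
`ΔW = Σ_atoms [U(r; r0_new) − U(r; r0_old)]` evaluated at the
instantaneous coordinates — no integral needs to be invented. We record
raw switching work without subtracting restraint bias at the
endpoints.

On the toy system — one particle in a harmonic well `k_s x²/2` steered
by a restraint of stiffness `k` over a displacement `d` — the
equilibrium free-energy change has the closed form
`ΔF = ½ · k·k_s/(k+k_s) · d²` (the Gaussian width is
center-independent, so only the minimum energy shifts), which gives an
exact oracle for the work accounting.

Two systematic effects separate the *expected* switching work from ΔF,
and both shaped the test design:

1. **Finite-N dissipation.** Each center jump of size δ dissipates
   `≈ k²δ²/(2(k+k_s))` even with perfect equilibration, and with a
   restraint much stiffer than the well the total excess
   `≈ d²k²/(2N(k+k_s))` dwarfs ΔF (at `k = 500`, `k_s = 1` it is
   ~25× ΔF). The quasi-static demonstration therefore uses a *soft*
   restraint, `k = 0.5`, `k_s = 1`, `d = 1.5` Å, where a mean-field
   recursion (perfect equilibration each stage, means lagging centers
   by the factor `k/(k+k_s)`) puts the protocol dissipation at ~0.04
   kcal/mol against ΔF = 0.375 kcal/mol — below the statistical
   resolution of a 10-seed mean at `k_BT = 0.616` kcal/mol (310 K).

2. **Measurement feedback.** The center update acts on *measured*
   stage means. At finite temperature those means carry sampling
   noise correlated with the atom's instantaneous position, and the
   schedule exploits that correlation like a feedback controller: the
   measured switching work can fall *below* ΔF (the naive second-law
   bound does not apply to feedback protocols). The effect scales as
   `k_BT · τ/w` per stage, with τ the position correlation time and
   `w` the averaging window, so the quasi-static run uses a timestep
   giving τ ≈ 13 steps against a window of 1000 steps. The
   second-law property itself (dissipated work ≥ 0, strictly for fast
   pulling) is demonstrated in the deterministic `k_BT = 0` limit,
   where the means are exact, the dynamics are gradient descent, and
   the bound is provable.

The toy backend integrates overdamped Langevin dynamics
(Euler–Maruyama, `r ← r + (F/γ)dt + sqrt(2 k_BT dt/γ) ξ`); there is no
inertia because the validation surface is equilibrium statistics, not
kinetics. Thermal energy is supplied directly as `k_BT` in kcal/mol to
match the restraint units. The discrete-time stationary variance of a
harmonic degree of freedom is `(k_BT/k_s)/(1 − k_s dt/2γ)`, which the
equipartition test uses as its target; at the timesteps employed the
discretization correction is ≤ 4%.

## What the synthetic generators emulate — and what they do not

`build_cb1_like_bundle()` produces seven ideal α-helices (rise 1.5 Å,
twist 100°, radius 2.3 Å) on a 12 Å ring, numbered so that every
default selection and collective-variable atom resolves
(TM1 100–134, TM2 145–180, TM3 186–224, TM4 234–258, TM5 270–298,
TM6 339–367, TM7 374–399). `make_conformational_pair()` applies an
exact rigid motion to a chosen sub-helix, giving activation-metric
ground truth to machine precision, and `make_jitter_trajectory()` adds
isotropic Gaussian noise with per-residue amplitude, giving
`RMSF = sqrt(3)·σ` exactly in expectation.

These fixtures validate the *measurement machinery*: superposition,
metric arithmetic, ordering, classification logic, RMSF estimation and
core detection. They do not emulate real receptor physics — no side
chains, no membrane, no correlated backbone motion, no partial
activation intermediates — so passing tests demonstrate correctness of
the metrics, not that any particular receptor behaves this way. In
particular the synthetic indicator displacement is a uniform
translation, for which RMSD = max distance = |t|; real conformational
changes produce the spread between RMSD and max distance seen in
crystal comparisons.

## Numerical choices and problem sizes

* Kabsch superposition uses the SVD of the 3×3 cross-covariance with
  the determinant correction, so reflections are never returned;
  near-collinear point sets trigger a rank-deficiency warning but
  still yield a proper rotation. The test suite cross-checks the
  minimal RMSD against an independent quaternion (Horn) superposition
  on random instances to 10⁻⁸ Å.
* Angles are reported in degrees; the arc-cosine argument is clamped
  to [−1, 1] to absorb rounding.
* PDB coordinates quantize at 0.001 Å; round-trip tests assert at that
  precision, and a second round trip is exact.
* Test problem sizes: jitter trajectories of 400–2000 frames × 219
  atoms; steered toy runs of 21 stages × 2000 steps × 10 seeds;
  1000-instance schedule-endpoint sweeps. These sizes keep the full
  suite around half a minute while leaving every statistical assertion
  at least 3 standard errors of headroom.

## Known limitations

* Activation scoring requires both references; there is no
  single-reference or unsupervised mode.
* Numbering mismatches between query and references are not
  reconciled by sequence alignment; structures must share author
  numbering.
* The crystal-reference comparisons (5XRA/5XR8/5TGZ) need the actual
  PDB entries, which cannot be redistributed with the package; the
  corresponding checks run only when the files are supplied.
* The steered-schedule work estimate inherits both systematic effects
  described above; for free-energy estimation the protocol should be
  run with a soft restraint, long stages, and ideally several seeds —
  or treated, as in its source context, as a means of *driving* a
  transformation rather than measuring ΔG precisely.
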