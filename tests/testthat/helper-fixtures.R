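# Shared fixtures, built in code at test time.

# A hand-written three-residue PDB with an altloc pair and a HETATM.
write_tiny_pdb <- function(path) {
  writeLines(c(
    "TITLE     TINY TEST STRUCTURE",
    "ATOM      1  N   ALA A 100      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A 100      11.639   6.071  -5.147  0.60  0.00           C",
    "ATOM      3  CA BALA A 100      11.700   6.100  -5.200  0.40  0.00           C",
    "ATOM      4  CA  GLY A 101       8.444   5.538  -4.745  1.00  0.00           C",
    "ATOM      5  CA  SER A 102       5.145   4.549  -5.393  1.00  0.00           C",
    "HETATM    6  O   HOH A 500       0.100   0.200   0.300  1.00  0.00           O",
    "END"), path)
  path
}

bundle_fixture <- function(seed = 7) build_cb1_like_bundle(seed = seed)

indicator_helices <- function(chain = "A") {
  # whole TM6 + TM7 helices: a superset of the indicator selection,
  # disjoint from the basement
  residue_selection(chain, c(339, 374), c(367, 399))
}

# Dynamics-free steering backend: atoms relax down the restraint gradient
# at zero temperature (friction gamma, timestep dt), no system potential.
# With enough steps per stage the positions converge onto the centers, so
# means track centers and schedule geometry can be checked exactly.
make_descent_backend <- function(positions0, gamma = 1, dt = 1e-4) {
  state <- new.env(parent = emptyenv())
  state$pos <- as.matrix(positions0)
  list(
    initialize = function(seed) state$pos <- as.matrix(positions0),
    step = function(restraints = list()) {
      f <- matrix(0, nrow(state$pos), 3)
      for (hr in restraints) {
        i <- match(hr$label, rownames(state$pos))
        f[i, ] <- f[i, ] - hr$k * (state$pos[i, ] - hr$center)
      }
      state$pos <- state$pos + f * (dt / gamma)
      invisible(NULL)
    },
    coordinates = function() state$pos
  )
}

# Parameters of the toy quasi-static work demonstration: a single
# particle in a harmonic well (k_s) pulled by a soft restraint (k) over
# displacement d.  Soft k keeps the stepwise-switching dissipation of
# the N-stage protocol well below the statistical resolution of a
# 10-seed mean, and the timestep keeps the position correlation time
# (~13 steps) far below the stage-mean averaging window so the
# measured means are accurate (see the methods vignette for the
# closed-form analysis and the feedback caveat).
toy_steering_setup <- function() {
  list(k_s = 1, k = 0.5, d = 1.5, kT = 0.616, gamma = 1, dt = 0.05,
       n_stages = 21)
}

run_toy_steering <- function(stage_length, seed, setup = toy_steering_setup(),
                             kT = setup$kT) {
  sys <- toy_system("P", wells = data.frame(label = "P", x = 0, y = 0, z = 0,
                                            k = setup$k_s),
                    kT = kT, gamma = setup$gamma, dt = setup$dt)
  pos0 <- matrix(0, 1, 3, dimnames = list("P", NULL))
  backend <- make_toy_backend(sys, pos0)
  sched <- steering_schedule("P", matrix(c(setup$d, 0, 0), 1, 3),
                             n_stages = setup$n_stages, k_pull = setup$k,
                             k_core = 80, stage_length = stage_length)
  run_steering(backend, sched, seed = seed)
}
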