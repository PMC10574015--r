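#' Toy overdamped-Langevin system
#'
#' A desk-scale stochastic dynamics backend used to exercise the steering
#' machinery: labelled particles moving in a potential made of harmonic
#' wells and optional pairwise harmonic bonds, integrated by the
#' overdamped (Brownian) Euler scheme.  Thermal energy is supplied
#' directly as `kT` in kcal/mol so all energies share the restraint
#' units.
#'
#' @param labels character vector of particle labels.
#' @param wells data frame (label, x, y, z, k): harmonic wells
#'   `U = k |r - c|^2 / 2` on individual particles; a label may appear in
#'   several rows.
#' @param bonds optional data frame (a, b, k, r0): harmonic bonds
#'   `U = k (|r_a - r_b| - r0)^2 / 2` between labelled particles.
#' @param kT thermal energy k_B T in kcal/mol (>= 0; 0.616 corresponds to
#'   310 K).
#' @param gamma friction coefficient (mass/time units; default 1).
#' @param dt integrator timestep (time units; default 0.01).
#' @return object of class `toy_system`.
#' @export
toy_system <- function(labels, wells = NULL, bonds = NULL,
                       kT = 0.616, gamma = 1, dt = 0.01) {
  stopifnot(dt > 0, gamma > 0, kT >= 0)
  if (!is.null(wells)) {
    stopifnot(all(c("label", "x", "y", "z", "k") %in% names(wells)))
    if (!all(wells$label %in% labels)) {
      stop("toy_system: well references unknown label", call. = FALSE)
    }
  }
  if (!is.null(bonds)) {
    stopifnot(all(c("a", "b", "k", "r0") %in% names(bonds)))
    if (!all(c(bonds$a, bonds$b) %in% labels)) {
      stop("toy_system: bond references unknown label", call. = FALSE)
    }
  }
  structure(list(labels = labels, wells = wells, bonds = bonds,
                 kT = kT, gamma = gamma, dt = dt),
            class = "toy_system")
}

system_forces <- function(positions, system) {
  f <- matrix(0, nrow(positions), 3)
  rownames(f) <- rownames(positions)
  w <- system$wells
  if (!is.null(w)) {
    i <- match(w$label, rownames(positions))
    contrib <- -w$k * (positions[i, , drop = FALSE] -
                         cbind(w$x, w$y, w$z))
    if (anyDuplicated(i)) {
      agg <- rowsum(contrib, i)
      f[as.integer(rownames(agg)), ] <- f[as.integer(rownames(agg)), ] + agg
    } else {
      f[i, ] <- f[i, ] + contrib
    }
  }
  b <- system$bonds
  if (!is.null(b)) {
    for (j in seq_len(nrow(b))) {
      ia <- match(b$a[j], rownames(positions))
      ib <- match(b$b[j], rownames(positions))
      d <- positions[ia, ] - positions[ib, ]
      r <- sqrt(sum(d^2))
      if (r > 1e-12) {
        fb <- -b$k[j] * (r - b$r0[j]) * d / r
        f[ia, ] <- f[ia, ] + fb
        f[ib, ] <- f[ib, ] - fb
      }
    }
  }
  f
}

#' One overdamped Langevin (Brownian) step
#'
#' Euler–Maruyama update
#' `r <- r + (F/gamma) dt + sqrt(2 kT dt / gamma) xi`,
#' with `xi` i.i.d. standard normal per coordinate and `F` the sum of the
#' system forces and any external restraint forces.  Uses R's global RNG,
#' so trajectories are reproducible under `set.seed()`.
#'
#' @param positions M x 3 matrix with particle labels as row names.
#' @param system a `toy_system`.
#' @param restraints list of [harmonic_restraint()]s (possibly empty).
#' @return updated M x 3 position matrix.
#' @export
brownian_step <- function(positions, system, restraints = list()) {
  f <- system_forces(positions, system)
  for (hr in restraints) {
    i <- match(hr$label, rownames(positions))
    if (is.na(i)) stop("brownian_step: restraint on unknown label ",
                       hr$label, call. = FALSE)
    f[i, ] <- f[i, ] - hr$k * (positions[i, ] - hr$center)
  }
  if (any(!is.finite(f))) {
    stop("brownian_step: non-finite force; positions: ",
         paste(sprintf("%.3g", positions), collapse = " "), call. = FALSE)
  }
  drift <- f * (system$dt / system$gamma)
  noise <- if (system$kT > 0) {
    matrix(stats::rnorm(length(positions),
                        sd = sqrt(2 * system$kT * system$dt / system$gamma)),
           nrow(positions), 3)
  } else 0
  positions + drift + noise
}

#' Toy backend implementing the steering contract
#'
#' Wraps a [toy_system()] and an initial configuration into the
#' three-callable backend contract consumed by [run_steering()]:
#' `initialize(seed)` (re)sets positions and the RNG, `step(restraints)`
#' advances one [brownian_step()], `coordinates()` returns the current
#' labelled position matrix.
#'
#' @param system a `toy_system`.
#' @param positions0 initial M x 3 matrix, row names = particle labels.
#' @return backend: list of callables sharing a private state.
#' @export
make_toy_backend <- function(system, positions0) {
  positions0 <- as.matrix(positions0)
  if (is.null(rownames(positions0))) rownames(positions0) <- system$labels
  state <- new.env(parent = emptyenv())
  state$pos <- positions0
  list(
    initialize = function(seed) {
      set.seed(seed)
      state$pos <- positions0
      invisible(NULL)
    },
    step = function(restraints = list()) {
      state$pos <- brownian_step(state$pos, system, restraints)
      invisible(NULL)
    },
    coordinates = function() state$pos
  )
}

#' Analytic steering free-energy change for a harmonic well
#'
#' For one particle in a well `U = k_s x^2 / 2` steered by a harmonic
#' restraint of constant `k` whose center moves from 0 to displacement
#' `d`, the equilibrium free-energy change of the combined system is
#' `dF = (1/2) * (k k_s / (k + k_s)) * d^2`
#' (the Gaussian width is center-independent, so only the minimum energy
#' shifts).  In the stiff-spring limit `k -> Inf` this tends to
#' `k_s d^2 / 2`.  Quasi-static switching work converges to this value.
#'
#' @param k_s well force constant, kcal/(mol A^2).
#' @param k restraint force constant, kcal/(mol A^2).
#' @param d center displacement, Angstrom.
#' @return free-energy change in kcal/mol.
#' @examples
#' analytic_steering_dF(1, 1, 2)  # 1.0
#' @export
analytic_steering_dF <- function(k_s, k, d) {
  stopifnot(k_s > 0, k > 0)
  0.5 * (k * k_s / (k + k_s)) * d^2
}
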