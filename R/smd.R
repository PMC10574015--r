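#' Harmonic positional restraint
#'
#' External potential `U = k |r - r0|^2 / 2` tethering one atom to a
#' center `r0`.
#'
#' @param label atom label the restraint acts on.
#' @param center length-3 center `r0` (Angstrom).
#' @param k force constant in kcal/(mol A^2), > 0.
#' @return object of class `harmonic_restraint`.
#' @export
harmonic_restraint <- function(label, center, k) {
  stopifnot(length(center) == 3, is.finite(k), k > 0)
  structure(list(label = label, center = as.numeric(center), k = k),
            class = "harmonic_restraint")
}

#' Energy and force of a harmonic restraint
#'
#' @param r length-3 position (Angstrom).
#' @param restraint a `harmonic_restraint` (or a list with `center`, `k`).
#' @return list with `U` (kcal/mol) and `F` (length-3 force,
#'   kcal/(mol A)); `F = -k (r - r0) = -grad U`.
#' @examples
#' hr <- harmonic_restraint("A:381:CA", c(0, 0, 0), 500)
#' restraint_energy_force(c(0.1, 0, 0), hr)$U  # 2.5 kcal/mol
#' @export
restraint_energy_force <- function(r, restraint) {
  d <- as.numeric(r) - restraint$center
  list(U = 0.5 * restraint$k * sum(d^2), F = -restraint$k * d)
}

#' Next restraint center of the steering schedule
#'
#' Stage update rule of the simplified steered-dynamics protocol: the new
#' center lies on the segment from the stage-mean atom position `<r>`
#' toward the destination `r*`, advancing by `1/(N - i)` of the remaining
#' gap,
#' `r0^(i+1) = <r>^(i) - (<r>^(i) - r*) / (N - i)`.
#' At `i = N - 1` the center lands on `r*` exactly (bitwise).
#'
#' @param mean_pos stage-mean position `<r>^(i)`; length-3 vector or
#'   M x 3 matrix.
#' @param destination destination `r*`, same shape as `mean_pos`.
#' @param i stage index, `1 <= i <= N - 1`.
#' @param n_stages total number of stages N (>= 2).
#' @return center for stage `i + 1`, same shape as the input.
#' @examples
#' next_center(c(0, 0, 0), c(2, 0, 0), i = 1, n_stages = 21)  # (0.1, 0, 0)
#' @export
next_center <- function(mean_pos, destination, i, n_stages) {
  if (n_stages < 2) stop("next_center: need n_stages >= 2", call. = FALSE)
  if (i < 1 || i > n_stages - 1) {
    stop(sprintf("next_center: stage index %d outside 1..%d", i, n_stages - 1),
         call. = FALSE)
  }
  if (n_stages - i == 1) return(destination)     # exact landing
  mean_pos - (mean_pos - destination) / (n_stages - i)
}

#' Switching-work increment at a center jump
#'
#' When restraint centers jump from `old_centers` to `new_centers` while
#' the restrained atoms sit at `coords`, the work done on the system by
#' the external potential is the instantaneous energy change
#' `sum_atoms [ U(r; r0_new) - U(r; r0_old) ]`.
#' Summed over all jumps of a slow schedule this stepwise switching work
#' converges to the free-energy change of the steered transformation.
#'
#' @param coords M x 3 positions at the moment of the jump.
#' @param old_centers,new_centers M x 3 center matrices.
#' @param k force constant, scalar or length-M vector, kcal/(mol A^2).
#' @return work increment in kcal/mol.
#' @export
stage_work_increment <- function(coords, old_centers, new_centers, k) {
  coords <- as.matrix(coords)
  old_centers <- as.matrix(old_centers)
  new_centers <- as.matrix(new_centers)
  if (!all(dim(coords) == dim(old_centers)) ||
      !all(dim(coords) == dim(new_centers))) {
    stop("stage_work_increment: mismatched atom sets", call. = FALSE)
  }
  u_new <- 0.5 * k * rowSums((coords - new_centers)^2)
  u_old <- 0.5 * k * rowSums((coords - old_centers)^2)
  sum(u_new - u_old)
}

#' Steering schedule
#'
#' Bookkeeping for the simplified steered-dynamics protocol: a set of
#' moved atoms pulled by stiff harmonic restraints whose centers are
#' stepped toward per-atom destinations over `n_stages` stages, while
#' core atoms are held by weaker restraints at their initial positions.
#' Defaults follow the published protocol: N = 21 stages, k = 500
#' kcal/(mol A^2) on the pulled atoms and k = 80 kcal/(mol A^2) on the
#' retained core.
#'
#' @param moved character vector of moved-atom labels.
#' @param destinations M x 3 matrix of destination coordinates `r*`
#'   (rows follow `moved`).
#' @param n_stages number of stages N (>= 2, default 21).
#' @param k_pull restraint constant on moved atoms (default 500).
#' @param k_core restraint constant on core atoms (default 80).
#' @param core character vector of core-atom labels (may be empty).
#' @param stage_length integrator steps per stage.
#' @param avg_window fraction of each stage, at the stage end, over which
#'   the mean position `<r>` is taken (default 0.5; the first half of a
#'   stage is treated as post-jump relaxation and discarded).
#' @return object of class `steering_schedule`.
#' @export
steering_schedule <- function(moved, destinations, n_stages = 21,
                              k_pull = 500, k_core = 80,
                              core = character(0), stage_length,
                              avg_window = 0.5) {
  destinations <- as.matrix(destinations)
  stopifnot(nrow(destinations) == length(moved), ncol(destinations) == 3)
  if (n_stages < 2) stop("steering_schedule: need n_stages >= 2", call. = FALSE)
  if (k_pull <= 0 || k_core <= 0) stop("steering_schedule: force constants must be > 0",
                                       call. = FALSE)
  if (avg_window <= 0 || avg_window > 1) stop("steering_schedule: avg_window in (0, 1]",
                                              call. = FALSE)
  if (stage_length < 1) stop("steering_schedule: stage_length must be >= 1",
                             call. = FALSE)
  structure(list(moved = moved, destinations = destinations,
                 n_stages = as.integer(n_stages), k_pull = k_pull,
                 k_core = k_core, core = core,
                 stage_length = as.integer(stage_length),
                 avg_window = avg_window),
            class = "steering_schedule")
}

#' Run a steering schedule on a dynamics backend
#'
#' Executes the N-stage protocol: in each stage the backend is advanced
#' `stage_length` steps under the system potential plus the current
#' restraints (pulled atoms at the stage centers with `k_pull`, core
#' atoms at their initial coordinates with `k_core`); the stage-mean
#' positions of the moved atoms are taken over the trailing
#' `avg_window` fraction of the stage; centers are then updated with
#' [next_center()] and the switching work of the jump (evaluated at the
#' instantaneous coordinates) is accumulated.  Stage-1 centers are the
#' moved atoms' starting coordinates; stage-N centers equal the
#' destinations exactly.
#'
#' The backend contract is three callables:
#' `initialize(seed)`, `step(restraints)` advancing one timestep under
#' the given list of [harmonic_restraint()]s, and `coordinates()`
#' returning the current positions as a matrix with atom labels as row
#' names.  [make_toy_backend()] implements it.
#'
#' @param backend a backend object (list of callables, see Details).
#' @param schedule a `steering_schedule`.
#' @param seed integer seed passed to `backend$initialize`.
#' @return object of class `steering_run`: `work` (total switching work,
#'   kcal/mol), `work_increments` (length N-1), `centers` and `means`
#'   (N x M x 3 arrays), `final_coords`, `trace` (long data frame:
#'   stage, atom, center/mean coordinates, work increment), `schedule`.
#' @export
run_steering <- function(backend, schedule, seed = 1) {
  stopifnot(inherits(schedule, "steering_schedule"))
  if (!is.null(backend$initialize)) backend$initialize(seed)
  xyz <- backend$coordinates()
  moved_idx <- match(schedule$moved, rownames(xyz))
  if (anyNA(moved_idx)) {
    stop("run_steering: backend does not know atom(s): ",
         paste(schedule$moved[is.na(moved_idx)], collapse = ", "),
         call. = FALSE)
  }
  core_idx <- match(schedule$core, rownames(xyz))
  if (anyNA(core_idx)) {
    stop("run_steering: backend does not know core atom(s): ",
         paste(schedule$core[is.na(core_idx)], collapse = ", "),
         call. = FALSE)
  }
  n <- schedule$n_stages
  m <- length(schedule$moved)
  len <- schedule$stage_length
  win <- max(1L, as.integer(ceiling(schedule$avg_window * len)))
  centers <- xyz[moved_idx, , drop = FALSE]      # r0^(1) = start positions
  core_centers <- xyz[core_idx, , drop = FALSE]  # fixed throughout
  core_restraints <- make_restraints(schedule$core, core_centers,
                                     schedule$k_core)
  centers_trace <- array(NA_real_, c(n, m, 3))
  means_trace <- array(NA_real_, c(n, m, 3))
  work_inc <- numeric(n - 1)
  for (i in seq_len(n)) {
    restraints <- c(make_restraints(schedule$moved, centers, schedule$k_pull),
                    core_restraints)
    acc <- matrix(0, m, 3)
    res <- withCallingHandlers(
      {
        for (s in seq_len(len)) {
          backend$step(restraints)
          if (s > len - win) {
            acc <- acc + backend$coordinates()[moved_idx, , drop = FALSE]
          }
        }
      },
      error = function(e) {
        stop(sprintf("run_steering: backend failure in stage %d: %s",
                     i, conditionMessage(e)), call. = FALSE)
      })
    means <- acc / win
    centers_trace[i, , ] <- centers
    means_trace[i, , ] <- means
    if (i < n) {
      new_centers <- next_center(means, schedule$destinations, i, n)
      xyz_now <- backend$coordinates()[moved_idx, , drop = FALSE]
      work_inc[i] <- stage_work_increment(xyz_now, centers, new_centers,
                                          schedule$k_pull)
      centers <- new_centers
    }
  }
  trace <- data.frame(
    stage = rep(seq_len(n), each = m),
    atom = rep(schedule$moved, n),
    center_x = as.numeric(aperm(centers_trace, c(2, 1, 3))[, , 1]),
    center_y = as.numeric(aperm(centers_trace, c(2, 1, 3))[, , 2]),
    center_z = as.numeric(aperm(centers_trace, c(2, 1, 3))[, , 3]),
    mean_x = as.numeric(aperm(means_trace, c(2, 1, 3))[, , 1]),
    mean_y = as.numeric(aperm(means_trace, c(2, 1, 3))[, , 2]),
    mean_z = as.numeric(aperm(means_trace, c(2, 1, 3))[, , 3]),
    work_increment = rep(c(work_inc, 0), each = m),
    stringsAsFactors = FALSE)
  structure(list(work = sum(work_inc), work_increments = work_inc,
                 centers = centers_trace, means = means_trace,
                 final_coords = backend$coordinates(),
                 trace = trace, schedule = schedule),
            class = "steering_run")
}

make_restraints <- function(labels, centers, k) {
  if (length(labels) == 0) return(list())
  lapply(seq_along(labels), function(j) {
    harmonic_restraint(labels[j], centers[j, ], k)
  })
}

#' @export
print.steering_run <- function(x, ...) {
  cat(sprintf("steering_run: %d stages, %d moved atom(s), total work %.3f kcal/mol\n",
              x$schedule$n_stages, length(x$schedule$moved), x$work))
  invisible(x)
}
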