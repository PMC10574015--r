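#' Ideal alpha-helix specification
#'
#' @param chain chain id.
#' @param first author residue number of the first residue.
#' @param length number of residues (>= 1).
#' @param origin length-3 axis origin (Angstrom).
#' @param direction length-3 axis direction (normalised internally).
#' @param phase initial azimuth in degrees.
#' @param rise rise per residue along the axis (default 1.5 A).
#' @param twist twist per residue in degrees (default 100, ~3.6
#'   residues/turn).
#' @param radius Calpha helix radius (default 2.3 A).
#' @return object of class `helix_spec`.
#' @export
helix_spec <- function(chain, first, length, origin = c(0, 0, 0),
                       direction = c(0, 0, 1), phase = 0,
                       rise = 1.5, twist = 100, radius = 2.3) {
  stopifnot(length >= 1, base::length(origin) == 3,
            base::length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("helix_spec: zero direction vector", call. = FALSE)
  structure(list(chain = as.character(chain), first = as.integer(first),
                 length = as.integer(length), origin = as.numeric(origin),
                 direction = as.numeric(direction) / nrm, phase = phase,
                 rise = rise, twist = twist, radius = radius),
            class = "helix_spec")
}

helix_frame <- function(direction) {
  a <- if (abs(direction[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(direction[2] * a[3] - direction[3] * a[2],
         direction[3] * a[1] - direction[1] * a[3],
         direction[1] * a[2] - direction[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(direction[2] * u[3] - direction[3] * u[2],
         direction[3] * u[1] - direction[1] * u[3],
         direction[1] * u[2] - direction[2] * u[1])
  list(u = u, v = v)
}

#' Build an ideal alpha helix of Calpha atoms
#'
#' Residue j (0-based) sits at
#' `origin + direction * j * rise + radius * (cos(phase + j twist) u +
#' sin(phase + j twist) v)` with `(u, v)` an orthonormal frame normal to
#' the axis.  Consecutive Calpha-Calpha distances are constant,
#' `sqrt(rise^2 + 4 r^2 sin^2(twist/2))` (~3.88 A at the defaults).
#'
#' @param spec a [helix_spec()].
#' @return list with `coords` (length x 3 matrix) and `labels` (data
#'   frame chain, resno, elety).
#' @export
build_helix <- function(spec) {
  stopifnot(inherits(spec, "helix_spec"))
  j <- seq_len(spec$length) - 1
  fr <- helix_frame(spec$direction)
  ang <- (spec$phase + j * spec$twist) * pi / 180
  axial <- outer(j * spec$rise, spec$direction)
  radial <- spec$radius * (outer(cos(ang), fr$u) + outer(sin(ang), fr$v))
  xyz <- sweep(axial + radial, 2, spec$origin, "+")
  list(coords = xyz,
       labels = data.frame(chain = spec$chain, resno = spec$first + j,
                           elety = "CA", stringsAsFactors = FALSE))
}

## 7TM spans with CB1-like author numbering; covers every residue the
## package's default selections and collective variables address.
bundle_spans <- function() {
  data.frame(
    name = paste0("TM", 1:7),
    first = c(100L, 145L, 186L, 234L, 270L, 339L, 374L),
    last = c(134L, 180L, 224L, 258L, 298L, 367L, 399L),
    stringsAsFactors = FALSE)
}

#' Synthetic 7-helix bundle with CB1-like residue numbering
#'
#' Seven ideal alpha helices (alternating up/down) arranged on a ring,
#' one chain, numbered so that the package's default basement/indicator
#' selections and collective-variable atoms (e.g. residues 102, 113,
#' 125, 179, 381) all resolve.  Deterministic for a given seed (the seed
#' sets the helix azimuthal phases).
#'
#' @param seed integer seed.
#' @param chain chain id (default `"A"`).
#' @param ring_radius ring radius of the helix axes (default 12 A).
#' @param backbone if `TRUE`, add idealised N and C backbone atoms per
#'   residue (for I/O round-trip testing; metrics only use Calpha).
#' @return a `structure_model`.
#' @examples
#' b <- build_cb1_like_bundle(seed = 1)
#' nrow(resolve_selection(b, default_selections()$basement))  # 27
#' @export
build_cb1_like_bundle <- function(seed = 1, chain = "A", ring_radius = 12,
                                  backbone = FALSE) {
  spans <- bundle_spans()
  set.seed(seed)
  phases <- stats::runif(nrow(spans), 0, 360)
  atoms <- NULL
  for (i in seq_len(nrow(spans))) {
    len <- spans$last[i] - spans$first[i] + 1L
    theta <- 2 * pi * (i - 1) / nrow(spans)
    up <- i %% 2 == 1
    origin <- c(ring_radius * cos(theta), ring_radius * sin(theta),
                if (up) 0 else (len - 1) * 1.5)
    hs <- helix_spec(chain, spans$first[i], len, origin = origin,
                     direction = c(0, 0, if (up) 1 else -1),
                     phase = phases[i])
    h <- build_helix(hs)
    df <- data.frame(chain = h$labels$chain, resno = h$labels$resno,
                     insert = NA_character_, resid = "ALA",
                     elety = "CA", alt = NA_character_, o = 1,
                     x = h$coords[, 1], y = h$coords[, 2], z = h$coords[, 3],
                     stringsAsFactors = FALSE)
    if (backbone) {
      dirv <- hs$direction
      n_at <- df
      n_at$elety <- "N"
      n_at[, c("x", "y", "z")] <- sweep(h$coords, 2, -0.6 * dirv, "+")
      c_at <- df
      c_at$elety <- "C"
      c_at[, c("x", "y", "z")] <- sweep(h$coords, 2, 0.55 * dirv, "+")
      df <- rbind(n_at, df, c_at)
      df <- df[order(df$resno, match(df$elety, c("N", "CA", "C"))), ]
    }
    atoms <- rbind(atoms, df)
  }
  rownames(atoms) <- NULL
  new_structure_model(atoms, title = "synthetic 7TM helix bundle",
                      source = sprintf("synthetic(seed=%d)", seed))
}

rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  cross <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
                  byrow = TRUE)
  diag(3) * c_ + s_ * cross + (1 - c_) * (a %o% a)
}

#' Rigid-displacement conformational pair with exact ground truth
#'
#' Returns the input structure unchanged as `reference` and a copy in
#' which the atoms of `moved` are rigidly displaced (optional rotation
#' about an axis, then translation), emulating a helix shift of known
#' magnitude.  The moved selection must not overlap the basement
#' selection, so a basement fit between the pair is exact and the
#' activation metrics have closed-form ground truth.
#'
#' @param bundle a `structure_model`.
#' @param moved `residue_selection` of atoms to displace.
#' @param translation length-3 translation (Angstrom).
#' @param rotation optional list with `axis` (length 3), `angle`
#'   (degrees) and `origin` (length-3 pivot point).
#' @param basement basement selection the motion must avoid (default
#'   [default_selections()]).
#' @return list: `reference`, `displaced` (both `structure_model`),
#'   `ground_truth` (data frame chain, resno, elety, displacement).
#' @export
make_conformational_pair <- function(bundle, moved, translation = c(0, 0, 0),
                                     rotation = NULL, basement = NULL) {
  if (is.null(basement)) {
    basement <- default_selections(chain = bundle$atom$chain[1])$basement
  }
  if (selections_overlap(moved, basement)) {
    stop("make_conformational_pair: moved selection overlaps the basement; ",
         "refusing (it would break the exact-fit ground truth)",
         call. = FALSE)
  }
  idx <- resolve_indices(bundle$atom, moved)
  old <- as.matrix(bundle$atom[idx, c("x", "y", "z")])
  new <- old
  if (!is.null(rotation)) {
    r <- rotation_about_axis(rotation$axis, rotation$angle)
    piv <- matrix(rotation$origin, nrow(new), 3, byrow = TRUE)
    new <- (new - piv) %*% t(r) + piv
  }
  new <- sweep(new, 2, translation, "+")
  displaced <- bundle
  displaced$atom[idx, c("x", "y", "z")] <- new
  gt <- data.frame(chain = bundle$atom$chain[idx],
                   resno = bundle$atom$resno[idx],
                   elety = bundle$atom$elety[idx],
                   displacement = sqrt(rowSums((new - old)^2)),
                   stringsAsFactors = FALSE)
  list(reference = bundle, displaced = displaced, ground_truth = gt)
}

#' Gaussian-jitter trajectory with prescribed per-residue amplitude
#'
#' Each frame is the reference Calpha structure plus isotropic Gaussian
#' noise: per-coordinate standard deviation `sigma_i` for atom i.  The
#' expected RMSF of atom i is `sqrt(3) * sigma_i`, which makes the
#' generator an exact oracle for the RMSF machinery.
#'
#' @param reference a `structure_model` (its CA atoms are used).
#' @param sigma per-coordinate standard deviation, Angstrom; scalar or
#'   vector over the CA atoms.
#' @param n_frames number of frames T (>= 2).
#' @param seed integer seed.
#' @return a `ca_trajectory`.
#' @export
make_jitter_trajectory <- function(reference, sigma, n_frames, seed = 1) {
  stopifnot(n_frames >= 2, all(sigma >= 0))
  ca <- reference$atom[reference$atom$elety == "CA", , drop = FALSE]
  m <- nrow(ca)
  sigma <- rep_len(sigma, m)
  ref <- as.matrix(ca[, c("x", "y", "z")])
  set.seed(seed)
  co <- array(NA_real_, c(n_frames, m, 3))
  for (t_ in seq_len(n_frames)) {
    co[t_, , ] <- ref + matrix(stats::rnorm(3 * m, sd = sigma), m, 3)
  }
  labels <- data.frame(chain = ca$chain, resno = ca$resno, elety = "CA",
                       stringsAsFactors = FALSE)
  ca_trajectory(co, labels)
}
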