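#' Calpha trajectory container
#'
#' @param coords numeric array T x M x 3 (frames, atoms, xyz) in Angstrom.
#' @param labels data frame with columns chain, resno, elety (and
#'   optionally insert) describing the M atoms, identical for all frames.
#' @param dt_ps frame spacing in picoseconds (metadata, optional).
#' @return object of class `ca_trajectory`.
#' @export
ca_trajectory <- function(coords, labels, dt_ps = NA_real_) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[1] < 2) stop("ca_trajectory: need at least 2 frames",
                               call. = FALSE)
  if (dim(coords)[2] != nrow(labels)) {
    stop("ca_trajectory: label count does not match atom count", call. = FALSE)
  }
  if (is.null(labels$insert)) labels$insert <- NA_character_
  structure(list(coords = coords, labels = labels, dt_ps = dt_ps),
            class = "ca_trajectory")
}

#' @export
print.ca_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("ca_trajectory: %d frames x %d atoms (dt = %s ps)\n",
              d[1], d[2], format(x$dt_ps)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `ca_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Read a trajectory from a multi-MODEL PDB file
#'
#' Each MODEL becomes one frame; the atom set of the first model defines
#' the labels and all models must match it.
#'
#' @param path multi-MODEL PDB file.
#' @param atoms atom names to keep (default `"CA"`).
#' @param dt_ps frame spacing metadata.
#' @return a `ca_trajectory`.
#' @export
read_trajectory_pdb <- function(path, atoms = "CA", dt_ps = NA_real_) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("read_trajectory_pdb: cannot parse '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  keep <- pdb$atom$type == "ATOM" & pdb$atom$elety %in% atoms
  if (sum(keep) == 0) stop("read_trajectory_pdb: no matching atoms",
                           call. = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  t_ <- nrow(xyz)
  idx <- which(keep)
  m <- length(idx)
  co <- array(NA_real_, c(t_, m, 3))
  for (k in 1:3) co[, , k] <- xyz[, 3 * (idx - 1) + k, drop = FALSE]
  labels <- data.frame(chain = pdb$atom$chain[idx], resno = pdb$atom$resno[idx],
                       insert = pdb$atom$insert[idx],
                       elety = pdb$atom$elety[idx], stringsAsFactors = FALSE)
  ca_trajectory(co, labels, dt_ps = dt_ps)
}

#' Write a trajectory as a multi-MODEL PDB file
#' @param traj a `ca_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  d <- dim(traj$coords)
  xyz <- matrix(NA_real_, d[1], 3 * d[2])
  for (k in 1:3) xyz[, 3 * (seq_len(d[2]) - 1) + k] <- traj$coords[, , k]
  n <- d[2]
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = xyz, type = rep("ATOM", n),
    resno = traj$labels$resno, resid = rep("ALA", n), eleno = seq_len(n),
    elety = traj$labels$elety, chain = traj$labels$chain,
    insert = rep("", n), alt = rep("", n), o = rep(1, n), b = rep(0, n)))
  invisible(path)
}

#' Read/write a plain-text per-frame coordinate table
#'
#' Whitespace-delimited columns `frame chain resno x y z` (header line
#' required), Calpha atoms implied.  Frames must appear in order with a
#' consistent atom set.
#'
#' @param path table file.
#' @param dt_ps frame spacing metadata.
#' @return a `ca_trajectory`.
#' @export
read_trajectory_table <- function(path, dt_ps = NA_real_) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("frame", "chain", "resno", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("read_trajectory_table: need columns ", paste(need, collapse = " "),
         call. = FALSE)
  }
  frames <- unique(tab$frame)
  f1 <- tab[tab$frame == frames[1], , drop = FALSE]
  m <- nrow(f1)
  t_ <- length(frames)
  co <- array(NA_real_, c(t_, m, 3))
  for (i in seq_along(frames)) {
    fi <- tab[tab$frame == frames[i], , drop = FALSE]
    if (nrow(fi) != m) stop("read_trajectory_table: frame ", frames[i],
                            " has a different atom count", call. = FALSE)
    co[i, , ] <- as.matrix(fi[, c("x", "y", "z")])
  }
  labels <- data.frame(chain = as.character(f1$chain), resno = f1$resno,
                       elety = "CA", stringsAsFactors = FALSE)
  ca_trajectory(co, labels, dt_ps = dt_ps)
}

#' @rdname read_trajectory_table
#' @param traj a `ca_trajectory` to write.
#' @export
write_trajectory_table <- function(traj, path) {
  d <- dim(traj$coords)
  tab <- data.frame(
    frame = rep(seq_len(d[1]), each = d[2]),
    chain = rep(traj$labels$chain, d[1]),
    resno = rep(traj$labels$resno, d[1]),
    x = as.numeric(t(traj$coords[, , 1])),
    y = as.numeric(t(traj$coords[, , 2])),
    z = as.numeric(t(traj$coords[, , 3])))
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove global rigid-body motion from a trajectory
#'
#' Two-pass alignment on a fit selection: frames are first superposed on
#' the initial frame, the time-mean structure of that pass is computed,
#' and the original frames are then superposed on the mean.  Fitting uses
#' only the selection's atoms; the transform is applied to all atoms.
#'
#' @param traj a `ca_trajectory`.
#' @param sel `residue_selection` defining the fit atoms (default: all
#'   atoms in the trajectory).
#' @return aligned `ca_trajectory`.
#' @export
align_trajectory <- function(traj, sel = NULL) {
  co <- traj$coords
  d <- dim(co)
  idx <- if (is.null(sel)) seq_len(d[2]) else {
    i <- resolve_indices(traj$labels, sel)
    if (length(i) < 3) stop("align_trajectory: fit selection resolves to fewer than 3 atoms",
                            call. = FALSE)
    as.integer(i)
  }
  pass <- function(co, ref_sub) {
    out <- co
    for (t_ in seq_len(d[1])) {
      fit <- kabsch_fit(co[t_, idx, , drop = TRUE], ref_sub)
      out[t_, , ] <- apply_transform(co[t_, , , drop = TRUE], fit)
    }
    out
  }
  a1 <- pass(co, co[1, idx, , drop = TRUE])
  mean_sub <- apply(a1[, idx, , drop = FALSE], c(2, 3), mean)
  traj$coords <- pass(co, mean_sub)
  traj
}

#' Per-atom root-mean-square fluctuation
#'
#' For each atom, the RMS deviation of its position from its time mean
#' over the trajectory: `rmsf_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`.
#' Align the trajectory first ([align_trajectory()]) so rigid-body drift
#' does not inflate the profile.
#'
#' @param traj an (aligned) `ca_trajectory` with at least 2 frames.
#' @return object of class `rmsf_profile`: data frame (chain, resno,
#'   elety, rmsf) with attribute `reference = "mean-structure"`.
#' @export
rmsf_profile <- function(traj) {
  co <- traj$coords
  if (dim(co)[1] < 2) stop("rmsf_profile: need at least 2 frames",
                           call. = FALSE)
  mu <- apply(co, c(2, 3), mean)
  dev2 <- (co - rep(mu, each = dim(co)[1]))^2
  msf <- apply(dev2, 2, mean) * 3   # mean over frames & xyz, times 3 dims
  out <- data.frame(chain = traj$labels$chain, resno = traj$labels$resno,
                    elety = traj$labels$elety, rmsf = sqrt(msf),
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- "mean-structure"
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Write an RMSF profile as TSV
#' @param profile an `rmsf_profile`.
#' @param path output file.
#' @export
write_rmsf_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[, c("resno", "rmsf")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("resid", "rmsf_A"))
  invisible(path)
}

#' Detect the stiff core from an RMSF profile
#'
#' Residues whose RMSF lies strictly below the given quantile of the
#' profile are merged into runs of consecutive residue numbers (per
#' chain); runs of at least `min_run` residues are returned as a
#' selection.  This mirrors the way the low-mobility "basement" segments
#' are picked out of a fluctuation profile.
#'
#' @param profile an `rmsf_profile`.
#' @param quantile quantile cut in (0, 1) (default 0.25).
#' @param min_run minimum run length in residues (default 4).
#' @return a `residue_selection` over the detected ranges (possibly with
#'   zero ranges).
#' @export
detect_stiff_core <- function(profile, quantile = 0.25, min_run = 4) {
  stopifnot(quantile > 0, quantile < 1)
  if (nrow(profile) == 0) stop("detect_stiff_core: empty profile",
                               call. = FALSE)
  thr <- stats::quantile(profile$rmsf, quantile, names = FALSE)
  low <- profile[profile$rmsf < thr, , drop = FALSE]
  if (nrow(low) == 0) {
    return(structure(list(ranges = data.frame(chain = character(0),
                                              start = integer(0),
                                              end = integer(0),
                                              stringsAsFactors = FALSE),
                          atoms = "CA"), class = "residue_selection"))
  }
  low <- low[order(low$chain, low$resno), , drop = FALSE]
  chains <- character(0); starts <- integer(0); ends <- integer(0)
  run_chain <- low$chain[1]; run_start <- low$resno[1]; prev <- low$resno[1]
  flush <- function() {
    if (prev - run_start + 1 >= min_run) {
      chains <<- c(chains, run_chain)
      starts <<- c(starts, run_start)
      ends <<- c(ends, prev)
    }
  }
  for (i in seq_len(nrow(low))[-1]) {
    if (low$chain[i] == run_chain && low$resno[i] == prev + 1) {
      prev <- low$resno[i]
    } else {
      flush()
      run_chain <- low$chain[i]; run_start <- low$resno[i]; prev <- low$resno[i]
    }
  }
  flush()
  if (length(starts) == 0) {
    return(structure(list(ranges = data.frame(chain = character(0),
                                              start = integer(0),
                                              end = integer(0),
                                              stringsAsFactors = FALSE),
                          atoms = "CA"), class = "residue_selection"))
  }
  residue_selection(chains, starts, ends, atoms = "CA")
}
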