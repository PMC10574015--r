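#' Default basement and indicator selections (CB1 numbering)
#'
#' The "basement" is the low-mobility core of the transmembrane domain —
#' residues 195-199 (TM3), 243-249 (TM4) and 275-289 (TM5) — used as the
#' superposition frame.  The activation indicator is the pooled TM6/TM7
#' region, residues 351-361 and 381-391, whose displacement relative to
#' the basement distinguishes active from inactive conformations.
#'
#' @param chain chain identifier carrying the receptor (default `"A"`).
#' @param tm5_end last TM5 basement residue; 289 by default, 283 selects
#'   the shorter stable-region variant.
#' @return list with components `basement` and `indicator`, both
#'   `residue_selection` objects over Calpha atoms.
#' @examples
#' s <- default_selections()
#' selection_size(s$basement)   # 27
#' selection_size(s$indicator)  # 22
#' @export
default_selections <- function(chain = "A", tm5_end = 289) {
  list(
    basement = residue_selection(chain, c(195, 243, 275), c(199, 249, tm5_end)),
    indicator = residue_selection(chain, c(351, 381), c(361, 391))
  )
}

#' Score the activation state of a conformation
#'
#' Superposes the query on each reference over the basement selection
#' (least-squares Calpha fit), then measures the pooled indicator-region
#' RMSD and maximum atom distance in that frame.  A query close to the
#' active reference and far from the inactive one (by more than `margin`)
#' is labelled `active-like`, the symmetric case `inactive-like`, anything
#' in between `indeterminate`.  The query is fitted independently to each
#' reference; per-segment indicator RMSDs are reported alongside the
#' pooled value.
#'
#' @param query,active,inactive `structure_model` objects sharing author
#'   numbering.
#' @param basement,indicator `residue_selection` objects; defaults from
#'   [default_selections()] using the query's first chain.
#' @param margin indeterminate margin in Angstrom (default 0.5): the
#'   nearer reference must win by more than this to assign a label.
#' @return object of class `activation_report` with fields
#'   `rmsd_active`, `max_active`, `rmsd_inactive`, `max_inactive`,
#'   `basement_rmsd_active`, `basement_rmsd_inactive`, `n_basement`,
#'   `n_indicator`, `segment_rmsd_active`, `segment_rmsd_inactive`,
#'   `label`, `margin`.
#' @export
activation_score <- function(query, active, inactive,
                             basement = NULL, indicator = NULL,
                             margin = 0.5) {
  if (is.null(basement) || is.null(indicator)) {
    defs <- default_selections(chain = query$atom$chain[1])
    if (is.null(basement)) basement <- defs$basement
    if (is.null(indicator)) indicator <- defs$indicator
  }
  sa <- score_against(query, active, basement, indicator)
  si <- score_against(query, inactive, basement, indicator)

  degenerate <- FALSE
  ref_pair <- tryCatch(score_against(active, inactive, basement, indicator),
                       error = function(e) NULL)
  if (!is.null(ref_pair) && ref_pair$rmsd < 1e-6) {
    warning("activation_score: active and inactive references are indistinguishable on the indicator region",
            call. = FALSE)
    degenerate <- TRUE
  }

  label <- if (degenerate) {
    "indeterminate"
  } else if (sa$rmsd + margin < si$rmsd) {
    "active-like"
  } else if (si$rmsd + margin < sa$rmsd) {
    "inactive-like"
  } else {
    "indeterminate"
  }

  structure(list(
    rmsd_active = sa$rmsd, max_active = sa$max,
    rmsd_inactive = si$rmsd, max_inactive = si$max,
    basement_rmsd_active = sa$fit_rmsd,
    basement_rmsd_inactive = si$fit_rmsd,
    n_basement = sa$n_basement, n_indicator = sa$n_indicator,
    segment_rmsd_active = sa$segments,
    segment_rmsd_inactive = si$segments,
    label = label, margin = margin
  ), class = "activation_report")
}

score_against <- function(query, ref, basement, indicator) {
  pb <- pair_structures(query, ref, basement)
  fit <- kabsch_fit(pb$coords_a, pb$coords_b)
  pi_ <- pair_structures(query, ref, indicator)
  qi <- apply_transform(pi_$coords_a, fit)
  segs <- segment_rmsds(qi, pi_$coords_b, pi_$labels, indicator)
  list(rmsd = rmsd(qi, pi_$coords_b),
       max = max_pair_distance(qi, pi_$coords_b),
       fit_rmsd = fit$rmsd,
       n_basement = nrow(pb$coords_a),
       n_indicator = nrow(pi_$coords_a),
       segments = segs)
}

segment_rmsds <- function(a, b, labels, sel) {
  r <- sel$ranges
  out <- numeric(nrow(r))
  names(out) <- sprintf("%s:%d-%d", r$chain, r$start, r$end)
  for (i in seq_len(nrow(r))) {
    in_seg <- labels$chain == r$chain[i] &
      labels$resno >= r$start[i] & labels$resno <= r$end[i]
    out[i] <- if (any(in_seg)) rmsd(a[in_seg, , drop = FALSE],
                                    b[in_seg, , drop = FALSE]) else NA_real_
  }
  out
}

#' @export
print.activation_report <- function(x, ...) {
  cat("activation_report\n")
  cat(sprintf("  vs active   : rmsd %.2f A, max %.2f A (basement fit %.2f A)\n",
              x$rmsd_active, x$max_active, x$basement_rmsd_active))
  cat(sprintf("  vs inactive : rmsd %.2f A, max %.2f A (basement fit %.2f A)\n",
              x$rmsd_inactive, x$max_inactive, x$basement_rmsd_inactive))
  cat(sprintf("  atoms: %d basement, %d indicator; margin %.2f A\n",
              x$n_basement, x$n_indicator, x$margin))
  cat("  state:", x$label, "\n")
  invisible(x)
}

#' Activation report as a one-row data frame
#' @param x an `activation_report`.
#' @param ... unused.
#' @return one-row data frame mirroring the report's scalar fields.
#' @export
as.data.frame.activation_report <- function(x, ...) {
  data.frame(rmsd_active = x$rmsd_active, max_active = x$max_active,
             rmsd_inactive = x$rmsd_inactive, max_inactive = x$max_inactive,
             label = x$label, stringsAsFactors = FALSE)
}

#' Per-residue displacement after a basement fit
#'
#' Superposes `query` on `reference` over the basement selection, then
#' reports the Euclidean displacement of each paired atom in the probe
#' selection, ordered by residue number — the readout used to quantify
#' individual helix shifts (e.g. a TM2 displacement growing from 1.5 to
#' 3.8 Angstrom along the helix).
#'
#' @param query,reference `structure_model` objects.
#' @param basement superposition `residue_selection`.
#' @param probe `residue_selection` whose displacements are reported.
#' @return data frame (chain, resno, elety, displacement) sorted by
#'   residue number.
#' @export
helix_displacement_profile <- function(query, reference, basement, probe) {
  pb <- pair_structures(query, reference, basement)
  fit <- kabsch_fit(pb$coords_a, pb$coords_b)
  pp <- pair_structures(query, reference, probe)
  qp <- apply_transform(pp$coords_a, fit)
  d <- sqrt(rowSums((qp - pp$coords_b)^2))
  out <- data.frame(chain = pp$labels$chain, resno = pp$labels$resno,
                    elety = pp$labels$elety, displacement = d,
                    stringsAsFactors = FALSE)
  out[order(out$chain, out$resno), , drop = FALSE]
}
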