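#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (first MODEL of a multi-model file), resolves
#' alternate locations by the requested policy, and separates HETATM
#' (ligand/solvent) records from the protein atom list.  Author residue
#' numbering is preserved throughout — all selections in this package
#' address residues by author numbering.
#'
#' @param path path to a PDB file.
#' @param altloc alternate-location policy: `"highest-occupancy"` (ties
#'   broken by lexicographically first altloc id) or `"first"` (file order).
#' @return A `structure_model`: list with `atom` (data frame of protein
#'   atoms: chain, resno, insert, resid, elety, alt, o, x, y, z), `het`
#'   (same layout, HETATM records), `title` and `source`.
#' @examples
#' b <- build_cb1_like_bundle(seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_structure(b, f)
#' read_structure(f)
#' @export
read_structure <- function(path, altloc = c("highest-occupancy", "first")) {
  altloc <- match.arg(altloc)
  if (!file.exists(path)) stop("read_structure: no such file: ", path,
                               call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("read_structure: cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad) > 0) {
    stop(sprintf(
      "read_structure: non-numeric coordinates at atom serial %s (line with eleno %s) in '%s'",
      at$eleno[bad[1]], at$eleno[bad[1]], path), call. = FALSE)
  }
  at <- resolve_altlocs(at, altloc)
  keep <- c("chain", "resno", "insert", "resid", "elety", "alt", "o",
            "x", "y", "z")
  protein <- at[at$type == "ATOM", keep, drop = FALSE]
  het <- at[at$type == "HETATM", keep, drop = FALSE]
  rownames(protein) <- NULL
  rownames(het) <- NULL
  if (nrow(protein) == 0) {
    stop("read_structure: no protein (ATOM) records in '", path, "'",
         call. = FALSE)
  }
  new_structure_model(protein, het = het, source = path)
}

resolve_altlocs <- function(at, policy) {
  alt <- as.character(at$alt)
  key <- paste(at$chain, at$resno,
               ifelse(is.na(at$insert), "", at$insert), at$elety, at$type)
  dup_key <- unique(key[duplicated(key)])
  if (length(dup_key) == 0) return(at)
  drop <- logical(nrow(at))
  for (k in dup_key) {
    rows <- which(key == k)
    keep_row <- if (policy == "first") {
      rows[1]
    } else {
      occ <- at$o[rows]
      occ[is.na(occ)] <- 0
      a <- alt[rows]
      a[is.na(a)] <- ""
      rows[order(-occ, a)][1]
    }
    drop[setdiff(rows, keep_row)] <- TRUE
  }
  at[!drop, , drop = FALSE]
}

new_structure_model <- function(atom, het = NULL, title = "", source = "") {
  stopifnot(is.data.frame(atom))
  need <- c("chain", "resno", "elety", "x", "y", "z")
  if (!all(need %in% names(atom))) {
    stop("structure_model: atom table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(atom$insert)) atom$insert <- NA_character_
  if (is.null(atom$resid)) atom$resid <- "ALA"
  if (is.null(atom$alt)) atom$alt <- NA_character_
  if (is.null(atom$o)) atom$o <- 1
  if (nrow(atom) > 0 &&
      any(!is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z))) {
    stop("structure_model: non-finite coordinates", call. = FALSE)
  }
  structure(list(atom = atom, het = het, title = title, source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d protein atoms, %d het atoms, chains: %s\n",
              nrow(x$atom), if (is.null(x$het)) 0L else nrow(x$het),
              paste(unique(x$atom$chain), collapse = " ")))
  invisible(x)
}

#' Coordinates of a structure as a numeric matrix
#' @param structure a `structure_model`.
#' @return M x 3 matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atom[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param structure a `structure_model`.
#' @param xyz M x 3 matrix matching the atom table.
#' @return modified `structure_model`.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$atom), ncol(xyz) == 3)
  structure$atom$x <- xyz[, 1]
  structure$atom$y <- xyz[, 2]
  structure$atom$z <- xyz[, 3]
  structure
}

#' Write a structure to a PDB file
#'
#' Protein atoms are written as ATOM records (coordinates at the PDB field
#' precision of 0.001 Angstrom); HETATM records, if present, follow.
#'
#' @param structure a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atom
  het <- structure$het
  if (!is.null(het) && nrow(het) > 0) {
    at <- rbind(at, het)
    het_flag <- c(rep(FALSE, nrow(structure$atom)), rep(TRUE, nrow(het)))
  } else {
    het_flag <- rep(FALSE, nrow(at))
  }
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(het_flag, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resid, eleno = seq_len(nrow(at)),
    elety = at$elety, chain = at$chain,
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    o = ifelse(is.na(at$o), 1, at$o), b = rep(0, nrow(at))))
  invisible(path)
}

#' Resolve a residue-range selection into an ordered atom table
#'
#' Atoms are returned in (range order, residue order, atom-name order);
#' residues named by the selection but absent from the structure are
#' reported in the `"missing"` attribute and via a warning — never silently
#' skipped and never interpolated.
#'
#' @param structure a `structure_model`.
#' @param sel a `residue_selection`.
#' @return data frame of atoms (subset of `structure$atom` rows, reordered)
#'   with attribute `missing` (data frame chain/resno).
#' @export
resolve_selection <- function(structure, sel) {
  idx <- resolve_indices(structure$atom, sel)
  missing <- attr(idx, "missing")
  if (nrow(missing) > 0) {
    warning(sprintf("resolve_selection: %d residue(s) absent from structure: %s",
                    nrow(missing),
                    paste(sprintf("(%s,%d)", missing$chain, missing$resno),
                          collapse = " ")), call. = FALSE)
  }
  if (length(idx) < 3) {
    stop(sprintf("resolve_selection: selection resolves to %d atom(s); need >= 3",
                 length(idx)), call. = FALSE)
  }
  out <- structure$atom[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  out
}

atom_keys <- function(atom) {
  paste(atom$chain, atom$resno,
        ifelse(is.na(atom$insert), "", as.character(atom$insert)),
        atom$elety, sep = ":")
}

#' Pair atoms of two structures over a selection
#'
#' Resolves the selection in both structures and keeps only atoms (same
#' chain, author residue number, insertion code and atom name) present in
#' both; atoms found in only one are listed in `dropped`.  Row `i` of
#' `coords_a` and `coords_b` always refers to the same atom label.
#'
#' @param a,b `structure_model` objects sharing a numbering convention.
#' @param sel a `residue_selection`.
#' @return list of class `paired_coordinates`: `labels` (data frame chain,
#'   resno, elety), `coords_a`, `coords_b` (M x 3 matrices), `dropped`
#'   (character vector of unpaired labels).
#' @export
pair_structures <- function(a, b, sel) {
  ra <- resolve_selection(a, sel)
  rb <- resolve_selection(b, sel)
  ka <- atom_keys(ra)
  kb <- atom_keys(rb)
  common <- ka[ka %in% kb]
  dropped <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(common) < 3) {
    stop(sprintf("pair_structures: only %d paired atom(s); need >= 3",
                 length(common)), call. = FALSE)
  }
  ia <- match(common, ka)
  ib <- match(common, kb)
  structure(list(
    labels = data.frame(chain = ra$chain[ia], resno = ra$resno[ia],
                        elety = ra$elety[ia], stringsAsFactors = FALSE),
    coords_a = as.matrix(ra[ia, c("x", "y", "z")]),
    coords_b = as.matrix(rb[ib, c("x", "y", "z")]),
    dropped = dropped
  ), class = "paired_coordinates")
}

#' Look up one atom by label
#' @param structure a `structure_model`.
#' @param label `"chain:resno:atom"` string, e.g. `"A:381:CA"`.
#' @return length-3 numeric coordinate vector.
#' @export
atom_coord <- function(structure, label) {
  p <- strsplit(label, ":", fixed = TRUE)[[1]]
  if (length(p) != 3) stop("atom_coord: label must be 'chain:resno:atom', got '",
                           label, "'", call. = FALSE)
  at <- structure$atom
  j <- which(at$chain == p[1] & at$resno == as.integer(p[2]) & at$elety == p[3])
  if (length(j) == 0) stop("atom_coord: no atom matching '", label, "'",
                           call. = FALSE)
  as.numeric(at[j[1], c("x", "y", "z")])
}
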