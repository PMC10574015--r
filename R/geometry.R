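#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' corresponding rows of `mobile` and `reference`.  The rotation is
#' computed from the SVD of the cross-covariance of the centred sets with
#' the usual determinant correction, so a reflection is never returned.
#'
#' @param mobile,reference M x 3 coordinate matrices, M >= 3, rows
#'   corresponding.
#' @return object of class `rigid_fit`: `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` (Angstrom, after superposition), `n` (atom count).
#'   Apply with [apply_transform()].
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' f <- kabsch_fit(x, x)
#' f$rmsd  # 0
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 ||
      ncol(reference) != 3) {
    stop("kabsch_fit: need two M x 3 matrices with equal M", call. = FALSE)
  }
  m <- nrow(mobile)
  if (m < 3) stop("kabsch_fit: need at least 3 points", call. = FALSE)
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  h <- crossprod(p, q)                # 3x3 cross-covariance
  s <- svd(h)
  if (s$d[1] > 0 && s$d[2] / s$d[1] < 1e-8) {
    warning("kabsch_fit: (near-)collinear point set, rotation about the axis is undetermined",
            call. = FALSE)
  }
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cr - rot %*% cm)
  moved <- p %*% t(rot)
  fit_rmsd <- sqrt(mean(rowSums((moved - q)^2)))
  structure(list(rotation = rot, translation = tr, rmsd = fit_rmsd, n = m),
            class = "rigid_fit")
}

#' @export
print.rigid_fit <- function(x, ...) {
  cat(sprintf("rigid_fit: %d atoms, rmsd %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param xyz M x 3 matrix (or length-3 vector).
#' @param fit a `rigid_fit`.
#' @return transformed coordinates, same shape as input.
#' @export
apply_transform <- function(xyz, fit) {
  vec <- is.null(dim(xyz))
  if (vec) xyz <- matrix(xyz, 1, 3)
  out <- xyz %*% t(fit$rotation) + matrix(fit$translation, nrow(xyz), 3,
                                          byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Invert a rigid transform
#' @param fit a `rigid_fit`.
#' @return a `rigid_fit` whose application undoes `fit` (rmsd/n copied).
#' @export
invert_transform <- function(fit) {
  structure(list(rotation = t(fit$rotation),
                 translation = as.numeric(-t(fit$rotation) %*% fit$translation),
                 rmsd = fit$rmsd, n = fit$n),
            class = "rigid_fit")
}

#' Root-mean-square deviation between corresponding rows
#'
#' No fitting is performed here: metrics are evaluated in whatever frame
#' the caller has established (typically after a basement fit).
#'
#' @param a,b M x 3 matrices, M >= 1, rows corresponding.
#' @return RMSD in the units of the input (Angstrom).
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("rmsd: row counts differ", call. = FALSE)
  if (nrow(a) == 0) stop("rmsd: empty coordinate sets", call. = FALSE)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Largest per-row distance between corresponding rows
#' @inheritParams rmsd
#' @return maximum pairwise distance (Angstrom); always >= [rmsd()].
#' @export
max_pair_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("max_pair_distance: row counts differ",
                               call. = FALSE)
  if (nrow(a) == 0) stop("max_pair_distance: empty coordinate sets",
                         call. = FALSE)
  sqrt(max(rowSums((a - b)^2)))
}

#' Collective variable: interatomic distance
#'
#' Euclidean distance between two labelled atoms, e.g. the Calpha
#' F381-V179 distance used to follow the TM7/TM2 approach during
#' activation.
#'
#' @param structure a `structure_model`.
#' @param a,b atom labels `"chain:resno:atom"`.
#' @return distance in Angstrom.
#' @export
cv_distance <- function(structure, a, b) {
  pa <- atom_coord(structure, a)
  pb <- atom_coord(structure, b)
  sqrt(sum((pa - pb)^2))
}

#' Collective variable: three-atom angle
#'
#' Angle at vertex `b` spanned by atoms `a` and `c` (e.g. the Calpha
#' T125-P113-F102 angle tracking the N-terminal loop lift).
#'
#' @param structure a `structure_model`.
#' @param a,b,c atom labels; `b` is the vertex.
#' @return angle in degrees, in [0, 180].
#' @export
cv_angle <- function(structure, a, b, c) {
  pa <- atom_coord(structure, a)
  pb <- atom_coord(structure, b)
  pc <- atom_coord(structure, c)
  u <- pa - pb
  v <- pc - pb
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) {
    stop("cv_angle: zero-length arm, angle undefined", call. = FALSE)
  }
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}
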