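# Independent oracles used to cross-check the implementation.

# Quaternion (Horn) superposition: minimal RMSD between corresponding
# point sets from the largest eigenvalue of the 4x4 key matrix.  Shares
# no code path with the SVD-based Kabsch implementation.
quaternion_rmsd <- function(mobile, reference) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  s <- crossprod(p, q)   # S_ab = sum_i p_a q_b
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,      -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,      -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(n4, symmetric = TRUE, only.values = TRUE)$values)
  ssq <- sum(p^2) + sum(q^2) - 2 * lambda
  sqrt(max(0, ssq) / nrow(mobile))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

rigid_motion <- function(xyz, rot = random_rotation(), shift = stats::rnorm(3, sd = 5)) {
  xyz %*% t(rot) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
}
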