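# Core geometric primitives: pairwise-distance deviation (CMAD) and
# least-squares rigid superposition RMSD.

#' Contact matrix average deviation (CMAD)
#'
#' The similarity score at the heart of the matching engine: the mean absolute
#' difference between corresponding pairwise distances of a template and of a
#' candidate local structure in the query. A CMAD of 0 means the two point
#' sets have identical internal distance geometry. The score is computed
#' separately for the C-alpha and the fa (furthest side-chain atom) point
#' sets by the caller; this function only compares two matched multisets of
#' pairwise distances.
#'
#' @param dists_t numeric vector of the template's C(n,2) unordered pairwise
#'   distances (Angstrom).
#' @param dists_q numeric vector of the corresponding query distances, in the
#'   same pair order.
#' @return the CMAD in Angstrom (non-negative, symmetric in its arguments).
#' @examples
#' cmad(c(3, 4, 5), c(4, 4, 5))  # 1/3
#' @export
cmad <- function(dists_t, dists_q) {
  if (length(dists_t) != length(dists_q)) {
    stop(sitematch_error("sitematch_value_error",
      sprintf("pair-count mismatch: %d vs %d distances",
              length(dists_t), length(dists_q))))
  }
  if (length(dists_t) == 0L) {
    stop(sitematch_error("sitematch_value_error",
                         "need at least one distance pair (n >= 2 points)"))
  }
  mean(abs(dists_t - dists_q))
}

# Unordered pairwise distances of an m x 3 coordinate matrix, in the fixed
# (j < k) column-major order used for all CMAD comparisons.
pairwise_distances <- function(xyz) {
  as.numeric(stats::dist(xyz))
}

#' Least-squares rigid-superposition RMSD
#'
#' Minimal root-mean-square deviation between two ordered point sets over all
#' proper rigid transformations (rotation + translation, no reflection),
#' computed with the Kabsch algorithm (SVD with determinant correction).
#' Degenerate configurations (collinear or coincident points, n = 2) are
#' handled; the result is symmetric in its arguments.
#'
#' @param a,b numeric matrices of equal dimension (n x 3), positional
#'   correspondence row by row.
#' @return RMSD in Angstrom.
#' @examples
#' a <- rbind(c(0, 0, 0), c(2, 0, 0))
#' b <- rbind(c(0, 0, 0), c(4, 0, 0))
#' superpose_rmsd(a, b)  # 1.0
#' @export
superpose_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L) {
    stop(sitematch_error("sitematch_value_error",
      "point sets must be equal-size n x 3 matrices"))
  }
  if (nrow(a) < 2L) {
    stop(sitematch_error("sitematch_value_error", "need at least 2 points"))
  }
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  h <- crossprod(bc, ac)          # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  br <- bc %*% t(rot)
  sqrt(sum((ac - br)^2) / nrow(a))
}
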