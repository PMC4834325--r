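#' Standard ellipsoid volume of a covariance matrix
#'
#' The standard ellipsoid of a multivariate-normal population is the
#' 1-Mahalanobis-unit surface \eqn{(x-\mu)^T \Sigma^{-1} (x-\mu) = 1}; its
#' semi-axes are the square roots of the eigenvalues of \eqn{\Sigma}. For
#' three isotopes the volume is \eqn{SEV = (4/3)\pi a b c =
#' (4/3)\pi\sqrt{\det\Sigma}} (per mil cubed); for two isotopes the standard
#' ellipse area \eqn{\pi\sqrt{\det\Sigma}} (per mil squared) is returned.
#'
#' @param sigma Symmetric positive-definite covariance matrix (2x2 or 3x3).
#' @return Strictly positive volume (d = 3) or area (d = 2).
#' @examples
#' sev_from_covariance(diag(3))          # unit sphere: 4*pi/3
#' sev_from_covariance(diag(c(4, 1, 1))) # 8*pi/3
#' @export
sev_from_covariance <- function(sigma) {
  sigma <- check_spd(sigma)
  d <- nrow(sigma)
  unit_ball_volume(d) * sqrt(det(sigma))
}

unit_ball_volume <- function(d) {
  if (d == 3L) 4 * pi / 3 else if (d == 2L) pi
  else stop("only 2 or 3 isotope dimensions are supported", call. = FALSE)
}

check_spd <- function(sigma, tol = 1e-10) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma) || !nrow(sigma) %in% 2:3)
    stop("covariance must be a 2x2 or 3x3 matrix", call. = FALSE)
  if (max(abs(sigma - t(sigma))) > tol * max(1, max(abs(sigma))))
    stop("covariance matrix is not symmetric", call. = FALSE)
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf(
      "covariance matrix is not positive definite (smallest eigenvalue %.3g)",
      min(ev)), call. = FALSE)
  (sigma + t(sigma)) / 2
}

#' Semi-axis lengths and directions of a standard ellipsoid
#'
#' Eigen-decomposes a covariance matrix: the semimajor axis has length
#' \eqn{a = \sqrt{\lambda_1}} along the leading eigenvector (the direction of
#' maximum variation), and the semiminor axes follow from the remaining
#' eigenvalues in descending order. Eigenvector signs are fixed by making
#' each vector's largest-magnitude component positive, so the decomposition
#' is reproducible across platforms.
#'
#' @inheritParams sev_from_covariance
#' @return A list with `lengths` (descending, per mil) and `directions`
#'   (orthonormal matrix, one unit eigenvector per column) satisfying
#'   `sigma == directions %*% diag(lengths^2) %*% t(directions)`.
#' @examples
#' axis_decomposition(diag(c(9, 4, 1)))$lengths # 3 2 1
#' @export
axis_decomposition <- function(sigma) {
  sigma <- check_spd(sigma)
  e <- eigen(sigma, symmetric = TRUE)
  q <- e$vectors
  for (j in seq_len(ncol(q))) {
    k <- which.max(abs(q[, j]))
    if (q[k, j] < 0) q[, j] <- -q[, j]
  }
  list(lengths = sqrt(e$values), directions = q)
}

#' Euclidean distance between two niche centroids
#'
#' @param mu_a,mu_b Centroid vectors of equal length (per mil).
#' @return Non-negative distance in per mil.
#' @examples
#' centroid_distance(c(0, 0, 0), c(1, 1, 1)) # sqrt(3)
#' @export
centroid_distance <- function(mu_a, mu_b) {
  if (length(mu_a) != length(mu_b))
    stop("centroid dimensions differ (", length(mu_a), " vs ",
         length(mu_b), ")", call. = FALSE)
  sqrt(sum((mu_a - mu_b)^2))
}
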