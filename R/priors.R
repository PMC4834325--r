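#' Prior specification for the multivariate-normal niche model
#'
#' The model places independent vague normal priors on the centroid
#' \eqn{\mu} (by default centred at 0 \eqn{\text{\textperthousand}} with variance 1000
#' \eqn{\text{\textperthousand}^2} per axis) and an inverse-Wishart prior
#' \eqn{\Sigma \sim IW(\Psi, \nu)} on the covariance, by default
#' \eqn{\Psi = 3 I_d}, \eqn{\nu = 4}. The inverse-Wishart density used is
#' proportional to \eqn{|\Sigma|^{-(\nu+d+1)/2} \exp(-\mathrm{tr}(\Psi
#' \Sigma^{-1})/2)}, so its mean (when it exists) is \eqn{\Psi/(\nu-d-1)}.
#'
#' @param d Dimension of isotope space (2 or 3).
#' @param mu_mean Prior mean of the centroid, length-`d` vector (per mil).
#' @param mu_var Prior variance per axis, positive scalar or length-`d`
#'   vector (per mil squared).
#' @param iw_scale Inverse-Wishart scale matrix \eqn{\Psi}, symmetric
#'   positive definite `d` x `d`.
#' @param iw_df Inverse-Wishart degrees of freedom \eqn{\nu}; must be at
#'   least `d + 1` for a proper prior.
#' @return An object of class `niche_prior`.
#' @examples
#' niche_prior(3)
#' niche_prior(2, iw_scale = diag(2, 2), iw_df = 5)
#' @export
niche_prior <- function(d = 3, mu_mean = rep(0, d), mu_var = 1000,
                        iw_scale = diag(3, d), iw_df = d + 1) {
  stopifnot(d %in% c(2L, 3L))
  if (length(mu_var) == 1) mu_var <- rep(mu_var, d)
  if (length(mu_mean) != d || length(mu_var) != d)
    stop("`mu_mean` and `mu_var` must have length ", d, call. = FALSE)
  if (any(mu_var <= 0)) stop("`mu_var` must be positive", call. = FALSE)
  iw_scale <- as.matrix(iw_scale)
  if (!isTRUE(all.equal(iw_scale, t(iw_scale))) ||
      any(eigen(iw_scale, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("`iw_scale` must be symmetric positive definite", call. = FALSE)
  if (iw_df < d + 1)
    stop("`iw_df` must be >= d + 1 for a proper inverse-Wishart prior",
         call. = FALSE)
  structure(
    list(d = as.integer(d), mu_mean = as.numeric(mu_mean),
         mu_var = as.numeric(mu_var), iw_scale = iw_scale,
         iw_df = as.numeric(iw_df)),
    class = "niche_prior"
  )
}

#' @export
print.niche_prior <- function(x, ...) {
  cat("<niche_prior d=", x$d, ">\n", sep = "")
  cat("  mu ~ N(", paste(x$mu_mean, collapse = ", "), "), var (",
      paste(x$mu_var, collapse = ", "), ")\n", sep = "")
  cat("  Sigma ~ IW(scale diag ", paste(diag(x$iw_scale), collapse = ", "),
      ", df ", x$iw_df, ")\n", sep = "")
  invisible(x)
}

#' MCMC settings for the Gibbs sampler
#'
#' Defaults follow common practice for this model: 4000 iterations with the
#' first 1000 discarded as burn-in, a single chain.
#'
#' @param n_iter Total iterations per chain.
#' @param burn_in Iterations discarded from the start of each chain.
#' @param n_chains Number of independent chains (draws are pooled).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return An object of class `mcmc_control`.
#' @export
mcmc_control <- function(n_iter = 4000, burn_in = 1000, n_chains = 1,
                         seed = NULL) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter, n_chains >= 1)
  structure(
    list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
         n_chains = as.integer(n_chains),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "mcmc_control"
  )
}
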