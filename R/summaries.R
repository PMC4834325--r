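#' Posterior summary of a fitted niche ellipsoid
#'
#' Summarizes the per-draw standard ellipsoid volume, centroid, and axis
#' lengths of one or more fitted populations: posterior median, mean, and
#' equal-tailed credible interval. Axis lengths and directions are the
#' eigen-decomposition of the element-wise posterior-median covariance, so
#' the reported directions form an exactly orthonormal basis.
#'
#' @param fit A `sev_fit` or `sev_fit_list`.
#' @param ci_level Credible-interval mass (default 0.95, equal-tailed).
#' @return A tibble with one row per population: `group`, `n`, `sev_median`,
#'   `sev_mean`, `sev_conf_low`, `sev_conf_high`, per-axis centroid columns
#'   `centroid_<isotope>` (posterior medians) with `_conf_low`/`_conf_high`,
#'   and list-columns `axis_lengths` (descending) and `axis_directions`.
#' @examples
#' d <- simulate_isotope_data(population_spec(c(0, 0, 0), 5), n = 30, seed = 1)
#' fit <- niche_fit(d, control = mcmc_control(500, 100, seed = 1))
#' niche_summary(fit)
#' @export
niche_summary <- function(fit, ci_level = 0.95) {
  if (inherits(fit, "sev_fit_list"))
    return(dplyr::bind_rows(lapply(fit, niche_summary, ci_level = ci_level)))
  stopifnot(inherits(fit, "sev_fit"))
  m <- nrow(fit$mu)
  if (m == 0) stop("fit contains no posterior draws", call. = FALSE)
  if (m < 100)
    warning("only ", m, " posterior draws; summaries will be noisy",
            call. = FALSE)
  a <- (1 - ci_level) / 2
  sev <- sev_draws(fit)
  med_sigma <- apply(fit$sigma, c(1, 2), median)
  med_sigma <- (med_sigma + t(med_sigma)) / 2
  ax <- axis_decomposition(med_sigma)

  out <- tibble::tibble(
    group = fit$group, n = fit$n,
    sev_median = median(sev), sev_mean = mean(sev),
    sev_conf_low = unname(quantile(sev, a)),
    sev_conf_high = unname(quantile(sev, 1 - a))
  )
  for (j in seq_len(fit$d)) {
    nm <- fit$isotopes[j]
    out[[paste0("centroid_", nm)]] <- median(fit$mu[, j])
    out[[paste0("centroid_", nm, "_conf_low")]] <-
      unname(quantile(fit$mu[, j], a))
    out[[paste0("centroid_", nm, "_conf_high")]] <-
      unname(quantile(fit$mu[, j], 1 - a))
  }
  out$axis_lengths <- list(ax$lengths)
  out$axis_directions <- list(ax$directions)
  out
}

#' Tidy posterior parameter summaries
#'
#' One row per derived quantity (SEV, each centroid coordinate, each axis
#' length), in broom's `term` / `estimate` / `conf.low` / `conf.high` layout.
#' Estimates are posterior medians.
#'
#' @param x A `sev_fit`.
#' @param ci_level Credible-interval mass.
#' @param ... Unused.
#' @export
tidy.sev_fit <- function(x, ci_level = 0.95, ...) {
  a <- (1 - ci_level) / 2
  sev <- sev_draws(x)
  ax <- t(vapply(seq_len(dim(x$sigma)[3]),
                 function(m) sqrt(sort(
                   eigen(x$sigma[, , m], symmetric = TRUE,
                         only.values = TRUE)$values, decreasing = TRUE)),
                 numeric(x$d)))
  qs <- function(v) c(median(v), mean(v), quantile(v, c(a, 1 - a)))
  rows <- rbind(
    sev = qs(sev),
    t(vapply(seq_len(x$d), function(j) qs(x$mu[, j]), numeric(4))),
    t(vapply(seq_len(x$d), function(j) qs(ax[, j]), numeric(4)))
  )
  tibble::tibble(
    group = x$group,
    term = c("sev", paste0("centroid_", x$isotopes),
             paste0("axis_", letters[seq_len(x$d)])),
    estimate = rows[, 1], mean = rows[, 2],
    conf.low = rows[, 3], conf.high = rows[, 4]
  )
}

#' @export
tidy.sev_fit_list <- function(x, ...) {
  dplyr::bind_rows(lapply(x, tidy, ...))
}

#' One-row fit overview
#'
#' @param x A `sev_fit`.
#' @param ... Passed to [niche_summary()].
#' @export
glance.sev_fit <- function(x, ...) {
  s <- niche_summary(x, ...)
  tibble::tibble(
    group = x$group, n = x$n, d = x$d, draws = nrow(x$mu),
    sev_median = s$sev_median, sev_mean = s$sev_mean,
    sev_conf_low = s$sev_conf_low, sev_conf_high = s$sev_conf_high
  )
}

#' @export
glance.sev_fit_list <- function(x, ...) {
  dplyr::bind_rows(lapply(x, glance, ...))
}
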