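#' Specification of a simulated population
#'
#' @param centroid True centroid location (length 2 or 3, per mil).
#' @param sev True standard ellipsoid volume (per mil cubed; area for d = 2).
#' @param label Population label.
#' @return A `population_spec` object.
#' @examples
#' population_spec(c(0, 0, 0), sev = 5, label = "pop1")
#' @export
population_spec <- function(centroid, sev, label = "pop") {
  stopifnot(length(centroid) %in% 2:3, sev > 0)
  structure(list(centroid = as.numeric(centroid), sev = as.numeric(sev),
                 label = as.character(label)),
            class = "population_spec")
}

#' The four standard simulation populations
#'
#' Populations with standard ellipsoid volumes 5, 7.5, 10, and 20 per mil
#' cubed at centroids (0,0,0), (1,1,1), (2,2,2), and (3,3,3) — a spread of
#' niche widths and positions typical of stable-isotope field studies.
#'
#' @return A list of four [population_spec()] objects.
#' @export
standard_populations <- function() {
  list(
    population_spec(c(0, 0, 0), 5.0, "pop1"),
    population_spec(c(1, 1, 1), 7.5, "pop2"),
    population_spec(c(2, 2, 2), 10.0, "pop3"),
    population_spec(c(3, 3, 3), 20.0, "pop4")
  )
}

#' Random covariance matrix with an exact standard ellipsoid volume
#'
#' Draws a random orthonormal basis (QR of a standard-normal matrix with the
#' sign of each diagonal of R fixed), draws eigenvalues as exponentials of
#' iid uniform(-1, 1) spreads so shapes range from near-spherical to oblong
#' with positive and negative correlations, then rescales the whole matrix
#' by \eqn{(SEV_{target}/SEV_{current})^{2/d}} so the determinant — and hence
#' the volume — hits the target exactly.
#'
#' @param target_sev Desired standard ellipsoid volume (> 0).
#' @param d Dimension (2 or 3).
#' @param seed Optional integer seed.
#' @return A `d` x `d` SPD matrix with `sev_from_covariance()` equal to
#'   `target_sev` to relative tolerance `1e-9`.
#' @export
random_covariance_for_sev <- function(target_sev, d = 3, seed = NULL) {
  stopifnot(target_sev > 0, d %in% 2:3)
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  lambda <- exp(runif(d, -1, 1))
  sigma <- q %*% (lambda * t(q))
  sigma <- (sigma + t(sigma)) / 2
  scale <- (target_sev / sev_from_covariance(sigma))^(2 / d)
  sigma * scale
}

#' Simulate an isotope dataset from a population specification
#'
#' Draws a fresh random covariance at the population's target volume, then
#' `n` individuals from \eqn{MVN(centroid, \Sigma)}. The realized covariance
#' is attached as attribute `sigma_true` for truth-tracking in simulation
#' studies.
#'
#' @param spec A [population_spec()].
#' @param n Number of individuals (>= 3).
#' @param seed Optional integer seed.
#' @param isotopes Column names for the isotope axes.
#' @return A tibble with columns `id`, `group`, and one column per isotope;
#'   attributes `sigma_true` and `spec` record the generating truth.
#' @export
simulate_isotope_data <- function(spec, n, seed = NULL,
                                  isotopes = default_axis_names(length(spec$centroid))) {
  stopifnot(inherits(spec, "population_spec"), n >= 3)
  d <- length(spec$centroid)
  stopifnot(length(isotopes) == d)
  if (!is.null(seed)) set.seed(seed)
  sigma <- random_covariance_for_sev(spec$sev, d)
  y <- MASS::mvrnorm(n, mu = spec$centroid, Sigma = sigma)
  out <- tibble::as_tibble(as.data.frame(y, col.names = isotopes))
  names(out) <- isotopes
  out <- dplyr::bind_cols(
    tibble::tibble(id = paste0(spec$label, "_", seq_len(n)),
                   group = spec$label),
    out
  )
  attr(out, "sigma_true") <- sigma
  attr(out, "spec") <- spec
  out
}

default_axis_names <- function(d) {
  if (d == 3) c("d13C", "d15N", "d34S") else c("d13C", "d15N")
}

#' Configuration for a simulation study
#'
#' Defaults are a desk-scale version of the full design: 200 replicate
#' datasets per cell over sample sizes 6–100, with 2000 Gibbs iterations and
#' a 500-draw burn-in. The full design (1000 replicates, every n from 6 to
#' 100, 4000/1000 iterations) is obtained by passing those values.
#'
#' @param populations List of [population_spec()] (first is the reference).
#' @param sample_sizes Integer vector of per-population sample sizes.
#' @param n_datasets Replicate datasets per (population, n) cell.
#' @param mcmc An [mcmc_control()]; its `seed` is ignored (per-cell seeds
#'   come from `master_seed`).
#' @param master_seed Master seed; each cell's seed is a deterministic mix
#'   of `(master_seed, population index, n, replicate)`.
#' @return A `study_config` object.
#' @export
study_config <- function(populations = standard_populations(),
                         sample_sizes = c(6, 10, 20, 30, 40, 50, 75, 100),
                         n_datasets = 200,
                         mcmc = mcmc_control(n_iter = 2000, burn_in = 500),
                         master_seed = 1L) {
  stopifnot(length(populations) >= 1, all(sample_sizes >= 3), n_datasets >= 1)
  structure(
    list(populations = populations, sample_sizes = as.integer(sample_sizes),
         n_datasets = as.integer(n_datasets), mcmc = mcmc,
         master_seed = as.integer(master_seed)),
    class = "study_config"
  )
}

fit_study_cell <- function(spec, n, cell_seed, mcmc) {
  dat <- simulate_isotope_data(spec, n, seed = cell_seed)
  ctl <- mcmc
  ctl$seed <- seed_mix(cell_seed, 1L)
  fit <- niche_fit(dat, isotopes = default_axis_names(length(spec$centroid)),
                   group = NULL, control = ctl)
  list(fit = fit, sigma_true = attr(dat, "sigma_true"))
}

#' Run a power / bias / coverage simulation study
#'
#' For every (population, sample size, replicate) cell: simulate a dataset
#' at the population's true volume and centroid, fit the Gibbs sampler, and
#' record the posterior-median volume, its 95% credible interval, whether
#' that interval covers the generating truth, and the estimated centroid.
#' Populations beyond the first are additionally compared against the
#' reference population's fit for the same cell: the probability that their
#' volume exceeds the reference's, the posterior-median centroid distance,
#' and the conservative centroid-difference probability.
#'
#' Cells already present in `previous` (matched on population, n, replicate)
#' are skipped, making long studies resumable; a failed cell is recorded
#' with `NA` results and an `error` string, never aborting the study.
#'
#' @param config A [study_config()].
#' @param previous Optional results tibble from an earlier (partial) run.
#' @param progress Print a line per completed (population, n) block.
#' @return A tibble of class `sev_study` with one row per cell.
#' @export
run_simulation_study <- function(config, previous = NULL, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  pops <- config$populations
  ref <- pops[[1]]
  rows <- list()
  for (n in config$sample_sizes) {
    ref_fits <- vector("list", config$n_datasets)
    for (pi in seq_along(pops)) {
      spec <- pops[[pi]]
      for (r in seq_len(config$n_datasets)) {
        # the reference population is always refitted (deterministic per-cell
        # seeds make that a no-op for the results) so comparisons of resumed
        # non-reference cells still have their paired reference fit
        if (pi > 1L && !is.null(previous) &&
            any(previous$population == spec$label & previous$n == n &
                previous$replicate == r)) {
          rows[[length(rows) + 1L]] <-
            previous[previous$population == spec$label & previous$n == n &
                       previous$replicate == r, , drop = FALSE]
          next
        }
        cell_seed <- seed_mix(config$master_seed, pi, n, r)
        row <- tryCatch({
          cell <- fit_study_cell(spec, n, cell_seed, config$mcmc)
          sev <- sev_draws(cell$fit)
          ci <- unname(quantile(sev, c(0.025, 0.975)))
          mu_hat <- apply(cell$fit$mu, 2, median)
          row <- tibble::tibble(
            population = spec$label, n = as.integer(n),
            replicate = as.integer(r), true_sev = spec$sev,
            sev_median = median(sev), sev_mean = mean(sev),
            sev_ci_lo = ci[1], sev_ci_hi = ci[2],
            ci_covers_truth = ci[1] <= spec$sev && spec$sev <= ci[2],
            centroid_error = centroid_distance(mu_hat, spec$centroid),
            true_distance_ref = centroid_distance(spec$centroid, ref$centroid),
            p_sev_greater_ref = NA_real_, distance_ref_median = NA_real_,
            p_centroids_differ_ref = NA_real_, error = NA_character_
          )
          if (pi == 1L) {
            ref_fits[[r]] <- cell$fit
          } else if (!is.null(ref_fits[[r]])) {
            rf <- ref_fits[[r]]
            row$p_sev_greater_ref <- prob_sev_greater(cell$fit, rf)
            row$distance_ref_median <-
              median(centroid_distance_draws(cell$fit, rf))
            row$p_centroids_differ_ref <- centroid_difference_probability(
              cell$fit, rf, split_seed = seed_mix(cell_seed, 2L))
          }
          row
        }, error = function(e) tibble::tibble(
          population = spec$label, n = as.integer(n),
          replicate = as.integer(r), true_sev = spec$sev,
          sev_median = NA_real_, sev_mean = NA_real_,
          sev_ci_lo = NA_real_, sev_ci_hi = NA_real_,
          ci_covers_truth = NA, centroid_error = NA_real_,
          true_distance_ref = centroid_distance(spec$centroid, ref$centroid),
          p_sev_greater_ref = NA_real_, distance_ref_median = NA_real_,
          p_centroids_differ_ref = NA_real_, error = conditionMessage(e)
        ))
        rows[[length(rows) + 1L]] <- row
      }
      if (progress)
        message("completed ", spec$label, " at n = ", n)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sev_study", class(out))
  out
}

#' Power curves from simulation-study results
#'
#' Summarizes, per non-reference population and sample size, the
#' distribution over replicates of the probability that the population's
#' standard ellipsoid volume exceeds the reference population's: the median
#' and the 2.5% / 97.5% quantiles.
#'
#' @param results A `sev_study` tibble from [run_simulation_study()].
#' @param pair Optional population label(s) to restrict to; an unknown label
#'   is an error.
#' @return A tibble keyed by `(population, n)` with `power_median`,
#'   `power_lo`, `power_hi`, and the analogous summaries of the
#'   centroid-difference probability.
#' @export
power_curves <- function(results, pair = NULL) {
  stopifnot(nrow(results) > 0)
  res <- dplyr::filter(results, !is.na(.data$p_sev_greater_ref))
  if (!is.null(pair)) {
    missing_pair <- setdiff(pair, unique(res$population))
    if (length(missing_pair))
      stop("no comparison results for population(s): ",
           paste(missing_pair, collapse = ", "), call. = FALSE)
    res <- dplyr::filter(res, .data$population %in% pair)
  }
  res |>
    dplyr::group_by(.data$population, .data$n) |>
    dplyr::summarise(
      power_median = median(.data$p_sev_greater_ref),
      power_lo = quantile(.data$p_sev_greater_ref, 0.025),
      power_hi = quantile(.data$p_sev_greater_ref, 0.975),
      cl_power_median = median(.data$p_centroids_differ_ref),
      cl_power_lo = quantile(.data$p_centroids_differ_ref, 0.025),
      cl_power_hi = quantile(.data$p_centroids_differ_ref, 0.975),
      .groups = "drop"
    )
}
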