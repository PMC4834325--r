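paired_draws <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "sev_fit"), inherits(fit_b, "sev_fit"))
  if (fit_a$d != fit_b$d)
    stop("fits have different isotope dimensions", call. = FALSE)
  ma <- nrow(fit_a$mu); mb <- nrow(fit_b$mu)
  if (ma == 0 || mb == 0) stop("a fit has no posterior draws", call. = FALSE)
  m <- min(ma, mb)
  if (ma != mb)
    warning("unequal draw counts (", ma, " vs ", mb, "); truncating to ", m,
            call. = FALSE)
  m
}

#' Posterior probability that one niche is larger than another
#'
#' The fraction of paired posterior iterations in which the first
#' population's standard ellipsoid volume strictly exceeds the second's.
#' Draws are paired by retained-iteration index; the two fits are
#' independent, so any pairing is exchangeable and index pairing keeps the
#' result reproducible.
#'
#' @param fit_a,fit_b Fitted populations (`sev_fit`).
#' @return Probability in `[0, 1]`.
#' @export
prob_sev_greater <- function(fit_a, fit_b) {
  m <- paired_draws(fit_a, fit_b)
  mean(sev_draws(fit_a)[seq_len(m)] > sev_draws(fit_b)[seq_len(m)])
}

#' Posterior draws of the distance between two centroids
#'
#' @inheritParams prob_sev_greater
#' @return Numeric vector of Euclidean distances (per mil), one per paired
#'   draw.
#' @export
centroid_distance_draws <- function(fit_a, fit_b) {
  m <- paired_draws(fit_a, fit_b)
  dif <- fit_a$mu[seq_len(m), , drop = FALSE] -
    fit_b$mu[seq_len(m), , drop = FALSE]
  sqrt(rowSums(dif^2))
}

#' Conservative probability that two centroid locations differ
#'
#' Euclidean distance between posterior centroids is always positive, so its
#' posterior never brackets zero even for coincident niches. This test
#' splits each population's centroid draws into equal-size null and test
#' halves and reports the fraction of aligned comparisons in which the
#' between-population test distance exceeds the sum of the two
#' within-population test-vs-null distances:
#' \deqn{D(\mu_{1t}, \mu_{2t}) - D(\mu_{1t}, \mu_{1n}) - D(\mu_{2t}, \mu_{2n}) > 0.}
#' Under a true null the within-population distances are of the same order
#' as the between-population one, making the statistic conservative (well
#' below 0.5 when the centroids coincide).
#'
#' @inheritParams prob_sev_greater
#' @param split `"random"` (default) permutes draws before halving, using
#'   `split_seed`; `"alternating"` assigns odd iterations to the test half
#'   and even to the null half, which is robust to residual autocorrelation.
#' @param split_seed Integer seed for the random split.
#' @return Probability in `[0, 1]`.
#' @export
centroid_difference_probability <- function(fit_a, fit_b,
                                            split = c("random", "alternating"),
                                            split_seed = 1L) {
  split <- match.arg(split)
  m <- paired_draws(fit_a, fit_b)
  if (m < 4) stop("need at least 4 paired draws", call. = FALSE)
  if (m %% 2 == 1) {
    warning("odd number of paired draws; dropping the last one", call. = FALSE)
    m <- m - 1
  }
  idx <- if (split == "random") {
    withr_seed <- get_rng_state()
    on.exit(restore_rng_state(withr_seed), add = TRUE)
    set.seed(split_seed)
    sample.int(m)
  } else {
    c(seq(1, m, by = 2), seq(2, m, by = 2))
  }
  h <- m / 2
  test_i <- idx[seq_len(h)]
  null_i <- idx[h + seq_len(h)]
  a_t <- fit_a$mu[test_i, , drop = FALSE]
  a_n <- fit_a$mu[null_i, , drop = FALSE]
  b_t <- fit_b$mu[test_i, , drop = FALSE]
  b_n <- fit_b$mu[null_i, , drop = FALSE]
  between <- sqrt(rowSums((a_t - b_t)^2))
  within_a <- sqrt(rowSums((a_t - a_n)^2))
  within_b <- sqrt(rowSums((b_t - b_n)^2))
  mean(between - within_a - within_b > 0)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Pairwise comparison table for fitted populations
#'
#' For every ordered pair of populations: the probability that the first has
#' the larger standard ellipsoid volume, the posterior median and credible
#' interval of the centroid distance, and the conservative
#' centroid-difference probability.
#'
#' @param fits A `sev_fit_list` (at least two populations).
#' @param ci_level Credible-interval mass for the distance summary.
#' @param split_seed Seed for the null/test split.
#' @return A tibble with one row per ordered pair.
#' @export
niche_compare <- function(fits, ci_level = 0.95, split_seed = 1L) {
  stopifnot(inherits(fits, "sev_fit_list"), length(fits) >= 2)
  a <- (1 - ci_level) / 2
  pairs <- tidyr::expand_grid(group_a = names(fits), group_b = names(fits)) |>
    dplyr::filter(.data$group_a != .data$group_b)
  purrr::pmap(pairs, function(group_a, group_b) {
    dd <- centroid_distance_draws(fits[[group_a]], fits[[group_b]])
    tibble::tibble(
      group_a = group_a, group_b = group_b,
      p_sev_greater = prob_sev_greater(fits[[group_a]], fits[[group_b]]),
      distance_median = median(dd),
      distance_conf_low = unname(quantile(dd, a)),
      distance_conf_high = unname(quantile(dd, 1 - a)),
      p_centroids_differ = centroid_difference_probability(
        fits[[group_a]], fits[[group_b]], split_seed = split_seed)
    )
  }) |> dplyr::bind_rows()
}
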