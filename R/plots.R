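ellipse_path <- function(mu, sigma2, n_points = 181) {
  # boundary of the 1-Mahalanobis-unit ellipse of a 2x2 covariance
  e <- eigen(sigma2, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(cos(theta), sin(theta))
  pts <- e$vectors %*% (sqrt(pmax(e$values, 0)) * circ) + mu
  tibble::tibble(x = pts[1, ], y = pts[2, ])
}

#' Two-dimensional projections of fitted niche ellipsoids
#'
#' Projects each population's posterior-median ellipsoid onto every pair of
#' isotope axes (the marginal 2x2 covariance blocks) and overlays the raw
#' standard-ellipse boundaries, one panel per axis pair. This is the flat
#' view of the three-dimensional ellipsoids; populations separated only on
#' the third axis look overlapping in the panel that omits it.
#'
#' @param fits A `sev_fit` or `sev_fit_list`.
#' @return A ggplot object.
#' @export
plot_niche_projections <- function(fits) {
  if (inherits(fits, "sev_fit"))
    fits <- structure(setNames(list(fits), fits$group),
                      class = "sev_fit_list")
  iso <- fits[[1]]$isotopes
  pairs <- utils::combn(seq_along(iso), 2, simplify = FALSE)
  paths <- purrr::map(fits, function(f) {
    mu <- apply(f$mu, 2, median)
    sig <- apply(f$sigma, c(1, 2), median)
    purrr::map(pairs, function(p)
      dplyr::mutate(ellipse_path(mu[p], sig[p, p]),
                    group = f$group,
                    panel = paste(iso[p[1]], "vs", iso[p[2]]))) |>
      dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(paths, ggplot2::aes(.data$x, .data$y,
                                      colour = .data$group)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "‰", y = "‰", colour = "population",
                  title = "Posterior-median standard ellipses by axis pair") +
    ggplot2::theme_minimal()
}

#' @rdname plot_niche_projections
#' @param object,... `sev_fit_list` and ignored extra arguments.
#' @export
autoplot.sev_fit_list <- function(object, ...) plot_niche_projections(object)

#' Simulation-study result panels
#'
#' Two linked panels in the style of a power/bias figure: the median (with
#' 95% replicate interval) probability that each non-reference population's
#' volume exceeds the reference's, and the median estimated volume with its
#' replicate interval against the generating truth, both as functions of
#' sample size.
#'
#' @param object A `sev_study` tibble from [run_simulation_study()].
#' @param ... Ignored.
#' @return A ggplot object (patchable list of two plots combined with
#'   facets).
#' @export
autoplot.sev_study <- function(object, ...) {
  rec <- object |>
    dplyr::filter(!is.na(.data$sev_median)) |>
    dplyr::group_by(.data$population, .data$n) |>
    dplyr::summarise(
      med = median(.data$sev_median),
      lo = quantile(.data$sev_median, 0.025),
      hi = quantile(.data$sev_median, 0.975),
      truth = .data$true_sev[1], .groups = "drop")
  ggplot2::ggplot(rec, ggplot2::aes(.data$n, .data$med)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$truth), colour = "white",
                       linewidth = 1) +
    ggplot2::facet_wrap(~population, scales = "free_y") +
    ggplot2::labs(x = "sample size per population",
                  y = "standard ellipsoid volume (‰³)",
                  title = "Volume recovery across sample sizes",
                  subtitle = "black: median estimate; white: truth; ribbon: 95% replicate interval") +
    ggplot2::theme_minimal()
}

#' Power-curve plot
#'
#' @param curves Output of [power_curves()].
#' @return A ggplot object.
#' @export
plot_power_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(.data$n, .data$power_median,
                                       colour = .data$population)) +
    ggplot2::geom_hline(yintercept = 0.9, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sample size per population",
                  y = "median P(SEV > reference SEV)",
                  title = "Power to detect the larger niche") +
    ggplot2::theme_minimal()
}
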