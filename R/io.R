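#' Read a stable-isotope CSV
#'
#' Expects a comma-separated, period-decimal, UTF-8 file with a header
#' `id,group,<isotope1>,<isotope2>[,<isotope3>]`. Rows with any missing
#' isotope value are dropped (the model has no missing-data mechanism) and
#' the count reported; groups left with fewer than 3 complete rows are
#' excluded with a warning.
#'
#' @param path Path to the CSV file.
#' @param group Name of the grouping column.
#' @param isotopes Isotope column names in axis order; `NULL` uses every
#'   numeric column except `id` (2 or 3 expected).
#' @return A tibble with the group column and isotope columns, row order
#'   preserved, ready for [niche_fit()]. The isotope column order is stored
#'   in attribute `isotopes`.
#' @export
read_isotope_csv <- function(path, group = "group", isotopes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(dat) == 0) stop("no data rows in '", path, "'", call. = FALSE)
  if (!group %in% names(dat))
    stop("group column '", group, "' not found in '", path, "'",
         call. = FALSE)
  if (is.null(isotopes)) {
    isotopes <- names(dat)[vapply(dat, is.numeric, logical(1))]
    isotopes <- setdiff(isotopes, c("id", group))
  }
  missing_cols <- setdiff(isotopes, names(dat))
  if (length(missing_cols))
    stop("isotope column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!length(isotopes) %in% 2:3)
    stop("expected 2 or 3 isotope columns, found ", length(isotopes),
         call. = FALSE)

  complete <- stats::complete.cases(dat[, isotopes])
  if (any(!complete)) {
    message(sum(!complete), " row(s) with missing isotope values dropped")
    dat <- dat[complete, , drop = FALSE]
  }
  sizes <- table(dat[[group]])
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("group(s) with fewer than 3 complete rows excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
    dat <- dat[!dat[[group]] %in% small, , drop = FALSE]
  }
  if (nrow(dat) == 0)
    stop("no usable rows remain in '", path, "'", call. = FALSE)
  attr(dat, "isotopes") <- isotopes
  dat
}

#' Write a synthetic multi-population isotope fixture
#'
#' Generates one dataset per population specification and writes them as a
#' single CSV in the package's input dialect
#' (`id,group,<isotopes...>`). The default populations emulate the
#' structure of three parapatric coastal-dolphin ecotypes: groups that
#' overlap heavily on the carbon and nitrogen axes but separate on the
#' sulfur (salinity) axis, with the inshore group owning the widest niche.
#' All values are synthetic draws, not measurements.
#'
#' @param path Output CSV path.
#' @param specs List of [population_spec()].
#' @param n Per-group sample sizes (recycled to `length(specs)`).
#' @param seed Integer seed; the same seed and specs give a byte-identical
#'   file.
#' @return `path`, invisibly.
#' @export
generate_fixture <- function(path, specs = dolphin_like_specs(),
                             n = c(18, 9, 8), seed = 42L) {
  stopifnot(length(specs) >= 1)
  n <- rep_len(n, length(specs))
  d <- length(specs[[1]]$centroid)
  datasets <- lapply(seq_along(specs), function(i)
    simulate_isotope_data(specs[[i]], n[i], seed = seed_mix(seed, i),
                          isotopes = default_axis_names(d)))
  out <- dplyr::bind_rows(datasets)
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                          ~ round(.x, 6)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Dolphin-like synthetic population specifications
#'
#' Three populations patterned on inshore / coastal / offshore ecotypes:
#' carbon and nitrogen centroids nearly shared, separation carried by the
#' sulfur axis (estuarine sulfur values are far below the marine ~20 per
#' mil), and a wider inshore niche.
#'
#' @return A list of three [population_spec()] objects.
#' @export
dolphin_like_specs <- function() {
  list(
    population_spec(c(-14.0, 13.0, 8.0), 12.0, "inshore"),
    population_spec(c(-16.0, 13.5, 14.0), 4.0, "coastal"),
    population_spec(c(-17.0, 14.0, 18.0), 4.0, "offshore")
  )
}

#' Export posterior draws to CSV
#'
#' One row per retained iteration: centroid components, then the upper
#' triangle of the covariance (column-major, diagonal included).
#'
#' @param fit A `sev_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  stopifnot(inherits(fit, "sev_fit"))
  d <- fit$d
  ut <- which(upper.tri(diag(d), diag = TRUE))
  sig_flat <- t(apply(fit$sigma, 3, function(s) s[ut]))
  pair_names <- outer(fit$isotopes, fit$isotopes,
                      function(a, b) paste0("cov_", a, "_", b))[ut]
  out <- tibble::as_tibble(cbind(fit$mu, sig_flat), .name_repair = "minimal")
  names(out) <- c(paste0("mu_", fit$isotopes), pair_names)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Export niche summaries to JSON
#'
#' Writes one object per population (volume and centroid summaries, axis
#' lengths and directions) plus the seed and MCMC settings used, so the
#' artifact is regenerable.
#'
#' @param fit A `sev_fit` or `sev_fit_list`.
#' @param path Output JSON path.
#' @param ci_level Credible-interval mass.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(fit, path, ci_level = 0.95) {
  fits <- if (inherits(fit, "sev_fit_list")) fit else
    structure(setNames(list(fit), fit$group), class = "sev_fit_list")
  payload <- lapply(fits, function(f) {
    s <- niche_summary(f, ci_level = ci_level)
    list(
      group = f$group, n = f$n, isotopes = f$isotopes,
      draws = nrow(f$mu),
      settings = list(n_iter = f$control$n_iter, burn_in = f$control$burn_in,
                      n_chains = f$control$n_chains,
                      seed = f$control$seed),
      data_fingerprint = f$data_fingerprint,
      sev = list(median = s$sev_median, mean = s$sev_mean,
                 conf_low = s$sev_conf_low, conf_high = s$sev_conf_high),
      centroid = lapply(seq_along(f$isotopes), function(j) list(
        isotope = f$isotopes[j],
        median = s[[paste0("centroid_", f$isotopes[j])]],
        conf_low = s[[paste0("centroid_", f$isotopes[j], "_conf_low")]],
        conf_high = s[[paste0("centroid_", f$isotopes[j], "_conf_high")]]
      )),
      axis_lengths = s$axis_lengths[[1]],
      axis_directions = s$axis_directions[[1]]
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
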