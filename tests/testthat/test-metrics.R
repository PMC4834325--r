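test_that("a point-mass posterior summarizes to zero-width intervals", {
  fit <- make_point_fit(c(1, 2, 3), diag(c(4, 1, 1)))
  s <- niche_summary(fit)
  expect_equal(s$sev_median, s$sev_mean)
  expect_equal(s$sev_conf_low, s$sev_conf_high)
  expect_equal(s$sev_median, 8 * pi / 3)
  expect_equal(s$centroid_a, 1)
  expect_equal(s$axis_lengths[[1]], c(2, 1, 1))
  expect_equal(crossprod(s$axis_directions[[1]]), diag(3), tolerance = 1e-8)
  expect_error(niche_summary(make_point_fit(c(0, 0, 0), diag(3), m = 0)),
               "no posterior draws")
})

test_that("volume summaries concentrate at large n", {
  set.seed(31)
  y <- MASS::mvrnorm(5000, rep(0, 3), diag(3))
  fit <- fit_mvn(y, seed = 32, n_iter = 1200, burn_in = 200)
  s <- niche_summary(fit)
  expect_lt(abs(s$sev_median - 4 * pi / 3) / (4 * pi / 3), 0.05)
})

test_that("tidy and glance return the broom-style layouts", {
  d <- simulate_isotope_data(population_spec(c(0, 0, 0), 5), 20, seed = 33)
  d2 <- simulate_isotope_data(population_spec(c(2, 2, 2), 10, "p2"), 20,
                              seed = 34)
  fits <- niche_fit(rbind(d, d2), control = fast_ctl(35, 800, 200))
  td <- tidy(fits)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$group), c("pop", "p2"))
  expect_true(all(c("term", "estimate", "conf.low", "conf.high")
                  %in% names(td)))
  expect_setequal(
    td$term[td$group == "pop"],
    c("sev", "centroid_d13C", "centroid_d15N", "centroid_d34S",
      "axis_a", "axis_b", "axis_c"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g <- glance(fits)
  expect_equal(nrow(g), 2)
  expect_equal(g$n, c(20L, 20L))
})

test_that("volume-ordering probability is 0 against itself and respects pairing", {
  fit <- make_point_fit(c(0, 0, 0), diag(3))
  expect_identical(prob_sev_greater(fit, fit), 0)
  big <- make_point_fit(c(0, 0, 0), diag(2, 3))
  expect_identical(prob_sev_greater(big, fit), 1)
  short <- make_point_fit(c(0, 0, 0), diag(3), m = 100)
  expect_warning(p <- prob_sev_greater(big, short), "truncating")
  expect_identical(p, 1)
})

test_that("centroid-difference probability is conservative under the null and decisive under separation", {
  pn <- ps <- numeric(15)
  for (r in 1:15) {
    da <- simulate_isotope_data(population_spec(c(0, 0, 0), 5), 20,
                                seed = 100 + r)
    db <- simulate_isotope_data(population_spec(c(0, 0, 0), 5), 20,
                                seed = 400 + r)
    dc <- simulate_isotope_data(population_spec(c(3, 3, 3), 5, "far"), 20,
                                seed = 700 + r)
    fa <- niche_fit(da, group = NULL, control = fast_ctl(1000 + r))
    fb <- niche_fit(db, group = NULL, control = fast_ctl(1300 + r))
    fc <- niche_fit(dc, group = NULL, control = fast_ctl(1600 + r))
    pn[r] <- centroid_difference_probability(fa, fb, split_seed = r)
    ps[r] <- centroid_difference_probability(fa, fc, split_seed = r)
  }
  expect_lt(median(pn), 0.5)
  expect_gt(median(ps), 0.99)
  # alternating split agrees closely with the random split
  da <- simulate_isotope_data(population_spec(c(0, 0, 0), 5), 20, seed = 41)
  dc <- simulate_isotope_data(population_spec(c(3, 3, 3), 5, "far"), 20,
                              seed = 42)
  fa <- niche_fit(da, group = NULL, control = fast_ctl(43))
  fc <- niche_fit(dc, group = NULL, control = fast_ctl(44))
  expect_equal(
    centroid_difference_probability(fa, fc, split = "alternating"),
    centroid_difference_probability(fa, fc, split_seed = 5),
    tolerance = 0.05)
  tiny <- make_point_fit(c(0, 0, 0), diag(3), m = 2)
  expect_error(centroid_difference_probability(tiny, tiny), "at least 4")
})

test_that("overlap endpoints: identical ellipsoids 100%, disjoint 0%", {
  fa <- make_point_fit(c(0, 0, 0), diag(3))
  expect_true(all(percent_overlap(fa, fa, method = "grid",
                                  resolution = 40) == 100))
  expect_true(all(percent_overlap(fa, fa, method = "montecarlo",
                                  n_points = 500, seed = 1) == 100))
  apart <- make_point_fit(c(2.01, 0, 0), diag(3))
  expect_true(all(percent_overlap(fa, apart, method = "grid",
                                  resolution = 40) == 0))
  expect_true(all(percent_overlap(fa, apart, method = "montecarlo",
                                  n_points = 500, seed = 1) == 0))
})

test_that("overlap of unit spheres one unit apart matches the sphere-cap closed form", {
  exact <- 100 * sphere_lens_volume(1) / (4 * pi / 3) # 31.25
  expect_equal(exact, 31.25)
  fa <- make_point_fit(c(0, 0, 0), diag(3), m = 5)
  fb <- make_point_fit(c(1, 0, 0), diag(3), m = 5)
  g <- percent_overlap(fa, fb, method = "grid", resolution = 64)[1]
  mc <- percent_overlap(fa, fb, method = "montecarlo", n_points = 1e5,
                        seed = 2)[1]
  expect_equal(g, exact, tolerance = 2 / exact)
  expect_equal(mc, exact, tolerance = 2 / exact)
  expect_lt(abs(g - mc), 2)
})

test_that("two-isotope overlap matches the circle-lens closed form", {
  exact <- 100 * circle_lens_area(1) / pi
  fa <- make_point_fit(c(0, 0), diag(2), m = 5)
  fb <- make_point_fit(c(1, 0), diag(2), m = 5)
  g <- percent_overlap(fa, fb, method = "grid", resolution = 100)[1]
  expect_equal(g, exact, tolerance = 1 / exact)
})

test_that("grid and Monte-Carlo integrators agree and the intersection is symmetric", {
  set.seed(36)
  for (i in 1:5) {
    sa <- rand_spd(); sb <- rand_spd()
    mu_b <- rnorm(3, sd = 0.8)
    fa <- make_point_fit(c(0, 0, 0), sa, m = 3)
    fb <- make_point_fit(mu_b, sb, m = 3)
    g_ab <- percent_overlap(fa, fb, method = "grid", resolution = 64)[1]
    m_ab <- percent_overlap(fa, fb, method = "montecarlo", n_points = 1e5,
                            seed = i)[1]
    expect_lt(abs(g_ab - m_ab), 2)
    # intersection volume recovered from either ordering
    a_ab <- g_ab / 100 * sev_from_covariance(sa)
    a_ba <- percent_overlap(fb, fa, method = "grid", resolution = 64)[1] /
      100 * sev_from_covariance(sb)
    expect_equal(a_ab, a_ba, tolerance = 0.05 * max(a_ab, 0.02))
  }
})

test_that("overlap draws stay in [0, 100] and summarize with one-sided bound", {
  d1 <- simulate_isotope_data(population_spec(c(0, 0, 0), 5), 15, seed = 37)
  d2 <- simulate_isotope_data(population_spec(c(1, 1, 1), 7.5, "p2"), 15,
                              seed = 38)
  f1 <- niche_fit(d1, group = NULL, control = fast_ctl(39))
  f2 <- niche_fit(d2, group = NULL, control = fast_ctl(40))
  ov <- percent_overlap(f1, f2, n_points = 300, seed = 41)
  expect_true(all(ov >= 0 & ov <= 100))
  s <- overlap_summary(ov)
  expect_true(s$overlap_conf_low <= s$overlap_median)
  expect_true(s$overlap_median <= s$overlap_conf_high)
  expect_true(s$overlap_upper95 <= s$overlap_conf_high + 1e-9)
})
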