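# shared fixtures and independent oracles, built in code at test time

fast_ctl <- function(seed, n_iter = 2000, burn_in = 500) {
  mcmc_control(n_iter = n_iter, burn_in = burn_in, seed = seed)
}

# random SPD matrix with condition kept moderate
rand_spd <- function(d = 3) {
  a <- matrix(rnorm(d * d), d, d)
  crossprod(a) + diag(0.5, d)
}

# random rotation via QR with positive-diagonal sign fix
rand_rotation <- function(d = 3) {
  qr_res <- qr(matrix(rnorm(d * d), d, d))
  q <- qr.Q(qr_res)
  q %*% diag(sign(diag(qr.R(qr_res))), d)
}

# synthetic point-mass "fit": every draw identical, for geometric oracles
make_point_fit <- function(mu, sigma, m = 200) {
  d <- length(mu)
  structure(
    list(mu = matrix(rep(mu, each = m), m),
         sigma = array(rep(sigma, m), c(d, d, m)),
         group = "synthetic", isotopes = letters[seq_len(d)],
         n = 10L, d = as.integer(d),
         prior = niche_prior(d), control = mcmc_control(seed = 1),
         data_fingerprint = "synthetic"),
    class = "sev_fit"
  )
}

# closed-form intersection of two unit spheres (radius r, centre distance s):
# twice the spherical-cap volume with height h = r - s/2
sphere_lens_volume <- function(s, r = 1) {
  h <- r - s / 2
  if (h <= 0) return(0)
  2 * pi * h^2 * (3 * r - h) / 3
}

# closed-form intersection area of two unit circles at centre distance s
circle_lens_area <- function(s, r = 1) {
  if (s >= 2 * r) return(0)
  2 * r^2 * acos(s / (2 * r)) - (s / 2) * sqrt(4 * r^2 - s^2)
}

fit_mvn <- function(y, seed, ...) {
  d <- as.data.frame(y)
  names(d) <- c("d13C", "d15N", "d34S")[seq_len(ncol(y))]
  niche_fit(d, isotopes = names(d), group = NULL,
            control = fast_ctl(seed, ...))
}

# memoised heavy studies shared between acceptance blocks
.study_cache <- new.env(parent = emptyenv())

cached_study <- function(key, config) {
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- run_simulation_study(config)
  .study_cache[[key]]
}
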