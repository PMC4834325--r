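#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Wishart(df, S) draw via Bartlett decomposition, S given by its lower
// Cholesky factor. RNG call order is fixed (diagonal chi-square first, then
// the sub-diagonal normals, row by row) so draws are reproducible under a
// given R seed.
static arma::mat rwishart_chol(double df, const arma::mat& S_chol_lower) {
  const arma::uword d = S_chol_lower.n_rows;
  arma::mat A(d, d, arma::fill::zeros);
  for (arma::uword i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat L = S_chol_lower * A;
  return L * L.t();
}

// Two-block Gibbs sampler for y_i ~ MVN(mu, Sigma) with independent
// N(mu0, diag(prior_var)) prior on mu and IW(Psi, nu) prior on Sigma.
// Update order per iteration: mu | Sigma, then Sigma | mu.
// [[Rcpp::export(name = ".gibbs_mvn_iw")]]
List gibbs_mvn_iw(const arma::mat& Y,
                  const arma::vec& mu0,
                  const arma::vec& prior_var,
                  const arma::mat& Psi,
                  double nu,
                  int n_iter,
                  int burn_in,
                  const arma::vec& mu_init,
                  const arma::mat& sigma_init) {
  const arma::uword n = Y.n_rows, d = Y.n_cols;
  const arma::vec ybar = arma::mean(Y, 0).t();
  const arma::vec prior_prec = 1.0 / prior_var;
  const int M = n_iter - burn_in;

  arma::mat mu_draws(M, d);
  arma::cube sigma_draws(d, d, M);

  arma::vec mu = mu_init;
  arma::mat Sigma = sigma_init;

  arma::vec z(d);
  for (int it = 0; it < n_iter; ++it) {
    // mu | Sigma, y : precision = n Sigma^-1 + diag(prior_prec)
    arma::mat Sinv;
    if (!arma::inv_sympd(Sinv, Sigma))
      stop("covariance draw not invertible at iteration %d", it + 1);
    arma::mat P = (double)n * Sinv;
    P.diag() += prior_prec;
    arma::mat V;
    if (!arma::inv_sympd(V, P))
      stop("conditional precision for the centroid is singular at iteration %d", it + 1);
    arma::vec m = V * ((double)n * (Sinv * ybar) + prior_prec % mu0);
    arma::mat Lv;
    if (!arma::chol(Lv, V, "lower"))
      stop("Cholesky failure in the centroid update at iteration %d", it + 1);
    for (arma::uword k = 0; k < d; ++k) z(k) = norm_rand();
    mu = m + Lv * z;

    // Sigma | mu, y : IW(Psi + scatter(mu), nu + n)
    arma::mat Yc = Y.each_row() - mu.t();
    arma::mat scale_post = Psi + Yc.t() * Yc;
    arma::mat scale_inv;
    if (!arma::inv_sympd(scale_inv, scale_post))
      stop("posterior scale matrix is singular at iteration %d", it + 1);
    arma::mat Lw;
    if (!arma::chol(Lw, scale_inv, "lower"))
      stop("Cholesky failure in the covariance update at iteration %d", it + 1);
    arma::mat W = rwishart_chol(nu + (double)n, Lw);
    if (!arma::inv_sympd(Sigma, W))
      stop("Wishart draw not invertible at iteration %d", it + 1);
    Sigma = arma::symmatu(Sigma);

    if (it >= burn_in) {
      mu_draws.row(it - burn_in) = mu.t();
      sigma_draws.slice(it - burn_in) = Sigma;
    }
  }

  return List::create(_["mu"] = mu_draws, _["sigma"] = sigma_draws);
}

static inline double mahal2(const arma::vec& x, const arma::vec& mu,
                            const arma::mat& Sinv) {
  arma::vec v = x - mu;
  return arma::as_scalar(v.t() * Sinv * v);
}

// Voxel-count intersection volume of the two 1-Mahalanobis-unit ellipsoids,
// per paired posterior draw. Grid spans the axis-aligned bounding box of the
// union; voxel-center rule. Returns the intersection volume A_{1,2} per draw.
// [[Rcpp::export(name = ".overlap_grid")]]
arma::vec overlap_grid(const arma::mat& mu_a, const arma::cube& sig_a,
                       const arma::mat& mu_b, const arma::cube& sig_b,
                       int resolution) {
  const arma::uword M = mu_a.n_rows, d = mu_a.n_cols;
  arma::vec out(M);
  arma::vec x(d), lo(d), hi(d), step(d);
  for (arma::uword m = 0; m < M; ++m) {
    arma::vec ma = mu_a.row(m).t(), mb = mu_b.row(m).t();
    arma::mat Sa = sig_a.slice(m), Sb = sig_b.slice(m);
    arma::mat Sa_inv = arma::inv_sympd(Sa), Sb_inv = arma::inv_sympd(Sb);
    // bounding half-widths of {x : (x-mu)' S^-1 (x-mu) <= 1} are sqrt(diag(S))
    for (arma::uword k = 0; k < d; ++k) {
      double wa = std::sqrt(Sa(k, k)), wb = std::sqrt(Sb(k, k));
      lo(k) = std::min(ma(k) - wa, mb(k) - wb);
      hi(k) = std::max(ma(k) + wa, mb(k) + wb);
      step(k) = (hi(k) - lo(k)) / resolution;
    }
    double vox = arma::prod(step);
    long count = 0;
    const long total = (long)std::pow((double)resolution, (double)d);
    for (long cell = 0; cell < total; ++cell) {
      long c = cell;
      for (arma::uword k = 0; k < d; ++k) {
        x(k) = lo(k) + (c % resolution + 0.5) * step(k);
        c /= resolution;
      }
      if (mahal2(x, ma, Sa_inv) <= 1.0 && mahal2(x, mb, Sb_inv) <= 1.0)
        ++count;
    }
    out(m) = count * vox;
  }
  return out;
}

// Monte-Carlo intersection volume: sample uniformly inside ellipsoid A
// (unit-ball draw mapped through the Cholesky factor of Sigma_a), score the
// fraction falling inside B, scale by A's volume (passed in by the caller).
// [[Rcpp::export(name = ".overlap_mc")]]
arma::vec overlap_mc(const arma::mat& mu_a, const arma::cube& sig_a,
                     const arma::mat& mu_b, const arma::cube& sig_b,
                     const arma::vec& vol_a, int n_points) {
  const arma::uword M = mu_a.n_rows, d = mu_a.n_cols;
  arma::vec out(M);
  arma::vec z(d);
  for (arma::uword m = 0; m < M; ++m) {
    arma::vec ma = mu_a.row(m).t(), mb = mu_b.row(m).t();
    arma::mat La = arma::chol(sig_a.slice(m), "lower");
    arma::mat Sb_inv = arma::inv_sympd(sig_b.slice(m));
    long inside = 0;
    for (int p = 0; p < n_points; ++p) {
      for (arma::uword k = 0; k < d; ++k) z(k) = norm_rand();
      double r = arma::norm(z);
      double u = std::pow(unif_rand(), 1.0 / d);
      arma::vec x = ma + La * (z * (u / r));
      if (mahal2(x, mb, Sb_inv) <= 1.0) ++inside;
    }
    out(m) = vol_a(m) * (double)inside / n_points;
  }
  return out;
}
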