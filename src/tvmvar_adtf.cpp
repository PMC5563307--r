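#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Kalman tracker for time-varying MVAR coefficients (random-walk state,
// process noise = uc * state covariance). Decoupled per-target-channel
// blocks sharing the lagged regressor, which keeps the update O(M * (Mp)^2)
// per sample instead of O((M^2 p)^2).
//
// y: M x N data matrix. Returns per-time coefficient slices (M x M*p,
// row = target channel, columns blocked by lag), innovations, and an
// exponentially weighted innovation covariance (symmetric PSD by
// construction). Time points t <= p (1-based) carry NaN.
// stationary least-squares VAR(p) coefficients (d x M, lag-blocked rows,
// column per target channel) via pseudo-inverse, tolerant of the rank
// deficiency introduced by common-average referencing
static mat ls_coef(const mat& yfull, const int p, const uword n_use,
                   const double ridge) {
  const mat y = yfull.cols(0, std::min(n_use, yfull.n_cols) - 1);
  const uword M = y.n_rows, N = y.n_cols;
  const uword d = static_cast<uword>(M) * p;
  mat Z(N - p, d);
  for (int k = 0; k < p; ++k)
    Z.cols(k * M, k * M + M - 1) = y.cols(p - 1 - k, N - 2 - k).t();
  mat Y = y.cols(p, N - 1).t();
  // ridge-regularized normal equations: band-limited, decimated EEG has
  // near-collinear lagged regressors (and common-average referencing adds
  // an exact rank deficiency), so plain or pseudo-inverse least squares
  // amplifies noise along ill-determined directions; the ridge leaves
  // those directions at zero for the Kalman filter to refine
  mat G = Z.t() * Z;
  const double lam = ridge * trace(G) / static_cast<double>(d);
  G.diag() += lam;
  mat B;
  if (!solve(B, G, Z.t() * Y))
    B.zeros(d, M);
  return B;
}

// [[Rcpp::export]]
Rcpp::List kalman_mvar_cpp(const arma::mat& y, const int p, const double uc,
                           const bool init_ls = false,
                           const double init_cov = -1.0,
                           const double init_ridge = 1e-2) {
  const uword M = y.n_rows, N = y.n_cols;
  const uword d = static_cast<uword>(M) * p;

  cube coeffs(M, d, N);
  coeffs.fill(datum::nan);
  mat innov(M, N);
  innov.fill(datum::nan);
  cube rcov(M, M, N);
  rcov.fill(datum::nan);

  // state: column m = coefficients for target m. Zero init with identity
  // state covariance is the neutral start; the stationary least-squares
  // init (with a correspondingly small state covariance, so the filter
  // refines rather than discards it) makes persistent structure visible
  // from the first tracked sample, which matters on short segments.
  // LS init uses the leading third of the segment: in discharge-centred
  // epochs that is pre-event data, so the init encodes the persistent
  // background model while event-locked coupling is left for the filter
  // to pick up. Ridge regularization makes it well-defined even when the
  // window is shorter than the state dimension.
  mat a(d, M, fill::zeros);
  double p0 = 1.0;
  const uword n_init = std::max<uword>(N / 3, std::min<uword>(N, 4 * p + 20));
  if (init_ls && n_init > static_cast<uword>(3 * p)) {
    bool ok = true;
    try { a = ls_coef(y, p, n_init, init_ridge); } catch (...) { ok = false; }
    if (ok && a.is_finite())
      p0 = 0.05;                               // near steady-state gain
    else a.zeros();
  }
  if (init_cov > 0) p0 = init_cov;
  std::vector<mat> P(M, eye<mat>(d, d) * p0);
  double vscale = mean(square(vectorise(y)));
  if (!(vscale > 0)) vscale = 1.0;
  vec v(M);
  v.fill(vscale);                    // adaptive observation-noise variances
  mat C = eye<mat>(M, M) * vscale;   // EWMA residual covariance

  vec phi(d), e(M);
  int bad_t = -1;

  for (uword t = static_cast<uword>(p); t < N; ++t) {
    for (int k = 0; k < p; ++k)
      phi.subvec(k * M, k * M + M - 1) = y.col(t - 1 - k);

    for (uword m = 0; m < M; ++m) {
      mat Ppred = (1.0 + uc) * P[m];
      vec Pphi = Ppred * phi;
      double S = dot(phi, Pphi) + v(m);
      double em = y(m, t) - dot(phi, a.col(m));
      vec K = Pphi / S;
      a.col(m) += K * em;
      mat Pnew = Ppred - K * Pphi.t();
      P[m] = 0.5 * (Pnew + Pnew.t());
      v(m) = (1.0 - uc) * v(m) + uc * em * em;
      e(m) = em;
    }

    if (!e.is_finite() || !a.is_finite()) { bad_t = static_cast<int>(t) + 1; break; }

    C = (1.0 - uc) * C + uc * (e * e.t());
    coeffs.slice(t) = a.t();
    innov.col(t) = e;
    rcov.slice(t) = C;
  }

  return Rcpp::List::create(
    Rcpp::Named("coeffs") = coeffs,
    Rcpp::Named("innovations") = innov,
    Rcpp::Named("resid_cov") = rcov,
    Rcpp::Named("diverged_at") = bad_t);
}

// Frequency-domain transform of time-varying MVAR coefficients and the
// normalized/integrated ADTF. coeffs: M x (M*p) x N cube as returned by
// kalman_mvar_cpp (NaN slices are skipped). freqs in Hz, dt = 1/fs,
// band_idx = 0-based indices into freqs over which Q2 averages.
// check_cond flags (f,t) points whose A(f,t) has reciprocal condition
// below cond_tol as unavailable (NaN).
// Returns gamma2 as an M x M x (F*N) cube (frequency fastest), Q2 cube
// (M x M x N), outflow (M x N), and H if keep_H.
// [[Rcpp::export]]
Rcpp::List adtf_cpp(const arma::cube& coeffs, const arma::vec& freqs,
                    const double dt, const arma::uvec& band_idx,
                    const bool keep_gamma, const bool keep_H,
                    const bool check_cond, const double cond_tol,
                    const int t_start = 0) {
  const uword M = coeffs.n_rows;
  const uword d = coeffs.n_cols;
  const int p = static_cast<int>(d / M);
  const uword N = coeffs.n_slices;
  const uword F = freqs.n_elem;
  const uword B = band_idx.n_elem;

  cube gamma2;
  if (keep_gamma) { gamma2.set_size(M, M, F * N); gamma2.fill(datum::nan); }
  cx_cube Hout;
  if (keep_H) { Hout.set_size(M, M, F * N); Hout.fill(cx_double(datum::nan, 0)); }
  cube Q2(M, M, N);
  Q2.fill(datum::nan);
  mat outflow(M, N);
  outflow.fill(datum::nan);

  // phase factors exp(-i 2 pi f dt k), k = 1..p, per frequency
  cx_mat ph(F, p);
  for (uword f = 0; f < F; ++f)
    for (int k = 1; k <= p; ++k)
      ph(f, k - 1) = std::exp(cx_double(0.0, -2.0 * datum::pi * freqs(f) * dt * k));

  cx_mat Af(M, M), H(M, M);
  mat g(M, M);
  const cx_mat I = eye<cx_mat>(M, M);

  std::vector<mat> lagblk(p);
  for (uword t = static_cast<uword>(std::max(t_start, 0)); t < N; ++t) {
    if (!coeffs.slice(t).is_finite()) continue;
    cube gband(M, M, B);   // band gamma2 values for this t
    gband.fill(datum::nan);
    for (int k = 0; k < p; ++k)
      lagblk[k] = coeffs.slice(t).cols(k * M, k * M + M - 1);

    for (uword f = 0; f < F; ++f) {
      Af = I;
      for (int k = 0; k < p; ++k) {
        const double re = ph(f, k).real(), im = ph(f, k).imag();
        Af -= cx_mat(re * lagblk[k], im * lagblk[k]);
      }

      bool ok = inv(H, Af);
      if (ok && check_cond) {
        double rc = rcond(Af);
        if (!(rc > cond_tol)) ok = false;
      }
      if (!ok) {
        if (keep_gamma) gamma2.slice(t * F + f).fill(datum::nan);
        continue;
      }
      // receiver-normalized ADTF: gamma2(i,j) = |H(i,j)|^2 / sum_m |H(i,m)|^2
      g = square(abs(H));
      vec rs = sum(g, 1);
      for (uword i = 0; i < M; ++i) {
        if (rs(i) > 0) g.row(i) /= rs(i);
        else g.row(i).fill(datum::nan);
      }
      if (keep_gamma) gamma2.slice(t * F + f) = g;
      if (keep_H) Hout.slice(t * F + f) = H;
      for (uword b = 0; b < B; ++b)
        if (band_idx(b) == f) gband.slice(b) = g;
    }

    // Q2: mean over band bins (bin-count divisor keeps Q2 in [0,1])
    mat q(M, M, fill::zeros);
    uword nb = 0;
    bool any_nan = false;
    for (uword b = 0; b < B; ++b) {
      if (gband.slice(b).is_finite()) { q += gband.slice(b); ++nb; }
      else any_nan = true;
    }
    if (nb > 0 && !any_nan) {
      q /= static_cast<double>(nb);
      Q2.slice(t) = q;
      for (uword j = 0; j < M; ++j) {
        double s = accu(q.col(j)) - q(j, j);
        outflow(j, t) = s / static_cast<double>(M - 1);
      }
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("Q2") = Q2,
    Rcpp::Named("outflow") = outflow);
  if (keep_gamma) out["gamma2"] = gamma2;
  if (keep_H) out["H"] = Hout;
  return out;
}

// Fast path for surrogate ensembles: segment -> Kalman -> band Q2 only,
// accumulating nothing beyond the Q2 cube. Identical numerics to
// kalman_mvar_cpp + adtf_cpp restricted to the band frequencies.
// [[Rcpp::export]]
Rcpp::NumericVector surrogate_q2_cpp(const arma::mat& y, const int p,
                                     const double uc,
                                     const arma::vec& band_freqs,
                                     const double dt,
                                     const bool init_ls = false,
                                     const double init_cov = -1.0,
                                     const double init_ridge = 1e-2,
                                     const int t_start = 0) {
  Rcpp::List kf = kalman_mvar_cpp(y, p, uc, init_ls, init_cov, init_ridge);
  int diverged = Rcpp::as<int>(kf["diverged_at"]);
  const uword M = y.n_rows, N = y.n_cols;
  if (diverged > 0) {
    cube bad(M, M, N);
    bad.fill(datum::nan);
    return Rcpp::wrap(bad);
  }
  // note: as<cube> borrows the List's memory, so the List must stay in
  // scope for as long as the cube (or anything derived from it) is used
  cube coeffs = Rcpp::as<cube>(kf["coeffs"]);
  uvec all_idx = regspace<uvec>(0, band_freqs.n_elem - 1);
  Rcpp::List a = adtf_cpp(coeffs, band_freqs, dt, all_idx,
                          false, false, false, 1e-12, t_start);
  return a["Q2"];                      // pass the owned SEXP through
}


// piecewise-stationary MVAR sample generator: the active lag-blocked
// coefficient matrix is Acoup where coupled[t] is true, Abase elsewhere;
// E holds the innovations. First p samples stay at E.
// [[Rcpp::export]]
arma::mat simulate_tvmvar_cpp(const arma::mat& Abase, const arma::mat& Acoup,
                              const arma::uvec& coupled, const arma::mat& E,
                              const int p) {
  const uword M = E.n_rows, N = E.n_cols;
  const uword d = static_cast<uword>(M) * p;
  mat y(M, N, fill::zeros);
  vec phi(d);
  for (uword t = static_cast<uword>(p); t < N; ++t) {
    for (int k = 0; k < p; ++k)
      phi.subvec(k * M, k * M + M - 1) = y.col(t - 1 - k);
    y.col(t) = (coupled(t) ? Acoup : Abase) * phi + E.col(t);
  }
  return y;
}
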