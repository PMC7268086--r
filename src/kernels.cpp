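// Compiled kernels: zero-phase IIR filtering of multichannel data and the
// whole-grid beamformer scan. Single-voxel beamforming has a pure-R
// counterpart (vector_beamformer etc.); tests assert agreement.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Direct-form II transposed IIR filter with initial state zi (scaled by
// caller). b and a padded to equal length, a[0] == 1.
static vec lfilter(const vec& b, const vec& a, const vec& x, const vec& zi) {
  const uword n = x.n_elem, m = b.n_elem - 1;
  vec z = zi;
  vec y(n);
  for (uword i = 0; i < n; ++i) {
    double xi = x(i);
    double yi = b(0) * xi + (m > 0 ? z(0) : 0.0);
    for (uword j = 0; j + 1 < m; ++j)
      z(j) = b(j + 1) * xi + z(j + 1) - a(j + 1) * yi;
    if (m > 0) z(m - 1) = b(m) * xi - a(m) * yi;
    y(i) = yi;
  }
  return y;
}

// Steady-state initial conditions for a step input of height 1
// (lfilter_zi construction: solve (I - A^T) zi = b[1:] - a[1:] * b[0]).
static vec lfilter_zi(const vec& b, const vec& a) {
  const uword m = b.n_elem - 1;
  if (m == 0) return vec();
  mat A(m, m, fill::zeros);
  A.col(0) = -a.subvec(1, m);
  for (uword j = 1; j < m; ++j) A(j - 1, j) = 1.0;
  vec B = b.subvec(1, m) - a.subvec(1, m) * b(0);
  return solve(eye(m, m) - A, B);
}

static vec filtfilt_one(const vec& b, const vec& a, const vec& x, uword padlen,
                        const vec& zi) {
  const uword n = x.n_elem;
  vec ext(n + 2 * padlen);
  for (uword i = 0; i < padlen; ++i)
    ext(i) = 2.0 * x(0) - x(padlen - i);
  ext.subvec(padlen, padlen + n - 1) = x;
  for (uword i = 0; i < padlen; ++i)
    ext(padlen + n + i) = 2.0 * x(n - 1) - x(n - 2 - i);
  vec y = lfilter(b, a, ext, zi * ext(0));
  y = reverse(y);
  y = lfilter(b, a, y, zi * y(0));
  y = reverse(y);
  return y.subvec(padlen, padlen + n - 1);
}

// Zero-phase filter each row of X (channels x samples).
// [[Rcpp::export(name = ".cpp_filtfilt_rows")]]
arma::mat cpp_filtfilt_rows(const arma::vec& b_in, const arma::vec& a_in,
                            const arma::mat& X, int padlen) {
  uword m = std::max(b_in.n_elem, a_in.n_elem);
  vec b(m, fill::zeros), a(m, fill::zeros);
  b.head(b_in.n_elem) = b_in;
  a.head(a_in.n_elem) = a_in;
  b /= a(0);
  a /= a(0);
  const uword n = X.n_cols;
  uword pl = std::min<uword>(std::max(padlen, 0), n - 1);
  vec zi = lfilter_zi(b, a);
  mat out(X.n_rows, n);
  for (uword r = 0; r < X.n_rows; ++r)
    out.row(r) = filtfilt_one(b, a, X.row(r).t(), pl, zi).t();
  return out;
}

// Partial-sensor selection: channels with gain-row norm >= min_fraction *
// max norm, expanded to at least min_count channels by descending norm
// (ties by channel index). Returns 0-based indices in ascending order.
static uvec partial_sensors(const vec& rn, double min_fraction,
                            uword min_count) {
  const uword n = rn.n_elem;
  double mx = rn.max();
  uvec keep = find(rn >= min_fraction * mx);
  if (keep.n_elem < std::min(min_count, n)) {
    // stable sort by descending norm, ties by index
    uvec idx = regspace<uvec>(0, n - 1);
    std::stable_sort(idx.begin(), idx.end(),
                     [&](uword i, uword j) { return rn(i) > rn(j); });
    uvec top = idx.head(std::min(min_count, n));
    std::vector<uword> merged(keep.begin(), keep.end());
    merged.insert(merged.end(), top.begin(), top.end());
    std::sort(merged.begin(), merged.end());
    merged.erase(std::unique(merged.begin(), merged.end()), merged.end());
    keep = uvec(merged);
  }
  return sort(keep);
}

// Whole-grid accumulated-source-image scan. data: channels x samples
// (epoch-demeaned, concatenated); C: channel covariance (loaded); L: lead
// field cube channels x 3 x V. Returns per-voxel Asi (sum |Q|), the
// unit-gain deviation in the effective basis, effective rank, and the
// estimated source orientation.
// [[Rcpp::export(name = ".cpp_beamform_scan")]]
Rcpp::List cpp_beamform_scan(const arma::mat& data, const arma::mat& C,
                             const arma::cube& L, double min_fraction,
                             int min_count, double rank_tol) {
  const uword V = L.n_slices, nch = C.n_rows, T = data.n_cols;
  vec asi(V, fill::zeros), gain_err(V, fill::value(datum::nan));
  ivec rank_out(V, fill::zeros);
  mat ori(3, V, fill::zeros);
  mat Wall(V, nch, fill::zeros);  // scalar-beamformer weights, full channels
  for (uword v = 0; v < V; ++v) {
    mat Lv = L.slice(v);
    vec rn = sqrt(sum(square(Lv), 1));
    double mx = rn.max();
    if (!(mx > 0)) continue;  // silent voxel (rank 0)
    uvec sel = partial_sensors(rn, min_fraction, (uword)min_count);
    mat Lsub = Lv.rows(sel);
    mat Csub = C.submat(sel, sel);
    mat U, Vb;
    vec s;
    if (!svd_econ(U, s, Vb, Lsub)) continue;
    uword k = 0;
    for (uword i = 0; i < s.n_elem; ++i)
      if (s(i) > rank_tol * s(0)) ++k;
    if (k < 2) { rank_out(v) = (int)k; continue; }
    mat Vk = Vb.cols(0, k - 1);
    mat Lr = Lsub * Vk;
    mat X = solve(Csub, Lr, solve_opts::likely_sympd);
    mat G = Lr.t() * X;
    mat W = solve(G, X.t());
    gain_err(v) = abs(W * Lr - eye(k, k)).max();
    rank_out(v) = (int)k;
    mat S = W * Csub * W.t();
    S = 0.5 * (S + S.t());
    vec eval;
    mat evec;
    eig_sym(eval, evec, S);
    vec u = evec.col(k - 1);
    vec o3 = Vk * u;
    o3 /= norm(o3);
    uword imax = index_max(abs(o3));
    if (o3(imax) < 0) { o3 = -o3; u = -u; }
    ori.col(v) = o3;
    rowvec w = u.t() * W;
    for (uword i = 0; i < sel.n_elem; ++i) Wall(v, sel(i)) = w(i);
  }
  // accumulate |Q| = |Wall * data| in time chunks
  const uword chunk = std::max<uword>(1, 8000000 / std::max<uword>(V, 1));
  for (uword t0 = 0; t0 < T; t0 += chunk) {
    uword t1 = std::min(T, t0 + chunk) - 1;
    asi += sum(abs(Wall * data.cols(t0, t1)), 1);
  }
  return Rcpp::List::create(Rcpp::Named("asi") = asi,
                            Rcpp::Named("gain_err") = gain_err,
                            Rcpp::Named("rank") = rank_out,
                            Rcpp::Named("orientation") = ori);
}

// Row-wise median and MAD (median absolute deviation, unscaled) for the
// spike-rejection baseline.
// [[Rcpp::export(name = ".cpp_row_median_mad")]]
Rcpp::List cpp_row_median_mad(const arma::mat& X) {
  vec med = median(X, 1);
  mat D = abs(X.each_col() - med);
  vec md = median(D, 1);
  return Rcpp::List::create(Rcpp::Named("median") = med,
                            Rcpp::Named("mad") = md);
}
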