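#include <Rcpp.h>
using namespace Rcpp;

// Renormalization accessibility check for one 0-based point.
// mask is the generator in column-major order: allowed[x + nu*y (+ nu^2*z)].
static bool site_accessible(const int *pt, const LogicalVector &mask,
                            int nu, int dim, int kmax) {
  int x[3];
  for (int i = 0; i < dim; ++i) x[i] = pt[i];
  // start at the point's stage (largest coordinate decides), capped at kmax
  int k = 1;
  long long p = nu;
  for (int i = 0; i < dim; ++i)
    while (x[i] >= p) { p *= nu; ++k; }
  if (k > kmax) return false; // outside the stage-kmax box
  for (; k >= 1; --k) {
    long long unit = 1;
    for (int j = 1; j < k; ++j) unit *= nu;
    long long idx = 0, mult = 1;
    for (int i = 0; i < dim; ++i) {
      int coarse = (int)(x[i] / unit);
      idx += coarse * mult;
      mult *= nu;
      x[i] = (int)(x[i] % unit);
    }
    if (!mask[(R_xlen_t)idx]) return false;
  }
  return true;
}

// [[Rcpp::export]]
LogicalVector cpp_is_accessible(IntegerMatrix pts, LogicalVector mask,
                                int nu, int dim, int kmax) {
  int n = pts.nrow();
  LogicalVector out(n);
  int pt[3];
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < dim; ++i) pt[i] = pts(r, i);
    out[r] = site_accessible(pt, mask, nu, dim, kmax);
  }
  return out;
}

// Blind-ant walk: at each tick propose one of the 2*dim signed unit
// directions uniformly; the move is taken iff the target site is inside the
// bounding box (when a support is given), accessible on the support, and
// within the geometric cap rmax2 (squared displacement from the start);
// otherwise the walker stays put and the tick is consumed.
// has_support = false gives the free (unbounded) lattice walk.
// [[Rcpp::export]]
IntegerMatrix cpp_blind_ant_walk(int nsteps, IntegerVector start,
                                 bool has_support, LogicalVector mask,
                                 int nu, int kmax, double rmax2) {
  int dim = start.size();
  if (dim < 1 || dim > 3) stop("dim must be 1, 2 or 3");
  IntegerMatrix out(nsteps + 1, dim);
  int cur[3], cand[3];
  long long side = 1;
  if (has_support) for (int j = 0; j < kmax; ++j) side *= nu;
  for (int i = 0; i < dim; ++i) { cur[i] = start[i]; out(0, i) = cur[i]; }
  bool capped = R_finite(rmax2);
  GetRNGstate();
  for (int s = 1; s <= nsteps; ++s) {
    int d = (int)(unif_rand() * 2 * dim);
    if (d >= 2 * dim) d = 2 * dim - 1;
    int axis = d >> 1, sgn = (d & 1) ? 1 : -1;
    for (int i = 0; i < dim; ++i) cand[i] = cur[i];
    cand[axis] += sgn;
    bool ok = true;
    if (has_support) {
      if (cand[axis] < 0 || cand[axis] >= side) ok = false;
      else ok = site_accessible(cand, mask, nu, dim, kmax);
    }
    if (ok && capped) {
      double r2 = 0.0;
      for (int i = 0; i < dim; ++i) {
        double dx = (double)cand[i] - (double)start[i];
        r2 += dx * dx;
      }
      if (r2 > rmax2) ok = false;
    }
    if (ok) for (int i = 0; i < dim; ++i) cur[i] = cand[i];
    for (int i = 0; i < dim; ++i) out(s, i) = cur[i];
  }
  PutRNGstate();
  return out;
}

// Variation scan of the subpopulation-averaging minimization:
// for each L in 1..Lmax build the ideal family g_l = gmin + l*(gmax-gmin)/L,
// average A(g_l)*t^{g_l} over l, and OLS-fit the slope of log(mean) on
// x = log(t). Returns cbind(gsub, csub) per L.
// [[Rcpp::export]]
NumericMatrix cpp_scan_family(NumericVector x, double gmin, double gmax,
                              int Lmax, bool gammaPrefactor) {
  int m = x.size();
  double xbar = 0.0;
  for (int i = 0; i < m; ++i) xbar += x[i];
  xbar /= m;
  double sxx = 0.0;
  for (int i = 0; i < m; ++i) sxx += (x[i] - xbar) * (x[i] - xbar);
  NumericMatrix out(Lmax, 2);
  std::vector<double> M(m);
  for (int L = 1; L <= Lmax; ++L) {
    std::fill(M.begin(), M.end(), 0.0);
    double dg = (gmax - gmin) / L;
    for (int l = 1; l <= L; ++l) {
      double g = gmin + dg * l;
      double A = gammaPrefactor ? std::tgamma(g) : 1.0;
      for (int i = 0; i < m; ++i) M[i] += A * std::exp(g * x[i]);
    }
    double ybar = 0.0;
    for (int i = 0; i < m; ++i) ybar += std::log(M[i] / L);
    ybar /= m;
    double sxy = 0.0;
    for (int i = 0; i < m; ++i)
      sxy += (x[i] - xbar) * (std::log(M[i] / L) - ybar);
    out(L - 1, 0) = sxy / sxx;          // gsub
    out(L - 1, 1) = ybar - sxy / sxx * xbar; // csub
  }
  return out;
}
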