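#include <Rcpp.h>
using namespace Rcpp;

// Pairwise quantities on delay-embedded point sets. All loops exclude
// temporally close pairs via a Theiler window on the (possibly strided)
// row index scale supplied by the caller.

// Correlation sums C(r) over a log-spaced radius grid, Chebyshev norm.
// [[Rcpp::export]]
NumericVector cpp_corr_sums(NumericMatrix pts, NumericVector r_grid, int theiler) {
  const int n = pts.nrow(), m = pts.ncol(), G = r_grid.size();
  std::vector<double> hist(G + 1, 0.0);
  double npairs = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + theiler + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(pts(i, k) - pts(j, k));
        if (a > d) d = a;
      }
      ++npairs;
      int lo = 0, hi = G;  // first grid index with r >= d
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (r_grid[mid] < d) lo = mid + 1; else hi = mid;
      }
      hist[lo] += 1.0;
    }
  }
  if (npairs <= 0.0) stop("no valid pairs (Theiler window too wide)");
  NumericVector out(G);
  double acc = 0.0;
  for (int g = 0; g < G; ++g) {
    acc += hist[g];
    out[g] = acc / npairs;
  }
  return out;
}

// Mean log-divergence curve (Rosenstein): for every point find its nearest
// neighbour outside the Theiler window, then track the Euclidean distance of
// the two trajectories k steps forward. curve[k] = mean log distance.
// [[Rcpp::export]]
NumericVector cpp_divergence_curve(NumericMatrix pts, int theiler, int kmax) {
  const int n = pts.nrow(), m = pts.ncol();
  std::vector<int> nn(n, -1);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = -1;
    for (int j = 0; j < n; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = pts(i, k) - pts(j, k);
        d2 += a * a;
      }
      if (d2 > 0.0 && d2 < best) { best = d2; bj = j; }
    }
    nn[i] = bj;
  }
  NumericVector curve(kmax + 1);
  int nvalid = 0;
  for (int k = 0; k <= kmax; ++k) {
    double s = 0.0;
    int cnt = 0;
    for (int i = 0; i < n; ++i) {
      int j = nn[i];
      if (j < 0 || i + k >= n || j + k >= n) continue;
      double d2 = 0.0;
      for (int c = 0; c < m; ++c) {
        double a = pts(i + k, c) - pts(j + k, c);
        d2 += a * a;
      }
      if (d2 > 0.0) { s += 0.5 * std::log(d2); ++cnt; }
    }
    curve[k] = cnt > 0 ? s / cnt : NA_REAL;
    if (cnt > 0) ++nvalid;
  }
  if (nvalid == 0) stop("no valid neighbour pairs for divergence tracking");
  return curve;
}

// Kennel false-nearest-neighbour fractions for embedding dims 1..max_dim.
// The test for dim m uses the extra coordinate x[i + m*tau].
// [[Rcpp::export]]
NumericVector cpp_fnn_fractions(NumericVector x, int tau, int max_dim,
                                int theiler, double rtol, double atol,
                                int max_points) {
  const int n = x.size();
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  double sig = 0.0;
  for (int i = 0; i < n; ++i) sig += (x[i] - mu) * (x[i] - mu);
  sig = std::sqrt(sig / (n - 1));
  NumericVector frac(max_dim, NA_REAL);
  for (int m = 1; m <= max_dim; ++m) {
    int N = n - m * tau;  // need coordinate i + m*tau
    if (N < 10) break;
    int stride = 1;
    if (max_points > 0 && N > max_points) stride = (N + max_points - 1) / max_points;
    std::vector<int> idx;
    for (int i = 0; i < N; i += stride) idx.push_back(i);
    const int ni = idx.size();
    int nfalse = 0, ntot = 0;
    // floor on neighbour distances: numerically duplicated points (exact
    // periodic orbits) would otherwise produce 0/0 distance ratios
    const double dmin2 = 1e-16 * sig * sig;
    for (int a = 0; a < ni; ++a) {
      int i = idx[a];
      double best = R_PosInf;
      int bj = -1;
      for (int b = 0; b < ni; ++b) {
        int j = idx[b];
        if (std::abs(i - j) <= theiler) continue;
        double d2 = 0.0;
        for (int k = 0; k < m; ++k) {
          double d = x[i + k * tau] - x[j + k * tau];
          d2 += d * d;
        }
        if (d2 > dmin2 && d2 < best) { best = d2; bj = j; }
      }
      if (bj < 0) continue;
      double rd = std::sqrt(best);
      double extra = std::fabs(x[i + m * tau] - x[bj + m * tau]);
      bool false_nb = (extra / rd > rtol) ||
        (std::sqrt(rd * rd + extra * extra) / sig > atol);
      if (false_nb) ++nfalse;
      ++ntot;
    }
    frac[m - 1] = ntot > 0 ? (double)nfalse / ntot : NA_REAL;
  }
  return frac;
}

// Sample entropy template-match counts (Richman–Moorman), Chebyshev norm,
// self-matches excluded. Returns c(A, B): matches at length m+1 and m.
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int N = n - m;  // templates 0..N-1 have both length-m and m+1 vectors
  double A = 0.0, B = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double a = std::fabs(x[i + m] - x[j + m]);
      if (a <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
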