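#include <Rcpp.h>
using namespace Rcpp;

// 2-means clustering in kernel form.  Lloyd's iteration for K = 2 depends on
// the data only through the Gram matrix G = X X^T: the squared distance of
// point i to the centroid of cluster C is
//   G_ii - 2 * S_C(i)/|C| + Q_C/|C|^2,
// with S_C(i) = sum_{j in C} G_ij and Q_C = sum_{i in C} S_C(i).  Working on
// G makes one iteration O(n^2) instead of O(n d), which matters because the
// significance test refits 2-means on hundreds of simulated null datasets.

// One Lloyd run seeded with rows i1, i2 as initial centroids.
// Empty-cluster repair: the point farthest from the surviving centroid is
// moved into the empty cluster.  Ties in assignment go to cluster 1.
// Returns the within-cluster SS; labels written into `lab`.
static double kernel_lloyd2(const double* G, int n, int i1, int i2,
                            std::vector<int>& lab, int max_iter) {
  std::vector<double> S1(n), S2(n), dist1(n), dist2(n);
  // initial assignment: nearest of the two seed rows
  for (int i = 0; i < n; ++i) {
    const double d1 = G[i + (size_t)i * n] - 2.0 * G[i + (size_t)i1 * n] +
      G[i1 + (size_t)i1 * n];
    const double d2 = G[i + (size_t)i * n] - 2.0 * G[i + (size_t)i2 * n] +
      G[i2 + (size_t)i2 * n];
    lab[i] = (d1 <= d2) ? 1 : 2;
  }

  int n1 = 0;
  for (int iter = 0; iter < max_iter; ++iter) {
    n1 = 0;
    for (int i = 0; i < n; ++i) if (lab[i] == 1) ++n1;

    // cluster inner-product sums
    std::fill(S1.begin(), S1.end(), 0.0);
    std::fill(S2.begin(), S2.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double* col = G + (size_t)j * n;
      if (lab[j] == 1) for (int i = 0; i < n; ++i) S1[i] += col[i];
      else             for (int i = 0; i < n; ++i) S2[i] += col[i];
    }
    double Q1 = 0.0, Q2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (lab[i] == 1) Q1 += S1[i]; else Q2 += S2[i];
    }

    bool changed = false;
    if (n1 > 0 && n1 < n) {
      const double c1 = Q1 / ((double)n1 * n1), c2 = Q2 / ((double)(n - n1) * (n - n1));
      for (int i = 0; i < n; ++i) {
        const double gii = G[i + (size_t)i * n];
        dist1[i] = gii - 2.0 * S1[i] / n1 + c1;
        dist2[i] = gii - 2.0 * S2[i] / (n - n1) + c2;
        const int nl = (dist1[i] <= dist2[i]) ? 1 : 2;
        if (nl != lab[i]) { lab[i] = nl; changed = true; }
      }
    } else {
      // one cluster emptied: all points sit with the full-data centroid;
      // push the farthest point into the empty cluster
      const int full = (n1 == 0) ? 2 : 1;
      const double Q = (full == 1) ? Q1 : Q2;
      const double* S = (full == 1) ? S1.data() : S2.data();
      const double cc = Q / ((double)n * n);
      double best = -1.0; int far = 0;
      for (int i = 0; i < n; ++i) {
        const double dd = G[i + (size_t)i * n] - 2.0 * S[i] / n + cc;
        if (dd > best) { best = dd; far = i; }
      }
      lab[far] = (full == 1) ? 2 : 1;
      changed = true;
    }
    if (!changed) break;
  }

  // within-SS at the fixed point: sum_C (sum_{i in C} G_ii - Q_C/|C|)
  n1 = 0;
  for (int i = 0; i < n; ++i) if (lab[i] == 1) ++n1;
  std::fill(S1.begin(), S1.end(), 0.0);
  std::fill(S2.begin(), S2.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    const double* col = G + (size_t)j * n;
    if (lab[j] == 1) for (int i = 0; i < n; ++i) S1[i] += col[i];
    else             for (int i = 0; i < n; ++i) S2[i] += col[i];
  }
  double Q1 = 0.0, Q2 = 0.0, T1 = 0.0, T2 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (lab[i] == 1) { Q1 += S1[i]; T1 += G[i + (size_t)i * n]; }
    else             { Q2 += S2[i]; T2 += G[i + (size_t)i * n]; }
  }
  double wss = 0.0;
  if (n1 > 0) wss += T1 - Q1 / n1;
  if (n1 < n) wss += T2 - Q2 / (n - n1);
  return wss;
}

static double gram_tss(const double* G, int n) {
  double trace = 0.0, total = 0.0;
  for (int j = 0; j < n; ++j) {
    trace += G[j + (size_t)j * n];
    const double* col = G + (size_t)j * n;
    for (int i = 0; i < n; ++i) total += col[i];
  }
  return trace - total / n;
}

// Best-of-restarts 2-means on a Gram matrix.  `inits` is 2 x R, 0-based seed
// row indices; smallest within-SS wins (first on ties: deterministic).
// [[Rcpp::export]]
List cpp_two_means_gram(NumericMatrix G, IntegerMatrix inits, int max_iter = 100) {
  const int n = G.nrow(), R = inits.ncol();
  if (n < 2) stop("two-means needs at least 2 rows");
  const double* g = REAL(G);
  std::vector<int> lab(n), best_lab(n);
  double best = R_PosInf;
  for (int r = 0; r < R; ++r) {
    const double w = kernel_lloyd2(g, n, inits(0, r), inits(1, r), lab, max_iter);
    if (w < best) { best = w; best_lab = lab; }
  }
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) labels[i] = best_lab[i];
  return List::create(_["labels"] = labels, _["within_ss"] = best,
                      _["total_ss"] = gram_tss(g, n));
}

static int sample_index(int n) {
  int i;
  do { i = (int)(unif_rand() * n); } while (i >= n);
  return i;
}

static double best_ci(const double* g, int n, int restarts, int max_iter,
                      std::vector<int>& lab) {
  double best = R_PosInf;
  for (int r = 0; r < restarts; ++r) {
    const int i1 = sample_index(n);
    int i2;
    do { i2 = sample_index(n); } while (i2 == i1);
    const double w = kernel_lloyd2(g, n, i1, i2, lab, max_iter);
    if (w < best) best = w;
  }
  const double tss = gram_tss(g, n);
  return (tss > 0) ? best / tss : NA_REAL;
}

// Null 2-means cluster indices for the single-Gaussian significance test.
// The null is n i.i.d. mean-zero Gaussian vectors in d dimensions with
// diagonal covariance: the estimated (thresholded) eigenvalues
// `lambda_est`, padded with `d_total - k` isotropic dimensions of variance
// `sigma2`.  Since the cluster index depends on the data only through the
// Gram matrix, each null dataset is drawn directly as
//   G = sum_j lambda_j z_j z_j^T + sigma2 * W,   z_j ~ N(0, I_n),
//   W ~ Wishart(I_n, d_total - k),
// which is equal in distribution to X X^T for X with rows
// N(0, diag(lambda)) — the isotropic bulk never has to be materialised.
// W is sampled by the Bartlett decomposition when its degrees of freedom
// allow, otherwise from explicit Gaussian columns.  Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_null_cis(NumericVector lambda_est, double sigma2,
                           int d_total, int n, int nsim, int restarts,
                           int max_iter = 100) {
  const int k = lambda_est.size();
  const int df = d_total - k;
  if (df < 0) stop("more estimated eigenvalues than dimensions");
  NumericVector out(nsim);  // RNG state handled by the generated wrapper
  std::vector<double> G((size_t)n * n), A((size_t)n * n), z(n);
  std::vector<int> lab(n);

  for (int s = 0; s < nsim; ++s) {
    std::fill(G.begin(), G.end(), 0.0);

    if (df >= n) {
      // Bartlett: W = A A^T, A lower-triangular, A_ii^2 ~ chisq(df - i)
      std::fill(A.begin(), A.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        A[j + (size_t)j * n] = std::sqrt(R::rchisq(df - j));
        for (int i = j + 1; i < n; ++i) A[i + (size_t)j * n] = norm_rand();
      }
      for (int j = 0; j < n; ++j) {        // G = sigma2 * A A^T (lower, then mirror)
        for (int i = j; i < n; ++i) {
          double acc = 0.0;
          const int kmax = std::min(i, j);
          for (int l = 0; l <= kmax; ++l)
            acc += A[i + (size_t)l * n] * A[j + (size_t)l * n];
          const double v = sigma2 * acc;
          G[i + (size_t)j * n] = v;
          G[j + (size_t)i * n] = v;
        }
      }
    } else if (df > 0 && sigma2 > 0) {
      for (int c = 0; c < df; ++c) {
        for (int i = 0; i < n; ++i) z[i] = norm_rand();
        for (int j = 0; j < n; ++j) {
          const double zj = sigma2 * z[j];
          for (int i = 0; i < n; ++i) G[i + (size_t)j * n] += z[i] * zj;
        }
      }
    }

    for (int c = 0; c < k; ++c) {          // rank-1 eigen-directions
      const double lam = lambda_est[c];
      for (int i = 0; i < n; ++i) z[i] = norm_rand();
      for (int j = 0; j < n; ++j) {
        const double zj = lam * z[j];
        for (int i = 0; i < n; ++i) G[i + (size_t)j * n] += z[i] * zj;
      }
    }

    out[s] = best_ci(G.data(), n, restarts, max_iter, lab);
  }
  return out;
}
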