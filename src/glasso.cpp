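#include <Rcpp.h>
using namespace Rcpp;

// Graphical lasso by block coordinate descent on the covariance estimate W
// (Friedman-Hastie-Tibshirani).  The diagonal is never penalized, so
// W[j,j] = S[j,j] throughout.  Each column update solves the lasso
//   min_b  0.5 b' W11 b - s12' b + sum_k lam_k |b_k|
// by cyclic coordinate descent, warm-started from the previous sweep.
//
// Convergence: outer loop stops when the largest absolute change of any
// W entry over a full sweep falls below  tol * mean(|S_offdiag|)
// (falling back to tol when S is diagonal).

inline double soft_thr(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
List glasso_cpp(NumericMatrix S, NumericMatrix Lambda,
                double tol, int maxit,
                Nullable<NumericMatrix> W_init = R_NilValue,
                Nullable<NumericMatrix> B_init = R_NilValue) {
  const int p = S.nrow();
  NumericMatrix W(p, p), B(p, p);

  if (W_init.isNotNull()) {
    NumericMatrix Wi(W_init);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) W(i, j) = Wi(i, j);
  } else {
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) W(i, j) = S(i, j);
  }
  for (int j = 0; j < p; ++j) W(j, j) = S(j, j);
  if (B_init.isNotNull()) {
    NumericMatrix Bi(B_init);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) B(i, j) = Bi(i, j);
  }

  double s_off = 0.0; int n_off = 0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) { s_off += std::fabs(S(i, j)); ++n_off; }
  double thr = (n_off > 0 && s_off > 0.0) ? tol * (s_off / n_off) : tol;
  const double inner_thr = thr / 10.0;
  const int inner_maxit = 200;

  bool converged = false;
  int iter = 0;
  for (iter = 0; iter < maxit; ++iter) {
    double dW = 0.0;
    for (int j = 0; j < p; ++j) {
      // lasso for column j, coefficients B(k, j), k != j
      for (int in_it = 0; in_it < inner_maxit; ++in_it) {
        double dB = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double grad = S(k, j);
          for (int l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            grad -= W(k, l) * B(l, j);
          }
          double bnew = soft_thr(grad, Lambda(k, j)) / W(k, k);
          double d = std::fabs(bnew - B(k, j));
          if (d > dB) dB = d;
          B(k, j) = bnew;
        }
        if (dB < inner_thr) break;
      }
      // w12 = W11 * beta
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double wk = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          wk += W(k, l) * B(l, j);
        }
        double d = std::fabs(wk - W(k, j));
        if (d > dW) dW = d;
        W(k, j) = wk;
        W(j, k) = wk;
      }
    }
    if (dW < thr) { converged = true; ++iter; break; }
  }

  // Recover the precision matrix from (W, B)
  NumericMatrix K(p, p);
  for (int j = 0; j < p; ++j) {
    double denom = W(j, j);
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      denom -= W(k, j) * B(k, j);
    }
    K(j, j) = 1.0 / denom;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      K(k, j) = -B(k, j) / denom;
    }
  }
  // symmetrize (exact zeros preserved when both directions are zero)
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      double v = 0.5 * (K(i, j) + K(j, i));
      K(i, j) = v;
      K(j, i) = v;
    }

  return List::create(_["wi"] = K, _["w"] = W, _["beta"] = B,
                      _["niter"] = iter, _["converged"] = converged);
}

// Per-rotation maxima of absolute off-diagonal correlations after
// independently permuting the rows of every column (columns are
// standardized internally).  Reproducible under set.seed().

// [[Rcpp::export]]
NumericVector rotation_maxcor_cpp(NumericMatrix Z, int n_rotations) {
  const int n = Z.nrow(), p = Z.ncol();
  NumericVector out(n_rotations);
  std::vector<double> zs(static_cast<size_t>(n) * p);
  for (int j = 0; j < p; ++j) {
    double m = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) m += Z(i, j);
    m /= n;
    for (int i = 0; i < n; ++i) {
      double d = Z(i, j) - m;
      ss += d * d;
    }
    double s = std::sqrt(ss / (n - 1));
    if (s <= 0) s = 1.0;
    double* col = &zs[static_cast<size_t>(j) * n];
    for (int i = 0; i < n; ++i) col[i] = (Z(i, j) - m) / s;
  }
  std::vector<double> buf(static_cast<size_t>(n) * p);
  std::vector<int> idx(n);
  // fast internal generator (xorshift64*), seeded once from R's RNG so
  // the whole call is reproducible under set.seed()
  RNGScope scope;
  uint64_t state = static_cast<uint64_t>(unif_rand() * 4294967296.0) << 32;
  state ^= static_cast<uint64_t>(unif_rand() * 4294967296.0);
  state |= 1ULL;
  auto next_u64 = [&state]() {
    state ^= state >> 12;
    state ^= state << 25;
    state ^= state >> 27;
    return state * 2685821657736338717ULL;
  };
  for (int r = 0; r < n_rotations; ++r) {
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i) idx[i] = i;
      for (int i = n - 1; i > 0; --i) {
        int k = static_cast<int>(next_u64() % static_cast<uint64_t>(i + 1));
        std::swap(idx[i], idx[k]);
      }
      double* col = &buf[static_cast<size_t>(j) * n];
      const double* src = &zs[static_cast<size_t>(j) * n];
      for (int i = 0; i < n; ++i) col[i] = src[idx[i]];
    }
    double best = 0.0;
    for (int a = 0; a < p - 1; ++a) {
      const double* ca = &buf[static_cast<size_t>(a) * n];
      for (int b = a + 1; b < p; ++b) {
        const double* cb = &buf[static_cast<size_t>(b) * n];
        double dot = 0.0;
        for (int i = 0; i < n; ++i) dot += ca[i] * cb[i];
        double r_ab = std::fabs(dot / (n - 1));
        if (r_ab > best) best = r_ab;
      }
    }
    out[r] = best;
  }
  return out;
}

// Nonparanormal transform of one matrix: per column, mid-ranks r
// (average over ties), u = r / (n + 1) Winsorized at [delta, 1 - delta],
// normal quantile, then centered and scaled to unit variance.

// [[Rcpp::export]]
NumericMatrix npn_transform_cpp(NumericMatrix X, double delta) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out(n, p);
  std::vector<int> ord(n);
  std::vector<double> rnk(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&X, j](int a, int b) { return X(a, j) < X(b, j); });
    int i = 0;
    while (i < n) {
      int k = i;
      while (k + 1 < n && X(ord[k + 1], j) == X(ord[i], j)) ++k;
      double mid = 0.5 * (i + k) + 1.0;   // average of ranks i+1 .. k+1
      for (int t = i; t <= k; ++t) rnk[ord[t]] = mid;
      i = k + 1;
    }
    double m = 0.0, ss = 0.0;
    for (int i2 = 0; i2 < n; ++i2) {
      double u = rnk[i2] / (n + 1.0);
      if (u < delta) u = delta;
      if (u > 1.0 - delta) u = 1.0 - delta;
      double q = R::qnorm(u, 0.0, 1.0, 1, 0);
      out(i2, j) = q;
      m += q;
    }
    m /= n;
    for (int i2 = 0; i2 < n; ++i2) {
      double d = out(i2, j) - m;
      ss += d * d;
    }
    double s = std::sqrt(ss / (n - 1));
    for (int i2 = 0; i2 < n; ++i2) out(i2, j) = (out(i2, j) - m) / s;
  }
  return out;
}
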