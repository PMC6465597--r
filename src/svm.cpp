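// Compiled kernels for pairwise linear-SVM decoding and cluster search.
//
// The decoding problem is millions of tiny two-class SVM fits (<= ~60 training
// points), so the dual is solved directly with SMO on a precomputed Gram
// matrix rather than through per-fit calls into an external library.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Sequential minimal optimization for the C-SVM dual with a precomputed
// Gram matrix K and labels y in {-1,+1}. Returns alpha; b via reference.
static vec smo_solve(const mat& K, const vec& y, double C, double& b_out,
                     double tol = 1e-8, int max_clean_passes = 3,
                     int max_sweeps = 2000) {
  const int n = K.n_rows;
  vec alpha(n, fill::zeros);
  double b = 0.0;

  auto fval = [&](int i) {
    double s = b;
    for (int j = 0; j < n; ++j)
      if (alpha[j] != 0.0) s += alpha[j] * y[j] * K(j, i);
    return s;
  };

  // Attempt the analytic pairwise update on (i, j); returns true on progress.
  auto try_update = [&](int i, int j, double Ei) {
    double Ej = fval(j) - y[j];
    double ai_old = alpha[i], aj_old = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    if (H - L < 1e-12) return false;
    double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
    if (eta > -1e-12) return false;
    double aj = aj_old - y[j] * (Ei - Ej) / eta;
    aj = std::min(H, std::max(L, aj));
    if (std::fabs(aj - aj_old) < 1e-12) return false;
    double ai = ai_old + y[i] * y[j] * (aj_old - aj);
    alpha[i] = ai; alpha[j] = aj;
    double b1 = b - Ei - y[i] * (ai - ai_old) * K(i, i) - y[j] * (aj - aj_old) * K(i, j);
    double b2 = b - Ej - y[i] * (ai - ai_old) * K(i, j) - y[j] * (aj - aj_old) * K(j, j);
    if (ai > 0 && ai < C) b = b1;
    else if (aj > 0 && aj < C) b = b2;
    else b = 0.5 * (b1 + b2);
    return true;
  };

  int clean = 0, sweeps = 0;
  while (clean < max_clean_passes && sweeps < max_sweeps) {
    ++sweeps;
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double Ei = fval(i) - y[i];
      if (!((y[i] * Ei < -tol && alpha[i] < C) ||
            (y[i] * Ei > tol && alpha[i] > 0)))
        continue;
      // second-choice heuristic: maximize |Ei - Ej|, falling back to every
      // other index so a failed first choice cannot stall convergence
      int jbest = -1; double dbest = -1.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double d = std::fabs(Ei - (fval(j) - y[j]));
        if (d > dbest) { dbest = d; jbest = j; }
      }
      bool ok = jbest >= 0 && try_update(i, jbest, Ei);
      if (!ok) {
        for (int j = 0; j < n && !ok; ++j)
          if (j != i && j != jbest) ok = try_update(i, j, Ei);
      }
      if (ok) ++changed;
    }
    if (changed == 0) ++clean; else clean = 0;
  }

  // Recompute the bias from the converged alphas (KKT interval midpoint when
  // no free support vector exists).
  vec f0(n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j)
      if (alpha[j] != 0.0) s += alpha[j] * y[j] * K(j, i);
    f0[i] = s;
  }
  const double eps = 1e-9 * std::max(1.0, C);
  double sum_free = 0.0; int n_free = 0;
  double lo = -datum::inf, hi = datum::inf;
  for (int i = 0; i < n; ++i) {
    double u = y[i] - f0[i];
    bool at0 = alpha[i] <= eps, atC = alpha[i] >= C - eps;
    if (!at0 && !atC) { sum_free += u; ++n_free; }
    else if ((y[i] > 0 && at0) || (y[i] < 0 && atC)) lo = std::max(lo, u);
    else hi = std::min(hi, u);
  }
  if (n_free > 0) b = sum_free / n_free;
  else if (std::isfinite(lo) && std::isfinite(hi)) b = 0.5 * (lo + hi);
  else if (std::isfinite(lo)) b = lo;
  else if (std::isfinite(hi)) b = hi;
  b_out = b;
  return alpha;
}

// Train a linear C-SVM on rows of X (n x d) with labels y in {-1,+1}.
// Exposed for cross-checking against an independent libsvm fit.
// [[Rcpp::export]]
Rcpp::List cpp_svm_train(const arma::mat& X, const arma::vec& y, double C) {
  mat K = X * X.t();
  double b;
  vec alpha = smo_solve(K, y, C, b);
  vec w = X.t() * (alpha % y);
  return Rcpp::List::create(Rcpp::Named("w") = w,
                            Rcpp::Named("b") = b,
                            Rcpp::Named("alpha") = alpha);
}

// Fold schedule shared by the 1-D and temporal-generalization decoders:
// fold k holds out pseudo-trial k of each class; training uses the remaining
// 2(N-1) pattern vectors. Classification: sign(w.x + b), ties -> class A.
// Returns per-fold weight vectors/biases at training time t via out params.
static void train_folds_at_t(const mat& Xa, const mat& Xb, double C,
                             mat& W, vec& bvec) {
  const int N = Xa.n_rows, S = Xa.n_cols;
  mat X2(2 * N, S);
  X2.rows(0, N - 1) = Xa;
  X2.rows(N, 2 * N - 1) = Xb;
  vec y2(2 * N);
  y2.head(N).fill(1.0);
  y2.tail(N).fill(-1.0);
  mat G = X2 * X2.t();
  W.set_size(N, S); bvec.set_size(N);
  uvec all = regspace<uvec>(0, 2 * N - 1);
  for (int k = 0; k < N; ++k) {
    uvec keep(2 * (N - 1));
    int c = 0;
    for (int i = 0; i < 2 * N; ++i)
      if (i != k && i != N + k) keep[c++] = i;
    mat Ksub = G.submat(keep, keep);
    vec ysub = y2.elem(keep);
    double b;
    vec alpha = smo_solve(Ksub, ysub, C, b);
    vec w = X2.rows(keep).t() * (alpha % ysub);
    W.row(k) = w.t();
    bvec[k] = b;
  }
}

// Leave-one-out pairwise decoding accuracy (%) at every time point.
// A, B: cubes [N x S x T] of pseudo-trials for the two images.
// [[Rcpp::export]]
arma::vec cpp_pair_decode(const arma::cube& A, const arma::cube& B, double C) {
  const int N = A.n_rows, T = A.n_slices;
  if ((int)B.n_rows != N || B.n_cols != A.n_cols || (int)B.n_slices != T)
    Rcpp::stop("pseudo-trial sets must have identical dimensions");
  if (N < 2) Rcpp::stop("need at least 2 pseudo-trials per image");
  vec acc(T);
  mat W; vec bvec;
  for (int t = 0; t < T; ++t) {
    train_folds_at_t(A.slice(t), B.slice(t), C, W, bvec);
    int correct = 0;
    for (int k = 0; k < N; ++k) {
      double da = dot(W.row(k), A.slice(t).row(k)) + bvec[k];
      double db = dot(W.row(k), B.slice(t).row(k)) + bvec[k];
      if (da >= 0) ++correct;       // class A predicted on tie
      if (db < 0) ++correct;
    }
    acc[t] = 100.0 * correct / (2.0 * N);
  }
  return acc;
}

// Temporal generalization: classifiers trained per fold at time t (the same
// fold schedule and solutions as the diagonal run) are tested on the held-out
// pseudo-trials at every time t'. Row = training time, column = testing time;
// the diagonal reproduces cpp_pair_decode exactly.
// [[Rcpp::export]]
arma::mat cpp_pair_tempgen(const arma::cube& A, const arma::cube& B, double C) {
  const int N = A.n_rows, T = A.n_slices;
  if ((int)B.n_rows != N || B.n_cols != A.n_cols || (int)B.n_slices != T)
    Rcpp::stop("pseudo-trial sets must have identical dimensions");
  if (N < 2) Rcpp::stop("need at least 2 pseudo-trials per image");
  mat acc(T, T);
  mat W; vec bvec;
  for (int t = 0; t < T; ++t) {
    train_folds_at_t(A.slice(t), B.slice(t), C, W, bvec);
    for (int u = 0; u < T; ++u) {
      int correct = 0;
      for (int k = 0; k < N; ++k) {
        double da = dot(W.row(k), A.slice(u).row(k)) + bvec[k];
        double db = dot(W.row(k), B.slice(u).row(k)) + bvec[k];
        if (da >= 0) ++correct;
        if (db < 0) ++correct;
      }
      acc(t, u) = 100.0 * correct / (2.0 * N);
    }
  }
  return acc;
}

// Per-row maximum run length of entries strictly above `thresh`
// (null distribution of the 1-D max cluster size under sign flips).
// [[Rcpp::export]]
arma::ivec cpp_max_run(const arma::mat& X, double thresh) {
  ivec out(X.n_rows);
  for (uword r = 0; r < X.n_rows; ++r) {
    int best = 0, cur = 0;
    for (uword c = 0; c < X.n_cols; ++c) {
      if (X(r, c) > thresh) { if (++cur > best) best = cur; }
      else cur = 0;
    }
    out[r] = best;
  }
  return out;
}

// 4-connected component labelling of a logical matrix (0 = background).
// [[Rcpp::export]]
arma::imat cpp_label_components(const arma::umat& M) {
  const int nr = M.n_rows, nc = M.n_cols;
  imat lab(nr, nc, fill::zeros);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!M(i, j) || lab(i, j)) continue;
    ++next;
    stack.push_back(i + j * nr);
    lab(i, j) = next;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int pi = p % nr, pj = p / nr;
      const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
      for (int q = 0; q < 4; ++q) {
        int qi = pi + di[q], qj = pj + dj[q];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        if (M(qi, qj) && !lab(qi, qj)) {
          lab(qi, qj) = next;
          stack.push_back(qi + qj * nr);
        }
      }
    }
  }
  return lab;
}

// For each row of Tperm (a flattened nr x nc t-map, column-major), the size
// of the largest 4-connected component of entries strictly above `thresh`.
// [[Rcpp::export]]
arma::ivec cpp_perm_max_component(const arma::mat& Tperm, int nr, int nc,
                                  double thresh) {
  if ((int)Tperm.n_cols != nr * nc)
    Rcpp::stop("Tperm columns must equal nr * nc");
  ivec out(Tperm.n_rows);
  for (uword r = 0; r < Tperm.n_rows; ++r) {
    umat M(nr, nc);
    for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i)
      M(i, j) = Tperm(r, i + j * nr) > thresh ? 1u : 0u;
    imat lab = cpp_label_components(M);
    int k = lab.max();
    int best = 0;
    if (k > 0) {
      std::vector<int> cnt(k + 1, 0);
      for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i)
        if (lab(i, j)) ++cnt[lab(i, j)];
      for (int q = 1; q <= k; ++q) best = std::max(best, cnt[q]);
    }
    out[r] = best;
  }
  return out;
}
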