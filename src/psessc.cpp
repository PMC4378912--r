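#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Canonical + wobble pairing over A/C/G/U.
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pairing (Nussinov) fold with a minimum hairpin loop.
// Traceback is deterministic: a position pairs with the largest admissible
// partner achieving the optimum, otherwise stays unpaired; bifurcation is
// implicit in the pair recursion (the split happens at the chosen partner).
// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
std::string nussinov_fold_cpp(std::string seq, int min_loop) {
  int L = seq.size();
  if (L == 0) stop("empty sequence");
  std::vector<std::vector<int> > N(L, std::vector<int>(L, 0));
  for (int span = min_loop + 1; span < L; ++span) {
    for (int i = 0; i + span < L; ++i) {
      int j = i + span;
      int best = N[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int inner = (k - i > 1) ? N[i + 1][k - 1] : 0;
        int outer = (k < j) ? N[k + 1][j] : 0;
        int v = inner + 1 + outer;
        if (v > best) best = v;
      }
      N[i][j] = best;
    }
  }
  std::string db(L, '.');
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, L - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (N[i][j] == 0) continue;
    int chosen = -1;
    for (int k = j; k > i + min_loop; --k) {  // largest admissible partner
      if (!can_pair(seq[i], seq[k])) continue;
      int inner = (k - i > 1) ? N[i + 1][k - 1] : 0;
      int outer = (k < j) ? N[k + 1][j] : 0;
      if (inner + 1 + outer == N[i][j]) { chosen = k; break; }
    }
    if (chosen < 0) {
      stack.push_back(std::make_pair(i + 1, j));
    } else {
      db[i] = '(';
      db[chosen] = ')';
      if (chosen - i > 1) stack.push_back(std::make_pair(i + 1, chosen - 1));
      if (chosen < j) stack.push_back(std::make_pair(chosen + 1, j));
    }
  }
  return db;
}

static inline double rbf(const NumericMatrix& A, int i,
                         const NumericMatrix& B, int j, double gamma) {
  double s = 0.0;
  int d = A.ncol();
  for (int t = 0; t < d; ++t) {
    double diff = A(i, t) - B(j, t);
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

// C-SVC with an RBF kernel, solved by SMO with maximal-violating-pair
// working-set selection and the usual duality-gap stopping rule. Dense
// kernel matrix: intended for the few-thousand-sample scale of this
// package's benchmarks.
// [[Rcpp::export(name = ".svm_smo_cpp")]]
List svm_smo_cpp(NumericMatrix X, NumericVector y, double C, double gamma,
                 double tol, int max_iter) {
  int n = X.nrow();
  if (n < 2) stop("need at least 2 training samples");
  std::vector<std::vector<double> > K(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      K[i][j] = K[j][i] = rbf(X, i, X, j, gamma);

  std::vector<double> alpha(n, 0.0), G(n, -1.0);  // G = Q alpha - e
  int iter = 0;
  bool converged = false;
  double m_up = 0.0, m_low = 0.0;
  while (iter < max_iter) {
    // maximal violating pair over I_up / I_low
    int i = -1, j = -1;
    double gmax = -INFINITY, gmin = INFINITY;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (in_up && v > gmax) { gmax = v; i = t; }
      if (in_low && v < gmin) { gmin = v; j = t; }
    }
    m_up = gmax; m_low = gmin;
    if (i < 0 || j < 0 || gmax - gmin < tol) { converged = true; break; }

    double Ei = y[i] * G[i], Ej = y[j] * G[j];
    double eta = K[i][i] + K[j][j] - 2.0 * K[i][j];
    if (eta <= 0) eta = 1e-12;
    double ai = alpha[i], aj = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj - ai);
      H = std::min(C, C + aj - ai);
    } else {
      L = std::max(0.0, ai + aj - C);
      H = std::min(C, ai + aj);
    }
    double aj_new = aj + y[j] * (Ei - Ej) / eta;
    if (aj_new > H) aj_new = H;
    if (aj_new < L) aj_new = L;
    double ai_new = ai + y[i] * y[j] * (aj - aj_new);
    // snap to the box: near-boundary residues (e.g. 1e-20) would otherwise
    // keep positions in the working sets with no room to move
    double snap = 1e-10 * C;
    if (aj_new < snap) aj_new = 0.0;
    if (aj_new > C - snap) aj_new = C;
    if (ai_new < snap) ai_new = 0.0;
    if (ai_new > C - snap) ai_new = C;
    double dai = ai_new - ai, daj = aj_new - aj;
    if (std::fabs(dai) < 1e-14 && std::fabs(daj) < 1e-14) {
      converged = true;  // pair cannot move: box-constrained optimum
      break;
    }
    alpha[i] = ai_new;
    alpha[j] = aj_new;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * y[i] * K[t][i] * dai + y[t] * y[j] * K[t][j] * daj;
    ++iter;
  }

  // intercept from free support vectors, midpoint of the bounds otherwise
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      b += -y[t] * G[t];
      ++nfree;
    }
  }
  if (nfree > 0) b /= nfree; else b = (m_up + m_low) / 2.0;

  return List::create(Named("alpha") = NumericVector(alpha.begin(), alpha.end()),
                      Named("b") = b,
                      Named("iterations") = iter,
                      Named("converged") = converged);
}

// Decision values f(x) = sum_t coef_t K(x_t, x) + b, coef = alpha * y.
// [[Rcpp::export(name = ".svm_decision_cpp")]]
NumericVector svm_decision_cpp(NumericMatrix Xtrain, NumericVector coef,
                               double b, double gamma, NumericMatrix Xnew) {
  int m = Xnew.nrow(), n = Xtrain.nrow();
  if (Xtrain.ncol() != Xnew.ncol()) stop("feature dimension mismatch");
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double s = b;
    for (int t = 0; t < n; ++t) {
      if (coef[t] == 0.0) continue;
      s += coef[t] * rbf(Xtrain, t, Xnew, q, gamma);
    }
    out[q] = s;
  }
  return out;
}
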