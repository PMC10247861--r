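// Dense numerical kernels for the edge-removal search and the coalescence
// machinery. Sizes are small (N <= ~60 in the dense paths) so direct LAPACK
// solvers are used throughout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static bool connected_bfs(const arma::mat& A) {
  const arma::uword n = A.n_rows;
  if (n == 0) return false;
  std::vector<char> seen(n, 0);
  std::vector<arma::uword> stack;
  stack.push_back(0);
  seen[0] = 1;
  arma::uword count = 1;
  while (!stack.empty()) {
    arma::uword v = stack.back();
    stack.pop_back();
    for (arma::uword u = 0; u < n; ++u) {
      if (A(v, u) > 0.5 && !seen[u]) {
        seen[u] = 1;
        ++count;
        stack.push_back(u);
      }
    }
  }
  return count == n;
}

// [[Rcpp::export]]
bool cpp_connected(const arma::mat& A) {
  return connected_bfs(A);
}

// Sorted eigenvalues of the standard (D - A) and normalized
// (I - D^{-1/2} A D^{-1/2}) Laplacians.
// [[Rcpp::export]]
List cpp_lap_spectra(const arma::mat& A) {
  const arma::uword n = A.n_rows;
  arma::vec k = arma::sum(A, 1);
  if (arma::any(k < 0.5)) stop("graph has an isolated vertex");
  arma::mat L = arma::diagmat(k) - A;
  arma::vec dinv = 1.0 / arma::sqrt(k);
  arma::mat Lam = arma::eye(n, n) - arma::diagmat(dinv) * A * arma::diagmat(dinv);
  arma::vec mu, lam;
  arma::eig_sym(mu, L);
  arma::eig_sym(lam, (Lam + Lam.t()) / 2.0);
  return List::create(_["mu"] = mu, _["lam"] = lam);
}

// Pairwise coalescence times of two coalescing random walkers (one walker
// moves per step, chosen with probability 1/2), solved as a dense linear
// system over the C(N,2) unordered vertex pairs.
// [[Rcpp::export]]
List cpp_coalescence(const arma::mat& A) {
  const arma::uword n = A.n_rows;
  if (n < 2) stop("need at least 2 vertices");
  if (!connected_bfs(A)) stop("graph is disconnected: coalescence times undefined");
  arma::vec deg = arma::sum(A, 1);
  const arma::uword m = n * (n - 1) / 2;

  // pair index: (i<j) -> row of the system
  arma::umat pidx(n, n, arma::fill::zeros);
  {
    arma::uword r = 0;
    for (arma::uword i = 0; i < n; ++i)
      for (arma::uword j = i + 1; j < n; ++j) pidx(i, j) = pidx(j, i) = r++;
  }

  arma::mat M(m, m, arma::fill::zeros);
  arma::vec b(m, arma::fill::ones);
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = i + 1; j < n; ++j) {
      const arma::uword row = pidx(i, j);
      M(row, row) += 1.0;
      for (arma::uword k = 0; k < n; ++k) {
        if (A(i, k) > 0.5 && k != j) M(row, pidx(k, j)) -= 0.5 / deg(i);
        if (A(j, k) > 0.5 && k != i) M(row, pidx(i, k)) -= 0.5 / deg(j);
      }
    }
  }
  arma::vec x = arma::solve(M, b);

  arma::mat tau(n, n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = i + 1; j < n; ++j) tau(i, j) = tau(j, i) = x(pidx(i, j));

  arma::vec tau_i(n, arma::fill::ones);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < n; ++j)
      if (A(i, j) > 0.5) tau_i(i) += tau(i, j) / deg(i);

  arma::vec pi = deg / arma::accu(deg);
  double n_eff = arma::dot(pi, tau_i);
  return List::create(_["tau_pair"] = tau, _["tau_remeet"] = tau_i,
                      _["pi"] = pi, _["n_eff"] = n_eff);
}

// All single-edge removals at vertex v (1-based): for each neighbor u return
// connectivity of the child and, when connected, its normalized-Laplacian
// spectrum. Used by the inner loop of the guided search.
// [[Rcpp::export]]
List cpp_eval_children(const arma::mat& A, int v1) {
  const arma::uword n = A.n_rows;
  const arma::uword v = (arma::uword)(v1 - 1);
  std::vector<arma::uword> nbr;
  for (arma::uword u = 0; u < n; ++u)
    if (A(v, u) > 0.5) nbr.push_back(u);
  List out(nbr.size());
  arma::mat child = A;
  for (size_t c = 0; c < nbr.size(); ++c) {
    arma::uword u = nbr[c];
    child(v, u) = child(u, v) = 0.0;
    bool conn = connected_bfs(child);
    if (conn) {
      arma::vec k = arma::sum(child, 1);
      arma::vec dinv = 1.0 / arma::sqrt(k);
      arma::mat Lam = arma::eye(n, n) -
        arma::diagmat(dinv) * child * arma::diagmat(dinv);
      arma::vec lam;
      arma::eig_sym(lam, (Lam + Lam.t()) / 2.0);
      out[c] = List::create(_["u"] = (int)(u + 1), _["connected"] = true,
                            _["lam"] = lam);
    } else {
      out[c] = List::create(_["u"] = (int)(u + 1), _["connected"] = false,
                            _["lam"] = R_NilValue);
    }
    child(v, u) = child(u, v) = A(v, u);
  }
  return out;
}

// Monte-Carlo estimate of the death-Birth fixation probability with uniform
// initialization. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
int cpp_fixation_mc(const arma::mat& A, double r, int reps) {
  const int n = (int)A.n_rows;
  std::vector<std::vector<int>> nbrs(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) > 0.5) nbrs[i].push_back(j);
  RNGScope scope;
  int fixed = 0;
  std::vector<char> mut(n);
  for (int rep = 0; rep < reps; ++rep) {
    std::fill(mut.begin(), mut.end(), 0);
    int start = (int)(unif_rand() * n);
    if (start >= n) start = n - 1;
    mut[start] = 1;
    int nmut = 1;
    while (nmut > 0 && nmut < n) {
      int v = (int)(unif_rand() * n);
      if (v >= n) v = n - 1;
      const std::vector<int>& nb = nbrs[v];
      double tot = 0.0;
      for (int u : nb) tot += mut[u] ? r : 1.0;
      double x = unif_rand() * tot;
      int chosen = nb.back();
      for (int u : nb) {
        x -= mut[u] ? r : 1.0;
        if (x <= 0.0) { chosen = u; break; }
      }
      if (mut[chosen] != mut[v]) {
        nmut += mut[chosen] ? 1 : -1;
        mut[v] = mut[chosen];
      }
    }
    if (nmut == n) ++fixed;
  }
  return fixed;
}
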