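// Least-squares rigid-body superposition (Kabsch, proper rotations only)
// and batched RMSD kernels used by the fixed-radius clustering loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kabsch_rmsd_mat(const mat& A, const mat& B) {
  // A, B: n x 3, n >= 3
  rowvec ca = mean(A, 0), cb = mean(B, 0);
  mat X = A.each_row() - ca;
  mat Y = B.each_row() - cb;
  mat H = X.t() * Y;               // 3 x 3 covariance
  mat U, V;
  vec s;
  svd(U, s, V, H);
  double d = det(V * U.t()) < 0 ? -1.0 : 1.0;
  // explicit proper rotation + residual RMSD (numerically stable for
  // near-identical structures, unlike the trace identity)
  mat D = eye(3, 3);
  D(2, 2) = d;
  mat R = V * D * U.t();
  mat res = Y - X * R.t();
  return std::sqrt(accu(res % res) / A.n_rows);
}

static mat row_as_coords(const mat& flat, uword i, uword natoms) {
  // flat row layout: x1, y1, z1, x2, ... -> n x 3
  mat out(natoms, 3);
  for (uword a = 0; a < natoms; ++a) {
    out(a, 0) = flat(i, 3 * a);
    out(a, 1) = flat(i, 3 * a + 1);
    out(a, 2) = flat(i, 3 * a + 2);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_kabsch_rmsd(const arma::mat& A, const arma::mat& B) {
  if (A.n_rows != B.n_rows || A.n_cols != 3 || B.n_cols != 3)
    Rcpp::stop("coordinate matrices must be n x 3 with equal n");
  if (A.n_rows < 3) Rcpp::stop("need at least 3 atoms for superposition");
  return kabsch_rmsd_mat(A, B);
}

// RMSD of one reference frame against every row of a flattened frame matrix.
// [[Rcpp::export]]
arma::vec cpp_rmsd_one_to_many(const arma::mat& ref, const arma::mat& flat) {
  uword natoms = ref.n_rows;
  if (flat.n_cols != 3 * natoms)
    Rcpp::stop("flattened frames do not match reference atom count");
  vec out(flat.n_rows);
  for (uword i = 0; i < flat.n_rows; ++i)
    out(i) = kabsch_rmsd_mat(ref, row_as_coords(flat, i, natoms));
  return out;
}

// For each member frame, the maximum pairwise RMSD to the other members
// (used to re-pick cluster centroids as the minimax member).
// [[Rcpp::export]]
arma::vec cpp_rmsd_minimax(const arma::mat& flat, int natoms) {
  uword n = flat.n_rows;
  uword na = (uword)natoms;
  if (flat.n_cols != 3 * na) Rcpp::stop("bad atom count");
  std::vector<mat> coords;
  coords.reserve(n);
  for (uword i = 0; i < n; ++i) coords.push_back(row_as_coords(flat, i, na));
  vec mx(n, fill::zeros);
  for (uword i = 0; i + 1 < n; ++i) {
    for (uword j = i + 1; j < n; ++j) {
      double r = kabsch_rmsd_mat(coords[i], coords[j]);
      if (r > mx(i)) mx(i) = r;
      if (r > mx(j)) mx(j) = r;
    }
  }
  return mx;
}
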