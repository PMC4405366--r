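// Internal-coordinate chain building (NeRF) and batched distance checks
// for the synthetic-ensemble generator.  Angles/torsions are sampled in R
// (keeping all randomness in the R RNG stream); this file only does the
// deterministic geometry.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Build chains from internal coordinates.
// bl: bond lengths, bl[k] = |atom(k-1) - atom(k)|, bl[0] unused.
// th: m x natoms bond angles (deg) at vertex k-1 for atom k; th[,0:1] unused.
// tau: m x natoms torsions (deg) over atoms k-3..k; tau[,0:2] unused.
// Returns m x 3*natoms flattened coordinates (x1, y1, z1, x2, ...).
// [[Rcpp::export]]
arma::mat cpp_chain_build(const arma::vec& bl, const arma::mat& th,
                          const arma::mat& tau) {
  const double D2R = M_PI / 180.0;
  uword m = th.n_rows, n = th.n_cols;
  mat out(m, 3 * n);
  for (uword f = 0; f < m; ++f) {
    vec A(3), B(3), C(3);
    A.zeros();
    B = {bl(1), 0, 0};
    out(f, 0) = 0; out(f, 1) = 0; out(f, 2) = 0;
    out(f, 3) = B(0); out(f, 4) = B(1); out(f, 5) = B(2);
    if (n < 3) continue;
    double t2 = th(f, 2) * D2R;
    C = {bl(1) - bl(2) * std::cos(t2), bl(2) * std::sin(t2), 0};
    out(f, 6) = C(0); out(f, 7) = C(1); out(f, 8) = C(2);
    for (uword k = 3; k < n; ++k) {
      double thr = th(f, k) * D2R;
      double tar = tau(f, k) * D2R;
      vec bc = normalise(C - B);
      vec nvec = normalise(cross(B - A, bc));
      vec mvec = cross(nvec, bc);
      double r = bl(k);
      vec D = C - r * std::cos(thr) * bc
                + r * std::sin(thr) * std::cos(tar) * mvec
                - r * std::sin(thr) * std::sin(tar) * nvec;
      out(f, 3 * k) = D(0); out(f, 3 * k + 1) = D(1);
      out(f, 3 * k + 2) = D(2);
      A = B; B = C; C = D;
    }
  }
  return out;
}

// Minimum distance per frame over atom pairs (from the index set `idx`,
// 1-based into the flattened layout's atom list) whose positions in `idx`
// differ by at least `min_sep`.
// [[Rcpp::export]]
arma::vec cpp_min_nonlocal_dist(const arma::mat& flat,
                                const arma::ivec& idx, int min_sep) {
  uword m = flat.n_rows, n = idx.n_elem;
  vec out(m);
  for (uword f = 0; f < m; ++f) {
    double best = datum::inf;
    for (uword i = 0; i + min_sep < n; ++i) {
      uword ai = (uword)(idx(i) - 1);
      double xi = flat(f, 3 * ai), yi = flat(f, 3 * ai + 1),
             zi = flat(f, 3 * ai + 2);
      for (uword j = i + min_sep; j < n; ++j) {
        uword aj = (uword)(idx(j) - 1);
        double dx = xi - flat(f, 3 * aj), dy = yi - flat(f, 3 * aj + 1),
               dz = zi - flat(f, 3 * aj + 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
    }
    out(f) = std::sqrt(best);
  }
  return out;
}

// Distances per frame for explicit atom pairs (1-based atom indices).
// [[Rcpp::export]]
arma::mat cpp_pair_dists(const arma::mat& flat, const arma::ivec& ai,
                         const arma::ivec& aj) {
  uword m = flat.n_rows, k = ai.n_elem;
  mat out(m, k);
  for (uword f = 0; f < m; ++f) {
    for (uword p = 0; p < k; ++p) {
      uword a = (uword)(ai(p) - 1), b = (uword)(aj(p) - 1);
      double dx = flat(f, 3 * a) - flat(f, 3 * b);
      double dy = flat(f, 3 * a + 1) - flat(f, 3 * b + 1);
      double dz = flat(f, 3 * a + 2) - flat(f, 3 * b + 2);
      out(f, p) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return out;
}
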