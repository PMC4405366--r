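// Clash-avoiding chain growth for the synthetic-ensemble generator.
// Random draws use R's RNG (single stream, so generation is bit-reproducible
// under set.seed); geometry is the same NeRF placement as chain.cpp.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double D2R = M_PI / 180.0;

static vec place(const vec& A, const vec& B, const vec& C, double r,
                 double theta_deg, double tau_deg) {
  double th = theta_deg * D2R, ta = tau_deg * D2R;
  vec bc = normalise(C - B);
  vec n = normalise(cross(B - A, bc));
  vec m = cross(n, bc);
  return C - r * std::cos(th) * bc + r * std::sin(th) * std::cos(ta) * m
           - r * std::sin(th) * std::sin(ta) * n;
}

// uniform on (-180, 180] excluding (lo, hi)
static double runif_excl(double lo, double hi) {
  double gap = hi - lo;
  double u = R::runif(0.0, 360.0 - gap);
  double tau = hi + u;
  return tau > 180.0 ? tau - 360.0 : tau;
}

static bool clash(const mat& placed, int upto, const vec& p, double rad2) {
  // placed: rows = CA positions already grown; check p against rows
  // 0..upto-1 (caller restricts to >= 3-residue separation)
  for (int j = 0; j < upto; ++j) {
    double dx = placed(j, 0) - p(0), dy = placed(j, 1) - p(1),
           dz = placed(j, 2) - p(2);
    if (dx * dx + dy * dy + dz * dz < rad2) return true;
  }
  return false;
}

// Grow CA-trace frames.  states: m x n (0/1).  Returns list(xyz, ok).
// [[Rcpp::export]]
Rcpp::List cpp_grow_ca(const arma::imat& states, double bond,
                       double helix_tau, double tau_jit,
                       double helix_th, double th_jit,
                       double coil_th_lo, double coil_th_hi,
                       double excl_lo, double excl_hi,
                       double radius, int max_retries) {
  uword m = states.n_rows, n = states.n_cols;
  mat out(m, 3 * n, fill::zeros);
  Rcpp::LogicalVector ok(m);
  double rad2 = radius * radius;
  mat ca(n, 3);
  for (uword f = 0; f < m; ++f) {
    bool good = true;
    ca.row(0) = rowvec({0, 0, 0});
    ca.row(1) = rowvec({bond, 0, 0});
    if (n >= 3) {
      double th = states(f, 1) == 1
        ? helix_th + R::runif(-th_jit, th_jit)
        : R::runif(coil_th_lo, coil_th_hi);
      ca.row(2) = rowvec({bond - bond * std::cos(th * D2R),
                          bond * std::sin(th * D2R), 0});
    }
    for (uword i = 3; i < n && good; ++i) {
      bool placed_ok = false;
      for (int t = 0; t <= max_retries; ++t) {
        bool hel_tau = states(f, i - 2) == 1 && states(f, i - 1) == 1;
        bool hel_th = states(f, i - 1) == 1;
        double tau = hel_tau ? helix_tau + R::runif(-tau_jit, tau_jit)
                             : runif_excl(excl_lo, excl_hi);
        double th = hel_th ? helix_th + R::runif(-th_jit, th_jit)
                           : R::runif(coil_th_lo, coil_th_hi);
        vec p = place(ca.row(i - 3).t(), ca.row(i - 2).t(),
                      ca.row(i - 1).t(), bond, th, tau);
        if (!clash(ca, (int)i - 2, p, rad2)) {  // rows 0..i-3
          ca.row(i) = p.t();
          placed_ok = true;
          break;
        }
      }
      if (!placed_ok) good = false;
    }
    ok[f] = good;
    if (good)
      for (uword a = 0; a < n; ++a) {
        out(f, 3 * a) = ca(a, 0);
        out(f, 3 * a + 1) = ca(a, 1);
        out(f, 3 * a + 2) = ca(a, 2);
      }
  }
  return Rcpp::List::create(Rcpp::Named("xyz") = out,
                            Rcpp::Named("ok") = ok);
}

// Grow N-CA-C backbone frames; excluded volume applies to CA atoms.
// [[Rcpp::export]]
Rcpp::List cpp_grow_ncac(const arma::imat& states,
                         double helix_phi, double helix_psi, double jit,
                         double phi_lo, double phi_hi,
                         double psi_lo, double psi_hi,
                         double radius, int max_retries) {
  // bond lengths / angles: C-N 1.329, N-CA 1.458, CA-C 1.525 A;
  // CA-C-N 116.2, C-N-CA 121.7, N-CA-C 111.0 deg
  const double bCN = 1.329, bNCA = 1.458, bCAC = 1.525;
  const double aCACN = 116.2, aCNCA = 121.7, aNCAC = 111.0;
  uword m = states.n_rows, n = states.n_cols;
  mat out(m, 9 * n, fill::zeros);
  Rcpp::LogicalVector ok(m);
  double rad2 = radius * radius;
  mat atoms(3 * n, 3);   // N, CA, C per residue
  mat ca(n, 3);
  for (uword f = 0; f < m; ++f) {
    bool good = true;
    // residue 1: N at origin, CA on x, C in plane
    atoms.row(0) = rowvec({0, 0, 0});
    atoms.row(1) = rowvec({bNCA, 0, 0});
    atoms.row(2) = rowvec({bNCA - bCAC * std::cos(aNCAC * D2R),
                           bCAC * std::sin(aNCAC * D2R), 0});
    ca.row(0) = atoms.row(1);
    std::vector<double> phi(n, NA_REAL);
    // phi of residue 1 is undefined; coil draw kept for bookkeeping only
    phi[0] = R::runif(-180.0, 180.0);
    for (uword i = 1; i < n && good; ++i) {
      bool placed_ok = false;
      for (int t = 0; t <= max_retries; ++t) {
        // psi of residue i-1
        double psi;
        if (states(f, i - 1) == 1) {
          psi = helix_psi + R::runif(-jit, jit);
        } else {
          bool phi_in = phi[i - 1] > phi_lo && phi[i - 1] < phi_hi;
          psi = phi_in ? runif_excl(psi_lo, psi_hi)
                       : R::runif(-180.0, 180.0);
        }
        vec N = place(atoms.row(3 * (i - 1)).t(),
                      atoms.row(3 * (i - 1) + 1).t(),
                      atoms.row(3 * (i - 1) + 2).t(), bCN, aCACN, psi);
        vec CA = place(atoms.row(3 * (i - 1) + 1).t(),
                       atoms.row(3 * (i - 1) + 2).t(), N, bNCA, aCNCA,
                       180.0);
        double ph = states(f, i) == 1 ? helix_phi + R::runif(-jit, jit)
                                      : R::runif(-180.0, 180.0);
        vec C = place(atoms.row(3 * (i - 1) + 2).t(), N, CA, bCAC, aNCAC,
                      ph);
        if (i < 3 || !clash(ca, (int)i - 2, CA, rad2)) {
          atoms.row(3 * i) = N.t();
          atoms.row(3 * i + 1) = CA.t();
          atoms.row(3 * i + 2) = C.t();
          ca.row(i) = CA.t();
          phi[i] = ph;
          placed_ok = true;
          break;
        }
      }
      if (!placed_ok) good = false;
    }
    ok[f] = good;
    if (good)
      for (uword a = 0; a < 3 * n; ++a) {
        out(f, 3 * a) = atoms(a, 0);
        out(f, 3 * a + 1) = atoms(a, 1);
        out(f, 3 * a + 2) = atoms(a, 2);
      }
  }
  return Rcpp::List::create(Rcpp::Named("xyz") = out,
                            Rcpp::Named("ok") = ok);
}
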