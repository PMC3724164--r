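#include <Rcpp.h>
using namespace Rcpp;

// Explicit ghost-fluid diffusion step for the MMP field.
//
// Face codes (per direction, precomputed from the level sets):
//   0 = plain interior face: flux = mean(Dc, Dn) * (Mn - Mc) / h^2
//   1 = zero-flux (mirror) face: BM / inert-cell / domain boundary -> flux 0
//   2 = Dirichlet face into a secreting cell: the neighbor is replaced by a
//       ghost value linearly extrapolated through the interface point,
//       ghost = Mb/theta + (1 - 1/theta) * Mc, giving
//       flux = Dc * (Mb - Mc) / (theta * h^2), theta clamped to
//       [theta_min, 1] for explicit stability.
// Inactive nodes (cell interiors, lumen) are copied unchanged.
// [[Rcpp::export]]
NumericMatrix gf_diffusion_step_cpp(const NumericMatrix& M,
                                    const NumericMatrix& D,
                                    const LogicalMatrix& active,
                                    const IntegerMatrix& codeW,
                                    const IntegerMatrix& codeE,
                                    const IntegerMatrix& codeS,
                                    const IntegerMatrix& codeN,
                                    const NumericMatrix& thW,
                                    const NumericMatrix& thE,
                                    const NumericMatrix& thS,
                                    const NumericMatrix& thN,
                                    double dt, double h, double Mb,
                                    double theta_min) {
  const int nx = M.nrow(), ny = M.ncol();
  NumericMatrix out(nx, ny);
  const double c = dt / (h * h);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!active(i, j)) { out(i, j) = M(i, j); continue; }
      const double mc = M(i, j), dc = D(i, j);
      double flux = 0.0;
      int code;

      code = codeW(i, j);
      if (code == 0)
        flux += 0.5 * (dc + D(i - 1, j)) * (M(i - 1, j) - mc);
      else if (code == 2) {
        double th = thW(i, j); if (th < theta_min) th = theta_min;
        flux += dc * (Mb - mc) / th;
      }

      code = codeE(i, j);
      if (code == 0)
        flux += 0.5 * (dc + D(i + 1, j)) * (M(i + 1, j) - mc);
      else if (code == 2) {
        double th = thE(i, j); if (th < theta_min) th = theta_min;
        flux += dc * (Mb - mc) / th;
      }

      code = codeS(i, j);
      if (code == 0)
        flux += 0.5 * (dc + D(i, j - 1)) * (M(i, j - 1) - mc);
      else if (code == 2) {
        double th = thS(i, j); if (th < theta_min) th = theta_min;
        flux += dc * (Mb - mc) / th;
      }

      code = codeN(i, j);
      if (code == 0)
        flux += 0.5 * (dc + D(i, j + 1)) * (M(i, j + 1) - mc);
      else if (code == 2) {
        double th = thN(i, j); if (th < theta_min) th = theta_min;
        flux += dc * (Mb - mc) / th;
      }

      double v = mc + c * flux;
      if (v < 0.0 && v > -1e-12) v = 0.0;  // round-off guard only
      out(i, j) = v;
    }
  }
  return out;
}

// Exact-exponential local reaction/decay update (unconditionally positive):
//   M <- M * exp(-(rM*E + dM) dt)   with E at its step-start value,
//   E <- E * exp(-rE*M dt)          with M at its step-start value.
// [[Rcpp::export]]
List reaction_decay_step_cpp(const NumericMatrix& M, const NumericMatrix& E,
                             double rM, double rE, double dM, double dt,
                             bool freeze_E) {
  const int nx = M.nrow(), ny = M.ncol();
  NumericMatrix Mn(nx, ny), En(nx, ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const double m = M(i, j), e = E(i, j);
      Mn(i, j) = m * std::exp(-(rM * e + dM) * dt);
      En(i, j) = freeze_E ? e : e * std::exp(-rE * m * dt);
    }
  }
  return List::create(_["M"] = Mn, _["E"] = En);
}
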