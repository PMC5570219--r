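// Recursive (bottom-up) evaluation of airway-network input impedance.
//
// Segments arrive in an order where every parent precedes its children,
// so a single reverse sweep visits children before parents.  For each
// segment the downstream admittance (parallel daughters, or the terminal
// tissue element) is combined in series with the distal half of the
// longitudinal impedance, placed in parallel with the gas-compression and
// wall-distension shunts acting at the segment midpoint, and the total is
// put in series with the proximal half of the longitudinal impedance.
//
// A zero downstream admittance marks a non-communicating (collapsed or
// obstructed) branch: the whole branch, shunts included, is pruned, i.e.
// it contributes zero admittance to its parent.

#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

typedef std::complex<double> cplx;

// [[Rcpp::export]]
ComplexVector network_impedance_cpp(IntegerVector parent,      // 1-based, 0 = root
                                    IntegerVector terminal_row, // 1-based into yterm, 0 = internal
                                    NumericVector Rseg,
                                    NumericVector Iseg,
                                    NumericVector Cg,
                                    NumericVector Gw,
                                    NumericVector Hw,
                                    NumericVector alphaw,
                                    ComplexMatrix yterm,        // n_terminal x n_freq
                                    NumericVector omega,
                                    bool gas_shunt,
                                    bool wall_shunt) {
  const int n = parent.size();
  const int nf = omega.size();
  std::vector<cplx> yacc((size_t)n * nf, cplx(0.0, 0.0));
  std::vector<cplx> root(nf, cplx(0.0, 0.0));

  for (int i = n - 1; i >= 0; --i) {
    const int trow = terminal_row[i];
    const int par = parent[i];
    for (int f = 0; f < nf; ++f) {
      cplx ydown;
      if (trow > 0) {
        Rcomplex yt = yterm(trow - 1, f);
        ydown = cplx(yt.r, yt.i);
      } else {
        ydown = yacc[(size_t)i * nf + f];
      }
      cplx ytop(0.0, 0.0);
      if (std::abs(ydown) > 0.0) {
        const double w = omega[f];
        const cplx zhalf(0.5 * Rseg[i], 0.5 * w * Iseg[i]);
        cplx y = 1.0 / (1.0 / ydown + zhalf);
        if (gas_shunt) y += cplx(0.0, w * Cg[i]);
        if (wall_shunt) {
          // constant-phase wall element (Gw - j Hw) / w^alphaw
          const double s = std::pow(w, alphaw[i]);
          y += s / cplx(Gw[i], -Hw[i]);
        }
        ytop = 1.0 / (1.0 / y + zhalf);
      }
      if (par > 0) {
        yacc[(size_t)(par - 1) * nf + f] += ytop;
      } else {
        root[f] = ytop;
      }
    }
  }

  ComplexVector out(nf);
  for (int f = 0; f < nf; ++f) {
    if (std::abs(root[f]) > 0.0) {
      cplx z = 1.0 / root[f];
      out[f].r = z.real();
      out[f].i = z.imag();
    } else {
      out[f].r = R_PosInf;  // fully non-ventilated: flagged by the R wrapper
      out[f].i = R_PosInf;
    }
  }
  return out;
}
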