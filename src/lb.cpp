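// D2Q9 BGK lattice-Boltzmann solver for steady channel flow.
// Full-way bounce-back on solid nodes (walls, ridges, step); parabolic
// velocity inlet at x = 0 (equilibrium at the imposed profile, with the
// density taken from the adjacent fluid column so the inlet pressure can
// adapt); zero-velocity-gradient, fixed-density outlet at x = nx-1
// (populations copied from the neighbour column and rescaled to rho = 1,
// which preserves the velocity exactly and anchors the outlet pressure).
// Works in lattice units; the R layer handles physical unit conversion.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int CX[9] = {0, 1, 0, -1, 0, 1, -1, -1, 1};
static const int CY[9] = {0, 0, 1, 0, -1, 1, 1, -1, -1};
static const int OPP[9] = {0, 3, 4, 1, 2, 7, 8, 5, 6};
static const double W[9] = {4.0 / 9, 1.0 / 9, 1.0 / 9, 1.0 / 9, 1.0 / 9,
                            1.0 / 36, 1.0 / 36, 1.0 / 36, 1.0 / 36};

static inline double feq(int q, double rho, double ux, double uy) {
  double cu = CX[q] * ux + CY[q] * uy;
  double u2 = ux * ux + uy * uy;
  return W[q] * rho * (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * u2);
}

// [[Rcpp::export]]
List cpp_lb_solve(LogicalMatrix solid, NumericVector inlet_ux,
                  NumericMatrix init_ux, double tau, double tol,
                  int max_iter, int check_every) {
  const int nx = solid.nrow(), ny = solid.ncol();
  const double omega = 1.0 / tau;
  std::vector<double> fa((size_t)nx * ny * 9), fb((size_t)nx * ny * 9);
  double* f = fa.data();
  double* fn = fb.data();
  std::vector<char> sol((size_t)nx * ny);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      sol[(size_t)i * ny + j] = solid(i, j) ? 1 : 0;

  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      size_t n = (size_t)i * ny + j;
      double ux = sol[n] ? 0.0 : init_ux(i, j);
      for (int q = 0; q < 9; ++q) {
        fa[n * 9 + q] = feq(q, 1.0, ux, 0.0);
        fb[n * 9 + q] = fa[n * 9 + q];
      }
    }

  std::vector<double> ux_prev((size_t)nx * ny, 0.0), uy_prev((size_t)nx * ny, 0.0);
  double resid = R_PosInf;
  int iter = 0;
  bool converged = false;
  double fpost[9];

  for (iter = 1; iter <= max_iter; ++iter) {
    // fused collide + push-stream
    for (int i = 0; i < nx; ++i)
      for (int j = 0; j < ny; ++j) {
        size_t n = (size_t)i * ny + j;
        const double* fc = &f[n * 9];
        if (sol[n]) {
          for (int q = 0; q < 9; ++q) fpost[q] = fc[OPP[q]];
        } else {
          double rho = 0.0, mx = 0.0, my = 0.0;
          for (int q = 0; q < 9; ++q) {
            rho += fc[q]; mx += fc[q] * CX[q]; my += fc[q] * CY[q];
          }
          double ux = mx / rho, uy = my / rho;
          double u2 = ux * ux + uy * uy;
          for (int q = 0; q < 9; ++q) {
            double cu = CX[q] * ux + CY[q] * uy;
            double fe = W[q] * rho * (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * u2);
            fpost[q] = fc[q] + omega * (fe - fc[q]);
          }
        }
        for (int q = 0; q < 9; ++q) {
          int ti = i + CX[q], tj = j + CY[q];
          if (ti < 0 || ti >= nx || tj < 0 || tj >= ny) continue;
          fn[((size_t)ti * ny + tj) * 9 + q] = fpost[q];
        }
      }
    // outlet: copy neighbour column, rescaled to rho = 1
    for (int j = 0; j < ny; ++j) {
      size_t n = (size_t)(nx - 1) * ny + j;
      size_t m = (size_t)(nx - 2) * ny + j;
      if (sol[n]) continue;
      double rho = 0.0;
      for (int q = 0; q < 9; ++q) rho += fn[m * 9 + q];
      for (int q = 0; q < 9; ++q) fn[n * 9 + q] = fn[m * 9 + q] / rho;
    }
    // inlet: equilibrium at the prescribed parabola, density from column 1
    for (int j = 0; j < ny; ++j) {
      size_t n = (size_t)j;          // i = 0
      size_t m = (size_t)ny + j;     // i = 1
      if (sol[n]) continue;
      double rho = 1.0;
      if (!sol[m]) {
        rho = 0.0;
        for (int q = 0; q < 9; ++q) rho += fn[m * 9 + q];
      }
      for (int q = 0; q < 9; ++q) fn[n * 9 + q] = feq(q, rho, inlet_ux[j], 0.0);
    }
    std::swap(f, fn);

    if (iter % check_every == 0) {
      double maxdiff = 0.0, maxu = 1e-300;
      for (size_t n = 0; n < (size_t)nx * ny; ++n) {
        if (sol[n]) continue;
        const double* fc = &f[n * 9];
        double rho = 0.0, mx = 0.0, my = 0.0;
        for (int q = 0; q < 9; ++q) {
          rho += fc[q]; mx += fc[q] * CX[q]; my += fc[q] * CY[q];
        }
        double ux = mx / rho, uy = my / rho;
        double du = std::fabs(ux - ux_prev[n]), dv = std::fabs(uy - uy_prev[n]);
        if (du > maxdiff) maxdiff = du;
        if (dv > maxdiff) maxdiff = dv;
        double sp = std::fabs(ux) + std::fabs(uy);
        if (sp > maxu) maxu = sp;
        ux_prev[n] = ux; uy_prev[n] = uy;
      }
      resid = maxdiff / maxu;
      if (resid < tol) { converged = true; break; }
    }
  }

  NumericMatrix ux(nx, ny), uy(nx, ny), rho_out(nx, ny);
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      size_t n = (size_t)i * ny + j;
      if (sol[n]) { ux(i, j) = 0.0; uy(i, j) = 0.0; rho_out(i, j) = 1.0; continue; }
      const double* fc = &f[n * 9];
      double rho = 0.0, mx = 0.0, my = 0.0;
      for (int q = 0; q < 9; ++q) {
        rho += fc[q]; mx += fc[q] * CX[q]; my += fc[q] * CY[q];
      }
      ux(i, j) = mx / rho;
      uy(i, j) = my / rho;
      rho_out(i, j) = rho;
    }
  return List::create(_["ux"] = ux, _["uy"] = uy, _["rho"] = rho_out,
                      _["iterations"] = iter, _["residual"] = resid,
                      _["converged"] = converged);
}
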