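// Particle interaction kernels: truncated LJ / soft-core pair force,
// uniform-grid neighbour search over obstacle elements and cells,
// nearest-obstacle queries for the monolayer confinement band.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// Signed pair force, positive = repulsive along the centre line.
// LJ branch written as 48*eps*((s/r)^12 - (s/r)^6): negative (attractive)
// for sigma < r < r_cutoff, zero at r = sigma. Soft-core branch is the
// neo-Hookean contact repulsion with contact radius a(r).
static inline double contact_area_cpp(double r, double r_cell, int variant) {
  if (variant == 1) return std::sqrt(r_cell * (2.0 * r_cell - r)); // caption
  return std::sqrt(0.5 * r_cell * (2.0 * r_cell - r));             // printed
}

static inline double pair_force_cpp(double r, double r_cell, double Cel,
                                    double eps, double sigma, double rcut,
                                    int variant) {
  if (r >= rcut) return 0.0;
  if (r >= 2.0 * r_cell) {
    double q6 = std::pow(sigma / r, 6);
    return 48.0 * eps * (q6 * q6 - q6);
  }
  double a = contact_area_cpp(r, r_cell, variant);
  double num = 8.0 * a * a * a * Cel *
    (16.0 * a * a - 36.0 * PI * a * r_cell + 27.0 * PI * PI * r_cell * r_cell);
  double den = 3.0 * r_cell * std::pow(4.0 * a - 3.0 * PI * r_cell, 2);
  return num / den;
}

// [[Rcpp::export]]
NumericVector cpp_pair_force(NumericVector r, double r_cell, double Cel,
                             double eps, double sigma, double rcut,
                             int variant) {
  int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = pair_force_cpp(r[i], r_cell, Cel, eps, sigma, rcut, variant);
  return out;
}

// ---------------------------------------------------------------------------
// Uniform 3D bin grid over a fixed point set (obstacle elements).
class PointGrid {
public:
  std::vector<double> px, py, pz;
  double ox, oy, oz, cell;
  int nx, ny, nz;
  std::vector<std::vector<int> > bins;

  PointGrid(const NumericMatrix& pts, double cellsize) {
    int n = pts.nrow();
    px.resize(n); py.resize(n); pz.resize(n);
    double xmin = std::numeric_limits<double>::infinity(), ymin = xmin, zmin = xmin;
    double xmax = -xmin, ymax = -xmin, zmax = -xmin;
    for (int i = 0; i < n; ++i) {
      px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
      xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
      ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
      zmin = std::min(zmin, pz[i]); zmax = std::max(zmax, pz[i]);
    }
    cell = cellsize;
    ox = xmin; oy = ymin; oz = zmin;
    nx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
    ny = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
    nz = std::max(1, (int)std::floor((zmax - zmin) / cell) + 1);
    bins.assign((size_t)nx * ny * nz, std::vector<int>());
    for (int i = 0; i < n; ++i) bins[idOf(px[i], py[i], pz[i])].push_back(i);
  }
  inline int clampi(int v, int hi) const { return v < 0 ? 0 : (v >= hi ? hi - 1 : v); }
  inline size_t idOf(double x, double y, double z) const {
    int i = clampi((int)std::floor((x - ox) / cell), nx);
    int j = clampi((int)std::floor((y - oy) / cell), ny);
    int k = clampi((int)std::floor((z - oz) / cell), nz);
    return ((size_t)i * ny + j) * nz + k;
  }
  inline void cellOf(double x, double y, double z, int& i, int& j, int& k) const {
    i = (int)std::floor((x - ox) / cell);
    j = (int)std::floor((y - oy) / cell);
    k = (int)std::floor((z - oz) / cell);
  }
};

// [[Rcpp::export]]
SEXP cpp_point_grid(NumericMatrix pts, double cellsize) {
  XPtr<PointGrid> p(new PointGrid(pts, cellsize), true);
  return p;
}

// Nearest point in the grid for each query position (expanding ring search).
// [[Rcpp::export]]
List cpp_nearest_point(NumericMatrix pos, SEXP gridptr) {
  XPtr<PointGrid> g(gridptr);
  int n = pos.nrow();
  NumericVector dist(n);
  IntegerVector index(n);
  int maxdim = std::max(g->nx, std::max(g->ny, g->nz));
  for (int q = 0; q < n; ++q) {
    double x = pos(q, 0), y = pos(q, 1), z = pos(q, 2);
    int ci, cj, ck;
    g->cellOf(x, y, z, ci, cj, ck);
    double best = std::numeric_limits<double>::infinity();
    int besti = -1;
    for (int ring = 0; ring <= maxdim; ++ring) {
      if (besti >= 0 && (double)(ring - 1) * g->cell > std::sqrt(best)) break;
      for (int i = ci - ring; i <= ci + ring; ++i) {
        if (i < 0 || i >= g->nx) continue;
        for (int j = cj - ring; j <= cj + ring; ++j) {
          if (j < 0 || j >= g->ny) continue;
          for (int k = ck - ring; k <= ck + ring; ++k) {
            if (k < 0 || k >= g->nz) continue;
            // only the shell of the ring
            if (std::max(std::abs(i - ci), std::max(std::abs(j - cj), std::abs(k - ck))) != ring)
              continue;
            const std::vector<int>& b = g->bins[((size_t)i * g->ny + j) * g->nz + k];
            for (size_t m = 0; m < b.size(); ++m) {
              int id = b[m];
              double dx = x - g->px[id], dy = y - g->py[id], dz = z - g->pz[id];
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) { best = d2; besti = id; }
            }
          }
        }
      }
    }
    dist[q] = std::sqrt(best);
    index[q] = besti + 1; // 1-based for R
  }
  return List::create(_["dist"] = dist, _["index"] = index);
}

// Sum of pairwise interaction forces on each cell: cell-cell pairs plus
// cell-obstacle pairs (obstacle elements are immobile and receive no force).
// Coincident mobile-cell pairs (r below 1e-12) are skipped and reported so
// the dynamics layer can perturb them.
// [[Rcpp::export]]
List cpp_interaction_forces(NumericMatrix pos, SEXP obstptr,
                            double r_cell, double Cel, double eps,
                            double sigma, double rcut, int variant) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  std::vector<int> coincident;

  // transient grid over the cells themselves
  if (n > 1) {
    PointGrid cg(pos, rcut);
    for (int i = 0; i < n; ++i) {
      double x = pos(i, 0), y = pos(i, 1), z = pos(i, 2);
      int ci, cj, ck;
      cg.cellOf(x, y, z, ci, cj, ck);
      for (int a = std::max(0, ci - 1); a <= std::min(cg.nx - 1, ci + 1); ++a)
        for (int b = std::max(0, cj - 1); b <= std::min(cg.ny - 1, cj + 1); ++b)
          for (int c = std::max(0, ck - 1); c <= std::min(cg.nz - 1, ck + 1); ++c) {
            const std::vector<int>& bin = cg.bins[((size_t)a * cg.ny + b) * cg.nz + c];
            for (size_t m = 0; m < bin.size(); ++m) {
              int j = bin[m];
              if (j <= i) continue; // each pair once; apply +/- to both
              double dx = x - pos(j, 0), dy = y - pos(j, 1), dz = z - pos(j, 2);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 >= rcut * rcut) continue;
              double r = std::sqrt(r2);
              if (r < 1e-12) { coincident.push_back(i + 1); coincident.push_back(j + 1); continue; }
              double f = pair_force_cpp(r, r_cell, Cel, eps, sigma, rcut, variant);
              double fx = f * dx / r, fy = f * dy / r, fz = f * dz / r;
              F(i, 0) += fx; F(i, 1) += fy; F(i, 2) += fz;
              F(j, 0) -= fx; F(j, 1) -= fy; F(j, 2) -= fz; // Newton's third law
            }
          }
    }
  }

  // cell-obstacle pairs
  if (!Rf_isNull(obstptr)) {
    XPtr<PointGrid> og(obstptr);
    for (int i = 0; i < n; ++i) {
      double x = pos(i, 0), y = pos(i, 1), z = pos(i, 2);
      int ci, cj, ck;
      og->cellOf(x, y, z, ci, cj, ck);
      int reach = (int)std::ceil(rcut / og->cell);
      for (int a = std::max(0, ci - reach); a <= std::min(og->nx - 1, ci + reach); ++a)
        for (int b = std::max(0, cj - reach); b <= std::min(og->ny - 1, cj + reach); ++b)
          for (int c = std::max(0, ck - reach); c <= std::min(og->nz - 1, ck + reach); ++c) {
            const std::vector<int>& bin = og->bins[((size_t)a * og->ny + b) * og->nz + c];
            for (size_t m = 0; m < bin.size(); ++m) {
              int id = bin[m];
              double dx = x - og->px[id], dy = y - og->py[id], dz = z - og->pz[id];
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 >= rcut * rcut || r2 < 1e-24) continue;
              double r = std::sqrt(r2);
              double f = pair_force_cpp(r, r_cell, Cel, eps, sigma, rcut, variant);
              F(i, 0) += f * dx / r; F(i, 1) += f * dy / r; F(i, 2) += f * dz / r;
            }
          }
    }
  }

  return List::create(_["F"] = F, _["coincident"] = wrap(coincident));
}

// External pointers do not survive serialization; the R layer rebuilds the
// grid when the address has been nulled.
// [[Rcpp::export]]
bool cpp_ptr_valid(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != NULL;
}

// Minimum pairwise distance among a point set (diagnostics / tests).
// [[Rcpp::export]]
double cpp_min_pair_distance(NumericMatrix pos) {
  int n = pos.nrow();
  if (n < 2) return R_PosInf;
  double best = std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}
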