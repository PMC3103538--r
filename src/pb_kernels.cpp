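#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Successive over-relaxation for the discrete linearised Poisson-Boltzmann
// operator.  phi holds boundary values on the outer planes (kept fixed) and
// an initial guess inside.  eps[xyz] are link dielectrics (link from node to
// its +x/+y/+z neighbour), kap2h2 is eps_s * kappa^2 * h^2 at ion-accessible
// nodes (0 elsewhere), src_h is 4*pi*332.0637*q/h per node.  Convergence is
// declared when the largest Gauss-Seidel update falls below tol.
// [[Rcpp::export]]
List cpp_sor(NumericVector phi, NumericVector epsx, NumericVector epsy,
             NumericVector epsz, NumericVector kap2h2, NumericVector src_h,
             IntegerVector dims, double tol, int maxit, double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double *p = REAL(phi);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *kp = REAL(kap2h2), *sr = REAL(src_h);
  double maxdiff = 0.0;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    maxdiff = 0.0;
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        for (int i = 1; i < nx - 1; ++i) {
          const int id = idx3(i, j, k, nx, ny);
          const double exm = ex[id - 1], exp_ = ex[id];
          const double eym = ey[id - nx], eyp = ey[id];
          const double ezm = ez[id - nx * ny], ezp = ez[id];
          const double den = exm + exp_ + eym + eyp + ezm + ezp + kp[id];
          const double num = exm * p[id - 1] + exp_ * p[id + 1] +
                             eym * p[id - nx] + eyp * p[id + nx] +
                             ezm * p[id - nx * ny] + ezp * p[id + nx * ny] +
                             sr[id];
          const double upd = omega * (num / den - p[id]);
          p[id] += upd;
          const double a = std::fabs(upd);
          if (a > maxdiff) maxdiff = a;
        }
      }
    }
    if (maxdiff < tol) break;
  }
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["max_update"] = maxdiff,
                      _["converged"] = (maxdiff < tol));
}

// Link dielectric maps.  The solute volume is the van der Waals union of
// the atom spheres; each link's dielectric is the harmonic average of the
// dielectric sampled at NSUB equidistant points along the link (exact for a
// planar interface crossing the link, and much smoother in grid-refinement
// studies than midpoint sampling).  A bitmask per link records which sample
// points lie inside any sphere.  Three full-size arrays are returned; the
// final plane of links in each direction is unused.
#define NSUB 8
// [[Rcpp::export]]
List cpp_eps_links(IntegerVector dims, NumericVector origin, double h,
                   NumericMatrix coords, NumericVector radii,
                   double eps_in, double eps_out) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<unsigned char> bx(n, 0), by(n, 0), bz(n, 0);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  double frac[NSUB];
  for (int m = 0; m < NSUB; ++m) frac[m] = (2.0 * m + 1.0) / (2.0 * NSUB);
  for (int a = 0; a < coords.nrow(); ++a) {
    const double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    const double r = radii[a], r2 = r * r;
    // bounding node box extended by one link length
    const int i0 = std::max(0, (int)std::floor((cx - r - ox) / h) - 1);
    const int i1 = std::min(nx - 1, (int)std::ceil((cx + r - ox) / h) + 1);
    const int j0 = std::max(0, (int)std::floor((cy - r - oy) / h) - 1);
    const int j1 = std::min(ny - 1, (int)std::ceil((cy + r - oy) / h) + 1);
    const int k0 = std::max(0, (int)std::floor((cz - r - oz) / h) - 1);
    const int k1 = std::min(nz - 1, (int)std::ceil((cz + r - oz) / h) + 1);
    for (int k = k0; k <= k1; ++k) {
      const double pz = oz + k * h, dz0 = pz - cz;
      for (int j = j0; j <= j1; ++j) {
        const double py = oy + j * h, dy0 = py - cy;
        for (int i = i0; i <= i1; ++i) {
          const double px = ox + i * h, dx0 = px - cx;
          const int id = idx3(i, j, k, nx, ny);
          if (i < nx - 1) {  // x-link
            const double perp = dy0 * dy0 + dz0 * dz0;
            if (perp <= r2)
              for (int m = 0; m < NSUB; ++m) {
                const double d = dx0 + frac[m] * h;
                if (perp + d * d <= r2) bx[id] |= (1u << m);
              }
          }
          if (j < ny - 1) {  // y-link
            const double perp = dx0 * dx0 + dz0 * dz0;
            if (perp <= r2)
              for (int m = 0; m < NSUB; ++m) {
                const double d = dy0 + frac[m] * h;
                if (perp + d * d <= r2) by[id] |= (1u << m);
              }
          }
          if (k < nz - 1) {  // z-link
            const double perp = dx0 * dx0 + dy0 * dy0;
            if (perp <= r2)
              for (int m = 0; m < NSUB; ++m) {
                const double d = dz0 + frac[m] * h;
                if (perp + d * d <= r2) bz[id] |= (1u << m);
              }
          }
        }
      }
    }
  }
  NumericVector ex(n), ey(n), ez(n);
  double harm[NSUB + 1];
  for (int c = 0; c <= NSUB; ++c) {
    const double f = (double)c / NSUB;
    harm[c] = 1.0 / (f / eps_in + (1.0 - f) / eps_out);
  }
  for (R_xlen_t id = 0; id < n; ++id) {
    int c = 0;
    for (int m = 0; m < NSUB; ++m) c += (bx[id] >> m) & 1u;
    ex[id] = harm[c];
    c = 0;
    for (int m = 0; m < NSUB; ++m) c += (by[id] >> m) & 1u;
    ey[id] = harm[c];
    c = 0;
    for (int m = 0; m < NSUB; ++m) c += (bz[id] >> m) & 1u;
    ez[id] = harm[c];
  }
  return List::create(_["ex"] = ex, _["ey"] = ey, _["ez"] = ez);
}

// Mark grid nodes lying within (radius + extra) of any atom centre.
// [[Rcpp::export]]
IntegerVector cpp_node_mask(IntegerVector dims, NumericVector origin,
                            double h, NumericMatrix coords,
                            NumericVector radii, double extra) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector mask((R_xlen_t)nx * ny * nz, 0);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  for (int a = 0; a < coords.nrow(); ++a) {
    const double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    const double r = radii[a] + extra, r2 = r * r;
    const int i0 = std::max(0, (int)std::ceil((cx - r - ox) / h));
    const int i1 = std::min(nx - 1, (int)std::floor((cx + r - ox) / h));
    const int j0 = std::max(0, (int)std::ceil((cy - r - oy) / h));
    const int j1 = std::min(ny - 1, (int)std::floor((cy + r - oy) / h));
    const int k0 = std::max(0, (int)std::ceil((cz - r - oz) / h));
    const int k1 = std::min(nz - 1, (int)std::floor((cz + r - oz) / h));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) {
          const double dx = ox + i * h - cx;
          const double dy = oy + j * h - cy;
          const double dz = oz + k * h - cz;
          if (dx * dx + dy * dy + dz * dz <= r2)
            mask[idx3(i, j, k, nx, ny)] = 1;
        }
  }
  return mask;
}

// Re-entrant (probe-rolled) correction: nodes inside the solvent-accessible
// envelope (mask_acc, atom radius + probe) that are farther than the probe
// radius from every accessible-exterior node are reassigned to the solute.
// Returns the corrected solute mask given the vdW mask and the envelope.
// [[Rcpp::export]]
IntegerVector cpp_ses_mask(IntegerVector dims, double h,
                           IntegerVector mask_vdw, IntegerVector mask_acc,
                           double probe) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out = clone(mask_vdw);
  const int m = (int)std::ceil(probe / h);
  const double p2 = probe * probe;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int id = idx3(i, j, k, nx, ny);
        if (!mask_acc[id] || mask_vdw[id]) continue;
        bool reachable = false;
        for (int dk = -m; dk <= m && !reachable; ++dk) {
          const int kk = k + dk;
          if (kk < 0 || kk >= nz) { reachable = true; break; }
          for (int dj = -m; dj <= m && !reachable; ++dj) {
            const int jj = j + dj;
            if (jj < 0 || jj >= ny) { reachable = true; break; }
            for (int di = -m; di <= m; ++di) {
              const int ii = i + di;
              if (ii < 0 || ii >= nx) { reachable = true; break; }
              if ((di * di + dj * dj + dk * dk) * h * h > p2) continue;
              if (!mask_acc[idx3(ii, jj, kk, nx, ny)]) {
                reachable = true;
                break;
              }
            }
          }
        }
        if (!reachable) out[id] = 1;
      }
  return out;
}
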