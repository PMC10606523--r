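#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Node-centred grid: node (i,j,k) sits at origin + h*(i,j,k), 0-based,
// linear index i + nx*(j + ny*k). Potentials in kcal/mol/e, charges in e,
// lengths in Angstrom.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (long long)ny * k);
}

static inline double hmean(double a, double b) {
  return 2.0 * a * b / (a + b);
}

// [[Rcpp::export]]
NumericVector cpp_spread_charges(NumericMatrix pos, NumericVector q,
                                 NumericVector origin, double h,
                                 IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector src((long long)nx * ny * nz);
  for (int a = 0; a < pos.nrow(); ++a) {
    double fx = (pos(a, 0) - origin[0]) / h;
    double fy = (pos(a, 1) - origin[1]) / h;
    double fz = (pos(a, 2) - origin[2]) / h;
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
        k0 = (int)std::floor(fz);
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 + 1 >= nx || j0 + 1 >= ny ||
        k0 + 1 >= nz)
      stop("charge outside grid interior");
    double wx = fx - i0, wy = fy - j0, wz = fz - k0;
    for (int di = 0; di <= 1; ++di)
      for (int dj = 0; dj <= 1; ++dj)
        for (int dk = 0; dk <= 1; ++dk) {
          double w = (di ? wx : 1 - wx) * (dj ? wy : 1 - wy) *
                     (dk ? wz : 1 - wz);
          src[idx3(i0 + di, j0 + dj, k0 + dk, nx, ny)] += w * q[a];
        }
  }
  return src;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector grid, IntegerVector dims,
                            NumericVector origin, double h,
                            NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(pts.nrow());
  for (int a = 0; a < pts.nrow(); ++a) {
    double fx = (pts(a, 0) - origin[0]) / h;
    double fy = (pts(a, 1) - origin[1]) / h;
    double fz = (pts(a, 2) - origin[2]) / h;
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
        k0 = (int)std::floor(fz);
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 + 1 >= nx || j0 + 1 >= ny ||
        k0 + 1 >= nz)
      stop("interpolation point outside grid");
    double wx = fx - i0, wy = fy - j0, wz = fz - k0;
    double v = 0;
    for (int di = 0; di <= 1; ++di)
      for (int dj = 0; dj <= 1; ++dj)
        for (int dk = 0; dk <= 1; ++dk) {
          double w = (di ? wx : 1 - wx) * (dj ? wy : 1 - wy) *
                     (dk ? wz : 1 - wz);
          v += w * grid[idx3(i0 + di, j0 + dj, k0 + dk, nx, ny)];
        }
    out[a] = v;
  }
  return out;
}

// Debye-screened monopole sum on the 6 box faces (Dirichlet boundary).
// [[Rcpp::export]]
NumericVector cpp_boundary_phi(NumericMatrix pos, NumericVector q,
                               NumericVector origin, double h,
                               IntegerVector dims, double eps_w,
                               double kappa, double coul) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi((long long)nx * ny * nz);
  int nq = pos.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        double x = origin[0] + i * h, y = origin[1] + j * h,
               z = origin[2] + k * h;
        double v = 0;
        for (int a = 0; a < nq; ++a) {
          double dx = x - pos(a, 0), dy = y - pos(a, 1), dz = z - pos(a, 2);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < 1e-6) r = 1e-6;
          v += coul * q[a] * std::exp(-kappa * r) / (eps_w * r);
        }
        phi[idx3(i, j, k, nx, ny)] = v;
      }
  return phi;
}

// Red-black SOR for sum_f eps_f (phi_n - phi_0) - lambda*salt_0*phi_0 = -b_0
// with b = 4*pi*coul*q/h and lambda = eps_w * kappa^2 * h^2.
// phi carries Dirichlet values on the faces; interior is updated in place.
// [[Rcpp::export]]
List cpp_pb_sor(NumericVector eps, NumericVector salt, NumericVector b,
                NumericVector phi0, IntegerVector dims, double lambda,
                double omega, double tol, int maxit) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(phi0);
  double bnorm = 0;
  for (R_xlen_t t = 0; t < b.size(); ++t) bnorm += b[t] * b[t];
  bnorm = std::sqrt(bnorm);
  if (bnorm < 1e-300) bnorm = 1.0;

  std::vector<double> resHist;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j) {
          int istart = 1 + ((j + k + color) & 1);
          for (int i = istart; i < nx - 1; i += 2) {
            int c = idx3(i, j, k, nx, ny);
            double e0 = eps[c];
            double exm = hmean(e0, eps[c - 1]);
            double exp_ = hmean(e0, eps[c + 1]);
            double eym = hmean(e0, eps[c - nx]);
            double eyp = hmean(e0, eps[c + nx]);
            double ezm = hmean(e0, eps[c - nx * ny]);
            double ezp = hmean(e0, eps[c + nx * ny]);
            double diag = exm + exp_ + eym + eyp + ezm + ezp +
                          lambda * salt[c];
            double off = exm * phi[c - 1] + exp_ * phi[c + 1] +
                         eym * phi[c - nx] + eyp * phi[c + nx] +
                         ezm * phi[c - nx * ny] + ezp * phi[c + nx * ny];
            double newv = (off + b[c]) / diag;
            phi[c] = phi[c] + omega * (newv - phi[c]);
          }
        }
    }
    if (it % 10 == 0 || it == maxit) {
      double rnorm = 0;
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j)
          for (int i = 1; i < nx - 1; ++i) {
            int c = idx3(i, j, k, nx, ny);
            double e0 = eps[c];
            double exm = hmean(e0, eps[c - 1]);
            double exp_ = hmean(e0, eps[c + 1]);
            double eym = hmean(e0, eps[c - nx]);
            double eyp = hmean(e0, eps[c + nx]);
            double ezm = hmean(e0, eps[c - nx * ny]);
            double ezp = hmean(e0, eps[c + nx * ny]);
            double diag = exm + exp_ + eym + eyp + ezm + ezp +
                          lambda * salt[c];
            double off = exm * phi[c - 1] + exp_ * phi[c + 1] +
                         eym * phi[c - nx] + eyp * phi[c + nx] +
                         ezm * phi[c - nx * ny] + ezp * phi[c + nx * ny];
            double r = b[c] + off - diag * phi[c];
            rnorm += r * r;
          }
      rnorm = std::sqrt(rnorm) / bnorm;
      resHist.push_back(rnorm);
      if (rnorm < tol) { converged = true; break; }
    }
  }
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["converged"] = converged,
                      _["residuals"] = NumericVector(resHist.begin(),
                                                     resHist.end()));
}

// Inflate atoms by per-atom radius; mask = 1 where a node lies within
// radius[a] of atom a for some a.
// [[Rcpp::export]]
IntegerVector cpp_inflate(NumericMatrix pos, NumericVector radius,
                          NumericVector origin, double h,
                          IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector mask((long long)nx * ny * nz);
  for (int a = 0; a < pos.nrow(); ++a) {
    double r = radius[a];
    double r2 = r * r;
    int i0 = std::max(0, (int)std::ceil((pos(a, 0) - r - origin[0]) / h));
    int i1 = std::min(nx - 1, (int)std::floor((pos(a, 0) + r - origin[0]) / h));
    int j0 = std::max(0, (int)std::ceil((pos(a, 1) - r - origin[1]) / h));
    int j1 = std::min(ny - 1, (int)std::floor((pos(a, 1) + r - origin[1]) / h));
    int k0 = std::max(0, (int)std::ceil((pos(a, 2) - r - origin[2]) / h));
    int k1 = std::min(nz - 1, (int)std::floor((pos(a, 2) + r - origin[2]) / h));
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * h - pos(a, 2);
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * h - pos(a, 1);
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * h - pos(a, 0);
          if (dx * dx + dyz <= r2) mask[idx3(i, j, k, nx, ny)] = 1;
        }
      }
    }
  }
  return mask;
}

// Solvent-excluded region on the grid: two-pass probe closing.
// Returns 2 for nodes inside an atom vdW sphere, 1 for reentrant interior
// (probe-inflated region not reachable by a probe centre), 0 for solvent.
// [[Rcpp::export]]
IntegerVector cpp_ses_mask(NumericMatrix pos, NumericVector radius,
                           NumericVector origin, double h, IntegerVector dims,
                           double probe) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector rInf(radius.size()), rVdw = radius;
  for (int a = 0; a < radius.size(); ++a) rInf[a] = radius[a] + probe;
  IntegerVector infl = cpp_inflate(pos, rInf, origin, h, dims);
  IntegerVector vdw = cpp_inflate(pos, rVdw, origin, h, dims);
  // carve: any non-inflated node is a valid probe centre; clear inflated
  // (non-vdW) nodes within `probe` of it
  int pr = (int)std::floor(probe / h);
  double p2 = probe * probe;
  IntegerVector out = clone(infl);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = idx3(i, j, k, nx, ny);
        if (infl[c]) continue;
        // only probe centres adjacent to the inflated surface matter
        bool nearSurf = false;
        for (int d = 0; d < 6 && !nearSurf; ++d) {
          int ii = i + (d == 0) - (d == 1);
          int jj = j + (d == 2) - (d == 3);
          int kk = k + (d == 4) - (d == 5);
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;
          if (infl[idx3(ii, jj, kk, nx, ny)]) nearSurf = true;
        }
        if (!nearSurf) continue;
        for (int dk = -pr; dk <= pr; ++dk) {
          int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          for (int dj = -pr; dj <= pr; ++dj) {
            int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            double djk = (double)dj * dj + (double)dk * dk;
            for (int di = -pr; di <= pr; ++di) {
              int ii = i + di;
              if (ii < 0 || ii >= nx) continue;
              if (((double)di * di + djk) * h * h > p2) continue;
              int cc = idx3(ii, jj, kk, nx, ny);
              if (out[cc] && !vdw[cc]) out[cc] = 0;
            }
          }
        }
      }
  for (R_xlen_t t = 0; t < out.size(); ++t)
    if (vdw[t]) out[t] = 2;
  return out;
}

// Count of polar atoms within kernelR of every node, atom-centred sweep.
// [[Rcpp::export]]
NumericVector cpp_polar_counts(NumericMatrix pos, NumericVector origin,
                               double h, IntegerVector dims, double kernelR) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector cnt((long long)nx * ny * nz);
  double r2 = kernelR * kernelR;
  for (int a = 0; a < pos.nrow(); ++a) {
    int i0 = std::max(0, (int)std::ceil((pos(a, 0) - kernelR - origin[0]) / h));
    int i1 = std::min(nx - 1,
                      (int)std::floor((pos(a, 0) + kernelR - origin[0]) / h));
    int j0 = std::max(0, (int)std::ceil((pos(a, 1) - kernelR - origin[1]) / h));
    int j1 = std::min(ny - 1,
                      (int)std::floor((pos(a, 1) + kernelR - origin[1]) / h));
    int k0 = std::max(0, (int)std::ceil((pos(a, 2) - kernelR - origin[2]) / h));
    int k1 = std::min(nz - 1,
                      (int)std::floor((pos(a, 2) + kernelR - origin[2]) / h));
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * h - pos(a, 2);
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * h - pos(a, 1);
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * h - pos(a, 0);
          if (dx * dx + dyz <= r2) cnt[idx3(i, j, k, nx, ny)] += 1.0;
        }
      }
    }
  }
  return cnt;
}

// Metropolis Monte Carlo over 2^N protonation microstates.
// Energies in pH units: E = sum_i x_i (pH - pKa_i)
//                         + 1/2 sum_{i != j} W_ij dq_i dq_j,
// dq_i = x_i - ref_i (ref 0 for acids, 1 for bases). Uses R's RNG.
// [[Rcpp::export]]
List cpp_mc_titrate(NumericVector pka, NumericMatrix W, IntegerVector ref,
                    NumericVector pHgrid, int burn, int scans, int batches,
                    double pairThreshold) {
  int n = pka.size();
  int nPH = pHgrid.size();
  const double LN10 = 2.302585092994046;
  // strongly coupled pairs get joint double flips
  std::vector<int> pi_, pj_;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (std::fabs(W(i, j)) > pairThreshold) { pi_.push_back(i); pj_.push_back(j); }
  int nPairs = (int)pi_.size();

  NumericMatrix frac(nPH, n), se(nPH, n);
  std::vector<int> x(n);
  std::vector<double> dq(n);
  RNGScope scope;

  for (int p = 0; p < nPH; ++p) {
    double pH = pHgrid[p];
    // start from the state minimizing the field term alone
    for (int i = 0; i < n; ++i) {
      x[i] = (pH < pka[i]) ? 1 : 0;
      dq[i] = x[i] - ref[i];
    }
    auto flipDE = [&](int i) {
      double dx = 1.0 - 2.0 * x[i];
      double de = dx * (pH - pka[i]);
      double coup = 0;
      for (int j = 0; j < n; ++j)
        if (j != i) coup += W(i, j) * dq[j];
      return de + dx * coup;
    };
    auto attempt = [&](int i) {
      double de = flipDE(i);
      if (de <= 0 || unif_rand() < std::exp(-LN10 * de)) {
        double dx = 1.0 - 2.0 * x[i];
        x[i] = 1 - x[i];
        dq[i] += dx;
      }
    };
    auto attemptPair = [&](int a, int b) {
      double dxa = 1.0 - 2.0 * x[a], dxb = 1.0 - 2.0 * x[b];
      double de = dxa * (pH - pka[a]) + dxb * (pH - pka[b]);
      double coupA = 0, coupB = 0;
      for (int j = 0; j < n; ++j) {
        if (j != a && j != b) {
          coupA += W(a, j) * dq[j];
          coupB += W(b, j) * dq[j];
        }
      }
      de += dxa * coupA + dxb * coupB;
      de += W(a, b) * ((dq[a] + dxa) * (dq[b] + dxb) - dq[a] * dq[b]);
      if (de <= 0 || unif_rand() < std::exp(-LN10 * de)) {
        x[a] = 1 - x[a]; x[b] = 1 - x[b];
        dq[a] += dxa; dq[b] += dxb;
      }
    };

    for (int s = 0; s < burn; ++s) {
      for (int i = 0; i < n; ++i) attempt(i);
      for (int q = 0; q < nPairs; ++q) attemptPair(pi_[q], pj_[q]);
    }
    int perBatch = scans / batches;
    std::vector<double> bm(n * batches, 0.0);
    for (int bIdx = 0; bIdx < batches; ++bIdx) {
      for (int s = 0; s < perBatch; ++s) {
        for (int i = 0; i < n; ++i) attempt(i);
        for (int q = 0; q < nPairs; ++q) attemptPair(pi_[q], pj_[q]);
        for (int i = 0; i < n; ++i) bm[bIdx * n + i] += x[i];
      }
      for (int i = 0; i < n; ++i) bm[bIdx * n + i] /= perBatch;
    }
    for (int i = 0; i < n; ++i) {
      double m = 0;
      for (int bIdx = 0; bIdx < batches; ++bIdx) m += bm[bIdx * n + i];
      m /= batches;
      double v = 0;
      for (int bIdx = 0; bIdx < batches; ++bIdx) {
        double d = bm[bIdx * n + i] - m;
        v += d * d;
      }
      v = (batches > 1) ? v / (batches - 1) : 0.0;
      frac(p, i) = m;
      se(p, i) = std::sqrt(v / batches);
    }
  }
  return List::create(_["fractions"] = frac, _["se"] = se,
                      _["nPairsCoupled"] = nPairs);
}
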