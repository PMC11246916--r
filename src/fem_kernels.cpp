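// Matrix-free assembly and preconditioned CG for the voxel finite-element
// volume-conduction problem: trilinear (first-order) elements on cubical
// voxels, Galerkin stiffness built from a reference 8x8 matrix scaled by the
// per-element conductivity and the element size. The pure-Neumann singularity
// is handled by projecting the constant mode out of the Krylov iteration.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;        // elements per axis
  int mx, my, mz;        // nodes per axis
  long long nelem, nnode;
  Grid(const IntegerVector& dims) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    mx = nx + 1; my = ny + 1; mz = nz + 1;
    nelem = (long long)nx * ny * nz;
    nnode = (long long)mx * my * mz;
  }
  inline long long node(int x, int y, int z) const {
    return (long long)x + (long long)mx * (y + (long long)my * z);
  }
};

// corner a = ax + 2*ay + 4*az, matching the R-side reference matrix ordering
inline void corner_bits(int a, int& ax, int& ay, int& az) {
  ax = a & 1; ay = (a >> 1) & 1; az = (a >> 2) & 1;
}

struct CSR {
  std::vector<long long> ptr;
  std::vector<int> col;
  std::vector<double> val;
  int n = 0;
};

void subtract_mean(std::vector<double>& v) {
  double m = 0;
  for (double x : v) m += x;
  m /= v.size();
  for (double& x : v) x -= m;
}

double dot(const std::vector<double>& a, const std::vector<double>& b) {
  double s = 0;
  for (size_t i = 0; i < a.size(); ++i) s += a[i] * b[i];
  return s;
}

void csr_matvec(const CSR& A, const std::vector<double>& x,
                std::vector<double>& y) {
  for (int i = 0; i < A.n; ++i) {
    double s = 0;
    for (long long k = A.ptr[i]; k < A.ptr[i + 1]; ++k)
      s += A.val[k] * x[A.col[k]];
    y[i] = s;
  }
}

// incomplete Cholesky with zero fill on the lower triangle (sorted columns);
// returns false on pivot breakdown
bool ic0(const CSR& L_pattern, std::vector<double>& lv) {
  const CSR& L = L_pattern;
  std::vector<double> diag(L.n, 0.0);
  for (int i = 0; i < L.n; ++i) {
    for (long long kk = L.ptr[i]; kk < L.ptr[i + 1]; ++kk) {
      int k = L.col[kk];
      // dot of rows i and k over columns < k
      double s = lv[kk];
      long long pi = L.ptr[i], pk = L.ptr[k];
      long long ei = L.ptr[i + 1] - 1, ek = L.ptr[k + 1] - 1; // exclude diagonals
      while (pi < ei && pk < ek) {
        int ci = L.col[pi], ck = L.col[pk];
        if (ci >= k || ck >= k) break;
        if (ci == ck) { s -= lv[pi] * lv[pk]; ++pi; ++pk; }
        else if (ci < ck) ++pi;
        else ++pk;
      }
      if (k < i) {
        if (diag[k] == 0.0) return false;
        lv[kk] = s / diag[k];
      } else {                     // diagonal entry (columns are sorted)
        if (s <= 0.0) return false;
        lv[kk] = std::sqrt(s);
        diag[i] = lv[kk];
      }
    }
  }
  return true;
}

void ic0_solve(const CSR& L, const std::vector<double>& lv,
               const std::vector<double>& r, std::vector<double>& z,
               std::vector<double>& work) {
  // forward: L y = r
  for (int i = 0; i < L.n; ++i) {
    double s = r[i];
    long long e = L.ptr[i + 1] - 1;
    for (long long k = L.ptr[i]; k < e; ++k) s -= lv[k] * work[L.col[k]];
    work[i] = s / lv[e];
  }
  // backward: L^T z = y (column-oriented)
  std::copy(work.begin(), work.end(), z.begin());
  for (int i = L.n - 1; i >= 0; --i) {
    long long e = L.ptr[i + 1] - 1;
    z[i] /= lv[e];
    double zi = z[i];
    for (long long k = L.ptr[i]; k < e; ++k) z[L.col[k]] -= lv[k] * zi;
  }
}

} // namespace

// Solve the Neumann volume-conduction system. sigma: per-element conductivity
// (S/m, 0 = excluded air), f: per-node load (A), Kref: unit-cube reference
// stiffness, hm: element edge in meters. Returns the nodal potential (V,
// zero-mean over the conducting domain), iteration count and residual
// history.
// [[Rcpp::export(name = ".fem_solve_cpp")]]
List fem_solve_cpp(IntegerVector dims, NumericVector sigma, NumericVector f,
                   NumericMatrix Kref, double hm, double tol, int maxit,
                   int precond) {
  Grid g(dims);
  if ((long long)sigma.size() != g.nelem) stop("sigma length mismatch");
  if ((long long)f.size() != g.nnode) stop("f length mismatch");

  // mark active nodes (touching a conducting element), assign contiguous ids
  std::vector<int> full2act((size_t)g.nnode, -1);
  {
    std::vector<char> act((size_t)g.nnode, 0);
    long long e = 0;
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y)
        for (int x = 0; x < g.nx; ++x, ++e) {
          if (sigma[e] <= 0) continue;
          for (int a = 0; a < 8; ++a) {
            int ax, ay, az; corner_bits(a, ax, ay, az);
            act[(size_t)g.node(x + ax, y + ay, z + az)] = 1;
          }
        }
    int id = 0;
    for (long long i = 0; i < g.nnode; ++i)
      if (act[(size_t)i]) full2act[(size_t)i] = id++;
    if (id == 0) stop("no conducting elements");
  }
  int nact = 0;
  std::vector<long long> act2full;
  for (long long i = 0; i < g.nnode; ++i)
    if (full2act[(size_t)i] >= 0) { act2full.push_back(i); ++nact; }

  // 27-point stencil accumulation over active nodes
  int OD[8][8];
  long long NOFF[8];
  for (int a = 0; a < 8; ++a) {
    int ax, ay, az; corner_bits(a, ax, ay, az);
    NOFF[a] = g.node(ax, ay, az);
    for (int b = 0; b < 8; ++b) {
      int bx, by, bz; corner_bits(b, bx, by, bz);
      OD[a][b] = (bx - ax + 1) + 3 * (by - ay + 1) + 9 * (bz - az + 1);
    }
  }
  double kr[8][8];
  for (int a = 0; a < 8; ++a)
    for (int b = 0; b < 8; ++b) kr[a][b] = Kref(a, b);

  std::vector<double> S((size_t)nact * 27, 0.0);
  {
    long long e = 0;
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y)
        for (int x = 0; x < g.nx; ++x, ++e) {
          double se = sigma[e];
          if (se <= 0) continue;
          double ke = se * hm;
          long long base = g.node(x, y, z);
          int ids[8];
          for (int a = 0; a < 8; ++a) ids[a] = full2act[(size_t)(base + NOFF[a])];
          for (int a = 0; a < 8; ++a) {
            double* row = &S[(size_t)ids[a] * 27];
            for (int b = 0; b < 8; ++b) row[OD[a][b]] += ke * kr[a][b];
          }
        }
  }

  // CSR over active nodes (sorted columns by construction)
  CSR A; A.n = nact;
  A.ptr.assign((size_t)nact + 1, 0);
  {
    std::vector<int> cnt(nact, 0);
    for (int i = 0; i < nact; ++i) {
      long long full = act2full[i];
      int x = (int)(full % g.mx);
      long long rest = full / g.mx;
      int y = (int)(rest % g.my);
      int zc = (int)(rest / g.my);
      const double* row = &S[(size_t)i * 27];
      for (int od = 0; od < 27; ++od) {
        if (row[od] == 0.0 && od != 13) continue;
        int dx = od % 3 - 1, dy = (od / 3) % 3 - 1, dz = od / 9 - 1;
        int nxp = x + dx, nyp = y + dy, nzp = zc + dz;
        if (nxp < 0 || nxp >= g.mx || nyp < 0 || nyp >= g.my ||
            nzp < 0 || nzp >= g.mz) continue;
        int j = full2act[(size_t)g.node(nxp, nyp, nzp)];
        if (j >= 0) ++cnt[i];
      }
    }
    for (int i = 0; i < nact; ++i) A.ptr[i + 1] = A.ptr[i] + cnt[i];
    A.col.resize((size_t)A.ptr[nact]);
    A.val.resize((size_t)A.ptr[nact]);
    for (int i = 0; i < nact; ++i) {
      long long full = act2full[i];
      int x = (int)(full % g.mx);
      long long rest = full / g.mx;
      int y = (int)(rest % g.my);
      int zc = (int)(rest / g.my);
      const double* row = &S[(size_t)i * 27];
      long long p = A.ptr[i];
      for (int od = 0; od < 27; ++od) {
        if (row[od] == 0.0 && od != 13) continue;
        int dx = od % 3 - 1, dy = (od / 3) % 3 - 1, dz = od / 9 - 1;
        int nxp = x + dx, nyp = y + dy, nzp = zc + dz;
        if (nxp < 0 || nxp >= g.mx || nyp < 0 || nyp >= g.my ||
            nzp < 0 || nzp >= g.mz) continue;
        int j = full2act[(size_t)g.node(nxp, nyp, nzp)];
        if (j < 0) continue;
        A.col[(size_t)p] = j;
        A.val[(size_t)p] = row[od];
        ++p;
      }
    }
  }
  S.clear(); S.shrink_to_fit();

  std::vector<double> b(nact);
  for (int i = 0; i < nact; ++i) b[i] = f[act2full[i]];
  subtract_mean(b);
  double normb = std::sqrt(dot(b, b));

  NumericVector phi_full((R_xlen_t)g.nnode);     // zeros
  if (normb == 0.0) {
    return List::create(_["phi"] = phi_full, _["iterations"] = 0,
                        _["relres"] = NumericVector::create(0.0),
                        _["converged"] = true, _["nactive"] = nact);
  }

  // preconditioner setup
  std::vector<double> diag(nact);
  for (int i = 0; i < nact; ++i) {
    for (long long k = A.ptr[i]; k < A.ptr[i + 1]; ++k)
      if (A.col[k] == i) { diag[i] = A.val[k]; break; }
  }
  CSR L; std::vector<double> lv;
  bool use_ic = (precond == 1);
  if (use_ic) {
    L.n = nact;
    L.ptr.assign((size_t)nact + 1, 0);
    std::vector<long long> cnt(nact, 0);
    for (int i = 0; i < nact; ++i)
      for (long long k = A.ptr[i]; k < A.ptr[i + 1]; ++k)
        if (A.col[k] <= i) ++cnt[i];
    for (int i = 0; i < nact; ++i) L.ptr[i + 1] = L.ptr[i] + cnt[i];
    L.col.resize((size_t)L.ptr[nact]);
    std::vector<double> av((size_t)L.ptr[nact]);
    for (int i = 0; i < nact; ++i) {
      long long p = L.ptr[i];
      for (long long k = A.ptr[i]; k < A.ptr[i + 1]; ++k)
        if (A.col[k] <= i) { L.col[(size_t)p] = A.col[k]; av[(size_t)p] = A.val[k]; ++p; }
    }
    double shift = 0.0;
    bool ok = false;
    for (int attempt = 0; attempt < 6 && !ok; ++attempt) {
      lv = av;
      if (shift > 0.0)
        for (int i = 0; i < nact; ++i) {
          long long e = L.ptr[i + 1] - 1;
          lv[(size_t)e] = av[(size_t)e] * (1.0 + shift);
        }
      ok = ic0(L, lv);
      shift = (shift == 0.0) ? 1e-3 : shift * 10.0;
    }
    if (!ok) use_ic = false;       // fall back to Jacobi
  }

  std::vector<double> x(nact, 0.0), r(b), z(nact), p(nact), q(nact), work(nact);
  std::vector<double> hist;
  double rho_old = 0.0;
  bool converged = false;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    if (use_ic) ic0_solve(L, lv, r, z, work);
    else for (int i = 0; i < nact; ++i) z[i] = r[i] / diag[i];
    subtract_mean(z);
    double rho = dot(r, z);
    if (it == 1) p = z;
    else {
      double beta = rho / rho_old;
      for (int i = 0; i < nact; ++i) p[i] = z[i] + beta * p[i];
    }
    rho_old = rho;
    csr_matvec(A, p, q);
    double pq = dot(p, q);
    if (pq <= 0) break;            // numerical breakdown
    double alpha = rho / pq;
    for (int i = 0; i < nact; ++i) { x[i] += alpha * p[i]; r[i] -= alpha * q[i]; }
    if (it % 50 == 0) subtract_mean(r);
    double rel = std::sqrt(dot(r, r)) / normb;
    hist.push_back(rel);
    if (rel <= tol) { converged = true; break; }
  }
  subtract_mean(x);
  for (int i = 0; i < nact; ++i) phi_full[act2full[i]] = x[i];
  return List::create(_["phi"] = phi_full,
                      _["iterations"] = (int)hist.size(),
                      _["relres"] = wrap(hist),
                      _["converged"] = converged,
                      _["nactive"] = nact);
}

// Stiffness action y = A * phi on the full node grid (matrix-free); used for
// residual reporting and conservation checks.
// [[Rcpp::export(name = ".fem_apply_cpp")]]
NumericVector fem_apply_cpp(IntegerVector dims, NumericVector sigma,
                            NumericVector phi, NumericMatrix Kref, double hm) {
  Grid g(dims);
  if ((long long)sigma.size() != g.nelem) stop("sigma length mismatch");
  if ((long long)phi.size() != g.nnode) stop("phi length mismatch");
  double kr[8][8];
  for (int a = 0; a < 8; ++a)
    for (int b = 0; b < 8; ++b) kr[a][b] = Kref(a, b);
  long long NOFF[8];
  for (int a = 0; a < 8; ++a) {
    int ax, ay, az; corner_bits(a, ax, ay, az);
    NOFF[a] = g.node(ax, ay, az);
  }
  NumericVector y((R_xlen_t)g.nnode);
  long long e = 0;
  for (int z = 0; z < g.nz; ++z)
    for (int yy = 0; yy < g.ny; ++yy)
      for (int x = 0; x < g.nx; ++x, ++e) {
        double se = sigma[e];
        if (se <= 0) continue;
        double ke = se * hm;
        long long base = g.node(x, yy, z);
        double ph[8];
        for (int a = 0; a < 8; ++a) ph[a] = phi[base + NOFF[a]];
        for (int a = 0; a < 8; ++a) {
          double s = 0;
          for (int b = 0; b < 8; ++b) s += kr[a][b] * ph[b];
          y[base + NOFF[a]] += ke * s;
        }
      }
  return y;
}

// Gradient of a nodal field at element centers (per-meter), from the
// trilinear shape functions: each component is the mean face difference.
// Returns -gradient, i.e. the electric field when given the potential.
// [[Rcpp::export(name = ".efield_cpp")]]
List efield_cpp(IntegerVector dims, NumericVector phi, double hm) {
  Grid g(dims);
  if ((long long)phi.size() != g.nnode) stop("phi length mismatch");
  NumericVector Ex((R_xlen_t)g.nelem), Ey((R_xlen_t)g.nelem), Ez((R_xlen_t)g.nelem);
  long long NOFF[8];
  int AX[8], AY[8], AZ[8];
  for (int a = 0; a < 8; ++a) {
    corner_bits(a, AX[a], AY[a], AZ[a]);
    NOFF[a] = g.node(AX[a], AY[a], AZ[a]);
  }
  double inv4h = 1.0 / (4.0 * hm);
  long long e = 0;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x, ++e) {
        long long base = g.node(x, y, z);
        double gx = 0, gy = 0, gz = 0;
        for (int a = 0; a < 8; ++a) {
          double v = phi[base + NOFF[a]];
          gx += (AX[a] ? v : -v);
          gy += (AY[a] ? v : -v);
          gz += (AZ[a] ? v : -v);
        }
        Ex[e] = -gx * inv4h; Ey[e] = -gy * inv4h; Ez[e] = -gz * inv4h;
      }
  return List::create(_["Ex"] = Ex, _["Ey"] = Ey, _["Ez"] = Ez);
}
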