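// Numerical kernels: Gaussian-primitive evaluation, basin ascent,
// two-electron quadrature sums, Coulomb sums, finite-difference Poisson.
// All lengths in bohr, energies in hartree unless noted.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EXP_CUT = 46.0;   // exp(-46) ~ 1e-20: primitive screening

// ---------------------------------------------------------------------------
// 1D Cartesian Gaussian factors and derivatives: X(x) = x^l exp(-a x^2)
static inline void gauss1d(double x, int l, double a, double e,
                           double &v, double &d1, double &d2) {
  double xl = 1.0, xlm1 = 0.0, xlm2 = 0.0;
  if (l > 0) { xlm1 = 1.0; for (int k = 1; k < l; ++k) xlm1 *= x; xl = xlm1 * x; }
  if (l > 1) { xlm2 = 1.0; for (int k = 2; k < l; ++k) xlm2 *= x; }
  double xlp1 = xl * x, xlp2 = xlp1 * x;
  v  = xl * e;
  d1 = (l * xlm1 - 2.0 * a * xlp1) * e;
  d2 = (l * (l - 1) * xlm2 - 2.0 * a * (2 * l + 1) * xl + 4.0 * a * a * xlp2) * e;
}

// MO values (and optional gradients) at points.
// prim arrays: center (0-based), l3 (nprim x 3), alpha, C (nprim x nmo).
// [[Rcpp::export]]
List cpp_eval_mo(IntegerVector center, IntegerMatrix l3, NumericVector alpha,
                 NumericMatrix C, NumericMatrix nuc, NumericMatrix pts,
                 int deriv) {
  int np = pts.nrow(), nprim = alpha.size(), nmo = C.ncol();
  NumericMatrix mo(np, nmo), gx, gy, gz;
  if (deriv >= 1) { gx = NumericMatrix(np, nmo); gy = NumericMatrix(np, nmo);
                    gz = NumericMatrix(np, nmo); }
  for (int ip = 0; ip < np; ++ip) {
    double px = pts(ip,0), py = pts(ip,1), pz = pts(ip,2);
    for (int q = 0; q < nprim; ++q) {
      int a = center[q];
      double dx = px - nuc(a,0), dy = py - nuc(a,1), dz = pz - nuc(a,2);
      double r2 = dx*dx + dy*dy + dz*dz, al = alpha[q];
      if (al * r2 > EXP_CUT) continue;
      double e = std::exp(-al * r2);
      double vX,dX,hX,vY,dY,hY,vZ,dZ,hZ;
      gauss1d(dx, l3(q,0), al, 1.0, vX, dX, hX);
      gauss1d(dy, l3(q,1), al, 1.0, vY, dY, hY);
      gauss1d(dz, l3(q,2), al, 1.0, vZ, dZ, hZ);
      double g = vX*vY*vZ*e;
      for (int m = 0; m < nmo; ++m) {
        double c = C(q,m);
        if (c == 0.0) continue;
        mo(ip,m) += c * g;
        if (deriv >= 1) {
          gx(ip,m) += c * dX*vY*vZ*e;
          gy(ip,m) += c * vX*dY*vZ*e;
          gz(ip,m) += c * vX*vY*dZ*e;
        }
      }
    }
  }
  if (deriv >= 1)
    return List::create(_["mo"]=mo, _["gx"]=gx, _["gy"]=gy, _["gz"]=gz);
  return List::create(_["mo"]=mo);
}

// Density (+gradient, +hessian, +positive-definite KED) at points.
// [[Rcpp::export]]
List cpp_density(IntegerVector center, IntegerMatrix l3, NumericVector alpha,
                 NumericMatrix C, NumericVector occ, NumericMatrix nuc,
                 NumericMatrix pts, int deriv) {
  int np = pts.nrow(), nprim = alpha.size(), nmo = C.ncol();
  NumericVector rho(np), ked;
  NumericMatrix grad, hess;
  if (deriv >= 1) { grad = NumericMatrix(np, 3); ked = NumericVector(np); }
  if (deriv >= 2) hess = NumericMatrix(np, 6); // xx yy zz xy xz yz
  std::vector<double> phi(nmo), dphix(nmo), dphiy(nmo), dphiz(nmo), h6(6*nmo);
  for (int ip = 0; ip < np; ++ip) {
    double px = pts(ip,0), py = pts(ip,1), pz = pts(ip,2);
    std::fill(phi.begin(), phi.end(), 0.0);
    if (deriv >= 1) {
      std::fill(dphix.begin(), dphix.end(), 0.0);
      std::fill(dphiy.begin(), dphiy.end(), 0.0);
      std::fill(dphiz.begin(), dphiz.end(), 0.0);
    }
    if (deriv >= 2) std::fill(h6.begin(), h6.end(), 0.0);
    for (int q = 0; q < nprim; ++q) {
      int a = center[q];
      double dx = px - nuc(a,0), dy = py - nuc(a,1), dz = pz - nuc(a,2);
      double r2 = dx*dx + dy*dy + dz*dz, al = alpha[q];
      if (al * r2 > EXP_CUT) continue;
      double e = std::exp(-al * r2);
      double vX,dX,hX,vY,dY,hY,vZ,dZ,hZ;
      gauss1d(dx, l3(q,0), al, 1.0, vX, dX, hX);
      gauss1d(dy, l3(q,1), al, 1.0, vY, dY, hY);
      gauss1d(dz, l3(q,2), al, 1.0, vZ, dZ, hZ);
      for (int m = 0; m < nmo; ++m) {
        double c = C(q,m);
        if (c == 0.0) continue;
        phi[m] += c * vX*vY*vZ*e;
        if (deriv >= 1) {
          dphix[m] += c * dX*vY*vZ*e;
          dphiy[m] += c * vX*dY*vZ*e;
          dphiz[m] += c * vX*vY*dZ*e;
        }
        if (deriv >= 2) {
          h6[0*nmo+m] += c * hX*vY*vZ*e;
          h6[1*nmo+m] += c * vX*hY*vZ*e;
          h6[2*nmo+m] += c * vX*vY*hZ*e;
          h6[3*nmo+m] += c * dX*dY*vZ*e;
          h6[4*nmo+m] += c * dX*vY*dZ*e;
          h6[5*nmo+m] += c * vX*dY*dZ*e;
        }
      }
    }
    double r = 0.0;
    for (int m = 0; m < nmo; ++m) r += occ[m] * phi[m]*phi[m];
    rho[ip] = r;
    if (deriv >= 1) {
      double gxx=0, gyy=0, gzz=0, kk=0;
      for (int m = 0; m < nmo; ++m) {
        gxx += 2.0*occ[m]*phi[m]*dphix[m];
        gyy += 2.0*occ[m]*phi[m]*dphiy[m];
        gzz += 2.0*occ[m]*phi[m]*dphiz[m];
        kk  += 0.5*occ[m]*(dphix[m]*dphix[m]+dphiy[m]*dphiy[m]+dphiz[m]*dphiz[m]);
      }
      grad(ip,0)=gxx; grad(ip,1)=gyy; grad(ip,2)=gzz; ked[ip]=kk;
    }
    if (deriv >= 2) {
      double H[6] = {0,0,0,0,0,0};
      for (int m = 0; m < nmo; ++m) {
        double o = occ[m];
        H[0] += 2.0*o*(dphix[m]*dphix[m] + phi[m]*h6[0*nmo+m]);
        H[1] += 2.0*o*(dphiy[m]*dphiy[m] + phi[m]*h6[1*nmo+m]);
        H[2] += 2.0*o*(dphiz[m]*dphiz[m] + phi[m]*h6[2*nmo+m]);
        H[3] += 2.0*o*(dphix[m]*dphiy[m] + phi[m]*h6[3*nmo+m]);
        H[4] += 2.0*o*(dphix[m]*dphiz[m] + phi[m]*h6[4*nmo+m]);
        H[5] += 2.0*o*(dphiy[m]*dphiz[m] + phi[m]*h6[5*nmo+m]);
      }
      for (int k = 0; k < 6; ++k) hess(ip,k) = H[k];
    }
  }
  List out = List::create(_["rho"]=rho);
  if (deriv >= 1) { out["grad"]=grad; out["ked"]=ked; }
  if (deriv >= 2) out["hess"]=hess;
  return out;
}

// ---------------------------------------------------------------------------
// Primitive overlap matrix via 1D Hermite recursion (E_0 coefficients).
static double e0_coeff(int i, int j, double a, double b, double AB) {
  // returns E_0^{ij}; builds the small table explicitly
  int ni = i + 1, nj = j + 1, nt = i + j + 1;
  std::vector<double> E((size_t)ni*nj*nt, 0.0);
  double p = a + b, mu = a*b/p;
  double XPA = -b/p*AB, XPB = a/p*AB;
  E[0] = std::exp(-mu*AB*AB);
  auto idx = [&](int ii,int jj,int tt){ return ((size_t)ii*nj+jj)*nt+tt; };
  for (int ii = 0; ii < ni; ++ii)
    for (int jj = 0; jj < nj; ++jj) {
      if (ii==0 && jj==0) continue;
      for (int t = 0; t <= ii+jj && t < nt; ++t) {
        double v = 0.0;
        if (jj == 0) {
          v = XPA * E[idx(ii-1,0,t)];
          if (t > 0) v += E[idx(ii-1,0,t-1)]/(2*p);
          if (t+1 <= ii-1) v += (t+1)*E[idx(ii-1,0,t+1)];
        } else {
          v = XPB * E[idx(ii,jj-1,t)];
          if (t > 0) v += E[idx(ii,jj-1,t-1)]/(2*p);
          if (t+1 <= ii+jj-1) v += (t+1)*E[idx(ii,jj-1,t+1)];
        }
        E[idx(ii,jj,t)] = v;
      }
    }
  return E[idx(i,j,0)];
}

// [[Rcpp::export]]
NumericMatrix cpp_prim_overlap(IntegerVector center, IntegerMatrix l3,
                               NumericVector alpha, NumericMatrix nuc) {
  int n = alpha.size();
  NumericMatrix S(n, n);
  for (int i = 0; i < n; ++i) {
    int ai = center[i];
    for (int j = 0; j <= i; ++j) {
      int aj = center[j];
      double p = alpha[i] + alpha[j];
      double ex = e0_coeff(l3(i,0), l3(j,0), alpha[i], alpha[j],
                           nuc(ai,0)-nuc(aj,0));
      double ey = e0_coeff(l3(i,1), l3(j,1), alpha[i], alpha[j],
                           nuc(ai,1)-nuc(aj,1));
      double ez = e0_coeff(l3(i,2), l3(j,2), alpha[i], alpha[j],
                           nuc(ai,2)-nuc(aj,2));
      double s = ex*ey*ez*std::pow(M_PI/p, 1.5);
      S(i,j) = S(j,i) = s;
    }
  }
  return S;
}

// ---------------------------------------------------------------------------
// allocation-free density/gradient at one point (used by the ascent loop)
static void density_point(const int *center, const int *l3, int nprim,
                          const double *alpha, const double *C,
                          const double *occv, int nmo,
                          const double *nuc, int natom,
                          double x, double y, double z, int deriv,
                          double *phi, double *dpx, double *dpy, double *dpz,
                          double &rho, double *grad) {
  for (int m = 0; m < nmo; ++m) {
    phi[m] = 0.0;
    if (deriv) { dpx[m] = 0.0; dpy[m] = 0.0; dpz[m] = 0.0; }
  }
  for (int q = 0; q < nprim; ++q) {
    int a = center[q];
    double dx = x - nuc[a], dy = y - nuc[a + natom], dz = z - nuc[a + 2*natom];
    double r2 = dx*dx + dy*dy + dz*dz, al = alpha[q];
    if (al * r2 > EXP_CUT) continue;
    double e = std::exp(-al * r2);
    double vX,dX,hX,vY,dY,hY,vZ,dZ,hZ;
    gauss1d(dx, l3[q], al, 1.0, vX, dX, hX);
    gauss1d(dy, l3[q + nprim], al, 1.0, vY, dY, hY);
    gauss1d(dz, l3[q + 2*nprim], al, 1.0, vZ, dZ, hZ);
    double g = vX*vY*vZ*e;
    for (int m = 0; m < nmo; ++m) {
      double c = C[q + (size_t)m*nprim];
      if (c == 0.0) continue;
      phi[m] += c * g;
      if (deriv) {
        dpx[m] += c * dX*vY*vZ*e;
        dpy[m] += c * vX*dY*vZ*e;
        dpz[m] += c * vX*vY*dZ*e;
      }
    }
  }
  rho = 0.0;
  if (deriv) { grad[0] = grad[1] = grad[2] = 0.0; }
  for (int m = 0; m < nmo; ++m) {
    rho += occv[m] * phi[m]*phi[m];
    if (deriv) {
      grad[0] += 2.0*occv[m]*phi[m]*dpx[m];
      grad[1] += 2.0*occv[m]*phi[m]*dpy[m];
      grad[2] += 2.0*occv[m]*phi[m]*dpz[m];
    }
  }
}

// ---------------------------------------------------------------------------
// Gradient-ascent basin assignment with backtracking steps.
// attract: attractor positions; beta: capture radii (assign when inside).
// Returns 1-based attractor index; 0 never (fallback handled internally);
// status: 0 ok, 1 = budget exhausted (nearest-attractor fallback),
//         2 = low-density floor (nearest-attractor).
// [[Rcpp::export]]
List cpp_ascend(IntegerVector center, IntegerMatrix l3, NumericVector alpha,
                NumericMatrix C, NumericVector occ, NumericMatrix nuc,
                NumericMatrix starts, NumericMatrix attract,
                NumericVector beta, double rho_floor, double h0,
                int max_steps) {
  int np = starts.nrow(), natt = attract.nrow();
  int nprim = alpha.size(), nmo = C.ncol(), natom = nuc.nrow();
  IntegerVector assign(np), status(np);
  // raw views for the allocation-free point evaluator
  std::vector<int> cen(center.begin(), center.end());
  std::vector<int> l3v((size_t)nprim*3);
  for (int q = 0; q < nprim; ++q)
    for (int k = 0; k < 3; ++k) l3v[q + (size_t)k*nprim] = l3(q,k);
  std::vector<double> alv(alpha.begin(), alpha.end());
  std::vector<double> Cv((size_t)nprim*nmo);
  for (int m = 0; m < nmo; ++m)
    for (int q = 0; q < nprim; ++q) Cv[q + (size_t)m*nprim] = C(q,m);
  std::vector<double> occv(occ.begin(), occ.end());
  std::vector<double> nucv((size_t)natom*3);
  for (int a = 0; a < natom; ++a)
    for (int k = 0; k < 3; ++k) nucv[a + (size_t)k*natom] = nuc(a,k);
  std::vector<double> phi(nmo), dpx(nmo), dpy(nmo), dpz(nmo);
  double grad[3];
  for (int ip = 0; ip < np; ++ip) {
    double x = starts(ip,0), y = starts(ip,1), z = starts(ip,2);
    int res = -1, st = 0;
    double h = h0;
    // immediate capture check
    for (int a = 0; a < natt; ++a) {
      double dx=x-attract(a,0), dy=y-attract(a,1), dz=z-attract(a,2);
      if (std::sqrt(dx*dx+dy*dy+dz*dz) <= beta[a]) { res = a; break; }
    }
    int it = 0, retried = 0;
    double rho_cur = -1.0, hfloor = 1e-5;
    while (res < 0) {
      double rho;
      density_point(cen.data(), l3v.data(), nprim, alv.data(), Cv.data(),
                    occv.data(), nmo, nucv.data(), natom, x, y, z, 1,
                    phi.data(), dpx.data(), dpy.data(), dpz.data(),
                    rho, grad);
      double gx=grad[0], gy=grad[1], gz=grad[2];
      double gn = std::sqrt(gx*gx+gy*gy+gz*gz);
      if (rho < rho_floor || gn < 1e-12) { st = 2; break; }
      rho_cur = rho;
      // midpoint (RK2) streamline step with backtracking: follows curved
      // gradient paths near ridges far better than a straight uphill step
      bool moved = false;
      while (h > hfloor) {
        double mx = x + 0.5*h*gx/gn, my = y + 0.5*h*gy/gn,
               mz = z + 0.5*h*gz/gn;
        double rho_m, gm[3];
        density_point(cen.data(), l3v.data(), nprim, alv.data(), Cv.data(),
                      occv.data(), nmo, nucv.data(), natom, mx, my, mz, 1,
                      phi.data(), dpx.data(), dpy.data(), dpz.data(),
                      rho_m, gm);
        double gmn = std::sqrt(gm[0]*gm[0]+gm[1]*gm[1]+gm[2]*gm[2]);
        if (gmn < 1e-14) { h *= 0.5; continue; }
        double nx = x + h*gm[0]/gmn, ny = y + h*gm[1]/gmn,
               nz = z + h*gm[2]/gmn;
        double rho2;
        density_point(cen.data(), l3v.data(), nprim, alv.data(), Cv.data(),
                      occv.data(), nmo, nucv.data(), natom, nx, ny, nz, 0,
                      phi.data(), dpx.data(), dpy.data(), dpz.data(),
                      rho2, grad);
        if (rho2 > rho_cur) {
          x=nx; y=ny; z=nz; rho_cur = rho2; moved = true;
          h = std::min(h*1.6, h0 * 2.0);
          break;
        }
        h *= 0.5;
      }
      if (!moved) {
        // stalled (sharp ridge or flat top): retry once at a finer scale
        if (retried < 1) { ++retried; hfloor = 1e-7; h = h0 * 0.02; continue; }
        st = 1; break;
      }
      for (int a = 0; a < natt; ++a) {
        double dx=x-attract(a,0), dy=y-attract(a,1), dz=z-attract(a,2);
        if (std::sqrt(dx*dx+dy*dy+dz*dz) <= beta[a]) { res = a; break; }
      }
      if (++it >= max_steps) { st = 1; break; }
    }
    if (res < 0) { // fallback: nearest attractor
      double best = R_PosInf;
      for (int a = 0; a < natt; ++a) {
        double dx=x-attract(a,0), dy=y-attract(a,1), dz=z-attract(a,2);
        double dd = dx*dx+dy*dy+dz*dz;
        if (dd < best) { best = dd; res = a; }
      }
    }
    assign[ip] = res + 1;
    status[ip] = st;
  }
  return List::create(_["attractor"]=assign, _["status"]=status);
}

// ---------------------------------------------------------------------------
// Inter-basin two-electron quadrature: Coulomb and HF-like xc parts.
// mo1/mo2: occupied-MO values at the two node sets; occ assumed 2 (checked
// in R).  Returns (coulomb, xc) where
//   coulomb = sum w1 w2 rho1 rho2 / r12
//   xc      = -2 * sum w1 w2 (sum_i mo1_i mo2_i)^2 / r12   [rho1 = 2 sum phi phi]
// r12 below rfloor contributes with r12 = rfloor (disjoint-basin guard).
// [[Rcpp::export]]
NumericVector cpp_pair_ee(NumericVector w1, NumericMatrix p1, NumericMatrix mo1,
                          NumericVector w2, NumericMatrix p2, NumericMatrix mo2,
                          double rfloor) {
  int n1 = w1.size(), n2 = w2.size(), nocc = mo1.ncol();
  std::vector<double> rho1(n1), rho2(n2);
  for (int i = 0; i < n1; ++i) {
    double r = 0; for (int m = 0; m < nocc; ++m) r += mo1(i,m)*mo1(i,m);
    rho1[i] = 2.0*r;
  }
  for (int j = 0; j < n2; ++j) {
    double r = 0; for (int m = 0; m < nocc; ++m) r += mo2(j,m)*mo2(j,m);
    rho2[j] = 2.0*r;
  }
  double coul = 0.0, xc = 0.0;
  for (int i = 0; i < n1; ++i) {
    double xi=p1(i,0), yi=p1(i,1), zi=p1(i,2), wi=w1[i], ri=rho1[i];
    if (wi == 0.0) continue;
    for (int j = 0; j < n2; ++j) {
      double dx=xi-p2(j,0), dy=yi-p2(j,1), dz=zi-p2(j,2);
      double r12 = std::sqrt(dx*dx+dy*dy+dz*dz);
      if (r12 < rfloor) r12 = rfloor;
      double invr = wi*w2[j]/r12;
      coul += invr * ri * rho2[j];
      double t = 0.0;
      for (int m = 0; m < nocc; ++m) t += mo1(i,m)*mo2(j,m);
      xc += invr * t * t;
    }
  }
  return NumericVector::create(coul, -2.0*xc);
}

// ---------------------------------------------------------------------------
// Real spherical harmonics (unit-normalized over the sphere) up to lmax,
// evaluated at unit vectors; returns (npts x (lmax+1)^2), index l*l + (m+l).
// [[Rcpp::export]]
NumericMatrix cpp_real_sph(NumericMatrix dirs, int lmax) {
  int n = dirs.nrow(), nlm = (lmax+1)*(lmax+1);
  NumericMatrix Y(n, nlm);
  int L = lmax;
  std::vector<double> P((L+1)*(L+1));
  for (int ip = 0; ip < n; ++ip) {
    double x = dirs(ip,0), y = dirs(ip,1), z = dirs(ip,2);
    double ct = z, stq = std::sqrt(std::max(0.0, 1.0 - z*z));
    double phi = std::atan2(y, x);
    // associated Legendre P_l^m(ct) with Condon-Shortley omitted
    auto pidx = [&](int l,int m){ return l*(L+1)+m; };
    P[pidx(0,0)] = 1.0;
    for (int m = 1; m <= L; ++m)
      P[pidx(m,m)] = P[pidx(m-1,m-1)] * (2*m-1) * stq;
    for (int m = 0; m < L; ++m)
      P[pidx(m+1,m)] = ct * (2*m+1) * P[pidx(m,m)];
    for (int l = 2; l <= L; ++l)
      for (int m = 0; m <= l-2; ++m)
        P[pidx(l,m)] = ((2*l-1)*ct*P[pidx(l-1,m)] - (l-1+m)*P[pidx(l-2,m)])/(l-m);
    for (int l = 0; l <= L; ++l) {
      for (int m = -l; m <= l; ++m) {
        int am = std::abs(m);
        double lg = 0.0; // log((l-|m|)!/(l+|m|)!)
        for (int k = l-am+1; k <= l+am; ++k) lg -= std::log((double)k);
        double N = std::sqrt((2.0*l+1.0)/(4.0*M_PI) * std::exp(lg));
        double v;
        if (m == 0) v = N * P[pidx(l,0)];
        else if (m > 0) v = std::sqrt(2.0)*N*P[pidx(l,am)]*std::cos(am*phi);
        else v = std::sqrt(2.0)*N*P[pidx(l,am)]*std::sin(am*phi);
        Y(ip, l*l + (m+l)) = v;
      }
    }
  }
  return Y;
}

// Spherical-harmonic (Laplace) projection of functions sampled on an
// atom-centred shell grid.  Shells: radial nodes (r, wrad with r^2
// absorbed), each pointing to one of the pooled angular sets via aset
// (0-based); angular sets described by (astart, acount) into angw/Y rows.
// fvals: node x nfun, already multiplied by any basin mask weights.
// Returns flm array as a numeric vector laid out [shell][lm][fun].
// [[Rcpp::export]]
NumericVector cpp_shell_project(NumericVector r, IntegerVector aset,
                                IntegerVector astart, IntegerVector acount,
                                NumericVector angw, NumericMatrix Y,
                                NumericMatrix fvals, int lmax) {
  int nsh = r.size(), nfun = fvals.ncol(), nlm = (lmax+1)*(lmax+1);
  std::vector<double> flm((size_t)nsh*nlm*nfun, 0.0);
  int node = 0;
  for (int s = 0; s < nsh; ++s) {
    int a0 = astart[aset[s]], na = acount[aset[s]];
    for (int j = 0; j < na; ++j, ++node) {
      double w = angw[a0 + j];
      for (int k = 0; k < nfun; ++k) {
        double fv = fvals(node, k) * w;
        if (fv == 0.0) continue;
        double *dst = &flm[((size_t)s*nlm)*nfun + k];
        for (int lm = 0; lm < nlm; ++lm)
          dst[(size_t)lm*nfun] += fv * Y(a0+j, lm);
      }
    }
  }
  return NumericVector(flm.begin(), flm.end());
}

// J'[f_k] = int int f_k(1) f_k(2)/r12 from shell projections (Laplace
// expansion of 1/r12; exact for the truncated lm content).
// [[Rcpp::export]]
NumericVector cpp_laplace_selfint(NumericVector r, NumericVector wrad,
                                  NumericVector flm_vec, int nfun, int lmax) {
  int nsh = r.size(), nlm = (lmax+1)*(lmax+1);
  const double *flm = flm_vec.begin();
  NumericVector out(nfun);
  for (int l = 0; l <= lmax; ++l) {
    double pref = 4.0*M_PI/(2.0*l+1.0);
    for (int m = -l; m <= l; ++m) {
      int lm = l*l + (m+l);
      for (int s1 = 0; s1 < nsh; ++s1) {
        double r1 = r[s1];
        for (int s2 = 0; s2 < nsh; ++s2) {
          double r2 = r[s2];
          double rl = (r1 < r2) ? r1 : r2, rg = (r1 < r2) ? r2 : r1;
          if (rg <= 0) continue;
          double kern = std::pow(rl/rg, l) / rg * wrad[s1]*wrad[s2]*pref;
          const double *a = &flm[((size_t)s1*nlm + lm)*nfun];
          const double *b = &flm[((size_t)s2*nlm + lm)*nfun];
          for (int k = 0; k < nfun; ++k) out[k] += kern * a[k]*b[k];
        }
      }
    }
  }
  return out;
}

// Radial potential profiles from shell projections (radial Poisson solve):
//   V_lm(r_s) = 4pi/(2l+1) [ I1(r_s)/r_s^{l+1} + I2(r_s) r_s^l ]
//   I1(r) = int_0^r f_lm(s) s^{l+2} ds,  I2(r) = int_r^rmax f_lm(s) s^{1-l} ds
// f_lm(r) is interpolated by a natural cubic spline through the shell
// values and integrated per interval with 4-point Gauss rules (the kernel
// kink at s = r falls exactly on interval boundaries, so each piece is
// smooth).  Below the first shell f_lm ~ f_lm(r_0) (r/r_0)^l.
// Returns [shell][lm][fun] profile plus multipole moments q_lm for the tail.
static void spline_second_derivs(const double *x, const double *y, int n,
                                 double *y2, double *u) {
  y2[0] = 0.0; u[0] = 0.0;
  for (int i = 1; i < n - 1; ++i) {
    double sig = (x[i]-x[i-1])/(x[i+1]-x[i-1]);
    double p = sig*y2[i-1] + 2.0;
    y2[i] = (sig-1.0)/p;
    u[i] = (y[i+1]-y[i])/(x[i+1]-x[i]) - (y[i]-y[i-1])/(x[i]-x[i-1]);
    u[i] = (6.0*u[i]/(x[i+1]-x[i-1]) - sig*u[i-1])/p;
  }
  y2[n-1] = 0.0;
  for (int i = n - 2; i >= 0; --i) y2[i] = y2[i]*y2[i+1] + u[i];
}

static inline double spline_eval(const double *x, const double *y,
                                 const double *y2, int lo, double s) {
  double h = x[lo+1]-x[lo];
  double A = (x[lo+1]-s)/h, B = (s-x[lo])/h;
  return A*y[lo] + B*y[lo+1] +
    ((A*A*A-A)*y2[lo] + (B*B*B-B)*y2[lo+1])*h*h/6.0;
}

static const double GL4_X[4] = {0.0694318442029737, 0.3300094782075719,
                                0.6699905217924281, 0.9305681557970263};
static const double GL4_W[4] = {0.1739274225687269, 0.3260725774312731,
                                0.3260725774312731, 0.1739274225687269};

// [[Rcpp::export]]
List cpp_laplace_potential(NumericVector r, NumericVector wrad,
                           NumericVector flm_vec, int nfun, int lmax) {
  int nsh = r.size(), nlm = (lmax+1)*(lmax+1);
  const double *flm = flm_vec.begin();
  NumericVector prof((size_t)nsh*nlm*nfun), qlm((size_t)nlm*nfun);
  std::vector<double> y(nsh), y2(nsh), u(nsh), I1(nsh), I2(nsh);
  std::vector<double> rx(r.begin(), r.end());
  for (int l = 0; l <= lmax; ++l) {
    double pref = 4.0*M_PI/(2.0*l+1.0);
    for (int m = -l; m <= l; ++m) {
      int lm = l*l + (m+l);
      for (int k = 0; k < nfun; ++k) {
        for (int s = 0; s < nsh; ++s)
          y[s] = flm[((size_t)s*nlm + lm)*nfun + k];
        spline_second_derivs(rx.data(), y.data(), nsh, y2.data(), u.data());
        // core piece: f ~ y0 (s/r0)^l  ->  int_0^{r0} = y0 r0^{l+3}/(2l+3)
        double core = y[0]*rx[0]*rx[0]*rx[0]/(2.0*l+3.0);
        for (int p = 0; p < l; ++p) core *= rx[0];
        I1[0] = core;
        for (int s = 1; s < nsh; ++s) {
          double a = rx[s-1], b = rx[s], acc = 0.0;
          for (int q = 0; q < 4; ++q) {
            double sq = a + (b-a)*GL4_X[q];
            double fy = spline_eval(rx.data(), y.data(), y2.data(), s-1, sq);
            acc += GL4_W[q]*fy*std::pow(sq, l+2.0);
          }
          I1[s] = I1[s-1] + (b-a)*acc;
        }
        I2[nsh-1] = 0.0;
        for (int s = nsh-2; s >= 0; --s) {
          double a = rx[s], b = rx[s+1], acc = 0.0;
          for (int q = 0; q < 4; ++q) {
            double sq = a + (b-a)*GL4_X[q];
            double fy = spline_eval(rx.data(), y.data(), y2.data(), s, sq);
            acc += GL4_W[q]*fy*std::pow(sq, 1.0-l);
          }
          I2[s] = I2[s+1] + (b-a)*acc;
        }
        for (int s = 0; s < nsh; ++s) {
          double rs = rx[s];
          prof[((size_t)s*nlm + lm)*nfun + k] =
            pref*(I1[s]/std::pow(rs, l+1.0) + I2[s]*std::pow(rs, (double)l));
        }
        qlm[(size_t)lm*nfun + k] = pref*I1[nsh-1];
      }
    }
  }
  return List::create(_["prof"]=prof, _["qlm"]=qlm);
}

// Evaluate the Laplace-expanded potential(s) of one center at target points.
// Linear interpolation of the radial profiles; multipole tail beyond the
// last shell; r^l limit inside the first shell.
// [[Rcpp::export]]
NumericMatrix cpp_eval_potential(NumericVector center, NumericVector r,
                                 NumericVector prof, NumericVector qlm,
                                 int nfun, int lmax, NumericMatrix targets) {
  int nsh = r.size(), nlm = (lmax+1)*(lmax+1), nt = targets.nrow();
  NumericMatrix out(nt, nfun);
  NumericMatrix dirs(nt, 3);
  NumericVector rts(nt);
  for (int it = 0; it < nt; ++it) {
    double dx = targets(it,0)-center[0], dy = targets(it,1)-center[1],
           dz = targets(it,2)-center[2];
    double rt = std::sqrt(dx*dx+dy*dy+dz*dz);
    if (rt < 1e-12) rt = 1e-12;
    rts[it] = rt;
    dirs(it,0)=dx/rt; dirs(it,1)=dy/rt; dirs(it,2)=dz/rt;
  }
  NumericMatrix Y = cpp_real_sph(dirs, lmax);
  for (int it = 0; it < nt; ++it) {
    double rt = rts[it];
    if (rt >= r[nsh-1]) {
      for (int lm = 0; lm < nlm; ++lm) {
        int l = (int)std::floor(std::sqrt((double)lm + 1e-9));
        double fac = Y(it,lm)/std::pow(rt, l+1);
        const double *q = &qlm[(size_t)lm*nfun];
        for (int k = 0; k < nfun; ++k) out(it,k) += fac*q[k];
      }
      continue;
    }
    int lo = 0, hi = nsh-1;
    while (hi - lo > 1) { int mid = (lo+hi)/2; if (r[mid] <= rt) lo = mid; else hi = mid; }
    double t = (rt - r[lo]) / (r[hi]-r[lo]);
    if (rt < r[0]) { lo = 0; hi = 0; t = 0.0; }
    for (int lm = 0; lm < nlm; ++lm) {
      double y = Y(it,lm);
      if (y == 0.0) continue;
      const double *p1 = &prof[((size_t)lo*nlm + lm)*nfun];
      const double *p2 = &prof[((size_t)hi*nlm + lm)*nfun];
      for (int k = 0; k < nfun; ++k)
        out(it,k) += y*((1.0-t)*p1[k] + t*p2[k]);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Coulomb sums: potential at target points from weighted sources.
// [[Rcpp::export]]
NumericVector cpp_coulomb_sum(NumericMatrix targets, NumericMatrix src,
                              NumericVector w, double rfloor) {
  int nt = targets.nrow(), ns = src.nrow();
  NumericVector pot(nt);
  for (int i = 0; i < nt; ++i) {
    double xi=targets(i,0), yi=targets(i,1), zi=targets(i,2), acc=0.0;
    for (int j = 0; j < ns; ++j) {
      double dx=xi-src(j,0), dy=yi-src(j,1), dz=zi-src(j,2);
      double rr = std::sqrt(dx*dx+dy*dy+dz*dz);
      if (rr < rfloor) rr = rfloor;
      acc += w[j]/rr;
    }
    pot[i] = acc;
  }
  return pot;
}

// ---------------------------------------------------------------------------
// Finite-difference Poisson solver (SOR, 7-point stencil, edge dielectrics).
// eps arrays give the dielectric on the +x/+y/+z edges of each node.
// rho: charge density * 4*pi*h^2 pre-scaled source term is built here from q.
// phi carries boundary values on the faces (Dirichlet) and initial guess.
// [[Rcpp::export]]
List cpp_poisson_sor(int nx, int ny, int nz, double h,
                     NumericVector epsx, NumericVector epsy, NumericVector epsz,
                     NumericVector src, NumericVector phi_init,
                     double omega, double tol, int maxit) {
  std::vector<double> phi(phi_init.begin(), phi_init.end());
  auto id = [&](int i,int j,int k){ return (size_t)i + nx*((size_t)j + (size_t)ny*k); };
  double resid = 0.0; int it;
  for (it = 0; it < maxit; ++it) {
    resid = 0.0;
    for (int rb = 0; rb < 2; ++rb) {
      for (int k = 1; k < nz-1; ++k)
        for (int j = 1; j < ny-1; ++j)
          for (int i = 1; i < nx-1; ++i) {
            if (((i+j+k) & 1) != rb) continue;
            size_t c = id(i,j,k);
            double exp_ = epsx[c], exm = epsx[id(i-1,j,k)];
            double eyp = epsy[c], eym = epsy[id(i,j-1,k)];
            double ezp = epsz[c], ezm = epsz[id(i,j,k-1)];
            double diag = exp_+exm+eyp+eym+ezp+ezm;
            double rhs = exp_*phi[id(i+1,j,k)] + exm*phi[id(i-1,j,k)]
                       + eyp*phi[id(i,j+1,k)] + eym*phi[id(i,j-1,k)]
                       + ezp*phi[id(i,j,k+1)] + ezm*phi[id(i,j,k-1)]
                       + src[c];
            double newphi = rhs / diag;
            double d = newphi - phi[c];
            phi[c] += omega * d;
            double ad = std::fabs(d);
            if (ad > resid) resid = ad;
          }
    }
    if (resid < tol) break;
  }
  return List::create(_["phi"]=NumericVector(phi.begin(), phi.end()),
                      _["iterations"]=it+1, _["residual"]=resid);
}

// ---------------------------------------------------------------------------
// Lennard-Jones + Coulomb pair sums over explicit index pairs (MM nonbonded).
// [[Rcpp::export]]
NumericMatrix cpp_lj_coulomb_pairs(NumericMatrix xyz, NumericVector q,
                                   NumericVector eps, NumericVector rmin2,
                                   IntegerMatrix pairs, NumericVector scale_ele,
                                   NumericVector scale_vdw, double kcoul) {
  int np = pairs.nrow();
  NumericMatrix out(np, 2); // ele, vdw (kcal/mol)
  for (int p = 0; p < np; ++p) {
    int i = pairs(p,0), j = pairs(p,1);
    double dx = xyz(i,0)-xyz(j,0), dy = xyz(i,1)-xyz(j,1), dz = xyz(i,2)-xyz(j,2);
    double r = std::sqrt(dx*dx+dy*dy+dz*dz);
    double e_ele = kcoul * q[i]*q[j] / r / scale_ele[p];
    double epsij = std::sqrt(eps[i]*eps[j]);
    double rm = rmin2[i] + rmin2[j];
    double s6 = std::pow(rm/r, 6.0);
    double e_vdw = epsij * (s6*s6 - 2.0*s6) / scale_vdw[p];
    out(p,0) = e_ele; out(p,1) = e_vdw;
  }
  return out;
}
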