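"""Minimal Gaussian-basis SCF engine (RHF + RKS/B3LYP) for fixture generation.

Independent of the R package: McMurchie-Davidson integrals over Cartesian
Gaussians, DIIS-converged SCF, Becke-grid numerical exchange-correlation.
Used once to generate the committed wavefunction fixtures (wfx / Molden) and
their manifest of oracle values. Not needed at package test time.

Conventions: atomic units throughout; closed-shell (optionally fractional
occupations for spherically averaged atoms, used to regenerate
correlation-consistent contraction coefficients).
"""

import json
import math
import numpy as np
from numpy.polynomial.legendre import leggauss

try:
    from numba import njit
except ImportError:  # pragma: no cover - numba is present in the build env
    def njit(*a, **k):
        if a and callable(a[0]):
            return a[0]
        return lambda f: f

# ---------------------------------------------------------------- Boys function

@njit(cache=True)
def boys(mmax, x, out):
    """F_0..F_mmax at x into out (length mmax+1)."""
    if x < 1e-13:
        for m in range(mmax + 1):
            out[m] = 1.0 / (2 * m + 1)
        return
    if x > 35.0:
        out[0] = 0.5 * math.sqrt(math.pi / x)
        ex = math.exp(-x)
        for m in range(mmax):
            out[m + 1] = ((2 * m + 1) * out[m] - ex) / (2 * x)
        return
    # series for F_mmax, downward recursion
    s = 0.0
    term = 1.0 / (2 * mmax + 1)
    k = 0
    while True:
        s += term
        k += 1
        term *= 2 * x / (2 * mmax + 2 * k + 1)
        if term < 1e-17 * s or k > 300:
            break
    ex = math.exp(-x)
    # F_m(x) = e^-x * sum_k (2x)^k / [(2m+1)(2m+3)...(2m+2k+1)]
    out[mmax] = s * ex
    for m in range(mmax - 1, -1, -1):
        out[m] = (2 * x * out[m + 1] + ex) / (2 * m + 1)


# ------------------------------------------------- Hermite expansion coefficients

@njit(cache=True)
def Etab(i_max, j_max, a, b, AB, out):
    """Hermite coefficients E_t^{ij} for 1D Gaussian product; out[i,j,t]."""
    p = a + b
    mu = a * b / p
    out[:, :, :] = 0.0
    out[0, 0, 0] = math.exp(-mu * AB * AB)
    XPA = -b / p * AB   # P - A with AB = A - B
    XPB = a / p * AB    # P - B
    for i in range(i_max + 1):
        for j in range(j_max + 1):
            if i == 0 and j == 0:
                continue
            if j == 0:
                for t in range(i + j + 1):
                    v = XPA * out[i - 1, 0, t]
                    if t > 0:
                        v += out[i - 1, 0, t - 1] / (2 * p)
                    if t + 1 <= i - 1:
                        v += (t + 1) * out[i - 1, 0, t + 1]
                    out[i, 0, t] = v
            else:
                for t in range(i + j + 1):
                    v = XPB * out[i, j - 1, t]
                    if t > 0:
                        v += out[i, j - 1, t - 1] / (2 * p)
                    if t + 1 <= i + j - 1:
                        v += (t + 1) * out[i, j - 1, t + 1]
                    out[i, j, t] = v


@njit(cache=True)
def Rtab(tmax, umax, vmax, p, PCx, PCy, PCz, out):
    """Hermite Coulomb integrals R^0_{tuv}; out[t,u,v]."""
    n_ord = tmax + umax + vmax
    R2 = PCx * PCx + PCy * PCy + PCz * PCz
    F = np.zeros(n_ord + 1)
    boys(n_ord, p * R2, F)
    # work array over auxiliary order
    buf = np.zeros((n_ord + 1, tmax + 1, umax + 1, vmax + 1))
    for n in range(n_ord + 1):
        buf[n, 0, 0, 0] = (-2.0 * p) ** n * F[n]
    for t in range(tmax + 1):
        for u in range(umax + 1):
            for v in range(vmax + 1):
                if t == 0 and u == 0 and v == 0:
                    continue
                for n in range(n_ord - (t + u + v) + 1):
                    if t > 0:
                        val = PCx * buf[n + 1, t - 1, u, v]
                        if t > 1:
                            val += (t - 1) * buf[n + 1, t - 2, u, v]
                    elif u > 0:
                        val = PCy * buf[n + 1, t, u - 1, v]
                        if u > 1:
                            val += (u - 1) * buf[n + 1, t, u - 2, v]
                    else:
                        val = PCz * buf[n + 1, t, u, v - 1]
                        if v > 1:
                            val += (v - 1) * buf[n + 1, t, u, v - 2]
                    buf[n, t, u, v] = val
    out[:, :, :] = buf[0]


# ------------------------------------------------------------------ basis setup

def dfact(n):
    r = 1
    while n > 1:
        r *= n
        n -= 2
    return r


def cart_components(l):
    return [(l - a, a - b, b) for a in range(l + 1) for b in range(a + 1)]


class Basis:
    """Cartesian contracted Gaussian basis.

    shells: list of dicts {atom, l, exps, coefs} (coefs already include
    primitive normalization; each contracted Cartesian component is
    renormalized to unit self-overlap at build time).
    """

    def __init__(self, atoms, shell_defs):
        self.atoms = atoms  # list of (Z, np.array xyz bohr)
        self.shells = []
        for (iat, l, exps, coefs) in shell_defs:
            exps = np.asarray(exps, float)
            coefs = np.asarray(coefs, float)
            # primitive normalization for the (l,0,0) component
            norm = (2 * exps / np.pi) ** 0.75 * (4 * exps) ** (l / 2.0) \
                / math.sqrt(dfact(2 * l - 1))
            self.shells.append(dict(atom=iat, l=l, exps=exps,
                                    coefs=coefs * norm))
        # flat function list
        self.funcs = []  # (shell idx, (lx,ly,lz), component norm factor)
        for si, sh in enumerate(self.shells):
            l = sh['l']
            for (lx, ly, lz) in cart_components(l):
                f = math.sqrt(dfact(2 * l - 1) /
                              (dfact(2 * lx - 1) * dfact(2 * ly - 1) * dfact(2 * lz - 1)))
                self.funcs.append((si, (lx, ly, lz), f))
        self.n = len(self.funcs)
        # renormalize each contracted component exactly
        S = self.one_electron()[0]
        self.comp_scale = 1.0 / np.sqrt(np.diag(S))
        self._S = S * np.outer(self.comp_scale, self.comp_scale)

    # ---- one-electron integrals (S, T, V, dipole) -------------------------
    def one_electron(self, with_scale=False):
        n = self.n
        S = np.zeros((n, n)); T = np.zeros((n, n)); V = np.zeros((n, n))
        D = np.zeros((3, n, n))
        atoms = self.atoms
        for ifn in range(n):
            si, (ix, iy, iz), fi = self.funcs[ifn]
            shi = self.shells[si]; A = atoms[shi['atom']][1]
            for jfn in range(ifn + 1):
                sj, (jx, jy, jz), fj = self.funcs[jfn]
                shj = self.shells[sj]; B = atoms[shj['atom']][1]
                s = t = v = 0.0; d = np.zeros(3)
                for a, ca in zip(shi['exps'], shi['coefs']):
                    for b, cb in zip(shj['exps'], shj['coefs']):
                        p = a + b
                        P = (a * A + b * B) / p
                        Ex = np.zeros((ix + 1, jx + 3, ix + jx + 3))
                        Ey = np.zeros((iy + 1, jy + 3, iy + jy + 3))
                        Ez = np.zeros((iz + 1, jz + 3, iz + jz + 3))
                        Etab(ix, jx + 2, a, b, A[0] - B[0], Ex)
                        Etab(iy, jy + 2, a, b, A[1] - B[1], Ey)
                        Etab(iz, jz + 2, a, b, A[2] - B[2], Ez)
                        pref = ca * cb * (np.pi / p) ** 1.5
                        sx = Ex[ix, jx, 0]; sy = Ey[iy, jy, 0]; sz = Ez[iz, jz, 0]
                        s += pref * sx * sy * sz
                        # kinetic via 1D pieces
                        def tk(E, i_, j_, bb):
                            out = -2 * bb * bb * E[i_, j_ + 2, 0] \
                                + bb * (2 * j_ + 1) * E[i_, j_, 0]
                            if j_ >= 2:
                                out -= 0.5 * j_ * (j_ - 1) * E[i_, j_ - 2, 0]
                            return out
                        t += pref * (tk(Ex, ix, jx, b) * sy * sz +
                                     sx * tk(Ey, iy, jy, b) * sz +
                                     sx * sy * tk(Ez, iz, jz, b))
                        # dipole (moments about origin)
                        mx = Ex[ix, jx, 1] if ix + jx >= 1 else 0.0
                        my = Ey[iy, jy, 1] if iy + jy >= 1 else 0.0
                        mz = Ez[iz, jz, 1] if iz + jz >= 1 else 0.0
                        d[0] += pref * (mx + P[0] * sx) * sy * sz
                        d[1] += pref * sx * (my + P[1] * sy) * sz
                        d[2] += pref * sx * sy * (mz + P[2] * sz)
                        # nuclear attraction
                        Rt = np.zeros((ix + jx + 1, iy + jy + 1, iz + jz + 1))
                        for (Z, C) in atoms:
                            Rtab(ix + jx, iy + jy, iz + jz, p,
                                 P[0] - C[0], P[1] - C[1], P[2] - C[2], Rt)
                            acc = 0.0
                            for tt in range(ix + jx + 1):
                                for uu in range(iy + jy + 1):
                                    for vv in range(iz + jz + 1):
                                        acc += Ex[ix, jx, tt] * Ey[iy, jy, uu] \
                                            * Ez[iz, jz, vv] * Rt[tt, uu, vv]
                            v -= Z * ca * cb * (2 * np.pi / p) * acc
                ff = fi * fj
                S[ifn, jfn] = S[jfn, ifn] = s * ff
                T[ifn, jfn] = T[jfn, ifn] = t * ff
                V[ifn, jfn] = V[jfn, ifn] = v * ff
                for k in range(3):
                    D[k, ifn, jfn] = D[k, jfn, ifn] = d[k] * ff
        if with_scale:
            sc = np.outer(self.comp_scale, self.comp_scale)
            return S * sc, T * sc, V * sc, D * sc[None, :, :]
        return S, T, V, D


# ----------------------------------------------------------- two-electron (ERI)

@njit(cache=True)
def eri_kernel(nf, f_shell, f_l3, f_scale, sh_atom, sh_l, sh_pstart, sh_pn,
               p_exp, p_coef, atxyz, G):
    """Full (ij|kl) tensor, naive shell-pair loops (fixture-scale systems)."""
    for ifn in range(nf):
        si = f_shell[ifn]
        ix, iy, iz = f_l3[ifn, 0], f_l3[ifn, 1], f_l3[ifn, 2]
        A = atxyz[sh_atom[si]]
        for jfn in range(ifn + 1):
            sj = f_shell[jfn]
            jx, jy, jz = f_l3[jfn, 0], f_l3[jfn, 1], f_l3[jfn, 2]
            B = atxyz[sh_atom[sj]]
            for kfn in range(ifn + 1):
                sk = f_shell[kfn]
                kx, ky, kz = f_l3[kfn, 0], f_l3[kfn, 1], f_l3[kfn, 2]
                C = atxyz[sh_atom[sk]]
                lmax = kfn if kfn < ifn else jfn
                if kfn == ifn:
                    lmax = jfn
                for lfn in range(lmax + 1):
                    sl = f_shell[lfn]
                    lx, ly, lz = f_l3[lfn, 0], f_l3[lfn, 1], f_l3[lfn, 2]
                    Dd = atxyz[sh_atom[sl]]
                    val = 0.0
                    for pa in range(sh_pn[si]):
                        a = p_exp[sh_pstart[si] + pa]
                        ca = p_coef[sh_pstart[si] + pa]
                        for pb in range(sh_pn[sj]):
                            b = p_exp[sh_pstart[sj] + pb]
                            cb = p_coef[sh_pstart[sj] + pb]
                            p = a + b
                            Px = (a * A[0] + b * B[0]) / p
                            Py = (a * A[1] + b * B[1]) / p
                            Pz = (a * A[2] + b * B[2]) / p
                            E1x = np.zeros((ix + 1, jx + 1, ix + jx + 1))
                            E1y = np.zeros((iy + 1, jy + 1, iy + jy + 1))
                            E1z = np.zeros((iz + 1, jz + 1, iz + jz + 1))
                            Etab(ix, jx, a, b, A[0] - B[0], E1x)
                            Etab(iy, jy, a, b, A[1] - B[1], E1y)
                            Etab(iz, jz, a, b, A[2] - B[2], E1z)
                            for pc in range(sh_pn[sk]):
                                c = p_exp[sh_pstart[sk] + pc]
                                cc = p_coef[sh_pstart[sk] + pc]
                                for pd in range(sh_pn[sl]):
                                    d = p_exp[sh_pstart[sl] + pd]
                                    cd = p_coef[sh_pstart[sl] + pd]
                                    q = c + d
                                    Qx = (c * C[0] + d * Dd[0]) / q
                                    Qy = (c * C[1] + d * Dd[1]) / q
                                    Qz = (c * C[2] + d * Dd[2]) / q
                                    E2x = np.zeros((kx + 1, lx + 1, kx + lx + 1))
                                    E2y = np.zeros((ky + 1, ly + 1, ky + ly + 1))
                                    E2z = np.zeros((kz + 1, lz + 1, kz + lz + 1))
                                    Etab(kx, lx, c, d, C[0] - Dd[0], E2x)
                                    Etab(ky, ly, c, d, C[1] - Dd[1], E2y)
                                    Etab(kz, lz, c, d, C[2] - Dd[2], E2z)
                                    alph = p * q / (p + q)
                                    tmx = ix + jx + kx + lx
                                    tmy = iy + jy + ky + ly
                                    tmz = iz + jz + kz + lz
                                    Rt = np.zeros((tmx + 1, tmy + 1, tmz + 1))
                                    Rtab(tmx, tmy, tmz, alph,
                                         Px - Qx, Py - Qy, Pz - Qz, Rt)
                                    acc = 0.0
                                    for t1 in range(ix + jx + 1):
                                        e1 = E1x[ix, jx, t1]
                                        if e1 == 0.0:
                                            continue
                                        for u1 in range(iy + jy + 1):
                                            e2 = e1 * E1y[iy, jy, u1]
                                            if e2 == 0.0:
                                                continue
                                            for v1 in range(iz + jz + 1):
                                                e3 = e2 * E1z[iz, jz, v1]
                                                if e3 == 0.0:
                                                    continue
                                                for t2 in range(kx + lx + 1):
                                                    g1 = E2x[kx, lx, t2]
                                                    if g1 == 0.0:
                                                        continue
                                                    sgn_t = -1.0 if (t2 % 2) else 1.0
                                                    for u2 in range(ky + ly + 1):
                                                        g2 = g1 * E2y[ky, ly, u2]
                                                        if g2 == 0.0:
                                                            continue
                                                        sgn_u = -sgn_t if (u2 % 2) else sgn_t
                                                        for v2 in range(kz + lz + 1):
                                                            g3 = g2 * E2z[kz, lz, v2]
                                                            if g3 == 0.0:
                                                                continue
                                                            sgn = -sgn_u if (v2 % 2) else sgn_u
                                                            acc += e3 * g3 * sgn * \
                                                                Rt[t1 + t2, u1 + u2, v1 + v2]
                                    val += ca * cb * cc * cd * acc * \
                                        2 * math.pi ** 2.5 / (p * q * math.sqrt(p + q))
                    val *= f_scale[ifn] * f_scale[jfn] * f_scale[kfn] * f_scale[lfn]
                    G[ifn, jfn, kfn, lfn] = val
                    G[jfn, ifn, kfn, lfn] = val
                    G[ifn, jfn, lfn, kfn] = val
                    G[jfn, ifn, lfn, kfn] = val
                    G[kfn, lfn, ifn, jfn] = val
                    G[lfn, kfn, ifn, jfn] = val
                    G[kfn, lfn, jfn, ifn] = val
                    G[lfn, kfn, jfn, ifn] = val


def eri_tensor(basis):
    nf = basis.n
    f_shell = np.array([f[0] for f in basis.funcs], np.int64)
    f_l3 = np.array([f[1] for f in basis.funcs], np.int64)
    f_scale = np.array([f[2] for f in basis.funcs]) * basis.comp_scale
    nsh = len(basis.shells)
    sh_atom = np.array([s['atom'] for s in basis.shells], np.int64)
    sh_l = np.array([s['l'] for s in basis.shells], np.int64)
    p_exp = np.concatenate([s['exps'] for s in basis.shells])
    p_coef = np.concatenate([s['coefs'] for s in basis.shells])
    sh_pn = np.array([len(s['exps']) for s in basis.shells], np.int64)
    sh_pstart = np.concatenate([[0], np.cumsum(sh_pn)[:-1]]).astype(np.int64)
    atxyz = np.array([a[1] for a in basis.atoms])
    G = np.zeros((nf, nf, nf, nf))
    eri_kernel(nf, f_shell, f_l3, f_scale, sh_atom, sh_l, sh_pstart, sh_pn,
               p_exp, p_coef, atxyz, G)
    return G


# ------------------------------------------------------------------- DFT pieces

def ao_values(basis, pts, deriv=1):
    """AO values (and gradients) at pts; returns (npts, nao) arrays."""
    npts = pts.shape[0]
    nao = basis.n
    val = np.zeros((npts, nao))
    grad = np.zeros((3, npts, nao)) if deriv else None
    for ifn, (si, (lx, ly, lz), f) in enumerate(basis.funcs):
        sh = basis.shells[si]
        A = basis.atoms[sh['atom']][1]
        d = pts - A
        r2 = (d ** 2).sum(1)
        polx = d[:, 0] ** lx; poly = d[:, 1] ** ly; polz = d[:, 2] ** lz
        scale = f * basis.comp_scale[ifn]
        for a, c in zip(sh['exps'], sh['coefs']):
            e = c * np.exp(-a * r2) * scale
            val[:, ifn] += polx * poly * polz * e
            if deriv:
                for ax, (lq, pol_ax) in enumerate(((lx, polx), (ly, poly), (lz, polz))):
                    dpol = -2 * a * d[:, ax] * pol_ax
                    if lq > 0:
                        dpol = dpol + lq * d[:, ax] ** (lq - 1)
                    others = [polx, poly, polz]
                    others[ax] = dpol
                    grad[ax, :, ifn] += others[0] * others[1] * others[2] * e
    return val, grad


BRAGG = {1: 0.35, 2: 1.40, 8: 0.60, 6: 0.70, 7: 0.65}  # angstrom, Slater radii


def becke_grid(atoms, n_rad=90, n_theta=24):
    """Becke molecular quadrature; product Gauss-Legendre x uniform-phi angular."""
    BOHR = 0.52917721067
    xs, ws = leggauss(n_theta)
    nphi = 2 * n_theta
    phis = 2 * np.pi * (np.arange(nphi) + 0.5) / nphi
    ang_pts = []
    ang_w = []
    for x, w in zip(xs, ws):
        st = math.sqrt(max(0.0, 1 - x * x))
        for ph in phis:
            ang_pts.append((st * math.cos(ph), st * math.sin(ph), x))
            ang_w.append(w * 2 * np.pi / nphi)
    ang_pts = np.array(ang_pts); ang_w = np.array(ang_w)
    allp = []; allw = []
    natom = len(atoms)
    coords = np.array([a[1] for a in atoms])
    for ia, (Z, A) in enumerate(atoms):
        Rm = BRAGG.get(Z, 0.8) / BOHR
        # Gauss-Chebyshev (2nd kind) nodes with the Becke r = Rm(1+x)/(1-x) map:
        # int_0^inf g r^2 dr = sum_i [pi/(n+1)] sin(th_i) r_i^2 [2 Rm/(1-x_i)^2] g
        i = np.arange(1, n_rad + 1)
        th = i * np.pi / (n_rad + 1.0)
        x = np.cos(th)
        r = Rm * (1 + x) / (1 - x)
        wr = (np.pi / (n_rad + 1.0)) * np.sin(th) * r ** 2 * 2.0 * Rm / (1 - x) ** 2
        pts = (A[None, None, :] + r[:, None, None] * ang_pts[None, :, :]).reshape(-1, 3)
        wts = (wr[:, None] * ang_w[None, :]).reshape(-1)
        # Becke partition weights
        dists = np.linalg.norm(pts[:, None, :] - coords[None, :, :], axis=2)
        P = np.ones((pts.shape[0], natom))
        for i1 in range(natom):
            for j1 in range(natom):
                if i1 == j1:
                    continue
                Rij = np.linalg.norm(coords[i1] - coords[j1])
                mu = (dists[:, i1] - dists[:, j1]) / Rij
                f = mu
                for _ in range(3):
                    f = 1.5 * f - 0.5 * f ** 3
                P[:, i1] *= 0.5 * (1 - f)
        wbecke = P[:, ia] / P.sum(1)
        allp.append(pts); allw.append(wts * wbecke)
    return np.vstack(allp), np.concatenate(allw)


def lyp_energy_density(ra, rb, gaa, gab, gbb):
    """LYP correlation energy density f(r) (Miehlich form), open-shell inputs."""
    a, b, c, d = 0.04918, 0.132, 0.2533, 0.349
    CF = 0.3 * (3 * np.pi ** 2) ** (2.0 / 3)
    rho = ra + rb
    rho = np.maximum(rho, 1e-300)
    rm13 = rho ** (-1.0 / 3)
    w = np.exp(-c * rm13) / (1 + d * rm13) * rho ** (-11.0 / 3)
    dl = c * rm13 + d * rm13 / (1 + d * rm13)
    gaa_t = gaa + 2 * gab + gbb  # |grad rho|^2
    t1 = -a * 4.0 / (1 + d * rm13) * ra * rb / rho
    t2 = 2 ** (11.0 / 3) * CF * (ra ** (8.0 / 3) + rb ** (8.0 / 3))
    t3 = (47.0 / 18 - 7.0 * dl / 18) * gaa_t
    t4 = -(2.5 - dl / 18.0) * (gaa + gbb)
    t5 = -(dl - 11.0) / 9.0 * (ra * gaa + rb * gbb) / rho
    t6 = -2.0 / 3 * rho ** 2 * gaa_t
    t7 = (2.0 / 3 * rho ** 2 - ra ** 2) * gbb
    t8 = (2.0 / 3 * rho ** 2 - rb ** 2) * gaa
    return t1 - a * b * w * (ra * rb * (t2 + t3 + t4 + t5) + t6 + t7 + t8)


def vwn5_ec(rho):
    """VWN5 paramagnetic correlation energy density per particle, epsilon_c."""
    rho = np.maximum(rho, 1e-300)
    rs = (3.0 / (4 * np.pi * rho)) ** (1.0 / 3)
    x = np.sqrt(rs)
    A, b, c, x0 = 0.0310907, 3.72744, 12.9352, -0.10498
    X = x * x + b * x + c
    X0 = x0 * x0 + b * x0 + c
    Q = math.sqrt(4 * c - b * b)
    at = np.arctan(Q / (2 * x + b))
    ec = A * (np.log(x * x / X) + 2 * b / Q * at
              - b * x0 / X0 * (np.log((x - x0) ** 2 / X) + 2 * (b + 2 * x0) / Q * at))
    return ec


def b88_enhancement(rho, grho2):
    """B88 gradient correction energy density (total, both spins, closed shell)."""
    beta = 0.0042
    ra = np.maximum(rho / 2, 1e-300)
    g_a = np.sqrt(np.maximum(grho2, 0.0)) / 2  # |grad rho_a|
    xa = g_a / ra ** (4.0 / 3)
    asin = np.arcsinh(xa)
    e_a = -beta * ra ** (4.0 / 3) * xa ** 2 / (1 + 6 * beta * xa * asin)
    return 2 * e_a


def b3lyp_exc_density(rho, grho2):
    """(E_xc density excluding exact exchange) for B3LYP on a grid."""
    Cx = -0.75 * (3.0 / np.pi) ** (1.0 / 3)
    ex_lsda = Cx * np.maximum(rho, 0.0) ** (4.0 / 3)
    ex_b88c = b88_enhancement(rho, grho2)
    ec_vwn = np.maximum(rho, 0.0) * vwn5_ec(rho)
    ra = rho / 2
    g4 = grho2 / 4
    ec_lyp = lyp_energy_density(ra, ra, g4, g4, g4)
    return 0.80 * ex_lsda + 0.72 * ex_b88c + 0.19 * ec_vwn + 0.81 * ec_lyp


def xc_matrix(basis, Dmat, pts, wts, aoval, aograd):
    """Numerical Vxc matrix + Exc for the non-exact-exchange part of B3LYP."""
    rho = np.einsum('pi,ij,pj->p', aoval, Dmat, aoval)
    grx = 2 * np.einsum('pi,ij,pj->p', aograd[0], Dmat, aoval)
    gry = 2 * np.einsum('pi,ij,pj->p', aograd[1], Dmat, aoval)
    grz = 2 * np.einsum('pi,ij,pj->p', aograd[2], Dmat, aoval)
    grho2 = grx ** 2 + gry ** 2 + grz ** 2
    good = rho > 1e-11
    exc = np.zeros_like(rho)
    exc[good] = b3lyp_exc_density(rho[good], grho2[good])
    Exc = np.sum(wts * exc)
    # numerical derivatives of f(rho, grho2)
    hr = np.maximum(rho * 1e-6, 1e-12)
    hg = np.maximum(grho2 * 1e-6, 1e-12)
    dfdr = np.zeros_like(rho); dfdg = np.zeros_like(rho)
    dfdr[good] = (b3lyp_exc_density(rho[good] + hr[good], grho2[good])
                  - b3lyp_exc_density(rho[good] - hr[good], grho2[good])) / (2 * hr[good])
    dfdg[good] = (b3lyp_exc_density(rho[good], grho2[good] + hg[good])
                  - b3lyp_exc_density(rho[good], grho2[good] - hg[good])) / (2 * hg[good])
    wv = wts * dfdr
    Vxc = aoval.T @ (wv[:, None] * aoval)
    wg = wts * dfdg * 2
    tmp = (wg * grx)[:, None] * aograd[0] + (wg * gry)[:, None] * aograd[1] \
        + (wg * grz)[:, None] * aograd[2]
    M = aoval.T @ tmp
    Vxc += M + M.T
    return Exc, Vxc


# ------------------------------------------------------------------------- SCF

def scf(basis, nelec, method='hf', occupations=None, conv=1e-9, maxiter=120,
        grid_par=(90, 24), verbose=True):
    S, T, V, Dip = basis.one_electron(with_scale=True)
    G = eri_tensor(basis)
    H = T + V
    # canonical orthogonalization
    ev, U = np.linalg.eigh(S)
    keep = ev > 1e-7
    X = U[:, keep] / np.sqrt(ev[keep])
    if occupations is None:
        nocc = nelec // 2
        occupations = np.zeros(basis.n); occupations[:nocc] = 2.0
    occupations = np.asarray(occupations, float)
    Dm = np.zeros_like(S)
    E_old = 0.0
    diis_F, diis_e = [], []
    aoval = aograd = pts = wts = None
    if method == 'b3lyp':
        pts, wts = becke_grid(basis.atoms, *grid_par)
        aoval, aograd = ao_values(basis, pts, deriv=1)
    Enuc = 0.0
    for i in range(len(basis.atoms)):
        for j in range(i):
            Zi, Ri = basis.atoms[i]; Zj, Rj = basis.atoms[j]
            Enuc += Zi * Zj / np.linalg.norm(Ri - Rj)
    C = None
    for it in range(maxiter):
        J = np.einsum('ijkl,kl->ij', G, Dm)
        K = np.einsum('ikjl,kl->ij', G, Dm)
        if method == 'hf':
            F = H + J - 0.5 * K
            Eel = np.sum(Dm * (H + 0.5 * J - 0.25 * K))
        else:
            Exc, Vxc = xc_matrix(basis, Dm, pts, wts, aoval, aograd)
            F = H + J - 0.5 * 0.20 * K + Vxc
            Eel = np.sum(Dm * (H + 0.5 * J)) - 0.25 * 0.20 * np.sum(Dm * K) + Exc
        E = Eel + Enuc
        err = X.T @ (F @ Dm @ S - S @ Dm @ F) @ X
        diis_F.append(F.copy()); diis_e.append(err.ravel())
        if len(diis_F) > 8:
            diis_F.pop(0); diis_e.pop(0)
        if len(diis_F) > 1:
            m = len(diis_F)
            B = -np.ones((m + 1, m + 1)); B[m, m] = 0.0
            for a_ in range(m):
                for b_ in range(m):
                    B[a_, b_] = diis_e[a_] @ diis_e[b_]
            rhs = np.zeros(m + 1); rhs[m] = -1.0
            try:
                cdiis = np.linalg.solve(B, rhs)[:m]
                F = sum(c * Fi for c, Fi in zip(cdiis, diis_F))
            except np.linalg.LinAlgError:
                pass
        Fp = X.T @ F @ X
        eps, Cp = np.linalg.eigh(Fp)
        C = X @ Cp
        occ = occupations[:C.shape[1]]
        Dm_new = (C * occ[None, :]) @ C.T
        dE = E - E_old
        rms = np.max(np.abs(err))
        if verbose:
            print(f'  it {it:3d}  E = {E:.10f}  dE = {dE:.2e}  |err| = {rms:.2e}')
        if abs(dE) < conv and rms < 1e-6 and it > 1:
            Dm = Dm_new
            break
        Dm = Dm_new
        E_old = E
    Ekin = np.sum(Dm * T)
    # dipole (electronic + nuclear), au
    dip = -np.array([np.sum(Dm * Dip[k]) for k in range(3)])
    for Z, R in basis.atoms:
        dip += Z * np.asarray(R)
    return dict(E=E, C=C, eps=eps, occ=occupations, S=S, Ekin=Ekin,
                dipole=dip, Dm=Dm, nelec=nelec)
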