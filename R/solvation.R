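# Implicit-solvent (PBSA-style) energies decomposed to atoms.
#
# Polar term: finite-difference Poisson reaction field (two solves on the
# same grid, vacuum-like and solvated dielectric; their difference at the
# atom positions removes the grid self-energy).  Nonpolar terms: cavity
# work proportional to per-atom solvent-accessible volumes, and an
# attractive dispersion term from the divergence-theorem surface form of
# the exterior solute-solvent r^-6 integral over the solvent-accessible
# surface (SAS).

#' Poisson-Boltzmann solver specification
#'
#' @param spacing grid spacing, Angstrom (default 0.33).
#' @param eps_solute solute dielectric (default 1).
#' @param eps_solvent solvent dielectric (default 80).
#' @param ionic_strength only 0 (pure Poisson) is supported.
#' @param probe solvent probe radius, Angstrom (default 1.4); used by the
#'   SAS/SAV constructions, not by the dielectric boundary (which follows
#'   the site PB radii as given).
#' @param padding box padding beyond the solute extent, Angstrom.
#' @param tol SOR convergence tolerance on the potential (e/Angstrom).
#' @param maxit iteration cap.
#' @return object of class `iqa_pb_spec`.
#' @export
pb_spec <- function(spacing = 0.33, eps_solute = 1, eps_solvent = 80,
                    ionic_strength = 0, probe = 1.4, padding = 8,
                    tol = 2e-6, maxit = 5000) {
  if (spacing <= 0) stop("grid spacing must be positive")
  if (!(eps_solvent > eps_solute && eps_solute >= 1))
    stop("need eps_solvent > eps_solute >= 1")
  if (ionic_strength != 0)
    stop("only null ionic strength (pure Poisson) is supported")
  structure(list(spacing = spacing, eps_solute = eps_solute,
                 eps_solvent = eps_solvent, probe = probe,
                 padding = padding, tol = tol, maxit = maxit),
            class = "iqa_pb_spec")
}

#' Solve for the reaction-field potential
#'
#' Two finite-difference solves of the Poisson equation on the same cubic
#' lattice - one with the solvent dielectric outside the solute cavity,
#' one with the solute dielectric everywhere - give the reaction field
#' `Phi_RF` as their difference at the atomic positions (trilinear
#' interpolation; charges spread to the lattice trilinearly).
#'
#' @param sites an `iqa_sites` with charges and PB radii.
#' @param spec an `iqa_pb_spec`.
#' @return object of class `iqa_reaction_field`: `phi_rf` in
#'   kcal/(mol e) at each site, solver diagnostics, and the grid metadata.
#' @export
solve_reaction_field <- function(sites, spec = pb_spec()) {
  require_charges(sites, "the Poisson solver")
  require_radii(sites, "the Poisson solver")
  B <- iqa_units$bohr_angstrom
  xyz <- sites_xyz(sites) * B     # Angstrom
  h <- spec$spacing
  lo <- apply(xyz, 2, min) - max(sites$radius) - spec$padding
  hi <- apply(xyz, 2, max) + max(sites$radius) + spec$padding
  n <- ceiling((hi - lo) / h) + 1L
  if (any((xyz < matrix(lo, nrow(xyz), 3, byrow = TRUE)) |
            (xyz > matrix(lo + (n - 1) * h, nrow(xyz), 3, byrow = TRUE))))
    stop("atom outside the finite-difference box")
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  ntot <- as.double(nx) * ny * nz
  if (ntot > 3.5e7) stop("finite-difference grid too large (",
                         nx, "x", ny, "x", nz, ")")
  gx <- lo[1] + (seq_len(nx) - 1) * h
  gy <- lo[2] + (seq_len(ny) - 1) * h
  gz <- lo[3] + (seq_len(nz) - 1) * h
  id <- function(i, j, k) i + nx * ((j - 1) + ny * (k - 1))
  # trilinear charge spreading -> src = 4 pi q / h at lattice nodes
  src <- numeric(ntot)
  for (a in seq_len(nrow(xyz))) {
    fx <- (xyz[a, 1] - lo[1]) / h; fy <- (xyz[a, 2] - lo[2]) / h
    fz <- (xyz[a, 3] - lo[3]) / h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      wt <- (if (di) tx else 1 - tx) * (if (dj) ty else 1 - ty) *
        (if (dk) tz else 1 - tz)
      node <- id(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)
      src[node] <- src[node] + 4 * pi * sites$q[a] * wt / h
    }
  }
  # edge dielectrics: fraction of each lattice edge inside the cavity
  # union (9-point sampling), combined by the harmonic mean (the exact
  # series dielectric of a piecewise-uniform edge)
  nsub <- 9L
  toff <- (seq_len(nsub) - 0.5) / nsub
  eps_edges <- function(eps_out) {
    mk <- function(axis) {
      if (eps_out == spec$eps_solute) return(rep(eps_out, ntot))
      # collect candidate edges near any sphere and OR the sampled
      # inside-ness over atoms
      cand <- new.env()
      for (a in seq_len(nrow(xyz))) {
        r <- sites$radius[a]
        ii <- which(gx > xyz[a, 1] - r - h & gx < xyz[a, 1] + r + h)
        jj <- which(gy > xyz[a, 2] - r - h & gy < xyz[a, 2] + r + h)
        kk <- which(gz > xyz[a, 3] - r - h & gz < xyz[a, 3] + r + h)
        if (!length(ii) || !length(jj) || !length(kk)) next
        sub <- expand.grid(i = ii, j = jj, k = kk)
        eid <- id(sub$i, sub$j, sub$k)
        px <- gx[sub$i]; py <- gy[sub$j]; pz <- gz[sub$k]
        for (q in seq_len(nsub)) {
          mx <- px + (axis == 1) * h * toff[q]
          my <- py + (axis == 2) * h * toff[q]
          mz <- pz + (axis == 3) * h * toff[q]
          ins <- (mx - xyz[a, 1])^2 + (my - xyz[a, 2])^2 +
            (mz - xyz[a, 3])^2 <= r^2
          key <- as.character(q)
          hit <- eid[ins]
          if (is.null(cand[[key]])) cand[[key]] <- hit
          else cand[[key]] <- c(cand[[key]], hit)
        }
      }
      eps <- rep(eps_out, ntot)
      allhit <- unique(unlist(lapply(as.character(seq_len(nsub)),
                                     function(k) unique(cand[[k]]))))
      if (!length(allhit)) return(eps)
      cnt <- numeric(length(allhit))
      for (q in seq_len(nsub)) {
        hq <- unique(cand[[as.character(q)]])
        cnt[match(hq, allhit)] <- cnt[match(hq, allhit)] + 1
      }
      f <- cnt / nsub
      eps[allhit] <- 1 / (f / spec$eps_solute + (1 - f) / eps_out)
      eps
    }
    list(mk(1), mk(2), mk(3))
  }
  # Dirichlet boundary: Coulomb field screened by the outer dielectric
  boundary_phi <- function(eps_out) {
    phi <- numeric(ntot)
    faces <- list(
      expand.grid(i = c(1, nx), j = seq_len(ny), k = seq_len(nz)),
      expand.grid(i = seq_len(nx), j = c(1, ny), k = seq_len(nz)),
      expand.grid(i = seq_len(nx), j = seq_len(ny), k = c(1, nz)))
    for (f in faces) {
      px <- gx[f$i]; py <- gy[f$j]; pz <- gz[f$k]
      v <- numeric(nrow(f))
      for (a in seq_len(nrow(xyz))) {
        r <- sqrt((px - xyz[a, 1])^2 + (py - xyz[a, 2])^2 +
                    (pz - xyz[a, 3])^2)
        v <- v + sites$q[a] / (eps_out * pmax(r, h))
      }
      phi[id(f$i, f$j, f$k)] <- v
    }
    phi
  }
  run <- function(eps_out) {
    ee <- eps_edges(eps_out)
    ph0 <- boundary_phi(eps_out)
    sol <- cpp_poisson_sor(nx, ny, nz, h, ee[[1]], ee[[2]], ee[[3]], src,
                           ph0, 1.9, spec$tol, spec$maxit)
    if (sol$residual > spec$tol)
      stop("Poisson solver did not converge: residual ",
           format(sol$residual, digits = 3), " after ", sol$iterations,
           " iterations")
    sol
  }
  het <- run(spec$eps_solvent)
  hom <- run(spec$eps_solute)
  interp <- function(phi) {
    out <- numeric(nrow(xyz))
    for (a in seq_len(nrow(xyz))) {
      fx <- (xyz[a, 1] - lo[1]) / h; fy <- (xyz[a, 2] - lo[2]) / h
      fz <- (xyz[a, 3] - lo[3]) / h
      i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
      tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
      v <- 0
      for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
        wt <- (if (di) tx else 1 - tx) * (if (dj) ty else 1 - ty) *
          (if (dk) tz else 1 - tz)
        v <- v + wt * phi[id(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
      }
      out[a] <- v
    }
    out
  }
  phi_rf <- (interp(het$phi) - interp(hom$phi)) * iqa_units$coulomb_kcal
  structure(list(phi_rf = phi_rf,
                 iterations = c(solvated = het$iterations,
                                reference = hom$iterations),
                 residual = c(solvated = het$residual,
                              reference = hom$residual),
                 dims = n, spacing = h, origin = lo, spec = spec),
            class = "iqa_reaction_field")
}

#' Atomic polar solvation terms
#'
#' Linear-response convention: `G_pol^I = 1/2 q_I Phi_RF(R_I)`; the sum is
#' the total polar solvation energy.
#'
#' @param sites an `iqa_sites`.
#' @param rf an `iqa_reaction_field` for the same sites.
#' @return numeric vector, kcal/mol.
#' @export
polar_atomic_terms <- function(sites, rf) {
  if (length(rf$phi_rf) != nrow(sites))
    stop("reaction field and site set sizes disagree")
  0.5 * sites$q * rf$phi_rf
}

#' ESP-fitted (CHELPG-style) atomic charges
#'
#' Least-squares fit of per-atom point charges to the electrostatic
#' potential of the QM charge density on a cubic-lattice shell between the
#' exclusion radii and an outer cutoff, under an exact total-charge
#' constraint.
#'
#' @param wfn an `iqa_wavefunction`.
#' @param grid an `iqa_basin_grid` (supplies the density quadrature).
#' @param gridspec list: `spacing` (0.5 A), `rmax` (2.8 A), `exclusion`
#'   named per-element radii in Angstrom (defaults inside).
#' @param mm_sites optional `iqa_sites` whose neighbourhoods (within their
#'   PB radii) are excluded from the fitting shell.
#' @return numeric charges (e) with attributes `rms` (fit residual,
#'   kcal/mol e) and `n_points`.
#' @export
chelpg_charges <- function(wfn, grid, gridspec = list(), mm_sites = NULL) {
  gs <- utils::modifyList(list(spacing = 0.5, rmax = 2.8,
                               exclusion = c(H = 1.45, He = 1.45, C = 1.5,
                                             N = 1.7, O = 1.7, F = 1.7,
                                             S = 2.0, P = 2.0, Cl = 2.0,
                                             Mg = 2.0, Zn = 2.0)),
                          gridspec)
  B <- iqa_units$bohr_angstrom
  nucA <- wfn$nuc * B
  elem <- wfn$symbol
  excl <- gs$exclusion[elem]
  excl[is.na(excl)] <- 1.7
  lo <- apply(nucA, 2, min) - gs$rmax
  hi <- apply(nucA, 2, max) + gs$rmax
  pts <- as.matrix(expand.grid(seq(lo[1], hi[1], by = gs$spacing),
                               seq(lo[2], hi[2], by = gs$spacing),
                               seq(lo[3], hi[3], by = gs$spacing)))
  dmin <- rep(Inf, nrow(pts)); inside <- rep(FALSE, nrow(pts))
  for (a in seq_len(wfn$natom)) {
    d <- sqrt((pts[, 1] - nucA[a, 1])^2 + (pts[, 2] - nucA[a, 2])^2 +
                (pts[, 3] - nucA[a, 3])^2)
    dmin <- pmin(dmin, d)
    inside <- inside | d < excl[a]
  }
  keep <- !inside & dmin <= gs$rmax
  if (!is.null(mm_sites) && nrow(mm_sites)) {
    mmA <- sites_xyz(mm_sites) * B
    rr <- ifelse(is.na(mm_sites$radius), 1.5, mm_sites$radius)
    for (a in seq_len(nrow(mmA))) {
      d <- sqrt((pts[, 1] - mmA[a, 1])^2 + (pts[, 2] - mmA[a, 2])^2 +
                  (pts[, 3] - mmA[a, 3])^2)
      keep <- keep & d > rr[a]
    }
  }
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < wfn$natom + 1)
    stop("ESP grid too small: ", nrow(pts), " points for ", wfn$natom,
         " charges")
  # ESP of the QM density (au) at the fitting points
  ptsb <- pts / B
  aw <- active_weights(grid)
  nz <- aw > 0
  rho <- evaluate_density(wfn, grid$points[nz, , drop = FALSE])
  vele <- cpp_coulomb_sum(ptsb, grid$points[nz, , drop = FALSE],
                          aw[nz] * rho, 1e-8)
  vnuc <- cpp_coulomb_sum(ptsb, wfn$nuc, wfn$Z, 1e-8)
  V <- vnuc - vele
  # design matrix in au
  A <- matrix(0, nrow(pts), wfn$natom)
  for (a in seq_len(wfn$natom)) {
    d <- sqrt(rowSums((ptsb - matrix(wfn$nuc[a, ], nrow(ptsb), 3,
                                     byrow = TRUE))^2))
    A[, a] <- 1 / d
  }
  Qtot <- round(sum(wfn$Z) - wfn$nelec)
  AtA <- crossprod(A)
  Atb <- crossprod(A, V)
  K <- rbind(cbind(AtA, 1), c(rep(1, wfn$natom), 0))
  sol <- solve(K, c(Atb, Qtot))
  q <- sol[seq_len(wfn$natom)]
  rms <- sqrt(mean((A %*% q - V)^2)) * iqa_units$hartree_kcal
  structure(q, rms = rms, n_points = nrow(pts))
}

#' Solvent-accessible surface mesh
#'
#' Shrake-Rupley-style construction on a deterministic Fibonacci sphere
#' lattice: per atom, points on the probe-inflated sphere that are not
#' buried inside any other inflated sphere, each carrying an equal area
#' element and the outward radial normal.
#'
#' @param sites an `iqa_sites` with radii.
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points lattice points per atom (default 960).
#' @return object of class `iqa_sas_mesh`: per-atom list with `points`
#'   (Angstrom), `normals`, `area_element`, and vector `area` of exposed
#'   areas (Angstrom^2).
#' @export
sas_surface <- function(sites, probe = 1.4, n_points = 960) {
  require_radii(sites, "the SAS construction")
  B <- iqa_units$bohr_angstrom
  xyz <- sites_xyz(sites) * B
  n <- nrow(sites)
  R <- sites$radius + probe
  # Fibonacci lattice (seedless, deterministic)
  k <- seq_len(n_points)
  ga <- pi * (3 - sqrt(5))
  z <- 1 - (2 * k - 1) / n_points
  rxy <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(rxy * cos(ga * k), rxy * sin(ga * k), z)
  atoms <- vector("list", n)
  area <- numeric(n)
  for (a in seq_len(n)) {
    p <- matrix(xyz[a, ], n_points, 3, byrow = TRUE) + R[a] * dirs
    buried <- rep(FALSE, n_points)
    for (b in seq_len(n)) {
      if (b == a) next
      d2 <- (p[, 1] - xyz[b, 1])^2 + (p[, 2] - xyz[b, 2])^2 +
        (p[, 3] - xyz[b, 3])^2
      buried <- buried | d2 < R[b]^2
    }
    keep <- !buried
    sigma <- 4 * pi * R[a]^2 / n_points
    atoms[[a]] <- list(points = p[keep, , drop = FALSE],
                       normals = dirs[keep, , drop = FALSE],
                       area_element = sigma)
    area[a] <- sigma * sum(keep)
  }
  structure(list(atoms = atoms, area = area, probe = probe,
                 n_points = n_points, centers = xyz, R = R),
            class = "iqa_sas_mesh")
}

#' Per-atom solvent-accessible volumes
#'
#' Lattice integration of the union of probe-inflated spheres; every
#' interior voxel is assigned to the atom whose inflated surface is
#' nearest (most negative signed distance), so the per-atom volumes sum to
#' the total exactly.
#'
#' @param sites an `iqa_sites` with radii.
#' @param probe probe radius, Angstrom.
#' @param resolution voxel edge, Angstrom (default 0.25).
#' @return numeric vector of volumes (Angstrom^3).
#' @export
sav_volumes <- function(sites, probe = 1.4, resolution = 0.25) {
  require_radii(sites, "the SAV construction")
  B <- iqa_units$bohr_angstrom
  xyz <- sites_xyz(sites) * B
  R <- sites$radius + probe
  lo <- apply(xyz, 2, min) - max(R) - resolution
  hi <- apply(xyz, 2, max) + max(R) + resolution
  gx <- seq(lo[1] + resolution / 2, hi[1], by = resolution)
  gy <- seq(lo[2] + resolution / 2, hi[2], by = resolution)
  gz <- seq(lo[3] + resolution / 2, hi[3], by = resolution)
  vol <- numeric(nrow(sites))
  vx <- resolution^3
  # slab-wise to bound memory
  for (iz in seq_along(gz)) {
    pts <- cbind(rep(gx, times = length(gy)),
                 rep(gy, each = length(gx)), gz[iz])
    best <- rep(Inf, nrow(pts))
    who <- integer(nrow(pts))
    for (a in seq_len(nrow(sites))) {
      sd <- sqrt((pts[, 1] - xyz[a, 1])^2 + (pts[, 2] - xyz[a, 2])^2 +
                   (pts[, 3] - xyz[a, 3])^2) - R[a]
      upd <- sd < best
      best[upd] <- sd[upd]
      who[upd] <- a
    }
    ins <- best < 0
    if (any(ins)) {
      tb <- tabulate(who[ins], nbins = nrow(sites))
      vol <- vol + tb * vx
    }
  }
  vol
}

#' Cavity-formation energies
#'
#' `G_cav^I = p V_I`.
#'
#' @param p solvent pressure parameter, kcal/(mol Angstrom^3); default
#'   0.069 (aqueous parametrization lineage of the volume-based cavity
#'   model).
#' @param volumes per-atom SAV volumes (Angstrom^3).
#' @return list with `per_atom` and `total` (kcal/mol).
#' @export
cavity_energy <- function(p = 0.069, volumes) {
  if (p < 0) stop("pressure parameter must be non-negative")
  list(per_atom = p * volumes, total = p * sum(volumes))
}

#' Surface-integral solute-solvent dispersion terms
#'
#' Divergence-theorem surface form of the exterior attractive r^-6
#' solute-solvent integral: for solute atom I and the SAS of atom J,
#' `G^IJ = -sum_s (rho_w C_I / 3) (r_s - R_I).n_s / |r_s - R_I|^6 sigma_s`
#' with `C_I = 2 eps_Iw rmin_Iw^6` from the solute-atom/water-oxygen LJ
#' pair.  The symmetrized terms `G'^IJ = (G^IJ + G^JI)/2` conserve the
#' total exactly.
#'
#' @param sites an `iqa_sites` with LJ parameters.
#' @param mesh an `iqa_sas_mesh` for the same sites.
#' @param solvent list: `rho_w` number density (0.03343 A^-3), `eps`
#'   (0.152 kcal/mol) and `rmin2` (1.7683 A) of the water-oxygen LJ site.
#' @return list with `G` (raw pair matrix), `Gsym` (symmetrized),
#'   `per_atom` (row sums of `Gsym`), `total` (kcal/mol).
#' @export
dispersion_surface_terms <- function(sites, mesh,
                                     solvent = list(rho_w = 0.03343,
                                                    eps = 0.152,
                                                    rmin2 = 1.7683)) {
  n <- nrow(sites)
  if (sum(mesh$area) == 0) {
    warning("zero-area SAS mesh: dispersion terms are zero")
    return(list(G = matrix(0, n, n), Gsym = matrix(0, n, n),
                per_atom = numeric(n), total = 0))
  }
  B <- iqa_units$bohr_angstrom
  xyz <- sites_xyz(sites) * B
  C_I <- 2 * sqrt(sites$eps * solvent$eps) *
    (sites$rmin2 + solvent$rmin2)^6
  G <- matrix(0, n, n)
  for (J in seq_len(n)) {
    m <- mesh$atoms[[J]]
    if (!nrow(m$points)) next
    for (I in seq_len(n)) {
      d <- m$points - matrix(xyz[I, ], nrow(m$points), 3, byrow = TRUE)
      r2 <- rowSums(d^2)
      flux <- rowSums(d * m$normals) / r2^3
      G[I, J] <- -solvent$rho_w * C_I[I] / 3 * sum(flux) * m$area_element
    }
  }
  Gsym <- (G + t(G)) / 2
  list(G = G, Gsym = Gsym, per_atom = rowSums(Gsym), total = sum(Gsym))
}

#' Per-atom solvation free energies
#'
#' `G_solv^I = G_pol^I + p V_I + sum_J G'^IJ`; the sum over atoms equals
#' the total PBSA solvation energy exactly (bookkeeping identity).
#'
#' @param polar per-atom polar terms (kcal/mol).
#' @param cavity per-atom cavity terms (kcal/mol).
#' @param disp per-atom symmetrized dispersion terms (kcal/mol).
#' @return object of class `iqa_solvation`: per-atom components, `g_solv`
#'   and `total`.
#' @export
atomic_solvation <- function(polar, cavity, disp) {
  n <- length(polar)
  if (length(cavity) != n || length(disp) != n)
    stop("mismatched atom sets among solvation components")
  g <- polar + cavity + disp
  structure(list(polar = polar, cavity = cavity, dispersion = disp,
                 g_solv = g, total = sum(g)),
            class = "iqa_solvation")
}

#' Default PB radii (Bondi set)
#'
#' @param elements character vector of element symbols.
#' @return numeric radii in Angstrom.
#' @export
default_pb_radii <- function(elements) {
  tab <- c(H = 1.2, He = 1.4, C = 1.7, N = 1.55, O = 1.52, F = 1.47,
           Mg = 1.73, P = 1.8, S = 1.8, Cl = 1.75, Zn = 1.39, Ca = 2.31)
  r <- tab[elements]
  r[is.na(r)] <- 1.7
  as.numeric(r)
}
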