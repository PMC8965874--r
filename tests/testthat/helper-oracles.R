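# Independent oracles: deliberately simple implementations that share no
# code path with the production routines they check.

# Direct-summation D3(BJ): plain scalar loops over the same parameter
# tables, written independently of the vectorized module code.
oracle_d3_total <- function(sites, params) {
  B <- iqadecomp::iqa_units$bohr_angstrom
  n <- nrow(sites)
  xyzA <- cbind(sites$x, sites$y, sites$z) * B
  cn <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    R <- sqrt(sum((xyzA[i, ] - xyzA[j, ])^2))
    rr <- (4 / 3) * (params$rcov[sites$element[i]] +
                       params$rcov[sites$element[j]])
    cn[i] <- cn[i] + 1 / (1 + exp(-16 * (rr / R - 1)))
  }
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    tab <- params$c6ref
    ei <- sites$element[i]; ej <- sites$element[j]
    ord <- match(c(ei, ej), names(params$rcov))
    a <- if (ord[1] <= ord[2]) ei else ej
    b <- if (ord[1] <= ord[2]) ej else ei
    ca <- if (ord[1] <= ord[2]) cn[i] else cn[j]
    cb <- if (ord[1] <= ord[2]) cn[j] else cn[i]
    sub <- tab[tab$elem_i == a & tab$elem_j == b, ]
    num <- 0; den <- 0
    for (r in seq_len(nrow(sub))) {
      w <- exp(-4 * ((sub$cn_i[r] - ca)^2 + (sub$cn_j[r] - cb)^2))
      num <- num + w * sub$c6[r]; den <- den + w
      if (a == b && sub$cn_i[r] != sub$cn_j[r]) {
        w2 <- exp(-4 * ((sub$cn_j[r] - ca)^2 + (sub$cn_i[r] - cb)^2))
        num <- num + w2 * sub$c6[r]; den <- den + w2
      }
    }
    c6 <- num / den
    c8 <- 3 * c6 * sqrt(params$q[ei] * params$q[ej])
    Rb <- sqrt(sum((sites$x[i] - sites$x[j])^2 +
                     (sites$y[i] - sites$y[j])^2 +
                     (sites$z[i] - sites$z[j])^2))
    f <- params$a1 * sqrt(c8 / c6) + params$a2
    total <- total - params$s6 * c6 / (Rb^6 + f^6) -
      params$s8 * c8 / (Rb^8 + f^8)
  }
  unname(total)
}

# Cube-lattice (grid-cell) Bader assignment: every cell inherits the
# label of its steepest-ascent neighbour, processed in descending density
# order - an on-grid algorithm entirely different from the package's
# continuous gradient ascent.  The steepest neighbour of every cell is
# precomputed with vectorized array shifts.
oracle_grid_bader_populations <- function(wfn, spacing = 0.14, pad = 5) {
  lo <- apply(wfn$nuc, 2, min) - pad
  hi <- apply(wfn$nuc, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  pts <- as.matrix(expand.grid(gx, gy, gz))
  rho <- iqadecomp::evaluate_density(wfn, pts)
  n <- nx * ny * nz
  # steepest-slope neighbour (26-connectivity, distance-weighted) per
  # cell, vectorized over shifts
  best_slope <- rep(0, n)
  best_id <- seq_len(n)
  ii <- rep(seq_len(nx), times = ny * nz)
  jj <- rep(rep(seq_len(ny), each = nx), times = nz)
  kk <- rep(seq_len(nz), each = nx * ny)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    dist <- sqrt(di^2 + dj^2 + dk^2)
    i2 <- ii + di; j2 <- jj + dj; k2 <- kk + dk
    ok <- i2 >= 1 & i2 <= nx & j2 >= 1 & j2 <= ny & k2 >= 1 & k2 <= nz
    id2 <- (k2 - 1L) * nx * ny + (j2 - 1L) * nx + i2
    slope <- (rho[ifelse(ok, id2, 1L)] - rho) / dist
    upd <- ok & slope > best_slope
    best_slope[upd] <- slope[upd]
    best_id[upd] <- id2[upd]
  }
  lab <- integer(n)
  ord <- order(-rho)
  for (cell in ord) {
    if (lab[cell] == 0L) {
      up <- best_id[cell]
      if (up == cell) {
        # lattice local maximum: attach to the nearest nucleus
        i <- (cell - 1L) %% nx + 1L
        j <- ((cell - 1L) %/% nx) %% ny + 1L
        k <- (cell - 1L) %/% (nx * ny) + 1L
        d2 <- (gx[i] - wfn$nuc[, 1])^2 + (gy[j] - wfn$nuc[, 2])^2 +
          (gz[k] - wfn$nuc[, 3])^2
        lab[cell] <- which.min(d2)
      } else lab[cell] <- lab[up]
    }
  }
  pop <- numeric(wfn$natom)
  for (a in seq_len(wfn$natom))
    pop[a] <- sum(rho[lab == a]) * spacing^3
  pop
}

# Brute-force exterior volume quadrature of the solute-solvent attractive
# r^-6 interaction (checks the divergence-theorem surface form).
oracle_dispersion_volume <- function(sites, probe = 1.4,
                                     solvent = list(rho_w = 0.03343,
                                                    eps = 0.152,
                                                    rmin2 = 1.7683),
                                     nr = 160, nang = 38, rcut = 40) {
  B <- iqadecomp::iqa_units$bohr_angstrom
  xyzA <- cbind(sites$x, sites$y, sites$z) * B
  R <- sites$radius + probe
  C_I <- 2 * sqrt(sites$eps * solvent$eps) *
    (sites$rmin2 + solvent$rmin2)^6
  gl <- iqadecomp:::gauss_legendre(nang)
  nphi <- 2 * nang
  phis <- 2 * pi * (seq_len(nphi) - 0.5) / nphi
  ct <- rep(gl$x, each = nphi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phis, nang)
  dirs <- cbind(st * cos(ph), st * sin(ph), ct)
  wang <- rep(gl$w, each = nphi) * (2 * pi / nphi)
  total <- 0
  for (I in seq_len(nrow(sites))) {
    # radial Gauss rule on [R_I, rcut] about atom I
    grl <- iqadecomp:::gauss_legendre(nr, R[I], rcut)
    for (s in seq_along(grl$x)) {
      pts <- matrix(xyzA[I, ], nrow(dirs), 3, byrow = TRUE) +
        grl$x[s] * dirs
      outside <- rep(TRUE, nrow(pts))
      for (b in seq_len(nrow(sites))) {
        d2 <- (pts[, 1] - xyzA[b, 1])^2 + (pts[, 2] - xyzA[b, 2])^2 +
          (pts[, 3] - xyzA[b, 3])^2
        outside <- outside & d2 >= R[b]^2
      }
      total <- total - solvent$rho_w * C_I[I] / grl$x[s]^6 *
        grl$w[s] * grl$x[s]^2 * sum(wang[outside])
    }
  }
  unname(total)
}
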