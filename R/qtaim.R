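#' Locate critical points of the electron density
#'
#' Newton search for stationary points of rho starting from nuclear
#' positions (attractors) and from the midpoints of the supplied candidate
#' atom pairs (bond critical points).  Points are classified by the signs
#' of the Hessian eigenvalues; converged points satisfy |grad rho| < 1e-8.
#' A pair whose search does not converge is reported CP-free (with a
#' message), not an error.
#'
#' @param wfn an `iqa_wavefunction`.
#' @param pairs two-column integer matrix of candidate atom pairs; default
#'   all pairs closer than 8 bohr.
#' @param gtol gradient norm convergence threshold (au).
#' @return data.frame of class `iqa_cps`: x, y, z, type ("nuclear"|"bond"|
#'   "ring"|"cage"|"nna"), rho, atoms (for bond CPs, "i-j"), plus attributes
#'   `attractors` (refined attractor positions) and `bcp_ends`.
#' @export
find_critical_points <- function(wfn, pairs = NULL, gtol = 1e-8) {
  nat <- wfn$natom
  if (is.null(pairs)) {
    pairs <- which(upper.tri(matrix(0, nat, nat)), arr.ind = TRUE)
    if (nrow(pairs)) {
      d <- sqrt(rowSums((wfn$nuc[pairs[, 1], , drop = FALSE] -
                           wfn$nuc[pairs[, 2], , drop = FALSE])^2))
      pairs <- pairs[d < 8, , drop = FALSE]
    }
  }
  newton <- function(x0, maxit = 80) {
    x <- x0
    for (it in seq_len(maxit)) {
      d <- cpp_density(wfn$prim_center - 1L, wfn$prim_l, wfn$prim_alpha,
                       wfn$C, wfn$occ, wfn$nuc, matrix(x, 1, 3), 2L)
      g <- as.numeric(d$grad)
      h6 <- as.numeric(d$hess)
      H <- matrix(c(h6[1], h6[4], h6[5],
                    h6[4], h6[2], h6[6],
                    h6[5], h6[6], h6[3]), 3, 3)
      gn <- sqrt(sum(g^2))
      if (gn < gtol)
        return(list(x = x, rho = d$rho[1], H = H, ok = TRUE))
      step <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) return(list(ok = FALSE))
      sn <- sqrt(sum(step^2))
      if (sn > 0.5) step <- step * 0.5 / sn
      x <- x + step
      if (sqrt(sum((x - x0)^2)) > 5) return(list(ok = FALSE))
    }
    list(ok = FALSE)
  }
  classify <- function(H) {
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    sig <- sum(sign(ev))
    rank <- sum(abs(ev) > 1e-10)
    if (rank < 3) return("degenerate")
    switch(as.character(sig),
           "-3" = "max", "-1" = "bond", "1" = "ring", "3" = "cage")
  }
  rows <- list()
  attractors <- NULL
  for (a in seq_len(nat)) {
    r <- newton(wfn$nuc[a, ])
    xa <- if (r$ok) r$x else wfn$nuc[a, ]
    rho <- if (r$ok) r$rho else evaluate_density(wfn, matrix(wfn$nuc[a, ], 1))
    attractors <- rbind(attractors, xa)
    rows[[length(rows) + 1]] <- data.frame(
      x = xa[1], y = xa[2], z = xa[3], type = "nuclear", rho = rho,
      atoms = as.character(a))
  }
  bcp_ends <- list()
  if (nrow(pairs)) for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    x0 <- (wfn$nuc[i, ] + wfn$nuc[j, ]) / 2
    r <- newton(x0)
    if (!r$ok) {
      message("critical-point search did not converge for pair ", i, "-", j,
              "; reported CP-free")
      next
    }
    ty <- classify(r$H)
    if (ty != "bond") next
    # avoid duplicates
    dup <- FALSE
    for (q in rows) if (q$type == "bond" &&
                        sum((c(q$x, q$y, q$z) - r$x)^2) < 1e-8) dup <- TRUE
    if (dup) next
    rows[[length(rows) + 1]] <- data.frame(
      x = r$x[1], y = r$x[2], z = r$x[3], type = "bond", rho = r$rho,
      atoms = paste0(i, "-", j))
    # steepest-ascent terminations from the two sides of the CP
    ev <- eigen(r$H, symmetric = TRUE)
    v <- ev$vectors[, which.max(ev$values)]
    ends <- integer(2)
    for (s in 1:2) {
      st <- r$x + (if (s == 1) 0.05 else -0.05) * v
      asc <- cpp_ascend(wfn$prim_center - 1L, wfn$prim_l, wfn$prim_alpha,
                        wfn$C, wfn$occ, wfn$nuc, matrix(st, 1, 3),
                        attractors, rep(0.2, nat), 1e-12, 0.1, 500)
      ends[s] <- asc$attractor[1]
    }
    bcp_ends[[length(bcp_ends) + 1]] <- ends
  }
  out <- do.call(rbind, rows)
  attr(out, "attractors") <- attractors
  attr(out, "bcp_ends") <- bcp_ends
  class(out) <- c("iqa_cps", "data.frame")
  out
}

#' Beta-sphere radii from critical points
#'
#' Radius = `fraction` x the distance from each nucleus to its closest bond
#' critical point.  Atoms with no bond CP fall back to `fraction` x half the
#' nearest-neighbour internuclear distance, capped at `r_max_beta`
#' (isolated-atom guard).
#'
#' @param cps an `iqa_cps` from [find_critical_points()], or NULL (fallback
#'   rule for every atom).
#' @param nuc natom x 3 nuclear positions (bohr).
#' @param fraction beta-sphere fraction (default 0.6).
#' @param r_max_beta cap in bohr (default 1.5).
#' @return numeric vector of radii (bohr).
#' @export
beta_sphere_radii <- function(cps, nuc, fraction = 0.6, r_max_beta = 1.5) {
  nat <- nrow(nuc)
  out <- numeric(nat)
  bcp <- if (!is.null(cps)) cps[cps$type == "bond", , drop = FALSE] else NULL
  for (a in seq_len(nat)) {
    d_bcp <- if (!is.null(bcp) && nrow(bcp))
      sqrt(rowSums((cbind(bcp$x, bcp$y, bcp$z) -
                      matrix(nuc[a, ], nrow(bcp), 3, byrow = TRUE))^2))
    else numeric(0)
    if (length(d_bcp)) {
      out[a] <- fraction * min(d_bcp)
    } else if (nat > 1) {
      others <- nuc[-a, , drop = FALSE]
      d_nn <- sqrt(rowSums((others -
                              matrix(nuc[a, ], nrow(others), 3,
                                     byrow = TRUE))^2))
      out[a] <- fraction * min(d_nn) / 2
    } else {
      out[a] <- Inf
    }
    out[a] <- min(out[a], r_max_beta)
  }
  out
}

#' Assign points to density attractors by gradient ascent
#'
#' Adaptive backtracking gradient ascent from each point; a trajectory is
#' captured as soon as it enters an attractor's beta sphere.  Points below
#' the density floor, and trajectories that exhaust the step budget, are
#' assigned to the nearest attractor (reported in `status`).  Exact
#' separatrix points (vanishing gradient) resolve to the lowest attractor
#' index; the rule is deterministic for fixed control parameters.
#'
#' @param wfn an `iqa_wavefunction`.
#' @param points n x 3 matrix (bohr).
#' @param attractors m x 3 attractor positions (default: the nuclei).
#' @param beta capture radii per attractor (default 0.2 bohr).
#' @param control list: `h0` initial step (0.1 bohr), `max_steps` (500),
#'   `rho_floor` (1e-12 au).
#' @return list with `attractor` (1-based index per point) and `status`
#'   (0 ok, 1 budget exhausted, 2 density floor).
#' @export
assign_attractor <- function(wfn, points, attractors = wfn$nuc,
                             beta = rep(0.2, nrow(attractors)),
                             control = list()) {
  ctl <- utils::modifyList(list(h0 = 0.1, max_steps = 500, rho_floor = 1e-12),
                           control)
  points <- as_points(points)
  res <- cpp_ascend(wfn$prim_center - 1L, wfn$prim_l, wfn$prim_alpha,
                    wfn$C, wfn$occ, wfn$nuc, points, as_points(attractors),
                    as.numeric(beta), ctl$rho_floor, ctl$h0,
                    as.integer(ctl$max_steps))
  nbudget <- sum(res$status == 1)
  if (nbudget)
    warning(nbudget, " ascent trajectories exhausted the step budget; ",
            "assigned to nearest attractor")
  res
}

PMAP_RADIAL <- 2  # power of the t -> r map on the outside radial segment

#' Build a basin-resolved quadrature grid
#'
#' Atom-centred grids: a Gauss-Legendre radial segment inside each atom's
#' beta sphere ([0, r_beta], always interior to the basin) and a composite
#' midpoint (Euler-Maclaurin-style) cell rule on [r_beta, r_max] outside,
#' under the quadratic power map t^2 of the cell coordinate; product angular
#' rules at the preset resolutions.  Every outside node is assigned to a
#' basin by gradient ascent; inside nodes belong to the owning atom by
#' construction.  With `refine_boundary = TRUE` (default) the interatomic
#' surface crossing along each radial ray is located by bisection and the
#' straddling radial cell's weight is split fractionally between the two
#' basins, removing the leading-order masking bias.
#'
#' @param system an `iqa_system` (wavefunction required), or an
#'   `iqa_wavefunction`.
#' @param preset an `iqa_grid_preset` or preset name (default "desk").
#' @param cps optional precomputed [find_critical_points()] result.
#' @param refine_boundary logical (default TRUE).
#' @return object of class `iqa_basin_grid`.
#' @export
build_basin_grid <- function(system, preset = "desk", cps = NULL,
                             refine_boundary = TRUE, beta_fraction = 0.6) {
  wfn <- if (inherits(system, "iqa_wavefunction")) system else system$wfn
  if (is.null(wfn)) stop("precondition error: system has no wavefunction")
  if (is.character(preset)) preset <- get_preset(preset)
  nat <- wfn$natom
  if (is.null(cps)) cps <- suppressMessages(find_critical_points(wfn))
  attractors <- attr(cps, "attractors")
  beta_r <- beta_sphere_radii(cps, wfn$nuc, fraction = beta_fraction)
  heavy <- wfn$Z > 1
  akey <- function(cls, seg) paste(cls, seg, sep = ".")
  asets <- list()
  for (cls in 1:2) for (seg in c("in", "out")) {
    npt <- if (seg == "out") preset$ang_out[cls] else preset$ang_in[cls]
    asets[[akey(cls, seg)]] <- angular_product_rule(angular_degree_for(npt))
  }
  shell_atom <- integer(0); shell_r <- numeric(0); shell_wrad <- numeric(0)
  shell_aset <- character(0); shell_seg <- character(0)
  shell_t <- numeric(0); shell_ht <- numeric(0)
  atom_rb <- numeric(nat)
  for (a in seq_len(nat)) {
    cls <- if (heavy[a]) 1L else 2L
    rb <- min(beta_r[a], preset$rmax[cls] * 0.5)
    atom_rb[a] <- rb
    gin <- gauss_legendre(preset$nrad_in[cls], 0, rb)
    nout <- preset$nrad_out[cls]
    ht <- 1 / nout
    tk <- (seq_len(nout) - 0.5) * ht
    span <- preset$rmax[cls] - rb
    rout <- rb + span * tk^PMAP_RADIAL
    wout <- ht * PMAP_RADIAL * tk^(PMAP_RADIAL - 1) * span * rout^2
    rs <- c(gin$x, rout)
    ws <- c(gin$w * gin$x^2, wout)
    seg <- c(rep("in", length(gin$x)), rep("out", nout))
    tt <- c(rep(NA_real_, length(gin$x)), tk)
    hh <- c(rep(NA_real_, length(gin$x)), rep(ht, nout))
    shell_atom <- c(shell_atom, rep(a, length(rs)))
    shell_r <- c(shell_r, rs)
    shell_wrad <- c(shell_wrad, ws)
    shell_seg <- c(shell_seg, seg)
    shell_t <- c(shell_t, tt)
    shell_ht <- c(shell_ht, hh)
    shell_aset <- c(shell_aset,
                    vapply(seg, function(sg) akey(cls, sg), ""))
  }
  nshell <- length(shell_r)
  counts <- vapply(asets, function(z) z$n, 1L)
  npts <- sum(counts[shell_aset])
  pts <- matrix(0, npts, 3)
  w <- numeric(npts); owner <- integer(npts); node_shell <- integer(npts)
  node_ang <- integer(npts)
  inside <- logical(npts)
  pos <- 0L
  for (s in seq_len(nshell)) {
    as_ <- asets[[shell_aset[s]]]
    n <- as_$n
    idx <- pos + seq_len(n)
    a <- shell_atom[s]
    pts[idx, ] <- matrix(wfn$nuc[a, ], n, 3, byrow = TRUE) +
      shell_r[s] * as_$dirs
    w[idx] <- shell_wrad[s] * as_$w
    owner[idx] <- a
    node_shell[idx] <- s
    node_ang[idx] <- seq_len(n)
    inside[idx] <- shell_seg[s] == "in"
    pos <- pos + n
  }
  basin <- integer(npts); status <- integer(npts)
  basin[inside] <- owner[inside]
  out_idx <- which(!inside)
  if (length(out_idx)) {
    res <- cpp_ascend(wfn$prim_center - 1L, wfn$prim_l, wfn$prim_alpha,
                      wfn$C, wfn$occ, wfn$nuc, pts[out_idx, , drop = FALSE],
                      attractors, beta_r, 1e-12, 0.1, 500L)
    basin[out_idx] <- res$attractor
    status[out_idx] <- res$status
  }
  frac <- rep(1, npts); sec <- integer(npts)
  if (refine_boundary && nat > 1) {
    ref <- refine_basin_boundaries(wfn, attractors, beta_r,
                                   shell_atom, shell_r, shell_t, shell_ht,
                                   shell_seg, shell_aset, asets,
                                   node_shell, node_ang, basin, atom_rb,
                                   preset)
    frac <- ref$frac; sec <- ref$sec
    if (!is.null(ref$basin)) basin <- ref$basin
  }
  becke <- becke_partition(pts, wfn$nuc, owner)
  structure(list(
    natom = nat, points = pts, weights = w, owner = owner, basin = basin,
    frac = frac, sec = sec, becke = becke,
    status = status, node_shell = node_shell, node_ang = node_ang,
    shell_atom = shell_atom, shell_r = shell_r, shell_wrad = shell_wrad,
    shell_aset = shell_aset, shell_seg = shell_seg, asets = asets,
    beta_r = beta_r, atom_rb = atom_rb,
    attractors = attractors, preset = preset),
    class = "iqa_basin_grid")
}

# Locate interatomic-surface crossings along each outside radial ray and
# split the straddling radial cell fractionally between the two basins.
refine_basin_boundaries <- function(wfn, attractors, beta_r,
                                    shell_atom, shell_r, shell_t, shell_ht,
                                    shell_seg, shell_aset, asets,
                                    node_shell, node_ang, basin, atom_rb,
                                    preset, n_bisect = 14L) {
  npts <- length(node_shell)
  frac <- rep(1, npts); sec <- integer(npts)
  nshell <- length(shell_r)
  shell_n <- vapply(asets, function(z) z$n, 1L)[shell_aset]
  shell_start <- cumsum(c(0L, shell_n[-nshell])) + 1L
  # collect crossings: consecutive outside shells of one atom, same ang index
  cross <- list()
  for (a in unique(shell_atom)) {
    sh_out <- which(shell_atom == a & shell_seg == "out")
    if (length(sh_out) < 2) next
    dirs <- asets[[shell_aset[sh_out[1]]]]$dirs
    nang <- nrow(dirs)
    bmat <- matrix(0L, length(sh_out), nang)
    for (si in seq_along(sh_out))
      bmat[si, ] <- basin[shell_start[sh_out[si]] + seq_len(nang) - 1L]
    for (j in seq_len(nang)) {
      bs <- bmat[, j]
      ch <- which(bs[-1] != bs[-length(bs)])
      for (ci in ch) {
        cross[[length(cross) + 1]] <- list(
          atom = a, j = j, dir = dirs[j, ],
          s_lo = sh_out[ci], s_hi = sh_out[ci + 1],
          b_lo = bs[ci], b_hi = bs[ci + 1])
      }
    }
  }
  if (!length(cross)) return(list(frac = frac, sec = sec))
  # sub-ray sampling: each crossing is probed along n_sub directions spread
  # over the angular cell, giving the volume fraction of the two straddling
  # radial cells on either side of the interatomic surface
  n_sub <- 4L
  ncross <- length(cross)
  ctr <- matrix(0, ncross * n_sub, 3)
  dirm <- matrix(0, ncross * n_sub, 3)
  r_lo <- numeric(ncross * n_sub); r_hi <- numeric(ncross * n_sub)
  b_lo_v <- integer(ncross * n_sub)
  for (ci in seq_along(cross)) {
    cr <- cross[[ci]]
    as_ <- asets[[shell_aset[cr$s_lo]]]
    ith <- ceiling(cr$j / as_$nphi)
    iph <- (cr$j - 1) %% as_$nphi + 1
    th <- as_$theta[ith]
    dth_lo <- if (ith > 1) (th - as_$theta[ith - 1]) / 2 else th / 2
    dth_hi <- if (ith < as_$ntheta) (as_$theta[ith + 1] - th) / 2
              else (pi - th) / 2
    ph <- as_$phi0 + 2 * pi * (iph - 0.5) / as_$nphi
    dph <- 2 * pi / as_$nphi
    subs <- rbind(c(th - dth_lo / 2, ph - dph / 4),
                  c(th - dth_lo / 2, ph + dph / 4),
                  c(th + dth_hi / 2, ph - dph / 4),
                  c(th + dth_hi / 2, ph + dph / 4))
    rows <- (ci - 1L) * n_sub + seq_len(n_sub)
    dirm[rows, ] <- cbind(sin(subs[, 1]) * cos(subs[, 2]),
                          sin(subs[, 1]) * sin(subs[, 2]),
                          cos(subs[, 1]))
    ctr[rows, ] <- matrix(wfn$nuc[cr$atom, ], n_sub, 3, byrow = TRUE)
    # bracket: full two-cell span around the crossing
    ht <- shell_ht[cr$s_lo]
    rb_beta <- atom_rb[cr$atom]
    span0 <- (shell_r[cr$s_hi] - rb_beta) / shell_t[cr$s_hi]^PMAP_RADIAL
    tmap <- function(t) rb_beta + span0 * t^PMAP_RADIAL
    r_lo[rows] <- tmap(max(shell_t[cr$s_lo] - ht / 2, 0))
    r_hi[rows] <- tmap(min(shell_t[cr$s_hi] + ht / 2, 1))
    b_lo_v[rows] <- cr$b_lo
  }
  for (it in seq_len(n_bisect)) {
    rm <- (r_lo + r_hi) / 2
    ptsm <- ctr + rm * dirm
    res <- cpp_ascend(wfn$prim_center - 1L, wfn$prim_l, wfn$prim_alpha,
                      wfn$C, wfn$occ, wfn$nuc, ptsm, attractors, beta_r,
                      1e-12, 0.05, 500L)
    low_side <- res$attractor == b_lo_v
    r_lo[low_side] <- rm[low_side]
    r_hi[!low_side] <- rm[!low_side]
  }
  r_b <- (r_lo + r_hi) / 2
  touched <- logical(npts)
  for (ci in seq_along(cross)) {
    cr <- cross[[ci]]
    rb_beta <- atom_rb[cr$atom]
    span0 <- (shell_r[cr$s_hi] - rb_beta) / shell_t[cr$s_hi]^PMAP_RADIAL
    rows <- (ci - 1L) * n_sub + seq_len(n_sub)
    t_b <- pmax(pmin(((r_b[rows] - rb_beta) / span0), 1), 0)^(1 / PMAP_RADIAL)
    ht <- shell_ht[cr$s_lo]
    for (side in 1:2) {
      s_id <- if (side == 1) cr$s_lo else cr$s_hi
      node <- shell_start[s_id] + cr$j - 1L
      if (touched[node]) next
      t_cell_lo <- shell_t[s_id] - ht / 2
      f_lo_side <- mean(pmax(pmin((t_b - t_cell_lo) / ht, 1), 0))
      if (f_lo_side >= 1 - 1e-12 || f_lo_side <= 1e-12) {
        # cell entirely on one side: keep the plain assignment
        next
      }
      touched[node] <- TRUE
      basin[node] <- cr$b_lo   # primary = low side with its fraction
      frac[node] <- f_lo_side
      sec[node] <- cr$b_hi
    }
  }
  list(frac = frac, sec = sec, basin = basin)
}

# Smooth Becke partition of unity across the overlapping atom-centred
# grids; each node carries the weight of its owner's cell in the molecular
# quadrature.  The partition is an exact regrouping (weights of the grids
# sum to one everywhere), so it introduces no model error; it routes each
# region of space to the grid that resolves it best.
becke_partition <- function(pts, nuc, owner, k_iter = 3) {
  nat <- nrow(nuc)
  if (nat == 1) return(rep(1, nrow(pts)))
  d <- matrix(0, nrow(pts), nat)
  for (a in seq_len(nat))
    d[, a] <- sqrt((pts[, 1] - nuc[a, 1])^2 + (pts[, 2] - nuc[a, 2])^2 +
                     (pts[, 3] - nuc[a, 3])^2)
  P <- matrix(1, nrow(pts), nat)
  for (i in seq_len(nat)) for (j in seq_len(nat)) {
    if (i == j) next
    Rij <- sqrt(sum((nuc[i, ] - nuc[j, ])^2))
    mu <- (d[, i] - d[, j]) / Rij
    f <- mu
    for (k in seq_len(k_iter)) f <- 1.5 * f - 0.5 * f^3
    P[, i] <- P[, i] * 0.5 * (1 - f)
  }
  P[cbind(seq_len(nrow(pts)), owner)] / rowSums(P)
}

#' Per-node weights toward one basin
#'
#' Quadrature weights of the molecular (Becke-partitioned union) grid
#' toward basin `atom`, including the fractional boundary-cell splits.
#' Summed over basins these weights reproduce the full molecular
#' quadrature exactly.
#'
#' @param grid an `iqa_basin_grid`.
#' @param atom basin index.
#' @return numeric vector over all grid nodes.
#' @export
basin_weights <- function(grid, atom) {
  grid$weights * grid$becke * basin_fraction(grid, atom)
}

# per-node fraction (0..1) of the node's radial cell inside basin `atom`
basin_fraction <- function(grid, atom) {
  f <- numeric(length(grid$weights))
  pri <- grid$basin == atom
  f[pri] <- grid$frac[pri]
  sec <- grid$sec == atom
  f[sec] <- f[sec] + (1 - grid$frac[sec])
  f
}

# owner-grid-only fraction, used for the single-center spherical-harmonic
# projections (basin I's density represented on its own grid)
proj_fraction <- function(grid, atom) {
  f <- basin_fraction(grid, atom)
  f[grid$owner != atom] <- 0
  f
}

#' @export
print.iqa_basin_grid <- function(x, ...) {
  cat("<iqa_basin_grid> preset:", x$preset$name, " atoms:", x$natom,
      " nodes:", length(x$weights), "\n")
  invisible(x)
}

#' Basin electron populations
#'
#' Integrates the density over each atomic basin; the sum over basins
#' reproduces the electron count to grid accuracy.
#'
#' @param wfn an `iqa_wavefunction`.
#' @param grid an `iqa_basin_grid`.
#' @return numeric vector of electron populations per atom.
#' @export
atomic_populations <- function(wfn, grid) {
  rho <- evaluate_density(wfn, grid$points)
  vapply(seq_len(grid$natom),
         function(a) sum(basin_weights(grid, a) * rho), 1.0)
}

#' Active integration weights of a basin grid
#'
#' Per-node weights for whole-space integrals: the sum over basins of each
#' grid's own-basin (fraction-weighted) node weights.  `sum(active_weights(g)
#' * f)` integrates `f` over all space consistently with the per-basin sums.
#'
#' @param grid an `iqa_basin_grid`.
#' @return numeric vector over nodes.
#' @export
active_weights <- function(grid) {
  grid$weights * grid$becke
}

#' Atomic overlap matrix over a basin
#'
#' `S^I_ij = int_{Omega_I} phi_i phi_j dV` for the occupied MOs; the sum of
#' the matrices over all basins resolves the MO orthonormality.
#'
#' @param wfn an `iqa_wavefunction`.
#' @param grid an `iqa_basin_grid`.
#' @param atom basin index.
#' @param movals optional cached [evaluate_mos()] result for `grid$points`.
#' @return symmetric nocc x nocc matrix.
#' @export
atomic_overlap_matrix <- function(wfn, grid, atom, movals = NULL) {
  bw <- basin_weights(grid, atom)
  sel <- bw > 0
  mo <- if (is.null(movals)) {
    evaluate_mos(wfn, grid$points[sel, , drop = FALSE])$mo
  } else movals$mo[sel, , drop = FALSE]
  wm <- mo * bw[sel]
  S <- t(wm) %*% mo
  (S + t(S)) / 2
}
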