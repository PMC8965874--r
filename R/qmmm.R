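# QM-MM coupling terms: basin-integrated electrostatics against MM point
# charges, Lennard-Jones van der Waals, MM bonded/nonbonded energies, and
# the bond-angle-torsion (BAT) atomic splitting.

#' Build the QM-MM interaction mask
#'
#' Electrostatics: every QM atom and link hydrogen interacts with every MM
#' site except MM sites bonded directly to a QM host (their interactions
#' are replaced by those of the link hydrogens).  van der Waals follows the
#' topology exclusion list (1-2, 1-3 excluded; 1-4 scaled).
#'
#' @param system an `iqa_system`.
#' @return object of class `iqa_mask`: `ele` and `vdw` logical matrices
#'   (QM/LINK x MM), `scale14_vdw` numeric matrix of 1-4 divisors, and the
#'   bonded-exclusion records.
#' @export
build_interaction_mask <- function(system) {
  qm <- system$qm_index; mm <- system$mm_index
  nq <- length(qm); nm <- length(mm)
  ele <- matrix(TRUE, nq, nm, dimnames = list(NULL, NULL))
  vdw <- matrix(TRUE, nq, nm)
  s14 <- matrix(1, nq, nm)
  excl <- derive_exclusions(system$topology)
  # MM sites bonded directly to a QM host: masked out of QM electrostatics
  if (!is.null(system$links) && nrow(system$links)) {
    for (r in seq_len(nrow(system$links))) {
      qh <- system$links$qm_host[r]
      if (!is.null(system$topology)) {
        b <- system$topology$bonds
        partners <- c(b$j[b$i == qh], b$i[b$j == qh])
        for (p in intersect(partners, mm))
          ele[, match(p, mm)] <- FALSE
      }
      mh <- system$links$mm_host[r]
      ele[, match(mh, mm)] <- FALSE
    }
  }
  if (!is.null(excl) && nrow(excl)) {
    for (r in seq_len(nrow(excl))) {
      i <- excl$i[r]; j <- excl$j[r]
      qi <- match(i, qm); mj <- match(j, mm)
      if (is.na(qi)) { qi <- match(j, qm); mj <- match(i, mm) }
      if (!is.na(qi) && !is.na(mj)) {
        if (excl$kind[r] == "14") {
          s14[qi, mj] <- system$topology$scale14["vdw"]
        } else {
          vdw[qi, mj] <- FALSE
          ele[qi, mj] <- FALSE
        }
      }
    }
  }
  structure(list(ele = ele, vdw = vdw, scale14_vdw = s14,
                 qm_index = qm, mm_index = mm, exclusions = excl),
            class = "iqa_mask")
}

# 1-2 and 1-3 (excluded) and 1-4 (scaled) pairs implied by the topology
derive_exclusions <- function(top) {
  if (is.null(top)) return(NULL)
  out <- NULL
  if (nrow(top$bonds))
    out <- rbind(out, data.frame(i = top$bonds$i, j = top$bonds$j,
                                 kind = "12"))
  if (nrow(top$angles))
    out <- rbind(out, data.frame(i = top$angles$i, j = top$angles$k,
                                 kind = "13"))
  if (nrow(top$dihedrals))
    out <- rbind(out, data.frame(i = top$dihedrals$i, j = top$dihedrals$l,
                                 kind = "14"))
  if (nrow(top$exclusions))
    out <- rbind(out, data.frame(i = top$exclusions$i, j = top$exclusions$j,
                                 kind = "12"))
  if (is.null(out)) return(NULL)
  key <- paste(pmin(out$i, out$j), pmax(out$i, out$j))
  pri <- order(match(out$kind, c("12", "13", "14")))  # strongest rule wins
  out <- out[pri, ][!duplicated(key[pri]), ]
  out
}

#' Basin-integrated QM-MM electrostatic energies
#'
#' `E_ele^IJ' = -q_J' int_{Omega_I} rho(r)/|r - R_J'| dV + Z_I q_J' /
#' |R_I - R_J'|` for every (QM basin I, MM site J') pair allowed by the
#' mask.  The sum over pairs equals the unpartitioned Coulomb interaction
#' of the full QM charge density with the MM charges to quadrature
#' accuracy.
#'
#' @param system an `iqa_system` with a wavefunction and charged MM sites.
#' @param grid an `iqa_basin_grid`.
#' @param mask an `iqa_mask` (default built from the system).
#' @return matrix (QM atoms x MM sites) of energies in hartree.
#' @export
qmmm_electrostatics <- function(system, grid, mask = NULL) {
  wfn <- system$wfn
  if (is.null(wfn)) stop("precondition error: no wavefunction")
  mm <- system$mm_index
  if (!length(mm)) return(matrix(0, grid$natom, 0))
  mmsites <- system$sites[mm, ]
  require_charges(mmsites, "QM-MM electrostatics")
  if (is.null(mask)) mask <- build_interaction_mask(system)
  rho <- evaluate_density(wfn, grid$points)
  mmxyz <- cbind(mmsites$x, mmsites$y, mmsites$z)
  out <- matrix(0, grid$natom, length(mm))
  for (I in seq_len(grid$natom)) {
    bwI <- basin_weights(grid, I)
    nz <- bwI > 0
    pts <- grid$points[nz, , drop = FALSE]
    # guard: MM site coincident with a grid node
    pot <- cpp_coulomb_sum(mmxyz, pts, (bwI * rho)[nz], 1e-6)
    nuc_d <- sqrt(rowSums((mmxyz -
                             matrix(wfn$nuc[I, ], length(mm), 3,
                                    byrow = TRUE))^2))
    out[I, ] <- mmsites$q * (-pot + wfn$Z[I] / nuc_d)
  }
  out[!mask$ele] <- 0
  out
}

#' QM-MM Lennard-Jones energies
#'
#' Amber convention: `eps_IJ [ (rmin_IJ/R)^12 - 2 (rmin_IJ/R)^6 ]` with
#' arithmetic `rmin` and geometric `eps` combining.
#'
#' @param system an `iqa_system`.
#' @param mask optional `iqa_mask` (vdW exclusions + 1-4 scaling).
#' @return matrix (QM sites x MM sites), kcal/mol.
#' @export
qmmm_vdw <- function(system, mask = NULL) {
  qm <- system$qm_index; mm <- system$mm_index
  if (!length(mm)) return(matrix(0, length(qm), 0))
  s <- system$sites
  if (anyNA(s$eps[c(qm, mm)]) )
    stop("missing LJ parameters on sites ",
         paste(which(is.na(s$eps)), collapse = ", "))
  if (is.null(mask)) mask <- build_interaction_mask(system)
  B <- iqa_units$bohr_angstrom
  out <- matrix(0, length(qm), length(mm))
  for (a in seq_along(qm)) {
    i <- qm[a]
    R <- sqrt((s$x[mm] - s$x[i])^2 + (s$y[mm] - s$y[i])^2 +
                (s$z[mm] - s$z[i])^2) * B     # Angstrom
    epsij <- sqrt(s$eps[i] * s$eps[mm])
    rmin <- s$rmin2[i] + s$rmin2[mm]
    s6 <- (rmin / R)^6
    out[a, ] <- epsij * (s6^2 - 2 * s6) / mask$scale14_vdw[a, ]
  }
  out[!mask$vdw] <- 0
  out
}

#' MM energy with per-record breakdown
#'
#' Amber functional form over the topology records plus nonbonded pair
#' energies over non-excluded MM-MM pairs (1-4 pairs divided by the
#' topology's scaling factors).  All energies in kcal/mol.
#'
#' @param topology an `iqa_topology`.
#' @param sites an `iqa_sites` carrying the coordinates (bohr) and charges.
#' @param pairs_within optional integer vector restricting nonbonded pairs
#'   to a subset of site indices (default: all sites in the topology).
#' @return object of class `iqa_mm_energy`: data.frames `bond_terms`,
#'   `angle_terms`, `dihedral_terms`, `nonbonded` (per pair ele/vdw), and
#'   `totals`.
#' @export
mm_energy <- function(topology, sites, pairs_within = NULL) {
  B <- iqa_units$bohr_angstrom
  xyz <- sites_xyz(sites) * B   # Angstrom
  bt <- topology$bonds
  bond_terms <- if (nrow(bt)) {
    r <- sqrt(rowSums((xyz[bt$i, , drop = FALSE] -
                         xyz[bt$j, , drop = FALSE])^2))
    data.frame(i = bt$i, j = bt$j, r = r,
               energy = bt$kb * (r - bt$r0)^2)
  } else data.frame(i = integer(0), j = integer(0), r = numeric(0),
                    energy = numeric(0))
  at <- topology$angles
  angle_terms <- if (nrow(at)) {
    v1 <- xyz[at$i, , drop = FALSE] - xyz[at$j, , drop = FALSE]
    v2 <- xyz[at$k, , drop = FALSE] - xyz[at$j, , drop = FALSE]
    ct <- rowSums(v1 * v2) /
      sqrt(rowSums(v1^2) * rowSums(v2^2))
    th <- acos(pmax(pmin(ct, 1), -1))
    data.frame(i = at$i, j = at$j, k = at$k, theta = th,
               energy = at$ktheta * (th - at$theta0)^2)
  } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                    theta = numeric(0), energy = numeric(0))
  dt <- topology$dihedrals
  dihedral_terms <- if (nrow(dt)) {
    phi <- dihedral_angle(xyz, dt$i, dt$j, dt$k, dt$l)
    data.frame(i = dt$i, j = dt$j, k = dt$k, l = dt$l, phi = phi,
               energy = dt$kn * (1 + cos(dt$n * phi - dt$gamma)))
  } else data.frame(i = integer(0), j = integer(0), k = integer(0),
                    l = integer(0), phi = numeric(0), energy = numeric(0))
  # nonbonded over non-excluded pairs
  n <- nrow(sites)
  idx <- if (is.null(pairs_within)) seq_len(n) else pairs_within
  excl <- derive_exclusions(topology)
  ekey <- if (!is.null(excl))
    paste(pmin(excl$i, excl$j), pmax(excl$i, excl$j)) else character(0)
  ekind <- if (!is.null(excl)) excl$kind else character(0)
  pairs <- NULL; se <- sv <- numeric(0)
  if (length(idx) > 1) {
    cmb <- utils::combn(idx, 2)
    key <- paste(pmin(cmb[1, ], cmb[2, ]), pmax(cmb[1, ], cmb[2, ]))
    mt <- match(key, ekey)
    kind <- ifelse(is.na(mt), "none", ekind[mt])
    keep <- kind %in% c("none", "14")
    pairs <- cbind(cmb[1, keep], cmb[2, keep])
    se <- ifelse(kind[keep] == "14", topology$scale14["ele"], 1)
    sv <- ifelse(kind[keep] == "14", topology$scale14["vdw"], 1)
  }
  nonbonded <- if (!is.null(pairs) && nrow(pairs)) {
    require_charges(sites[unique(as.integer(pairs)), ], "MM nonbonded terms")
    en <- cpp_lj_coulomb_pairs(xyz, sites$q, sites$eps, sites$rmin2,
                               pairs - 1L, se, sv, iqa_units$coulomb_kcal)
    data.frame(i = pairs[, 1], j = pairs[, 2], ele = en[, 1], vdw = en[, 2])
  } else data.frame(i = integer(0), j = integer(0), ele = numeric(0),
                    vdw = numeric(0))
  totals <- c(bond = sum(bond_terms$energy), angle = sum(angle_terms$energy),
              dihedral = sum(dihedral_terms$energy),
              ele = sum(nonbonded$ele), vdw = sum(nonbonded$vdw))
  structure(list(bond_terms = bond_terms, angle_terms = angle_terms,
                 dihedral_terms = dihedral_terms, nonbonded = nonbonded,
                 totals = c(totals, total = sum(totals)), n_sites = n),
            class = "iqa_mm_energy")
}

dihedral_angle <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  b2 <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  b3 <- xyz[l, , drop = FALSE] - xyz[k, , drop = FALSE]
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
              n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
              n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1]) /
    sqrt(rowSums(b2^2))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

#' @export
print.iqa_mm_energy <- function(x, ...) {
  cat("<iqa_mm_energy> totals (kcal/mol):\n")
  print(round(x$totals, 6))
  invisible(x)
}

#' Bond-angle-torsion atomic splitting
#'
#' Distributes each bonded-record energy evenly over its participating
#' atoms: one-half of bond energies, one-third of angle energies and
#' one-fourth of torsion energies to each atom.  The per-atom shares sum to
#' the per-record total exactly (the fractions are exact rationals).
#'
#' @param breakdown an `iqa_mm_energy`.
#' @return numeric vector of per-atom BAT energies (kcal/mol).
#' @export
bat_atomic_split <- function(breakdown) {
  n <- breakdown$n_sites
  out <- numeric(n)
  b <- breakdown$bond_terms
  for (r in seq_len(nrow(b))) {
    out[b$i[r]] <- out[b$i[r]] + b$energy[r] / 2
    out[b$j[r]] <- out[b$j[r]] + b$energy[r] / 2
  }
  a <- breakdown$angle_terms
  for (r in seq_len(nrow(a))) for (col in c("i", "j", "k"))
    out[a[[col]][r]] <- out[a[[col]][r]] + a$energy[r] / 3
  d <- breakdown$dihedral_terms
  for (r in seq_len(nrow(d))) for (col in c("i", "j", "k", "l"))
    out[d[[col]][r]] <- out[d[[col]][r]] + d$energy[r] / 4
  out
}

#' Merge QM-MM terms into an IQA term matrix
#'
#' @param terms an `iqa_terms`.
#' @param ele QM-MM electrostatic matrix (hartree), from
#'   [qmmm_electrostatics()].
#' @param vdw QM-MM LJ matrix (kcal/mol), from [qmmm_vdw()].
#' @return updated `iqa_terms`.
#' @export
merge_qmmm_terms <- function(terms, ele = NULL, vdw = NULL) {
  if (!is.null(ele)) terms$qmmm_ele <- ele
  if (!is.null(vdw)) terms$qmmm_vdw <- vdw
  terms
}
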