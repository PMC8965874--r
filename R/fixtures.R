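# Synthetic test systems with closed-form reference values, plus access to
# the packaged wavefunction fixtures.

#' Path to a packaged wavefunction fixture
#'
#' @param name fixture stem, e.g. `"h2o_hf_sto3g"`; see
#'   [fixture_manifest()].
#' @param ext file extension (default "wfx").
#' @return file path.
#' @export
fixture_path <- function(name, ext = "wfx") {
  p <- system.file("extdata", "wfn", paste0(name, ".", ext),
                   package = "iqadecomp")
  if (!nzchar(p)) stop("no packaged fixture '", name, ".", ext, "'")
  p
}

#' Oracle manifest of the packaged wavefunctions
#'
#' Reference values (SCF total, kinetic energy, dipole, energy components)
#' recorded by the independent generator that produced the fixtures.
#'
#' @return named list.
#' @export
fixture_manifest <- function() {
  jsonlite::fromJSON(system.file("extdata", "wfn", "manifest.json",
                                 package = "iqadecomp"))
}

#' Analytic spherical-Gaussian model system
#'
#' "Atoms" are single normalized s-Gaussian orbitals with electron weight
#' w and nuclear charge Z; every density-derived reference has a closed
#' form.  The emitted object is a regular `iqa_wavefunction`, consumable
#' by the full pipeline (use `weight = 2` for closed-shell operations).
#' With the orbital exponent alpha, the charge cloud of one atom is a
#' Gaussian with density exponent `beta = 2 alpha`, and the Coulomb energy
#' between unit clouds i and j at distance R is
#' `erf(sqrt(beta_i beta_j / (beta_i + beta_j)) R) / R`.
#'
#' @param n number of centers.
#' @param alpha orbital exponents (recycled).
#' @param weight electron weight per center (recycled; 2 = closed shell).
#' @param Z nuclear charges (recycled).
#' @param min_sep minimum center separation, bohr.
#' @param box placement cube half-width, bohr.
#' @param seed RNG seed for placement.
#' @return list with `wfn`, `expected` (populations, coulomb matrix,
#'   dipole vector) and the generating parameters.
#' @export
make_analytic_system <- function(n = 2, alpha = 1.0, weight = 1.0, Z = 1,
                                 min_sep = 8, box = 12, seed = 1) {
  if (any(alpha <= 0)) stop("exponents must be positive")
  alpha <- rep_len(alpha, n); weight <- rep_len(weight, n)
  Z <- rep_len(Z, n)
  set.seed(seed)
  centers <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    repeat {
      cand <- stats::runif(3, -box, box)
      if (i == 1 || all(sqrt(colSums((t(centers[seq_len(i - 1), ,
                                                 drop = FALSE]) -
                                        cand)^2)) >= min_sep)) {
        centers[i, ] <- cand
        break
      }
    }
  }
  norm <- (2 * alpha / pi)^0.75
  C <- diag(norm, n, n)
  wfn <- new_wavefunction(list(
    natom = n, Z = Z, nuc = centers,
    symbol = rep("H", n),
    prim_center = seq_len(n), prim_l = matrix(0L, n, 3),
    prim_alpha = alpha, C = C, occ = weight,
    mo_energy = rep(NA_real_, n), nelec = as.integer(round(sum(weight))),
    charge = as.integer(round(sum(Z) - sum(weight))),
    method = "HF", functional = "", scf_energy = NA_real_,
    source = "analytic", format = "analytic"))
  beta <- 2 * alpha
  coul <- matrix(0, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    R <- sqrt(sum((centers[i, ] - centers[j, ])^2))
    mu <- sqrt(beta[i] * beta[j] / (beta[i] + beta[j]))
    coul[i, j] <- coul[j, i] <-
      weight[i] * weight[j] * pracma_erf(mu * R) / R
  }
  dip <- colSums(centers * (Z - weight))
  list(wfn = wfn,
       expected = list(populations = weight, coulomb = coul, dipole = dip),
       alpha = alpha, weight = weight, centers = centers, seed = seed)
}

pracma_erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Metal-ion/water cluster generator
#'
#' A divalent metal cation surrounded by shells of rigid three-site
#' (TIP3P-geometry) waters: the first shell is octahedral with six
#' molecules; outer shells place molecules on spheres along deterministic
#' Fibonacci directions (plus a seeded azimuthal twist), oxygens toward
#' the ion.  Water charges are TIP3P (-0.834/+0.417 e).
#'
#' @param metal element symbol, "Mg" or "Zn".
#' @param shells number of water molecules per shell, e.g.
#'   `c(6, 12, 24, 48, 96)`.
#' @param qm_shells how many of the innermost shells are tagged QM
#'   (the ion is always QM when `qm_shells > 0`, MM otherwise).
#' @param r1 first-shell metal-oxygen distance, Angstrom (default 2.1).
#' @param shell_gap increment between shell radii, Angstrom (default 1.4).
#' @param min_sep minimum O-O distance between placed waters, Angstrom.
#' @param seed RNG seed for the azimuthal twists.
#' @return list with `sites` (`iqa_sites`, positions bohr), `n_waters`,
#'   `cumulative_qm_waters` and the per-shell radii.
#' @export
make_metal_cluster <- function(metal = "Zn", shells = c(6, 12, 24, 48, 96),
                               qm_shells = 1, r1 = 2.1, shell_gap = 1.4,
                               min_sep = 2.4, seed = 1) {
  if (any(shells <= 0)) stop("shell counts must be positive")
  set.seed(seed)
  B <- iqa_units$bohr_angstrom
  roh <- 0.9572; ang <- 104.52 * pi / 180
  water_at <- function(opos, outward) {
    # oxygen at opos, H-H bisector along +outward (H away from the ion)
    u <- outward / sqrt(sum(outward^2))
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ref - sum(ref * u) * u; v <- v / sqrt(sum(v^2))
    h1 <- opos + roh * (cos(ang / 2) * u + sin(ang / 2) * v)
    h2 <- opos + roh * (cos(ang / 2) * u - sin(ang / 2) * v)
    rbind(opos, h1, h2)
  }
  oct_dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))
  fib_dirs <- function(m, twist) {
    k <- seq_len(m)
    ga <- pi * (3 - sqrt(5))
    z <- 1 - (2 * k - 1) / m
    rxy <- sqrt(pmax(0, 1 - z^2))
    cbind(rxy * cos(ga * k + twist), rxy * sin(ga * k + twist), z)
  }
  xyz <- NULL; elem <- character(0); q <- numeric(0); region <- character(0)
  eps <- numeric(0); rmin2 <- numeric(0)
  radius_of_shell <- numeric(length(shells))
  placed_O <- NULL
  for (s in seq_along(shells)) {
    m <- shells[s]
    rs <- r1 + (s - 1) * shell_gap
    dirs <- if (s == 1 && m == 6) oct_dirs
            else fib_dirs(m, stats::runif(1, 0, 2 * pi))
    # enforce minimum O-O separation by inflating the shell if needed
    repeat {
      opos <- rs * dirs
      allO <- rbind(placed_O, opos)
      dmin <- min(stats::dist(allO))
      if (dmin >= min_sep || rs > 40) break
      rs <- rs + 0.1
    }
    radius_of_shell[s] <- rs
    tag <- if (s <= qm_shells) "QM" else "MM"
    for (k in seq_len(m)) {
      w <- water_at(opos[k, ], dirs[k, ])
      xyz <- rbind(xyz, w)
      elem <- c(elem, "O", "H", "H")
      q <- c(q, -0.834, 0.417, 0.417)
      region <- c(region, rep(tag, 3))
      eps <- c(eps, 0.1520, 0, 0)
      rmin2 <- c(rmin2, 1.7683, 0, 0)
    }
    placed_O <- rbind(placed_O, opos)
  }
  xyz <- rbind(c(0, 0, 0), xyz)
  elem <- c(metal, elem)
  q <- c(2, q)
  region <- c(if (qm_shells > 0) "QM" else "MM", region)
  eps <- c(0.013, eps)       # representative divalent-cation LJ well
  rmin2 <- c(1.42, rmin2)
  sites <- site_set(elem, xyz / B, q = q, eps = eps, rmin2 = rmin2,
                    radius = default_pb_radii(elem), region = region)
  list(sites = sites, n_waters = sum(shells),
       cumulative_qm_waters = cumsum(shells)[seq_len(max(qm_shells, 0))],
       shell_radii = radius_of_shell, shells = shells, seed = seed)
}

#' Toy host-guest complex for the end-to-end scoring exercise
#'
#' A packaged QM water "ligand" inside an MM point-charge "receptor" cage
#' (alternating charges on a sphere, net zero), with consistent inputs
#' for the complex and the two isolated species at identical geometries.
#'
#' @param seed RNG seed (azimuthal twist of the cage).
#' @param n_cage number of cage sites (even; default 12).
#' @param cage_radius cage radius in Angstrom (default 5).
#' @param cage_q magnitude of the alternating cage charges (default 0.4).
#' @return list with `complex` (`iqa_system`), `ligand_wfn`,
#'   `receptor_sites`, `fragment_scheme` (ligand/receptor) and geometry
#'   metadata.
#' @export
make_toy_complex <- function(seed = 1, n_cage = 12, cage_radius = 5,
                             cage_q = 0.4) {
  if (n_cage %% 2 != 0) stop("n_cage must be even for a neutral cage")
  set.seed(seed)
  B <- iqa_units$bohr_angstrom
  wfn <- load_wavefunction(fixture_path("h2o_hf_sto3g"))
  k <- seq_len(n_cage)
  ga <- pi * (3 - sqrt(5))
  tw <- stats::runif(1, 0, 2 * pi)
  z <- 1 - (2 * k - 1) / n_cage
  rxy <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(rxy * cos(ga * k + tw), rxy * sin(ga * k + tw), z)
  cage <- dirs * cage_radius / B  # bohr
  qs <- rep(c(cage_q, -cage_q), length.out = n_cage)
  qm_sites <- site_set(wfn$symbol, wfn$nuc, q = NA_real_,
                       eps = c(0.1521, 0.0, 0.0),
                       rmin2 = c(1.7683, 0.6, 0.6),
                       radius = default_pb_radii(wfn$symbol), region = "QM")
  mm_sites <- site_set(rep("Cl", n_cage), cage, q = qs, eps = 0.1,
                       rmin2 = 1.9, radius = 1.9, region = "MM")
  system <- assemble_system(wfn = wfn, qm_sites = qm_sites,
                            mm_sites = mm_sites)
  list(complex = system, ligand_wfn = wfn, receptor_sites = mm_sites,
       fragment_scheme = fragment_scheme(rep("ligand", 3)),
       cage_radius = cage_radius, seed = seed)
}
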