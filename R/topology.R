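#' Construct an MM topology
#'
#' Bonded-term records in the Amber functional form: bond energies
#' `k_b (r - r0)^2`, angle energies `k_theta (theta - theta0)^2` and
#' torsions `sum_n k_n (1 + cos(n phi - gamma))` (force constants already
#' contain the conventional 1/2).  Angles/phases are stored in radians
#' internally; readers convert from degrees.
#'
#' @param bonds data.frame(i, j, kb, r0): kcal/mol/A^2, Angstrom.
#' @param angles data.frame(i, j, k, ktheta, theta0): kcal/mol/rad^2, radians.
#' @param dihedrals data.frame(i, j, k, l, kn, n, gamma): kcal/mol, periodicity,
#'   radians.  Multiple rows per dihedral express Fourier series.
#' @param exclusions data.frame(i, j) of extra nonbonded exclusions (beyond
#'   the 1-2/1-3 pairs implied by bonds/angles).
#' @param scale14 named numeric: `ele` and `vdw` 1-4 scaling divisors
#'   (Amber defaults 1.2 and 2.0).
#' @param n_sites number of sites indexed by the records.
#' @return object of class `iqa_topology`.
#' @export
mm_topology <- function(bonds = NULL, angles = NULL, dihedrals = NULL,
                        exclusions = NULL, scale14 = c(ele = 1.2, vdw = 2.0),
                        n_sites = NULL) {
  empty <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                        cols))
    df
  }
  top <- list(
    bonds = if (is.null(bonds)) empty(c("i", "j", "kb", "r0")) else bonds,
    angles = if (is.null(angles)) empty(c("i", "j", "k", "ktheta", "theta0"))
             else angles,
    dihedrals = if (is.null(dihedrals))
      empty(c("i", "j", "k", "l", "kn", "n", "gamma")) else dihedrals,
    exclusions = if (is.null(exclusions)) empty(c("i", "j")) else exclusions,
    scale14 = scale14,
    n_sites = n_sites)
  class(top) <- "iqa_topology"
  validate_topology(top)
  top
}

validate_topology <- function(top) {
  idx <- c(top$bonds$i, top$bonds$j, top$angles$i, top$angles$j, top$angles$k,
           top$dihedrals$i, top$dihedrals$j, top$dihedrals$k, top$dihedrals$l,
           top$exclusions$i, top$exclusions$j)
  if (length(idx) && any(idx < 1))
    stop("topology consistency error: non-positive site index")
  if (!is.null(top$n_sites) && length(idx) && any(idx > top$n_sites))
    stop("topology consistency error: site index ", max(idx),
         " exceeds n_sites = ", top$n_sites)
  if (nrow(top$dihedrals) && any(top$dihedrals$n < 1))
    stop("topology consistency error: dihedral periodicity must be >= 1")
  invisible(top)
}

#' @export
print.iqa_topology <- function(x, ...) {
  cat("<iqa_topology> bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " dihedrals:", nrow(x$dihedrals), "\n")
  invisible(x)
}

#' Load an MM topology (+ sites) from file
#'
#' Two dialects are supported: a minimal subset of the Amber `prmtop`
#' format (charges, Lennard-Jones parameters, bond/angle/dihedral records,
#' PB radii; other sections are ignored with a notice) and a simple
#' declarative `toy` format for hand-written test systems (see
#' `vignette("iqa-qmmm")` for the schema).
#'
#' @param path file path.
#' @param dialect `"prmtop"` or `"toy"` (default guessed from content).
#' @return list with elements `topology` (`iqa_topology`) and `sites`
#'   (`iqa_sites`; positions NA for prmtop, which carries none).
#' @export
load_topology <- function(path, dialect = c("auto", "prmtop", "toy")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("topology file not found: ", path)
  head1 <- readLines(path, n = 1, warn = FALSE)
  if (dialect == "auto")
    dialect <- if (grepl("^%VERSION", head1)) "prmtop" else "toy"
  switch(dialect, prmtop = load_prmtop(path), toy = load_toytop(path))
}

load_toytop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  tok <- strsplit(trimws(lines), "\\s+")
  kw <- vapply(tok, `[[`, "", 1)
  num <- function(t, from, n, line) {
    v <- suppressWarnings(as.numeric(t[from:(from + n - 1)]))
    if (anyNA(v)) stop("toy topology parse error near: ", line)
    v
  }
  sites <- NULL; bonds <- NULL; angles <- NULL; dihedrals <- NULL
  excl <- NULL; s14 <- c(ele = 1.2, vdw = 2.0)
  B <- iqa_units$bohr_angstrom
  for (k in seq_along(tok)) {
    t <- tok[[k]]
    switch(kw[k],
      site = {
        v <- num(t, 4, 4, lines[k])
        xyz <- if (length(t) >= 11) num(t, 9, 3, lines[k]) else rep(NA_real_, 3)
        sites <- rbind(sites, data.frame(
          name = t[2], element = t[3], q = v[1], eps = v[2], rmin2 = v[3],
          radius = v[4], region = t[8],
          x = xyz[1] / B, y = xyz[2] / B, z = xyz[3] / B))
      },
      bond = {
        v <- num(t, 2, 4, lines[k])
        bonds <- rbind(bonds, data.frame(i = v[1], j = v[2], kb = v[3],
                                         r0 = v[4]))
      },
      angle = {
        v <- num(t, 2, 5, lines[k])
        angles <- rbind(angles, data.frame(i = v[1], j = v[2], k = v[3],
                                           ktheta = v[4],
                                           theta0 = v[5] * pi / 180))
      },
      dihedral = {
        v <- num(t, 2, 7, lines[k])
        dihedrals <- rbind(dihedrals, data.frame(
          i = v[1], j = v[2], k = v[3], l = v[4], kn = v[5], n = v[6],
          gamma = v[7] * pi / 180))
      },
      exclude = {
        v <- num(t, 2, 2, lines[k])
        excl <- rbind(excl, data.frame(i = v[1], j = v[2]))
      },
      scale14 = { s14 <- c(ele = as.numeric(t[2]), vdw = as.numeric(t[3])) },
      toytop = NULL,
      stop("toy topology parse error: unknown keyword '", kw[k], "'"))
  }
  ss <- if (is.null(sites)) {
    site_set(character(0), matrix(0, 0, 3))
  } else {
    site_set(sites$element, cbind(sites$x, sites$y, sites$z), q = sites$q,
             eps = sites$eps, rmin2 = sites$rmin2, radius = sites$radius,
             region = sites$region, name = sites$name)
  }
  top <- mm_topology(bonds, angles, dihedrals, excl, s14,
                     n_sites = nrow(ss))
  list(topology = top, sites = ss)
}

prmtop_section <- function(lines, flag, required = TRUE) {
  i <- grep(paste0("^%FLAG ", flag, "\\s*$"), lines)
  if (!length(i)) {
    if (required) stop("prmtop parse error: missing mandatory section %FLAG ",
                       flag)
    return(NULL)
  }
  j <- i[1] + 1
  while (grepl("^%", lines[j])) j <- j + 1
  k <- j
  while (k <= length(lines) && !grepl("^%", lines[k])) k <- k + 1
  body <- lines[j:(k - 1)]
  unlist(strsplit(trimws(body), "\\s+"))
}

load_prmtop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nums <- function(flag, required = TRUE) {
    v <- prmtop_section(lines, flag, required)
    if (is.null(v)) return(NULL)
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out)) stop("prmtop parse error: non-numeric data in ", flag)
    out
  }
  ptr <- as.integer(nums("POINTERS"))
  natom <- ptr[1]; ntypes <- ptr[2]
  charge <- nums("CHARGE") / iqa_units$prmtop_charge
  if (length(charge) != natom)
    stop("prmtop consistency error: CHARGE length != NATOM")
  mass <- nums("MASS", required = FALSE)
  tidx <- as.integer(nums("ATOM_TYPE_INDEX"))
  nbidx <- as.integer(nums("NONBONDED_PARM_INDEX"))
  acoef <- nums("LENNARD_JONES_ACOEF")
  bcoef <- nums("LENNARD_JONES_BCOEF")
  eps <- rmin2 <- numeric(natom)
  for (a in seq_len(natom)) {
    ti <- tidx[a]
    pp <- nbidx[ntypes * (ti - 1) + ti]
    A <- acoef[pp]; Bc <- bcoef[pp]
    if (A > 0 && Bc > 0) {
      eps[a] <- Bc^2 / (4 * A)
      rmin2[a] <- 0.5 * (2 * A / Bc)^(1 / 6)
    }
  }
  radii <- nums("RADII", required = FALSE)
  elem <- if (!is.null(mass)) {
    guess <- c(H = 1.008, He = 4.003, C = 12.01, N = 14.01, O = 16.0,
               F = 19.0, Mg = 24.305, P = 30.97, S = 32.06, Cl = 35.45,
               Ca = 40.08, Zn = 65.38)
    names(guess)[apply(abs(outer(mass, guess, "-")), 1, which.min)]
  } else rep("X", natom)
  nm <- prmtop_section(lines, "ATOM_NAME", required = FALSE)
  bonded <- function(flagH, flagA, per, kflag, eqflag, extra = NULL) {
    raw <- c(nums(flagH, required = FALSE), nums(flagA, required = FALSE))
    if (is.null(raw) || !length(raw)) return(NULL)
    m <- matrix(as.integer(raw), ncol = per, byrow = TRUE)
    m
  }
  bk <- nums("BOND_FORCE_CONSTANT", required = FALSE)
  br <- nums("BOND_EQUIL_VALUE", required = FALSE)
  bm <- bonded("BONDS_INC_HYDROGEN", "BONDS_WITHOUT_HYDROGEN", 3)
  bonds <- NULL
  if (!is.null(bm)) {
    bonds <- data.frame(i = bm[, 1] / 3 + 1, j = bm[, 2] / 3 + 1,
                        kb = bk[bm[, 3]], r0 = br[bm[, 3]])
  }
  ak <- nums("ANGLE_FORCE_CONSTANT", required = FALSE)
  a0 <- nums("ANGLE_EQUIL_VALUE", required = FALSE)  # radians in prmtop
  am <- bonded("ANGLES_INC_HYDROGEN", "ANGLES_WITHOUT_HYDROGEN", 4)
  angles <- NULL
  if (!is.null(am)) {
    angles <- data.frame(i = am[, 1] / 3 + 1, j = am[, 2] / 3 + 1,
                         k = am[, 3] / 3 + 1, ktheta = ak[am[, 4]],
                         theta0 = a0[am[, 4]])
  }
  dk <- nums("DIHEDRAL_FORCE_CONSTANT", required = FALSE)
  dn <- nums("DIHEDRAL_PERIODICITY", required = FALSE)
  dp <- nums("DIHEDRAL_PHASE", required = FALSE)     # radians
  dm <- bonded("DIHEDRALS_INC_HYDROGEN", "DIHEDRALS_WITHOUT_HYDROGEN", 5)
  dihedrals <- NULL
  if (!is.null(dm)) {
    dihedrals <- data.frame(i = dm[, 1] / 3 + 1, j = dm[, 2] / 3 + 1,
                            k = abs(dm[, 3]) / 3 + 1, l = abs(dm[, 4]) / 3 + 1,
                            kn = dk[dm[, 5]], n = dn[dm[, 5]],
                            gamma = dp[dm[, 5]])
  }
  s14 <- c(ele = 1.2, vdw = 2.0)
  scee <- nums("SCEE_SCALE_FACTOR", required = FALSE)
  scnb <- nums("SCNB_SCALE_FACTOR", required = FALSE)
  if (!is.null(scee) && length(scee)) s14["ele"] <- scee[1]
  if (!is.null(scnb) && length(scnb)) s14["vdw"] <- scnb[1]
  message("prmtop: read charges/LJ/bonded subset; other sections ignored")
  sites <- site_set(elem, matrix(NA_real_, natom, 3), q = charge, eps = eps,
                    rmin2 = rmin2,
                    radius = if (is.null(radii)) NA_real_ else radii,
                    region = "MM",
                    name = if (is.null(nm)) elem else nm[seq_len(natom)])
  top <- mm_topology(bonds, angles, dihedrals, NULL, s14, n_sites = natom)
  list(topology = top, sites = sites)
}
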