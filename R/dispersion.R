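# Pairwise D3 dispersion with Becke-Johnson rational damping.
#
# The model: fractional coordination numbers from a smooth counting
# function over covalent radii; pair C6 coefficients interpolated over the
# tabulated (CN_i, CN_j) reference points with Gaussian weights; C8 from
# C6 and per-element multipole factors; BJ-damped -C6/R^6 - C8/R^8 pair
# energies.  Parameter tables are data assets in inst/extdata/d3 (the
# shipped C6/Q tables are synthetic stand-ins, see their file names and
# data-raw/make_d3_data.R; drop-in replacement files with the published
# values use the same schema).

D3_K1 <- 16    # CN counting-function steepness
D3_K2 <- 4 / 3 # covalent-radius scaling
D3_K3 <- 4     # Gaussian C6 interpolation exponent

#' Load a D3 parameter set
#'
#' @param functional damping-set label (default `"b3lyp"`).
#' @param dir data directory (default: the packaged tables).
#' @return object of class `iqa_d3_params`: damping constants (s6, s8, a1,
#'   a2), covalent radii, per-element multipole factors and the C6
#'   reference table.
#' @export
d3_params <- function(functional = "b3lyp",
                      dir = system.file("extdata", "d3",
                                        package = "iqadecomp")) {
  damping <- utils::read.csv(file.path(dir, "d3_damping.csv"))
  row <- damping[damping$functional == tolower(functional), ]
  if (!nrow(row)) stop("no BJ damping set for functional '", functional, "'")
  rcov <- utils::read.csv(file.path(dir, "d3_covalent_radii.csv"))
  qf <- utils::read.csv(file.path(dir, "d3_q_factor_synthetic.csv"))
  c6 <- utils::read.csv(file.path(dir, "d3_c6_reference_synthetic.csv"))
  if (any(c6$c6 <= 0) || row$s6 <= 0) stop("invalid D3 data")
  structure(list(functional = row$functional, s6 = row$s6, s8 = row$s8,
                 a1 = row$a1, a2 = row$a2,
                 rcov = stats::setNames(rcov$r_cov, rcov$element),
                 q = stats::setNames(qf$q, qf$element),
                 c6ref = c6),
            class = "iqa_d3_params")
}

d3_check_elements <- function(elements, params) {
  missing <- setdiff(unique(elements), names(params$rcov))
  if (length(missing))
    stop("element(s) not covered by the D3 parameter tables: ",
         paste(missing, collapse = ", "))
}

#' Fractional coordination numbers
#'
#' `CN_i = sum_j 1 / (1 + exp(-16 (4/3 (r_i + r_j) / R_ij - 1)))` over all
#' other sites; zero for an isolated atom.
#'
#' @param sites an `iqa_sites` (positions in bohr, elements used for the
#'   radii).
#' @param params an `iqa_d3_params`.
#' @return numeric vector of coordination numbers.
#' @export
coordination_numbers <- function(sites, params = d3_params()) {
  d3_check_elements(sites$element, params)
  n <- nrow(sites)
  if (n == 0) return(numeric(0))
  B <- iqa_units$bohr_angstrom
  xyz <- sites_xyz(sites) * B
  rc <- params$rcov[sites$element]
  cn <- numeric(n)
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    if (!length(j)) next
    R <- sqrt(rowSums((xyz[j, , drop = FALSE] -
                         matrix(xyz[i, ], length(j), 3, byrow = TRUE))^2))
    cn[i] <- sum(1 / (1 + exp(-D3_K1 * (D3_K2 * (rc[i] + rc[j]) / R - 1))))
  }
  cn
}

d3_c6_pair <- function(ei, ej, cni, cnj, params) {
  tab <- params$c6ref
  swap <- match(ei, names(params$rcov)) > match(ej, names(params$rcov))
  a <- if (swap) ej else ei
  b <- if (swap) ei else ej
  ca <- if (swap) cnj else cni
  cb <- if (swap) cni else cnj
  sel <- tab$elem_i == a & tab$elem_j == b
  sub <- tab[sel, ]
  if (!nrow(sub)) stop("no C6 reference data for pair ", ei, "-", ej)
  w <- exp(-D3_K3 * ((sub$cn_i - ca)^2 + (sub$cn_j - cb)^2))
  # same-element pairs carry each (cn_i, cn_j) once; mirror the weights
  if (a == b) {
    wm <- exp(-D3_K3 * ((sub$cn_j - ca)^2 + (sub$cn_i - cb)^2))
    w <- w + ifelse(sub$cn_i == sub$cn_j, 0, wm)
  }
  sum(w * sub$c6) / sum(w)
}

#' Pairwise D3(BJ) dispersion energies
#'
#' `E_ij = -s6 C6/(R^6 + f^6) - s8 C8/(R^8 + f^8)` with
#' `f = a1 sqrt(C8/C6) + a2` and `C8 = 3 C6 sqrt(Q_i Q_j)`.
#'
#' @param sites an `iqa_sites`.
#' @param params an `iqa_d3_params`.
#' @param cn optional precomputed coordination numbers.
#' @return list with `pairs` (symmetric matrix, hartree) and `total`.
#' @export
d3bj_pair_energies <- function(sites, params = d3_params(), cn = NULL) {
  d3_check_elements(sites$element, params)
  n <- nrow(sites)
  E <- matrix(0, n, n)
  if (n >= 2) {
    if (is.null(cn)) cn <- coordination_numbers(sites, params)
    xyz <- sites_xyz(sites)  # bohr
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      R <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      c6 <- d3_c6_pair(sites$element[i], sites$element[j], cn[i], cn[j],
                       params)
      c8 <- 3 * c6 * sqrt(params$q[sites$element[i]] *
                            params$q[sites$element[j]])
      f <- params$a1 * sqrt(c8 / c6) + params$a2
      e <- -params$s6 * c6 / (R^6 + f^6) - params$s8 * c8 / (R^8 + f^8)
      E[i, j] <- E[j, i] <- e
    }
  }
  list(pairs = E, total = sum(E[upper.tri(E)]), cn = cn,
       functional = params$functional)
}

#' Merge D3 pair energies into an IQA term matrix
#'
#' Adds the dispersion pair matrix for the QM atoms to the term object;
#' dispersion then enters the diatomic interactions and additive energies.
#'
#' @param terms an `iqa_terms`.
#' @param disp result of [d3bj_pair_energies()] for the QM sites (matrix
#'   dimension must match the QM atom count).
#' @return updated `iqa_terms`.
#' @export
merge_dispersion <- function(terms, disp) {
  P <- if (is.list(disp)) disp$pairs else disp
  if (!all(dim(P) == terms$natom))
    stop("dispersion pair matrix dimension does not match the QM atoms")
  terms$disp <- P
  terms
}
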