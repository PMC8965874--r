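#' @useDynLib iqadecomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal wavefunction representation: everything reduced to unnormalized
# Cartesian primitives.  Fields:
#   natom, Z, nuc (natom x 3, bohr), symbol
#   nprim, prim_center (1-based), prim_l (nprim x 3), prim_alpha
#   C (nprim x nmo): MO coefficients over unnormalized primitives
#   occ, mo_energy, nelec, charge, method ("HF"|"DFT"), functional,
#   scf_energy (hartree), source, format

ELEMENT_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10, Na = 11, Mg = 12, P = 15, S = 16, Cl = 17,
               Ca = 20, Zn = 30)

# wfn/wfx primitive type table (AIMPAC ordering), type -> (lx, ly, lz)
WFX_TYPES <- rbind(
  c(0,0,0),
  c(1,0,0), c(0,1,0), c(0,0,1),
  c(2,0,0), c(0,2,0), c(0,0,2), c(1,1,0), c(1,0,1), c(0,1,1),
  c(3,0,0), c(0,3,0), c(0,0,3), c(2,1,0), c(2,0,1), c(0,2,1),
  c(1,2,0), c(1,0,2), c(0,1,2), c(1,1,1))

new_wavefunction <- function(fields) {
  structure(fields, class = "iqa_wavefunction")
}

#' @export
print.iqa_wavefunction <- function(x, ...) {
  cat("<iqa_wavefunction> ", x$method,
      if (nzchar(x$functional)) paste0("(", x$functional, ")"), "\n")
  cat("  nuclei:", x$natom, " electrons:", x$nelec,
      " occupied MOs:", ncol(x$C), " primitives:", nrow(x$C), "\n")
  cat("  SCF energy:", format(x$scf_energy, digits = 10), "hartree\n")
  invisible(x)
}

wfx_section <- function(lines, tag, required = TRUE) {
  open <- paste0("<", tag, ">"); close <- paste0("</", tag, ">")
  i <- which(trimws(lines) == open)
  j <- which(trimws(lines) == close)
  if (length(i) != 1 || length(j) != 1 || j <= i) {
    if (required) stop("wfx parse error: missing or malformed section <",
                       tag, ">")
    return(NULL)
  }
  lines[(i + 1):(j - 1)]
}

wfx_numbers <- function(lines, tag, required = TRUE) {
  sec <- wfx_section(lines, tag, required)
  if (is.null(sec)) return(NULL)
  out <- suppressWarnings(as.numeric(unlist(strsplit(trimws(sec), "\\s+"))))
  if (anyNA(out)) stop("wfx parse error: non-numeric data in <", tag, ">")
  out
}

load_wfx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  natom <- as.integer(wfx_numbers(lines, "Number of Nuclei"))
  nmo <- as.integer(wfx_numbers(lines, "Number of Occupied Molecular Orbitals"))
  nelec <- as.integer(wfx_numbers(lines, "Number of Electrons"))
  charge <- as.integer(wfx_numbers(lines, "Net Charge"))
  Z <- wfx_numbers(lines, "Nuclear Charges")
  coords <- matrix(wfx_numbers(lines, "Nuclear Cartesian Coordinates"),
                   ncol = 3, byrow = TRUE)
  if (nrow(coords) != natom) stop("wfx consistency error: nucleus count")
  nprim <- as.integer(wfx_numbers(lines, "Number of Primitives"))
  cen <- as.integer(wfx_numbers(lines, "Primitive Centers"))
  typ <- as.integer(wfx_numbers(lines, "Primitive Types"))
  alpha <- wfx_numbers(lines, "Primitive Exponents")
  if (length(cen) != nprim || length(typ) != nprim || length(alpha) != nprim)
    stop("wfx parse error: primitive record lengths disagree")
  if (any(typ < 1 | typ > nrow(WFX_TYPES)))
    stop("wfx parse error: unsupported primitive type (beyond f functions)")
  if (any(cen < 1 | cen > natom))
    stop("wfx consistency error: primitive center index out of range")
  occ <- wfx_numbers(lines, "Molecular Orbital Occupation Numbers")
  ene <- wfx_numbers(lines, "Molecular Orbital Energies", required = FALSE)
  mosec <- wfx_section(lines, "Molecular Orbital Primitive Coefficients")
  # strip <MO Number> blocks
  keep <- !grepl("MO Number", mosec)
  drop_num <- rep(FALSE, length(mosec))
  inblk <- FALSE
  for (k in seq_along(mosec)) {
    t <- trimws(mosec[k])
    if (t == "<MO Number>") { inblk <- TRUE; drop_num[k] <- TRUE }
    else if (t == "</MO Number>") { inblk <- FALSE; drop_num[k] <- TRUE }
    else if (inblk) drop_num[k] <- TRUE
  }
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(mosec[!drop_num]),
                                                      "\\s+"))))
  if (anyNA(vals) || length(vals) != nprim * nmo)
    stop("wfx parse error: MO coefficient block has ", length(vals),
         " values, expected ", nprim * nmo)
  C <- matrix(vals, nrow = nprim, ncol = nmo)
  energy <- wfx_numbers(lines, "Energy = T + Vne + Vee + Vnn", required = FALSE)
  title <- wfx_section(lines, "Title", required = FALSE)
  func <- ""
  method <- "HF"
  if (!is.null(title) && grepl("B3LYP|PBE|DFT|TPSS|M06", title[1],
                               ignore.case = TRUE)) {
    method <- "DFT"
    func <- regmatches(title[1], regexpr("B3LYP|PBE0?|TPSS|M06\\S*", title[1]))
    if (length(func) == 0) func <- "unknown"
  }
  new_wavefunction(list(
    natom = natom, Z = Z, nuc = coords,
    symbol = names(ELEMENT_Z)[match(round(Z), ELEMENT_Z)],
    prim_center = cen, prim_l = WFX_TYPES[typ, , drop = FALSE],
    prim_alpha = alpha, C = C, occ = occ,
    mo_energy = if (is.null(ene)) rep(NA_real_, nmo) else ene,
    nelec = nelec, charge = charge, method = method, functional = func,
    scf_energy = if (is.null(energy)) NA_real_ else energy,
    source = path, format = "wfx"))
}

# Molden Cartesian component orders per angular momentum
MOLDEN_ORDER <- list(
  `0` = rbind(c(0,0,0)),
  `1` = rbind(c(1,0,0), c(0,1,0), c(0,0,1)),
  `2` = rbind(c(2,0,0), c(0,2,0), c(0,0,2), c(1,1,0), c(1,0,1), c(0,1,1)),
  `3` = rbind(c(3,0,0), c(0,3,0), c(0,0,3), c(1,2,0), c(2,1,0), c(2,0,1),
              c(1,0,2), c(0,1,2), c(0,2,1), c(1,1,1)))

dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

load_molden <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lt <- trimws(lines)
  if (!any(grepl("^\\[Molden Format\\]", lt, ignore.case = TRUE)))
    stop("molden parse error: missing [Molden Format] header")
  if (any(grepl("^\\[(5D|7F|9G|5D7F|5D10F)\\]", lt, ignore.case = TRUE)))
    stop("molden parse error: spherical-harmonic basis ([5D]/[7F]) not ",
         "supported; re-export with Cartesian functions")
  sec_idx <- grep("^\\[", lt)
  find_sec <- function(name) {
    i <- grep(paste0("^\\[", name, "\\]"), lt, ignore.case = TRUE)
    if (length(i) != 1) stop("molden parse error: missing [", name, "] section")
    nexti <- sec_idx[sec_idx > i]
    end <- if (length(nexti)) min(nexti) - 1 else length(lt)
    (i):(end)
  }
  # Atoms
  ai <- find_sec("Atoms")
  hdr <- lt[ai[1]]
  unit <- if (grepl("AU", hdr, ignore.case = TRUE)) "au" else "angstrom"
  rows <- lt[ai[-1]]; rows <- rows[nzchar(rows)]
  at <- do.call(rbind, lapply(rows, function(r) strsplit(r, "\\s+")[[1]]))
  Z <- as.numeric(at[, 3])
  coords <- matrix(as.numeric(at[, 4:6]), ncol = 3)
  if (unit == "angstrom") coords <- coords / iqa_units$bohr_angstrom
  natom <- length(Z)
  # GTO
  gi <- find_sec("GTO")
  gl <- lt[gi[-1]]
  shells <- list()   # each: list(atom, l, exps, coefs) input convention
  k <- 1
  while (k <= length(gl)) {
    row <- gl[k]
    if (!nzchar(row)) { k <- k + 1; next }
    tok <- strsplit(row, "\\s+")[[1]]
    if (length(tok) >= 1 && grepl("^[0-9]+$", tok[1]) &&
        (length(tok) == 1 || grepl("^[0-9]+$", tok[2]))) {
      cur_atom <- as.integer(tok[1]); k <- k + 1
      repeat {
        if (k > length(gl) || !nzchar(gl[k])) { k <- k + 1; break }
        st <- strsplit(gl[k], "\\s+")[[1]]
        lsym <- tolower(st[1])
        if (!lsym %in% c("s", "p", "d", "f"))
          stop("molden parse error: unsupported shell type '", st[1], "'")
        nprim <- as.integer(st[2]); k <- k + 1
        ex <- co <- numeric(nprim)
        for (q in seq_len(nprim)) {
          pr <- strsplit(gsub("[dD]", "e", gl[k]), "\\s+")[[1]]
          ex[q] <- as.numeric(pr[1]); co[q] <- as.numeric(pr[2]); k <- k + 1
        }
        if (anyNA(ex) || anyNA(co))
          stop("molden parse error: non-numeric primitive in [GTO]")
        shells[[length(shells) + 1]] <-
          list(atom = cur_atom, l = match(lsym, c("s","p","d","f")) - 1L,
               exps = ex, coefs = co)
        if (k > length(gl) || !nzchar(gl[k])) { k <- k + 1; break }
      }
    } else k <- k + 1
  }
  if (!length(shells)) stop("molden parse error: no shells in [GTO]")
  # expand contracted Cartesian functions -> primitives
  prim_center <- integer(0); prim_l <- NULL; prim_alpha <- numeric(0)
  fn_shell <- integer(0); fn_comp <- NULL
  fn_prim_start <- integer(0); fn_prim_n <- integer(0)
  prim_coef <- numeric(0)  # includes primitive + component normalization
  for (si in seq_along(shells)) {
    sh <- shells[[si]]
    comps <- MOLDEN_ORDER[[as.character(sh$l)]]
    # primitive norms for (l,0,0)
    nrm <- (2 * sh$exps / pi)^0.75 * (4 * sh$exps)^(sh$l / 2) /
      sqrt(dfact(2 * sh$l - 1))
    for (ci in seq_len(nrow(comps))) {
      l3 <- comps[ci, ]
      f <- sqrt(dfact(2 * sh$l - 1) /
                  (dfact(2 * l3[1] - 1) * dfact(2 * l3[2] - 1) *
                     dfact(2 * l3[3] - 1)))
      raw <- sh$coefs * nrm * f
      # unit-normalize the contracted component: same-center overlap
      p <- outer(sh$exps, sh$exps, "+")
      ssmat <- (pi / p)^1.5 *
        dfact(2 * l3[1] - 1) * dfact(2 * l3[2] - 1) * dfact(2 * l3[3] - 1) /
        (2 * p)^sh$l
      s2 <- as.numeric(t(raw) %*% ssmat %*% raw)
      raw <- raw / sqrt(s2)
      fn_shell <- c(fn_shell, si)
      fn_prim_start <- c(fn_prim_start, length(prim_alpha) + 1L)
      fn_prim_n <- c(fn_prim_n, length(sh$exps))
      prim_center <- c(prim_center, rep(sh$atom, length(sh$exps)))
      prim_l <- rbind(prim_l, matrix(rep(l3, length(sh$exps)),
                                     ncol = 3, byrow = TRUE))
      prim_alpha <- c(prim_alpha, sh$exps)
      prim_coef <- c(prim_coef, raw)
    }
  }
  nfn <- length(fn_shell)
  # MO section
  mi <- find_sec("MO")
  ml <- lt[mi[-1]]
  mo_starts <- grep("^Sym=", ml)
  if (!length(mo_starts)) mo_starts <- grep("^Ene=", ml)
  occ <- numeric(0); ene <- numeric(0); Cao <- NULL
  blocks <- c(mo_starts, length(ml) + 1)
  for (b in seq_along(mo_starts)) {
    blk <- ml[blocks[b]:(blocks[b + 1] - 1)]
    e <- as.numeric(sub("Ene=\\s*", "", blk[grepl("^Ene=", blk)][1]))
    o <- as.numeric(sub("Occup=\\s*", "", blk[grepl("^Occup=", blk)][1]))
    rows <- blk[grepl("^[0-9]+\\s", blk)]
    cv <- numeric(nfn)
    for (r in rows) {
      tk <- strsplit(trimws(r), "\\s+")[[1]]
      cv[as.integer(tk[1])] <- as.numeric(tk[2])
    }
    occ <- c(occ, o); ene <- c(ene, e); Cao <- cbind(Cao, cv)
  }
  keep <- occ > 1e-10
  occ <- occ[keep]; ene <- ene[keep]; Cao <- Cao[, keep, drop = FALSE]
  nmo <- ncol(Cao)
  # AO -> primitive expansion
  nprim <- length(prim_alpha)
  C <- matrix(0, nprim, nmo)
  for (ifn in seq_len(nfn)) {
    rows <- seq(fn_prim_start[ifn], length.out = fn_prim_n[ifn])
    C[rows, ] <- C[rows, ] + outer(prim_coef[rows], Cao[ifn, ])
  }
  nelec <- as.integer(round(sum(occ)))
  new_wavefunction(list(
    natom = natom, Z = Z, nuc = coords,
    symbol = names(ELEMENT_Z)[match(round(Z), ELEMENT_Z)],
    prim_center = prim_center, prim_l = prim_l, prim_alpha = prim_alpha,
    C = C, occ = occ, mo_energy = ene, nelec = nelec,
    charge = as.integer(round(sum(Z) - sum(occ))),
    method = "HF", functional = "", scf_energy = NA_real_,
    source = path, format = "molden"))
}

#' Load a wavefunction from a wfx or Molden file
#'
#' Reads a closed-shell Gaussian-basis wavefunction into the internal
#' primitive representation used by all density and energy evaluators.
#' Supported formats are the AIM wavefunction-exchange format (`wfx`) and
#' Cartesian-basis Molden files.  Occupations are validated against the
#' declared electron count and the molecular-orbital orthonormality is
#' checked from the analytically recomputed primitive overlap matrix.
#'
#' @param path path to the wavefunction file.
#' @param format `"wfx"` or `"molden"`; default guesses from the extension.
#' @param check logical, run invariant checks (default TRUE).
#' @return an object of class `iqa_wavefunction`.
#' @export
load_wavefunction <- function(path, format = c("auto", "wfx", "molden"),
                              check = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("wavefunction file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.wfx$", path, ignore.case = TRUE)) "wfx"
    else if (grepl("\\.molden", path, ignore.case = TRUE)) "molden"
    else stop("cannot guess wavefunction format from extension: ", path)
  }
  wfn <- switch(format, wfx = load_wfx(path), molden = load_molden(path))
  if (check) validate_wavefunction(wfn)
  wfn
}

#' Validate wavefunction invariants
#'
#' Checks (i) occupations sum to the declared electron count, (ii) MO
#' orthonormality recomputed from the analytic primitive overlaps, and
#' (iii) primitive center indices address existing nuclei.
#'
#' @param wfn an `iqa_wavefunction`.
#' @param tol orthonormality tolerance (default 1e-6).
#' @return the wavefunction, invisibly; stops on violation.
#' @export
validate_wavefunction <- function(wfn, tol = 1e-6) {
  if (abs(sum(wfn$occ) - wfn$nelec) > 1e-6)
    stop("wavefunction consistency error: occupations sum to ",
         format(sum(wfn$occ)), " but file declares ", wfn$nelec, " electrons")
  if (any(wfn$prim_center < 1 | wfn$prim_center > wfn$natom))
    stop("wavefunction consistency error: primitive center out of range")
  S <- cpp_prim_overlap(wfn$prim_center - 1L, wfn$prim_l, wfn$prim_alpha,
                        wfn$nuc)
  M <- t(wfn$C) %*% S %*% wfn$C
  dev <- max(abs(M - diag(ncol(M))))
  if (dev > tol)
    stop("wavefunction consistency error: MO overlap deviates from ",
         "orthonormality by ", format(dev, digits = 3))
  invisible(wfn)
}

is_closed_shell <- function(wfn) all(abs(wfn$occ - 2) < 1e-8)

require_closed_shell <- function(wfn, what = "this operation") {
  if (!is_closed_shell(wfn))
    stop("unsupported feature: ", what, " requires a closed-shell ",
         "(doubly occupied) wavefunction")
  invisible(wfn)
}
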