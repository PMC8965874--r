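#' Construct a site set
#'
#' A site set is the MM-side (and QM-mirror) atom list: element, position,
#' partial charge, Lennard-Jones parameters, Poisson-Boltzmann radius and
#' region tag.  Positions are stored in bohr internally; file readers convert
#' from Angstrom.  LJ parameters keep the Amber convention (epsilon in
#' kcal/mol, r_min/2 in Angstrom).
#'
#' @param element character vector of element symbols.
#' @param xyz n x 3 matrix of positions, bohr.
#' @param q partial charges (e); NA when unknown.
#' @param eps LJ well depths (kcal/mol).
#' @param rmin2 LJ r_min/2 (Angstrom).
#' @param radius PB radii (Angstrom).
#' @param region one of "QM", "MM", "LINK" per site.
#' @param name optional site names.
#' @return object of class `iqa_sites` (a data.frame).
#' @export
site_set <- function(element, xyz, q = NA_real_, eps = 0, rmin2 = 0,
                     radius = NA_real_, region = "MM", name = element) {
  xyz <- as_points(xyz)
  n <- nrow(xyz)
  df <- data.frame(name = rep_len(as.character(name), n),
                   element = rep_len(as.character(element), n),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   q = rep_len(as.numeric(q), n),
                   eps = rep_len(as.numeric(eps), n),
                   rmin2 = rep_len(as.numeric(rmin2), n),
                   radius = rep_len(as.numeric(radius), n),
                   region = rep_len(as.character(region), n),
                   stringsAsFactors = FALSE)
  validate_sites(df)
  class(df) <- c("iqa_sites", "data.frame")
  df
}

validate_sites <- function(df) {
  if (!all(df$region %in% c("QM", "MM", "LINK")))
    stop("site region tags must be QM, MM or LINK")
  if (any(!is.na(df$eps) & df$eps < 0))
    stop("LJ epsilon must be non-negative")
  invisible(df)
}

sites_xyz <- function(sites) cbind(sites$x, sites$y, sites$z)

#' Load sites from xyzq, PQR or PDB files
#'
#' * `xyzq`: whitespace columns `element x y z q` (Angstrom, e), comment
#'   lines starting with `#`.
#' * `pqr`: ATOM/HETATM records with trailing charge and radius columns.
#' * `pdb`: ATOM/HETATM records; charges left NA (downstream operations that
#'   need charges raise precondition errors).
#'
#' @param path file path.
#' @param format `"xyzq"`, `"pqr"` or `"pdb"` (default from extension).
#' @param region region tag assigned to all loaded sites (default "MM").
#' @return an `iqa_sites` object.
#' @export
load_sites <- function(path, format = c("auto", "xyzq", "pqr", "pdb"),
                       region = "MM") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("site file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyzq = "xyzq", pqr = "pqr", pdb = "pdb",
                     stop("cannot guess site format for .", ext))
  }
  B <- iqa_units$bohr_angstrom
  lines <- readLines(path, warn = FALSE)
  if (format == "xyzq") {
    keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
    el <- character(0); xyz <- NULL; q <- numeric(0)
    for (k in keep) {
      tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
      if (length(tok) < 5)
        stop("xyzq parse error at line ", k, ": need 'element x y z q'")
      v <- suppressWarnings(as.numeric(tok[2:5]))
      if (anyNA(v))
        stop("xyzq parse error at line ", k, ": non-numeric field")
      el <- c(el, tok[1]); xyz <- rbind(xyz, v[1:3]); q <- c(q, v[4])
    }
    return(site_set(el, xyz / B, q = q, region = region))
  }
  rec <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(rec)) stop(format, " parse error: no ATOM/HETATM records")
  if (format == "pqr") {
    el <- character(0); xyz <- NULL; q <- numeric(0); rad <- numeric(0)
    nm <- character(0)
    for (k in seq_along(rec)) {
      tok <- strsplit(trimws(rec[k]), "\\s+")[[1]]
      nt <- length(tok)
      v <- suppressWarnings(as.numeric(tok[(nt - 4):nt]))
      if (anyNA(v))
        stop("pqr parse error at record ", k, ": non-numeric field")
      nm <- c(nm, tok[3])
      el <- c(el, gsub("[0-9]", "", tok[3]))
      xyz <- rbind(xyz, v[1:3]); q <- c(q, v[4]); rad <- c(rad, v[5])
    }
    return(site_set(el, xyz / B, q = q, radius = rad, region = region,
                    name = nm))
  }
  # pdb: fixed columns
  nm <- trimws(substr(rec, 13, 16))
  el <- trimws(substr(rec, 77, 78))
  el[!nzchar(el)] <- gsub("[0-9]", "", nm[!nzchar(el)])
  xyz <- cbind(as.numeric(substr(rec, 31, 38)),
               as.numeric(substr(rec, 39, 46)),
               as.numeric(substr(rec, 47, 54)))
  if (anyNA(xyz)) stop("pdb parse error: malformed coordinate field")
  site_set(el, xyz / B, q = NA_real_, region = region, name = nm)
}

require_charges <- function(sites, what = "this operation") {
  if (anyNA(sites$q))
    stop("precondition error: ", what, " requires partial charges on all ",
         "sites (found NA)")
  invisible(sites)
}

require_radii <- function(sites, what = "this operation") {
  if (anyNA(sites$radius) || any(sites$radius <= 0))
    stop("precondition error: ", what, " requires positive PB radii on all ",
         "sites")
  invisible(sites)
}
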