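# Term-matrix exchange container: a structured JSON document whose floats
# round-trip bit-exactly (17 significant digits).

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "null"
  out
}

num_to_json <- function(x) {
  if (is.matrix(x)) {
    rows <- apply(x, 1, function(r) paste0("[", paste(fmt17(r),
                                                      collapse = ","), "]"))
    paste0("[", paste(rows, collapse = ","), "]")
  } else if (is.numeric(x)) {
    if (length(x) == 1) fmt17(x)
    else paste0("[", paste(fmt17(x), collapse = ","), "]")
  } else if (is.character(x)) {
    if (length(x) == 1) paste0("\"", x, "\"")
    else paste0("[", paste0("\"", x, "\"", collapse = ","), "]")
  } else if (is.null(x)) "null"
  else stop("unsupported field type")
}

#' Write an IQA term matrix to the exchange container
#'
#' Floats are serialized with 17 significant digits, so write-then-read
#' reproduces every value bit-exactly.
#'
#' @param terms an `iqa_terms`.
#' @param path output path (.json).
#' @return the path, invisibly.
#' @export
write_term_matrix <- function(terms, path) {
  fields <- list(
    natom = terms$natom, E_net = terms$E_net,
    T = terms$net_components$T, V_ne_own = terms$net_components$V_ne_own,
    Vee_coul_intra = terms$net_components$Vee_coul_intra,
    Vee_xc_intra = terms$net_components$Vee_xc_intra,
    N = terms$net_components$N,
    V_nn = terms$V_nn, V_en = terms$V_en, Vee_coul = terms$Vee_coul,
    Vee_xc = terms$Vee_xc, E_ele = terms$E_ele, E_xc = terms$E_xc,
    E_int = terms$E_int,
    qmmm_ele = terms$qmmm_ele, qmmm_vdw = terms$qmmm_vdw,
    disp = terms$disp,
    kappa = terms$kappa, method = terms$method,
    scf_energy = terms$scf_energy,
    screen_threshold = terms$screen_threshold, lmax = terms$lmax,
    preset = terms$preset, ee_method = terms$ee_method)
  body <- vapply(names(fields), function(nm)
    paste0("\"", nm, "\":", num_to_json(fields[[nm]])), "")
  writeLines(paste0("{", paste(body, collapse = ",\n"), "}"), path)
  invisible(path)
}

#' Read an IQA term matrix from the exchange container
#'
#' @param path path written by [write_term_matrix()].
#' @return an `iqa_terms`.
#' @export
read_term_matrix <- function(path) {
  j <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                collapse = "\n"))
  msh <- function(x) if (is.null(x)) NULL else as.matrix(x)
  structure(list(
    natom = as.integer(j$natom), E_net = as.numeric(j$E_net),
    net_components = data.frame(T = as.numeric(j$T),
                                V_ne_own = as.numeric(j$V_ne_own),
                                Vee_coul_intra = as.numeric(j$Vee_coul_intra),
                                Vee_xc_intra = as.numeric(j$Vee_xc_intra),
                                N = as.numeric(j$N)),
    V_nn = msh(j$V_nn), V_en = msh(j$V_en), Vee_coul = msh(j$Vee_coul),
    Vee_xc = msh(j$Vee_xc), E_ele = msh(j$E_ele), E_xc = msh(j$E_xc),
    E_int = msh(j$E_int),
    qmmm_ele = msh(j$qmmm_ele), qmmm_vdw = msh(j$qmmm_vdw),
    disp = msh(j$disp),
    kappa = j$kappa, method = j$method,
    scf_energy = if (is.null(j$scf_energy)) NA_real_ else j$scf_energy,
    screen_threshold = j$screen_threshold, lmax = j$lmax,
    preset = j$preset, ee_method = j$ee_method,
    subsets = NULL),
    class = "iqa_terms")
}
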