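# Interacting-quantum-fragments (IQF) regrouping, formation-energy
# decomposition, fragment additive energies with solvation, and
# MM-PBSA-style binding scorings.

#' Define a fragment scheme
#'
#' @param labels character vector: one fragment label per atom.
#' @return object of class `iqa_fragments` (factor with atom map).
#' @export
fragment_scheme <- function(labels) {
  f <- factor(labels)
  if (anyNA(f)) stop("every atom needs a fragment label")
  structure(list(labels = f, fragments = levels(f)),
            class = "iqa_fragments")
}

#' Regroup atomic IQA terms into fragment terms
#'
#' Fragment net energies absorb the intra-fragment atomic net energies and
#' intra-fragment pair interactions; inter-fragment matrices collect the
#' pairwise electrostatic, exchange-correlation, dispersion and (via the
#' QM-MM block) vdW components.  The regrouping conserves the atomic-level
#' total exactly.
#'
#' @param terms an `iqa_terms` (QM atoms), optionally carrying QM-MM and
#'   dispersion blocks.
#' @param scheme an `iqa_fragments` covering the QM atoms (and the MM
#'   sites through `mm_labels` when QM-MM terms are present).
#' @param solv optional per-QM-atom solvation energies (kcal/mol) to
#'   regroup alongside.
#' @param mm_labels fragment labels of the MM sites (required when the
#'   term matrix has QM-MM blocks).
#' @return object of class `iqa_fragment_matrix`.
#' @export
iqf_regroup <- function(terms, scheme, solv = NULL, mm_labels = NULL) {
  lab <- scheme$labels
  if (length(lab) != terms$natom)
    stop("fragment scheme covers ", length(lab), " atoms; term matrix has ",
         terms$natom)
  fr <- scheme$fragments
  nf <- length(fr)
  idx <- lapply(fr, function(f) which(lab == f))
  E_net_F <- numeric(nf)
  ele <- xc <- int <- disp <- matrix(0, nf, nf, dimnames = list(fr, fr))
  dmat <- if (!is.null(terms$disp)) terms$disp else
    matrix(0, terms$natom, terms$natom)
  for (A in seq_len(nf)) {
    ia <- idx[[A]]
    E_net_F[A] <- sum(terms$E_net[ia]) +
      sum(terms$E_int[ia, ia][upper.tri(matrix(0, length(ia), length(ia)))]) +
      sum(dmat[ia, ia][upper.tri(dmat[ia, ia, drop = FALSE])])
    for (B_ in seq_len(nf)) {
      if (B_ == A) next
      ib <- idx[[B_]]
      ele[A, B_] <- sum(terms$E_ele[ia, ib])
      xc[A, B_] <- sum(terms$E_xc[ia, ib])
      disp[A, B_] <- sum(dmat[ia, ib])
      int[A, B_] <- ele[A, B_] + xc[A, B_] + disp[A, B_]
    }
  }
  qmmm_ele_F <- qmmm_vdw_F <- NULL
  if (!is.null(terms$qmmm_ele)) {
    if (is.null(mm_labels))
      stop("mm_labels needed to regroup the QM-MM blocks")
    mf <- factor(mm_labels, levels = union(fr, unique(mm_labels)))
    qmmm_ele_F <- matrix(0, nf, nlevels(mf), dimnames = list(fr, levels(mf)))
    qmmm_vdw_F <- qmmm_ele_F
    for (A in seq_len(nf)) {
      sel <- idx[[A]]
      qmmm_ele_F[A, ] <- tapply(colSums(terms$qmmm_ele[sel, , drop = FALSE]),
                                mf, sum, default = 0)
      if (!is.null(terms$qmmm_vdw))
        qmmm_vdw_F[A, ] <- tapply(colSums(terms$qmmm_vdw[sel, , drop = FALSE]),
                                  mf, sum, default = 0)
    }
  }
  g_solv_F <- if (!is.null(solv))
    as.numeric(tapply(solv, lab, sum, default = 0)) else NULL
  pops <- as.numeric(tapply(terms$net_components$N, lab, sum, default = 0))
  structure(list(fragments = fr, E_net = E_net_F, E_ele = ele, E_xc = xc,
                 E_disp = disp, E_int = int,
                 qmmm_ele = qmmm_ele_F, qmmm_vdw = qmmm_vdw_F,
                 g_solv = g_solv_F, populations = pops,
                 atomic_total = reconstruct_total(terms)$total),
            class = "iqa_fragment_matrix")
}

#' @export
print.iqa_fragment_matrix <- function(x, ...) {
  cat("<iqa_fragment_matrix>", length(x$fragments), "fragments:",
      paste(x$fragments, collapse = ", "), "\n")
  invisible(x)
}

#' Formation-energy decomposition of a two-fragment aggregate
#'
#' Rigid decomposition `dE_form = E_def^A + E_def^B + E_int^AB` where each
#' deformation term is the fragment's in-complex net energy minus its
#' isolated energy at the identical internal geometry.
#'
#' @param complex_terms an `iqa_fragment_matrix` of the aggregate.
#' @param isolated named numeric: isolated-fragment total energies
#'   (hartree) at the in-complex geometries.
#' @param geometry_check optional list with `complex` and `isolated`
#'   coordinate matrices per fragment to enforce the rigid assumption
#'   (tolerance 1e-4 bohr).
#' @return list with `E_def` (per fragment), `E_int` components between
#'   the two fragments and `dE_form` (hartree).
#' @export
formation_decomposition <- function(complex_terms, isolated,
                                    geometry_check = NULL) {
  fr <- as.character(complex_terms$fragments)
  if (length(fr) != 2)
    stop("formation decomposition is defined for two fragments")
  if (!all(fr %in% names(isolated)))
    stop("isolated energies missing for: ",
         paste(setdiff(fr, names(isolated)), collapse = ", "))
  if (!is.null(geometry_check)) {
    for (f in names(geometry_check$complex)) {
      d <- geometry_check$complex[[f]] - geometry_check$isolated[[f]]
      d <- d - matrix(colMeans(d), nrow(d), 3, byrow = TRUE)
      if (max(abs(d)) > 1e-4)
        stop("rigid-fragment assumption violated for ", f,
             ": geometries differ by ", format(max(abs(d)), digits = 3),
             " bohr")
    }
  }
  E_def <- stats::setNames(
    complex_terms$E_net - as.numeric(isolated[fr]), fr)
  comp <- c(ele = complex_terms$E_ele[1, 2], xc = complex_terms$E_xc[1, 2],
            disp = complex_terms$E_disp[1, 2])
  E_int <- complex_terms$E_int[1, 2]
  list(E_def = E_def, E_int_components = comp, E_int = E_int,
       dE_form = sum(E_def) + E_int)
}

#' Fragment additive energy with solvation
#'
#' `dG_add^X = dE_net^X + dG_solv^X + dE_int^X / 2` (half-share
#' convention, matching per-fragment interaction halves); summed over
#' fragments this reproduces the total energy change.
#'
#' @param dE_net fragment net-energy change (kcal/mol).
#' @param dG_solv fragment solvation change (kcal/mol).
#' @param half_dE_int half the fragment interaction-energy change
#'   (kcal/mol).
#' @return numeric additive energies.
#' @export
fragment_additive_energy <- function(dE_net, dG_solv, half_dE_int) {
  dE_net + dG_solv + half_dE_int
}

#' QM/MM-PBSA binding score
#'
#' `dG = G(cmplx) - G(enz*) - G(inh*)` with
#' `G = E^QM/MM + G_solv (+ 3RT)`; the asterisk species use their
#' in-complex geometries.  With `include_3rt` the net `-3RT` of losing six
#' translational/rotational degrees of freedom on binding is added.
#'
#' @param cmplx,enz,inh named numeric component vectors (kcal/mol), e.g.
#'   `c(coul = ..., vdw = ..., solv = ...)`; any shared set of names works.
#' @param spec list: `temperature` (K, default 300), `include_3rt`
#'   (default FALSE).
#' @return object of class `iqa_score`: per-component changes, `dG`, and
#'   the 3RT term applied.
#' @export
qmmm_pbsa_score <- function(cmplx, enz, inh,
                            spec = list(temperature = 300,
                                        include_3rt = FALSE)) {
  spec <- utils::modifyList(list(temperature = 300, include_3rt = FALSE),
                            spec)
  if (spec$temperature <= 0) stop("temperature must be positive")
  nm <- names(cmplx)
  if (is.null(nm) || !setequal(nm, names(enz)) || !setequal(nm, names(inh)))
    stop("the three species need identical component names")
  delta <- cmplx - enz[nm] - inh[nm]
  rt3 <- if (spec$include_3rt)
    -3 * iqa_units$boltzmann_kcal * spec$temperature else 0
  dG <- sum(delta) + rt3
  structure(list(components = delta, three_rt = rt3, dG = dG,
                 temperature = spec$temperature,
                 include_3rt = spec$include_3rt),
            class = "iqa_score")
}

#' @export
print.iqa_score <- function(x, ...) {
  cat("<iqa_score> dG =", round(x$dG, 4), "kcal/mol\n")
  print(round(x$components, 4))
  if (x$include_3rt) cat("  includes -3RT =", round(x$three_rt, 4), "\n")
  invisible(x)
}

#' Consistency diagnostics of a decomposition
#'
#' Verifies the bookkeeping identities: `E_int = E_ele + E_xc` per pair;
#' additive energies sum to the reconstructed total; fragment terms sum to
#' the atomic total; per-atom solvation sums to the total solvation
#' energy.  Violations are reported with magnitudes, never raised.
#'
#' @param terms an `iqa_terms`.
#' @param fragment_matrix optional `iqa_fragment_matrix`.
#' @param solvation optional `iqa_solvation`.
#' @param tol tolerance for flagging (default 1e-9).
#' @return data.frame of checks: name, magnitude, ok.
#' @export
consistency_check <- function(terms, fragment_matrix = NULL,
                              solvation = NULL, tol = 1e-9) {
  checks <- list()
  add <- function(name, mag) checks[[length(checks) + 1]] <<-
    data.frame(check = name, magnitude = mag, ok = mag <= tol)
  add("E_int = E_ele + E_xc (pairwise)",
      max(abs(terms$E_int - terms$E_ele - terms$E_xc -
                (if (!is.null(terms$disp)) 0 * terms$disp else 0))))
  tot <- reconstruct_total(terms)
  # with QM-MM blocks the closure identity lives in the qm-full convention
  # (half-share leaves the other halves on the MM atoms)
  conv <- if (is.null(terms$qmmm_ele)) "half_share" else "qm_full_qmmm"
  add("sum(E_add) = reconstructed total",
      abs(sum(additive_energies(terms, conv)) - tot$total))
  add("pair matrices symmetric",
      max(abs(terms$E_int - t(terms$E_int)),
          abs(terms$E_ele - t(terms$E_ele))))
  if (!is.null(fragment_matrix)) {
    ftot <- sum(fragment_matrix$E_net) +
      sum(fragment_matrix$E_int[upper.tri(fragment_matrix$E_int)]) +
      (if (!is.null(fragment_matrix$qmmm_ele))
        sum(fragment_matrix$qmmm_ele) else 0) +
      (if (!is.null(fragment_matrix$qmmm_vdw))
        sum(fragment_matrix$qmmm_vdw) / iqa_units$hartree_kcal else 0)
    add("fragment regrouping conserves the total",
        abs(ftot - fragment_matrix$atomic_total))
  }
  if (!is.null(solvation))
    add("sum(G_solv^I) = total solvation",
        abs(sum(solvation$g_solv) - solvation$total))
  out <- do.call(rbind, checks)
  class(out) <- c("iqa_consistency", "data.frame")
  out
}

#' Write decomposition reports
#'
#' Per-atom and (when given) per-fragment tables in TSV or JSON, with a
#' metadata block recording preset, conventions, the xc scaling factor and
#' the reconstruction residual.  JSON floats round-trip exactly.
#'
#' @param terms an `iqa_terms`.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @param fragment_matrix optional `iqa_fragment_matrix`.
#' @param solvation optional `iqa_solvation` (per QM atom).
#' @param convention additive-energy convention for the tables.
#' @return the path, invisibly.
#' @export
write_report <- function(terms, path, format = c("tsv", "json"),
                         fragment_matrix = NULL, solvation = NULL,
                         convention = "half_share") {
  format <- match.arg(format)
  H <- iqa_units$hartree_kcal
  tot <- reconstruct_total(terms)
  atoms <- data.frame(
    atom = seq_len(terms$natom),
    N = terms$net_components$N,
    E_net = terms$E_net,
    E_int_half = rowSums(terms$E_int) / 2,
    E_add = additive_energies(terms, convention))
  if (!is.null(solvation)) atoms$G_solv_kcal <- solvation$g_solv
  meta <- list(preset = terms$preset, method = terms$method,
               kappa = terms$kappa, convention = convention,
               screen_threshold = terms$screen_threshold,
               lmax = terms$lmax,
               residual_hartree = tot$residual,
               hartree_to_kcal = H)
  if (format == "json") {
    payload <- list(metadata = meta, atoms = atoms)
    if (!is.null(fragment_matrix))
      payload$fragments <- list(
        labels = as.character(fragment_matrix$fragments),
        E_net = fragment_matrix$E_net,
        E_int = fragment_matrix$E_int,
        populations = fragment_matrix$populations,
        g_solv = fragment_matrix$g_solv)
    writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                                matrix = "rowmajor"), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(meta))
      writeLines(sprintf("# %s\t%s", nm, format(meta[[nm]], digits = 17)),
                 con)
    utils::write.table(format(atoms, digits = 17), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(fragment_matrix)) {
      writeLines("# fragments", con)
      fd <- data.frame(fragment = fragment_matrix$fragments,
                       E_net = fragment_matrix$E_net,
                       E_int_half = rowSums(fragment_matrix$E_int) / 2,
                       population = fragment_matrix$populations)
      if (!is.null(fragment_matrix$g_solv))
        fd$G_solv_kcal <- fragment_matrix$g_solv
      utils::write.table(format(fd, digits = 17), con, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
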