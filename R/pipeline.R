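#' Full QM/MM IQA decomposition of a system
#'
#' Orchestrates the standard pipeline: basin grid construction, IQA atomic
#' and diatomic terms, DFT xc scaling (when applicable), QM-MM
#' electrostatic and van der Waals coupling, and optional D3 dispersion -
#' returning one merged term matrix.
#'
#' @param system an `iqa_system` with a wavefunction.
#' @param preset grid preset or name (default "desk").
#' @param dispersion logical: add D3(BJ) pair terms over the QM atoms
#'   (default FALSE; the functional label of the wavefunction selects the
#'   damping set, falling back to B3LYP).
#' @param grid optional prebuilt `iqa_basin_grid`.
#' @param ... passed to [iqa_atomic_terms()].
#' @return an `iqa_terms` with QM-MM (and dispersion) blocks merged.
#' @export
decompose_system <- function(system, preset = "desk", dispersion = FALSE,
                             grid = NULL, ...) {
  wfn <- system$wfn
  if (is.null(wfn)) stop("precondition error: system has no wavefunction")
  if (is.null(grid)) grid <- build_basin_grid(wfn, preset)
  terms <- iqa_atomic_terms(wfn, grid, ...)
  if (terms$method == "DFT" && !is.na(terms$scf_energy))
    terms <- scale_dft_xc(terms)
  if (length(system$mm_index)) {
    mask <- build_interaction_mask(system)
    ele <- qmmm_electrostatics(system, grid, mask)
    vdw <- if (!anyNA(system$sites$eps)) qmmm_vdw(system, mask) else NULL
    terms <- merge_qmmm_terms(terms, ele, vdw)
  }
  if (dispersion) {
    func <- if (nzchar(wfn$functional)) tolower(wfn$functional) else "b3lyp"
    params <- tryCatch(d3_params(func), error = function(e) d3_params())
    qm <- system$sites[system$qm_index, ]
    terms <- merge_dispersion(terms, d3bj_pair_energies(qm, params))
  }
  attr(terms, "grid") <- grid
  terms
}
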