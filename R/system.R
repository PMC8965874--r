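#' Assemble a QM/MM system model
#'
#' Binds a wavefunction, the site list, the MM topology and the link-atom
#' map into the single object the decomposition pipelines operate on.  The
#' QM nuclei of the wavefunction must correspond one-to-one (in order) with
#' the QM-tagged sites; positions must agree within 1e-4 bohr.
#'
#' @param wfn an `iqa_wavefunction`, or NULL for MM-only systems.
#' @param qm_sites `iqa_sites` with region "QM" (and "LINK" for link
#'   hydrogens present in the wavefunction).
#' @param mm_sites `iqa_sites` with region "MM"; may be NULL.
#' @param topology an `iqa_topology` indexing the combined site list
#'   (QM sites first, then MM sites); may be NULL.
#' @param link_spec data.frame(qm_host, mm_host, link_site) with indices into
#'   the combined site list; NULL when the boundary is non-covalent.
#' @param fragments optional character vector of fragment labels per combined
#'   site.
#' @return object of class `iqa_system` with elements `wfn`, `sites`
#'   (combined), `topology`, `links`, `fragments`, `qm_index`, `mm_index`,
#'   `units`.
#' @export
assemble_system <- function(wfn = NULL, qm_sites = NULL, mm_sites = NULL,
                            topology = NULL, link_spec = NULL,
                            fragments = NULL) {
  if (is.null(qm_sites) && is.null(mm_sites))
    stop("assembly error: no sites given")
  sites <- rbind(
    if (!is.null(qm_sites)) as.data.frame(qm_sites),
    if (!is.null(mm_sites)) as.data.frame(mm_sites))
  class(sites) <- c("iqa_sites", "data.frame")
  qm_index <- which(sites$region %in% c("QM", "LINK"))
  mm_index <- which(sites$region == "MM")
  if (!is.null(wfn)) {
    if (length(qm_index) != wfn$natom)
      stop("assembly error: wavefunction has ", wfn$natom,
           " nuclei but ", length(qm_index), " QM/LINK sites are tagged")
    d <- sqrt(rowSums((sites_xyz(sites)[qm_index, , drop = FALSE] -
                         wfn$nuc)^2))
    bad <- which(d > 1e-4)
    if (length(bad))
      stop("assembly error: QM site/nucleus position mismatch (bohr) at ",
           "site(s) ", paste(qm_index[bad], collapse = ", "),
           " (max deviation ", format(max(d), digits = 3), ")")
  }
  if (!is.null(link_spec) && nrow(link_spec)) {
    for (r in seq_len(nrow(link_spec))) {
      ls <- link_spec[r, ]
      if (sites$region[ls$link_site] != "LINK")
        stop("assembly error: link_site ", ls$link_site, " not tagged LINK")
      if (sites$region[ls$qm_host] != "QM")
        stop("assembly error: qm_host ", ls$qm_host, " not tagged QM")
      if (sites$region[ls$mm_host] != "MM")
        stop("assembly error: mm_host ", ls$mm_host, " not tagged MM")
    }
    link_counts <- table(link_spec$link_site)
    if (any(link_counts != 1))
      stop("assembly error: every LINK site needs exactly one host pair")
  } else {
    if (any(sites$region == "LINK"))
      stop("assembly error: LINK sites present but no link_spec given")
  }
  if (!is.null(topology)) {
    topology$n_sites <- nrow(sites)
    validate_topology(topology)
  }
  if (!is.null(fragments) && length(fragments) != nrow(sites))
    stop("assembly error: fragment labels must cover all sites")
  structure(list(wfn = wfn, sites = sites, topology = topology,
                 links = link_spec, fragments = fragments,
                 qm_index = qm_index, mm_index = mm_index,
                 units = iqa_units),
            class = "iqa_system")
}

#' @export
print.iqa_system <- function(x, ...) {
  cat("<iqa_system> QM/LINK sites:", length(x$qm_index),
      " MM sites:", length(x$mm_index),
      if (!is.null(x$wfn)) paste0(" [", x$wfn$method, " wavefunction]"), "\n")
  invisible(x)
}
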