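#' Evaluate the electron density (and gradient) at points
#'
#' Pointwise evaluation of rho(r) from the occupied molecular orbitals,
#' optionally with the analytic gradient.  Distant points underflow cleanly
#' to zero through primitive screening.
#'
#' @param wfn an `iqa_wavefunction`.
#' @param points numeric matrix (n x 3), coordinates in bohr.
#' @param order `"value"` for rho only, `"gradient"` for rho + gradient.
#' @return For `"value"`: numeric vector rho.  For `"gradient"`: list with
#'   `rho` (n), `grad` (n x 3) and `ked` (n, positive-definite kinetic-energy
#'   density).
#' @export
evaluate_density <- function(wfn, points, order = c("value", "gradient")) {
  order <- match.arg(order)
  points <- as_points(points)
  if (!all(is.finite(points))) stop("non-finite coordinates")
  out <- cpp_density(wfn$prim_center - 1L, wfn$prim_l, wfn$prim_alpha,
                     wfn$C, wfn$occ, wfn$nuc, points,
                     if (order == "value") 0L else 1L)
  if (order == "value") return(as.numeric(out$rho))
  list(rho = as.numeric(out$rho), grad = out$grad, ked = as.numeric(out$ked))
}

#' Evaluate the first-order reduced density matrix rho1(r1, r2)
#'
#' Closed-shell first-order RDM, `rho1(r1, r2) = 2 sum_i phi_i(r1) phi_i(r2)`.
#' Diagonal equals the density; symmetric for real orbitals.
#'
#' @param wfn closed-shell `iqa_wavefunction`.
#' @param r1,r2 points (vectors of length 3 or n x 3 matrices of equal size).
#' @return numeric vector of rho1 values.
#' @export
evaluate_rdm1 <- function(wfn, r1, r2) {
  require_closed_shell(wfn, "the first-order RDM")
  r1 <- as_points(r1); r2 <- as_points(r2)
  if (nrow(r1) != nrow(r2)) stop("r1 and r2 must have matching rows")
  m1 <- cpp_eval_mo(wfn$prim_center - 1L, wfn$prim_l, wfn$prim_alpha,
                    wfn$C, wfn$nuc, r1, 0L)$mo
  m2 <- cpp_eval_mo(wfn$prim_center - 1L, wfn$prim_l, wfn$prim_alpha,
                    wfn$C, wfn$nuc, r2, 0L)$mo
  2 * rowSums(m1 * m2)
}

#' Evaluate the positive-definite kinetic-energy density
#'
#' `ked(r) = 1/2 sum_i n_i |grad phi_i(r)|^2`; non-negative everywhere and
#' integrates to the SCF kinetic energy.
#'
#' @param wfn an `iqa_wavefunction`.
#' @param points n x 3 matrix, bohr.
#' @return numeric vector (hartree/bohr^3).
#' @export
evaluate_ked <- function(wfn, points) {
  evaluate_density(wfn, points, "gradient")$ked
}

#' Evaluate occupied molecular orbitals at points
#'
#' @param wfn an `iqa_wavefunction`.
#' @param points n x 3 matrix (bohr).
#' @param deriv 0 for values, 1 to include gradients.
#' @return list with `mo` (n x nmo) and, if requested, `gx`, `gy`, `gz`.
#' @export
evaluate_mos <- function(wfn, points, deriv = 0L) {
  points <- as_points(points)
  cpp_eval_mo(wfn$prim_center - 1L, wfn$prim_l, wfn$prim_alpha,
              wfn$C, wfn$nuc, points, as.integer(deriv))
}

#' Molecular dipole moment from the density on a basin grid
#'
#' mu = sum_I Z_I R_I - int r rho(r) dV, integrated over the union of the
#' basin-assigned quadrature nodes.
#'
#' @param wfn an `iqa_wavefunction`.
#' @param grid a `basin_grid` built for the same wavefunction.
#' @return list with `dipole_au` (length-3), `dipole_debye` (magnitude, D).
#' @export
density_dipole <- function(wfn, grid) {
  aw <- active_weights(grid)
  act <- aw > 0
  pts <- grid$points[act, , drop = FALSE]
  rho <- evaluate_density(wfn, pts)
  w <- aw[act]
  ele <- -colSums(pts * (w * rho))
  nucp <- colSums(wfn$nuc * wfn$Z)
  mu <- nucp + ele
  list(dipole_au = mu,
       dipole_debye = sqrt(sum(mu^2)) * iqa_units$ebohr_debye)
}

as_points <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) %% 3 != 0) stop("points must be length-3 or n x 3")
    x <- matrix(x, ncol = 3, byrow = TRUE)
  }
  storage.mode(x) <- "double"
  x
}
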