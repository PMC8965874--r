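# Angular and radial quadrature machinery for basin grids.
#
# Angular integration uses product quadratures (Gauss-Legendre in cos(theta)
# x uniform phi) exact to a requested spherical-harmonic degree.  Preset
# angular resolutions are declared with the familiar Lebedev point counts
# and mapped to the product rule of at least the same polynomial degree;
# successive radial shells are rotated in phi by the golden angle to
# decorrelate the sampling of sharp basin boundaries.

# Published Lebedev rule sizes and their polynomial degrees.
LEBEDEV_ORDERS <- data.frame(
  n = c(6, 14, 26, 38, 50, 74, 86, 110, 146, 170, 194, 230, 266, 302, 350,
        434, 590, 770, 974, 1202, 1454, 1730, 2030, 2354, 2702, 3074, 3470,
        3890, 4334, 4802, 5294, 5810),
  degree = c(3, 5, 7, 9, 11, 13, 15, 17, 19, 21, 23, 25, 27, 29, 31, 35, 41,
             47, 53, 59, 65, 71, 77, 83, 89, 95, 101, 107, 113, 119, 125, 131))

angular_degree_for <- function(n_points) {
  i <- which(LEBEDEV_ORDERS$n >= n_points)
  if (!length(i)) return(max(LEBEDEV_ORDERS$degree))
  LEBEDEV_ORDERS$degree[min(i)]
}

gauss_legendre <- function(n, a = -1, b = 1) {
  # Golub-Welsch via symmetric tridiagonal eigen-decomposition
  if (n == 1) {
    x <- 0; w <- 2
  } else {
    k <- seq_len(n - 1)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1)] <- beta
    J[cbind(k + 1, k)] <- beta
    e <- eigen(J, symmetric = TRUE)
    x <- rev(e$values)
    w <- 2 * rev(e$vectors[1, ]^2)
  }
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

# Product angular rule of given degree with a phi rotation offset.
angular_product_rule <- function(degree, phi0 = 0) {
  ntheta <- ceiling((degree + 1) / 2)
  nphi <- degree + 1
  gl <- gauss_legendre(ntheta)
  phis <- phi0 + 2 * pi * (seq_len(nphi) - 0.5) / nphi
  ct <- rep(gl$x, each = nphi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phis, ntheta)
  dirs <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$w, each = nphi) * (2 * pi / nphi)
  list(dirs = dirs, w = w, n = nrow(dirs), degree = degree,
       ntheta = ntheta, nphi = nphi, theta = acos(gl$x), phi0 = phi0)
}

#' Define a basin-grid preset
#'
#' Angular resolutions are given as Lebedev-style point counts (mapped
#' internally to product rules of at least the same polynomial degree);
#' radial counts are Gauss-Legendre points on the two segments inside and
#' outside the beta sphere.
#'
#' @param name preset label.
#' @param ang_out,ang_in angular point counts outside/inside beta spheres,
#'   length-2 `c(heavy, hydrogen)`.
#' @param nrad_out,nrad_in radial points outside/inside, `c(heavy, hydrogen)`.
#' @param rmax radial cutoffs in bohr, `c(heavy, hydrogen)`.
#' @param lmax `c(outside, inside)` maximum angular momentum for the
#'   Laplace/bipolar expansions of 1/r12.
#' @return object of class `iqa_grid_preset`.
#' @export
grid_preset <- function(name = "custom",
                        ang_out = c(194, 110), ang_in = c(110, 50),
                        nrad_out = c(96, 80), nrad_in = c(64, 56),
                        rmax = c(12, 9), lmax = c(10, 6)) {
  ok <- function(v) all(v %in% LEBEDEV_ORDERS$n)
  if (!ok(ang_out) || !ok(ang_in))
    stop("angular counts must be supported Lebedev rule sizes (",
         paste(utils::head(LEBEDEV_ORDERS$n, 12), collapse = ", "), ", ...)")
  structure(list(name = name, ang_out = ang_out, ang_in = ang_in,
                 nrad_out = nrad_out, nrad_in = nrad_in, rmax = rmax,
                 lmax = lmax),
            class = "iqa_grid_preset")
}

#' Named grid presets
#'
#' `"desk"` is the package default for laptop-scale systems; `"paper"`
#' mirrors production-quality settings (5810/974-point angular rules,
#' 512/384 radial points, r_max 15/10 bohr); `"mini"` is for fast unit
#' tests; `"dense"` is the oracle-grade refinement of `"desk"`.
#'
#' @param name one of `"desk"`, `"paper"`, `"mini"`, `"dense"`.
#' @return an `iqa_grid_preset`.
#' @export
get_preset <- function(name = c("desk", "paper", "mini", "dense")) {
  name <- match.arg(name)
  switch(name,
    desk = grid_preset("desk"),
    paper = grid_preset("paper", ang_out = c(5810, 3890),
                        ang_in = c(974, 590), nrad_out = c(512, 384),
                        nrad_in = c(384, 256), rmax = c(15, 10),
                        lmax = c(10, 6)),
    mini = grid_preset("mini", ang_out = c(110, 74), ang_in = c(50, 26),
                       nrad_out = c(48, 40), nrad_in = c(32, 28),
                       rmax = c(10, 8), lmax = c(8, 6)),
    dense = grid_preset("dense", ang_out = c(434, 302), ang_in = c(194, 110),
                        nrad_out = c(192, 160), nrad_in = c(128, 112),
                        rmax = c(13, 10), lmax = c(12, 8)))
}
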