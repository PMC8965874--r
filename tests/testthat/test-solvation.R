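# Implicit solvation: Poisson reaction field, polar terms, CHELPG, SAS,
# SAV, cavity and surface-dispersion terms.

test_that("the reaction field reproduces the Born ion within 2 percent", {
  exact <- born_exact(1, 2.0, 80)
  expect_equal(born_case(0.33), exact, tolerance = 0.02)
  # sign convention: field opposes the ion's own charge
  s <- site_set("Na", matrix(0, 1, 3), q = 1, radius = 2.0)
  rf <- cached("born_rf", solve_reaction_field(s, pb_spec()))
  expect_lt(rf$phi_rf[1], 0)
})

test_that("Born error decreases monotonically with grid refinement", {
  exact <- born_exact(1, 2.0, 80)
  errs <- abs(vapply(c(0.5, 0.33, 0.25), born_case, 1.0) - exact)
  expect_true(all(diff(errs) < 0))
})

test_that("zero charges give a zero reaction field", {
  s <- site_set(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 4)), q = 0,
                radius = 1.7)
  rf <- solve_reaction_field(s, pb_spec(spacing = 0.5, padding = 6))
  expect_lt(max(abs(rf$phi_rf)), 1e-6)
})

test_that("polar atomic terms follow the half-qPhi convention", {
  s <- site_set("X", matrix(0, 1, 3), q = 1, radius = 1.5)
  rf <- structure(list(phi_rf = -10), class = "iqa_reaction_field")
  expect_equal(polar_atomic_terms(s, rf), -5)
  s0 <- site_set("X", matrix(0, 1, 3), q = 0, radius = 1.5)
  expect_equal(polar_atomic_terms(s0, rf), 0)
})

test_that("CHELPG fitting honors the charge constraint exactly", {
  # one closed-shell Gaussian 'ion': Z = 4, 2 electrons -> net +2
  as1 <- make_analytic_system(n = 1, alpha = 1.2, weight = 2, Z = 4)
  g <- cached("grid_chelpg_ion", build_basin_grid(as1$wfn, "mini"))
  q <- chelpg_charges(as1$wfn, g)
  expect_equal(as.numeric(q), 2, tolerance = 1e-9)
})

test_that("CHELPG charges reproduce the molecular dipole", {
  wfn <- get_wfn("h2o_hf_sto3g")
  g <- get_grid("h2o_hf_sto3g", "desk")
  q <- cached("chelpg_h2o", chelpg_charges(wfn, g))
  expect_equal(sum(q), 0, tolerance = 1e-10)
  mu_q <- colSums(wfn$nuc * as.numeric(q)) * iqa_units$ebohr_debye
  mu_rho <- cached("dipole_h2o_sto3g", density_dipole(wfn, g))
  expect_equal(sqrt(sum(mu_q^2)), mu_rho$dipole_debye, tolerance = 0.1 / 2)
  # stability: doubling the grid density moves charges by < 0.01 e
  q2 <- chelpg_charges(wfn, g, gridspec = list(spacing = 0.35))
  expect_lt(max(abs(q - q2)), 0.01)
})

test_that("SAS areas are exact for spheres and additive when disjoint", {
  s1 <- site_set("C", matrix(0, 1, 3), q = 0, eps = 0.1, rmin2 = 1.9,
                 radius = 1.6)
  m1 <- sas_surface(s1)
  expect_equal(m1$area, 4 * pi * 3.0^2, tolerance = 1e-12)
  B <- iqa_units$bohr_angstrom
  s2 <- site_set(c("C", "C"), rbind(c(0, 0, 0), c(20, 0, 0)) / B,
                 q = 0, eps = 0.1, rmin2 = 1.9, radius = 1.6)
  m2 <- sas_surface(s2)
  expect_equal(sum(m2$area), 2 * 4 * pi * 3.0^2, tolerance = 1e-12)
  # overlapping dimer: two-sphere lens closed form
  d <- 4.0
  s3 <- site_set(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)) / B,
                 q = 0, eps = 0.1, rmin2 = 1.9, radius = 1.6)
  m3 <- sas_surface(s3, n_points = 960)
  R <- 3.0
  # exposed area of each sphere: cap of half-angle where the other sphere
  # cuts: exposed = 4 pi R^2 - 2 pi R h, h = R - d/2
  lens_exact <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
  expect_equal(sum(m3$area), lens_exact, tolerance = 0.01 * lens_exact)
})

test_that("SAV volumes are exact for spheres and split the union", {
  s1 <- site_set("C", matrix(0, 1, 3), q = 0, radius = 1.6)
  v1 <- sav_volumes(s1)
  expect_equal(v1, 4 / 3 * pi * 27, tolerance = 0.005 * 4 / 3 * pi * 27)
  B <- iqa_units$bohr_angstrom
  s2 <- site_set(c("C", "C"), rbind(c(0, 0, 0), c(20, 0, 0)) / B,
                 q = 0, radius = 1.6)
  v2 <- sav_volumes(s2)
  expect_equal(sum(v2), 2 * 4 / 3 * pi * 27, tolerance = 0.01 * 8 / 3 * pi * 27)
  # overlapping dimer vs the closed-form union of two spheres
  d <- 4.0; R <- 3.0
  s3 <- site_set(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)) / B,
                 q = 0, radius = 1.6)
  v3 <- sav_volumes(s3)
  lens <- pi * (2 * R - d)^2 * (d^2 + 4 * d * R) / (12 * d)
  union_exact <- 2 * (4 / 3) * pi * R^3 - lens
  expect_equal(sum(v3), union_exact, tolerance = 0.01 * union_exact)
  expect_equal(v3[1], v3[2], tolerance = 0.01 * v3[1])
})

test_that("cavity terms are linear in p and monotone in the radii", {
  expect_equal(cavity_energy(0, c(100, 50))$total, 0)
  ce <- cavity_energy(0.05, c(100, 50))
  expect_equal(ce$per_atom, c(5.0, 2.5))
  expect_equal(ce$total, 7.5)
  s <- site_set(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 3.4)), q = 0,
                radius = c(1.7, 1.52))
  sBig <- s; sBig$radius <- s$radius * 1.1
  expect_gt(cavity_energy(0.05, sav_volumes(sBig))$total,
            cavity_energy(0.05, sav_volumes(s))$total)
})

test_that("surface dispersion matches closed form and volume quadrature", {
  # single sphere: closed form -4 pi rho_w C / (3 (r + probe)^3)
  s1 <- site_set("C", matrix(0, 1, 3), q = 0, eps = 0.1, rmin2 = 1.9,
                 radius = 1.6)
  m1 <- sas_surface(s1)
  dt <- dispersion_surface_terms(s1, m1)
  C1 <- 2 * sqrt(0.1 * 0.152) * (1.9 + 1.7683)^6
  exact <- -4 * pi * 0.03343 * C1 / (3 * 3.0^3)
  expect_equal(dt$total, exact, tolerance = 0.01 * abs(exact))
  # rho_w = 0: all terms vanish
  z <- dispersion_surface_terms(s1, m1, solvent = list(rho_w = 0,
                                                       eps = 0.152,
                                                       rmin2 = 1.7683))
  expect_identical(z$total, 0)
  # symmetrization conserves the total exactly
  B <- iqa_units$bohr_angstrom
  s2 <- site_set(c("C", "O"), rbind(c(0, 0, 0), c(3.2, 0, 0)) / B,
                 q = 0, eps = c(0.1, 0.2), rmin2 = c(1.9, 1.66),
                 radius = c(1.6, 1.5))
  m2 <- sas_surface(s2)
  d2 <- dispersion_surface_terms(s2, m2)
  expect_equal(sum(d2$Gsym), sum(d2$G), tolerance = 1e-14)
  # agreement with the brute-force exterior volume quadrature
  oracle <- cached("disp_vol_oracle", oracle_dispersion_volume(s2))
  expect_equal(d2$total, oracle, tolerance = 0.02 * abs(oracle))
})

test_that("per-atom solvation closes exactly on its components", {
  g <- atomic_solvation(polar = c(-3, -1), cavity = c(0.5, 0.4),
                        disp = c(-0.6, -0.2))
  expect_equal(g$g_solv, c(-3.1, -0.8))
  expect_equal(g$total, sum(g$g_solv), tolerance = 1e-15)
  expect_equal(atomic_solvation(0, 0, 0)$total, 0)
  expect_error(atomic_solvation(c(1, 2), 1, c(1, 2)), "mismatched")
  # Born ion with no nonpolar part: G_solv equals the polar total
  b <- atomic_solvation(polar = -81.98, cavity = 0, disp = 0)
  expect_equal(b$g_solv, -81.98)
})
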