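# QM-MM coupling: masks, basin-integrated electrostatics, LJ, MM energies
# and the BAT atomic split.

test_that("LJ pair energies hit the textbook landmarks", {
  # R = r_min -> -eps exactly; R -> infinity -> 0
  mkpair <- function(R) {
    qm <- site_set("C", matrix(0, 1, 3), q = 0, eps = 0.1, rmin2 = 1.7,
                   region = "QM")
    mm <- site_set("C", matrix(c(R / iqa_units$bohr_angstrom, 0, 0), 1, 3),
                   q = 0, eps = 0.1, rmin2 = 1.7, region = "MM")
    assemble_system(NULL, qm, mm)
  }
  expect_equal(qmmm_vdw(mkpair(3.4))[1, 1], -0.1, tolerance = 1e-12)
  expect_lt(abs(qmmm_vdw(mkpair(60))[1, 1]), 1e-8)
  # missing parameters are reported
  qm <- site_set("C", matrix(0, 1, 3), q = 0, eps = NA, region = "QM")
  mm <- site_set("C", matrix(c(5, 0, 0), 1, 3), q = 0, eps = 0.1,
                 region = "MM")
  expect_error(qmmm_vdw(assemble_system(NULL, qm, mm)), "missing LJ")
})

test_that("zero MM charges give identically zero electrostatics", {
  wfn <- get_wfn("h2o_hf_sto3g")
  qm <- site_set(wfn$symbol, wfn$nuc, region = "QM")
  mm <- site_set(c("X", "X"), rbind(c(8, 0, 0), c(0, 8, 0)), q = 0,
                 region = "MM")
  sys <- assemble_system(wfn, qm, mm)
  ele <- qmmm_electrostatics(sys, get_grid("h2o_hf_sto3g", "mini"))
  expect_true(all(ele == 0))
})

test_that("basin electrostatics matches the analytic Gaussian-cloud form", {
  # one closed-shell s-Gaussian atom (2 electrons, Z = 2) and a unit MM
  # charge: electron term is the erf potential of the cloud, nuclear term
  # is Z q / d
  # a diffuse cloud so the charge-penetration term is well above the
  # quadrature floor
  as1 <- make_analytic_system(n = 1, alpha = 0.12, weight = 2, Z = 2)
  ctr <- as1$wfn$nuc[1, ]
  d <- 4
  qm <- site_set("He", matrix(ctr, 1, 3), region = "QM")
  mm <- site_set("X", matrix(ctr + c(0, 0, d), 1, 3), q = 1, region = "MM")
  sys <- assemble_system(as1$wfn, qm, mm)
  g <- cached("grid_analytic1", build_basin_grid(as1$wfn, "mini"))
  ele <- qmmm_electrostatics(sys, g)
  beta <- 2 * as1$alpha[1]
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  # Gaussian cloud exp(-beta r^2): V(d) = erf(sqrt(beta) d) / d
  exact <- -2 * erf(sqrt(beta) * d) / d + 2 * 1 / d
  expect_gt(abs(exact), 1e-3)
  expect_equal(ele[1, 1], exact, tolerance = 5e-5 / abs(exact))
})

test_that("pairwise QM-MM electrostatics closes on the direct integral", {
  wfn <- get_wfn("h2o_hf_sto3g")
  qm <- site_set(wfn$symbol, wfn$nuc, region = "QM")
  B <- iqa_units$bohr_angstrom
  mmx <- rbind(c(0, 0, 5.5), c(1.2, 0, 6.9), c(-1.2, 0, 6.9))
  mm <- site_set(c("O", "H", "H"), mmx, q = c(-0.834, 0.417, 0.417),
                 region = "MM")
  sys <- assemble_system(wfn, qm, mm)
  g <- get_grid("h2o_hf_sto3g", "desk")
  ele <- qmmm_electrostatics(sys, g)
  # unpartitioned oracle: whole-density quadrature, no basin resolution
  aw <- active_weights(g)
  nz <- aw > 0
  rho <- evaluate_density(wfn, g$points[nz, , drop = FALSE])
  pot_e <- cpp_coulomb_sum(mmx, g$points[nz, , drop = FALSE],
                           aw[nz] * rho, 1e-8)
  direct <- sum(mm$q * (-pot_e)) +
    sum(outer(wfn$Z, mm$q) / as.matrix(stats::dist(rbind(wfn$nuc, mmx)))[1:3, 4:6])
  expect_equal(sum(ele), direct, tolerance = 1e-5)
})

test_that("MM bonded energies follow the Amber functional form", {
  # bond: k (r - r0)^2 with k = 100, r0 = 1, r = 1.1 -> 1.0 kcal/mol
  f <- tempfile(fileext = ".toy")
  writeLines(c("toytop v1",
               "site A C 0 0 0 1.7 MM 0 0 0",
               "site B C 0 0 0 1.7 MM 1.1 0 0",
               "bond 1 2 100 1.0"), f)
  tt <- load_topology(f)
  me <- mm_energy(tt$topology, tt$sites)
  expect_equal(unname(me$totals["bond"]), 1.0, tolerance = 1e-10)
  # dihedral: k (1 + cos(n phi - gamma)), phi = 180 deg, n = 1, gamma = 0
  f2 <- tempfile(fileext = ".toy")
  writeLines(c("toytop v1",
               "site A C 0 0 0 1.7 MM 0 1.0 0",
               "site B C 0 0 0 1.7 MM 0 0 0",
               "site C C 0 0 0 1.7 MM 1.5 0 0",
               "site D C 0 0 0 1.7 MM 1.5 -1.0 0",
               "dihedral 1 2 3 4 2 1 0"), f2)
  t2 <- load_topology(f2)
  m2 <- mm_energy(t2$topology, t2$sites)
  expect_equal(unname(m2$totals["dihedral"]), 0, tolerance = 1e-10)
  # TIP3P water at its reference geometry: bonded terms vanish, and a
  # hand-computed stretched geometry matches term by term
  me3 <- mm_energy(load_topology(toy_water_file(0))$topology,
                   load_topology(toy_water_file(0))$sites)
  expect_lt(me3$totals["bond"] + me3$totals["angle"], 1e-10)
  tw <- load_topology(toy_water_file(0.1))
  me4 <- mm_energy(tw$topology, tw$sites)
  # the toy file carries 6-decimal coordinates; compare at that precision
  expect_equal(unname(me4$totals["bond"]), 2 * 553 * 0.1^2,
               tolerance = 1e-5)
})

test_that("TIP3P dimer nonbonded energy matches the hand-computed oracle", {
  # two rigid TIP3P waters, O-O along x at 2.8 A: Coulomb + LJ with the
  # published parameters, computed independently with plain arithmetic
  tw <- load_topology(system.file("extdata", "toy", "tip3p_water.prmtop",
                                  package = "iqadecomp"))
  B <- iqa_units$bohr_angstrom
  r <- 0.9572; ang <- 104.52 * pi / 180
  w1 <- rbind(c(0, 0, 0), c(-r, 0, 0), c(-r * cos(ang), r * sin(ang), 0))
  w2 <- cbind(2.8 + abs(w1[, 1]), w1[, 2], w1[, 3])  # hydrogens point away
  xyz <- rbind(w1, w2)
  sites <- suppressMessages(site_set(
    rep(c("O", "H", "H"), 2), xyz / B, q = rep(c(-0.834, 0.417, 0.417), 2),
    eps = rep(c(0.152, 0, 0), 2), rmin2 = rep(c(1.7683, 0, 0), 2),
    region = "MM"))
  top <- mm_topology(
    bonds = data.frame(i = c(1, 1, 4, 4), j = c(2, 3, 5, 6),
                       kb = 553, r0 = 0.9572),
    angles = data.frame(i = c(2, 5), j = c(1, 4), k = c(3, 6),
                        ktheta = 100, theta0 = ang),
    n_sites = 6)
  me <- mm_energy(top, sites)
  # independent oracle: scalar loops
  oe <- 0; ov <- 0
  for (i in 1:3) for (j in 4:6) {
    Rij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    oe <- oe + 332.0637 * sites$q[i] * sites$q[j] / Rij
    if (i == 1 && j == 4) {
      s6 <- ((1.7683 * 2) / Rij)^6
      ov <- ov + 0.152 * (s6^2 - 2 * s6)
    }
  }
  expect_equal(unname(me$totals["ele"]), oe, tolerance = 1e-4)
  expect_equal(unname(me$totals["vdw"]), ov, tolerance = 1e-4)
})

test_that("the BAT split conserves every record exactly", {
  # one bond of 2.0 -> 1.0 each; angle of 3.0 -> 1.0 x3; torsion 4.0 -> 1 x4
  brk <- structure(list(
    bond_terms = data.frame(i = 1, j = 2, r = 1, energy = 2.0),
    angle_terms = data.frame(i = 1, j = 2, k = 3, theta = 2, energy = 3.0),
    dihedral_terms = data.frame(i = 1, j = 2, k = 3, l = 4, phi = 0,
                                energy = 4.0),
    nonbonded = data.frame(), totals = c(), n_sites = 4),
    class = "iqa_mm_energy")
  bat <- bat_atomic_split(brk)
  expect_equal(bat, c(1 + 1 + 1, 1 + 1 + 1, 1 + 1, 1))
  expect_equal(sum(bat), 2 + 3 + 4, tolerance = 1e-15)
  # mixed toy topology: conservation to machine precision
  tw <- load_topology(toy_water_file(0.07))
  me <- mm_energy(tw$topology, tw$sites)
  expect_equal(sum(bat_atomic_split(me)),
               sum(me$totals[c("bond", "angle", "dihedral")]),
               tolerance = 1e-14)
})

test_that("interaction masks encode the link-atom exclusion rules", {
  # ethane-like split (combined order QM, LINK, then MM):
  # QM carbon 1, link H 2, MM host carbon 3, distant MM oxygens 4-5
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1.05), c(0, 0, 2.9), c(0, 3, 5),
               c(0, -3, 5))
  sites <- site_set(c("C", "H", "C", "O", "O"), xyz,
                    q = c(-0.1, 0.1, -0.1, -0.4, -0.4),
                    eps = 0.1, rmin2 = 1.7,
                    region = c("QM", "LINK", "MM", "MM", "MM"))
  top <- mm_topology(bonds = data.frame(i = 1, j = 3, kb = 300, r0 = 1.53),
                     n_sites = 5)
  links <- data.frame(qm_host = 1, mm_host = 3, link_site = 2)
  sys <- assemble_system(NULL, sites[sites$region != "MM", ],
                         sites[sites$region == "MM", ],
                         topology = top, link_spec = links)
  mask <- build_interaction_mask(sys)
  # MM host carbon (first MM site) excluded from QM electrostatics for
  # every QM basin, including the link H
  expect_true(all(!mask$ele[, 1]))
  # distant MM sites stay included; the link H row exists (it is a source)
  expect_true(all(mask$ele[, 2:3]))
  expect_equal(nrow(mask$ele), 2L)  # QM carbon + link H
  # no links: full mask
  sys2 <- assemble_system(NULL,
                          site_set("C", matrix(0, 1, 3), q = 0,
                                   region = "QM"),
                          site_set("O", matrix(c(0, 0, 6), 1, 3), q = -0.4,
                                   region = "MM"))
  expect_true(all(build_interaction_mask(sys2)$ele))
})
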