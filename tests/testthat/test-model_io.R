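# Wavefunction, site and topology readers; pointwise field evaluation.

test_that("wfx fixtures load with the header values and pass invariants", {
  m <- manifest()
  h2 <- get_wfn("h2_hf_sto3g")
  expect_equal(h2$nelec, 2L)
  expect_equal(ncol(h2$C), 1L)
  expect_equal(h2$natom, 2L)
  expect_equal(h2$scf_energy, m$h2_hf_sto3g$scf_energy, tolerance = 1e-12)
  h2o <- get_wfn("h2o_hf_sto3g")
  expect_equal(h2o$nelec, 10L)
  expect_equal(ncol(h2o$C), 5L)
  expect_silent(validate_wavefunction(h2o))
  heh <- get_wfn("heh_cation_hf_sto3g")
  expect_equal(heh$charge, 1L)
})

test_that("molden and wfx readers agree pointwise on the same density", {
  a <- get_wfn("h2o_hf_sto3g", "wfx")
  b <- get_wfn("h2o_hf_sto3g", "molden")
  set.seed(7)
  pts <- matrix(stats::rnorm(45, sd = 1.2), 15, 3)
  expect_equal(evaluate_density(b, pts), evaluate_density(a, pts),
               tolerance = 1e-8)
})

test_that("inconsistent occupation/electron headers are rejected", {
  path <- fixture_path("h2_hf_sto3g")
  lines <- readLines(path)
  i <- grep("<Number of Electrons>", lines)
  lines[i + 1] <- " 4"
  bad <- tempfile(fileext = ".wfx")
  writeLines(lines, bad)
  expect_error(load_wavefunction(bad), "consistency error")
})

test_that("malformed wfx records name the offending section", {
  path <- fixture_path("he_hf_sto3g")
  # break the exponents section open tag
  lines2 <- readLines(path)
  lines2[grep("<Primitive Exponents>", lines2)] <- "<Primitive Exp>"
  bad <- tempfile(fileext = ".wfx")
  writeLines(lines2, bad)
  expect_error(load_wavefunction(bad), "Primitive Exponents")
})

test_that("density closed forms and gradient consistency hold", {
  # one electron in a normalized s-Gaussian, alpha = 1: rho(0) = (2/pi)^1.5
  as1 <- make_analytic_system(n = 1, alpha = 1, weight = 1, Z = 1)
  ctr <- as1$wfn$nuc[1, ]
  expect_equal(evaluate_density(as1$wfn, matrix(ctr, 1, 3)),
               (2 / pi)^1.5, tolerance = 1e-10)
  # gradient vs central differences
  wfn <- get_wfn("h2o_hf_sto3g")
  set.seed(3)
  pts <- matrix(stats::rnorm(30, sd = 1.0), 10, 3)
  g <- evaluate_density(wfn, pts, "gradient")
  h <- 1e-5
  for (ax in 1:3) {
    pp <- pts; pp[, ax] <- pp[, ax] + h
    pm <- pts; pm[, ax] <- pm[, ax] - h
    fd <- (evaluate_density(wfn, pp) - evaluate_density(wfn, pm)) / (2 * h)
    expect_equal(g$grad[, ax], fd,
                 tolerance = 1e-6 * max(1, max(abs(fd))))
  }
  # H2 midpoint: gradient vanishes by symmetry
  h2 <- get_wfn("h2_hf_sto3g")
  gm <- evaluate_density(h2, matrix(c(0, 0, 0.7), 1, 3), "gradient")
  expect_lt(max(abs(gm$grad)), 1e-12)
  # distant points evaluate to zero, not NaN
  expect_identical(evaluate_density(h2, matrix(c(90, 90, 90), 1, 3)), 0)
})

test_that("rho1 diagonal equals rho and matches direct contraction", {
  wfn <- get_wfn("h2o_hf_sto3g")
  set.seed(11)
  p1 <- matrix(stats::rnorm(15, sd = 1), 5, 3)
  p2 <- matrix(stats::rnorm(15, sd = 1), 5, 3)
  expect_equal(evaluate_rdm1(wfn, p1, p1), evaluate_density(wfn, p1),
               tolerance = 1e-12)
  expect_equal(evaluate_rdm1(wfn, p1, p2), evaluate_rdm1(wfn, p2, p1),
               tolerance = 1e-12)
  # brute-force sum over occupied orbitals
  mo1 <- evaluate_mos(wfn, p1)$mo
  mo2 <- evaluate_mos(wfn, p2)$mo
  brute <- vapply(1:5, function(k) 2 * sum(mo1[k, ] * mo2[k, ]), 1.0)
  expect_equal(evaluate_rdm1(wfn, p1, p2), brute, tolerance = 1e-12)
  # single-MO system: rho1 = 2 phi(r1) phi(r2)
  h2 <- get_wfn("h2_hf_sto3g")
  a <- matrix(c(0, 0, 0.2), 1, 3); b <- matrix(c(0.3, 0, 1.1), 1, 3)
  expect_equal(evaluate_rdm1(h2, a, b),
               2 * evaluate_mos(h2, a)$mo[1, 1] *
                 evaluate_mos(h2, b)$mo[1, 1], tolerance = 1e-12)
})

test_that("kinetic-energy density is positive and integrates to T_scf", {
  m <- manifest()
  for (nm in c("h2_hf_sto3g", "he_hf_sto3g")) {
    wfn <- get_wfn(nm)
    set.seed(5)
    pts <- matrix(stats::runif(3000, -4, 4), 1000, 3)
    expect_true(all(evaluate_ked(wfn, pts) >= 0))
    g <- get_grid(nm, "desk")
    ked_int <- sum(active_weights(g) * evaluate_ked(wfn, g$points))
    expect_equal(ked_int, m[[nm]]$kinetic_energy, tolerance = 1e-4)
  }
})

test_that("site readers populate charges, radii and regions", {
  f <- tempfile(fileext = ".xyzq")
  writeLines(c("# comment", "O 0 0 0 -0.834", "H 0.9572 0 0 0.417"), f)
  s <- load_sites(f)
  expect_equal(nrow(s), 2L)
  expect_equal(s$q, c(-0.834, 0.417))
  expect_equal(s$x[2] * iqa_units$bohr_angstrom, 0.9572, tolerance = 1e-10)
  # pqr with radius column
  fp <- tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM      1  O   WAT     1       0.000   0.000   0.000 -0.8340 1.5000",
    "ATOM      2  H1  WAT     1       0.957   0.000   0.000  0.4170 0.8000"),
    fp)
  sp <- load_sites(fp)
  expect_equal(sp$radius, c(1.5, 0.8))
  # pdb without charges: downstream q-requiring ops fail loudly
  fb <- tempfile(fileext = ".pdb")
  writeLines(c(
    paste0("ATOM      1  O   HOH A   1       0.000   0.000   0.000",
           "  1.00  0.00           O"),
    paste0("ATOM      2  H1  HOH A   1       0.957   0.000   0.000",
           "  1.00  0.00           H")), fb)
  sb <- load_sites(fb)
  expect_true(all(is.na(sb$q)))
  expect_error(iqadecomp:::require_charges(sb), "precondition")
  # non-numeric field reports the line
  fbad <- tempfile(fileext = ".xyzq")
  writeLines(c("O 0 0 zero -0.8"), fbad)
  expect_error(load_sites(fbad), "line 1")
})

test_that("topology loaders parse toy and prmtop dialects", {
  f <- tempfile(fileext = ".toy")
  writeLines(c("toytop v1",
               "site A C 0 0.1 1.9 1.7 MM 0 0 0",
               "site B C 0 0.1 1.9 1.7 MM 1.0 0 0",
               "bond 1 2 100 1.0"), f)
  tt <- load_topology(f)
  expect_equal(nrow(tt$topology$bonds), 1L)
  expect_equal(tt$topology$bonds$kb, 100)
  expect_equal(tt$topology$bonds$r0, 1.0)
  # empty topology + charged sites is valid
  f2 <- tempfile(fileext = ".toy")
  writeLines(c("toytop v1",
               "site A Na 1 0 0 2.0 MM 0 0 0",
               "site B Cl -1 0 0 2.0 MM 4 0 0"), f2)
  t2 <- load_topology(f2)
  expect_equal(nrow(t2$topology$bonds), 0L)
  expect_equal(t2$sites$q, c(1, -1))
  # prmtop: unit conversion of charges, LJ recovery, radii
  pp <- suppressMessages(
    load_topology(system.file("extdata", "toy", "tip3p_water.prmtop",
                              package = "iqadecomp")))
  expect_equal(pp$sites$q[1], -0.834, tolerance = 1e-8)
  expect_equal(pp$sites$eps[1], 0.152, tolerance = 1e-8)
  expect_equal(pp$sites$rmin2[1], 1.7683, tolerance = 1e-6)
  expect_equal(nrow(pp$topology$bonds), 2L)
  expect_error(load_topology(tempfile()), "not found")
})

test_that("system assembly enforces site/nucleus correspondence and links", {
  wfn <- get_wfn("h2o_hf_sto3g")
  qm <- site_set(wfn$symbol, wfn$nuc, region = "QM")
  mm <- site_set("X", matrix(c(0, 0, 8), 1, 3), q = -0.5, region = "MM")
  sys <- assemble_system(wfn, qm, mm)
  expect_s3_class(sys, "iqa_system")
  expect_equal(length(sys$qm_index), 3L)
  # mismatched position
  bad <- qm; bad$x[1] <- bad$x[1] + 0.1
  expect_error(assemble_system(wfn, bad, mm), "mismatch")
  # link record bookkeeping on an ethane-like MM-only model
  # combined ordering is QM/LINK sites first, then MM sites
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1.05), c(1.9, 0, -0.6),
               c(0, 0, 2.9), c(-0.9, 1.6, 3.5))
  sites <- site_set(c("C", "H", "H", "C", "H"), xyz,
                    q = c(-0.1, 0.1, 0.05, -0.1, 0.05),
                    region = c("QM", "LINK", "QM", "MM", "MM"))
  top <- mm_topology(bonds = data.frame(i = 1, j = 4, kb = 300, r0 = 1.53))
  links <- data.frame(qm_host = 1, mm_host = 4, link_site = 2)
  sys2 <- assemble_system(NULL, sites[sites$region != "MM", ],
                          sites[sites$region == "MM", ],
                          topology = top, link_spec = links)
  expect_equal(nrow(sys2$links), 1L)
  expect_error(assemble_system(NULL, sites, NULL, link_spec = NULL),
               "LINK")
})

test_that("unit conversion table is exact", {
  expect_identical(convert_energy(1, "hartree", "kcal"), 627.509)
  expect_identical(convert_energy(627.509, "kcal", "hartree"), 1)
})
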