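# IQF regrouping, formation decomposition, scoring, consistency, reports.

test_that("fragment regrouping conserves the total for any scheme", {
  tm <- get_terms("h2o_hf_sto3g", "mini")
  # all atoms in one fragment: E_net^A is the full reconstruction
  one <- iqf_regroup(tm, fragment_scheme(c("mol", "mol", "mol")))
  expect_equal(one$E_net, reconstruct_total(tm)$total, tolerance = 1e-12)
  expect_true(all(one$E_int == 0))
  # two-fragment split: pair terms are the atomic components
  two <- iqf_regroup(tm, fragment_scheme(c("O", "H2", "H2")))
  expect_equal(two$E_int["O", "H2"],
               tm$E_int[1, 2] + tm$E_int[1, 3], tolerance = 1e-12)
  ftot <- sum(two$E_net) + two$E_int["O", "H2"]
  expect_equal(ftot, reconstruct_total(tm)$total, tolerance = 1e-12)
  # three singleton fragments reproduce the atomic matrix exactly
  three <- iqf_regroup(tm, fragment_scheme(c("a", "b", "c")))
  expect_equal(as.numeric(three$E_net), tm$E_net, tolerance = 1e-15)
  expect_error(iqf_regroup(tm, fragment_scheme(c("a", "b"))), "covers")
})

test_that("formation decomposition is exact arithmetic", {
  # synthetic ledger: E_def = (2, 3), E_int = -10 -> dE_form = -5
  fm <- structure(list(
    fragments = factor(c("A", "B")), E_net = c(12, 23),
    E_ele = matrix(c(0, -8, -8, 0), 2, 2,
                   dimnames = list(c("A", "B"), c("A", "B"))),
    E_xc = matrix(c(0, -2, -2, 0), 2, 2),
    E_disp = matrix(0, 2, 2),
    E_int = matrix(c(0, -10, -10, 0), 2, 2),
    populations = c(1, 1), atomic_total = 15),
    class = "iqa_fragment_matrix")
  fd <- formation_decomposition(fm, c(A = 10, B = 20))
  expect_equal(unname(fd$E_def), c(2, 3))
  expect_equal(fd$dE_form, -5)
  # geometry drift beyond tolerance violates the rigid assumption
  gc <- list(complex = list(A = matrix(0, 2, 3)),
             isolated = list(A = matrix(c(0.001, 0, 0, -0.001, 0, 0),
                                        2, 3)))
  expect_error(formation_decomposition(fm, c(A = 10, B = 20),
                                       geometry_check = gc), "rigid")
})

test_that("separated rigid fragments form a non-interacting limit", {
  # He...He at 8 bohr: interaction and deformation vanish together
  tm <- he_pair_terms(8, "near")
  fm <- iqf_regroup(tm, fragment_scheme(c("A", "B")))
  iso <- get_terms("he_hf_sto3g", "desk")$E_net
  fd <- formation_decomposition(fm, c(A = iso, B = iso))
  expect_lt(abs(fd$E_int), 1e-4)
  expect_lt(abs(fd$dE_form), 1e-3)
})

test_that("fragment additive energies are the three-term sum", {
  expect_equal(fragment_additive_energy(0, 0, 0), 0)
  expect_equal(fragment_additive_energy(91.6, 72.5, -172.1), -8.0,
               tolerance = 1e-12)
  # closure: summed over fragments equals the total change
  dn <- c(1.5, -0.3); ds <- c(-2, 0.7); hi <- c(-4, -4)
  expect_equal(sum(fragment_additive_energy(dn, ds, hi)),
               sum(dn) + sum(ds) + sum(hi), tolerance = 1e-15)
})

test_that("binding scores subtract species components exactly", {
  sc <- qmmm_pbsa_score(c(coul = -10, vdw = -5, solv = 8),
                        c(coul = -2, vdw = -1, solv = 3),
                        c(coul = -1, vdw = 0, solv = 2))
  expect_equal(sc$dG, (-10 + 2 + 1) + (-5 + 1 + 0) + (8 - 3 - 2))
  # identical species: dG = -G(species)
  g <- c(coul = -4, vdw = -2, solv = 5)
  expect_equal(qmmm_pbsa_score(g, g, g)$dG, -sum(g))
  # the 3RT term at 300 K
  s3 <- qmmm_pbsa_score(g, g, g, list(include_3rt = TRUE,
                                      temperature = 300))
  expect_equal(s3$dG - (-sum(g)), -3 * 0.0019872 * 300, tolerance = 1e-12)
  expect_error(qmmm_pbsa_score(g, g, c(a = 1)), "component names")
})

test_that("consistency checks flag injected faults and pass clean runs", {
  tm <- get_terms("h2o_hf_sto3g", "mini")
  ck <- consistency_check(tm)
  expect_true(all(ck$ok))
  bad <- tm
  bad$E_int[1, 2] <- bad$E_int[1, 2] + 1e-3
  ck2 <- consistency_check(bad)
  expect_false(all(ck2$ok))
  expect_gte(max(ck2$magnitude), 1e-3 - 1e-12)
})

test_that("reports round-trip and expose the metadata block", {
  tm <- get_terms("h2o_hf_sto3g", "mini")
  fj <- tempfile(fileext = ".json")
  write_report(tm, fj, "json",
               fragment_matrix = iqf_regroup(tm,
                                             fragment_scheme(c("O", "H",
                                                               "H"))))
  j <- jsonlite::fromJSON(fj)
  expect_equal(j$atoms$E_add, additive_energies(tm), tolerance = 1e-12)
  expect_identical(j$metadata$preset, tm$preset)
  ft <- tempfile(fileext = ".tsv")
  write_report(tm, ft, "tsv")
  txt <- readLines(ft)
  expect_true(any(grepl("E_add", txt)))
  expect_true(any(grepl("residual_hartree", txt)))
})
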