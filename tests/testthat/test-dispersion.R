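# D3(BJ) dispersion: coordination numbers, C6 interpolation, damping,
# merge bookkeeping.

test_that("coordination numbers behave like smooth bond counts", {
  p <- d3_params()
  # isolated atom: zero
  one <- site_set("C", matrix(0, 1, 3), region = "QM")
  expect_identical(coordination_numbers(one, p), 0)
  # H2 at 1.4 bohr: frozen value from the independent scalar oracle
  h2 <- site_set(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)),
                 region = "QM")
  cn <- coordination_numbers(h2, p)
  expect_equal(cn[1], cn[2], tolerance = 1e-14)
  expect_gt(cn[1], 0.85); expect_lt(cn[1], 1.0)
  # water monomer: O sees about two bonds, H about one
  B <- iqa_units$bohr_angstrom
  ang <- 104.52 * pi / 180
  xyz <- rbind(c(0, 0, 0),
               c(0.9572 * sin(ang / 2), 0, 0.9572 * cos(ang / 2)),
               c(-0.9572 * sin(ang / 2), 0, 0.9572 * cos(ang / 2))) / B
  w <- site_set(c("O", "H", "H"), xyz, region = "QM")
  cnw <- coordination_numbers(w, p)
  expect_equal(cnw[1], 2, tolerance = 0.05)
  expect_equal(cnw[2], 1, tolerance = 0.05)
  # uncovered element
  bad <- site_set("Xx", matrix(0, 1, 3), region = "QM")
  expect_error(coordination_numbers(bad, p), "Xx")
})

test_that("pair energies reach the undamped asymptote and stay symmetric", {
  p <- d3_params()
  one <- site_set("O", matrix(0, 1, 3), region = "QM")
  r1 <- d3bj_pair_energies(one, p)
  expect_identical(r1$total, 0)
  far <- site_set(c("O", "O"), rbind(c(0, 0, 0), c(0, 0, 50)),
                  region = "QM")
  r <- d3bj_pair_energies(far, p)
  c6 <- iqadecomp:::d3_c6_pair("O", "O", r$cn[1], r$cn[2], p)
  expect_equal(r$pairs[1, 2], -p$s6 * c6 / 50^6, tolerance = 1e-4)
  expect_identical(r$pairs, t(r$pairs))
  expect_identical(r$total, sum(r$pairs[upper.tri(r$pairs)]))
})

test_that("totals are invariant under rigid motion", {
  p <- d3_params()
  B <- iqa_units$bohr_angstrom
  xyz <- rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0),
               c(2.9, 0.5, 0.3)) / B
  s <- site_set(c("O", "H", "H", "O"), xyz, region = "QM")
  t0 <- d3bj_pair_energies(s, p)$total
  # rotate + translate
  th <- 0.83
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz2 <- xyz %*% t(Rz) + matrix(c(3, -2, 7), 4, 3, byrow = TRUE)
  s2 <- site_set(c("O", "H", "H", "O"), xyz2, region = "QM")
  expect_equal(d3bj_pair_energies(s2, p)$total, t0, tolerance = 1e-12)
})

test_that("the water-dimer total matches the independent oracle to 1e-8", {
  p <- d3_params("b3lyp")
  B <- iqa_units$bohr_angstrom
  ang <- 104.52 * pi / 180
  w1 <- rbind(c(0, 0, 0),
              c(-0.9572 * sin(ang / 2), 0, -0.9572 * cos(ang / 2)),
              c(0.9572 * sin(ang / 2), 0, -0.9572 * cos(ang / 2)))
  w2 <- rbind(c(0, 0, 2.98), c(0.24, 0.93, 3.3), c(0.24, -0.93, 3.3))
  s <- site_set(rep(c("O", "H", "H"), 2), rbind(w1, w2) / B, region = "QM")
  mine <- d3bj_pair_energies(s, p)$total
  oracle <- oracle_d3_total(s, p)
  expect_equal(mine, oracle, tolerance = 1e-8 / abs(oracle))
  expect_lt(mine, 0)  # attractive
})

test_that("dispersion merges into the term matrix additively", {
  tm <- synthetic_terms(E_net = c(-1, -2), E_int12 = -0.5)
  disp <- matrix(c(0, -0.01, -0.01, 0), 2, 2)
  tm2 <- merge_dispersion(tm, disp)
  expect_equal(reconstruct_total(tm2)$total,
               reconstruct_total(tm)$total - 0.01, tolerance = 1e-15)
  expect_equal(sum(additive_energies(tm2)),
               reconstruct_total(tm2)$total, tolerance = 1e-15)
  expect_error(merge_dispersion(tm, matrix(0, 3, 3)), "dimension")
})
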