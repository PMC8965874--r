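# Term-matrix exchange container round-trip.

test_that("write-then-read reproduces every float bit-exactly", {
  tm <- get_terms("h2o_hf_sto3g", "mini")
  f <- tempfile(fileext = ".json")
  write_term_matrix(tm, f)
  back <- read_term_matrix(f)
  expect_identical(back$E_net, tm$E_net)
  expect_identical(back$E_int, tm$E_int)
  expect_identical(back$Vee_xc, tm$Vee_xc)
  expect_identical(back$net_components$T, tm$net_components$T)
  expect_identical(back$scf_energy, tm$scf_energy)
  expect_identical(reconstruct_total(back)$total,
                   reconstruct_total(tm)$total)
})

test_that("containers carry the QM-MM and dispersion blocks", {
  tm <- synthetic_terms(E_net = c(-1, -2), E_int12 = -0.5,
                        qmmm = matrix(c(-0.1, 0.03), 2, 1))
  tm$disp <- matrix(c(0, -1e-3, -1e-3, 0), 2, 2)
  f <- tempfile(fileext = ".json")
  write_term_matrix(tm, f)
  back <- read_term_matrix(f)
  expect_identical(back$qmmm_ele, tm$qmmm_ele)
  expect_identical(back$disp, tm$disp)
  expect_identical(sum(additive_energies(back, "qm_full_qmmm")),
                   sum(additive_energies(tm, "qm_full_qmmm")))
})
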