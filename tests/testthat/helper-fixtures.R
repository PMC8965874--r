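# Shared fixtures and caches.  Expensive objects (wavefunctions, basin
# grids, term matrices) are built once per test run and reused.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

manifest <- function() cached("manifest", fixture_manifest())

get_wfn <- function(name, ext = "wfx") {
  cached(paste0("wfn_", name, ext),
         load_wavefunction(fixture_path(name, ext)))
}

get_grid <- function(name, preset = "mini") {
  cached(paste0("grid_", name, "_", preset),
         build_basin_grid(get_wfn(name), preset))
}

get_terms <- function(name, preset = "mini", ...) {
  cached(paste0("terms_", name, "_", preset),
         iqa_atomic_terms(get_wfn(name), get_grid(name, preset), ...))
}

# a minimal toy topology file for MM tests (TIP3P-like water at a
# stretched geometry so bonded terms are nonzero)
toy_water_file <- function(stretch = 0.1) {
  f <- tempfile(fileext = ".toy")
  r <- 0.9572 + stretch
  ang <- 104.52 * pi / 180
  writeLines(c(
    "toytop v1",
    sprintf("site O1 O -0.834 0.152 1.7683 1.52 MM 0 0 0"),
    sprintf("site H1 H 0.417 0 0 1.2 MM %.6f 0 0", r),
    sprintf("site H2 H 0.417 0 0 1.2 MM %.6f %.6f 0",
            r * cos(ang), r * sin(ang)),
    "bond 1 2 553 0.9572",
    "bond 1 3 553 0.9572",
    "angle 2 1 3 100 104.52"), f)
  f
}

# synthetic iqa_terms object for bookkeeping-arithmetic tests
synthetic_terms <- function(E_net = c(-1, -2), E_int12 = -0.5,
                            qmmm = NULL) {
  n <- length(E_net)
  Eint <- matrix(0, n, n)
  if (n >= 2) Eint[1, 2] <- Eint[2, 1] <- E_int12
  structure(list(
    natom = n, E_net = E_net,
    net_components = data.frame(T = rep(0, n), V_ne_own = E_net,
                                Vee_coul_intra = rep(0, n),
                                Vee_xc_intra = rep(0, n), N = rep(1, n)),
    V_nn = matrix(0, n, n), V_en = matrix(0, n, n),
    Vee_coul = matrix(0, n, n), Vee_xc = matrix(0, n, n),
    E_ele = Eint, E_xc = matrix(0, n, n), E_int = Eint,
    qmmm_ele = qmmm, qmmm_vdw = NULL, disp = NULL,
    kappa = 1, method = "HF", scf_energy = NA_real_,
    screen_threshold = 0, lmax = 0, subsets = NULL, preset = "synthetic",
    ee_method = "laplace"),
    class = "iqa_terms")
}

bdiag2 <- function(A, B) {
  out <- matrix(0, nrow(A) + nrow(B), ncol(A) + ncol(B))
  out[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  out[nrow(A) + seq_len(nrow(B)), ncol(A) + seq_len(ncol(B))] <- B
  out
}

born_exact <- function(q, r, eps) {
  -(iqa_units$coulomb_kcal / 2) * q^2 * (1 - 1 / eps) / r
}

born_case <- function(spacing) {
  cached(paste0("born_", spacing), {
    s <- site_set("Na", matrix(0, 1, 3), q = 1, radius = 2.0)
    rf <- solve_reaction_field(s, pb_spec(spacing = spacing))
    sum(polar_atomic_terms(s, rf))
  })
}


# two-He-atom wavefunction (block-diagonal copies of the fixture) at the
# given separation, with cached terms
he_pair_terms <- function(sep, key) {
  cached(paste0("terms_hepair_", key), {
    he <- get_wfn("he_hf_sto3g")
    pair <- he
    pair$natom <- 2L
    pair$Z <- rep(he$Z, 2)
    pair$nuc <- rbind(he$nuc, he$nuc + c(0, 0, sep))
    pair$symbol <- rep("He", 2)
    pair$prim_center <- c(he$prim_center, he$prim_center + 1L)
    pair$prim_l <- rbind(he$prim_l, he$prim_l)
    pair$prim_alpha <- rep(he$prim_alpha, 2)
    pair$C <- bdiag2(he$C, he$C)
    pair$occ <- rep(2, 2)
    pair$mo_energy <- rep(NA_real_, 2)
    pair$nelec <- 4L
    pair$scf_energy <- NA_real_
    g <- build_basin_grid(pair, "mini")
    iqa_atomic_terms(pair, g)
  })
}
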