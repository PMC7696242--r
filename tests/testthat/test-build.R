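test_that("builder reproduces arbitrary dihedral targets at zero noise", {
  set.seed(21)
  for (k in 1:10) {
    targets <- cbind(runif(3, -179, 180), runif(3, -179, 180))
    fr <- build_tripeptide("FIF", targets)
    d <- backbone_dihedrals(fr, 0)
    expect_lt(max(abs(unname(d) - c(t(targets)))), 1e-6)
  }
  expect_error(build_tripeptide("FXF", rbind(c(0, 0), c(0, 0), c(0, 0))),
               class = "tf_invalid_input")
})

test_that("builder noise is reproducible from the seed", {
  t3 <- rbind(c(-135, 135), c(-135, 135), c(-135, 135))
  a <- build_tripeptide("FFF", t3, noise_sigma = 0.01, seed = 42)
  b <- build_tripeptide("FFF", t3, noise_sigma = 0.01, seed = 42)
  c_ <- build_tripeptide("FFF", t3, noise_sigma = 0.01, seed = 43)
  expect_identical(coords(a), coords(b))
  expect_false(isTRUE(all.equal(coords(a), coords(c_))))
})

test_that("basin-center fixtures classify to their own codes", {
  fr <- build_tripeptide("FFF", code_phi_psi("RRR"))
  expect_identical(classify_peptide(fr, 0), "RRR")
  fr <- build_tripeptide("III", code_phi_psi("BLP", default_region_map(FALSE)))
  expect_identical(classify_peptide(fr, 0, default_region_map(FALSE)), "BLP")
})

test_that("filament construction fixes the rise and adjacency by construction", {
  pep <- build_tripeptide("FFF", code_phi_psi("BBB"))
  fil <- build_filament(pep, n_copies = 6, rise = 4.8, twist_per_step = 0)
  expect_equal(n_peptides(fil), 6)
  fs <- detect_filaments(fil)
  expect_length(fs$filaments, 1)
  r <- interchain_rise(fs$filaments[[1]], fil)
  expect_equal(r$mean, 4.8, tolerance = 1e-9)
  expect_equal(r$sd, 0, tolerance = 1e-9)
  # two copies: exactly one adjacent pair
  dim2 <- build_filament(pep, n_copies = 2, rise = 4.8)
  fs2 <- detect_filaments(dim2)
  expect_length(fs2$filaments, 1)
  expect_equal(interchain_rise(fs2$filaments[[1]], dim2)$n_pairs, 1)
  expect_error(build_filament(pep, n_copies = 1), class = "tf_invalid_input")
})

test_that("default rises within the cross-beta window are reproduced exactly", {
  pep <- build_tripeptide("FFF", code_phi_psi("BBB"))
  for (rise in c(4.6, 4.9)) {
    fil <- build_filament(pep, n_copies = 3, rise = rise, orient = "none")
    fs <- list(filaments = list(0:2))
    expect_equal(interchain_rise(fs$filaments[[1]], fil)$mean, rise,
                 tolerance = 1e-9)
  }
})

test_that("bundles merge with renumbered ids; a single filament is the identity", {
  pep <- build_tripeptide("FFF", code_phi_psi("BBB"))
  fil <- build_filament(pep, n_copies = 6, rise = 4.8)
  one <- build_bundle(list(fil))
  expect_identical(coords(one), coords(fil))
  b <- build_bundle(list(fil, fil, fil))
  expect_equal(n_peptides(b), 18)
  expect_identical(peptide_ids(b), 0:17)
  g <- aggregate_components(b)
  expect_length(g$components, 1)
})

test_that("a four-filament arrangement emulating the extra packed filament builds cleanly", {
  pep <- build_tripeptide("FFF", code_phi_psi("BBB"))
  fil <- build_filament(pep, n_copies = 4, rise = 4.8)
  ang <- 2 * pi * (0:2) / 3
  offsets <- rbind(cbind(0.7 * cos(ang), 0.7 * sin(ang)), c(2.0, 0))
  expect_no_warning(b4 <- build_bundle(list(fil, fil, fil, fil),
                                       offsets = offsets))
  expect_equal(n_peptides(b4), 16)
})

test_that("solvent shell respects density, exclusion and reproducibility", {
  pep <- build_tripeptide("FFF", code_phi_psi("BBB"))
  box <- c(5, 5, 5)
  expect_identical(add_solvent_shell(pep, box, density = 0)$atoms, pep$atoms)
  s1 <- add_solvent_shell(pep, box, density = 3, exclusion_radius = 0.5, seed = 9)
  s2 <- add_solvent_shell(pep, box, density = 3, exclusion_radius = 0.5, seed = 9)
  expect_identical(s1$atoms, s2$atoms)
  w <- which(s1$atoms$residue_name == "W")
  solute <- which(s1$atoms$residue_name != "W")
  expect_gt(length(w), 0)
  dmin <- min(tripfib:::.pair_dists(coords(s1, w), coords(s1, solute), box))
  expect_gte(dmin, 0.5)
})

test_that("solvent bead count is Poisson-consistent with density x free volume", {
  pep <- build_tripeptide("FFF", code_phi_psi("BBB"))
  box <- c(5, 5, 5); density <- 3; rex <- 0.5
  # Monte-Carlo estimate of the free-volume fraction
  set.seed(31)
  probe <- cbind(runif(4000, 0, 5), runif(4000, 0, 5), runif(4000, 0, 5))
  dd <- tripfib:::.pair_dists(probe, coords(pep), box)
  frac_free <- mean(apply(dd, 1, min) >= rex)
  lambda <- density * prod(box) * frac_free
  counts <- vapply(1:5, function(s)
    sum(add_solvent_shell(pep, box, density, rex, seed = s)$atoms$residue_name == "W"),
    numeric(1))
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 5) + 3)
})

test_that("mixture ensembles validate weights and are seed-reproducible", {
  expect_error(make_mixture_trajectory("FFF", c(BBB = 0.7, RRB = 0.2),
                                       n_frames = 2, n_runs = 1),
               class = "tf_invalid_input")
  expect_error(make_mixture_trajectory("FFF", c(0.5, 0.5), n_frames = 2, n_runs = 1),
               class = "tf_invalid_input")
  e1 <- make_mixture_trajectory("FFF", c(BBB = 0.5, RRB = 0.5), n_peptides = 5,
                                n_frames = 3, n_runs = 2, seed = 77)
  e2 <- make_mixture_trajectory("FFF", c(BBB = 0.5, RRB = 0.5), n_peptides = 5,
                                n_frames = 3, n_runs = 2, seed = 77)
  expect_identical(coords(e1$runs[[2]]$frames[[3]]), coords(e2$runs[[2]]$frames[[3]]))
  expect_identical(attr(e1, "draws"), attr(e2, "draws"))
})

test_that("a single-component mixture classifies to that code in every observation", {
  ens <- make_mixture_trajectory("FFF", c(BBB = 1.0), n_peptides = 4,
                                 n_frames = 5, n_runs = 2, seed = 3)
  pt <- population_table(ens)
  expect_identical(most_populated(pt)$code, "BBB")
  expect_equal(most_populated(pt)$fraction, 1.0)
  expect_equal(pt$sd_fraction[pt$code == "BBB"], 0)
})
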