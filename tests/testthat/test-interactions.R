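test_that("contact counting straddles the printed cutoff bit-exactly", {
  two <- function(d) bead_frame(rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(count_contacts(two(0.60), 1, 2), 1)
  expect_equal(count_contacts(two(0.649), 1, 2), 1)
  expect_equal(count_contacts(two(0.65), 1, 2), 0)
  expect_equal(count_contacts(two(0.70), 1, 2), 0)
  # periodic wrap: 5.9 nm apart along x in a 6 nm box is a 0.1 nm contact
  pbc <- bead_frame(rbind(c(0.05, 0, 0), c(5.95, 0, 0)), box = c(6, 6, 6))
  expect_equal(count_contacts(pbc, 1, 2), 1)
  expect_equal(count_contacts(pbc, integer(0), 2), 0)
})

test_that("contact counts match the brute-force oracle on random bead frames", {
  set.seed(41)
  for (k in 1:5) {
    xyz <- matrix(runif(300, 0, 3), ncol = 3)
    fr <- bead_frame(xyz, box = if (k %% 2) c(3, 3, 3) else NULL)
    selA <- sample(100, 40); selB <- sample(100, 40)
    crit <- interaction_criteria()
    expect_equal(count_contacts(fr, selA, selB, crit),
                 oracle_contacts(fr, selA, selB))
    # symmetry in the selections
    expect_equal(count_contacts(fr, selB, selA, crit),
                 count_contacts(fr, selA, selB, crit))
    # self-selection: each unordered pair once
    expect_equal(count_contacts(fr, selA, selA, crit),
                 oracle_contacts(fr, selA, selA))
  }
})

test_that("contact counting is invariant under lattice wrapping", {
  set.seed(42)
  xyz <- matrix(runif(150, 0, 3), ncol = 3)
  fr <- bead_frame(xyz, box = c(3, 3, 3))
  n0 <- count_contacts(fr, 1:50, 1:50)
  wrapped <- fr
  shift <- matrix(rep(c(3, 0, -3), length.out = 150), ncol = 3, byrow = TRUE)
  wrapped <- set_coords(wrapped, xyz + shift)
  expect_equal(count_contacts(wrapped, 1:50, 1:50), n0)
})

test_that("hydrogen-bond criteria straddle the printed thresholds", {
  hb_frame <- function(d_no, angle) {
    # donor N at origin with H along +x; acceptor O placed so that the
    # N-H-O angle at H is `angle` and |N-O| = d_no
    n <- c(0, 0, 0); h <- c(0.1, 0, 0)
    th <- (180 - angle) * pi / 180
    # position O on the cone around H; solve along the (cos, sin) direction
    dir <- c(cos(th), sin(th), 0)
    # choose |H-O| so that |N-O| = d_no
    r <- function(L) sqrt(sum((h + L * dir - n)^2)) - d_no
    L <- uniroot(r, c(0.01, 2))$root
    o <- h + L * dir
    structure_frame(data.frame(
      name = c("N", "H", "O"), residue_index = c(1L, 1L, 1L),
      residue_name = c("PHE", "PHE", "PHE"), peptide_id = c(0L, 0L, 1L),
      x = c(n[1], h[1], o[1]), y = c(n[2], h[2], o[2]), z = c(n[3], h[3], o[3])),
      validate = FALSE)
  }
  crit <- interaction_criteria()
  expect_equal(nrow(detect_hbonds(hb_frame(0.30, 175), crit)), 1)
  expect_equal(nrow(detect_hbonds(hb_frame(0.349, 121), crit)), 1)
  expect_equal(nrow(detect_hbonds(hb_frame(0.36, 175), crit)), 0)
  expect_equal(nrow(detect_hbonds(hb_frame(0.351, 175), crit)), 0)
  expect_equal(nrow(detect_hbonds(hb_frame(0.30, 100), crit)), 0)
  expect_equal(nrow(detect_hbonds(hb_frame(0.30, 119), crit)), 0)
})

test_that("hydrogen bonds in stacked filaments match the brute-force oracle", {
  pep <- build_tripeptide("FFF", code_phi_psi("BBB"))
  dimer <- build_filament(pep, n_copies = 2, rise = 4.8)
  hb <- detect_hbonds(dimer)
  expect_gte(nrow(hb), 1)
  expect_equal(nrow(hb), oracle_hbonds(dimer))
  # per-peptide involvement: each chain of the dimer sees every bond once
  expect_equal(sum(hb$donor_peptide == 0) + sum(hb$acceptor_peptide == 0) +
                 sum(hb$donor_peptide == 1) + sum(hb$acceptor_peptide == 1),
               2 * nrow(hb))
})

test_that("solvent exposure counts W beads per residue and resolves burial", {
  pep <- build_tripeptide("FFF", code_phi_psi("BBB"))
  expect_equal(sum(solvent_exposure(pep)$water_count), 0)
  one <- pep
  cb <- coords(pep, tripfib:::.atom_row(pep, 0L, 2L, "CB"))
  one$atoms <- rbind(one$atoms, data.frame(
    name = "W", residue_index = 0L, residue_name = "W", peptide_id = -1L,
    x = cb[1] + 0.5, y = cb[2], z = cb[3]))
  se <- solvent_exposure(one)
  expect_equal(se$water_count[se$residue == 2], 1)
  # a solvated bundle: core residues see strictly less water than surface
  fil <- build_filament(pep, n_copies = 4, rise = 4.8)
  bun <- build_bundle(list(fil, fil, fil))
  bun <- transform_frame(bun, diag(3), c(3, 3, 3) - colMeans(coords(bun)))
  sol <- add_solvent_shell(bun, c(6, 6, 6), density = 4, exclusion_radius = 0.35,
                           seed = 6)
  ex <- solvent_exposure(sol)
  axis_d <- vapply(seq_len(nrow(ex)), function(i) {
    rows <- which(sol$atoms$peptide_id == ex$peptide[i] &
                    sol$atoms$residue_index == ex$residue[i] &
                    !(sol$atoms$name %in% tripfib:::.BACKBONE_NAMES))
    m <- colMeans(coords(sol, rows))
    sqrt(sum((m[1:2] - c(3, 3))^2))
  }, numeric(1))
  core <- ex$water_count[axis_d <= stats::quantile(axis_d, 0.25)]
  surf <- ex$water_count[axis_d >= stats::quantile(axis_d, 0.75)]
  expect_lt(mean(core), mean(surf))
})

test_that("the core filter keeps axial peptides and drops detached outliers", {
  pep <- build_tripeptide("FFF", code_phi_psi("BBB"))
  fil <- build_filament(pep, n_copies = 6, rise = 4.8)
  expect_identical(core_filter(fil), 0:5)
  far <- build_tripeptide("FFF", code_phi_psi("BBB"), peptide_id = 6L)
  far <- transform_frame(far, diag(3), c(3, 0, 1) - colMeans(coords(far)))
  joint <- structure_frame(rbind(fil$atoms, far$atoms), validate = TRUE)
  kept <- core_filter(joint)
  expect_true(all(0:5 %in% kept))
  expect_false(6 %in% kept)
  # rigid-motion invariance
  moved <- transform_frame(joint, random_rotation(5), c(1, -2, 0.4))
  expect_identical(core_filter(moved), kept)
  # straddle the 1 nm radius with point peptides on a line plus one offset
  expect_error(core_filter(bead_frame(matrix(numeric(0), ncol = 3))),
               class = "tf_invalid_input")
})

test_that("the core radius itself is applied bit-exactly", {
  # five collinear single-bead "peptides" define the axis; probes sit at
  # 0.99 and 1.01 nm off-axis
  xyz <- rbind(cbind(0, 0, seq(0, 2, 0.5)), c(0.99, 0, 1), c(1.01, 0, 1))
  fr <- bead_frame(xyz, names = "CB", peptide_id = 0:6,
                   residue_index = rep(1L, 7))
  crit <- interaction_criteria(contact_cutoff = 0.55)
  kept <- core_filter(fr, crit)
  expect_true(5 %in% kept)
  expect_false(6 %in% kept)
})

test_that("interaction profiles are computed per peptide and respond to solvent", {
  pep <- build_tripeptide("FIF", code_phi_psi("BBB"))
  dimer <- build_filament(pep, n_copies = 2, rise = 4.8)
  prof <- interaction_profile(dimer)
  expect_setequal(prof$metric, c("phe_sc_water", "ile_sc_water", "phe_phe",
                                 "ile_ile", "phe_ile", "hb"))
  expect_gte(prof$mean[prof$metric == "hb"], 1)
  expect_equal(prof$mean[prof$metric == "hb"], oracle_hbonds(dimer))
  expect_true(all(prof$mean >= 0))
  # adding solvent raises the water metrics monotonically
  dimer_c <- transform_frame(dimer, diag(3), c(2.5, 2.5, 2.5) - colMeans(coords(dimer)))
  s1 <- add_solvent_shell(dimer_c, c(5, 5, 5), density = 2, seed = 1)
  s2 <- add_solvent_shell(dimer_c, c(5, 5, 5), density = 6, seed = 1)
  p1 <- interaction_profile(s1); p2 <- interaction_profile(s2)
  expect_gte(p2$mean[p2$metric == "phe_sc_water"],
             p1$mean[p1$metric == "phe_sc_water"])
  expect_gt(p2$mean[p2$metric == "phe_sc_water"], 0)
})

test_that("a frame with no surviving peptides is a named failure", {
  w <- bead_frame(matrix(runif(30, 0, 3), ncol = 3), names = "W",
                  residue_name = "W")
  w$atoms$peptide_id <- -1L
  expect_error(interaction_profile(w), class = "tf_invalid_input")
})
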