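# Hand-made two-residue CA/CB scaffolds with known torsion geometry.
theta_fixture <- function(angle_deg) {
  ca1 <- c(0, 0, 0); ca2 <- c(0.4, 0, 0)
  cb1 <- c(0, 0.15, 0)
  rot <- tripfib:::.rotation_about(c(1, 0, 0), angle_deg)
  cb2 <- ca2 + as.numeric(rot %*% c(0, 0.15, 0))
  structure_frame(data.frame(
    name = c("CA", "CB", "CA", "CB"),
    residue_index = c(1L, 1L, 2L, 2L),
    residue_name = "PHE", peptide_id = 0L,
    x = c(ca1[1], cb1[1], ca2[1], cb2[1]),
    y = c(ca1[2], cb1[2], ca2[2], cb2[2]),
    z = c(ca1[3], cb1[3], ca2[3], cb2[3])), validate = FALSE)
}

test_that("rotation angle reads off constructed syn / anti scaffolds", {
  expect_equal(rotation_angle(theta_fixture(0), 0, 1), 0, tolerance = 1e-9)
  expect_equal(abs(rotation_angle(theta_fixture(180), 0, 1)), 180, tolerance = 1e-9)
  for (a in c(-150, -60, 30, 115)) {
    expect_equal(rotation_angle(theta_fixture(a), 0, 1), a, tolerance = 1e-9)
    expect_equal(rotation_angle(theta_fixture(a), 0, 1, method = "projected"), a,
                 tolerance = 1e-9)
  }
})

test_that("rotation angle is rigid-motion invariant and mirror-antisymmetric", {
  fr <- build_tripeptide("FIF", rbind(c(-95, -45), c(-135, 135), c(-75, 150)))
  th <- theta_pair(fr, 0)
  moved <- transform_frame(fr, random_rotation(17), c(-1, 2, 0.3))
  expect_equal(theta_pair(moved, 0), th, tolerance = 1e-9)
  mir <- fr
  mir$atoms$x <- -mir$atoms$x
  expect_equal(unname(theta_pair(mir, 0)), unname(-th), tolerance = 1e-9)
})

test_that("missing CB fails with the residue named", {
  fr <- build_tripeptide("FFF", code_phi_psi("BBB"))
  fr$atoms <- fr$atoms[!(fr$atoms$name == "CB" & fr$atoms$residue_index == 2), ]
  err <- expect_error(rotation_angle(fr, 0, 1), class = "tf_topology_error")
  expect_match(conditionMessage(err), "residue 2")
})

test_that("topology grouping implements the syn/anti thresholds and the excluded band", {
  expect_identical(topology_group(170, -168), "all_anti")
  expect_identical(topology_group(30, -150), "n_syn")
  expect_identical(topology_group(-150, 30), "c_syn")
  expect_identical(topology_group(10, -45), "all_syn")
  expect_identical(topology_group(90, 150), "other")
  # the quoted thresholds are strict inequalities: exact 60 / 115 fall in
  # the excluded band
  expect_identical(topology_group(60, 150), "other")
  expect_identical(topology_group(150, 115), "other")
  expect_identical(topology_group(116, 116), "all_anti")
  expect_identical(topology_group(59, 59), "all_syn")
})

test_that("the reference theta chart puts BBB in all-anti and RRB in all-syn", {
  chart <- reference_theta_map()
  expect_identical(chart$group[chart$code == "BBB"], "all_anti")
  expect_identical(chart$group[chart$code == "RRB"], "all_syn")
  expect_identical(chart, reference_theta_map())
  expect_setequal(unique(chart$group),
                  c("all_anti", "all_syn", "n_syn", "c_syn", "other"))
})

test_that("anchor group assignments are stable under basin-center perturbation", {
  rm0 <- default_region_map()
  set.seed(23)
  for (k in 1:10) {
    rmp <- rm0
    rmp$centers <- rm0$centers + matrix(runif(8, -10, 10), ncol = 2)
    frB <- build_tripeptide("FFF", code_phi_psi("BBB", rmp))
    frR <- build_tripeptide("FFF", code_phi_psi("RRB", rmp))
    expect_identical(topology_group(theta_pair(frB, 0)), "all_anti")
    expect_identical(topology_group(theta_pair(frR, 0)), "all_syn")
  }
})

test_that("group populations sum to one and recover a 53/47 split", {
  ens <- make_mixture_trajectory("FII", c(RRB = 0.53, BBB = 0.47),
                                 n_peptides = 20, n_frames = 25, n_runs = 3,
                                 seed = 12)
  gp <- group_populations(ens)
  per_run <- attr(gp, "per_run")
  expect_equal(unname(colSums(per_run)), rep(1, 3), tolerance = 1e-9)
  n <- gp$n_obs[1] / 3
  se <- sqrt(0.53 * 0.47 / (3 * n))
  expect_lt(abs(gp$mean_fraction[gp$group == "all_syn"] - 0.53), 3 * se + 0.01)
  expect_lt(abs(gp$mean_fraction[gp$group == "all_anti"] - 0.47), 3 * se + 0.01)
})

test_that("group fractions are invariant to frame order", {
  ens <- make_mixture_trajectory("FFF", c(BBB = 0.5, RRB = 0.5), n_peptides = 6,
                                 n_frames = 6, n_runs = 1, seed = 5)
  gp1 <- group_populations(ens)
  shuffled <- ens
  shuffled$runs[[1]]$frames <- rev(shuffled$runs[[1]]$frames)
  gp2 <- group_populations(shuffled)
  expect_equal(gp1$mean_fraction, gp2$mean_fraction)
})
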