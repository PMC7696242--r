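test_that("GRO write/read round-trips topology exactly and coordinates to format precision", {
  fr <- build_tripeptide("FIF", rbind(c(-135, 135), c(-95, -45), c(-75, 150)))
  fr$box <- c(6, 6, 6)
  path <- tempfile(fileext = ".gro")
  write_gro(fr, path)
  back <- read_gro(path)
  expect_identical(back$atoms$name, fr$atoms$name)
  expect_identical(back$atoms$residue_name, fr$atoms$residue_name)
  expect_identical(back$atoms$peptide_id, fr$atoms$peptide_id)
  expect_identical(back$atoms$residue_index, fr$atoms$residue_index)
  expect_lt(max(abs(coords(back) - coords(fr))), 0.001)
  expect_equal(back$box, c(6, 6, 6))
})

test_that("PDB write/read round-trips, including multi-model files", {
  fr1 <- build_tripeptide("FFF", rbind(c(-135, 135), c(-135, 135), c(-135, 135)))
  fr2 <- transform_frame(fr1, random_rotation(3), c(1, 0, 0))
  path <- tempfile(fileext = ".pdb")
  write_pdb(trajectory(list(fr1, fr2)), path)
  tr <- read_pdb(path)
  expect_s3_class(tr, "trajectory")
  expect_length(tr$frames, 2)
  expect_lt(max(abs(coords(tr$frames[[1]]) - coords(fr1))), 0.001)
  expect_lt(max(abs(coords(tr$frames[[2]]) - coords(fr2))), 0.001)
  # single-model read gives a frame
  write_pdb(fr1, path)
  expect_s3_class(read_pdb(path), "structure_frame")
})

test_that("topology validation names the offending peptide and residue", {
  fr <- build_tripeptide("FFF", rbind(c(-135, 135), c(-135, 135), c(-135, 135)))
  broken <- fr
  broken$atoms <- broken$atoms[!(broken$atoms$residue_index == 2 &
                                   broken$atoms$name == "CB"), ]
  err <- expect_error(structure_frame(broken$atoms), class = "tf_topology_error")
  expect_match(conditionMessage(err), "residue 2")
  expect_match(conditionMessage(err), "CB")
  ids_bad <- fr$atoms
  ids_bad$peptide_id <- 5L
  expect_error(structure_frame(ids_bad), class = "tf_topology_error")
})

test_that("backbone dihedrals reproduce builder targets and are rigid-motion invariant", {
  targets <- rbind(c(-120, 130), c(-120, 130), c(-120, 130))
  fr <- build_tripeptide("FFF", targets)
  d <- backbone_dihedrals(fr, 0)
  expect_lt(max(abs(unname(d) - c(t(targets)))), 1e-4)
  rot <- transform_frame(fr, random_rotation(7), c(0.3, -1, 2))
  expect_equal(backbone_dihedrals(rot, 0), d, tolerance = 1e-9)
})

test_that("missing caps make the corresponding dihedral fail by name", {
  fr <- build_tripeptide("FFF", rbind(c(-135, 135), c(-135, 135), c(-135, 135)))
  no_c <- fr
  no_c$atoms <- no_c$atoms[no_c$atoms$residue_index != 4, ]
  err <- expect_error(backbone_dihedrals(no_c, 0), class = "tf_topology_error")
  expect_match(conditionMessage(err), "psi3")
  no_n <- fr
  no_n$atoms <- no_n$atoms[no_n$atoms$residue_index != 0, ]
  err <- expect_error(backbone_dihedrals(no_n, 0), class = "tf_topology_error")
  expect_match(conditionMessage(err), "phi1")
})

test_that("amide hydrogen reconstruction recovers the planar position", {
  fr <- build_tripeptide("FFF", rbind(c(-135, 135), c(-135, 135), c(-135, 135)))
  href <- coords(fr, which(fr$atoms$name == "H"))
  stripped <- fr
  stripped$atoms <- stripped$atoms[stripped$atoms$name != "H", ]
  rebuilt <- reconstruct_amide_h(stripped)
  hnew <- coords(rebuilt, which(rebuilt$atoms$name == "H"))
  expect_equal(nrow(hnew), nrow(href))
  # same N-H length and close to the builder's trans-amide position
  for (k in seq_len(nrow(hnew))) {
    d <- sqrt(rowSums(sweep(href, 2, hnew[k, ])^2))
    expect_lt(min(d), 0.035)
  }
})

test_that("trajectories enforce one topology and reject emptiness", {
  fr <- build_tripeptide("FFF", rbind(c(-135, 135), c(-135, 135), c(-135, 135)))
  expect_error(trajectory(list()), class = "tf_invalid_input")
  short <- fr
  short$atoms <- short$atoms[-1, ]
  expect_error(trajectory(list(fr, short)), class = "tf_topology_error")
  path <- tempfile(fileext = ".gro")
  writeLines(character(0), path)
  expect_error(read_gro_trajectory(path), class = "tf_io_error")
})

test_that("multi-frame GRO trajectories round-trip frame count and coordinates", {
  frames <- lapply(1:3, function(k)
    transform_frame(build_tripeptide("IIF", rbind(c(-135, 135), c(-95, -45), c(-135, 135))),
                    diag(3), c(k * 0.1, 0, 0)))
  frames <- lapply(frames, function(f) { f$box <- c(6, 6, 6); f })
  path <- tempfile(fileext = ".gro")
  con <- file(path, "w"); close(con)
  for (f in frames) {
    tmp <- tempfile(fileext = ".gro")
    write_gro(f, tmp)
    cat(readLines(tmp), file = path, sep = "\n", append = TRUE)
  }
  tr <- read_trajectory(path)
  expect_length(tr$frames, 3)
  for (k in 1:3)
    expect_lt(max(abs(coords(tr$frames[[k]]) - coords(frames[[k]]))), 0.001)
})
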