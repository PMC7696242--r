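# Synthetic-structure generator: internal-coordinate construction of capped
# tripeptides at target (phi, psi), stacking into in-register parallel
# filaments, lateral bundling, coarse solvent shells and mixture
# pseudo-trajectories. This module is the stand-in for simulation data: it
# produces geometry with the stated conformational and architectural
# features, not physically relaxed structures.

# Standard backbone internal coordinates (nm / degrees).
.BOND <- list(N_CA = 0.146, CA_C = 0.152, C_N = 0.133, C_O = 0.123,
              N_H = 0.100, CA_CB = 0.153, CH3_C = 0.152)
.ANG <- list(CA_C_N = 116.2, C_N_CA = 121.7, N_CA_C = 111.0,
             CA_C_O = 120.5, C_N_H = 119.0, N_CA_CB = 110.5, C_CA_CB = 110.1)
# L-amino-acid branch: CB sits at phi - 122.6 deg about the N-CA axis
.CB_PHI_OFFSET <- -122.6

.RES3 <- c(F = "PHE", I = "ILE")

# NeRF atom placement: D bonded to C, with |CD| = bond, angle B-C-D and
# torsion A-B-C-D (matching dihedral_angle's sign convention).
.place_atom <- function(a, b, c_, bond, angle_deg, torsion_deg) {
  th <- (180 - angle_deg) / .DEG
  ph <- torsion_deg / .DEG
  d2 <- c(bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  bc <- c_ - b; bc <- bc / .norm(bc)
  n <- .cross(b - a, bc)
  if (.norm(n) < .DEGENERATE_NORM)
    tf_stop("tf_invalid_geometry", "collinear frame atoms in NeRF placement")
  n <- n / .norm(n)
  m <- cbind(bc, .cross(n, bc), n)
  as.numeric(c_ + m %*% d2)
}

#' Build a capped tripeptide at target backbone dihedrals
#'
#' Constructs an acetyl/amide-capped tripeptide by sequential
#' internal-coordinate (NeRF) placement with standard bond lengths and
#' angles, the peptide bond fixed at omega = 180 degrees, and CB placed at
#' tetrahedral geometry on the L-amino-acid branch. At zero noise the six
#' measured backbone dihedrals equal the targets to numerical precision.
#'
#' @param sequence Three-letter string over {F, I}, e.g. "FFF".
#' @param phi_psi 3 x 2 matrix (or list of 3 pairs) of target (phi, psi)
#'   in degrees, each in (-180, 180].
#' @param noise_sigma Isotropic Gaussian coordinate noise, nm (applied
#'   last; default 0).
#' @param seed Integer seed making the noise reproducible.
#' @param peptide_id Peptide id to stamp on the atoms.
#' @return A `structure_frame` holding one peptide.
#' @export
build_tripeptide <- function(sequence, phi_psi, noise_sigma = 0, seed = NULL,
                             peptide_id = 0L) {
  letters3 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters3) != 3L || !all(letters3 %in% names(.RES3)))
    tf_stop("tf_invalid_input",
            "sequence must be 3 letters over {F, I}, got '%s'", sequence)
  if (is.list(phi_psi)) phi_psi <- do.call(rbind, phi_psi)
  phi_psi <- matrix(as.numeric(phi_psi), ncol = 2)
  if (nrow(phi_psi) != 3L || any(phi_psi <= -180) || any(phi_psi > 180))
    tf_stop("tf_invalid_input", "phi_psi must be 3 pairs in (-180, 180]")

  atoms <- list()
  put <- function(name, ri, rn, xyz)
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, residue_index = ri, residue_name = rn,
      peptide_id = 0L, x = xyz[1], y = xyz[2], z = xyz[3])

  # acetyl cap in the xy plane
  ch3 <- c(0, 0, 0)
  c0 <- c(.BOND$CH3_C, 0, 0)
  a <- (180 - .ANG$CA_C_N) / .DEG
  n1 <- c0 + .BOND$C_N * c(cos(a), sin(a), 0)
  o0 <- .place_atom(n1, ch3, c0, .BOND$C_O, 121.0, 180)
  put("CH3", 0L, "ACE", ch3); put("C", 0L, "ACE", c0); put("O", 0L, "ACE", o0)

  prev <- list(ca = ch3, c = c0, o = o0)
  n <- n1
  for (ri in 1:3) {
    rn <- .RES3[[letters3[ri]]]
    phi <- phi_psi[ri, 1]; psi <- phi_psi[ri, 2]
    h <- .place_atom(prev$o, prev$c, n, .BOND$N_H, .ANG$C_N_H, 180)
    ca <- .place_atom(prev$ca, prev$c, n, .BOND$N_CA, .ANG$C_N_CA, 180)
    cc <- .place_atom(prev$c, n, ca, .BOND$CA_C, .ANG$N_CA_C, phi)
    cb <- .place_atom(prev$c, n, ca, .BOND$CA_CB, .ANG$N_CA_CB,
                      phi + .CB_PHI_OFFSET)
    o <- .place_atom(n, ca, cc, .BOND$C_O, .ANG$CA_C_O, psi + 180)
    next_n <- .place_atom(n, ca, cc, .BOND$C_N, .ANG$CA_C_N, psi)
    put("N", ri, rn, n); put("H", ri, rn, h); put("CA", ri, rn, ca)
    put("CB", ri, rn, cb); put("C", ri, rn, cc); put("O", ri, rn, o)
    prev <- list(ca = ca, c = cc, o = o)
    n <- next_n
  }
  h4 <- .place_atom(prev$o, prev$c, n, .BOND$N_H, .ANG$C_N_H, 180)
  put("N", 4L, "NH2", n); put("H", 4L, "NH2", h4)

  at <- do.call(rbind, atoms)
  if (noise_sigma > 0) {
    if (!is.null(seed)) {
      old <- .save_rng(); on.exit(.restore_rng(old))
      set.seed(seed)
    }
    at$x <- at$x + stats::rnorm(nrow(at), 0, noise_sigma)
    at$y <- at$y + stats::rnorm(nrow(at), 0, noise_sigma)
    at$z <- at$z + stats::rnorm(nrow(at), 0, noise_sigma)
  }
  fr <- structure_frame(at, validate = TRUE)
  fr$atoms$peptide_id <- as.integer(peptide_id)
  fr
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Hydrogen-bond score of a monomer orientation for filament stacking: how
# many donor/acceptor pairs satisfy the geometric HB criterion between a
# peptide and its image translated by `rise` along z, minus a steric
# penalty. Used to pick a stacking-compatible orientation.
.stack_hb_score <- function(xyz, don_n, don_h, acc_o, heavy, rise_nm,
                            criteria = interaction_criteria()) {
  up <- xyz; up[, 3] <- up[, 3] + rise_nm
  score <- 0; soft <- 0
  for (k in seq_along(don_n)) {
    for (j in seq_along(acc_o)) {
      # donor in image above, acceptor below (and the reverse by symmetry)
      dno <- .norm(up[don_n[k], ] - xyz[acc_o[j], ])
      ang <- tryCatch(planar_angle(up[don_n[k], ], up[don_h[k], ], xyz[acc_o[j], ]),
                      error = function(e) 0)
      if (dno < criteria$hb_da_cutoff && ang > criteria$hb_angle_min)
        score <- score + 1
      soft <- soft + exp(-((dno - 0.29) / 0.05)^2) * exp(-((ang - 160) / 40)^2)
    }
  }
  dd <- .pair_dists(xyz[heavy, , drop = FALSE], up[heavy, , drop = FALSE])
  clash <- sum(dd < 0.17)
  c(hb = score, soft = soft - 5 * clash, clash = clash)
}

# Deterministic low-discrepancy grid over rotations (axis from a Fibonacci
# sphere, angle uniform) used to initialise the orientation search.
.rotation_grid <- function(n_axis = 60, n_angle = 12) {
  i <- seq_len(n_axis) - 0.5
  phi <- acos(1 - 2 * i / n_axis)
  theta <- pi * (1 + sqrt(5)) * i
  axes <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  angles <- seq(0, 360, length.out = n_angle + 1)[-(n_angle + 1)]
  out <- vector("list", n_axis * n_angle)
  k <- 1L
  for (ia in seq_len(n_axis)) for (ag in angles) {
    out[[k]] <- .rotation_about(axes[ia, ], ag); k <- k + 1L
  }
  out
}

#' Stack a tripeptide into an in-register parallel filament
#'
#' Places `n_copies` of the peptide along the z axis, translated by `rise`
#' per step and rotated by `twist_per_step` about the filament axis. With
#' `orient = "hbond"` the monomer is first rotated (rigidly, conformation
#' untouched) into the orientation that maximises the number of geometric
#' backbone hydrogen bonds between adjacent copies, emulating the
#' hydrogen-bonded stacking of beta-strand filaments.
#'
#' @param peptide A single-peptide `structure_frame`.
#' @param n_copies Number of chains (>= 2).
#' @param rise Stacking rise between adjacent chains, in Angstrom
#'   (default 4.8, the typical cross-beta spacing).
#' @param twist_per_step Twist about the axis per step, degrees.
#' @param orient "hbond" (search for a hydrogen-bonding orientation) or
#'   "none" (stack as given).
#' @return A `structure_frame` with peptide ids 0..n_copies-1.
#' @export
build_filament <- function(peptide, n_copies = 6L, rise = 4.8,
                           twist_per_step = 0, orient = c("hbond", "none")) {
  orient <- match.arg(orient)
  if (n_peptides(peptide) != 1L)
    tf_stop("tf_invalid_input", "build_filament expects a single tripeptide")
  if (n_copies < 2L) tf_stop("tf_invalid_input", "n_copies must be >= 2")
  if (rise <= 0) tf_stop("tf_invalid_input", "rise must be positive (Angstrom)")
  rise_nm <- rise / 10
  at <- peptide$atoms
  xyz <- coords(peptide)
  xyz <- sweep(xyz, 2, colMeans(xyz))  # centre the monomer

  if (orient == "hbond") {
    hres <- paste(at$peptide_id, at$residue_index)[at$name == "H"]
    don <- which(at$name == "N" &
                   paste(at$peptide_id, at$residue_index) %in% hres)
    don_h <- vapply(don, function(i) {
      which(at$name == "H" & at$residue_index == at$residue_index[i] &
              at$peptide_id == at$peptide_id[i])[1]
    }, integer(1))
    acc <- which(at$name == "O")
    heavy <- which(at$name != "H")
    best <- NULL; best_key <- c(-Inf, -Inf)
    for (r in .rotation_grid()) {
      sc <- .stack_hb_score(xyz %*% t(r), don, don_h, acc, heavy, rise_nm)
      key <- c(sc[["hb"]] - 5 * sc[["clash"]], sc[["soft"]])
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2])) {
        best_key <- key; best <- r
      }
    }
    # local refinement of the soft score around the best grid rotation
    obj <- function(par) {
      r <- .rotation_about(c(1, 0, 0), par[1]) %*%
        .rotation_about(c(0, 1, 0), par[2]) %*%
        .rotation_about(c(0, 0, 1), par[3]) %*% best
      sc <- .stack_hb_score(xyz %*% t(r), don, don_h, acc, heavy, rise_nm)
      -(10 * (sc[["hb"]] - 5 * sc[["clash"]]) + sc[["soft"]])
    }
    op <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                       control = list(maxit = 200))
    best <- .rotation_about(c(1, 0, 0), op$par[1]) %*%
      .rotation_about(c(0, 1, 0), op$par[2]) %*%
      .rotation_about(c(0, 0, 1), op$par[3]) %*% best
    xyz <- xyz %*% t(best)
  }

  pieces <- vector("list", n_copies)
  for (k in seq_len(n_copies)) {
    r <- .rotation_about(c(0, 0, 1), twist_per_step * (k - 1))
    xk <- xyz %*% t(r)
    xk[, 3] <- xk[, 3] + rise_nm * (k - 1)
    ak <- at
    ak$peptide_id <- k - 1L
    ak$x <- xk[, 1]; ak$y <- xk[, 2]; ak$z <- xk[, 3]
    pieces[[k]] <- ak
  }
  out <- structure_frame(do.call(rbind, pieces), box = peptide$box,
                         validate = TRUE)
  .warn_if_clash(out)
  out
}

.warn_if_clash <- function(frame, cutoff = 0.05) {
  at <- frame$atoms
  pep <- which(at$peptide_id >= 0)
  if (length(pep) < 2) return(invisible(frame))
  xyz <- coords(frame, pep)
  dd <- .pair_dists(xyz, xyz, frame$box)
  same <- outer(at$peptide_id[pep], at$peptide_id[pep], "==")
  dd[same] <- Inf
  if (any(dd < cutoff))
    warning(sprintf("steric collapse: %d interchain atom pair(s) closer than %.2f nm",
                    sum(dd < cutoff) / 2, cutoff), call. = FALSE)
  invisible(frame)
}

#' Bundle filaments laterally into a fiber
#'
#' Rigidly places each filament at an xy offset (and optional rotation
#' about its own axis) and merges them with renumbered peptide ids,
#' emulating the lateral association of filaments into a nanofiber.
#'
#' @param filaments List of `structure_frame`s (each one filament).
#' @param offsets n x 2 matrix of xy displacements in nm; by default the
#'   filaments are placed on a circle of radius `radius`.
#' @param rotations Per-filament rotation about z, degrees.
#' @param radius Default circle radius in nm used when `offsets` is NULL
#'   (0.7 nm puts the three filament axes ~1.2 nm apart, matching a
#'   nanofiber diameter of roughly 2-2.5 nm).
#' @return A merged `structure_frame`.
#' @export
build_bundle <- function(filaments, offsets = NULL, rotations = NULL,
                         radius = 0.7) {
  nf <- length(filaments)
  if (nf < 1L) tf_stop("tf_invalid_input", "need at least one filament")
  if (nf == 1L) return(filaments[[1]])
  if (is.null(offsets)) {
    ang <- 2 * pi * (seq_len(nf) - 1) / nf
    offsets <- cbind(radius * cos(ang), radius * sin(ang))
  }
  offsets <- matrix(as.numeric(offsets), ncol = 2)
  if (is.null(rotations)) rotations <- rep(0, nf)
  pieces <- vector("list", nf)
  next_id <- 0L
  for (k in seq_len(nf)) {
    fr <- transform_frame(filaments[[k]],
                          .rotation_about(c(0, 0, 1), rotations[k]),
                          c(offsets[k, 1], offsets[k, 2], 0))
    ak <- fr$atoms
    ids <- sort(unique(ak$peptide_id[ak$peptide_id >= 0]))
    ak$peptide_id[ak$peptide_id >= 0] <-
      next_id + match(ak$peptide_id[ak$peptide_id >= 0], ids) - 1L
    next_id <- next_id + length(ids)
    pieces[[k]] <- ak
  }
  out <- structure_frame(do.call(rbind, pieces), box = filaments[[1]]$box,
                         validate = TRUE)
  .warn_if_clash(out)
  out
}

#' Add a coarse solvent shell of W beads
#'
#' Places single-bead coarse water uniformly at random in the box,
#' rejecting positions within `exclusion_radius` of any existing atom.
#'
#' @param frame A `structure_frame`.
#' @param box Length-3 box edges in nm (also stored on the result).
#' @param density Beads per nm^3 (the bead count is Poisson over the
#'   whole box volume; excluded positions are rejected).
#' @param exclusion_radius Minimum distance to any solute atom, nm.
#' @param seed Integer seed.
#' @return The frame with W beads appended (peptide_id -1).
#' @export
add_solvent_shell <- function(frame, box, density = 2, exclusion_radius = 0.4,
                              seed = 1L) {
  box <- .check_box(box)
  if (density < 0) tf_stop("tf_invalid_input", "density must be >= 0")
  frame$box <- box
  if (density == 0) return(frame)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n_try <- stats::rpois(1, density * prod(box))
  if (n_try == 0) return(frame)
  pos <- cbind(stats::runif(n_try, 0, box[1]),
               stats::runif(n_try, 0, box[2]),
               stats::runif(n_try, 0, box[3]))
  solute <- coords(frame)
  keep <- rep(TRUE, n_try)
  if (nrow(solute)) {
    dd <- .pair_dists(pos, solute, box)
    keep <- apply(dd, 1, min) >= exclusion_radius
  }
  pos <- pos[keep, , drop = FALSE]
  if (nrow(pos)) {
    w <- data.frame(name = "W", residue_index = 0L, residue_name = "W",
                    peptide_id = -1L, x = pos[, 1], y = pos[, 2], z = pos[, 3])
    frame$atoms <- rbind(frame$atoms, w)
    rownames(frame$atoms) <- NULL
  }
  frame
}

#' Generate a mixture pseudo-trajectory ensemble
#'
#' Emulates the population structure of a self-assembly ensemble: for every
#' run, frame and peptide, a conformation code is drawn independently from
#' `mixture`, the peptide is realised at the Ramachandran basin centers of
#' that code (plus Gaussian coordinate noise), randomly oriented, and
#' placed on a dispersed grid in the box.
#'
#' @param sequence Three letters over {F, I}.
#' @param mixture Named numeric vector of weights; names are conformation
#'   codes such as "BBB" or "RRB" (see [conformation_codes()]). Weights
#'   must be >= 0 and sum to 1 (tolerance 1e-9).
#' @param n_peptides Peptides per frame (default 30, the simulated system
#'   size).
#' @param n_frames Frames per run (default 200).
#' @param n_runs Independent runs (default 3, matching the convention of
#'   averaging over three independent simulations).
#' @param noise_sigma Coordinate noise, nm (default 0.01).
#' @param box Box edges, nm (default 6 x 6 x 6).
#' @param regions A region map (for basin centers).
#' @param seed Integer seed; the whole ensemble is reproducible from it.
#' @return A `tripfib_ensemble` with an attribute `draws` recording the
#'   codes drawn (run x frame x peptide).
#' @export
make_mixture_trajectory <- function(sequence, mixture, n_peptides = 30L,
                                    n_frames = 200L, n_runs = 3L,
                                    noise_sigma = 0.01, box = c(6, 6, 6),
                                    regions = default_region_map(), seed = 1L) {
  w <- as.numeric(mixture)
  codes <- names(mixture)
  if (is.null(codes) || any(!nzchar(codes)))
    tf_stop("tf_invalid_input", "mixture must be a named weight vector")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    tf_stop("tf_invalid_input", "mixture weights must be >= 0 and sum to 1")
  lapply(codes, parse_conformation_code)  # validates the codes

  # one template per component, realised at basin centers
  templates <- lapply(codes, function(code) {
    pp <- code_phi_psi(code, regions)
    fr <- build_tripeptide(sequence, pp)
    xyz <- coords(fr)
    sweep(xyz, 2, colMeans(xyz))
  })
  proto <- build_tripeptide(sequence, code_phi_psi(codes[1], regions))
  at0 <- proto$atoms
  na <- nrow(at0)

  # dispersed grid sites
  spacing <- 1.5
  nside <- ceiling(n_peptides^(1 / 3))
  sites <- as.matrix(expand.grid(x = seq_len(nside), y = seq_len(nside),
                                 z = seq_len(ceiling(n_peptides / nside^2))))
  sites <- sites[seq_len(n_peptides), , drop = FALSE] * spacing

  old <- .save_rng(); on.exit(.restore_rng(old))
  runs <- vector("list", n_runs)
  draws <- array(NA_character_, dim = c(n_runs, n_frames, n_peptides))
  for (r in seq_len(n_runs)) {
    set.seed(seed + 7919L * (r - 1L))
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      pick <- sample.int(length(w), n_peptides, replace = TRUE, prob = w)
      draws[r, f, ] <- codes[pick]
      blocks <- vector("list", n_peptides)
      for (p in seq_len(n_peptides)) {
        u <- stats::rnorm(4)           # random rotation via unit quaternion
        u <- u / sqrt(sum(u^2))
        rot <- .quat_to_rot(u)
        xyz <- templates[[pick[p]]] %*% t(rot)
        xyz <- sweep(xyz, 2, sites[p, ], "+")
        if (noise_sigma > 0)
          xyz <- xyz + matrix(stats::rnorm(3 * na, 0, noise_sigma), ncol = 3)
        ak <- at0
        ak$peptide_id <- p - 1L
        ak$x <- xyz[, 1]; ak$y <- xyz[, 2]; ak$z <- xyz[, 3]
        blocks[[p]] <- ak
      }
      frames[[f]] <- structure_frame(do.call(rbind, blocks), box = box,
                                     frame_index = f - 1L, validate = FALSE)
    }
    runs[[r]] <- trajectory(frames, run_id = sprintf("run%02d", r))
  }
  out <- ensemble(runs)
  attr(out, "draws") <- draws
  out
}

.quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}
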