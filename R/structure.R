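# Data model for capped tripeptide systems.
#
# A structure_frame holds an atom table (one row per particle) plus an
# optional orthorhombic box. Residue indexing inside a peptide is 1..3 for
# the amino acids, 0 for the N-terminal acetyl cap and 4 for the C-terminal
# amide cap. Coarse water beads are single particles named W with
# peptide_id -1. Coordinates are nm throughout.

.BACKBONE_NAMES <- c("N", "H", "H2", "CA", "C", "O", "CH3")

#' Construct a structure frame
#'
#' @param atoms data.frame with columns `name`, `residue_index`,
#'   `residue_name`, `peptide_id`, `x`, `y`, `z` (nm).
#' @param box NULL or length-3 orthorhombic edges (nm).
#' @param frame_index Integer frame number.
#' @param time Time in ps, or NA.
#' @param validate Check tripeptide topology (default TRUE).
#' @return An object of class `structure_frame`.
#' @export
structure_frame <- function(atoms, box = NULL, frame_index = 0L, time = NA_real_,
                            validate = TRUE) {
  need <- c("name", "residue_index", "residue_name", "peptide_id", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    tf_stop("tf_invalid_input", "atom table must have columns: %s",
            paste(need, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  atoms$name <- as.character(atoms$name)
  atoms$residue_name <- as.character(atoms$residue_name)
  atoms$residue_index <- as.integer(atoms$residue_index)
  atoms$peptide_id <- as.integer(atoms$peptide_id)
  fr <- structure(
    list(atoms = atoms, box = .check_box(box),
         frame_index = as.integer(frame_index), time = time),
    class = "structure_frame")
  if (validate) validate_topology(fr)
  fr
}

#' @export
print.structure_frame <- function(x, ...) {
  np <- n_peptides(x)
  nw <- sum(x$atoms$peptide_id < 0)
  cat(sprintf("<structure_frame> %d atoms, %d peptide(s), %d solvent bead(s)%s\n",
              nrow(x$atoms), np, nw,
              if (is.null(x$box)) "" else sprintf(", box %.2f x %.2f x %.2f nm",
                                                  x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Number of peptides in a frame
#' @param frame A `structure_frame`.
#' @export
n_peptides <- function(frame) {
  ids <- unique(frame$atoms$peptide_id)
  length(ids[ids >= 0])
}

#' Peptide ids present in a frame
#' @param frame A `structure_frame`.
#' @export
peptide_ids <- function(frame) {
  ids <- sort(unique(frame$atoms$peptide_id))
  ids[ids >= 0]
}

#' Validate capped-tripeptide topology
#'
#' Every peptide must carry exactly three amino-acid residues
#' (residue_index 1..3), each with N, CA, C, O and CB present; peptide ids
#' must be contiguous from 0. Amide hydrogens and cap methyl particles are
#' optional.
#'
#' @param frame A `structure_frame`.
#' @return Invisibly TRUE; signals a `tf_topology_error` otherwise.
#' @export
validate_topology <- function(frame) {
  at <- frame$atoms
  ids <- peptide_ids(frame)
  if (length(ids) && !identical(ids, seq(0L, length(ids) - 1L)))
    tf_stop("tf_topology_error", "peptide ids must be contiguous from 0")
  for (pid in ids) {
    pa <- at[at$peptide_id == pid, ]
    res <- sort(unique(pa$residue_index[pa$residue_index %in% 1:3]))
    if (!identical(res, 1:3))
      tf_stop("tf_topology_error",
              "peptide %d: expected residues 1..3, found {%s}",
              pid, paste(res, collapse = ","))
    for (ri in 1:3) {
      have <- pa$name[pa$residue_index == ri]
      miss <- setdiff(c("N", "CA", "C", "O", "CB"), have)
      if (length(miss))
        tf_stop("tf_topology_error",
                "peptide %d residue %d: missing atom(s) %s",
                pid, ri, paste(miss, collapse = ","))
    }
  }
  invisible(TRUE)
}

# Row index of one named atom; errors (or NA if must=FALSE) when absent.
.atom_row <- function(frame, pid, ri, name, must = TRUE) {
  at <- frame$atoms
  i <- which(at$peptide_id == pid & at$residue_index == ri & at$name == name)
  if (length(i) == 0L) {
    if (must)
      tf_stop("tf_topology_error", "peptide %d residue %d: atom %s not found",
              pid, ri, name)
    return(NA_integer_)
  }
  i[1]
}

.atom_xyz <- function(frame, pid, ri, name) {
  i <- .atom_row(frame, pid, ri, name)
  as.numeric(frame$atoms[i, c("x", "y", "z")])
}

#' Coordinates of a frame as a matrix
#' @param frame A `structure_frame`.
#' @param rows Optional row subset.
#' @return n x 3 numeric matrix (nm).
#' @export
coords <- function(frame, rows = NULL) {
  m <- as.matrix(frame$atoms[, c("x", "y", "z")])
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  m
}

#' Replace the coordinates of a frame
#' @param frame A `structure_frame`.
#' @param xyz n x 3 matrix (nm) matching the atom count.
#' @export
set_coords <- function(frame, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(frame$atoms) || ncol(xyz) != 3L)
    tf_stop("tf_invalid_input", "coordinate matrix does not match atom count")
  frame$atoms$x <- xyz[, 1]; frame$atoms$y <- xyz[, 2]; frame$atoms$z <- xyz[, 3]
  frame
}

#' Apply a rigid transform to a frame
#' @param frame A `structure_frame`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 shift in nm.
#' @export
transform_frame <- function(frame, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(frame) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  set_coords(frame, xyz)
}

#' The six backbone dihedrals of one peptide
#'
#' Returns (phi1, psi1, phi2, psi2, phi3, psi3) in degrees. The acetyl cap
#' supplies the carbonyl carbon needed by phi1 and the amide cap supplies
#' the nitrogen needed by psi3.
#'
#' @param frame A `structure_frame`.
#' @param peptide_id Peptide id (0-based).
#' @return Named numeric vector of six angles in degrees.
#' @export
backbone_dihedrals <- function(frame, peptide_id) {
  g <- function(ri, name) .atom_xyz(frame, peptide_id, ri, name)
  c0 <- .atom_row(frame, peptide_id, 0L, "C", must = FALSE)
  if (is.na(c0))
    tf_stop("tf_topology_error",
            "peptide %d: missing acetyl cap carbon, phi1 undefined", peptide_id)
  n4 <- .atom_row(frame, peptide_id, 4L, "N", must = FALSE)
  if (is.na(n4))
    tf_stop("tf_topology_error",
            "peptide %d: missing amide cap nitrogen, psi3 undefined", peptide_id)
  out <- numeric(6)
  prev_c <- g(0L, "C")
  for (ri in 1:3) {
    n <- g(ri, "N"); ca <- g(ri, "CA"); cc <- g(ri, "C")
    next_n <- if (ri < 3) g(ri + 1L, "N") else g(4L, "N")
    out[2 * ri - 1] <- dihedral_angle(prev_c, n, ca, cc)
    out[2 * ri] <- dihedral_angle(n, ca, cc, next_n)
    prev_c <- cc
  }
  names(out) <- c("phi1", "psi1", "phi2", "psi2", "phi3", "psi3")
  out
}

#' Reconstruct missing amide hydrogens
#'
#' For every backbone nitrogen (residues 1..3 and the C-terminal amide cap)
#' lacking an H, places one at 0.1 nm from N in the C(prev)-N-CA plane,
#' external bisector of the two bonds, i.e. the standard planar trans-amide
#' position. Needed because the hydrogen-bond criterion uses the
#' donor-hydrogen-acceptor angle.
#'
#' @param frame A `structure_frame`.
#' @return The frame with hydrogens added where they were absent.
#' @export
reconstruct_amide_h <- function(frame) {
  add <- list()
  for (pid in peptide_ids(frame)) {
    for (ri in c(1:3, 4L)) {
      nrow_i <- .atom_row(frame, pid, ri, "N", must = FALSE)
      if (is.na(nrow_i)) next
      if (!is.na(.atom_row(frame, pid, ri, "H", must = FALSE))) next
      n <- as.numeric(frame$atoms[nrow_i, c("x", "y", "z")])
      prev_c <- .atom_xyz(frame, pid, ri - 1L, "C")
      ca_i <- .atom_row(frame, pid, ri, "CA", must = FALSE)
      if (!is.na(ca_i)) {
        # external bisector of the C(prev)-N and CA-N bonds, in their plane
        other <- as.numeric(frame$atoms[ca_i, c("x", "y", "z")])
        u <- (prev_c - n); u <- u / .norm(u)
        v <- (other - n); v <- v / .norm(v)
        bis <- -(u + v)
        if (.norm(bis) < .DEGENERATE_NORM)
          tf_stop("tf_invalid_geometry",
                  "degenerate amide geometry at peptide %d residue %d", pid, ri)
        h <- n + 0.1 * bis / .norm(bis)
      } else {
        # amide cap has no CA: place H trans to the carbonyl oxygen
        prev_o <- .atom_xyz(frame, pid, ri - 1L, "O")
        h <- .place_atom(prev_o, prev_c, n, 0.1, 119, 180)
      }
      add[[length(add) + 1L]] <- data.frame(
        name = "H", residue_index = ri,
        residue_name = frame$atoms$residue_name[nrow_i],
        peptide_id = pid, x = h[1], y = h[2], z = h[3])
    }
  }
  if (length(add)) {
    frame$atoms <- rbind(frame$atoms, do.call(rbind, add))
    # keep a stable, grouped atom order
    o <- order(frame$atoms$peptide_id, frame$atoms$residue_index)
    frame$atoms <- frame$atoms[o, , drop = FALSE]
    rownames(frame$atoms) <- NULL
  }
  frame
}

# ---------------------------------------------------------------------------
# File formats. GRO is read/written natively (fixed-width per the format
# definition); PDB reading goes through bio3d which handles multi-model
# records; a simple standard-conformant PDB writer covers output.

.gro_resname <- function(residue_name) substr(residue_name, 1, 5)

#' Write a frame as a GRO file
#' @param frame A `structure_frame`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gro <- function(frame, path) {
  at <- frame$atoms
  con <- file(path, "w")
  on.exit(close(con))
  title <- sprintf("tripfib frame %d%s", frame$frame_index,
                   if (is.na(frame$time)) "" else sprintf(", t= %.3f", frame$time))
  writeLines(c(title, sprintf("%5d", nrow(at))), con)
  # residue numbering: global, one per (peptide, residue) or per W bead
  key <- ifelse(at$peptide_id >= 0,
                sprintf("p%06d_r%02d", at$peptide_id, at$residue_index),
                sprintf("w%06d", seq_len(nrow(at))))
  resid <- as.integer(factor(key, levels = unique(key)))
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   resid %% 100000L, .gro_resname(at$residue_name),
                   substr(at$name, 1, 5), seq_len(nrow(at)) %% 100000L,
                   at$x, at$y, at$z)
  writeLines(lines, con)
  box <- if (is.null(frame$box)) c(0, 0, 0) else frame$box
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  invisible(path)
}

# Recover peptide_id / residue_index bookkeeping from residue names and
# sequential residue numbers: caps ACE/NH2 delimit peptides; W is solvent.
.assign_bookkeeping <- function(resname, resid_raw) {
  n <- length(resname)
  peptide_id <- integer(n); residue_index <- integer(n)
  cur_pep <- -1L; cur_res <- 0L; last_resid <- NA
  in_pep <- FALSE
  for (i in seq_len(n)) {
    if (resname[i] == "W") {
      peptide_id[i] <- -1L; residue_index[i] <- 0L
      in_pep <- FALSE
      next
    }
    new_res <- is.na(last_resid) || resid_raw[i] != last_resid
    last_resid <- resid_raw[i]
    if (resname[i] == "ACE" && new_res) {
      cur_pep <- cur_pep + 1L; cur_res <- 0L; in_pep <- TRUE
    } else if (new_res) {
      if (!in_pep) { cur_pep <- cur_pep + 1L; cur_res <- 1L; in_pep <- TRUE }
      else cur_res <- cur_res + 1L
    }
    peptide_id[i] <- cur_pep
    residue_index[i] <- cur_res
  }
  list(peptide_id = peptide_id, residue_index = residue_index)
}

#' Read a GRO file
#' @param path Path to a GRO file (single frame, or first frame of a
#'   multi-frame file).
#' @param validate Run topology validation (default TRUE).
#' @return A `structure_frame`.
#' @export
read_gro <- function(path, validate = TRUE) {
  frames <- read_gro_trajectory(path, validate = validate)
  frames$frames[[1]]
}

#' Read a (possibly multi-frame) GRO file as a trajectory
#' @param path Path to a GRO file; concatenated frames are supported.
#' @param run_id Label for the trajectory.
#' @param validate Run topology validation on each frame.
#' @return A `trajectory` object.
#' @export
read_gro_trajectory <- function(path, run_id = basename(path), validate = TRUE) {
  if (!file.exists(path)) tf_stop("tf_io_error", "file not found: %s", path)
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms))
      tf_stop("tf_io_error", "malformed GRO atom count at line %d", i + 1L)
    body <- lines[(i + 2L):(i + 1L + natoms)]
    resname <- trimws(substr(body, 6, 10))
    name <- trimws(substr(body, 11, 15))
    resid_raw <- as.integer(substr(body, 1, 5))
    x <- as.numeric(substr(body, 21, 28))
    y <- as.numeric(substr(body, 29, 36))
    z <- as.numeric(substr(body, 37, 44))
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]])
    box <- if (all(boxline[1:3] > 0)) boxline[1:3] else NULL
    bk <- .assign_bookkeeping(resname, resid_raw)
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    tval <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
    frames[[length(frames) + 1L]] <- structure_frame(
      data.frame(name = name, residue_index = bk$residue_index,
                 residue_name = resname, peptide_id = bk$peptide_id,
                 x = x, y = y, z = z),
      box = box, frame_index = length(frames), time = tval,
      validate = validate)
    i <- i + 3L + natoms
  }
  if (!length(frames)) tf_stop("tf_io_error", "no frames in %s", path)
  trajectory(frames, run_id = run_id)
}

#' Write a frame (or frames) as a PDB file
#'
#' Multiple frames are written as MODEL/ENDMDL records; a box becomes a
#' CRYST1 record. Coordinates are converted from nm to Angstrom.
#'
#' @param frame A `structure_frame` or a `trajectory`.
#' @param path Output path.
#' @export
write_pdb <- function(frame, path) {
  frames <- if (inherits(frame, "trajectory")) frame$frames else list(frame)
  con <- file(path, "w")
  on.exit(close(con))
  box <- frames[[1]]$box
  if (!is.null(box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       box[1] * 10, box[2] * 10, box[3] * 10, 90, 90, 90), con)
  multi <- length(frames) > 1L
  for (k in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    at <- frames[[k]]$atoms
    key <- ifelse(at$peptide_id >= 0,
                  sprintf("p%06d_r%02d", at$peptide_id, at$residue_index),
                  sprintf("w%06d", seq_len(nrow(at))))
    resid <- as.integer(factor(key, levels = unique(key)))
    chain <- ifelse(at$peptide_id >= 0,
                    LETTERS[(at$peptide_id %% 26) + 1L], "Z")
    elem <- substr(ifelse(at$name == "W", "C", at$name), 1, 1)
    lines <- sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(nrow(at)) %% 100000L, substr(at$name, 1, 4),
                     substr(at$residue_name, 1, 3), chain, resid %% 10000L,
                     at$x * 10, at$y * 10, at$z * 10, 1, 0, elem)
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a PDB file (multi-model supported)
#'
#' Parsing is delegated to bio3d; each MODEL becomes one frame.
#'
#' @param path Path to a PDB file.
#' @param validate Run topology validation.
#' @return A `structure_frame` for single-model files, a `trajectory`
#'   for multi-model files.
#' @export
read_pdb <- function(path, validate = TRUE) {
  if (!file.exists(path)) tf_stop("tf_io_error", "file not found: %s", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  resname <- trimws(at$resid)
  name <- trimws(at$elety)
  resid_raw <- at$resno + 1000L * match(at$chain, unique(at$chain))
  bk <- .assign_bookkeeping(resname, resid_raw)
  box <- NULL
  if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3 &&
      all(is.finite(pdb$cryst1$abc)) && all(pdb$cryst1$abc > 0))
    box <- pdb$cryst1$abc / 10
  xyz <- pdb$xyz
  nmodels <- nrow(xyz)
  frames <- lapply(seq_len(nmodels), function(k) {
    m <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) / 10
    structure_frame(
      data.frame(name = name, residue_index = bk$residue_index,
                 residue_name = resname, peptide_id = bk$peptide_id,
                 x = m[, 1], y = m[, 2], z = m[, 3]),
      box = box, frame_index = k - 1L, validate = validate)
  })
  if (nmodels == 1L) frames[[1]] else trajectory(frames, run_id = basename(path))
}

#' Read a structure file by format
#' @param path Input path.
#' @param format "pdb" or "gro"; guessed from the extension by default.
#' @param validate Run topology validation.
#' @return A `structure_frame` (first model for multi-model input).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"), validate = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  out <- switch(format, gro = read_gro(path, validate = validate),
                pdb = read_pdb(path, validate = validate))
  if (inherits(out, "trajectory")) out$frames[[1]] else out
}

#' Construct a trajectory
#' @param frames List of `structure_frame`s sharing one topology.
#' @param run_id Label.
#' @export
trajectory <- function(frames, run_id = "run") {
  if (!length(frames)) tf_stop("tf_invalid_input", "a trajectory needs at least one frame")
  n0 <- nrow(frames[[1]]$atoms)
  for (f in frames)
    if (nrow(f$atoms) != n0)
      tf_stop("tf_topology_error", "frames disagree on atom count (%d vs %d)",
              nrow(f$atoms), n0)
  structure(list(frames = frames, run_id = run_id), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s'> %d frame(s), %d atoms\n",
              x$run_id, length(x$frames), nrow(x$frames[[1]]$atoms)))
  invisible(x)
}

#' Read a trajectory from a topology file plus a coordinate series
#'
#' Supported: multi-frame GRO ("gro"), multi-model PDB ("pdb"), and DCD
#' ("dcd", read via bio3d against the GRO/PDB topology).
#'
#' @param topology_path Structure file defining the topology.
#' @param traj_path Trajectory file; may equal `topology_path` for
#'   multi-frame GRO / multi-model PDB.
#' @param format "gro", "pdb" or "dcd".
#' @return A `trajectory`.
#' @export
read_trajectory <- function(topology_path, traj_path = topology_path,
                            format = c("auto", "gro", "pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(traj_path))
    format <- if (ext %in% c("gro", "pdb", "dcd")) ext else
      tf_stop("tf_io_error", "cannot guess trajectory format of %s", traj_path)
  }
  if (format == "gro") return(read_gro_trajectory(traj_path))
  if (format == "pdb") {
    out <- read_pdb(traj_path)
    if (inherits(out, "structure_frame")) out <- trajectory(list(out), basename(traj_path))
    return(out)
  }
  topo <- read_structure(topology_path)
  dcd <- bio3d::read.dcd(traj_path, verbose = FALSE)
  if (ncol(dcd) != 3L * nrow(topo$atoms))
    tf_stop("tf_topology_error",
            "trajectory atom count (%d) does not match topology (%d)",
            ncol(dcd) / 3, nrow(topo$atoms))
  frames <- lapply(seq_len(nrow(dcd)), function(k) {
    m <- matrix(dcd[k, ], ncol = 3, byrow = TRUE) / 10
    fr <- set_coords(topo, m)
    fr$frame_index <- k - 1L
    fr
  })
  trajectory(frames, run_id = basename(traj_path))
}

#' Bundle trajectories into an ensemble of independent runs
#' @param runs List of `trajectory` objects sharing topology.
#' @export
ensemble <- function(runs) {
  if (!length(runs)) tf_stop("tf_invalid_input", "an ensemble needs at least one run")
  structure(list(runs = runs), class = "tripfib_ensemble")
}

#' @export
print.tripfib_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d run(s) x %d frame(s)\n",
              length(x$runs), length(x$runs[[1]]$frames)))
  invisible(x)
}
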