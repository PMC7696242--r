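# Noncovalent-interaction accounting: sidechain-sidechain contacts,
# sidechain-solvent exposure, geometric backbone hydrogen bonds, the
# fiber-core filter and the per-residue-normalised per-peptide profile.

#' Interaction criteria
#'
#' Geometric thresholds of the contact / hydrogen-bond / core analyses:
#' two particles within `contact_cutoff` are in contact; a hydrogen bond
#' requires donor-acceptor distance below `hb_da_cutoff` and a
#' donor-hydrogen-acceptor angle above `hb_angle_min`; only peptides within
#' `core_radius` of the fiber core are profiled.
#'
#' @param contact_cutoff Contact distance, nm (default 0.65).
#' @param hb_da_cutoff Donor-acceptor distance, nm (default 0.35).
#' @param hb_angle_min D-H-A angle, degrees (default 120).
#' @param core_radius Core filter radius, nm (default 1.0).
#' @export
interaction_criteria <- function(contact_cutoff = 0.65, hb_da_cutoff = 0.35,
                                 hb_angle_min = 120, core_radius = 1.0) {
  if (any(c(contact_cutoff, hb_da_cutoff, hb_angle_min, core_radius) <= 0))
    tf_stop("tf_invalid_input", "all interaction criteria must be positive")
  structure(list(contact_cutoff = contact_cutoff, hb_da_cutoff = hb_da_cutoff,
                 hb_angle_min = hb_angle_min, core_radius = core_radius),
            class = "interaction_criteria")
}

#' Row indices of sidechain particles
#'
#' Sidechain particles are everything beyond the backbone/cap vocabulary
#' (N, H, H2, CA, C, O, CH3): CB and any further sidechain atoms or beads.
#'
#' @param frame A `structure_frame`.
#' @param residue_name Optional residue-name filter (e.g. "PHE").
#' @param peptide_id Optional peptide filter.
#' @export
sidechain_rows <- function(frame, residue_name = NULL, peptide_id = NULL) {
  at <- frame$atoms
  sel <- at$peptide_id >= 0 & !(at$name %in% .BACKBONE_NAMES)
  if (!is.null(residue_name)) sel <- sel & at$residue_name %in% residue_name
  if (!is.null(peptide_id)) sel <- sel & at$peptide_id %in% peptide_id
  which(sel)
}

#' Count pair contacts between two particle selections
#'
#' A contact is a pair of particles within the contact cutoff (minimum
#' image when the frame has a box). For overlapping or identical
#' selections each unordered pair is counted once; pairs within the same
#' residue of the same peptide are excluded.
#'
#' @param frame A `structure_frame`.
#' @param selA,selB Integer vectors of atom-row indices.
#' @param criteria An `interaction_criteria`.
#' @param return_pairs Also return the contact pair list.
#' @return The count, or (with `return_pairs`) a list(count, pairs).
#' @export
count_contacts <- function(frame, selA, selB, criteria = interaction_criteria(),
                           return_pairs = FALSE) {
  empty <- if (return_pairs)
    list(count = 0L, pairs = matrix(integer(0), ncol = 2)) else 0L
  if (!length(selA) || !length(selB)) return(empty)
  at <- frame$atoms
  dd <- .pair_dists(coords(frame, selA), coords(frame, selB), frame$box)
  hit <- which(dd < criteria$contact_cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  ia <- selA[hit[, 1]]; ib <- selB[hit[, 2]]
  keep <- ia != ib &
    !(at$peptide_id[ia] == at$peptide_id[ib] &
        at$residue_index[ia] == at$residue_index[ib] &
        at$peptide_id[ia] >= 0)
  ia <- ia[keep]; ib <- ib[keep]
  # dedupe unordered pairs (relevant when selections overlap)
  key <- paste(pmin(ia, ib), pmax(ia, ib))
  u <- !duplicated(key)
  ia <- ia[u]; ib <- ib[u]
  if (return_pairs) list(count = length(ia), pairs = cbind(ia, ib))
  else length(ia)
}

#' Detect geometric hydrogen bonds
#'
#' Donors are backbone/cap amide N-H groups, acceptors backbone/cap
#' carbonyl oxygens. A bond requires donor-acceptor distance below the
#' cutoff and D-H-A angle above the minimum. Hydrogens missing from the
#' input are reconstructed at the planar amide position first. By default
#' only interpeptide bonds are returned -- the chain-stacking interactions
#' of a filament.
#'
#' @param frame A `structure_frame`.
#' @param criteria An `interaction_criteria`.
#' @param include_intra Keep bonds within one peptide (default FALSE).
#' @param include_caps Let cap amides donate/accept (default TRUE).
#' @return data.frame: donor_peptide, donor_residue, acceptor_peptide,
#'   acceptor_residue, distance (nm), angle (degrees).
#' @export
detect_hbonds <- function(frame, criteria = interaction_criteria(),
                          include_intra = FALSE, include_caps = TRUE) {
  frame <- reconstruct_amide_h(frame)
  at <- frame$atoms
  res_ok <- if (include_caps) 0:4 else 1:3
  hkey <- paste(at$peptide_id, at$residue_index)[at$name == "H"]
  don_n <- which(at$name == "N" & at$peptide_id >= 0 &
                   at$residue_index %in% res_ok &
                   paste(at$peptide_id, at$residue_index) %in% hkey)
  if (length(don_n) && any(!paste(at$peptide_id, at$residue_index)[don_n] %in% hkey))
    tf_stop("tf_topology_error", "donor nitrogen without an amide hydrogen")
  acc_o <- which(at$name == "O" & at$peptide_id >= 0 &
                   at$residue_index %in% res_ok)
  if (!length(don_n) || !length(acc_o))
    return(data.frame(donor_peptide = integer(0), donor_residue = integer(0),
                      acceptor_peptide = integer(0), acceptor_residue = integer(0),
                      distance = numeric(0), angle = numeric(0)))
  don_h <- vapply(don_n, function(i)
    which(at$name == "H" & at$peptide_id == at$peptide_id[i] &
            at$residue_index == at$residue_index[i])[1], integer(1))
  dd <- .pair_dists(coords(frame, don_n), coords(frame, acc_o), frame$box)
  hit <- which(dd < criteria$hb_da_cutoff, arr.ind = TRUE)
  out <- list()
  for (k in seq_len(nrow(hit))) {
    i <- hit[k, 1]; j <- hit[k, 2]
    ni <- don_n[i]; oi <- acc_o[j]
    if (!include_intra && at$peptide_id[ni] == at$peptide_id[oi]) next
    if (at$peptide_id[ni] == at$peptide_id[oi] &&
        at$residue_index[ni] == at$residue_index[oi]) next
    npos <- as.numeric(at[ni, c("x", "y", "z")])
    hpos <- as.numeric(at[don_h[i], c("x", "y", "z")])
    opos <- as.numeric(at[oi, c("x", "y", "z")])
    # min-image the acceptor relative to the donor for the angle
    if (!is.null(frame$box)) {
      d <- opos - npos
      opos <- npos + d - frame$box * round(d / frame$box)
      dh <- hpos - npos
      hpos <- npos + dh - frame$box * round(dh / frame$box)
    }
    ang <- planar_angle(npos, hpos, opos)
    if (ang <= criteria$hb_angle_min) next
    out[[length(out) + 1L]] <- data.frame(
      donor_peptide = at$peptide_id[ni], donor_residue = at$residue_index[ni],
      acceptor_peptide = at$peptide_id[oi], acceptor_residue = at$residue_index[oi],
      distance = dd[i, j], angle = ang)
  }
  if (!length(out))
    return(data.frame(donor_peptide = integer(0), donor_residue = integer(0),
                      acceptor_peptide = integer(0), acceptor_residue = integer(0),
                      distance = numeric(0), angle = numeric(0)))
  do.call(rbind, out)
}

#' Solvent exposure of sidechains, per residue
#'
#' Counts W beads within the contact cutoff of any sidechain particle of
#' each selected residue.
#'
#' @param frame A `structure_frame`.
#' @param residue_name Residue filter (default both PHE and ILE).
#' @param criteria An `interaction_criteria`.
#' @return data.frame: peptide, residue, residue_name, water_count.
#' @export
solvent_exposure <- function(frame, residue_name = c("PHE", "ILE"),
                             criteria = interaction_criteria()) {
  at <- frame$atoms
  wrows <- which(at$residue_name == "W")
  sel <- which(at$peptide_id >= 0 & at$residue_name %in% residue_name &
                 !(at$name %in% .BACKBONE_NAMES))
  if (!length(sel))
    return(data.frame(peptide = integer(0), residue = integer(0),
                      residue_name = character(0), water_count = integer(0)))
  key <- paste(at$peptide_id[sel], at$residue_index[sel])
  ukey <- unique(key)
  counts <- integer(length(ukey))
  if (length(wrows)) {
    dd <- .pair_dists(coords(frame, sel), coords(frame, wrows), frame$box)
    near <- dd < criteria$contact_cutoff
    for (u in seq_along(ukey)) {
      rows <- which(key == ukey[u])
      # a W bead touching any sidechain particle of the residue counts once
      counts[u] <- sum(apply(near[rows, , drop = FALSE], 2, any))
    }
  }
  first <- sel[match(ukey, key)]
  data.frame(peptide = at$peptide_id[first], residue = at$residue_index[first],
             residue_name = at$residue_name[first], water_count = counts)
}

#' Fiber-core filter
#'
#' Restricts analysis to peptides near the fiber interior: the fiber axis
#' is the principal axis of the largest aggregate's peptide-centroid
#' cloud, and peptides whose centroid lies within `core_radius` of that
#' axis are retained. (A literal point-centroid filter is available via
#' `mode = "point"`.)
#'
#' @param frame A `structure_frame`.
#' @param criteria An `interaction_criteria`.
#' @param mode "axis" (distance to the principal axis, default) or
#'   "point" (distance to the aggregate centroid).
#' @return Integer vector of retained peptide ids.
#' @export
core_filter <- function(frame, criteria = interaction_criteria(),
                        mode = c("axis", "point")) {
  mode <- match.arg(mode)
  ids <- peptide_ids(frame)
  if (!length(ids)) tf_stop("tf_invalid_input", "frame contains no peptides")
  cents <- t(vapply(ids, function(p) {
    rows <- which(frame$atoms$peptide_id == p)
    colMeans(coords(frame, rows))
  }, numeric(3)))
  graph <- aggregate_components(frame, criteria)
  comp_sizes <- table(graph$membership)
  big <- as.integer(names(comp_sizes)[which.max(comp_sizes)])
  in_big <- ids[graph$membership == big]
  cc <- cents[match(in_big, ids), , drop = FALSE]
  center <- colMeans(cc)
  if (mode == "point" || nrow(cc) < 3) {
    d <- sqrt(rowSums(sweep(cents, 2, center)^2))
  } else {
    cv <- stats::cov(cc)
    axis <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    rel <- sweep(cents, 2, center)
    along <- rel %*% axis
    perp <- rel - along %*% t(axis)
    d <- sqrt(rowSums(perp^2))
  }
  ids[d <= criteria$core_radius]
}

# Per-peptide metric table for one frame (after core filtering).
.frame_profile <- function(frame, criteria, per_residue = TRUE) {
  keep <- core_filter(frame, criteria)
  if (!length(keep))
    tf_stop("tf_empty_selection", "no peptides survive the core filter")
  at <- frame$atoms
  hb <- detect_hbonds(frame, criteria)
  expo <- solvent_exposure(frame, criteria = criteria)
  phe_all <- sidechain_rows(frame, "PHE")
  ile_all <- sidechain_rows(frame, "ILE")
  out <- lapply(keep, function(p) {
    n_phe <- length(unique(at$residue_index[at$peptide_id == p &
                                              at$residue_name == "PHE"]))
    n_ile <- 3L - n_phe
    phe_p <- sidechain_rows(frame, "PHE", p)
    ile_p <- sidechain_rows(frame, "ILE", p)
    norm <- function(count, nres) if (per_residue && nres > 0) count / nres
                                  else if (nres > 0) count else 0
    pw <- expo$water_count[expo$peptide == p & expo$residue_name == "PHE"]
    iw <- expo$water_count[expo$peptide == p & expo$residue_name == "ILE"]
    data.frame(
      peptide = p,
      phe_sc_water = if (n_phe) mean(pw) else 0,
      ile_sc_water = if (n_ile) mean(iw) else 0,
      phe_phe = norm(count_contacts(frame, phe_p, phe_all, criteria), n_phe),
      ile_ile = norm(count_contacts(frame, ile_p, ile_all, criteria), n_ile),
      phe_ile = norm(count_contacts(frame, phe_p, ile_all, criteria) +
                       count_contacts(frame, ile_p, setdiff(phe_all, phe_p),
                                      criteria),
                     max(1L, n_phe + n_ile)),
      hb = sum(hb$donor_peptide == p) + sum(hb$acceptor_peptide == p))
  })
  do.call(rbind, out)
}

.PROFILE_METRICS <- c("phe_sc_water", "ile_sc_water", "phe_phe", "ile_ile",
                      "phe_ile", "hb")

#' Per-peptide interaction profile of an ensemble
#'
#' Applies the core filter per frame, computes the six metric families
#' (Phe/Ile sidechain water counts, the three sidechain-sidechain contact
#' families, interchain hydrogen bonds), averages per peptide over frames
#' and peptides within each run, and reports mean and standard deviation
#' across runs. Contact families are per-residue normalised by the number
#' of residues of the relevant type in the peptide.
#'
#' @param ens A `tripfib_ensemble` (or a single `structure_frame`, treated
#'   as a one-frame run).
#' @param criteria An `interaction_criteria`.
#' @param per_residue Normalise contact counts per residue (default TRUE).
#' @return data.frame: metric, mean, sd; per-run matrix in attribute
#'   `per_run`.
#' @export
interaction_profile <- function(ens, criteria = interaction_criteria(),
                                per_residue = TRUE) {
  if (inherits(ens, "structure_frame"))
    ens <- ensemble(list(trajectory(list(ens), "single")))
  mat <- matrix(NA_real_, nrow = length(.PROFILE_METRICS),
                ncol = length(ens$runs),
                dimnames = list(.PROFILE_METRICS, NULL))
  for (r in seq_along(ens$runs)) {
    tabs <- lapply(ens$runs[[r]]$frames, .frame_profile, criteria = criteria,
                   per_residue = per_residue)
    all_t <- do.call(rbind, tabs)
    mat[, r] <- vapply(.PROFILE_METRICS, function(m) mean(all_t[[m]]),
                       numeric(1))
  }
  sdv <- if (ncol(mat) > 1) apply(mat, 1, stats::sd) else rep(0, nrow(mat))
  out <- data.frame(metric = rownames(mat), mean = rowMeans(mat), sd = sdv,
                    row.names = NULL)
  attr(out, "per_run") <- mat
  class(out) <- c("interaction_profile", "data.frame")
  out
}

#' Write an interaction profile as JSON
#' @param profile An `interaction_profile`.
#' @param path Output path.
#' @export
write_interaction_json <- function(profile, path) {
  x <- stats::setNames(lapply(seq_len(nrow(profile)), function(i)
    list(mean = profile$mean[i], sd = profile$sd[i])), profile$metric)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
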