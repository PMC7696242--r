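# Sidechain-orientation order parameters: the rotation angle theta between
# the CA->CB vectors of adjacent residues, realised as the CB-CA-CA-CB
# torsion about the CA_i - CA_{i+1} axis, and the five-way syn/anti
# taxonomy it induces. |theta| > 115 deg means the two sidechains sit on
# opposite sides of the backbone (anti); |theta| < 60 deg means the same
# side (syn); the 60-115 band is "other".

.TOPOLOGY_GROUPS <- c("all_anti", "all_syn", "n_syn", "c_syn", "other")

#' Sidechain rotation angle theta
#'
#' The torsion CB_i - CA_i - CA_{i+1} - CB_{i+1}: the rotation of the
#' CA->CB vector of residue i+1 relative to that of residue i, measured
#' about the CA_i-CA_{i+1} axis. Signed, in (-180, 180]; invariant under
#' rigid motion and sign-flipping under mirror reflection.
#'
#' @param frame A `structure_frame`.
#' @param peptide_id Peptide id.
#' @param i Which adjacent pair: 1 (residues 1-2) or 2 (residues 2-3).
#' @param method "torsion" (default) or "projected" (angle between the two
#'   CA->CB vectors after projecting out the CA-CA axis; identical up to
#'   sign handling, offered as a sensitivity check).
#' @return Signed angle in degrees.
#' @export
rotation_angle <- function(frame, peptide_id, i,
                           method = c("torsion", "projected")) {
  method <- match.arg(method)
  if (!i %in% 1:2) tf_stop("tf_invalid_input", "i must be 1 or 2")
  cb1 <- .atom_xyz(frame, peptide_id, i, "CB")
  ca1 <- .atom_xyz(frame, peptide_id, i, "CA")
  ca2 <- .atom_xyz(frame, peptide_id, i + 1L, "CA")
  cb2 <- .atom_xyz(frame, peptide_id, i + 1L, "CB")
  if (method == "torsion") return(dihedral_angle(cb1, ca1, ca2, cb2))
  axis <- ca2 - ca1; axis <- axis / .norm(axis)
  v1 <- cb1 - ca1; v1 <- v1 - sum(v1 * axis) * axis
  v2 <- cb2 - ca2; v2 <- v2 - sum(v2 * axis) * axis
  if (.norm(v1) < .DEGENERATE_NORM || .norm(v2) < .DEGENERATE_NORM)
    tf_stop("tf_invalid_geometry", "CA->CB vector parallel to the CA-CA axis")
  ang <- planar_angle(ca1 + v1, ca1, ca1 + v2)
  s <- sign(sum(.cross(v1, v2) * axis))
  if (s == 0) s <- 1
  s * ang
}

#' Both rotation angles of a tripeptide
#' @inheritParams rotation_angle
#' @return Named vector c(theta1, theta2), degrees.
#' @export
theta_pair <- function(frame, peptide_id, method = c("torsion", "projected")) {
  method <- match.arg(method)
  c(theta1 = rotation_angle(frame, peptide_id, 1L, method),
    theta2 = rotation_angle(frame, peptide_id, 2L, method))
}

#' Five-way sidechain topology group from (theta1, theta2)
#'
#' With a = |theta1| and b = |theta2|: both above `anti_cut` is all-anti;
#' both below `syn_cut` is all-syn; a below / b above is N-syn (N-terminal
#' sidechain with the middle one); a above / b below is C-syn; any value in
#' the closed band [syn_cut, anti_cut] is "other" (the excluded region of
#' the taxonomy -- the quoted thresholds are strict inequalities, so exact
#' boundary values fall in the band).
#'
#' @param theta1,theta2 Signed angles in degrees (a named pair may be
#'   passed as `theta1`).
#' @param syn_cut,anti_cut Thresholds in degrees (defaults 60 and 115).
#' @return One of "all_anti", "all_syn", "n_syn", "c_syn", "other".
#' @export
topology_group <- function(theta1, theta2 = NULL, syn_cut = 60, anti_cut = 115) {
  if (is.null(theta2)) { theta2 <- theta1[2]; theta1 <- theta1[1] }
  a <- abs(theta1); b <- abs(theta2)
  if (a > anti_cut && b > anti_cut) return("all_anti")
  if (a < syn_cut && b < syn_cut) return("all_syn")
  if (a < syn_cut && b > anti_cut) return("n_syn")
  if (a > anti_cut && b < syn_cut) return("c_syn")
  "other"
}

#' Reference theta map over all conformation codes
#'
#' Builds the ideal capped-tripeptide fixture at the basin centers of every
#' enumerated code and records its (theta1, theta2) and topology group --
#' a computed reference chart of sidechain orientations across the whole
#' conformational state space.
#'
#' @param regions A `region_map`.
#' @param sequence Sequence used for the fixtures (theta depends only on
#'   backbone + CB, so the default "FFF" is representative).
#' @return data.frame with columns code, theta1, theta2, group.
#' @export
reference_theta_map <- function(regions = default_region_map(),
                                sequence = "FFF") {
  codes <- conformation_codes(regions)
  th <- t(vapply(codes, function(code) {
    fr <- build_tripeptide(sequence, code_phi_psi(code, regions))
    theta_pair(fr, 0L)
  }, c(theta1 = 0, theta2 = 0)))
  data.frame(code = codes, theta1 = th[, 1], theta2 = th[, 2],
             group = vapply(seq_along(codes), function(i)
               topology_group(th[i, 1], th[i, 2]), character(1)),
             row.names = NULL)
}

#' Per-frame theta table of an ensemble run
#' @param frame A `structure_frame`.
#' @return data.frame: peptide, theta1, theta2, group.
#' @export
frame_theta_table <- function(frame) {
  ids <- peptide_ids(frame)
  th <- t(vapply(ids, function(p) theta_pair(frame, p), c(theta1 = 0, theta2 = 0)))
  data.frame(peptide = ids, theta1 = th[, 1], theta2 = th[, 2],
             group = vapply(seq_along(ids), function(i)
               topology_group(th[i, 1], th[i, 2]), character(1)))
}

#' Topology-group populations of an ensemble
#'
#' Fractions of the five groups over all peptide-frame observations, per
#' run, with mean and standard deviation across runs. The five fractions
#' sum to 1 in every run.
#'
#' @param ens A `tripfib_ensemble`.
#' @param syn_cut,anti_cut Thresholds in degrees.
#' @return data.frame with columns group, mean_fraction, sd_fraction,
#'   n_obs; per-run matrix in attribute `per_run`.
#' @export
group_populations <- function(ens, syn_cut = 60, anti_cut = 115) {
  if (!inherits(ens, "tripfib_ensemble") || !length(ens$runs))
    tf_stop("tf_invalid_input", "group_populations needs a non-empty ensemble")
  mat <- matrix(0, nrow = length(.TOPOLOGY_GROUPS), ncol = length(ens$runs),
                dimnames = list(.TOPOLOGY_GROUPS, NULL))
  n_obs <- 0L
  for (r in seq_along(ens$runs)) {
    gs <- unlist(lapply(ens$runs[[r]]$frames, function(fr) {
      vapply(peptide_ids(fr), function(p)
        topology_group(theta_pair(fr, p), syn_cut = syn_cut,
                       anti_cut = anti_cut), character(1))
    }))
    tab <- table(factor(gs, levels = .TOPOLOGY_GROUPS))
    n_obs <- n_obs + sum(tab)
    mat[, r] <- as.numeric(tab) / sum(tab)
  }
  sdv <- if (ncol(mat) > 1) apply(mat, 1, stats::sd) else rep(0, nrow(mat))
  out <- data.frame(group = rownames(mat), mean_fraction = rowMeans(mat),
                    sd_fraction = sdv, n_obs = n_obs, row.names = NULL)
  attr(out, "per_run") <- mat
  out
}
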