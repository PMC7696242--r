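# Backbone rotamer-state classification: each residue's (phi, psi) is
# assigned to one of four Ramachandran basins -- right-handed helical (R,
# alpha_R), left-handed helical (L, alpha_L), extended beta (B) and
# left-handed polyproline II (P) -- and a tripeptide is summarised by the
# ordered three-letter code of its residues. A terminal-reduction rule
# merges the geometrically closest pair (beta / PP_II) at the C-terminal
# position, which brings the 4^3 = 64 raw codes down to 4 x 4 x 3 = 48
# distinct states.

.STATES <- c("R", "L", "B", "P")
.STATE_LABELS <- c(R = "alpha_R", L = "alpha_L", B = "beta", P = "PP_II")

#' Default Ramachandran region map
#'
#' Rectangular (phi, psi) regions in degrees, jointly covering the torus
#' exactly once. Regions are closed on their lower phi/psi edge and open on
#' the upper, so boundary points are owned deterministically. Representative
#' basin points (used by the structure builder) are alpha_R (-95, -45),
#' alpha_L (95, 45), beta (-135, 135), PP_II (-75, 150). The helical points
#' sit deep in their (broad) basins so that the sidechain rotation angle of
#' helical-helical neighbours lands robustly in the syn band, reproducing
#' the canonical group assignments of the conformational chart; the beta
#' point is the textbook extended value, which also keeps it several
#' standard deviations of classification jitter away from every region
#' boundary under the builder's default coordinate noise. All of it is
#' overridable.
#'
#' @param reduce_terminal Merge beta and PP_II at the C-terminal position
#'   (default TRUE; gives the 48-state scheme).
#' @return An object of class `region_map`.
#' @export
default_region_map <- function(reduce_terminal = TRUE) {
  rect <- function(phi_lo, phi_hi, psi_lo, psi_hi)
    c(phi_lo = phi_lo, phi_hi = phi_hi, psi_lo = psi_lo, psi_hi = psi_hi)
  regions <- list(
    R = list(rect(-180, 0, -120, 50)),
    L = list(rect(0, 180.000001, -180, 180.000001)),
    B = list(rect(-180, -100, 50, 180.000001), rect(-180, -100, -180, -120)),
    P = list(rect(-100, 0, 50, 180.000001), rect(-100, 0, -180, -120))
  )
  centers <- rbind(R = c(-95, -45), L = c(95, 45), B = c(-135, 135),
                   P = c(-75, 150))
  colnames(centers) <- c("phi", "psi")
  structure(list(regions = regions, centers = centers,
                 reduce_terminal = reduce_terminal),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> 4 rotamer states; terminal beta/PP_II merge %s\n",
              if (x$reduce_terminal) "on (48 codes)" else "off (64 codes)"))
  invisible(x)
}

#' Read / write a region map as YAML
#' @param path YAML file path.
#' @export
read_region_map <- function(path) {
  y <- yaml::read_yaml(path)
  rm0 <- default_region_map()
  if (!is.null(y$reduce_terminal)) rm0$reduce_terminal <- isTRUE(y$reduce_terminal)
  if (!is.null(y$centers))
    for (s in names(y$centers)) rm0$centers[s, ] <- as.numeric(y$centers[[s]])
  if (!is.null(y$regions))
    rm0$regions <- lapply(y$regions, function(rs)
      lapply(rs, function(r) c(phi_lo = r[[1]], phi_hi = r[[2]],
                               psi_lo = r[[3]], psi_hi = r[[4]])))
  rm0
}

#' @rdname read_region_map
#' @param regions A `region_map`.
#' @export
write_region_map <- function(regions, path) {
  yaml::write_yaml(list(
    reduce_terminal = regions$reduce_terminal,
    centers = stats::setNames(lapply(rownames(regions$centers), function(s)
      as.numeric(regions$centers[s, ])), rownames(regions$centers)),
    regions = lapply(regions$regions, function(rs)
      lapply(rs, function(r) as.numeric(r)))
  ), path)
  invisible(path)
}

.wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a <= -180, a + 360, a)
}

#' Classify one residue's (phi, psi) into a rotamer state
#'
#' Total and deterministic: every angle pair maps to exactly one of the
#' four states; region edges are owned by the region closed on that edge
#' (lower edges closed, upper open).
#'
#' @param phi,psi Angles in degrees (wrapped into (-180, 180]).
#' @param regions A `region_map`.
#' @return One of "R", "L", "B", "P".
#' @export
classify_residue <- function(phi, psi, regions = default_region_map()) {
  phi <- .wrap_angle(phi); psi <- .wrap_angle(psi)
  for (s in .STATES) {
    for (r in regions$regions[[s]]) {
      if (phi >= r["phi_lo"] && phi < r["phi_hi"] &&
          psi >= r["psi_lo"] && psi < r["psi_hi"]) return(s)
    }
  }
  tf_stop("tf_invalid_input",
          "region map does not cover (phi, psi) = (%.2f, %.2f)", phi, psi)
}

#' Parse / render three-letter conformation codes
#'
#' Codes are strings over {R, L, B, P} of length 3, e.g. "BBB" (beta beta
#' beta) or "RRB" (alpha_R alpha_R beta).
#'
#' @param code A code string.
#' @return Character vector of 3 per-residue states.
#' @export
parse_conformation_code <- function(code) {
  s <- strsplit(code, "")[[1]]
  if (length(s) != 3L || !all(s %in% .STATES))
    tf_stop("tf_invalid_input",
            "'%s' is not a three-letter code over {R, L, B, P}", code)
  s
}

#' @rdname parse_conformation_code
#' @param states Character vector of 3 states.
#' @export
render_conformation_code <- function(states) {
  if (length(states) != 3L || !all(states %in% .STATES))
    tf_stop("tf_invalid_input", "states must be 3 values over {R, L, B, P}")
  paste(states, collapse = "")
}

#' Human-readable label of a code
#' @param code Code string such as "RRB".
#' @return E.g. "alpha_R alpha_R beta".
#' @export
code_label <- function(code) {
  paste(.STATE_LABELS[parse_conformation_code(code)], collapse = " ")
}

#' Representative (phi, psi) targets realising a code
#'
#' Returns the 3 x 2 matrix of basin representative points for the three
#' states of `code`, suitable as `phi_psi` targets for
#' [build_tripeptide()].
#'
#' @param code Code string such as "BBB".
#' @param regions A `region_map` supplying the representative points.
#' @export
code_phi_psi <- function(code, regions = default_region_map()) {
  s <- parse_conformation_code(code)
  regions$centers[s, , drop = FALSE]
}

.reduce_code <- function(states, regions) {
  if (isTRUE(regions$reduce_terminal) && states[3] == "P") states[3] <- "B"
  states
}

#' Classify a whole tripeptide into a conformation code
#'
#' Applies [classify_residue()] to the three (phi, psi) pairs from
#' [backbone_dihedrals()], then the terminal-reduction rule of the region
#' map (beta/PP_II merged at position 3 when enabled).
#'
#' @param frame A `structure_frame`.
#' @param peptide_id Peptide id.
#' @param regions A `region_map`.
#' @return A code string.
#' @export
classify_peptide <- function(frame, peptide_id, regions = default_region_map()) {
  d <- backbone_dihedrals(frame, peptide_id)
  states <- vapply(1:3, function(i)
    classify_residue(d[2 * i - 1], d[2 * i], regions), character(1))
  render_conformation_code(.reduce_code(states, regions))
}

#' Enumerate the distinct conformation codes of the scheme
#'
#' With the terminal reduction enabled the count is 4 x 4 x 3 = 48; with
#' it disabled, 4^3 = 64.
#'
#' @param regions A `region_map`.
#' @return Lexicographically ordered character vector of codes.
#' @export
conformation_codes <- function(regions = default_region_map()) {
  g <- expand.grid(a = .STATES, b = .STATES, c = .STATES,
                   stringsAsFactors = FALSE)
  codes <- unique(vapply(seq_len(nrow(g)), function(i)
    render_conformation_code(.reduce_code(c(g$a[i], g$b[i], g$c[i]), regions)),
    character(1)))
  sort(codes)
}

# Per-run fraction matrix (codes x runs) over peptide x frame observations.
.code_fractions <- function(ens, regions) {
  all_codes <- conformation_codes(regions)
  runs <- ens$runs
  mat <- matrix(0, nrow = length(all_codes), ncol = length(runs),
                dimnames = list(all_codes, NULL))
  counts <- integer(length(runs))
  for (r in seq_along(runs)) {
    tab <- table(unlist(lapply(runs[[r]]$frames, function(fr)
      vapply(peptide_ids(fr), function(p) classify_peptide(fr, p, regions),
             character(1)))))
    counts[r] <- sum(tab)
    mat[names(tab), r] <- as.numeric(tab) / sum(tab)
  }
  list(fractions = mat, n_obs = counts)
}

#' Conformation-code population table across an ensemble
#'
#' Per-run fractions are computed over all peptide-frame observations;
#' the table reports the mean and standard deviation across runs -- the
#' error-bar convention of averaging over independent simulations.
#'
#' @param ens A `tripfib_ensemble`.
#' @param regions A `region_map`.
#' @return A data.frame (class `population_table`) with columns `code`,
#'   `mean_fraction`, `sd_fraction`, `n_obs`, plus the per-run fraction
#'   matrix in attribute `per_run`.
#' @export
population_table <- function(ens, regions = default_region_map()) {
  if (!inherits(ens, "tripfib_ensemble") || !length(ens$runs))
    tf_stop("tf_invalid_input", "population_table needs a non-empty ensemble")
  cf <- .code_fractions(ens, regions)
  sdv <- if (ncol(cf$fractions) > 1) apply(cf$fractions, 1, stats::sd)
         else rep(0, nrow(cf$fractions))
  out <- data.frame(code = rownames(cf$fractions),
                    mean_fraction = rowMeans(cf$fractions),
                    sd_fraction = sdv,
                    n_obs = sum(cf$n_obs), row.names = NULL)
  out <- out[order(-out$mean_fraction, out$code), ]
  rownames(out) <- NULL
  attr(out, "per_run") <- cf$fractions
  class(out) <- c("population_table", "data.frame")
  out
}

#' Most populated conformation code
#' @param table A `population_table`.
#' @return List with `code` and `fraction`; ties broken lexicographically.
#' @export
most_populated <- function(table) {
  best <- max(table$mean_fraction)
  cand <- sort(table$code[table$mean_fraction == best])
  list(code = cand[1], fraction = best)
}

#' Write a population table as CSV
#' @param table A `population_table`.
#' @param path Output path.
#' @export
write_population_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
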