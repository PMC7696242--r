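# Assembly morphology: peptide-level contact graph and aggregates,
# in-register filament detection, stacking-rise measurement, and
# minimum-RMSD matching of sampled conformers against reference structures.

#' Peptide contact graph and aggregate components
#'
#' Builds the graph whose nodes are peptides and whose edges join peptide
#' pairs with at least one interchain particle pair within the contact
#' cutoff (any peptide particle, backbone or sidechain); aggregates are
#' its connected components.
#'
#' @param frame A `structure_frame`.
#' @param criteria An `interaction_criteria`.
#' @return List (class `assembly_graph`): `peptides`, `edges` (2-column
#'   matrix of peptide ids), `membership` (component id per peptide),
#'   `components` (list of peptide-id vectors, largest first).
#' @export
aggregate_components <- function(frame, criteria = interaction_criteria()) {
  ids <- peptide_ids(frame)
  at <- frame$atoms
  rows <- which(at$peptide_id >= 0)
  xyz <- coords(frame, rows)
  pid <- at$peptide_id[rows]
  edges <- matrix(integer(0), ncol = 2)
  if (length(ids) > 1) {
    dd <- .pair_dists(xyz, xyz, frame$box)
    close <- dd < criteria$contact_cutoff
    ep <- list()
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (b <= a) next
        ra <- pid == ids[a]; rb <- pid == ids[b]
        if (any(close[ra, rb]))
          ep[[length(ep) + 1L]] <- c(ids[a], ids[b])
      }
    }
    if (length(ep)) edges <- do.call(rbind, ep)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1][seq_len(nrow(edges))]),
               to = as.character(edges[, 2][seq_len(nrow(edges))])),
    directed = FALSE, vertices = data.frame(name = as.character(ids)))
  comp <- igraph::components(g)
  membership <- comp$membership[as.character(ids)]
  comps <- split(ids, membership)
  comps <- comps[order(-vapply(comps, length, integer(1)))]
  structure(list(peptides = ids, edges = edges,
                 membership = as.integer(membership),
                 components = unname(comps)),
            class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat(sprintf("<assembly_graph> %d peptide(s), %d contact edge(s), %d component(s); sizes: %s\n",
              length(x$peptides), nrow(x$edges), length(x$components),
              paste(vapply(x$components, length, integer(1)), collapse = ", ")))
  invisible(x)
}

# In-register mean CA-CA distance between two peptides (parallel mapping,
# residue i of one chain against residue i of the other), nm.
.register_distance <- function(frame, p, q) {
  mean(vapply(1:3, function(i)
    min_image_distance(.atom_xyz(frame, p, i, "CA"),
                       .atom_xyz(frame, q, i, "CA"), frame$box), numeric(1)))
}

#' Detect in-register filaments
#'
#' Within each aggregate, peptide pairs whose in-register mean CA-CA
#' distance falls in `register_range` and that share at least one
#' interchain backbone hydrogen bond are chained together; the connected
#' chains of two or more peptides are the filaments. Each peptide belongs
#' to at most one filament; members are ordered along the stacking axis.
#'
#' @param frame A `structure_frame`.
#' @param criteria An `interaction_criteria`.
#' @param register_range Stacking-distance window in nm (default
#'   c(0.40, 0.60), bracketing the 4.6-4.9 Angstrom cross-beta rise).
#' @param graph Optionally a precomputed `assembly_graph`.
#' @return List (class `filament_set`): `filaments` (list of ordered
#'   peptide-id vectors) and `singletons`.
#' @export
detect_filaments <- function(frame, criteria = interaction_criteria(),
                             register_range = c(0.40, 0.60), graph = NULL) {
  if (is.null(graph)) graph <- aggregate_components(frame, criteria)
  ids <- graph$peptides
  hb <- detect_hbonds(frame, criteria)
  hb_pairs <- unique(paste(pmin(hb$donor_peptide, hb$acceptor_peptide),
                           pmax(hb$donor_peptide, hb$acceptor_peptide)))
  stack_edges <- list()
  for (comp in graph$components) {
    if (length(comp) < 2) next
    for (a in seq_along(comp)) for (b in seq_along(comp)) {
      if (b <= a) next
      p <- comp[a]; q <- comp[b]
      if (!paste(min(p, q), max(p, q)) %in% hb_pairs) next
      d <- .register_distance(frame, p, q)
      if (d >= register_range[1] && d <= register_range[2])
        stack_edges[[length(stack_edges) + 1L]] <- c(p, q)
    }
  }
  if (length(stack_edges)) {
    se <- do.call(rbind, stack_edges)
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(se[, 1]), to = as.character(se[, 2])),
      directed = FALSE, vertices = data.frame(name = as.character(ids)))
    comp <- igraph::components(g)
    groups <- split(ids, comp$membership[as.character(ids)])
  } else groups <- as.list(ids)
  fil <- groups[vapply(groups, length, integer(1)) >= 2]
  singles <- unlist(groups[vapply(groups, length, integer(1)) < 2])
  # order each filament along its own principal axis
  fil <- lapply(fil, function(members) {
    cents <- t(vapply(members, function(p)
      colMeans(coords(frame, which(frame$atoms$peptide_id == p))), numeric(3)))
    rel <- sweep(cents, 2, colMeans(cents))
    axis <- if (nrow(cents) > 2)
      eigen(stats::cov(cents), symmetric = TRUE)$vectors[, 1]
    else rel[2, ] - rel[1, ]
    members[order(rel %*% axis)]
  })
  structure(list(filaments = unname(fil),
                 singletons = as.integer(if (is.null(singles)) integer(0) else singles)),
            class = "filament_set")
}

#' @export
print.filament_set <- function(x, ...) {
  cat(sprintf("<filament_set> %d filament(s) (sizes %s), %d singleton(s)\n",
              length(x$filaments),
              paste(vapply(x$filaments, length, integer(1)), collapse = ", "),
              length(x$singletons)))
  invisible(x)
}

#' Stacking rise of a filament
#'
#' Mean in-register CA-CA distance over adjacent chain pairs along the
#' filament, reported in Angstrom with its standard deviation.
#'
#' @param filament Ordered vector of peptide ids (one element of
#'   `detect_filaments()$filaments`).
#' @param frame The `structure_frame`.
#' @return List: `mean` and `sd` in Angstrom, `n_pairs`.
#' @export
interchain_rise <- function(filament, frame) {
  if (length(filament) < 2)
    tf_stop("tf_invalid_input", "a filament needs at least two peptides")
  d <- vapply(seq_len(length(filament) - 1), function(k)
    .register_distance(frame, filament[k], filament[k + 1]), numeric(1))
  list(mean = mean(d) * 10,
       sd = if (length(d) > 1) stats::sd(d) * 10 else 0,
       n_pairs = length(d))
}

.RMSD_SELECTION <- c("N", "CA", "C", "O", "CB")

# Comparison coordinates of one peptide: backbone + CB of residues 1..3
# (caps excluded by default), in a fixed atom order.
.rmsd_coords <- function(frame, peptide_id = NULL,
                         selection = .RMSD_SELECTION) {
  if (is.null(peptide_id)) peptide_id <- peptide_ids(frame)[1]
  rows <- integer(0)
  for (ri in 1:3) for (nm in selection) {
    i <- .atom_row(frame, peptide_id, ri, nm, must = FALSE)
    if (!is.na(i)) rows <- c(rows, i)
  }
  coords(frame, rows)
}

#' Minimum-RMSD match of sampled conformers against a reference
#'
#' Superposes every sampled conformer onto the reference with the Kabsch
#' algorithm over the backbone + CB atoms of the three residues and
#' returns the conformer with the smallest RMSD -- the convention used
#' when comparing sampled conformations with crystal structures. Ties go
#' to the first occurrence in input order.
#'
#' @param sampled List of single-peptide `structure_frame`s (or a
#'   `trajectory`).
#' @param reference A single-peptide `structure_frame`.
#' @param regions A `region_map` used to report the best conformer's code.
#' @param selection Atom names compared per residue (default backbone + CB).
#' @return List: `index`, `rmsd` (Angstrom), `code`, and `rmsds` (all
#'   conformer RMSDs).
#' @export
min_rmsd_to_reference <- function(sampled, reference,
                                  regions = default_region_map(),
                                  selection = .RMSD_SELECTION) {
  if (inherits(sampled, "trajectory")) sampled <- sampled$frames
  if (!length(sampled)) tf_stop("tf_invalid_input", "no sampled conformers")
  ref_xyz <- .rmsd_coords(reference, selection = selection)
  rmsds <- vapply(sampled, function(fr) {
    xyz <- .rmsd_coords(fr, selection = selection)
    if (nrow(xyz) != nrow(ref_xyz))
      tf_stop("tf_invalid_input",
              "conformer and reference disagree on the comparison atom set")
    kabsch_superpose(xyz, ref_xyz)$rmsd
  }, numeric(1))
  best <- which.min(rmsds)
  list(index = best, rmsd = rmsds[best],
       code = classify_peptide(sampled[[best]],
                               peptide_ids(sampled[[best]])[1], regions),
       rmsds = rmsds)
}

#' Morphology report of one frame
#'
#' Aggregate components, filament membership and per-filament rises, as a
#' JSON-ready list.
#'
#' @param frame A `structure_frame`.
#' @param criteria An `interaction_criteria`.
#' @export
morphology_report <- function(frame, criteria = interaction_criteria()) {
  graph <- aggregate_components(frame, criteria)
  fil <- detect_filaments(frame, criteria, graph = graph)
  list(
    n_peptides = length(graph$peptides),
    components = lapply(graph$components, as.integer),
    filaments = lapply(fil$filaments, as.integer),
    singletons = fil$singletons,
    rises = lapply(fil$filaments, function(f) {
      r <- interchain_rise(f, frame)
      list(mean_A = r$mean, sd_A = r$sd, n_pairs = r$n_pairs)
    }))
}
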