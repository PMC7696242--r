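# Independent brute-force oracles, deliberately coded along different
# routes than the package implementations they check.

# Dihedral via projection onto the plane orthogonal to the central bond:
# express the two outer bonds in an explicit orthonormal basis of that
# plane and take atan2 of the components.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  e3 <- b2 / sqrt(sum(b2^2))
  u <- p1 - p2
  u_perp <- u - sum(u * e3) * e3
  e1 <- u_perp / sqrt(sum(u_perp^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  v <- p4 - p3
  v_perp <- v - sum(v * e3) * e3
  ang <- atan2(sum(v_perp * e2), sum(v_perp * e1)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

oracle_planar_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# Minimum over all 27 periodic images.
oracle_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    bb <- b + c(i, j, k) * box
    best <- min(best, sqrt(sum((a - bb)^2)))
  }
  best
}

# Optimal-superposition RMSD via the Horn quaternion eigenvalue method.
oracle_rmsd_quaternion <- function(mobile, reference) {
  p <- sweep(mobile, 2, colMeans(mobile))
  q <- sweep(reference, 2, colMeans(reference))
  m <- crossprod(p, q)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz
  ), nrow = 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE)$values)
  e2 <- (sum(p^2) + sum(q^2) - 2 * lam) / nrow(p)
  sqrt(max(0, e2)) * 10
}

# O(n^2) double-loop contact count between two row-index selections.
oracle_contacts <- function(frame, selA, selB, cutoff = 0.65) {
  at <- frame$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  seen <- character(0)
  count <- 0L
  for (i in selA) for (j in selB) {
    if (i == j) next
    if (at$peptide_id[i] >= 0 && at$peptide_id[i] == at$peptide_id[j] &&
        at$residue_index[i] == at$residue_index[j]) next
    key <- paste(min(i, j), max(i, j))
    if (key %in% seen) next
    d <- if (is.null(frame$box)) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
         else oracle_min_image(xyz[i, ], xyz[j, ], frame$box)
    if (d < cutoff) { count <- count + 1L; seen <- c(seen, key) }
  }
  count
}

# Double-loop interpeptide hydrogen-bond enumeration (donor N-H, acceptor
# O, distance < 0.35 nm, D-H-A angle > 120 deg).
oracle_hbonds <- function(frame, da_cutoff = 0.35, angle_min = 120) {
  at <- frame$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  dn <- which(at$name == "N" & at$peptide_id >= 0)
  ac <- which(at$name == "O" & at$peptide_id >= 0)
  n_hb <- 0L
  for (i in dn) {
    h <- which(at$name == "H" & at$peptide_id == at$peptide_id[i] &
                 at$residue_index == at$residue_index[i])
    if (!length(h)) next
    for (j in ac) {
      if (at$peptide_id[i] == at$peptide_id[j]) next
      d <- if (is.null(frame$box)) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
           else oracle_min_image(xyz[i, ], xyz[j, ], frame$box)
      if (d >= da_cutoff) next
      ang <- oracle_planar_angle(xyz[i, ], xyz[h[1], ], xyz[j, ])
      if (ang > angle_min) n_hb <- n_hb + 1L
    }
  }
  n_hb
}

# Deterministic random rotation matrix from a seed.
random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Minimal hand-made frame from a coordinate matrix (for geometry tests
# that do not need peptide topology).
bead_frame <- function(xyz, box = NULL, names = "CB", residue_name = "PHE",
                       peptide_id = NULL, residue_index = NULL) {
  n <- nrow(xyz)
  structure_frame(data.frame(
    name = rep_len(names, n),
    residue_index = if (is.null(residue_index)) seq_len(n) else residue_index,
    residue_name = rep_len(residue_name, n),
    peptide_id = if (is.null(peptide_id)) seq_len(n) - 1L else peptide_id,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]), box = box, validate = FALSE)
}
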