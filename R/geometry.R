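# Geometric kernels shared by every analysis: torsions, planar angles,
# minimum-image distances and Kabsch superposition. Coordinates are always
# in nm; angles in degrees; RMSD is reported in Angstrom because that is the
# unit the field prints for backbone RMSD and stacking rise.

.DEG <- 180 / pi
.DEGENERATE_NORM <- 1e-9  # nm; vectors shorter than this are degenerate

tf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tripfib_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

.as_point <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p)))
    tf_stop("tf_invalid_geometry", "a point must be 3 finite coordinates")
  p
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.norm <- function(v) sqrt(sum(v * v))

#' Signed torsion angle of four points
#'
#' Computes the dihedral angle defined by four points using the
#' polymer (IUPAC) sign convention: looking from `p2` towards `p3`,
#' a clockwise rotation of the far bond relative to the near bond is
#' positive. The all-trans planar arrangement gives +180 degrees.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (nm).
#' @return Signed angle in degrees, in the half-open range (-180, 180].
#' @examples
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))  # 180
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- .as_point(p1); p2 <- .as_point(p2)
  p3 <- .as_point(p3); p4 <- .as_point(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (.norm(b1) < .DEGENERATE_NORM || .norm(b2) < .DEGENERATE_NORM ||
      .norm(b3) < .DEGENERATE_NORM)
    tf_stop("tf_invalid_geometry", "coincident consecutive points in dihedral")
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (.norm(n1) < .DEGENERATE_NORM || .norm(n2) < .DEGENERATE_NORM)
    tf_stop("tf_invalid_geometry", "collinear bond vectors in dihedral")
  b2n <- b2 / .norm(b2)
  x <- sum(n1 * n2)
  y <- sum(.cross(n1, n2) * b2n)
  ang <- atan2(y, x) * .DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Planar angle at a vertex
#'
#' Angle p1-p2-p3 at the vertex `p2`, e.g. the donor-hydrogen-acceptor
#' angle of a hydrogen-bond test.
#'
#' @param p1,p2,p3 Numeric length-3 coordinate vectors (nm).
#' @return Angle in degrees in [0, 180]; symmetric in `p1`/`p3`.
#' @export
planar_angle <- function(p1, p2, p3) {
  p1 <- .as_point(p1); p2 <- .as_point(p2); p3 <- .as_point(p3)
  u <- p1 - p2; v <- p3 - p2
  nu <- .norm(u); nv <- .norm(v)
  if (nu < .DEGENERATE_NORM || nv < .DEGENERATE_NORM)
    tf_stop("tf_invalid_geometry", "coincident points in planar angle")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * .DEG
}

.check_box <- function(box) {
  if (is.null(box)) return(NULL)
  box <- as.numeric(box)
  if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0))
    tf_stop("tf_invalid_box", "box must be 3 positive orthorhombic edge lengths (nm)")
  box
}

#' Minimum-image distance between two points
#'
#' Shortest distance over all periodic images for an orthorhombic box;
#' plain Euclidean distance when `box` is NULL. Triclinic boxes are not
#' supported.
#'
#' @param a,b Numeric length-3 coordinate vectors (nm).
#' @param box NULL or length-3 positive edge lengths (nm).
#' @return Distance in nm.
#' @export
min_image_distance <- function(a, b, box = NULL) {
  a <- .as_point(a); b <- .as_point(b)
  box <- .check_box(box)
  d <- b - a
  if (!is.null(box)) d <- d - box * round(d / box)
  .norm(d)
}

# Vectorised minimum-image displacement for an n x 3 matrix of differences.
.min_image_mat <- function(d, box = NULL) {
  if (!is.null(box)) {
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  }
  d
}

# All pairwise minimum-image distances between the rows of xa and xb.
.pair_dists <- function(xa, xb, box = NULL) {
  na <- nrow(xa); nb <- nrow(xb)
  dx <- outer(xa[, 1], xb[, 1], "-")
  dy <- outer(xa[, 2], xb[, 2], "-")
  dz <- outer(xa[, 3], xb[, 3], "-")
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` over all
#' proper rotations and translations, via SVD of the covariance matrix
#' with the usual determinant correction against improper rotations.
#'
#' @param mobile,reference n x 3 matrices (nm), n >= 3, equal sizes.
#' @return A list with `rotation` (3 x 3, applied on the right as
#'   `x %*% t(rotation)`), `translation` (length 3, nm), `rmsd`
#'   (Angstrom), and `transform()` applying the fit to an n x 3 matrix.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    tf_stop("tf_invalid_input", "mobile and reference must have identical dimensions")
  if (ncol(mobile) != 3L || nrow(mobile) < 3L)
    tf_stop("tf_invalid_input", "superposition needs at least 3 points of dimension 3")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm); q <- sweep(reference, 2, cr)
  h <- crossprod(p, q)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- p %*% t(rot)
  rmsd_nm <- sqrt(mean(rowSums((fitted - q)^2)))
  list(
    rotation = rot,
    translation = as.numeric(cr - rot %*% cm),
    rmsd = rmsd_nm * 10,
    transform = function(x) sweep(sweep(as.matrix(x), 2, cm) %*% t(rot), 2, cr, "+")
  )
}

#' Root-mean-square deviation without superposition
#'
#' @param a,b n x 3 coordinate matrices in nm.
#' @return RMSD in Angstrom.
#' @export
raw_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    tf_stop("tf_invalid_input", "coordinate sets must have identical dimensions")
  sqrt(mean(rowSums((a - b)^2))) * 10
}

# Rotation matrix about an arbitrary unit axis by an angle in degrees.
.rotation_about <- function(axis, angle_deg) {
  u <- axis / .norm(axis)
  th <- angle_deg / .DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}
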