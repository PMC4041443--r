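# Vector geometry shared across the pipeline: ring planes, tilt angles,
# minimum distances, rigid superposition, dihedrals, idealized hydrogens.
# Angles are degrees, distances Angstrom, throughout.

DEG <- 180 / pi

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

as_xyz_matrix <- function(points) {
  m <- as.matrix(points)
  if (ncol(m) != 3L) stop("points must be an n x 3 matrix of coordinates")
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("non-finite coordinates")
  m
}

#' Least-squares ring plane
#'
#' Fits the plane minimizing the sum of squared perpendicular deviations of a
#' set of ring atoms, via the smallest singular direction of the centered
#' coordinates. Used for every interplanar tilt and every face-participation
#' test in the contact survey.
#'
#' @param points numeric n x 3 matrix (n >= 3, not collinear), Angstrom.
#' @param source_atoms optional character vector of atom names, for reporting.
#' @return an object of class `ring_plane`: list with `centroid` (3-vector),
#'   `normal` (unit 3-vector; sign is arbitrary and all downstream angle
#'   computations are sign-free), `rms` (out-of-plane RMS, Angstrom) and
#'   `source_atoms`.
#' @examples
#' hex <- t(sapply(0:5, function(k) c(cos(k * pi / 3), sin(k * pi / 3), 0)))
#' p <- fit_ring_plane(hex)
#' abs(p$normal[3])   # 1: normal along z
#' p$rms              # 0: exactly planar
#' @export
fit_ring_plane <- function(points, source_atoms = NULL) {
  m <- as_xyz_matrix(points)
  if (nrow(m) < 3L) stop("plane fit needs at least 3 points")
  ctr <- colMeans(m)
  x <- sweep(m, 2L, ctr)
  sv <- svd(x)
  # collinear (or coincident) points: two near-zero singular values
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-8))
    stop("degenerate (collinear) points: plane undefined")
  n <- sv$v[, 3L]
  rms <- sqrt(mean((x %*% n)^2))
  structure(list(centroid = ctr, normal = as.numeric(n), rms = rms,
                 source_atoms = source_atoms),
            class = "ring_plane")
}

#' @export
print.ring_plane <- function(x, ...) {
  cat(sprintf("ring plane: centroid (%.3f, %.3f, %.3f), rms %.4f A\n",
              x$centroid[1], x$centroid[2], x$centroid[3], x$rms))
  invisible(x)
}

#' Interplanar tilt angle
#'
#' Angle between two best-fit ring-plane normals, folded into \[0, 90\]
#' degrees so it is independent of the (arbitrary) normal signs. This is the
#' tilt used to classify pi-pi contacts as stacked, inclined or T-shaped.
#'
#' @param plane_a,plane_b `ring_plane` objects (or unit 3-vectors).
#' @return tilt in degrees, in \[0, 90\].
#' @export
tilt_angle <- function(plane_a, plane_b) {
  na <- if (inherits(plane_a, "ring_plane")) plane_a$normal else vunit(plane_a)
  nb <- if (inherits(plane_b, "ring_plane")) plane_b$normal else vunit(plane_b)
  acos(clamp1(abs(sum(na * nb)))) * DEG
}

#' Closest heavy-atom distance between two atom sets
#'
#' @param atoms_a,atoms_b n x 3 coordinate matrices (heavy atoms only).
#' @return minimum pairwise Euclidean distance, Angstrom.
#' @export
min_heavy_distance <- function(atoms_a, atoms_b) {
  a <- as_xyz_matrix(atoms_a); b <- as_xyz_matrix(atoms_b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty atom set")
  # |a - b|^2 = |a|^2 + |b|^2 - 2 a.b, vectorized over the pair grid
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-RMSD proper rotation + translation taking `mobile` onto `reference`
#' under the given 1:1 atom correspondence; reflections are excluded.
#'
#' @param mobile,reference equal-length n x 3 matrices, n >= 3 non-collinear.
#' @return class `rigid_transform`: list with `rotation` (3 x 3, det +1),
#'   `translation` (3-vector) and `rmsd` (Angstrom). Apply with
#'   [apply_transform()].
#' @export
superpose <- function(mobile, reference) {
  m <- as_xyz_matrix(mobile); r <- as_xyz_matrix(reference)
  if (nrow(m) != nrow(r)) stop("point lists differ in length")
  if (nrow(m) < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(m); cr <- colMeans(r)
  xm <- sweep(m, 2L, cm); xr <- sweep(r, 2L, cr)
  h <- crossprod(xm, xr)              # covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- xm %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - xr)^2)))
  structure(list(rotation = rot, translation = as.numeric(cr - rot %*% cm),
                 rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param points n x 3 matrix.
#' @param transform a `rigid_transform` from [superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(points, transform) {
  m <- as_xyz_matrix(points)
  sweep(m %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform, rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

#' Signed torsion angle
#'
#' IUPAC sign convention: looking from p2 to p3, the angle is positive when
#' p4 is rotated clockwise from p1.
#'
#' @param p1,p2,p3,p4 3-vectors.
#' @return degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("degenerate dihedral: coincident consecutive points")
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("degenerate dihedral: collinear points")
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * vunit(b2))
  ang <- atan2(y, x) * DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place atom D from internal coordinates along the chain a-b-c (NeRF-style):
# |c-D| = bond, angle(b,c,D) = angle_deg, dihedral(a,b,c,D) = dihedral_deg.
place_internal <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  ang <- angle_deg / DEG; dih <- dihedral_deg / DEG
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d[1L] * bc + d[2L] * m + d[3L] * n
}

TET_ANGLE <- 109.4712206

#' Idealized hydrogen construction
#'
#' Builds missing hydrogens on heavy-atom-only structures (crystal structures
#' at survey resolution carry no protons). sp3 centers are completed to ideal
#' tetrahedral geometry; hydroxyl and methyl hydrogens are placed at an
#' explicit reference dihedral. Bond lengths: C-H 1.09, N-H 1.01, O-H 0.96 A.
#'
#' @param heavy_center 3-vector, the atom carrying the hydrogens.
#' @param bonded_heavies n x 3 matrix of its known heavy neighbours, ordered;
#'   for the dihedral-placed cases the first row must be preceded by
#'   `dihedral_ref` (the atom bonded to `bonded_heavies[1,]`).
#' @param n_h number of hydrogens to build (1-3).
#' @param element element of `heavy_center` ("C", "N" or "O"), sets the bond
#'   length.
#' @param dihedral_ref 3-vector: reference atom defining the dihedral
#'   `dihedral(dihedral_ref, bonded_heavies[1,], heavy_center, H)`; required
#'   when only one heavy neighbour is known.
#' @param reference_dihedral degrees; dihedral at which the (first) hydrogen
#'   is placed in the one-neighbour case. Further methyl hydrogens follow at
#'   +120 and +240 degrees.
#' @return n_h x 3 matrix of hydrogen positions.
#' @export
build_hydrogens <- function(heavy_center, bonded_heavies, n_h,
                            element = "C",
                            dihedral_ref = NULL, reference_dihedral = NULL) {
  x <- as.numeric(heavy_center)
  nb <- as_xyz_matrix(bonded_heavies)
  len <- switch(element, C = 1.09, N = 1.01, O = 0.96,
                stop("unsupported element for hydrogen construction: ", element))
  k <- nrow(nb)
  if (k == 3L && n_h == 1L) {
    u <- apply(nb, 1L, function(p) vunit(p - x))   # 3 columns
    dir <- -vunit(rowSums(u))
    return(matrix(x + len * dir, 1L, 3L))
  }
  if (k == 2L && n_h == 2L) {
    u1 <- vunit(nb[1L, ] - x); u2 <- vunit(nb[2L, ] - x)
    bis <- -vunit(u1 + u2)
    perp <- vunit(vcross(u1, u2))
    half <- (TET_ANGLE / 2) / DEG
    h1 <- x + len * (cos(half) * bis + sin(half) * perp)
    h2 <- x + len * (cos(half) * bis - sin(half) * perp)
    return(rbind(h1, h2))
  }
  if (k == 1L && n_h >= 1L && n_h <= 3L) {
    if (is.null(dihedral_ref) || is.null(reference_dihedral))
      stop("one known neighbour: dihedral_ref and reference_dihedral required")
    dihs <- reference_dihedral + 120 * seq_len(n_h) - 120
    hs <- t(vapply(dihs, function(d)
      place_internal(dihedral_ref, nb[1L, ], x, len, TET_ANGLE, d),
      numeric(3L)))
    return(hs)
  }
  stop("unsupported hybridization/neighbour count: ", k,
       " neighbours for ", n_h, " hydrogens")
}

# In-plane hydrogen on an sp2 ring atom with two ring neighbours: along the
# external bisector. Used for aromatic CH/NH when capping monomers.
build_sp2_hydrogen <- function(center, nb1, nb2, element = "C") {
  len <- switch(element, C = 1.09, N = 1.01, O = 0.96)
  u1 <- vunit(nb1 - center); u2 <- vunit(nb2 - center)
  center - len * vunit(u1 + u2)
}

# Rotation matrix about a unit axis (Rodrigues).
rotation_about_axis <- function(axis, angle_deg) {
  u <- vunit(axis); th <- angle_deg / DEG
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3L, 3L,
               byrow = TRUE)
  diag(3L) * ct + st * ux + (1 - ct) * (u %o% u)
}

# Uniform-ish random rotation from three random angles (adequate for
# invariance testing; not a Haar sample).
random_rigid_transform <- function(max_shift = 25) {
  r <- rotation_about_axis(c(1, 0, 0), stats::runif(1, 0, 360)) %*%
       rotation_about_axis(c(0, 1, 0), stats::runif(1, 0, 360)) %*%
       rotation_about_axis(c(0, 0, 1), stats::runif(1, 0, 360))
  structure(list(rotation = r,
                 translation = stats::runif(3L, -max_shift, max_shift),
                 rmsd = 0),
            class = "rigid_transform")
}

# ---- planar polygon tests (participation geometry) ----

# Orthonormal in-plane basis for a ring_plane.
plane_basis <- function(plane) {
  n <- plane$normal
  seed <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- vunit(vcross(n, seed))
  e2 <- vcross(n, e1)
  rbind(e1, e2)
}

# Perpendicular height above the plane and lateral offset outside the ring
# polygon (0 when the projection falls inside), for points against a ring.
# ring_xy: polygon vertices projected into the plane, in cyclic order.
project_to_plane <- function(points, plane, basis = plane_basis(plane)) {
  m <- as_xyz_matrix(points)
  rel <- sweep(m, 2L, plane$centroid)
  h <- as.numeric(rel %*% plane$normal)
  xy <- rel %*% t(basis)
  list(height = h, xy = xy)
}

point_in_polygon <- function(pt, poly) {
  # even-odd ray casting
  n <- nrow(poly); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2L]; yj <- poly[j, 2L]
    if ((yi > pt[2L]) != (yj > pt[2L])) {
      xcross <- poly[j, 1L] + (pt[2L] - yj) / (yi - yj) * (poly[i, 1L] - poly[j, 1L])
      if (pt[1L] < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(1, max(0, t))
  vnorm(p - (a + t * ab))
}

# Lateral offset of 2D points from a cyclic polygon: 0 inside, else the
# distance to the nearest edge.
polygon_offset <- function(xy, poly) {
  apply(xy, 1L, function(p) {
    if (point_in_polygon(p, poly)) return(0)
    n <- nrow(poly)
    min(vapply(seq_len(n), function(i) {
      j <- if (i == n) 1L else i + 1L
      dist_point_segment(p, poly[i, ], poly[j, ])
    }, numeric(1L)))
  })
}
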