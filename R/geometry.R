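# Low-level vector geometry shared by the grid scan, the genetic algorithm
# and the complex builder.  All coordinates are in Angstrom, all angles in
# degrees unless a name says otherwise.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Dihedral angle defined by four points
#'
#' Returns the torsion p1-p2-p3-p4 in degrees in the interval
#' \code{[-180, 180)}, using the standard atan2 formulation.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Dihedral angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  wrap_angle(ang)
}

# wrap to [-180, 180)
wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[x >= 180] <- x[x >= 180] - 360
  x
}

# angle a-b-c in degrees
bond_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Rodrigues rotation matrix about a unit axis
rotation_about_axis <- function(axis, theta_deg) {
  u <- unitv(axis)
  th <- deg2rad(theta_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux * ux * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy * uy * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz * uz * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

# rotate rows of xyz (n x 3) about the axis through `origin` with direction
# `axis` by theta_deg
rotate_points <- function(xyz, origin, axis, theta_deg) {
  R <- rotation_about_axis(axis, theta_deg)
  shifted <- sweep(xyz, 2L, origin)
  sweep(shifted %*% t(R), 2L, origin, FUN = "+")
}

# Natural extension reference frame (NeRF) placement: position atom D such
# that |D-C| = bond, angle(D,C,B) = angle_deg and torsion(D,C,B,A) =
# torsion_deg, given already-placed atoms C (parent), B, A.
place_atom_nerf <- function(C, B, A, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg)
  tor <- deg2rad(torsion_deg)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- unitv(C - B)
  n <- unitv(cross3(B - A, bc))
  M <- cbind(bc, cross3(n, bc), n)
  as.numeric(M %*% d2 + C)
}

# Kabsch: rotation R (3x3) minimizing || Q - P %*% t(R) ||, i.e. mapping
# rows of P onto rows of Q.  Proper rotation enforced.
kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  sv$v %*% D %*% t(sv$u)
}

#' Ideal octahedron vertex directions
#'
#' @return A 6 x 3 matrix of unit vectors along \code{+-x}, \code{+-y},
#'   \code{+-z}, the vertex directions of a regular octahedron centred at
#'   the origin.
#' @export
octahedron_vertices <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0),
        c(0, 1, 0), c(0, -1, 0),
        c(0, 0, 1), c(0, 0, -1))
}

#' Deviation of a donor arrangement from octahedral geometry
#'
#' For every pair of donor atoms the angle subtended at the metal is
#' compared with the nearest ideal octahedral value (90 or 180 degrees);
#' the root-mean-square of the deviations is returned.  A perfect
#' octahedron (or any subset of its vertices) scores 0.
#'
#' @param metal Numeric 3-vector, metal position (Angstrom).
#' @param donors Matrix (n x 3) of donor-atom positions; 2 to 6 rows.
#' @return RMS angular deviation in degrees (non-negative).
#' @export
octahedral_deviation <- function(metal, donors) {
  donors <- rbind(donors)
  n <- nrow(donors)
  if (n < 2L) stop("octahedral_deviation needs at least 2 donors")
  u <- sweep(donors, 2L, metal)
  u <- u / sqrt(rowSums(u * u))
  cosmat <- tcrossprod(u)
  idx <- which(upper.tri(cosmat))
  theta <- rad2deg(acos(pmax(-1, pmin(1, cosmat[idx]))))
  ideal <- ifelse(theta < 135, 90, 180)
  sqrt(mean((theta - ideal)^2))
}

#' Analytic overlap volume of two spheres
#'
#' Lens (spherical-cap intersection) volume of two spheres of radii
#' \code{r1}, \code{r2} at centre distance \code{d}; the engulfed case
#' returns the volume of the smaller sphere, disjoint spheres return 0.
#'
#' @param r1,r2 Sphere radii (Angstrom).
#' @param d Centre-centre distance (Angstrom); vectorized.
#' @return Overlap volume(s) in cubic Angstrom.
#' @export
sphere_overlap_volume <- function(r1, r2, d) {
  stopifnot(all(r1 > 0), all(r2 > 0), all(d >= 0))
  k <- max(length(r1), length(r2), length(d))
  r1 <- rep_len(r1, k); r2 <- rep_len(r2, k); d <- rep_len(d, k)
  v <- numeric(k)
  eng <- d <= abs(r1 - r2)
  v[eng] <- (4 / 3) * pi * pmin(r1[eng], r2[eng])^3
  lens <- !eng & d < (r1 + r2)
  if (any(lens)) {
    dd <- d[lens]; a <- r1[lens]; b <- r2[lens]
    v[lens] <- pi * (a + b - dd)^2 *
      (dd^2 + 2 * dd * (a + b) - 3 * (a - b)^2) / (12 * dd)
  }
  v
}

#' Van der Waals radii used for clash volumes
#'
#' Bondi radii for the elements occurring in peptides, with Al assigned
#' its ionic radius (the cation is far smaller than a neutral atom).
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, AL = 0.60)
}

#' Steric clash volume between two atom sets
#'
#' Sums the analytic sphere-sphere overlap volume over all probe/context
#' atom pairs.  Pairs listed in \code{exclude} (e.g. covalently bonded or
#' 1-3 neighbours, or members of the same first coordination sphere) are
#' skipped.
#'
#' @param probe_xyz Matrix (np x 3) of probe atom positions.
#' @param context_xyz Matrix (nc x 3) of context atom positions.
#' @param probe_elements,context_elements Character vectors of element
#'   symbols matching the rows of the coordinate matrices.
#' @param radii Named radii table (Angstrom), default [vdw_radii()].
#' @param exclude Optional two-column integer matrix of (probe row,
#'   context row) pairs to skip.
#' @return Total overlap volume in cubic Angstrom (>= 0).
#' @export
clash_volume <- function(probe_xyz, context_xyz, probe_elements,
                         context_elements, radii = vdw_radii(),
                         exclude = NULL) {
  probe_xyz <- rbind(probe_xyz)
  context_xyz <- rbind(context_xyz)
  np <- nrow(probe_xyz); nc <- nrow(context_xyz)
  if (np == 0L || nc == 0L) return(0)
  rp <- radii[toupper(probe_elements)]
  rc <- radii[toupper(context_elements)]
  if (anyNA(rp) || anyNA(rc)) {
    bad <- unique(c(probe_elements[is.na(rp)], context_elements[is.na(rc)]))
    stop("no van der Waals radius for element(s): ", paste(bad, collapse = ", "))
  }
  d2 <- outer(rowSums(probe_xyz^2), rowSums(context_xyz^2), "+") -
    2 * tcrossprod(probe_xyz, context_xyz)
  d2[d2 < 0] <- 0
  rsum <- outer(rp, rc, "+")
  mask <- d2 < rsum^2
  if (!is.null(exclude) && length(exclude)) {
    exclude <- rbind(exclude)
    mask[exclude] <- FALSE
  }
  if (!any(mask)) return(0)
  idx <- which(mask)
  pi_ <- ((idx - 1L) %% np) + 1L
  ci <- ((idx - 1L) %/% np) + 1L
  sum(sphere_overlap_volume(rp[pi_], rc[ci], sqrt(d2[idx])))
}

# deterministic uniform random rotation matrix (uses current RNG stream)
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- vnorm(q)
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}
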