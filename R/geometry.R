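# Geometry analytics on Cartesian structures: signed torsions, amide
# planarity, the distance H-bond criterion, rigid superposition and
# inter-group distances.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed torsion angle of four points
#'
#' IUPAC sign convention: looking from `p2` towards `p3`, a clockwise
#' rotation of the far bond relative to the near bond is positive. The
#' result lies in (-180, 180], with 180 preferred over -180, and is
#' antisymmetric under reversal of the point order.
#'
#' @param p1,p2,p3,p4 numeric length-3 vectors, Cartesian coordinates in
#'   Angstrom.
#' @return torsion angle in degrees.
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))  # 0, eclipsed
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)) # 180, anti
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-12 || sqrt(sum(b2^2)) < 1e-12 ||
      sqrt(sum(b3^2)) < 1e-12) {
    stop("undefined torsion: consecutive points coincide", call. = FALSE)
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("undefined torsion: three consecutive points are collinear", call. = FALSE)
  }
  u2 <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * u2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Atom map for named backbone torsions
#'
#' Binds the named backbone torsions of the dipeptide-ester scaffold
#' (psi_n, omega, phi_c, psi_c) to atom indices of a specific structure,
#' plus optional indices for the H-bond criterion (amino donor nitrogen
#' and amide hydrogen) and an amide-frame index set for superposition.
#' Index assignment is user input: element order in optimized geometries
#' is not standardized.
#'
#' @param psi_n,omega,phi_c,psi_c integer vectors of length 4 (1-based atom
#'   indices defining each torsion).
#' @param hbond_donor,amide_h optional single indices (amino N, amide H).
#' @param frame optional integer vector (>= 3 indices) of amide-moiety
#'   atoms used for alignment.
#' @return object of class `"atom_map"`.
#' @export
atom_map <- function(psi_n, omega, phi_c, psi_c,
                     hbond_donor = NA_integer_, amide_h = NA_integer_,
                     frame = integer(0)) {
  quads <- list(psi_n = psi_n, omega = omega, phi_c = phi_c, psi_c = psi_c)
  for (nm in names(quads)) {
    q <- as.integer(quads[[nm]])
    if (length(q) != 4L || anyNA(q) || any(q < 1L) || anyDuplicated(q)) {
      stop(sprintf("atom map for '%s' must be 4 distinct positive indices", nm),
           call. = FALSE)
    }
    quads[[nm]] <- q
  }
  out <- c(quads, list(hbond_donor = as.integer(hbond_donor),
                       amide_h = as.integer(amide_h),
                       frame = as.integer(frame)))
  class(out) <- "atom_map"
  out
}

#' Backbone torsions of a structure
#'
#' Evaluates the four named backbone torsions through [dihedral()] using
#' an [atom_map()].
#'
#' @param structure an `"xyz_structure"`.
#' @param map an `"atom_map"` valid for `structure`.
#' @return named numeric vector `c(psi_n=, omega=, phi_c=, psi_c=)`,
#'   degrees in (-180, 180].
#' @export
backbone_dihedrals <- function(structure, map) {
  stopifnot(inherits(structure, "xyz_structure"), inherits(map, "atom_map"))
  n <- n_atoms(structure)
  out <- c(psi_n = NA_real_, omega = NA_real_, phi_c = NA_real_, psi_c = NA_real_)
  for (nm in names(out)) {
    q <- map[[nm]]
    if (any(q > n)) {
      stop(sprintf("atom map for '%s' exceeds structure bounds (%d atoms)", nm, n),
           call. = FALSE)
    }
    val <- tryCatch(
      dihedral(structure$coords[q[1], ], structure$coords[q[2], ],
               structure$coords[q[3], ], structure$coords[q[4], ]),
      error = function(e) stop(sprintf("torsion '%s': %s", nm, conditionMessage(e)),
                               call. = FALSE))
    out[nm] <- val
  }
  out
}

#' Deviation of the amide torsion from planarity
#'
#' Angular distance of omega to the nearer of the two planar references
#' (0 for cis, 180 for trans), so the same rule serves both isomers.
#'
#' @param omega amide torsion(s), degrees.
#' @return deviation(s) in degrees, in `[0, 90]`.
#' @examples
#' planarity_deviation(169.5) # 10.5
#' @export
planarity_deviation <- function(omega) {
  pmin(angular_distance(omega, 0), angular_distance(omega, 180))
}

#' Amide-planarity distortion flag
#'
#' An amide bond counts as distorted when its torsion deviates from ideal
#' planarity by more than the tolerance (default 5 degrees).
#'
#' @param omega amide torsion(s), degrees.
#' @param tol planarity tolerance in degrees (default 5).
#' @return logical vector.
#' @export
is_distorted <- function(omega, tol = 5) {
  planarity_deviation(omega) > tol
}

#' Distance criterion for the amino/amide hydrogen bond
#'
#' The hydrogen bond between the N-terminal amino nitrogen and the amide
#' hydrogen is scored purely by the N...H distance: present when the
#' distance does not exceed the cutoff (inclusive), absent beyond it.
#'
#' @param dist_nh N...H distance(s), Angstrom.
#' @param cutoff distance cutoff, Angstrom (default 2.3).
#' @return logical vector.
#' @export
hbond_present <- function(dist_nh, cutoff = 2.3) {
  if (any(dist_nh < 0)) stop("distance must be non-negative", call. = FALSE)
  dist_nh <= cutoff
}

#' Least-squares rigid superposition
#'
#' Kabsch superposition of `mobile` onto `ref` over paired atoms:
#' rotation plus translation, with a determinant guard so reflections are
#' never introduced (molecular chirality is preserved). All atoms of
#' `mobile` are transformed.
#'
#' @param mobile,ref `"xyz_structure"` objects.
#' @param index_pairs two-column integer matrix; column 1 indexes atoms of
#'   `mobile`, column 2 the paired atoms of `ref`. At least 3
#'   non-collinear pairs are required.
#' @return list with `rmsd` (Angstrom, over paired atoms), `transformed`
#'   (all of `mobile`, moved), `rotation` (3x3) and `translation`
#'   (length 3).
#' @export
superpose <- function(mobile, ref, index_pairs) {
  stopifnot(inherits(mobile, "xyz_structure"), inherits(ref, "xyz_structure"))
  ip <- matrix(as.integer(index_pairs), ncol = 2)
  if (nrow(ip) < 3L) {
    stop("degenerate alignment: at least 3 atom pairs are required", call. = FALSE)
  }
  if (any(ip[, 1] > n_atoms(mobile)) || any(ip[, 2] > n_atoms(ref)) || any(ip < 1L)) {
    stop("index pairs exceed structure bounds", call. = FALSE)
  }
  A <- mobile$coords[ip[, 1], , drop = FALSE]
  B <- ref$coords[ip[, 2], , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  # collinear pair sets leave the rotation about the common axis undetermined
  if (qr(A0)$rank < 2L || qr(B0)$rank < 2L) {
    stop("degenerate alignment: paired atoms are collinear", call. = FALSE)
  }
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved_pairs <- sweep(A0 %*% t(R), 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((moved_pairs - B)^2)))
  all_moved <- sweep(sweep(mobile$coords, 2, ca) %*% t(R), 2, cb, "+")
  transformed <- xyz_structure(mobile$elements, all_moved, label = mobile$label)
  list(rmsd = rmsd, transformed = transformed, rotation = R,
       translation = as.numeric(cb - ca %*% t(R)))
}

#' Minimum inter-group distance
#'
#' Minimum pairwise Euclidean distance between two disjoint atom groups,
#' e.g. between the two tert-butyl groups of a strained cis geometry.
#'
#' @param structure an `"xyz_structure"`.
#' @param group_a,group_b disjoint, non-empty integer index vectors.
#' @return distance in Angstrom.
#' @export
min_group_distance <- function(structure, group_a, group_b) {
  stopifnot(inherits(structure, "xyz_structure"))
  group_a <- as.integer(group_a)
  group_b <- as.integer(group_b)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups must be disjoint", call. = FALSE)
  }
  n <- n_atoms(structure)
  if (any(c(group_a, group_b) < 1L) || any(c(group_a, group_b) > n)) {
    stop("group indices exceed structure bounds", call. = FALSE)
  }
  A <- structure$coords[group_a, , drop = FALSE]
  B <- structure$coords[group_b, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}
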