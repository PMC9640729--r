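#' Alpha-shape surface extraction with solid-angle convexity
#'
#' Builds the weighted alpha complex of the atoms (point weights `w^2`, with
#' `w` the atom weight column) and reports, per atom: whether it lies on the
#' complex boundary (a "surface atom"), its solid angle `omega` (steradians,
#' summed over incident alpha-complex tetrahedra), the convexity score
#' `omega_prime = cos(omega)/4`, and the convex/concave label.
#'
#' At the default `alpha = 0` the complex boundary is the weighted alpha
#' shape dual to the space-filling model, the standard molecular-surface
#' choice.  Atoms incident to no tetrahedron at all are exposed and reported
#' as surface with `omega = NA`.  Degenerate (cospherical) configurations
#' are resolved by a deterministic symbolic perturbation keyed on atom
#' serial, so repeated runs are identical.  Solid angles are evaluated on
#' the unperturbed coordinates.
#'
#' @param atoms an atom tibble (see [atom_table()]); needs at least 4 atoms
#'   in non-coplanar position.
#' @param alpha alpha parameter, squared-length units (angstrom^2).
#' @return a tibble with one row per atom: `serial`, `on_surface`,
#'   `n_incident`, `omega`, `omega_prime`, `shape_label` (`"convex"` /
#'   `"concave"`, `NA` off-surface or for tetrahedron-free atoms),
#'   `boundary_score` (TRUE when `omega_prime` is 0 within 1e-12) and
#'   `high_omega` (TRUE when `omega > 2*pi`; such atoms are nearly enclosed
#'   yet score positive, and are flagged rather than reinterpreted).
#'   Attributes: `alpha`, `tetrahedra` (m x 4 serial matrix),
#'   `boundary_facets` (b x 3 serial matrix).
#' @examples
#' tet <- atom_table(1:4, c(0, 2, 0, 0), c(0, 0, 2, 0), c(0, 0, 0, 2))
#' alpha_surface(tet, alpha = 0)
#' @export
alpha_surface <- function(atoms, alpha = 0) {
  validate_atoms(atoms)
  if (nrow(atoms) < 4)
    abort("degenerate geometry: need at least 4 atoms")
  pos <- cbind(atoms$x, atoms$y, atoms$z)
  sv <- svd(scale(pos, scale = FALSE))$d
  if (sv[3] < 1e-9 * (sv[1] + 1e-300))
    abort("degenerate geometry: atom positions are coplanar")

  scale_hint <- max(apply(pos, 2, function(v) diff(range(v)))) + 1
  res <- .alpha_complex_cpp(pos, atoms$weight^2, atoms$serial,
                            alpha, 1e-7 * scale_hint)
  omega <- ifelse(res$n_incident > 0, res$omega, NA_real_)
  cls <- classify_convexity(omega)
  out <- tibble(
    serial = atoms$serial,
    on_surface = as.logical(res$on_surface),
    n_incident = as.integer(res$n_incident),
    omega = omega,
    omega_prime = cls$omega_prime,
    shape_label = ifelse(as.logical(res$on_surface), cls$shape_label,
                         NA_character_),
    boundary_score = cls$boundary_score,
    high_omega = !is.na(omega) & omega > 2 * pi
  )
  tetra <- res$tetra; bf <- res$boundary_facets
  tetra[] <- atoms$serial[tetra]
  if (length(bf) > 0) bf[] <- atoms$serial[bf]
  attr(out, "alpha") <- alpha
  attr(out, "tetrahedra") <- tetra
  attr(out, "boundary_facets") <- bf
  class(out) <- c("bindresp_surface", class(out))
  out
}

#' Convexity classification from a solid angle
#'
#' The convexity score is `omega_prime = cos(omega)/4`, positive for a
#' protruding (convex) atom and negative for a recessed (concave) one.  A
#' score of exactly 0 (within `tol`) is classified concave by convention and
#' flagged via `boundary_score`.
#'
#' @param omega solid angle(s), steradians; `NA` propagates.
#' @param tol tolerance for the zero-score tie-break.
#' @return tibble with `omega_prime`, `shape_label`, `boundary_score`.
#' @examples
#' classify_convexity(c(0, pi, pi / 2))
#' @export
classify_convexity <- function(omega, tol = 1e-12) {
  op <- cos(omega) / 4
  boundary <- !is.na(op) & abs(op) <= tol
  label <- ifelse(is.na(op), NA_character_,
                  ifelse(op > tol, "convex", "concave"))
  tibble(omega_prime = op, shape_label = label, boundary_score = boundary)
}

#' Solid angle at a vertex from incident tetrahedra
#'
#' For each tetrahedron the contribution is the sum of the three dihedral
#' angles along the edges meeting at the vertex, minus pi; contributions are
#' summed over tetrahedra.  For tetrahedra tiling a full neighbourhood the
#' total is `4*pi`.
#'
#' @param vertex numeric length-3 position.
#' @param tetrahedra list of 4x3 coordinate matrices, each containing
#'   `vertex` as one of its rows (within `tol`).
#' @param tol matching tolerance for locating `vertex` among the rows.
#' @return solid angle in steradians.
#' @examples
#' solid_angle_at_vertex(c(0, 0, 0), list(rbind(c(0, 0, 0), diag(3))))
#' @export
solid_angle_at_vertex <- function(vertex, tetrahedra, tol = 1e-9) {
  stopifnot(length(vertex) == 3)
  total <- 0
  for (tet in tetrahedra) {
    tet <- as.matrix(tet)
    if (!all(dim(tet) == c(4, 3)))
      abort("each tetrahedron must be a 4x3 coordinate matrix")
    d <- sqrt(rowSums((tet - matrix(vertex, 4, 3, byrow = TRUE))^2))
    iv <- which(d <= tol)
    if (length(iv) != 1)
      abort("vertex must match exactly one row of each tetrahedron")
    rest <- tet[-iv, , drop = FALSE]
    if (abs(det(sweep(rest, 2, vertex))) < 1e-12)
      abort("degenerate (zero-volume) tetrahedron")
    total <- total +
      dihedral_angle(vertex, rest[1, ], rest[2, ], rest[3, ]) +
      dihedral_angle(vertex, rest[2, ], rest[1, ], rest[3, ]) +
      dihedral_angle(vertex, rest[3, ], rest[1, ], rest[2, ]) - pi
  }
  total
}

# interior dihedral angle along edge (v, a) of tetrahedron (v, a, b, c)
dihedral_angle <- function(v, a, b, c) {
  e <- a - v
  n1 <- cross3(e, b - v)
  n2 <- cross3(e, c - v)
  atan2(sqrt(sum(cross3(n1, n2)^2)), sum(n1 * n2))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Orthogonality relation between two weighted atoms
#'
#' Two weighted atoms `(p1, w1)`, `(p2, w2)` are orthogonal when their
#' spheres are tangent, `|p1 - p2| = w1 + w2`, and sub-orthogonal when the
#' spheres overlap, `|p1 - p2| < w1 + w2`.
#'
#' @param a1,a2 one-row atom tibbles (or any lists with `x`, `y`, `z`,
#'   `weight`).
#' @param tolerance tangency tolerance in angstroms.
#' @return tibble with `relation` (`"orthogonal"`, `"sub_orthogonal"`,
#'   `"neither"`) and `gap` (`|p1 - p2| - (w1 + w2)`).
#' @examples
#' a <- atom_table(1:2, c(0, 5), c(0, 0), c(0, 0), weight = c(2, 3))
#' orthogonality(a[1, ], a[2, ])
#' @export
orthogonality <- function(a1, a2, tolerance = 1e-9) {
  d <- sqrt((a1$x - a2$x)^2 + (a1$y - a2$y)^2 + (a1$z - a2$z)^2)
  if (d < 1e-12)
    abort("coincident atom positions")
  gap <- d - (a1$weight + a2$weight)
  relation <- if (abs(gap) <= tolerance) "orthogonal"
              else if (gap < 0) "sub_orthogonal"
              else "neither"
  tibble(relation = relation, gap = gap)
}
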