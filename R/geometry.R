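# Geometric predicates and measures for the tessellation kernel.
#
# Predicates are evaluated on determinants normalised by the sum of the
# absolute monomials, so the fixed tolerance .TOL_PREDICATE is
# scale-invariant. Values within tolerance of zero are reported as 0
# (collinear / cocircular); the triangulator resolves such ties
# deterministically (ties are never carved).

.as_simplex_matrix <- function(simplex) {
  if (is.list(simplex) && !is.data.frame(simplex))
    simplex <- do.call(rbind, simplex)
  m <- as.matrix(simplex)
  storage.mode(m) <- "double"
  m
}

.check_simplex <- function(m) {
  d <- ncol(m)
  if (!(d %in% c(2L, 3L)))
    .vc_stop("vcellsim_invalid_input", "simplex vertices must be 2D or 3D")
  if (nrow(m) != d + 1L)
    .vc_stop("vcellsim_invalid_input",
             "a %dD simplex needs %d vertices, got %d", d, d + 1L, nrow(m))
  if (!all(is.finite(m)))
    .vc_stop("vcellsim_invalid_input", "non-finite coordinate in simplex")
  m
}

#' Orientation of a simplex
#'
#' Sign of the orientation determinant of 3 points in 2D or 4 points in 3D:
#' `+1` for counter-clockwise / positively oriented, `-1` for the opposite
#' orientation, and `0` when the points are collinear (2D) or coplanar (3D)
#' within the kernel tolerance.
#'
#' @param simplex a numeric matrix with one vertex per row (3x2 or 4x3), or a
#'   list of coordinate vectors.
#' @return integer in `-1, 0, +1`.
#' @examples
#' orientation(rbind(c(0, 0), c(1, 0), c(0, 1)))  # +1
#' orientation(rbind(c(0, 0), c(1, 1), c(2, 2)))  # 0, collinear
#' @export
orientation <- function(simplex) {
  m <- .check_simplex(.as_simplex_matrix(simplex))
  v <- .cpp_orient(m)
  if (abs(v) <= .TOL_PREDICATE) return(0L)
  as.integer(sign(v))
}

#' Position of a point relative to a simplex circumball
#'
#' Implements the Delaunay empty-circumball test: `+1` if `query` lies
#' strictly inside the circumcircle (2D) / circumsphere (3D) of the simplex,
#' `-1` strictly outside, `0` on the boundary within tolerance. The result
#' does not depend on the ordering of the simplex vertices.
#'
#' @param simplex as in [orientation()]; must be non-degenerate.
#' @param query numeric coordinate vector of the same dimension.
#' @return integer in `-1, 0, +1`.
#' @examples
#' tri <- rbind(c(0, 0), c(2, 0), c(0, 2))
#' in_circumball(tri, c(1, 1))  # +1 (the circumcenter)
#' in_circumball(tri, c(2, 2))  # 0  (cocircular corner)
#' @export
in_circumball <- function(simplex, query) {
  m <- .check_simplex(.as_simplex_matrix(simplex))
  query <- as.numeric(query)
  if (length(query) != ncol(m) || !all(is.finite(query)))
    .vc_stop("vcellsim_invalid_input", "query point has wrong dimension")
  if (orientation(m) == 0L)
    .vc_stop("vcellsim_degenerate_simplex",
             "in_circumball: degenerate (collinear/coplanar) simplex")
  v <- .cpp_insphere(m, query)
  if (abs(v) <= .TOL_PREDICATE) return(0L)
  as.integer(sign(v))
}

#' Circumscribing ball of a simplex
#'
#' Center and radius of the circumcircle (2D) or circumsphere (3D); the
#' center is equidistant from all simplex vertices.
#'
#' @inheritParams orientation
#' @return a list with elements `center` (numeric vector) and `radius`
#'   (non-negative scalar), of class `"dv_ball"`.
#' @examples
#' circumball(rbind(c(0, 0), c(2, 0), c(0, 2)))  # center (1,1), radius sqrt(2)
#' @export
circumball <- function(simplex) {
  m <- .check_simplex(.as_simplex_matrix(simplex))
  if (orientation(m) == 0L)
    .vc_stop("vcellsim_degenerate_simplex",
             "circumball: degenerate (collinear/coplanar) simplex")
  d <- ncol(m)
  a <- m[1L, ]
  rows <- m[-1L, , drop = FALSE]
  A <- 2 * sweep(rows, 2L, a)
  b <- rowSums(rows^2) - sum(a^2)
  center <- as.numeric(solve(A, b))
  radius <- sqrt(sum((center - a)^2))
  structure(list(center = center, radius = radius), class = "dv_ball")
}

#' @export
print.dv_ball <- function(x, ...) {
  cat(sprintf("circumball: center (%s), radius %.6g\n",
              paste(signif(x$center, 8), collapse = ", "), x$radius))
  invisible(x)
}

#' Area of a simple polygon
#'
#' Shoelace area of a polygon given by its boundary vertices in order
#' (either orientation); the absolute value is returned.
#'
#' @param vertices numeric matrix (n x 2) of boundary vertices in boundary
#'   order, not necessarily closed.
#' @return non-negative area.
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L || ncol(v) != 2L)
    .vc_stop("vcellsim_invalid_input",
             "polygon_area needs at least 3 vertices in 2D")
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Volume of a closed convex polyhedral surface
#'
#' The surface is given as a set of faces, each an ordered coordinate ring.
#' Volume is computed by signed-tetrahedra decomposition from an interior
#' reference point (the vertex centroid); because the region is convex and
#' the reference point interior, each face contribution is taken in absolute
#' value, making the result independent of face orientation.
#'
#' A closed-surface check requires every undirected edge to be shared by
#' exactly two faces.
#'
#' @param faces list of numeric matrices (one ring per face, rows are 3D
#'   vertices in boundary order).
#' @return non-negative volume.
#' @export
polyhedron_volume <- function(faces) {
  if (!is.list(faces) || length(faces) < 4L)
    .vc_stop("vcellsim_invalid_input",
             "polyhedron_volume needs a list of at least 4 faces")
  faces <- lapply(faces, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3L || nrow(f) < 3L)
      .vc_stop("vcellsim_invalid_input", "each face must be a ring of 3D points")
    f
  })
  # closed-surface check on vertex keys (rounded to merge fp twins)
  key <- function(p) paste(signif(p, 12), collapse = ",")
  edge_count <- new.env(parent = emptyenv())
  for (f in faces) {
    n <- nrow(f)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      ks <- sort(c(key(f[i, ]), key(f[j, ])))
      ek <- paste(ks, collapse = "|")
      edge_count[[ek]] <- (edge_count[[ek]] %||% 0L) + 1L
    }
  }
  counts <- unlist(as.list(edge_count))
  if (length(counts) == 0L || any(counts != 2L))
    .vc_stop("vcellsim_invalid_surface",
             "faces do not form a closed surface (%d edges with count != 2)",
             sum(counts != 2L))
  allv <- do.call(rbind, faces)
  ref <- colMeans(allv)
  total <- 0
  for (f in faces) {
    n <- nrow(f)
    s <- 0
    for (i in 2:(n - 1L)) {
      u <- f[1L, ] - ref; v <- f[i, ] - ref; w <- f[i + 1L, ] - ref
      s <- s + (u[1] * (v[2] * w[3] - v[3] * w[2]) -
                u[2] * (v[1] * w[3] - v[3] * w[1]) +
                u[3] * (v[1] * w[2] - v[2] * w[1])) / 6
    }
    total <- total + abs(s)
  }
  total
}
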