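# Delaunay mesh construction and Voronoi V-cell extraction.
#
# The mesh is rebuilt from scratch whenever generators change (see the
# engine); at the problem sizes this framework targets (n up to a few
# thousand) a full rebuild is cheap and removes a whole class of incremental
# update bugs.

.points_to_matrix <- function(points) {
  if (is.data.frame(points)) {
    cols <- intersect(c("x", "y", "z"), names(points))
    if (!all(c("x", "y") %in% cols) || !("id" %in% names(points)))
      .vc_stop("vcellsim_invalid_input",
               "points data.frame needs columns id, x, y and optionally z")
    z <- if ("z" %in% cols) points$z else NULL
    d <- if (!is.null(z) && !all(is.na(z))) 3L else 2L
    if (d == 3L && any(is.na(z)))
      .vc_stop("vcellsim_invalid_input", "mixed 2D/3D coordinates")
    m <- cbind(points$x, points$y, if (d == 3L) points$z)
    ids <- as.integer(points$id)
  } else {
    m <- as.matrix(points)
    ids <- if (!is.null(rownames(m))) as.integer(rownames(m)) else seq_len(nrow(m))
  }
  storage.mode(m) <- "double"
  if (anyDuplicated(ids))
    .vc_stop("vcellsim_invalid_input", "generator ids must be unique")
  if (!all(is.finite(m)))
    .vc_stop("vcellsim_invalid_input", "non-finite generator coordinate")
  list(coords = m, ids = ids)
}

# vectorised circumcenters for all simplices (rows of `simp` index `coords`)
.circumcenters <- function(coords, simp) {
  d <- ncol(coords)
  if (d == 2L) {
    a <- coords[simp[, 1L], , drop = FALSE]
    b <- coords[simp[, 2L], , drop = FALSE]
    c <- coords[simp[, 3L], , drop = FALSE]
    an <- rowSums(a^2); bn <- rowSums(b^2); cn <- rowSums(c^2)
    den <- 2 * (a[, 1] * (b[, 2] - c[, 2]) + b[, 1] * (c[, 2] - a[, 2]) +
                c[, 1] * (a[, 2] - b[, 2]))
    ux <- (an * (b[, 2] - c[, 2]) + bn * (c[, 2] - a[, 2]) + cn * (a[, 2] - b[, 2])) / den
    uy <- (an * (c[, 1] - b[, 1]) + bn * (a[, 1] - c[, 1]) + cn * (b[, 1] - a[, 1])) / den
    ctr <- cbind(ux, uy)
  } else {
    a <- coords[simp[, 1L], , drop = FALSE]
    u <- coords[simp[, 2L], , drop = FALSE] - a
    v <- coords[simp[, 3L], , drop = FALSE] - a
    w <- coords[simp[, 4L], , drop = FALSE] - a
    r1 <- rowSums(u^2) / 2; r2 <- rowSums(v^2) / 2; r3 <- rowSums(w^2) / 2
    # Cramer's rule on rows u, v, w
    cvw1 <- v[, 2] * w[, 3] - v[, 3] * w[, 2]
    cvw2 <- v[, 3] * w[, 1] - v[, 1] * w[, 3]
    cvw3 <- v[, 1] * w[, 2] - v[, 2] * w[, 1]
    det <- u[, 1] * cvw1 + u[, 2] * cvw2 + u[, 3] * cvw3
    cwu1 <- w[, 2] * u[, 3] - w[, 3] * u[, 2]
    cwu2 <- w[, 3] * u[, 1] - w[, 1] * u[, 3]
    cwu3 <- w[, 1] * u[, 2] - w[, 2] * u[, 1]
    cuv1 <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cuv2 <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cuv3 <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    x <- (r1 * cvw1 + r2 * cwu1 + r3 * cuv1) / det
    y <- (r1 * cvw2 + r2 * cwu2 + r3 * cuv2) / det
    z <- (r1 * cvw3 + r2 * cwu3 + r3 * cuv3) / det
    ctr <- a + cbind(x, y, z)
  }
  radii <- sqrt(rowSums((ctr - coords[simp[, 1L], , drop = FALSE])^2))
  list(centers = ctr, radii = radii)
}

#' Delaunay triangulation / tetrahedralization of generator points
#'
#' Builds the Delaunay simplicial complex over a set of generator points by
#' incremental Bowyer-Watson insertion (ascending id order), with cached
#' circumball centers and radii for the Voronoi dual. Cocircular /
#' cospherical ties are never carved; in 2D remaining cocircular ambiguity is
#' canonicalised so the chosen diagonal passes through the lexicographically
#' smallest vertex.
#'
#' @param points a data.frame with columns `id`, `x`, `y` and optionally `z`,
#'   or a numeric matrix (one point per row; rownames taken as ids).
#' @return an object of class `"dv_mesh"`: list with `dim`, `ids`, `coords`
#'   (rows named by id), `simplices` (matrix of generator ids, one simplex
#'   per row), `centers` and `radii` (circumballs, one per simplex), and
#'   `hull_ids` (generators on the convex hull).
#' @examples
#' m <- triangulate(data.frame(id = 1:4, x = c(0, 3, 0, 4), y = c(0, 0, 3, 4)))
#' m$simplices
#' @export
triangulate <- function(points) {
  pm <- .points_to_matrix(points)
  coords <- pm$coords; ids <- pm$ids
  d <- ncol(coords)
  n <- nrow(coords)
  if (n < d + 1L)
    .vc_stop("vcellsim_cannot_triangulate",
             "need at least %d points in %dD, got %d", d + 1L, d, n)
  # ascending-id insertion order
  ord <- order(ids)
  coords <- coords[ord, , drop = FALSE]
  ids <- ids[ord]
  diam <- sqrt(sum((apply(coords, 2L, max) - apply(coords, 2L, min))^2))
  if (diam == 0)
    .vc_stop("vcellsim_duplicate_point", "all points coincide")
  dmin <- min(dist(coords))
  if (dmin < .DUP_FACTOR * diam)
    .vc_stop("vcellsim_duplicate_point",
             "points closer than %.3g (duplicate-point threshold)",
             .DUP_FACTOR * diam)
  res <- tryCatch(
    .cpp_delaunay(coords, .TOL_PREDICATE),
    error = function(e) {
      if (grepl("cannot-triangulate", conditionMessage(e)))
        .vc_stop("vcellsim_cannot_triangulate", "%s", conditionMessage(e))
      stop(e)
    }
  )
  simp <- res$simplices
  if (d == 2L) simp <- .canonicalize_ties_2d(coords, simp)
  cb <- .circumcenters(coords, simp)
  simp_ids <- matrix(ids[simp], nrow = nrow(simp))
  rownames(coords) <- as.character(ids)
  structure(list(
    dim = d,
    ids = ids,
    coords = coords,
    simplices = simp_ids,
    centers = cb$centers,
    radii = cb$radii,
    hull_ids = sort(ids[res$hull])
  ), class = "dv_mesh")
}

# Lawson-style pass over cocircular adjacent triangle pairs: among the two
# valid diagonals of a cocircular convex quad, keep the one through the
# lexicographically smallest of its four vertices (deterministic tie-break).
.canonicalize_ties_2d <- function(coords, simp) {
  lex_rank <- order(coords[, 1L], coords[, 2L])
  rank_of <- integer(nrow(coords)); rank_of[lex_rank] <- seq_len(nrow(coords))
  max_pass <- 10L + 2L * nrow(simp)   # one flip per pass; ties are few
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    # edge -> triangle incidence (vectorised)
    e1 <- c(simp[, 1L], simp[, 1L], simp[, 2L])
    e2 <- c(simp[, 2L], simp[, 3L], simp[, 3L])
    keys <- paste(pmin(e1, e2), pmax(e1, e2))
    tri_idx <- rep(seq_len(nrow(simp)), 3L)
    dup <- keys %in% keys[duplicated(keys)]
    shared <- split(tri_idx[dup], keys[dup])
    shared <- shared[lengths(shared) == 2L]
    if (length(shared)) {
      # cheap cocircularity pre-filter: opposite vertex of t2 must sit on
      # t1's circumcircle for the pair to be a genuine tie
      cb <- .circumcenters(coords, simp)
      near <- vapply(shared, function(pair) {
        t1 <- simp[pair[1L], ]; t2 <- simp[pair[2L], ]
        o2 <- setdiff(t2, t1)
        if (length(o2) != 1L) return(FALSE)
        abs(sqrt(sum((cb$centers[pair[1L], ] - coords[o2, ])^2)) -
              cb$radii[pair[1L]]) <= 1e-9 * cb$radii[pair[1L]]
      }, TRUE)
      shared <- shared[near]
    }
    for (pair in shared) {
      t1 <- simp[pair[1L], ]; t2 <- simp[pair[2L], ]
      common <- intersect(t1, t2)
      o1 <- setdiff(t1, common); o2 <- setdiff(t2, common)
      if (length(o1) != 1L || length(o2) != 1L) next
      v <- .cpp_insphere(coords[t1, , drop = FALSE], coords[o2, ])
      if (abs(v) > .TOL_PREDICATE) next           # not cocircular
      quad <- c(common, o1, o2)
      best <- quad[which.min(rank_of[quad])]
      if (best %in% common) next                   # current diagonal already ok
      # flip only if the quad is strictly convex (both new triangles valid)
      n1 <- c(o1, o2, common[1L]); n2 <- c(o1, o2, common[2L])
      s1 <- .cpp_orient(coords[n1, , drop = FALSE])
      s2 <- .cpp_orient(coords[n2, , drop = FALSE])
      if (abs(s1) <= .TOL_PREDICATE || abs(s2) <= .TOL_PREDICATE) next
      a1 <- .cpp_orient(coords[c(common[1L], o1, o2), , drop = FALSE])
      a2 <- .cpp_orient(coords[c(common[2L], o1, o2), , drop = FALSE])
      if (sign(a1) == sign(a2)) next               # not convex across diagonal
      simp[pair[1L], ] <- n1
      simp[pair[2L], ] <- n2
      changed <- TRUE
      break                                        # incidence is stale; rescan
    }
    if (!changed) break
  }
  simp
}

#' @export
print.dv_mesh <- function(x, ...) {
  cat(sprintf("dv_mesh: %dD, %d generators, %d simplices, %d on hull\n",
              x$dim, length(x$ids), nrow(x$simplices), length(x$hull_ids)))
  invisible(x)
}

.check_mesh_id <- function(mesh, generator_id) {
  if (!(generator_id %in% mesh$ids))
    .vc_stop("vcellsim_unknown_generator",
             "generator %s not in mesh", format(generator_id))
}

#' 1-hop Delaunay neighborhood of a generator
#'
#' The set of generator ids joined to `generator_id` by a Delaunay edge:
#' the agent's entire observable environment.
#'
#' @param mesh a `"dv_mesh"`.
#' @param generator_id a generator id present in the mesh.
#' @return sorted integer vector of neighbor ids (never contains the
#'   generator itself).
#' @export
neighbors <- function(mesh, generator_id) {
  .check_mesh_id(mesh, generator_id)
  hit <- rowSums(mesh$simplices == generator_id) > 0L
  sort(setdiff(unique(as.vector(mesh$simplices[hit, , drop = FALSE])),
               generator_id))
}

#' Generators on the convex hull
#'
#' Generators whose Voronoi cells are unbounded. Biological agents must never
#' appear here; the media enclosure convention exists precisely to keep them
#' off the hull.
#'
#' @inheritParams neighbors
#' @return sorted integer vector of ids.
#' @export
hull_generators <- function(mesh) {
  stopifnot(inherits(mesh, "dv_mesh"))
  mesh$hull_ids
}

#' Voronoi cell (V-cell) of a generator
#'
#' In 2D the V-cell boundary is the ring of circumcircle centers of the
#' triangles incident to the generator, ordered angularly around it. In 3D
#' the cell has one face per Delaunay neighbor; each face is the ring of
#' circumsphere centers of the tetrahedra incident to the shared Delaunay
#' edge, ordered cyclically around that edge.
#'
#' @inheritParams neighbors
#' @return an object of class `"dv_vcell"`: `generator_id`, `dim`,
#'   `boundary` (2D: vertex matrix; 3D: named list of face rings, one per
#'   neighbor id), `measure` (area or volume), `bounded` (always `TRUE`;
#'   hull generators raise an unbounded-cell error instead).
#' @export
vcell <- function(mesh, generator_id) {
  .check_mesh_id(mesh, generator_id)
  if (generator_id %in% mesh$hull_ids)
    .vc_stop("vcellsim_unbounded_cell",
             "generator %d lies on the convex hull; its V-cell is unbounded (enclose the scenario in media)",
             generator_id)
  g <- mesh$coords[as.character(generator_id), ]
  inc <- which(rowSums(mesh$simplices == generator_id) > 0L)
  if (mesh$dim == 2L) {
    ctr <- mesh$centers[inc, , drop = FALSE]
    ang <- atan2(ctr[, 2L] - g[2L], ctr[, 1L] - g[1L])
    ring <- ctr[order(ang), , drop = FALSE]
    measure <- polygon_area(ring)
    boundary <- ring
  } else {
    nb <- neighbors(mesh, generator_id)
    boundary <- vector("list", length(nb))
    names(boundary) <- as.character(nb)
    vol <- 0
    for (k in seq_along(nb)) {
      q <- mesh$coords[as.character(nb[k]), ]
      both <- inc[rowSums(mesh$simplices[inc, , drop = FALSE] == nb[k]) > 0L]
      ctr <- mesh$centers[both, , drop = FALSE]
      if (nrow(ctr) < 3L)
        .vc_stop("vcellsim_unbounded_cell",
                 "open circumcenter fan around edge (%d,%d)", generator_id, nb[k])
      axis <- q - g
      axis <- axis / sqrt(sum(axis^2))
      # orthonormal basis in the face plane
      seed <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- seed - sum(seed * axis) * axis
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(axis[2L] * e1[3L] - axis[3L] * e1[2L],
              axis[3L] * e1[1L] - axis[1L] * e1[3L],
              axis[1L] * e1[2L] - axis[2L] * e1[1L])
      # order around the face's own centroid: the edge midpoint (axis
      # crossing) can lie outside the face for non-Gabriel Delaunay edges
      rel <- sweep(ctr, 2L, colMeans(ctr))
      ang <- atan2(rel %*% e2, rel %*% e1)
      face <- ctr[order(ang), , drop = FALSE]
      boundary[[k]] <- face
      # signed fan volume of the pyramid (generator apex, face base)
      s <- 0
      for (i in 2:(nrow(face) - 1L)) {
        u <- face[1L, ] - g; v <- face[i, ] - g; w <- face[i + 1L, ] - g
        s <- s + (u[1] * (v[2] * w[3] - v[3] * w[2]) -
                  u[2] * (v[1] * w[3] - v[3] * w[1]) +
                  u[3] * (v[1] * w[2] - v[2] * w[1])) / 6
      }
      vol <- vol + abs(s)
    }
    measure <- vol
  }
  structure(list(
    generator_id = generator_id,
    dim = mesh$dim,
    boundary = boundary,
    measure = as.numeric(measure),
    bounded = TRUE
  ), class = "dv_vcell")
}

#' @export
print.dv_vcell <- function(x, ...) {
  nv <- if (x$dim == 2L) nrow(x$boundary) else sum(vapply(x$boundary, nrow, 1L))
  cat(sprintf("dv_vcell of generator %d (%dD): %d boundary vertices, %s = %.6g\n",
              x$generator_id, x$dim, nv,
              if (x$dim == 2L) "area" else "volume", x$measure))
  invisible(x)
}

#' Area (2D) or volume (3D) of a generator's V-cell
#'
#' @inheritParams neighbors
#' @return non-negative measure.
#' @export
vcell_measure <- function(mesh, generator_id) {
  vcell(mesh, generator_id)$measure
}
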