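# Independent oracles used by the unit and acceptance tests. These are
# deliberately brute-force (enumeration over all triples/quadruples,
# half-plane clipping against *all* other generators) and share no code with
# the incremental Bowyer-Watson / dual-extraction paths they check.

# --- brute-force Delaunay edge sets -----------------------------------------

# 2D: a triangle is Delaunay iff no other point lies strictly inside its
# circumcircle; edges are collected from all such triangles.
oracle_delaunay_edges_2d <- function(p, tol = 1e-9) {
  n <- nrow(p)
  tri <- combn(n, 3L)
  edges <- NULL
  for (k in seq_len(ncol(tri))) {
    ijk <- tri[, k]
    A <- 2 * rbind(p[ijk[2], ] - p[ijk[1], ], p[ijk[3], ] - p[ijk[1], ])
    if (abs(det(A)) < 1e-13) next
    b <- c(sum(p[ijk[2], ]^2) - sum(p[ijk[1], ]^2),
           sum(p[ijk[3], ]^2) - sum(p[ijk[1], ]^2))
    ctr <- solve(A, b)
    r <- sqrt(sum((p[ijk[1], ] - ctr)^2))
    dd <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
    dd[ijk] <- Inf
    if (all(dd >= r * (1 - tol)))
      edges <- rbind(edges, cbind(ijk[c(1, 1, 2)], ijk[c(2, 3, 3)]))
  }
  unique(cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
}

# 3D analogue over all quadruples / circumspheres
oracle_delaunay_edges_3d <- function(p, tol = 1e-9) {
  n <- nrow(p)
  quad <- combn(n, 4L)
  edges <- NULL
  pairs <- combn(4L, 2L)
  for (k in seq_len(ncol(quad))) {
    q <- quad[, k]
    A <- 2 * rbind(p[q[2], ] - p[q[1], ], p[q[3], ] - p[q[1], ],
                   p[q[4], ] - p[q[1], ])
    if (abs(det(A)) < 1e-13) next
    b <- c(sum(p[q[2], ]^2), sum(p[q[3], ]^2), sum(p[q[4], ]^2)) - sum(p[q[1], ]^2)
    ctr <- solve(A, b)
    r <- sqrt(sum((p[q[1], ] - ctr)^2))
    dd <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2 + (p[, 3] - ctr[3])^2)
    dd[q] <- Inf
    if (all(dd >= r * (1 - tol)))
      edges <- rbind(edges, cbind(q[pairs[1, ]], q[pairs[2, ]]))
  }
  unique(cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
}

mesh_edge_set <- function(mesh) {
  s <- mesh$simplices
  pairs <- combn(ncol(s), 2L)
  e <- NULL
  for (k in seq_len(ncol(pairs))) e <- rbind(e, s[, pairs[, k]])
  unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

edge_sets_equal <- function(a, b) {
  ka <- sort(paste(a[, 1], a[, 2]))
  kb <- sort(paste(b[, 1], b[, 2]))
  identical(ka, kb)
}

# --- half-plane / half-space V-cell oracles ---------------------------------

# Sutherland-Hodgman clip of convex polygon `poly` by half-plane n.x <= b
clip_halfplane <- function(poly, nrm, b) {
  n <- nrow(poly)
  out <- NULL
  val <- poly %*% nrm - b
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- val[i] <= 0; pj_in <- val[j] <= 0
    if (pi_in) out <- rbind(out, poly[i, ])
    if (xor(pi_in, pj_in)) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Voronoi cell of generator `gi` by clipping a large box against the
# perpendicular bisectors of ALL other generators
oracle_vcell_2d <- function(coords, gi) {
  g <- coords[gi, ]
  # generous box: interior cells near the hull can reach far outside it
  R <- 50 * max(sqrt(rowSums(sweep(coords, 2L, g)^2)))
  poly <- rbind(g + c(-R, -R), g + c(R, -R), g + c(R, R), g + c(-R, R))
  for (q in seq_len(nrow(coords))) {
    if (q == gi) next
    nrm <- coords[q, ] - g
    b <- sum(nrm * (g + coords[q, ]) / 2)
    poly <- clip_halfplane(poly, nrm, b)
    if (is.null(poly) || nrow(poly) < 3L) stop("oracle cell vanished")
  }
  area <- abs(sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                  c(poly[-1, 1], poly[1, 1]) * poly[, 2])) / 2
  list(ring = poly, area = area)
}

# 3D: vertex enumeration over all triples of bisector (+ bounding box)
# planes, faces grouped by active plane, pyramid volumes from the generator
oracle_vcell_volume_3d <- function(coords, gi, tol = 1e-9) {
  g <- coords[gi, ]
  others <- coords[-gi, , drop = FALSE]
  nrm <- sweep(others, 2L, g)
  b <- rowSums(nrm * sweep(others, 2L, g, "+") / 2)
  R <- 4 * max(sqrt(rowSums(nrm^2)))
  box_n <- rbind(diag(3), -diag(3))
  box_b <- c(g[1] + R, g[2] + R, g[3] + R, R - g[1], R - g[2], R - g[3])
  N <- rbind(nrm, box_n); B <- c(b, box_b)
  m <- nrow(N)
  scale <- sqrt(rowSums(N^2))
  verts <- NULL; active <- NULL
  tr <- combn(m, 3L)
  for (k in seq_len(ncol(tr))) {
    idx <- tr[, k]
    A <- N[idx, ]
    if (abs(det(A)) < 1e-12 * prod(scale[idx])) next
    v <- solve(A, B[idx])
    slack <- (N %*% v - B) / scale
    if (all(slack <= tol)) { verts <- rbind(verts, as.numeric(v)); active <- rbind(active, idx) }
  }
  if (is.null(verts)) stop("oracle polytope empty")
  # deduplicate vertices
  key <- apply(round(verts, 9), 1L, paste, collapse = ",")
  total <- 0
  for (pl in seq_len(m)) {
    on <- which(abs(verts %*% N[pl, ] - B[pl]) / scale[pl] <= tol)
    if (length(on) < 3L) next
    fv <- verts[on, , drop = FALSE]
    fv <- fv[!duplicated(key[on]), , drop = FALSE]
    if (nrow(fv) < 3L) next
    ctr <- colMeans(fv)
    ax <- N[pl, ] / scale[pl]
    seed <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- seed - sum(seed * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ax[2] * e1[3] - ax[3] * e1[2], ax[3] * e1[1] - ax[1] * e1[3],
            ax[1] * e1[2] - ax[2] * e1[1])
    rel <- sweep(fv, 2L, ctr)
    fv <- fv[order(atan2(rel %*% e2, rel %*% e1)), , drop = FALSE]
    s <- 0
    for (i in 2:(nrow(fv) - 1L)) {
      u <- fv[1, ] - g; v <- fv[i, ] - g; w <- fv[i + 1, ] - g
      s <- s + (u[1] * (v[2] * w[3] - v[3] * w[2]) -
                u[2] * (v[1] * w[3] - v[3] * w[1]) +
                u[3] * (v[1] * w[2] - v[2] * w[1])) / 6
    }
    total <- total + abs(s)
  }
  total
}

# --- convex hull oracles -----------------------------------------------------

# Andrew's monotone chain, returns indices of hull vertices (including
# collinear boundary points is NOT required here: used on general-position
# random clouds only)
oracle_hull_2d <- function(p) {
  o <- order(p[, 1], p[, 2])
  cross <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  build <- function(idx) {
    h <- integer()
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(p[h[length(h) - 1], ], p[h[length(h)], ], p[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(o); upper <- build(rev(o))
  sort(unique(c(lower, upper)))
}

# 3D: i is a hull vertex iff some plane through i and two others has all
# remaining points strictly on one side
oracle_hull_3d <- function(p) {
  n <- nrow(p)
  hull <- logical(n)
  tr <- combn(n, 3L)
  for (k in seq_len(ncol(tr))) {
    idx <- tr[, k]
    a <- p[idx[1], ]; u <- p[idx[2], ] - a; v <- p[idx[3], ] - a
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    s <- sweep(p[-idx, , drop = FALSE], 2L, a) %*% nrm
    if (all(s > 1e-12) || all(s < -1e-12)) hull[idx] <- TRUE
  }
  which(hull)
}

# --- minimal independent legacy-VTK reader -----------------------------------

read_vtk_summary <- function(path) {
  lines <- readLines(path)
  stopifnot(grepl("^# vtk DataFile", lines[1]))
  dataset <- sub("DATASET ", "", grep("^DATASET", lines, value = TRUE)[1])
  pi_ <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[pi_], " ")[[1]][2])
  pts <- do.call(rbind, lapply(lines[(pi_ + 1):(pi_ + np)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  ci <- grep("^(CELLS|POLYGONS)", lines)[1]
  hdr <- strsplit(lines[ci], " ")[[1]]
  nc <- as.integer(hdr[2])
  cells <- lapply(lines[(ci + 1):(ci + nc)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]]))
  scalars <- list()
  for (si in grep("^SCALARS", lines)) {
    nm <- strsplit(lines[si], " ")[[1]][2]
    # values run from after LOOKUP_TABLE to the next keyword/blank
    j <- si + 2L; vals <- integer()
    while (j <= length(lines) && grepl("^-?[0-9]+$", trimws(lines[j]))) {
      vals <- c(vals, as.integer(lines[j])); j <- j + 1L
    }
    scalars[[nm]] <- vals
  }
  list(dataset = dataset, n_points = np, points = pts, n_cells = nc,
       cells = cells, scalars = scalars)
}

# --- shared fixtures ----------------------------------------------------------

# media-bounded random scenario: biological cloud inside a media ring/shell
random_bounded_scenario <- function(dim = 2L, n_bio = 18L, seed = 1L) {
  set.seed(seed)
  cloud <- generate_random_cloud(dim, n_bio, bounds = c(-1, 1),
                                 min_separation = 0.18)
  if (dim == 2L) {
    med <- vcellsim:::.ring_points(16L, 3.5)
    medz <- NA_real_
  } else {
    med <- vcellsim:::.fibonacci_sphere(32L, 3.5)
    medz <- med[, 3]
  }
  media <- data.frame(id = n_bio + seq_len(nrow(med)), type = "media",
                      x = med[, 1], y = med[, 2], z = medz,
                      info = NA_character_, stringsAsFactors = FALSE)
  rbind(cloud, media)
}

scenario_coords <- function(scen, dim) {
  m <- cbind(scen$x, scen$y, if (dim == 3L) scen$z)
  rownames(m) <- as.character(scen$id)
  m
}

expect_rings_match <- function(ring_a, ring_b, tol) {
  # vertex sets equal up to ordering/duplication (Hausdorff on vertices)
  dmat <- as.matrix(dist(rbind(ring_a, ring_b)))
  na <- nrow(ring_a)
  cross <- dmat[seq_len(na), na + seq_len(nrow(ring_b)), drop = FALSE]
  expect_lt(max(apply(cross, 1L, min)), tol)
  expect_lt(max(apply(cross, 2L, min)), tol)
}
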