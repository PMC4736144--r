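jittered_grid <- function(k, d = 2L, spacing = 1, jitter = 1e-3, seed = 1L) {
  set.seed(seed)
  g <- as.matrix(do.call(expand.grid, rep(list(seq_len(k) * spacing), d)))
  g <- g + matrix(runif(length(g), -jitter * spacing, jitter * spacing), nrow(g))
  data.frame(id = seq_len(nrow(g)), x = g[, 1], y = g[, 2],
             z = if (d == 3L) g[, 3] else NA_real_)
}

test_that("triangulate handles the base cases and input validation", {
  m <- triangulate(data.frame(id = 1:3, x = c(0, 4, 0), y = c(0, 0, 4)))
  expect_equal(nrow(m$simplices), 1L)
  expect_true(edge_sets_equal(mesh_edge_set(m), rbind(c(1, 2), c(1, 3), c(2, 3))))
  expect_identical(hull_generators(m), 1:3)

  expect_error(triangulate(data.frame(id = 1:2, x = c(0, 1), y = c(0, 0))),
               class = "vcellsim_cannot_triangulate")
  expect_error(triangulate(data.frame(id = 1:4, x = 1:4, y = 1:4)),
               class = "vcellsim_cannot_triangulate")
  expect_error(triangulate(data.frame(id = 1:3, x = c(0, 0, 1), y = c(0, 0, 1))),
               class = "vcellsim_duplicate_point")
  expect_error(triangulate(data.frame(id = c(1, 1, 2), x = c(0, 1, 0), y = c(0, 0, 1))),
               class = "vcellsim_invalid_input")
})

test_that("triangulate picks the Delaunay diagonal (brute-force verified)", {
  m <- triangulate(data.frame(id = 1:4, x = c(0, 3, 0, 4), y = c(0, 0, 3, 4)))
  expect_equal(nrow(m$simplices), 2L)
  e <- mesh_edge_set(m)
  expect_true(edge_sets_equal(
    e, oracle_delaunay_edges_2d(cbind(c(0, 3, 0, 4), c(0, 0, 3, 4)))))
  keys <- paste(e[, 1], e[, 2])
  expect_true("2 3" %in% keys)    # diagonal (3,0)-(0,3)
  expect_false("1 4" %in% keys)
})

test_that("cocircular tie-break: diagonal through the lexicographically smallest vertex", {
  # unit square in several insertion orders; both diagonals are Delaunay,
  # the canonical one passes through (0,0)
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  for (ord in list(1:4, c(2, 3, 4, 1), c(4, 2, 1, 3))) {
    pts <- data.frame(id = 1:4, x = sq[ord, 1], y = sq[ord, 2])
    m <- triangulate(pts)
    expect_equal(nrow(m$simplices), 2L)
    corner <- pts$id[pts$x == 0 & pts$y == 0]
    opposite <- pts$id[pts$x == 1 & pts$y == 1]
    keys <- paste(mesh_edge_set(m)[, 1], mesh_edge_set(m)[, 2])
    expect_true(paste(min(corner, opposite), max(corner, opposite)) %in% keys)
  }
})

test_that("neighbors: fan fixtures and oracle agreement, symmetry, irreflexivity", {
  m1 <- triangulate(data.frame(id = 1:3, x = c(0, 4, 0), y = c(0, 0, 4)))
  expect_identical(neighbors(m1, 1L), 2:3)

  hx <- hexagon_fixture()
  hx <- hx[hx$type == "lec", ]
  mh <- triangulate(hx[, c("id", "x", "y")])
  expect_identical(neighbors(mh, 1L), 2:7)
  expect_error(neighbors(mh, 99L), class = "vcellsim_unknown_generator")

  g <- jittered_grid(5L, jitter = 0.05, seed = 3)
  m <- triangulate(g)
  oe <- oracle_delaunay_edges_2d(cbind(g$x, g$y))
  center <- 13L  # middle of the 5x5 grid
  onb <- sort(unique(c(oe[oe[, 1] == center, 2], oe[oe[, 2] == center, 1])))
  expect_identical(neighbors(m, center), onb)
  for (id in m$ids) {
    nb <- neighbors(m, id)
    expect_false(id %in% nb)
    for (q in nb) expect_true(id %in% neighbors(m, q))
  }
})

test_that("vcell: hexagon closed form and bisector-plane symmetry", {
  hx <- hexagon_fixture(ring_radius = 2)
  m <- triangulate(hx[, c("id", "x", "y")])
  vc <- vcell(m, 1L)
  expect_equal(vc$measure, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(nrow(vc$boundary), 6L)
  # apothem 1: all edge midpoints at distance 1; vertices at 2/sqrt(3)
  expect_equal(max(abs(sqrt(rowSums(vc$boundary^2)) - 2 / sqrt(3))), 0,
               tolerance = 1e-9)
  expect_error(vcell(m, hx$id[hx$type == "media"][1]),
               class = "vcellsim_unbounded_cell")

  # two generators at (+-1, 0, 0) inside a media shell share the plane x = 0
  med <- vcellsim:::.fibonacci_sphere(32L, 4)
  pts <- data.frame(id = 1:34,
                    x = c(-1, 1, med[, 1]), y = c(0, 0, med[, 2]),
                    z = c(0, 0, med[, 3]))
  m3 <- triangulate(pts)
  vc1 <- vcell(m3, 1L)
  face <- vc1$boundary[["2"]]
  expect_false(is.null(face))
  expect_lt(max(abs(face[, 1])), 1e-9)
})

test_that("vcell matches the half-plane-intersection oracle on a jittered grid", {
  g <- jittered_grid(4L, jitter = 0.08, seed = 5)
  m <- triangulate(g)
  coords <- cbind(g$x, g$y)
  interior <- setdiff(m$ids, m$hull_ids)
  expect_gt(length(interior), 0L)
  for (id in interior) {
    vc <- vcell(m, id)
    oc <- oracle_vcell_2d(coords, id)
    expect_equal(vc$measure, oc$area, tolerance = 1e-8)
    expect_rings_match(vc$boundary, oc$ring, 1e-8)
  }
})

test_that("3D vcell volume: jittered grid cell is ~unit and matches the half-space oracle", {
  g <- jittered_grid(3L, d = 3L, jitter = 1e-3, seed = 7)
  m <- triangulate(g)
  center <- 14L  # middle of the 3x3x3 grid
  expect_false(center %in% m$hull_ids)
  v <- vcell_measure(m, center)
  expect_equal(v, 1.0, tolerance = 1e-2)  # jitter perturbs at O(1e-3)
  expect_equal(v, oracle_vcell_volume_3d(cbind(g$x, g$y, g$z), center),
               tolerance = 1e-6)
})

test_that("hull_generators matches independent hull oracles", {
  hx <- hexagon_fixture()
  lec <- hx[hx$type == "lec", ]
  m <- triangulate(lec[, c("id", "x", "y")])
  expect_identical(hull_generators(m), 2:7)

  set.seed(21)
  p <- matrix(runif(60, -1, 1), ncol = 2)
  m2 <- triangulate(data.frame(id = 1:30, x = p[, 1], y = p[, 2]))
  expect_identical(hull_generators(m2), oracle_hull_2d(p))

  q <- matrix(runif(48, -1, 1), ncol = 3)
  m3 <- triangulate(data.frame(id = 1:16, x = q[, 1], y = q[, 2], z = q[, 3]))
  expect_identical(hull_generators(m3), oracle_hull_3d(q))
})

test_that("mesh invariants: Delaunay property, Euler count, duality, determinism", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 25L
    p <- matrix(runif(2 * n), ncol = 2)
    pts <- data.frame(id = seq_len(n), x = p[, 1], y = p[, 2])
    m <- triangulate(pts)
    # empty circumball, checked directly against all other generators
    for (r in seq_len(nrow(m$simplices))) {
      s <- m$simplices[r, ]
      others <- setdiff(m$ids, s)
      dd <- sqrt(rowSums(sweep(p[others, , drop = FALSE], 2L, m$centers[r, ])^2))
      expect_gt(min(dd) / m$radii[r], 1 - 1e-9)
    }
    # Euler count: t = 2n - 2 - h
    expect_identical(nrow(m$simplices),
                     2L * n - 2L - length(m$hull_ids))
    # duality: circumcenters equidistant from their 3 generators
    for (r in seq_len(nrow(m$simplices))) {
      dd <- sqrt(rowSums(sweep(p[m$simplices[r, ], ], 2L, m$centers[r, ])^2))
      expect_lt(max(abs(dd - m$radii[r])) / m$radii[r], 1e-9)
    }
    # determinism: same map in shuffled row order -> identical simplices
    m2 <- triangulate(pts[sample(n), ])
    expect_identical(m$simplices, m2$simplices)
    expect_identical(triangulate(pts)$simplices, m$simplices)
  }
})

test_that("interior V-cells tile the interior (conservation)", {
  scen <- random_bounded_scenario(2L, n_bio = 15L, seed = 9L)
  m <- triangulate(scen[, c("id", "x", "y")])
  bio <- scen$id[scen$type != "media"]
  expect_length(intersect(bio, m$hull_ids), 0L)
  pkg_sum <- sum(vapply(bio, function(id) vcell_measure(m, id), 1.0))
  coords <- scenario_coords(scen, 2L)
  oracle_sum <- sum(vapply(bio, function(id) oracle_vcell_2d(coords, id)$area, 1.0))
  expect_equal(pkg_sum, oracle_sum, tolerance = 1e-6)
})
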