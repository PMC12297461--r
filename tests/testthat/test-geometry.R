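# Restricted and adaptive Voronoi tessellation.

dodeca_volume <- function(edge) (15 + 7 * sqrt(5)) / 4 * edge^3

test_that("an isolated cell is the bounding dodecahedron (closed form and Monte Carlo)", {
  tess <- restricted_voronoi(matrix(0, 1, 3), edge_length = 100)
  expect_equal(tess$volume, dodeca_volume(100), tolerance = 1e-6)
  expect_true(tess$is_boundary)
  expect_equal(tess$n_unshared, 12L)
  expect_equal(length(tess$neighbours[[1]]), 0L)

  # Monte-Carlo volume oracle: plane-membership test inside the bounding box
  dod <- oracle_dodeca_planes(100)
  set.seed(1)
  R <- 140.2
  q <- matrix(stats::runif(3e5, -R, R), ncol = 3)
  inside <- rowSums(sweep(q %*% t(dod$normals), 2, dod$offsets, ">")) == 0
  mc_vol <- mean(inside) * (2 * R)^3
  expect_equal(tess$volume, mc_vol, tolerance = 0.02)
})

test_that("two seeds give mirror-symmetric cells and reflection auxiliary points", {
  A <- c(0, 0, 0); B <- c(10, 0, 0)
  tess <- restricted_voronoi(rbind(A, B), 100)
  expect_equal(tess$volume[1], tess$volume[2], tolerance = 1e-6)
  expect_equal(lengths(tess$neighbours), c(1L, 1L))
  aux <- generate_auxiliary_points(tess)
  expect_equal(nrow(aux), 2L)
  want <- rbind(2 * A - B, 2 * B - A)
  expect_equal(aux[order(aux[, 1]), ], want[order(want[, 1]), ],
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("cubic lattice interior cells are exact unit cells", {
  g <- as.matrix(expand.grid(0:4, 0:4, 0:4)) * 10
  tess <- restricted_voronoi(g, 100)
  ctr <- which(rowSums(g == 20) == 3)
  expect_equal(tess$volume[ctr], 1000, tolerance = 1e-6)
  expect_equal(length(tess$neighbours[[ctr]]), 6L)
  expect_lt(sqrt(sum((tess$centroid[ctr, ] - g[ctr, ])^2)), 1e-4)
  adj <- adjacency(tess)
  expect_equal(adj$distances[[ctr]], rep(10, 6), tolerance = 1e-6)
})

test_that("adaptive closure caps boundary cells without touching the interior", {
  g <- as.matrix(expand.grid(0:4, 0:4, 0:4)) * 10
  t1 <- restricted_voronoi(g, 100)
  t2 <- adaptive_voronoi(g, 100)
  corner <- which(rowSums(g == 0) == 3)
  interior <- !t1$is_boundary
  expect_true(any(interior))
  # interior untouched, boundary never grows
  expect_equal(t2$volume[interior], t1$volume[interior], tolerance = 1e-9)
  expect_true(all(t2$volume <= t1$volume * (1 + 1e-9)))
  # corner capped near the local spacing (vs ~1e6 unclosed)
  expect_lt(t2$volume[corner], 2 * 1000)
  expect_gt(t1$volume[corner], 1e5)
})

test_that("a flat monolayer is all-boundary with in-plane reflections and finite cells", {
  g <- cbind(as.matrix(expand.grid(0:6, 0:6)) * 10, 0)
  t1 <- restricted_voronoi(g, 100)
  expect_true(all(t1$is_boundary))
  # the reflection rule maps in-plane neighbours to in-plane points
  aux <- generate_auxiliary_points(t1)
  expect_gt(nrow(aux), 0)
  expect_true(all(abs(aux[, 3]) < 1e-4))
  t2 <- adaptive_voronoi(g, 100)
  dod_vol <- (15 + 7 * sqrt(5)) / 4 * 1e6
  expect_true(all(is.finite(t2$volume)))
  expect_true(all(t2$volume > 0 & t2$volume <= dod_vol))
  # perimeter columns are capped to the same footprint as inner columns
  inner <- rowSums(g[, 1:2] == 30) == 2
  expect_lt(max(t2$volume) / min(t2$volume[inner]), 2.5)
})

test_that("tessellation matches the brute-force half-space oracle", {
  pts <- oracle_cloud()
  tess <- restricted_voronoi(pts, 100)
  for (i in c(1, 5, 12, 20, 27, 33, 40)) {
    oc <- oracle_cell(pts, i, 100)
    expect_equal(tess$volume[i], oc$volume, tolerance = 1e-6)
    expect_equal(tess$centroid[i, ], oc$centroid, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_identical(tess$neighbours[[i]], oc$neighbours)
  }
})

test_that("cell volumes are bounded by the dodecahedron and partition a container", {
  pts <- oracle_cloud()
  tess <- restricted_voronoi(pts, 100)
  expect_true(all(tess$volume <= dodeca_volume(100) * (1 + 1e-9)))
  cont <- rbind(c(1, 0, 0, 50), c(-1, 0, 0, 0), c(0, 1, 0, 50),
                c(0, -1, 0, 0), c(0, 0, 1, 50), c(0, 0, -1, 0))
  set.seed(7)
  p2 <- matrix(stats::runif(90, 5, 45), 30, 3)
  tc <- restricted_voronoi(p2, 100, container = cont)
  expect_equal(sum(tc$volume), 50^3, tolerance = 1e-6)
})

test_that("volumes and adjacency are invariant under rigid motion (interior cells)", {
  set.seed(42)
  pts <- matrix(stats::runif(900, 0, 50), 300, 3)
  ta <- adaptive_voronoi(pts, 100)
  # translation: exact for every cell
  tt <- adaptive_voronoi(pts + 17.3, 100)
  expect_equal(tt$volume, ta$volume, tolerance = 1e-9)
  expect_identical(lengths(tt$neighbours), lengths(ta$neighbours))
  # rotation: cells whose geometry is independent of the bounding solid
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- adaptive_voronoi(pts %*% t(R) + 5, 100)
  both <- !ta$is_boundary & !tr$is_boundary
  expect_gt(sum(both), 20)
  expect_equal(tr$volume[both], ta$volume[both], tolerance = 1e-6)
  expect_identical(lengths(tr$neighbours[both]), lengths(ta$neighbours[both]))
})

test_that("degenerate inputs raise informative errors", {
  expect_error(restricted_voronoi(matrix(0, 0, 3)), "at least 1")
  expect_error(restricted_voronoi(rbind(c(0, 0, 0), c(0, 0, 0))), "coincident")
  expect_error(restricted_voronoi(rbind(c(0, 0, 0), c(NA, 0, 0))), "non-finite")
  # interior cell fully caged by neighbours emits no auxiliary points
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) * 10
  t1 <- restricted_voronoi(g, 100)
  ctr <- which(rowSums(g == 0) == 3)
  expect_false(t1$is_boundary[ctr])
})

test_that("convex hull volume, facets and boundary distance are correct", {
  corners <- as.matrix(expand.grid(c(0, 50), c(0, 50), c(0, 50)))
  set.seed(3)
  pts <- rbind(corners, matrix(stats::runif(60, 5, 45), 20, 3))
  hull <- convex_hull_3d(pts)
  expect_equal(hull$volume, 50^3, tolerance = 1e-6)
  expect_equal(hull$centroid, rep(25, 3), tolerance = 1e-6)
  expect_equal(hull_boundary_distance(hull, matrix(25, 1, 3)), 25,
               tolerance = 1e-6)
  expect_lt(hull_boundary_distance(hull, matrix(c(60, 25, 25), 1, 3)), 0)
  # tetrahedron: volume = |det| / 6
  tet <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0), c(0, 0, 30))
  ht <- convex_hull_3d(tet)
  expect_equal(ht$volume, 30^3 / 6, tolerance = 1e-6)
})
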