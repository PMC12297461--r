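#' @useDynLib nuqloud, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Regular dodecahedron of a given edge length, canonical orientation,
# centred at the origin. Vertices follow the standard (+-1,+-1,+-1) /
# golden-ratio construction; faces are returned as ordered vertex loops with
# unit outward normals and plane offsets (n . x <= d).
dodecahedron_solid <- function(edge_length) {
  phi <- (1 + sqrt(5)) / 2
  s <- edge_length * phi / 2            # raw solid has edge 2 / phi
  v1 <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  cyc <- function(a, b) {
    g <- as.matrix(expand.grid(a, b))
    rbind(cbind(0, g[, 1], g[, 2]),
          cbind(g[, 1], g[, 2], 0),
          cbind(g[, 2], 0, g[, 1]))
  }
  v2 <- cyc(c(-1 / phi, 1 / phi), c(-phi, phi))
  vert <- rbind(v1, v2) * s
  dimnames(vert) <- NULL

  nrm <- cyc(c(-phi, phi), c(-1, 1))
  nrm <- nrm / sqrt(rowSums(nrm^2))
  faces <- vector("list", 12)
  offsets <- numeric(12)
  for (f in seq_len(12)) {
    d <- vert %*% nrm[f, ]
    top <- order(d, decreasing = TRUE)[1:5]
    offsets[f] <- mean(d[top])
    ctr <- colMeans(vert[top, , drop = FALSE])
    e1 <- vert[top[1], ] - ctr
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[f, 2] * e1[3] - nrm[f, 3] * e1[2],
            nrm[f, 3] * e1[1] - nrm[f, 1] * e1[3],
            nrm[f, 1] * e1[2] - nrm[f, 2] * e1[1])
    rel <- sweep(vert[top, , drop = FALSE], 2, ctr)
    ang <- atan2(rel %*% e2, rel %*% e1)
    faces[[f]] <- as.integer(top[order(ang)])
  }
  list(vertices = vert, faces = faces, normals = nrm, offsets = offsets,
       edge_length = edge_length, circumradius = sqrt(3) * s,
       volume = (15 + 7 * sqrt(5)) / 4 * edge_length^3)
}

# Deterministic symbolic perturbation: tiny fixed-seed jiggle that removes
# cospherical degeneracies (perfect lattices) without measurably moving any
# result (amplitude 1e-9 x edge length; analytic tests carry 1e-6 slack).
.jiggle_points <- function(points, edge_length) {
  amp <- 1e-9 * edge_length
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(903161L)
  points + matrix(stats::runif(length(points), -amp, amp), nrow = nrow(points))
}

.validate_points <- function(points, n_min = 1L) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L)
    stop("`points` must be an n x 3 matrix of coordinates in micrometres")
  if (nrow(points) < n_min)
    stop(sprintf("at least %d point(s) required, got %d", n_min, nrow(points)))
  if (any(!is.finite(points)))
    stop(sprintf("non-finite coordinate in row(s) %s",
                 paste(which(rowSums(!is.finite(points)) > 0), collapse = ", ")))
  if (nrow(points) > 1L && cpp_min_pair_distance(points) < 1e-9) {
    key <- apply(round(points / 1e-9), 1, paste, collapse = ",")
    bad <- which(key %in% key[duplicated(key)])
    stop(sprintf("coincident points (within 1e-9): indices %s",
                 paste(utils::head(bad, 20), collapse = ", ")))
  }
  points
}

.symmetrise <- function(nbr) {
  n <- length(nbr)
  add <- vector("list", n)
  for (i in seq_len(n)) for (j in nbr[[i]]) {
    if (!(i %in% nbr[[j]])) add[[j]] <- c(add[[j]], i)
  }
  lapply(seq_len(n), function(i) sort(unique(c(nbr[[i]], add[[i]]))))
}

.voronoi_pass <- function(points_all, n_compute, edge_length, container) {
  solid <- dodecahedron_solid(edge_length)
  if (is.null(container)) container <- matrix(0, 0, 4)
  cpp_restricted_voronoi(points_all, as.integer(n_compute),
                         solid$vertices, solid$faces, solid$normals,
                         container, 1e-9, 1e-9 * edge_length)
}

.new_tessellation <- function(points, res, n_real, edge_length, aux_points, pass) {
  nbr_all <- res$neighbours
  n_aux_faces <- vapply(nbr_all, function(v) sum(v > n_real), integer(1))
  nbr <- lapply(nbr_all, function(v) v[v <= n_real])
  nbr <- .symmetrise(nbr)
  structure(list(
    points = points,
    volume = as.numeric(res$volume),
    centroid = res$centroid,
    neighbours = nbr,
    n_unshared = as.integer(res$n_unshared),
    n_aux_faces = n_aux_faces,
    is_boundary = res$n_unshared >= 1L | n_aux_faces >= 1L,
    aux_points = aux_points,
    edge_length = edge_length,
    pass = pass
  ), class = "nq_tessellation")
}

#' Restricted 3D Voronoi tessellation (first pass)
#'
#' Each cell is initialised as a regular dodecahedron of the given edge length
#' centred on its seed and clipped by the perpendicular-bisector half-spaces
#' to all other seeds. Interior cells equal unrestricted Voronoi cells;
#' boundary cells retain faces of the bounding solid and are flagged.
#'
#' @param points numeric matrix, one nucleus centroid per row (x, y, z in um).
#' @param edge_length edge length of the bounding dodecahedron in um.
#' @param container optional matrix of additional clipping half-spaces, one
#'   row per plane `(nx, ny, nz, d)` with unit normal, keeping `n.x <= d`.
#' @return an object of class `nq_tessellation` with per-cell `volume` (um^3),
#'   `centroid`, face-sharing `neighbours` (real seeds only, symmetric),
#'   `n_unshared` bounding-solid faces and `is_boundary` flags.
#' @export
restricted_voronoi <- function(points, edge_length = 100, container = NULL) {
  points <- .validate_points(points)
  pj <- .jiggle_points(points, edge_length)
  res <- .voronoi_pass(pj, nrow(pj), edge_length, container)
  .new_tessellation(points, res, nrow(pj), edge_length,
                    matrix(0, 0, 3), "restricted")
}

#' Auxiliary points closing boundary Voronoi cells
#'
#' For every boundary cell i and each of its face neighbours j, the neighbour
#' is mirrored through the boundary seed (2 x_i - x_j), extending each local
#' neighbourhood outward by one cell layer. Emitted points are deduplicated
#' (1e-6 um) and points closer than 1e-3 um to a real nucleus are dropped.
#'
#' @param tessellation a first-pass [restricted_voronoi()] result.
#' @return matrix of auxiliary point coordinates (possibly 0 rows).
#' @export
generate_auxiliary_points <- function(tessellation) {
  stopifnot(inherits(tessellation, "nq_tessellation"))
  p <- tessellation$points
  idx <- which(tessellation$is_boundary)
  if (length(idx) == 0) return(matrix(0, 0, 3))
  aux <- do.call(rbind, lapply(idx, function(i) {
    js <- tessellation$neighbours[[i]]
    if (length(js) == 0) return(NULL)
    matrix(2 * p[i, ], length(js), 3, byrow = TRUE) - p[js, , drop = FALSE]
  }))
  if (is.null(aux) || nrow(aux) == 0) return(matrix(0, 0, 3))
  key <- apply(round(aux / 1e-6), 1, paste, collapse = ",")
  aux <- aux[!duplicated(key), , drop = FALSE]
  near <- cpp_nearest_seed(p, aux)$distance
  aux[near >= 1e-3, , drop = FALSE]
}

#' Adaptively restricted Voronoi tessellation (full pipeline)
#'
#' Runs the first tessellation pass, mirrors the neighbourhoods of boundary
#' cells outward as auxiliary points, and re-tessellates over the union so
#' that boundary cells are capped at a size matching their local
#' neighbourhood. Cells are reported only for real nuclei; interior cells are
#' unchanged and boundary cell volumes never increase.
#'
#' @inheritParams restricted_voronoi
#' @return an `nq_tessellation`; `aux_points` holds the closure points and
#'   `n_aux_faces` the number of faces each cell shares with them.
#' @export
adaptive_voronoi <- function(points, edge_length = 100, container = NULL) {
  points <- .validate_points(points)
  pj <- .jiggle_points(points, edge_length)
  res1 <- .voronoi_pass(pj, nrow(pj), edge_length, container)
  t1 <- .new_tessellation(points, res1, nrow(pj), edge_length,
                          matrix(0, 0, 3), "restricted")
  t1$points <- pj  # reflections computed from the perturbed seeds
  aux <- generate_auxiliary_points(t1)
  if (nrow(aux) == 0) {
    t1$points <- points
    t1$pass <- "adaptive"
    return(t1)
  }
  res2 <- .voronoi_pass(rbind(pj, aux), nrow(pj), edge_length, container)
  .new_tessellation(points, res2, nrow(pj), edge_length, aux, "adaptive")
}

#' Face-sharing adjacency of a tessellation
#'
#' @param tessellation an `nq_tessellation`.
#' @return list with `neighbours` (list of neighbour indices per cell),
#'   `distances` (matching seed-to-seed distances in um) and `edges`, a
#'   data frame of unique undirected edges `(i, j, distance)`.
#' @export
adjacency <- function(tessellation) {
  stopifnot(inherits(tessellation, "nq_tessellation"))
  p <- tessellation$points
  nbr <- tessellation$neighbours
  dists <- lapply(seq_along(nbr), function(i) {
    js <- nbr[[i]]
    if (length(js) == 0) return(numeric(0))
    sqrt(rowSums((p[js, , drop = FALSE] -
                    matrix(p[i, ], length(js), 3, byrow = TRUE))^2))
  })
  ii <- rep.int(seq_along(nbr), lengths(nbr))
  jj <- unlist(nbr, use.names = FALSE)
  if (length(ii) == 0) {
    edges <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  } else {
    keep <- ii < jj
    edges <- data.frame(i = ii[keep], j = jj[keep],
                        distance = unlist(dists, use.names = FALSE)[keep])
  }
  list(neighbours = nbr, distances = dists, edges = edges)
}

#' @export
print.nq_tessellation <- function(x, ...) {
  cat(sprintf("Restricted Voronoi tessellation (%s pass)\n", x$pass))
  cat(sprintf("  cells: %d  (boundary: %d)\n", length(x$volume), sum(x$is_boundary)))
  cat(sprintf("  auxiliary points: %d\n", nrow(x$aux_points)))
  cat(sprintf("  bounding dodecahedron edge: %g um\n", x$edge_length))
  invisible(x)
}

#' Export a tessellation as per-cell and edge tables
#'
#' @param tessellation an `nq_tessellation`.
#' @return list of two data frames: `cells` (volume, centroid, neighbour
#'   count, boundary flag) and `edges` (i, j, distance).
#' @export
tessellation_tables <- function(tessellation) {
  adj <- adjacency(tessellation)
  cells <- data.frame(
    volume = tessellation$volume,
    centroid_x = tessellation$centroid[, 1],
    centroid_y = tessellation$centroid[, 2],
    centroid_z = tessellation$centroid[, 3],
    n_neighbours = lengths(tessellation$neighbours),
    is_boundary = tessellation$is_boundary
  )
  list(cells = cells, edges = adj$edges)
}

# --- convex hull (polar duality + half-space clipping) ----------------------

#' 3D convex hull of a point cloud
#'
#' Computes the facet planes, volume and centroid of the convex hull. The
#' hull is obtained by polar duality: the dual polytope of the (centred,
#' scaled) points is carved by half-space clipping, and its vertices map back
#' to hull facet planes.
#'
#' @param points numeric n x 3 matrix (n >= 4, non-degenerate).
#' @return object of class `nq_hull`: unit outward facet `normals`, plane
#'   `offsets` (n.x <= d), `volume` (um^3) and `centroid`.
#' @export
convex_hull_3d <- function(points) {
  points <- .validate_points(points, n_min = 4L)
  ctr <- colMeans(points)
  q <- sweep(points, 2, ctr)
  r <- sqrt(rowSums(q^2))
  s <- 1 / stats::median(r[r > 0])
  q <- q * s
  # dual polytope {y : q_i . y <= 1}
  qn <- sqrt(rowSums(q^2))
  keep <- qn > 1e-12
  planes <- cbind(q[keep, , drop = FALSE] / qn[keep], 1 / qn[keep])
  dual <- cpp_clip_region(planes, 1e4, 0, 1e-9)
  y <- dual$vertices
  # dedupe dual vertices (each is one hull facet)
  key <- apply(round(y * 1e7), 1, paste, collapse = ",")
  y <- y[!duplicated(key), , drop = FALSE]
  yn <- sqrt(rowSums(y^2))
  ok <- yn > 1e-12
  y <- y[ok, , drop = FALSE]; yn <- yn[ok]
  normals <- y / yn
  offsets_local <- 1 / yn                      # in scaled, centred frame
  vol_loc <- cpp_clip_region(cbind(normals, offsets_local),
                             2 * max(qn) + 1, 0, 1e-9)
  structure(list(
    normals = normals,
    offsets = as.numeric(normals %*% ctr + offsets_local / s),
    volume = vol_loc$volume / s^3,
    centroid = as.numeric(vol_loc$centroid / s + ctr),
    scale = s, center = ctr, offsets_local = offsets_local
  ), class = "nq_hull")
}

#' Distance from interior points to the hull boundary
#'
#' @param hull an [convex_hull_3d()] result.
#' @param points n x 3 matrix of query points.
#' @return numeric vector; positive inside the hull, negative outside (the
#'   signed distance to the nearest facet plane).
#' @export
hull_boundary_distance <- function(hull, points) {
  stopifnot(inherits(hull, "nq_hull"))
  points <- as.matrix(points)
  d <- sweep(hull$normals %*% t(points), 1, hull$offsets)  # facet x point
  apply(-d, 2, min)
}
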