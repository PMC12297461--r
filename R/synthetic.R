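# Synthetic point clouds, intensity mixtures and toy volumes with the
# statistical structure the pipeline assumes: a "crystalline" surrogate
# (low-density, anisotropic, regular: an axis-scaled jittered lattice), an
# "amorphous" surrogate (dense, isotropic, irregular: a hard-core point
# process) and a composite two-population embryo for archetype recovery.

.region_spec <- function(region) {
  if (is.numeric(region)) region <- list(type = "box", size = region)
  stopifnot(region$type %in% c("box", "ball", "ellipsoid"))
  if (region$type == "ball") region$size <- rep(region$size[1], 3)
  region
}

.region_volume <- function(region) {
  s <- region$size
  switch(region$type,
         box = prod(s),
         ball = 4 / 3 * pi * prod(s),
         ellipsoid = 4 / 3 * pi * prod(s))
}

# uniform draws inside a region (box: [0, size]; ball/ellipsoid: centred at 0
# with semi-axes size)
.region_sample <- function(n, region) {
  s <- region$size
  if (region$type == "box")
    return(matrix(stats::runif(3 * n), n, 3) %*% diag(s))
  acc <- matrix(0, 0, 3)
  while (nrow(acc) < n) {
    m <- ceiling((n - nrow(acc)) * 2.2) + 16
    p <- (matrix(stats::runif(3 * m), m, 3) * 2 - 1) %*% diag(s)
    inside <- rowSums(sweep(p, 2, s, "/")^2) <= 1
    acc <- rbind(acc, p[inside, , drop = FALSE])
  }
  acc[seq_len(n), , drop = FALSE]
}

#' Jittered anisotropic lattice (crystalline surrogate)
#'
#' A rectangular lattice scaled per axis and perturbed by isotropic Gaussian
#' jitter: the low-density, anisotropic, regular organisational phenotype.
#'
#' @param spacing lattice constant before axis scaling (um).
#' @param dims integer length-3 number of points per axis.
#' @param jitter_sd isotropic Gaussian jitter, must be `< spacing / 4` (um).
#' @param axis_scales per-axis scale factors (anisotropy).
#' @param seed integer RNG seed.
#' @return an [nq_cloud()] with `metadata$population = "crystalline"`.
#' @export
make_lattice <- function(spacing = 10, dims = c(5, 5, 5), jitter_sd = 0,
                         axis_scales = c(1, 1, 1), seed = 1) {
  stopifnot(spacing > 0, all(dims >= 1))
  if (jitter_sd >= spacing / 4)
    stop("config error: jitter_sd must be < spacing / 4")
  g <- as.matrix(expand.grid(seq_len(dims[1]) - 1, seq_len(dims[2]) - 1,
                             seq_len(dims[3]) - 1)) * spacing
  g <- g %*% diag(axis_scales)
  dimnames(g) <- NULL
  set.seed(seed)
  if (jitter_sd > 0)
    g <- g + matrix(stats::rnorm(length(g), 0, jitter_sd), nrow(g), 3)
  nq_cloud(g, sample_id = "lattice",
           metadata = list(population = rep("crystalline", nrow(g)),
                           generator = "lattice", seed = seed))
}

#' Hard-core point process (amorphous surrogate)
#'
#' Random sequential placement of points with a guaranteed minimum pairwise
#' separation at a target intensity: the dense, isotropic, irregular
#' organisational phenotype. With `hardcore = 0` this is a homogeneous
#' Poisson process.
#'
#' @param intensity target intensity in points / um^3.
#' @param region box size (length-3 numeric, origin corner) or
#'   `list(type = "ball"/"ellipsoid", size = semi-axes)` centred at 0.
#' @param hardcore minimum pairwise distance (um); the packing fraction
#'   `intensity * (4 pi / 3) (hardcore / 2)^3` must stay below 0.3.
#' @param seed integer RNG seed.
#' @return an [nq_cloud()] with `metadata$population = "amorphous"`.
#' @export
make_amorphous <- function(intensity, region = c(100, 100, 100), hardcore = 0,
                           seed = 1) {
  region <- .region_spec(region)
  packing <- intensity * 4 / 3 * pi * (hardcore / 2)^3
  if (packing >= 0.3)
    stop(sprintf("infeasible packing: fraction %.3f >= 0.3", packing))
  set.seed(seed)
  vol <- .region_volume(region)
  n_target <- stats::rpois(1, intensity * vol)
  pts <- matrix(0, 0, 3)
  attempts <- 0L
  while (nrow(pts) < n_target && attempts < 50L) {
    prop <- .region_sample(max(5L * (n_target - nrow(pts)), 100L), region)
    keep <- cpp_hardcore_thin(rbind(pts, prop), hardcore, n_target)
    pts <- rbind(pts, prop)[keep, , drop = FALSE]
    attempts <- attempts + 1L
  }
  if (nrow(pts) < n_target)
    stop(sprintf("hard-core placement failed after bounded attempts (%d / %d points)",
                 nrow(pts), n_target))
  nq_cloud(pts, sample_id = "amorphous",
           metadata = list(population = rep("amorphous", nrow(pts)),
                           generator = "amorphous", seed = seed,
                           intensity = intensity, hardcore = hardcore))
}

#' Two-population synthetic embryo
#'
#' An ellipsoidal tissue whose halves carry opposing organisational
#' phenotypes: a dense isotropic hard-core ("amorphous") population fills
#' `x < 0`, an axis-scaled jittered lattice ("crystalline") fills `x > 0`.
#' Ground-truth population labels and an interior annotation (distance to the
#' hull and to the inter-population interface) are attached.
#'
#' @param semi_axes ellipsoid semi-axes (um).
#' @param amorphous_intensity intensity of the amorphous half (points/um^3).
#' @param amorphous_hardcore minimum separation in the amorphous half (um).
#' @param lattice_spacing lattice constant of the crystalline half (um).
#' @param lattice_scales per-axis anisotropy of the crystalline half.
#' @param lattice_jitter jitter of the crystalline half (um).
#' @param interior_margin distance to hull and interface below which a cell
#'   is annotated non-interior (um).
#' @param seed integer RNG seed.
#' @return an [nq_cloud()] with metadata `population`, `dist_hull`,
#'   `interior`.
#' @export
make_embryo <- function(semi_axes = c(200, 130, 130),
                        amorphous_intensity = 2e-3, amorphous_hardcore = 4,
                        lattice_spacing = 8, lattice_scales = c(1, 1, 2),
                        lattice_jitter = 0.5, interior_margin = c(20, 15),
                        seed = 1) {
  region <- list(type = "ellipsoid", size = semi_axes)
  set.seed(seed)
  # amorphous half (x < 0)
  vol_half <- .region_volume(region) / 2
  n_am <- stats::rpois(1, amorphous_intensity * vol_half)
  pts <- matrix(0, 0, 3)
  attempts <- 0L
  while (nrow(pts) < n_am && attempts < 50L) {
    prop <- .region_sample(max(6L * (n_am - nrow(pts)), 100L), region)
    prop <- prop[prop[, 1] < 0, , drop = FALSE]
    keep <- cpp_hardcore_thin(rbind(pts, prop), amorphous_hardcore, n_am)
    pts <- rbind(pts, prop)[keep, , drop = FALSE]
    attempts <- attempts + 1L
  }
  am <- pts[seq_len(min(nrow(pts), n_am)), , drop = FALSE]
  # crystalline half (x > 0): lattice cropped to the half-ellipsoid
  sp <- lattice_spacing * lattice_scales
  grid <- as.matrix(expand.grid(
    seq(sp[1] / 2, semi_axes[1], by = sp[1]),
    seq(-semi_axes[2], semi_axes[2], by = sp[2]),
    seq(-semi_axes[3], semi_axes[3], by = sp[3])))
  dimnames(grid) <- NULL
  grid <- grid + matrix(stats::rnorm(length(grid), 0, lattice_jitter),
                        nrow(grid), 3)
  inside <- rowSums(sweep(grid, 2, semi_axes, "/")^2) <= 1 & grid[, 1] > 0
  cr <- grid[inside, , drop = FALSE]

  pts <- rbind(am, cr)
  pop <- c(rep("amorphous", nrow(am)), rep("crystalline", nrow(cr)))
  # radial distance to the ellipsoid surface (annotation, not exact normal
  # distance) and distance to the interface plane x = 0
  m <- sqrt(rowSums(sweep(pts, 2, semi_axes, "/")^2))
  r <- sqrt(rowSums(pts^2))
  dist_hull <- r * (1 - m) / pmax(m, 1e-9)
  interior <- dist_hull >= interior_margin[1] & abs(pts[, 1]) >= interior_margin[2]
  nq_cloud(pts, sample_id = "embryo",
           metadata = list(population = pop, dist_hull = dist_hull,
                           interior = interior, generator = "embryo",
                           seed = seed))
}

#' Labelled two-component Gaussian intensity mixture
#'
#' @param n number of draws.
#' @param noise_mean,noise_sd noise component parameters.
#' @param signal_mean,signal_sd signal component parameters
#'   (`signal_mean > noise_mean`).
#' @param signal_fraction mixing weight of the signal component.
#' @param seed integer RNG seed.
#' @return list with `values` and ground-truth `labels`
#'   (`"noise"`/`"signal"`).
#' @export
make_intensity_mixture <- function(n, noise_mean = 100, noise_sd = 10,
                                   signal_mean = 1000, signal_sd = 100,
                                   signal_fraction = 0.5, seed = 1) {
  if (signal_mean <= noise_mean)
    stop("config error: signal_mean must exceed noise_mean")
  if (noise_sd <= 0 || signal_sd <= 0)
    stop("config error: standard deviations must be positive")
  set.seed(seed)
  is_sig <- stats::runif(n) < signal_fraction
  values <- ifelse(is_sig, stats::rnorm(n, signal_mean, signal_sd),
                   stats::rnorm(n, noise_mean, noise_sd))
  list(values = values, labels = ifelse(is_sig, "signal", "noise"))
}

#' Synthetic volume of Gaussian blobs
#'
#' Sum of isotropic Gaussian blobs on a zero background; a fixture for
#' intensity extraction.
#'
#' @param points n x 3 blob centres (um).
#' @param amplitudes peak amplitude per blob.
#' @param blob_sd isotropic Gaussian width (um).
#' @param shape integer length-3 volume dimensions (voxels, 1 um isotropic).
#' @return an [nq_volume()].
#' @export
make_blob_image <- function(points, amplitudes, blob_sd, shape) {
  points <- as.matrix(points)
  arr <- array(0, dim = shape)
  ax <- lapply(shape, function(d) seq_len(d) - 0.5)
  half <- ceiling(4 * blob_sd)
  for (b in seq_len(nrow(points))) {
    if (amplitudes[b] == 0) next
    win <- lapply(1:3, function(j) {
      i <- which(abs(ax[[j]] - points[b, j]) <= half)
      if (length(i) == 0) integer(0) else i
    })
    if (any(lengths(win) == 0)) next
    gs <- lapply(1:3, function(j)
      exp(-(ax[[j]][win[[j]]] - points[b, j])^2 / (2 * blob_sd^2)))
    blob <- amplitudes[b] * outer(outer(gs[[1]], gs[[2]]), gs[[3]])
    arr[win[[1]], win[[2]], win[[3]]] <-
      arr[win[[1]], win[[2]], win[[3]]] + blob
  }
  nq_volume(arr, c(1, 1, 1))
}
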