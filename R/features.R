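# The fourteen per-nucleus organisational features.
#
# Density class:     shell densities 0-10 / 10-20 / 20-30 um (counts per
#                    shell volume, um^-3) and Voronoi density (mean inverse
#                    distance to face-sharing neighbours, um^-1).
# Anisotropy class:  Voronoi volume (um^3), centroid offset (um), polarity
#                    (offset / volume^(1/3), dimensionless) and the
#                    neighbourhood statistics of volume and centroid offset.
# Irregularity class: neighbour count, its neighbourhood statistics, and the
#                    neighbourhood standard deviation of Voronoi volume.

#' Names of the fourteen organisational features
#' @return character vector of length 14, in canonical column order.
#' @export
feature_names <- function() {
  c("density_0_10", "density_10_20", "density_20_30",
    "voronoi_density", "voronoi_volume", "n_neighbours",
    "centroid_offset", "polarity",
    "nbh_mean_volume", "nbh_std_volume",
    "nbh_mean_n_neighbours", "nbh_std_n_neighbours",
    "nbh_mean_centroid_offset", "nbh_std_centroid_offset")
}

# canonical feature -> class map used to name dendrogram cuts
.feature_classes <- function() {
  list(density = c("density_0_10", "density_10_20", "density_20_30",
                   "voronoi_density"),
       anisotropy = c("voronoi_volume", "nbh_mean_volume", "centroid_offset",
                      "nbh_mean_centroid_offset", "nbh_std_centroid_offset",
                      "polarity"),
       irregularity = c("n_neighbours", "nbh_mean_n_neighbours",
                        "nbh_std_n_neighbours", "nbh_std_volume"))
}

#' Multi-scale shell densities
#'
#' For every nucleus, the count of other nuclei in each concentric spherical
#' shell `(a, b]`, divided by the shell volume `(4 pi / 3)(b^3 - a^3)`. The
#' focal nucleus is excluded.
#'
#' @param points numeric n x 3 matrix (um).
#' @param radii strictly increasing positive shell boundaries (um);
#'   default `c(10, 20, 30)` giving shells 0-10, 10-20 and 20-30 um.
#' @return matrix n x length(radii) of densities (um^-3).
#' @export
shell_densities <- function(points, radii = c(10, 20, 30)) {
  if (any(diff(c(0, radii)) <= 0))
    stop("config error: shell radii must be strictly increasing and positive")
  points <- .validate_points(points)
  counts <- cpp_count_shells(points, radii)
  vols <- 4 / 3 * pi * diff(c(0, radii)^3)
  dens <- sweep(counts, 2, vols, "/")
  lo <- c(0, radii[-length(radii)])
  colnames(dens) <- sprintf("density_%g_%g", lo, radii)
  dens
}

#' Per-cell Voronoi features
#'
#' Voronoi volume, Voronoi density (mean inverse distance to face-sharing
#' neighbours), neighbour count, centroid offset and polarity (centroid
#' offset normalised by the cell's cube-root volume).
#'
#' @param tessellation an `nq_tessellation` (normally the adaptive pass).
#' @return data frame with columns `voronoi_volume`, `voronoi_density`,
#'   `n_neighbours`, `centroid_offset`, `polarity` and a QC flag
#'   `qc_isolated` marking cells without any real face neighbour (their
#'   Voronoi density is reported as 0).
#' @export
cell_features <- function(tessellation) {
  stopifnot(inherits(tessellation, "nq_tessellation"))
  adj <- adjacency(tessellation)
  inv_mean <- vapply(adj$distances, function(d)
    if (length(d) == 0) 0 else mean(1 / d), numeric(1))
  isolated <- lengths(adj$neighbours) == 0L
  if (any(isolated))
    warning(sprintf("%d cell(s) have no real face neighbours; voronoi_density set to 0",
                    sum(isolated)))
  off <- sqrt(rowSums((tessellation$centroid - tessellation$points)^2))
  data.frame(voronoi_volume = tessellation$volume,
             voronoi_density = inv_mean,
             n_neighbours = lengths(adj$neighbours),
             centroid_offset = off,
             polarity = off / tessellation$volume^(1 / 3),
             qc_isolated = isolated)
}

#' Neighbourhood statistics
#'
#' Mean and population standard deviation of base features across each
#' cell's immediate face-sharing neighbourhood, the cell itself excluded.
#' Cells with exactly one neighbour get standard deviation 0.
#'
#' @param neighbours list of neighbour index vectors (from [adjacency()]).
#' @param base data frame with columns `voronoi_volume`, `n_neighbours`,
#'   `centroid_offset`.
#' @return data frame of six `nbh_*` columns.
#' @export
neighbourhood_stats <- function(neighbours, base) {
  stat <- function(values) {
    m <- vapply(neighbours, function(js)
      if (length(js) == 0) 0 else mean(values[js]), numeric(1))
    s <- vapply(neighbours, function(js) {
      if (length(js) <= 1) return(0)
      v <- values[js]
      sqrt(mean((v - mean(v))^2))
    }, numeric(1))
    list(mean = m, std = s)
  }
  v <- stat(base$voronoi_volume)
  n <- stat(base$n_neighbours)
  o <- stat(base$centroid_offset)
  data.frame(nbh_mean_volume = v$mean, nbh_std_volume = v$std,
             nbh_mean_n_neighbours = n$mean, nbh_std_n_neighbours = n$std,
             nbh_mean_centroid_offset = o$mean, nbh_std_centroid_offset = o$std)
}

#' Full organisational feature extraction
#'
#' Builds the adaptive restricted Voronoi tessellation and assembles the
#' fourteen organisational features for one sample cloud (or a list of
#' clouds, row-bound).
#'
#' @param cloud an [nq_cloud()] (>= 5 nuclei) or list of clouds.
#' @param edge_length bounding dodecahedron edge (um).
#' @param shell_radii shell boundaries for the densities (um).
#' @param keep_tessellation attach the tessellation as an attribute.
#' @return data frame: `sample_id`, `nucleus_id`, the 14 feature columns of
#'   [feature_names()], and `qc_isolated`.
#' @export
organisational_features <- function(cloud, edge_length = 100,
                                    shell_radii = c(10, 20, 30),
                                    keep_tessellation = FALSE) {
  if (!inherits(cloud, "nq_cloud")) {
    stopifnot(is.list(cloud), all(vapply(cloud, inherits, logical(1), "nq_cloud")))
    out <- do.call(rbind, lapply(cloud, organisational_features,
                                 edge_length = edge_length,
                                 shell_radii = shell_radii))
    rownames(out) <- NULL
    return(out)
  }
  if (nrow(cloud$points) < 5L)
    stop("geometric operations need at least 5 nuclei, got ", nrow(cloud$points))
  t0 <- proc.time()[["elapsed"]]
  tess <- adaptive_voronoi(cloud$points, edge_length = edge_length)
  dens <- shell_densities(cloud$points, shell_radii)
  cf <- cell_features(tess)
  nbh <- neighbourhood_stats(tess$neighbours, cf)
  out <- cbind(data.frame(sample_id = cloud$sample_id,
                          nucleus_id = cloud$nucleus_id),
               as.data.frame(dens),
               cf[c("voronoi_density", "voronoi_volume", "n_neighbours",
                    "centroid_offset", "polarity")],
               nbh)
  out <- out[, c("sample_id", "nucleus_id", feature_names())]
  out$qc_isolated <- cf$qc_isolated
  rownames(out) <- NULL
  .nq_log("features", n = nrow(out), sample = cloud$sample_id,
          elapsed = proc.time()[["elapsed"]] - t0)
  if (keep_tessellation) attr(out, "tessellation") <- tess
  out
}

#' Pooled z-score normalisation
#'
#' Standardises the 14 feature columns to zero mean and unit variance. By
#' default the parameters are estimated pooled across all rows (all samples
#' of the dataset), preserving inter-sample differences, and returned for
#' reuse on new data.
#'
#' @param table feature data frame from [organisational_features()].
#' @param params optional stored parameters (list with `mean`, `sd` named by
#'   feature) from a previous call; feature names must match.
#' @param per_sample estimate parameters per sample instead of pooled
#'   (non-default; breaks cross-sample comparability).
#' @return the table with standardised feature columns and attributes
#'   `zscore_params` (the parameters used) and `zscore_pooled`.
#' @export
zscore_features <- function(table, params = NULL, per_sample = FALSE) {
  feats <- feature_names()
  stopifnot(all(feats %in% names(table)))
  if (per_sample && is.null(params)) {
    parts <- lapply(split(table, table$sample_id), zscore_features)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    attr(out, "zscore_params") <- lapply(parts, attr, "zscore_params")
    attr(out, "zscore_pooled") <- FALSE
    return(out)
  }
  if (is.null(params)) {
    mu <- vapply(table[feats], mean, numeric(1))
    sd <- vapply(table[feats], stats::sd, numeric(1))
    low <- names(sd)[sd < 1e-12]
    if (length(low) > 0)
      stop("constant feature column(s): ", paste(low, collapse = ", "))
    params <- list(mean = mu, sd = sd)
  } else {
    if (!setequal(names(params$mean), feats))
      stop("z-score parameter names do not match the feature set")
    params$mean <- params$mean[feats]
    params$sd <- params$sd[feats]
  }
  for (f in feats) table[[f]] <- (table[[f]] - params$mean[[f]]) / params$sd[[f]]
  attr(table, "zscore_params") <- params
  attr(table, "zscore_pooled") <- !per_sample
  table
}

#' Invert a z-score transform
#'
#' @param table z-scored feature table carrying `zscore_params`.
#' @return table on the original feature scale.
#' @export
unzscore_features <- function(table) {
  params <- attr(table, "zscore_params")
  if (is.null(params)) stop("table carries no z-score parameters")
  for (f in feature_names())
    table[[f]] <- table[[f]] * params$sd[[f]] + params$mean[[f]]
  attr(table, "zscore_params") <- NULL
  table
}

#' Correlation-based grouping of features into classes
#'
#' Per-sample feature-feature Pearson correlation matrices are averaged
#' across samples; features are clustered on distance `1 - correlation` with
#' Ward-linkage hierarchical agglomeration, and the tree is cut into
#' `n_classes` groups. Groups are named `density` / `anisotropy` /
#' `irregularity` by maximal overlap with the canonical class map.
#'
#' @param table feature table (raw or z-scored) including `sample_id`.
#' @param n_classes number of classes to cut (default 3).
#' @return list with `classes` (named character vector feature -> class),
#'   `tree` (hclust), and `correlation` (the averaged matrix).
#' @export
classify_features <- function(table, n_classes = 3) {
  feats <- feature_names()
  stopifnot(all(feats %in% names(table)))
  mats <- lapply(split(table[feats], table$sample_id), function(d) {
    if (nrow(d) < 3) stop("need >= 3 cells per sample for correlation")
    stats::cor(as.matrix(d))
  })
  if (any(vapply(mats, function(m) any(!is.finite(m)), logical(1))))
    stop("constant feature within a sample: correlation undefined")
  cbar <- Reduce("+", mats) / length(mats)
  d <- stats::as.dist(1 - cbar)
  tree <- stats::hclust(d, method = "ward.D2")
  cut <- stats::cutree(tree, k = n_classes)
  canon <- .feature_classes()
  classes <- rep(NA_character_, length(feats))
  names(classes) <- feats
  if (n_classes == length(canon)) {
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    best <- NULL; best_score <- -1
    for (p in perms) {
      score <- sum(vapply(1:3, function(g)
        sum(names(cut)[cut == g] %in% canon[[p[g]]]), numeric(1)))
      if (score > best_score) { best_score <- score; best <- p }
    }
    for (g in 1:3) classes[names(cut)[cut == g]] <- names(canon)[best[g]]
  } else {
    classes[] <- paste0("class_", cut)
  }
  list(classes = classes, tree = tree, correlation = cbar)
}
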