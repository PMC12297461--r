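# Per-nucleus fluorescence quantification and expressing/non-expressing
# calls. Nuclear-localised signals are averaged in a dilated spherical
# region around each centroid; cytosolic/punctate signals are integrated
# over each nucleus' Voronoi cell. Calls come from a two-component
# Gaussian signal/noise mixture (lower-mean component = noise) or from
# Otsu's threshold.

.voxel_centres <- function(volume) {
  lapply(1:3, function(j)
    (seq_len(dim(volume$data)[j]) - 0.5) * volume$voxel_size[j])
}

#' Mean nuclear intensity in a dilated spherical region
#'
#' Mean voxel intensity within a sphere of radius
#' `dilation * nuclear_radius` centred on each nucleus, clipped to the
#' volume bounds. Centroids outside the volume yield `NA` (flagged missing,
#' not zero).
#'
#' @param volume an [nq_volume()].
#' @param centroids n x 3 matrix of nuclear centroids (um, volume frame).
#' @param nuclear_radius nuclear radius (um).
#' @param dilation dilation factor of the sampled region (default 2).
#' @return numeric vector of mean intensities (`NA` when outside).
#' @export
nuclear_intensity <- function(volume, centroids, nuclear_radius, dilation = 2) {
  stopifnot(inherits(volume, "nq_volume"), nuclear_radius > 0)
  centroids <- as.matrix(centroids)
  ax <- .voxel_centres(volume)
  ext <- dim(volume$data) * volume$voxel_size
  r <- dilation * nuclear_radius
  vapply(seq_len(nrow(centroids)), function(i) {
    p <- centroids[i, ]
    if (any(p < 0) || any(p > ext)) return(NA_real_)
    win <- lapply(1:3, function(j) which(abs(ax[[j]] - p[j]) <= r))
    if (any(lengths(win) == 0)) return(NA_real_)
    d2 <- outer(outer((ax[[1]][win[[1]]] - p[1])^2,
                      (ax[[2]][win[[2]]] - p[2])^2, "+"),
                (ax[[3]][win[[3]]] - p[3])^2, "+")
    block <- volume$data[win[[1]], win[[2]], win[[3]], drop = FALSE]
    inside <- d2 <= r^2
    if (!any(inside)) return(NA_real_)
    mean(block[inside])
  }, numeric(1))
}

#' Integrated intensity over Voronoi cells
#'
#' Sums voxel intensities over the voxels whose centres fall inside each
#' nucleus' restricted Voronoi cell (nearest-seed assignment among real and
#' auxiliary seeds, limited to the bounding dodecahedron). Every in-bounds
#' voxel contributes to exactly one cell or to none; assigned plus
#' unassigned intensity equals the total exactly.
#'
#' @param volume an [nq_volume()].
#' @param tessellation `nq_tessellation` built from centroids in the same
#'   frame.
#' @return list with `integrated` (per-cell sums), `n_voxels` (per-cell
#'   voxel counts) and `unassigned` (intensity not inside any cell).
#' @export
voronoi_intensity <- function(volume, tessellation) {
  stopifnot(inherits(volume, "nq_volume"),
            inherits(tessellation, "nq_tessellation"))
  ax <- .voxel_centres(volume)
  vox <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  dimnames(vox) <- NULL
  seeds <- rbind(tessellation$points, tessellation$aux_points)
  nn <- cpp_nearest_seed(seeds, vox)
  n_real <- nrow(tessellation$points)
  solid <- dodecahedron_solid(tessellation$edge_length)
  assigned <- nn$index
  assigned[assigned > n_real] <- 0L
  ok <- which(assigned > 0L)
  if (length(ok) > 0) {
    rel <- vox[ok, , drop = FALSE] -
      tessellation$points[assigned[ok], , drop = FALSE]
    inside <- rowSums(sweep(rel %*% t(solid$normals), 2, solid$offsets, ">")) == 0
    assigned[ok[!inside]] <- 0L
  }
  vals <- as.numeric(volume$data)
  integrated <- vapply(seq_len(n_real), function(i)
    sum(vals[assigned == i]), numeric(1))
  list(integrated = integrated,
       n_voxels = tabulate(assigned, nbins = n_real),
       unassigned = sum(vals[assigned == 0L]))
}

#' Two-component signal/noise intensity fit
#'
#' Fits a 1D two-Gaussian mixture by EM (k-means initialised, deterministic
#' given `seed`); the lower-mean component is noise, the higher one signal.
#' A nucleus is called expressing when its posterior signal probability
#' exceeds 0.5. If the two means collapse (within 0.1 pooled sd) the fit is
#' degenerate: all calls are non-expressing and a warning is raised.
#'
#' @param intensities numeric vector (>= 50 finite values).
#' @param seed integer RNG seed.
#' @param nucleus_id optional identifiers carried into the result.
#' @return data frame `nucleus_id`, `raw_intensity`, `posterior_signal`,
#'   `expressing`, with attribute `components` (noise/signal mean, sd,
#'   weight, `degenerate` flag).
#' @export
fit_signal_noise <- function(intensities, seed = 1, nucleus_id = NULL) {
  v <- as.numeric(intensities)
  if (length(v) < 50) stop("need >= 50 intensity values")
  if (any(!is.finite(v))) stop("non-finite intensity values")
  set.seed(seed)
  if (stats::sd(v) < 1e-12) {
    mu <- c(mean(v), mean(v)); sg <- c(1e-6, 1e-6); w <- c(1, 0)
    degenerate <- TRUE
  } else {
    km <- stats::kmeans(v, 2, nstart = 10)
    ord <- order(km$centers)
    mu <- as.numeric(km$centers[ord])
    sg <- pmax(vapply(ord, function(k) stats::sd(v[km$cluster == k]), numeric(1)),
               1e-6 * stats::sd(v), 1e-12)
    w <- as.numeric(table(factor(km$cluster, levels = ord)) / length(v))
    ll_old <- -Inf
    for (it in 1:500) {
      lp <- cbind(log(w[1]) + stats::dnorm(v, mu[1], sg[1], log = TRUE),
                  log(w[2]) + stats::dnorm(v, mu[2], sg[2], log = TRUE))
      mx <- pmax(lp[, 1], lp[, 2])
      lse <- mx + log(exp(lp[, 1] - mx) + exp(lp[, 2] - mx))
      ll <- mean(lse)
      r2 <- exp(lp[, 2] - lse)
      if (is.finite(ll_old) && abs(ll - ll_old) < 1e-8) break
      ll_old <- ll
      w <- c(1 - mean(r2), mean(r2))
      mu <- c(sum((1 - r2) * v) / sum(1 - r2), sum(r2 * v) / sum(r2))
      sg <- sqrt(c(sum((1 - r2) * (v - mu[1])^2) / sum(1 - r2),
                   sum(r2 * (v - mu[2])^2) / sum(r2)))
      sg <- pmax(sg, 1e-6 * stats::sd(v))
    }
    if (mu[2] < mu[1]) { mu <- rev(mu); sg <- rev(sg); w <- rev(w) }
    pooled <- sqrt(mean(sg^2))
    degenerate <- (mu[2] - mu[1]) < 0.1 * pooled
  }
  if (degenerate) {
    warning("degenerate signal/noise fit (component means within 0.1 pooled sd); all calls non-expressing")
    post <- rep(0, length(v))
  } else {
    lp <- cbind(log(w[1]) + stats::dnorm(v, mu[1], sg[1], log = TRUE),
                log(w[2]) + stats::dnorm(v, mu[2], sg[2], log = TRUE))
    mx <- pmax(lp[, 1], lp[, 2])
    post <- exp(lp[, 2] - (mx + log(exp(lp[, 1] - mx) + exp(lp[, 2] - mx))))
  }
  out <- data.frame(
    nucleus_id = if (is.null(nucleus_id)) seq_along(v) else nucleus_id,
    raw_intensity = v, posterior_signal = post, expressing = post > 0.5)
  attr(out, "components") <- list(
    noise = c(mean = mu[1], sd = sg[1], weight = w[1]),
    signal = c(mean = mu[2], sd = sg[2], weight = w[2]),
    degenerate = degenerate)
  out
}

#' Otsu threshold split
#'
#' Threshold maximising the between-class variance on a 256-bin histogram.
#'
#' @param values numeric vector with >= 2 distinct values.
#' @return list `threshold`, `labels` (`"low"`/`"high"` per value).
#' @export
otsu_split <- function(values) {
  v <- as.numeric(values)
  if (length(unique(v)) < 2) stop("Otsu split needs >= 2 distinct values")
  nb <- 256L
  br <- seq(min(v), max(v), length.out = nb + 1L)
  h <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), nb), nb)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(nb + 1)]) / 2
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[nb]
  between <- (mt * w0 - m0)^2 / pmax(w0 * (1 - w0), 1e-300)
  between[w0 <= 0 | w0 >= 1] <- -Inf
  k <- which.max(between)
  thr <- br[k + 1L]
  list(threshold = thr, labels = ifelse(v > thr, "high", "low"))
}

#' Min-max normalisation of a line profile
#'
#' `(I - I_min) / (I_max - I_min)` after optional scalar background
#' subtraction; endpoints map exactly to 0 and 1. Idempotent.
#'
#' @param intensity numeric profile with `max > min`.
#' @param background scalar background to subtract first (default 0).
#' @return normalised profile in `[0, 1]`.
#' @export
normalise_profile <- function(intensity, background = 0) {
  v <- as.numeric(intensity) - background
  rng <- range(v)
  if (diff(rng) <= 0) stop("constant profile: normalisation undefined")
  (v - rng[1]) / diff(rng)
}
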