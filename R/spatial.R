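# Pair correlation function g(r), normalised against the homogeneous
# Poisson expectation. Intensity is estimated from the convex hull of the
# point cloud; edge effects are removed by minus-sampling: for a bin with
# outer radius r, only reference points at least r from the hull boundary
# contribute.

#' Pair correlation function
#'
#' Auto mode (`points_B = NULL`): for each reference point of `points_A`
#' deeper than the bin's outer radius inside the hull, count other A-points
#' per distance shell; `g(r)` is the observed pair density over the Poisson
#' expectation `lambda * shell_volume`. Cross mode: reference points come
#' from A, counted points from B (intensity of B used).
#'
#' @param points_A n x 3 reference point set (>= 100 points, um).
#' @param points_B optional counted point set (cross mode).
#' @param r_max maximum distance (um); must be below half the study-region
#'   diameter.
#' @param dr bin width (um).
#' @param edge_correction `"minus"` (default) erodes the reference set per
#'   bin; `"none"` uses all reference points (biased near the boundary).
#' @return object of class `nq_pcf`: data frame `r` (bin centres), `g`,
#'   `pair_count`, `n_ref`, plus attributes `intensity` (points/um^3) and
#'   `hull_volume`.
#' @export
pair_correlation <- function(points_A, points_B = NULL, r_max = 50, dr = 2,
                             edge_correction = c("minus", "none")) {
  edge_correction <- match.arg(edge_correction)
  A <- .validate_points(points_A)
  if (nrow(A) < 100) stop("need >= 100 reference points")
  same <- is.null(points_B)
  B <- if (same) A else .validate_points(points_B)
  allp <- if (same) A else rbind(A, B)
  hull <- convex_hull_3d(allp)
  diam <- 2 * max(sqrt(rowSums(sweep(allp, 2, hull$centroid)^2)))
  if (r_max >= diam / 2)
    stop(sprintf("r_max (%g) must be below half the study-region diameter (%g)",
                 r_max, diam / 2))
  edges <- seq(0, r_max, by = dr)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  dbound <- if (edge_correction == "minus") hull_boundary_distance(hull, A)
            else rep(Inf, nrow(A))
  if (edge_correction == "minus" && !any(dbound >= r_max))
    stop(sprintf(
      "no reference points survive erosion by r_max = %g; largest usable r_max is about %g",
      r_max, max(dbound)))
  res <- cpp_pair_counts(A, B, dbound, edges, same)
  lambda <- (nrow(B) - as.integer(same)) / hull$volume
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  g <- res$counts / (pmax(res$n_ref, 1) * lambda * shell_vol)
  g[res$n_ref == 0] <- NA_real_
  out <- data.frame(r = (edges[-1] + edges[-length(edges)]) / 2,
                    r_lo = edges[-length(edges)], r_hi = edges[-1],
                    g = g, pair_count = res$counts, n_ref = res$n_ref)
  structure(out, class = c("nq_pcf", "data.frame"),
            intensity = lambda, hull_volume = hull$volume, mode = if (same) "auto" else "cross")
}

#' @export
print.nq_pcf <- function(x, ...) {
  cat(sprintf("Pair correlation (%s mode): %d bins to r = %g um, intensity %.3g /um^3\n",
              attr(x, "mode"), nrow(x), max(x$r_hi), attr(x, "intensity")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
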