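# Staged 2D reference embedding of organisational feature space, and
# projection of partial-imaging data onto it.
#
# The reference embedding follows a two-stage t-SNE protocol: a subsample of
# up to 25,000 cells is pre-embedded with PCA initialisation, multi-scale
# affinities at dual perplexities (50, 500), cosine distance and learning
# rate n/12 (250 iterations at exaggeration 12 / momentum 0.5, then 750 at
# exaggeration 1 / momentum 0.8); remaining cells enter at their
# feature-space nearest neighbour's coordinates and the full embedding is
# optimised at perplexity 30 (500 iterations at exaggeration 4 / momentum
# 0.5, then 500 at exaggeration 3 / momentum 0.8). New data is projected by
# nearest-neighbour initialisation and 500 iterations at exaggeration 3
# with the reference frozen.

.unit_rows <- function(x) {
  n <- sqrt(rowSums(x^2))
  x / pmax(n, 1e-12)
}

# squared cosine distance matrix between row sets
.cosine_dist2 <- function(x, y = NULL) {
  xu <- .unit_rows(x)
  yu <- if (is.null(y)) xu else .unit_rows(y)
  d <- 1 - tcrossprod(xu, yu)
  d[d < 0] <- 0
  d * d
}

# Row-conditional affinities at a fixed perplexity via vectorised binary
# search over the Gaussian bandwidths. `d2` may be rectangular (rows:
# queries, cols: candidates); `self` marks entries to exclude.
.conditional_p <- function(d2, perplexity, self = NULL, iters = 50) {
  n <- nrow(d2)
  if (!is.null(self)) d2[self] <- Inf
  target <- log(perplexity)
  beta <- rep(1, n)
  lo <- rep(0, n)
  hi <- rep(Inf, n)
  P <- NULL
  for (it in seq_len(iters)) {
    W <- exp(-d2 * beta)
    W[!is.finite(d2)] <- 0
    sw <- pmax(rowSums(W), 1e-300)
    P <- W / sw
    # Shannon entropy of each row
    H <- -rowSums(ifelse(P > 0, P * log(P), 0))
    too_high <- H > target
    lo[too_high] <- beta[too_high]
    hi[!too_high] <- beta[!too_high]
    beta <- ifelse(is.finite(hi), (lo + hi) / 2,
                   ifelse(too_high, beta * 2, beta / 2))
  }
  P
}

# multi-scale symmetric affinity matrix (average over perplexities)
.affinity_matrix <- function(x, perplexities) {
  n <- nrow(x)
  d2 <- .cosine_dist2(x)
  self <- cbind(seq_len(n), seq_len(n))
  perplexities <- pmin(perplexities, floor((n - 1) / 3))
  perplexities <- pmax(perplexities, 2)
  P <- Reduce("+", lapply(perplexities, function(pp)
    .conditional_p(d2, pp, self))) / length(perplexities)
  P <- (P + t(P)) / (2 * n)
  P / sum(P)
}

# gradient-descent optimiser for symmetric t-SNE with staged phases
# (momentum and adaptive gains restart at each phase boundary)
.tsne_optimise <- function(Y, P, phases, learning_rate) {
  for (ph in phases)
    Y <- cpp_tsne_phase(Y, P, as.integer(ph$iters), ph$exaggeration,
                        ph$momentum, learning_rate)
  Y
}

# nearest reference row (cosine distance) for each query row
.nearest_feature_neighbour <- function(reference_x, query_x) {
  sim <- tcrossprod(.unit_rows(query_x), .unit_rows(reference_x))
  max.col(sim, ties.method = "first")
}

#' Fit the staged 2D reference embedding
#'
#' @param features z-scored feature table (carrying `zscore_params`) or
#'   matrix; >= 100 cells, no missing values.
#' @param seed integer RNG seed; the embedding is deterministic given seed.
#' @param pre_n pre-embedding subsample size (default 25000).
#' @param pre_perplexities dual perplexities of the pre-embedding.
#' @param full_perplexity perplexity of the full-embedding stage.
#' @param pre_phases,full_phases lists of optimisation phases
#'   (`iters`, `exaggeration`, `momentum`); defaults follow the staged
#'   protocol described above.
#' @return object of class `nq_embedding`: `coords` (n x 2), the reference
#'   `features`, stored `zscore_params`, and a `schedule` record that fully
#'   determines a rerun.
#' @export
fit_reference <- function(features, seed = 1, pre_n = 25000,
                          pre_perplexities = c(50, 500), full_perplexity = 30,
                          pre_phases = list(
                            list(iters = 250, exaggeration = 12, momentum = 0.5),
                            list(iters = 750, exaggeration = 1, momentum = 0.8)),
                          full_phases = list(
                            list(iters = 500, exaggeration = 4, momentum = 0.5),
                            list(iters = 500, exaggeration = 3, momentum = 0.8))) {
  x <- .feature_matrix(features)
  n <- nrow(x)
  if (n < 100) stop("need >= 100 cells for a reference embedding")
  if (3 * min(pre_perplexities) > n - 1)
    warning("perplexities reduced to fit the sample size")
  t0 <- proc.time()[["elapsed"]]
  set.seed(seed)
  sub <- if (n > pre_n) sort(sample.int(n, pre_n)) else seq_len(n)
  xs <- x[sub, , drop = FALSE]
  # stage 1: pre-embedding of the subsample
  P1 <- .affinity_matrix(xs, pre_perplexities)
  pc <- stats::prcomp(xs, rank. = 2)$x
  Y1 <- pc / stats::sd(pc[, 1]) * 1e-4
  Y1 <- .tsne_optimise(Y1, P1, pre_phases, learning_rate = length(sub) / 12)
  # stage 2: remaining cells at their nearest pre-embedded neighbour
  Y <- matrix(0, n, 2)
  Y[sub, ] <- Y1
  rest <- setdiff(seq_len(n), sub)
  if (length(rest) > 0) {
    nn <- .nearest_feature_neighbour(xs, x[rest, , drop = FALSE])
    Y[rest, ] <- Y1[nn, , drop = FALSE]
  }
  Pf <- .affinity_matrix(x, full_perplexity)
  Y <- .tsne_optimise(Y, Pf, full_phases, learning_rate = n / 12)
  .nq_log("embedding", n = n, elapsed = proc.time()[["elapsed"]] - t0)
  structure(list(
    coords = Y, features = x,
    zscore_params = attr(features, "zscore_params"),
    schedule = list(seed = seed, pre_n = length(sub),
                    pre_perplexities = pre_perplexities,
                    full_perplexity = full_perplexity,
                    pre_phases = pre_phases, full_phases = full_phases,
                    learning_rate = "n/12", metric = "cosine",
                    momentum_as_printed = 8, momentum_used = 0.8)),
    class = "nq_embedding")
}

#' @export
print.nq_embedding <- function(x, ...) {
  cat(sprintf("Reference embedding: %d cells, seed %d\n",
              nrow(x$coords), x$schedule$seed))
  invisible(x)
}

#' Project partial data onto a reference embedding
#'
#' New cells must be normalised with the reference's stored z-score
#' parameters (enforced); they are initialised at the embedding coordinates
#' of their feature-space nearest neighbour (cosine distance) and optimised
#' for 500 iterations at exaggeration 3 / momentum 0.8 with the reference
#' coordinates held fixed.
#'
#' @param reference an [fit_reference()] result.
#' @param features z-scored feature table of the new cells; must carry the
#'   reference's `zscore_params` (use
#'   `zscore_features(new, params = reference$zscore_params)`).
#' @param perplexity affinity perplexity towards the reference (default 30).
#' @param iters,exaggeration,momentum optimisation settings.
#' @return n x 2 matrix of embedding coordinates.
#' @export
project_partial <- function(reference, features, perplexity = 30,
                            iters = 500, exaggeration = 3, momentum = 0.8) {
  stopifnot(inherits(reference, "nq_embedding"))
  if (is.data.frame(features)) {
    fn <- intersect(feature_names(), names(features))
    if (!setequal(fn, colnames(reference$features)))
      stop("feature names do not match the reference")
    params <- attr(features, "zscore_params")
    if (is.null(params))
      stop("new data must be z-scored with the reference parameters ",
           "(zscore_features(new, params = reference$zscore_params))")
    if (!is.null(reference$zscore_params) &&
        !isTRUE(all.equal(params, reference$zscore_params, tolerance = 1e-10)))
      stop("new data was z-scored with its own statistics; ",
           "use the reference's stored z-score parameters")
  }
  xq <- .feature_matrix(features)
  xr <- reference$features
  Yr <- reference$coords
  nn <- .nearest_feature_neighbour(xr, xq)
  Yq <- Yr[nn, , drop = FALSE]
  d2 <- .cosine_dist2(xq, xr)
  P <- .conditional_p(d2, min(perplexity, floor((nrow(xr) - 1) / 3)))
  P <- P / sum(P)
  lr <- max(nrow(xq) / 12, 1)
  cpp_tsne_phase_fixed(Yq, Yr, P, as.integer(iters), exaggeration, momentum, lr)
}
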