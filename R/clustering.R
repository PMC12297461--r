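# Organisational motifs and archetypes.
#
# Motifs: full-covariance Gaussian mixture over the 14 z-scored features,
# EM-fitted from a k-means partition (10 restarts), covariance diagonals
# floored at 1e-6, max 500 iterations, tolerance 1e-4 on the mean
# log-likelihood. Archetypes: Ward-linkage agglomeration of motif mean
# profiles, cut at 2 by default; the denser archetype is named "amorphous",
# the other "crystalline".

.feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    feats <- intersect(feature_names(), names(features))
    if (length(feats) == 0) stop("no feature columns found")
    x <- as.matrix(features[feats])
  } else x <- as.matrix(features)
  if (any(!is.finite(x))) stop("missing or non-finite feature values")
  x
}

.log_mvn <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

.gmm_loglik_matrix <- function(x, model) {
  K <- model$K
  ll <- matrix(0, nrow(x), K)
  for (k in seq_len(K))
    ll[, k] <- log(model$weights[k]) +
      .log_mvn(x, model$means[k, ], model$covariances[, , k])
  ll
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Log-density of a fitted motif model
#' @param model an `nq_motif_model`.
#' @param x feature matrix or table on the model's (z-scored) scale.
#' @return log mixture density per row.
#' @export
motif_logdensity <- function(model, x) {
  .logsumexp_rows(.gmm_loglik_matrix(.feature_matrix(x), model))
}

#' Fit organisational motifs (Gaussian mixture model)
#'
#' EM-fitted full-covariance mixture over z-scored organisational features,
#' initialised from a k-means partition; deterministic given `seed`. Labels
#' are maximum-posterior component indices.
#'
#' @param features z-scored feature table (or matrix); no missing values.
#' @param K number of mixture components (default 11).
#' @param seed integer RNG seed (k-means initialisation).
#' @param max_iter,tol EM stopping rule: `max_iter` iterations or change in
#'   mean log-likelihood below `tol`.
#' @param reg covariance regularisation floor added to diagonals.
#' @return object of class `nq_motif_model`: `K`, `means`, `covariances`,
#'   `weights`, `labels` (1..K), `loglik`, `bic`, `converged`, `seed`.
#' @export
fit_motifs <- function(features, K = 11, seed = 1, max_iter = 500,
                       tol = 1e-4, reg = 1e-6) {
  x <- .feature_matrix(features)
  n <- nrow(x); d <- ncol(x)
  if (K < 1) stop("config error: K must be >= 1")
  if (n < 10 * K)
    stop(sprintf("size error: need n >= 10 K cells (n = %d, K = %d)", n, K))
  set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  if (K == 1) resp <- matrix(1, n, 1)
  else {
    km <- stats::kmeans(x, centers = K, nstart = 10, iter.max = 100)
    resp <- matrix(0, n, K)
    resp[cbind(seq_len(n), km$cluster)] <- 1
  }
  means <- matrix(0, K, d); covs <- array(0, c(d, d, K)); w <- numeric(K)
  mstep <- function(resp) {
    nk <- pmax(colSums(resp), 1e-10)
    w <<- nk / n
    for (k in seq_len(K)) {
      means[k, ] <<- colSums(x * resp[, k]) / nk[k]
      xc <- sweep(x, 2, means[k, ])
      covs[, , k] <<- crossprod(xc * resp[, k], xc) / nk[k] + diag(reg, d)
    }
  }
  mstep(resp)
  model <- list(K = K, means = means, covariances = covs, weights = w)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    lm <- .gmm_loglik_matrix(x, model)
    lse <- .logsumexp_rows(lm)
    ll <- mean(lse)
    resp <- exp(lm - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    mstep(resp)
    model$means <- means; model$covariances <- covs; model$weights <- w
  }
  if (!converged)
    warning("EM did not converge within max_iter; returning best-so-far model")
  lm <- .gmm_loglik_matrix(x, model)
  labels <- max.col(lm, ties.method = "first")
  loglik <- sum(.logsumexp_rows(lm))
  p <- (K - 1) + K * d + K * d * (d + 1) / 2
  .nq_log("motifs", n = n, K = K, elapsed = proc.time()[["elapsed"]] - t0)
  structure(c(model, list(labels = labels, loglik = loglik,
                          bic = -2 * loglik + p * log(n),
                          converged = converged, seed = seed,
                          feature_names = colnames(x))),
            class = "nq_motif_model")
}

#' @export
print.nq_motif_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture motif model: K = %d, n = %d cells, BIC = %.1f%s\n",
              x$K, length(x$labels), x$bic,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

# Monte-Carlo draws from a fitted mixture
.gmm_sample <- function(model, n) {
  d <- ncol(model$means)
  comp <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
  out <- matrix(0, n, d)
  for (k in seq_len(model$K)) {
    idx <- which(comp == k)
    if (length(idx) == 0) next
    ch <- chol(model$covariances[, , k])
    out[idx, ] <- matrix(stats::rnorm(length(idx) * d), length(idx), d) %*% ch
    out[idx, ] <- sweep(out[idx, , drop = FALSE], 2, model$means[k, ], "+")
  }
  out
}

# Monte-Carlo Jensen-Shannon divergence between two fitted mixtures
.gmm_jsd <- function(m1, m2, mc_n = 1e4) {
  xs1 <- .gmm_sample(m1, mc_n)
  xs2 <- .gmm_sample(m2, mc_n)
  mix <- function(x) {
    lp <- .logsumexp_rows(.gmm_loglik_matrix(x, m1))
    lq <- .logsumexp_rows(.gmm_loglik_matrix(x, m2))
    lm <- pmax(lp, lq) + log1p(exp(-abs(lp - lq))) - log(2)
    list(lp = lp, lq = lq, lm = lm)
  }
  a <- mix(xs1); b <- mix(xs2)
  0.5 * mean(a$lp - a$lm) + 0.5 * mean(b$lq - b$lm)
}

#' Select the motif component count
#'
#' Fits mixtures over a range of component counts and reports the mean
#' silhouette (on a subsample), the Bayesian information criterion, the
#' Monte-Carlo Jensen-Shannon divergence between each model and the next
#' smaller one, and its finite-difference gradient over K. The recommended K
#' is the first interior local minimum of that gradient (ties toward smaller
#' K; falls back to the gradient argmin).
#'
#' @param features z-scored feature table or matrix.
#' @param K_range increasing integer vector of candidate K within `[2, 64]`,
#'   length >= 3.
#' @param seed integer RNG seed (fits, subsampling, Monte-Carlo draws).
#' @param silhouette_n subsample size for the silhouette score.
#' @param mc_n Monte-Carlo draws per model for the divergence.
#' @return list with `diagnostics` (data frame K, silhouette, bic, jsd,
#'   jsd_gradient) and `recommended_K`.
#' @export
select_motif_count <- function(features, K_range = 2:12, seed = 1,
                               silhouette_n = 5000, mc_n = 1e4) {
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) < 3)
    stop("config error: K_range needs >= 3 values (gradient undefined)")
  if (min(K_range) < 2 || max(K_range) > 64)
    stop("config error: K_range must lie within [2, 64]")
  x <- .feature_matrix(features)
  fits <- list()
  for (K in c(min(K_range) - 1, K_range))
    if (K >= 1) fits[[as.character(K)]] <- fit_motifs(x, K = K, seed = seed)
  set.seed(seed + 1)
  sub <- if (nrow(x) > silhouette_n) sample.int(nrow(x), silhouette_n) else seq_len(nrow(x))
  dsub <- stats::dist(x[sub, , drop = FALSE])
  sil <- vapply(as.character(K_range), function(K) {
    lb <- fits[[K]]$labels[sub]
    if (length(unique(lb)) < 2) return(NA_real_)
    mean(cluster::silhouette(lb, dsub)[, 3])
  }, numeric(1))
  bic <- vapply(as.character(K_range), function(K) fits[[K]]$bic, numeric(1))
  set.seed(seed + 2)
  jsd <- vapply(seq_along(K_range), function(i) {
    prev <- as.character(K_range[i] - 1)
    if (!prev %in% names(fits)) return(NA_real_)
    .gmm_jsd(fits[[as.character(K_range[i])]], fits[[prev]], mc_n)
  }, numeric(1))
  grad <- c(NA, diff(jsd) / diff(K_range))
  inner <- which(!is.na(grad))
  rec <- NA_integer_
  for (i in inner) {
    lo <- if (i - 1 >= 2) grad[i - 1] else Inf
    hi <- if (i + 1 <= length(grad)) grad[i + 1] else Inf
    if (!is.na(grad[i]) && grad[i] < lo && grad[i] <= ifelse(is.na(hi), Inf, hi)) {
      rec <- K_range[i]; break
    }
  }
  if (is.na(rec)) rec <- K_range[which.min(grad)]
  list(diagnostics = data.frame(K = K_range, silhouette = sil, bic = bic,
                                jsd = jsd, jsd_gradient = grad),
       recommended_K = rec)
}

#' Random-forest feature importance of the motif classification
#'
#' Impurity-based importances of the features for predicting motif labels,
#' normalised to sum to one. Features with importance below
#' `1 / (10 n_features)` are flagged as underutilised.
#'
#' @param features z-scored feature table or matrix.
#' @param labels motif labels (>= 2 distinct values).
#' @param seed integer RNG seed.
#' @param ntree number of trees.
#' @return data frame `feature`, `importance`, `underutilised`.
#' @export
feature_importance <- function(features, labels, seed = 1, ntree = 300) {
  x <- .feature_matrix(features)
  if (length(unique(labels)) < 2) stop("need >= 2 distinct motif labels")
  set.seed(seed)
  rf <- randomForest::randomForest(x, factor(labels), ntree = ntree)
  imp <- rf$importance[, "MeanDecreaseGini"]
  imp <- imp / sum(imp)
  data.frame(feature = colnames(x), importance = as.numeric(imp),
             underutilised = as.numeric(imp) < 1 / (10 * ncol(x)),
             row.names = NULL)
}

#' Agglomerate motifs into archetypes
#'
#' Motif mean feature profiles (in z-scored space) are clustered with
#' Ward-linkage agglomeration, the tree is cut at `n_archetypes`, and each
#' cell inherits its motif's archetype. With two archetypes, the one with
#' the higher mean over the density-class features is named `"amorphous"`,
#' the other `"crystalline"`.
#'
#' @param model fitted `nq_motif_model`.
#' @param features the z-scored features the model was fitted on.
#' @param n_archetypes number of archetypes (default 2; must be <= K).
#' @param metric `"euclidean"` distance between profiles (default) or
#'   `"correlation"` (distance `1 - r` between profile vectors).
#' @return object of class `nq_archetype_map`: `motif_archetype` (per motif),
#'   `labels` (per cell), `profiles`, `tree`.
#' @export
cluster_archetypes <- function(model, features, n_archetypes = 2,
                               metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "nq_motif_model"))
  if (n_archetypes > model$K)
    stop("config error: n_archetypes must not exceed the motif count")
  x <- .feature_matrix(features)
  profiles <- do.call(rbind, lapply(seq_len(model$K), function(k) {
    idx <- model$labels == k
    if (any(idx)) colMeans(x[idx, , drop = FALSE]) else model$means[k, ]
  }))
  rownames(profiles) <- paste0("motif_", seq_len(model$K))
  d <- if (metric == "euclidean") stats::dist(profiles)
       else stats::as.dist(1 - stats::cor(t(profiles)))
  tree <- stats::hclust(d, method = "ward.D2")
  grp <- stats::cutree(tree, k = n_archetypes)
  arch_names <- paste0("archetype_", seq_len(n_archetypes))
  if (n_archetypes == 2) {
    dens <- .feature_classes()$density
    dcol <- intersect(dens, colnames(x))
    mdens <- vapply(1:2, function(g)
      mean(profiles[grp == g, dcol, drop = FALSE]), numeric(1))
    arch_names <- character(2)
    arch_names[which.max(mdens)] <- "amorphous"
    arch_names[which.min(mdens)] <- "crystalline"
  }
  motif_archetype <- arch_names[grp]
  structure(list(motif_archetype = motif_archetype,
                 labels = motif_archetype[model$labels],
                 profiles = profiles, tree = tree, metric = metric),
            class = "nq_archetype_map")
}

#' @export
print.nq_archetype_map <- function(x, ...) {
  cat("Archetype map:\n")
  print(table(x$motif_archetype))
  invisible(x)
}

#' Silhouette-selected archetype count
#'
#' Mean silhouette of the motif mean profiles over cuts of the archetype
#' dendrogram; returns the cut with the highest silhouette.
#'
#' @param model fitted `nq_motif_model`.
#' @param features the z-scored features the model was fitted on.
#' @param candidates candidate archetype counts (default 2 to K - 1).
#' @return list `n_archetypes`, `silhouette` (named vector over candidates).
#' @export
select_archetype_count <- function(model, features,
                                   candidates = 2:min(model$K - 1, 8)) {
  x <- .feature_matrix(features)
  profiles <- do.call(rbind, lapply(seq_len(model$K), function(k) {
    idx <- model$labels == k
    if (any(idx)) colMeans(x[idx, , drop = FALSE]) else model$means[k, ]
  }))
  d <- stats::dist(profiles)
  tree <- stats::hclust(d, method = "ward.D2")
  sil <- vapply(candidates, function(k) {
    grp <- stats::cutree(tree, k = k)
    if (length(unique(grp)) < 2) return(NA_real_)
    mean(cluster::silhouette(grp, d)[, 3])
  }, numeric(1))
  names(sil) <- candidates
  list(n_archetypes = candidates[which.max(sil)], silhouette = sil)
}

#' Archetype robustness to the initial motif granularity
#'
#' Refits motifs at several component counts, cuts each into two archetypes
#' and reports the pairwise adjusted Rand index between the per-cell
#' archetype bipartitions.
#'
#' @param features z-scored feature table or matrix.
#' @param K_list motif counts to scan (default 2, 4, 8, 16).
#' @param seed integer RNG seed.
#' @return list with `ari` (pairwise ARI matrix), `labels` (per-K archetype
#'   label matrix) and `min_ari`.
#' @export
archetype_robustness <- function(features, K_list = c(2, 4, 8, 16), seed = 1) {
  x <- .feature_matrix(features)
  if (nrow(x) < 10 * max(K_list))
    stop("size error: need n >= 10 max(K_list) cells")
  labels <- sapply(K_list, function(K) {
    m <- fit_motifs(x, K = K, seed = seed)
    cluster_archetypes(m, x, n_archetypes = 2)$labels
  })
  colnames(labels) <- paste0("K", K_list)
  nk <- length(K_list)
  ari <- matrix(1, nk, nk, dimnames = list(colnames(labels), colnames(labels)))
  for (a in seq_len(nk - 1)) for (b in (a + 1):nk)
    ari[a, b] <- ari[b, a] <-
      mclust::adjustedRandIndex(labels[, a], labels[, b])
  list(ari = ari, labels = labels, min_ari = min(ari))
}
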