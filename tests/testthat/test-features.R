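# The fourteen organisational features, z-scoring and feature classes.

test_that("shell densities count neighbours per shell volume", {
  # isolated point: all shells empty
  far <- rbind(c(0, 0, 0), c(500, 500, 500))
  expect_true(all(shell_densities(far) == 0))
  # one neighbour at 15 um lands in the middle shell only
  two <- rbind(c(0, 0, 0), c(15, 0, 0))
  d <- shell_densities(two)
  expect_equal(d[1, "density_10_20"], 1 / (4 / 3 * pi * (20^3 - 10^3)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(d[1, "density_0_10"], 0, ignore_attr = TRUE)
  expect_equal(d[1, "density_20_30"], 0, ignore_attr = TRUE)
  expect_error(shell_densities(two, radii = c(10, 10, 30)), "config error")
})

test_that("shell densities scale linearly with Poisson intensity", {
  side <- 120
  dens <- vapply(c(0.01, 0.005), function(lam) {
    po <- make_amorphous(lam, c(side, side, side), hardcore = 0, seed = 11)
    d <- shell_densities(po$points)
    int <- rowSums(po$points > 30 & po$points < side - 30) == 3
    colMeans(d[int, , drop = FALSE])
  }, numeric(3))
  expect_equal(dens[, 1] / 0.01, rep(1, 3), tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(dens[, 1] / dens[, 2], rep(2, 3), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("per-cell Voronoi features follow their definitions", {
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  tess <- restricted_voronoi(two, 100)
  cf <- cell_features(tess)
  expect_equal(cf$voronoi_density, c(0.1, 0.1), tolerance = 1e-6)
  expect_equal(cf$n_neighbours, c(1L, 1L))
  # lattice interior: symmetric cell, zero offset and polarity
  g <- as.matrix(expand.grid(0:4, 0:4, 0:4)) * 10
  tl <- adaptive_voronoi(g, 100)
  cfl <- cell_features(tl)
  ctr <- which(rowSums(g == 20) == 3)
  expect_lt(cfl$centroid_offset[ctr], 1e-4)
  expect_lt(cfl$polarity[ctr], 1e-5)
  expect_equal(cfl$voronoi_volume[ctr], 1000, tolerance = 1e-6)
})

test_that("neighbourhood statistics use the population form and handle degeneracy", {
  base <- data.frame(voronoi_volume = c(1, 2, 3, 10),
                     n_neighbours = c(1, 1, 1, 1),
                     centroid_offset = c(0, 0, 0, 0))
  nbr <- list(2:4, c(1L, 3L), c(1L, 2L), 1L)
  st <- neighbourhood_stats(nbr, base)
  expect_equal(st$nbh_mean_volume[1], mean(c(2, 3, 10)))
  expect_equal(st$nbh_std_volume[2], sqrt(mean((c(1, 3) - 2)^2)))
  expect_equal(st$nbh_std_volume[4], 0)  # single neighbour
  # {1,2,3}: mean 2, population sd sqrt(2/3)
  st2 <- neighbourhood_stats(list(2:4, integer(0), integer(0), integer(0)),
                             data.frame(voronoi_volume = c(0, 1, 2, 3),
                                        n_neighbours = 0, centroid_offset = 0))
  expect_equal(st2$nbh_mean_volume[1], 2)
  expect_equal(st2$nbh_std_volume[1], sqrt(2 / 3), tolerance = 1e-12)
})

test_that("the default pipeline emits exactly the fourteen features, all finite", {
  feats <- embryo_features()
  expect_identical(sum(names(feats) %in% feature_names()), 14L)
  x <- as.matrix(feats[feature_names()])
  expect_true(all(is.finite(x)))
  # raw densities, volumes, offsets, counts are non-negative
  expect_true(all(x >= 0))
})

test_that("features are invariant under rigid motion of the cloud", {
  set.seed(21)
  pts <- matrix(stats::runif(2400, 0, 60), 800, 3)
  cl1 <- nq_cloud(pts, "a")
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  cl2 <- nq_cloud(pts %*% t(R) + 20, "a")
  f1 <- suppressWarnings(organisational_features(cl1, keep_tessellation = TRUE))
  f2 <- suppressWarnings(organisational_features(cl2, keep_tessellation = TRUE))
  t1 <- attr(f1, "tessellation"); t2 <- attr(f2, "tessellation")
  # compare cells that are interior (with interior neighbourhoods) in both
  both <- !t1$is_boundary & !t2$is_boundary
  core <- which(both & vapply(seq_len(nrow(pts)), function(i)
    all(both[t1$neighbours[[i]]]), logical(1)))
  expect_gt(length(core), 10)
  a <- as.matrix(f1[core, feature_names()])
  b <- as.matrix(f2[core, feature_names()])
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("z-scoring pools across samples, is invertible and rejects constants", {
  feats <- embryo_features()
  z <- embryo_zscored()
  x <- as.matrix(z[feature_names()])
  expect_true(all(abs(colMeans(x)) < 1e-9))
  expect_true(all(abs(apply(x, 2, stats::sd) - 1) < 1e-9))
  # inverse transform returns the original values
  back <- unzscore_features(z)
  expect_equal(as.matrix(back[feature_names()]),
               as.matrix(feats[feature_names()]), tolerance = 1e-12)
  # stored parameters preserve between-sample differences in sign
  f2 <- feats
  f2$sample_id <- rep(c("s1", "s2"), length.out = nrow(f2))
  f2$voronoi_volume[f2$sample_id == "s2"] <- f2$voronoi_volume[f2$sample_id == "s2"] + 50
  z2 <- zscore_features(f2)
  d <- tapply(z2$voronoi_volume, z2$sample_id, mean)
  expect_gt(d["s2"], d["s1"])
  # constant column is rejected by name
  bad <- feats
  bad$polarity <- 1
  expect_error(zscore_features(bad), "polarity")
  # reusing stored params on new data reproduces the same transform
  z3 <- zscore_features(feats, params = attr(z, "zscore_params"))
  expect_equal(z3$voronoi_volume, z$voronoi_volume)
})

test_that("feature classes recover correlation blocks and the canonical map", {
  # three independent blocks with within-block correlation 0.9
  set.seed(11)
  n <- 2000
  blocks <- lapply(c(5, 5, 4), function(k) {
    base <- stats::rnorm(n)
    vapply(seq_len(k), function(j) 0.9 * base + sqrt(1 - 0.81) * stats::rnorm(n),
           numeric(n))
  })
  x <- do.call(cbind, blocks)
  colnames(x) <- feature_names()
  tab <- cbind(data.frame(sample_id = "s1", nucleus_id = seq_len(n)),
               as.data.frame(x))
  cf <- classify_features(tab)
  truth <- rep(1:3, c(5, 5, 4))
  expect_equal(mclust::adjustedRandIndex(cf$classes, truth), 1)
  # a duplicated feature lands with its twin
  tab2 <- tab
  tab2$polarity <- tab2$voronoi_volume
  cf2 <- classify_features(tab2)
  expect_identical(cf2$classes[["polarity"]], cf2$classes[["voronoi_volume"]])
  # on the embryo, the density features co-cluster (>= 3 of 4 together)
  cfe <- classify_features(embryo_zscored())
  dens <- cfe$classes[c("density_0_10", "density_10_20", "density_20_30",
                        "voronoi_density")]
  expect_gte(max(table(dens)), 3L)
})

test_that("feature directions separate amorphous from crystalline organisation", {
  emb <- embryo_cloud()
  feats <- embryo_features()
  int <- which(emb$metadata$interior)
  set.seed(2)
  am <- sample(int[emb$metadata$population[int] == "amorphous"], 1000)
  cr <- sample(int[emb$metadata$population[int] == "crystalline"], 1000)
  wt <- function(col, alt) stats::wilcox.test(feats[[col]][am],
                                              feats[[col]][cr],
                                              alternative = alt)$p.value
  # amorphous: higher shell densities, smaller cells, more variable
  # neighbour counts
  expect_lt(wt("density_0_10", "greater"), 1e-3)
  expect_lt(wt("density_10_20", "greater"), 1e-3)
  expect_lt(wt("voronoi_volume", "less"), 1e-3)
  expect_lt(wt("nbh_std_n_neighbours", "greater"), 1e-3)
  # volume and local density are negatively correlated on the mixture
  expect_lt(stats::cor(feats$voronoi_volume[int], feats$density_0_10[int]),
            -0.5)
})
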