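# Synthetic generators: lattices, hard-core processes, the two-population
# embryo, intensity mixtures and blob volumes.

test_that("lattices have exact spacing, anisotropy and bounded jitter", {
  lat <- make_lattice(spacing = 10, dims = c(5, 5, 5), jitter_sd = 0, seed = 1)
  expect_equal(length(lat), 125L)
  expect_equal(nuqloud:::cpp_min_pair_distance(lat$points), 10)
  expect_true(all(lat$metadata$population == "crystalline"))

  # axis scales stretch one axis: spacings 10 (x, y) and 30 (z)
  an <- make_lattice(spacing = 10, dims = c(4, 4, 4), jitter_sd = 0,
                     axis_scales = c(1, 1, 3), seed = 1)
  expect_equal(nuqloud:::cpp_min_pair_distance(an$points), 10)
  z <- sort(unique(an$points[, 3]))
  expect_equal(diff(z), rep(30, 3))

  # jittered lattice: adjacent-pair distances stay at the spacing; the
  # nearest-neighbour mean sits below it (minimum over six jittered
  # neighbours; expected values frozen from a direct simulation oracle)
  stats_by_seed <- vapply(1:3, function(s) {
    p <- make_lattice(10, c(6, 6, 6), jitter_sd = 0.5, seed = s)$points
    nn <- mean(vapply(seq_len(nrow(p)), function(i)
      min(sqrt(rowSums(sweep(p[-i, ], 2, p[i, ])^2))), numeric(1)))
    ix <- which(rep(1:6, 36) < 6)
    adj <- mean(sqrt(rowSums((p[ix + 1, ] - p[ix, ])^2)))
    c(nn = nn, adj = adj)
  }, numeric(2))
  expect_true(all(abs(stats_by_seed["adj", ] - 10) < 0.2))
  expect_true(all(abs(stats_by_seed["nn", ] - 9.20) < 0.2))

  expect_error(make_lattice(10, jitter_sd = 3), "jitter_sd")
})

test_that("hard-core placement honours separation and Poisson counts", {
  hc <- make_amorphous(8e-4, region = c(100, 100, 100), hardcore = 5, seed = 1)
  n <- length(hc)
  expect_gt(n, 800 - 4 * sqrt(800))
  expect_lt(n, 800 + 4 * sqrt(800))
  expect_gte(nuqloud:::cpp_min_pair_distance(hc$points), 5)

  # hardcore 0 is a Poisson process
  po <- make_amorphous(1e-3, c(100, 100, 100), hardcore = 0, seed = 2)
  expect_gt(length(po), 1000 - 4 * sqrt(1000))
  expect_lt(length(po), 1000 + 4 * sqrt(1000))

  # determinism and infeasible packing
  hc2 <- make_amorphous(8e-4, c(100, 100, 100), hardcore = 5, seed = 1)
  expect_identical(hc2$points, hc$points)
  expect_error(make_amorphous(5e-3, c(100, 100, 100), hardcore = 10),
               "infeasible packing")
})

test_that("the synthetic embryo is large, labelled and deterministic", {
  emb <- embryo_cloud()
  expect_gte(length(emb), 20000L)
  expect_setequal(unique(emb$metadata$population), c("amorphous", "crystalline"))
  expect_true(any(emb$metadata$interior))
  expect_true(all(c("dist_hull", "interior") %in% names(emb$metadata)))
  emb2 <- make_embryo(seed = 1)
  expect_identical(emb2$points, emb$points)
  # population geometry: amorphous fills x < 0, crystalline x > 0
  expect_true(all(emb$points[emb$metadata$population == "amorphous", 1] < 0))
  expect_true(all(emb$points[emb$metadata$population == "crystalline", 1] > 0))
})

test_that("embryo populations separate in local density and linearly in feature space", {
  emb <- embryo_cloud()
  feats <- embryo_features()
  int <- emb$metadata$interior
  am <- int & emb$metadata$population == "amorphous"
  cr <- int & emb$metadata$population == "crystalline"
  # interior amorphous cells are denser than interior crystalline cells at
  # the 0-10 um scale: the bulks separate, overlapping only in the Poisson
  # tails of the shell counts
  # shell counts are discrete, so touching quantiles count as separated
  expect_gte(stats::quantile(feats$density_0_10[am], 0.10),
             stats::quantile(feats$density_0_10[cr], 0.90))
  expect_gt(stats::median(feats$density_0_10[am]),
            1.5 * stats::median(feats$density_0_10[cr]))
  # a linear read-out of the 14 raw features separates the populations
  y <- as.integer(emb$metadata$population[int] == "amorphous")
  x <- as.matrix(feats[int, feature_names()])
  fit <- suppressWarnings(stats::glm.fit(cbind(1, scale(x)), y,
                                         family = stats::binomial()))
  acc <- mean((fit$fitted.values > 0.5) == (y == 1))
  expect_gte(acc, 0.95)
})

test_that("intensity mixtures are labelled draws from the stated components", {
  mx <- make_intensity_mixture(1e4, 100, 10, 1000, 100, 0.5, seed = 1)
  expect_length(mx$values, 1e4)
  m_n <- mean(mx$values[mx$labels == "noise"])
  m_s <- mean(mx$values[mx$labels == "signal"])
  expect_lt(abs(m_n - 100), 3 * 10 / sqrt(sum(mx$labels == "noise")) * 3 + 1)
  expect_lt(abs(m_s - 1000), 3 * 100 / sqrt(sum(mx$labels == "signal")) * 3 + 10)
  expect_true(all(make_intensity_mixture(100, signal_fraction = 0,
                                         seed = 1)$labels == "noise"))
  expect_error(make_intensity_mixture(10, 100, 10, 50, 5), "signal_mean")
})

test_that("blob volumes integrate to the Gaussian mass", {
  pts <- rbind(c(20, 20, 20), c(35, 30, 25))
  img <- make_blob_image(pts, c(5, 3), blob_sd = 2, shape = c(50, 50, 50))
  peak <- which(img$data == max(img$data), arr.ind = TRUE)[1, ]
  expect_true(all(abs(peak - 0.5 - pts[1, ]) <= 1))
  expect_equal(sum(img$data), (5 + 3) * (2 * pi)^1.5 * 2^3, tolerance = 0.01)
  zero <- make_blob_image(pts, c(0, 0), 2, c(30, 30, 30))
  expect_true(all(zero$data == 0))
})
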