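# Shared fixtures, computed lazily and cached for the whole test run.
# The synthetic embryo pipeline (tessellation + 14 features + motif model)
# is the expensive part; every test that needs it reuses one computation.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

embryo_cloud <- function() fixture("embryo", function() make_embryo(seed = 1))

embryo_features <- function() fixture("embryo_feats", function()
  suppressWarnings(organisational_features(embryo_cloud())))

embryo_zscored <- function() fixture("embryo_z", function()
  zscore_features(embryo_features()))

embryo_motifs <- function() fixture("embryo_motifs", function()
  fit_motifs(embryo_zscored(), K = 11, seed = 1))

embryo_archetypes <- function() fixture("embryo_arch", function()
  cluster_archetypes(embryo_motifs(), embryo_zscored()))

embryo_robustness <- function() fixture("embryo_robust", function()
  archetype_robustness(embryo_zscored(), K_list = c(2, 4, 8, 16), seed = 1))

# small dense random cloud for geometry oracle comparisons
oracle_cloud <- function() fixture("oracle_cloud", function() {
  set.seed(42)
  matrix(stats::runif(120, 0, 35), 40, 3)
})

# two well-separated 14-d feature clusters for embedding tests
embedding_fixture <- function() fixture("embed_fix", function() {
  set.seed(5)
  n <- 600
  x <- rbind(matrix(stats::rnorm(n * 14, 0, 1), n, 14),
             matrix(stats::rnorm(n * 14, 6, 1), n, 14))
  list(x = x, labels = rep(1:2, each = n), n = n)
})
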