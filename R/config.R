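# Run configuration and structured logging.

#' Default run configuration
#'
#' One declarative object collecting every tunable of the pipeline; values
#' can be overridden by arguments, a YAML file ([read_config()]) or CLI
#' flags. Every stochastic operation takes an explicit seed that is
#' recorded in output metadata.
#'
#' @param ... named overrides of the defaults.
#' @return named list of class `nq_config`.
#' @export
nq_config <- function(...) {
  cfg <- list(
    edge_length = 100,             # bounding dodecahedron edge, um
    shell_radii = c(10, 20, 30),   # density shell boundaries, um
    K = 11,                        # motif components
    n_archetypes = 2,
    seed = 1,
    gr = list(r_max = 50, dr = 2), # pair correlation, um
    embedding = list(pre_n = 25000, pre_perplexities = c(50, 500),
                     full_perplexity = 30),
    expression = list(strategy = "nuclear", nuclear_radius = 3, dilation = 2)
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  if (any(diff(c(0, cfg$shell_radii)) <= 0))
    stop("config error: shell radii must be strictly increasing and positive")
  if (cfg$K < 1 || cfg$n_archetypes < 1)
    stop("config error: K and n_archetypes must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "nq_config")
}

#' Read a YAML configuration file
#'
#' @param path YAML file with any subset of the [nq_config()] fields.
#' @return an `nq_config` with the file's overrides applied.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(nq_config, vals)
}

# one structured log line per pipeline stage (opt-in via
# options(nuqloud.verbose = TRUE))
.nq_log <- function(stage, ...) {
  if (!isTRUE(getOption("nuqloud.verbose", FALSE))) return(invisible())
  kv <- list(...)
  msg <- paste(sprintf("%s=%s", names(kv),
                       vapply(kv, function(v) format(v, digits = 4), "")),
               collapse = " ")
  message(sprintf("[nuqloud] stage=%s %s", stage, msg))
  invisible()
}
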