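#' Default experiment configuration
#'
#' The study conditions of the multi-resolution experiment: a 960 x 960 m
#' synthetic landscape (the extent is a multiple of 960 m, the least common
#' multiple of the six cell sizes, so every resolution tiles exactly) on a
#' 16 m baseline with the default site-class shares, six analysis
#' resolutions, power benefit z = 0.25, unit weights and top fractions of
#' 2 % and 10 %.
#'
#' @return nested list with `landscape` and `analysis` blocks.
#' @export
default_config <- function() {
  list(
    landscape = list(
      extent_x = 960, extent_y = 960, cell_size = 16,
      shares = c(0.324, 0.511, 0.156, 0.009),
      smoothness = 80, seed = 1L,
      species = NULL,   # NULL -> default_species_params()
      ddw = NULL        # NULL -> generate_ddw() defaults
    ),
    analysis = list(
      resolutions = c(16, 32, 48, 64, 80, 96),
      z = 0.25, weights = 1,
      fractions = c(0.02, 0.10),
      tie_rule = "lexicographic", warp = 1L
    )
  )
}

#' Load and validate an experiment configuration from YAML
#'
#' Reads a YAML file with optional `landscape:` and `analysis:` blocks,
#' fills unspecified values with the defaults of [default_config()], and
#' rejects unknown keys by name.  An empty file yields the full default
#' configuration.
#'
#' @param path path to a YAML file.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config block: ", paste(bad, collapse = ", "))
  for (blk in names(user)) {
    bad <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
    if (length(bad))
      stop("unknown config key in `", blk, "`: ",
           paste(bad, collapse = ", "))
    for (k in names(user[[blk]])) cfg[[blk]][[k]] <- user[[blk]][[k]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  lc <- cfg$landscape; an <- cfg$analysis
  check_divisible(lc$extent_x, lc$cell_size, "extent_x")
  check_divisible(lc$extent_y, lc$cell_size, "extent_y")
  if (abs(sum(lc$shares) - 1) > 1e-9) stop("site-class shares must sum to 1")
  an$resolutions <- as.numeric(an$resolutions)
  base <- min(an$resolutions)
  if (base != lc$cell_size)
    stop("finest analysis resolution (", base,
         " m) must equal the baseline cell size (", lc$cell_size, " m)")
  for (r in an$resolutions) {
    if (abs(r / base - round(r / base)) > 1e-9)
      stop("resolution ", r, " m is not a multiple of the baseline ",
           base, " m")
    check_divisible(lc$extent_x, r, "extent_x")
    check_divisible(lc$extent_y, r, "extent_y")
  }
  if (any(an$fractions <= 0 | an$fractions > 1))
    stop("top fractions must lie in (0, 1]")
  if (any(an$z <= 0 | an$z > 1)) stop("z must lie in (0, 1]")
  if (!an$tie_rule %in% c("lexicographic", "random"))
    stop("tie_rule must be 'lexicographic' or 'random'")
  if (an$warp < 1) stop("warp must be a positive integer")
  cfg$landscape$seed <- as.integer(lc$seed)
  cfg$analysis <- an
  cfg
}

# small stable polynomial hash of the serialized configuration, for
# stamping outputs with provenance
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, version = 2L))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}
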