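#' Expand a coarse selection mask to the baseline grid
#'
#' Every selected coarse cell expands to the `(R / baseline)^2` baseline
#' cells it covers, so selections made at different resolutions can be
#' compared cell-by-cell on the baseline lattice.
#'
#' @param mask logical matrix at the coarse resolution.
#' @param factor integer edge ratio coarse/baseline (e.g. 6 for 96 m on a
#'   16 m baseline).
#' @return logical matrix at the baseline resolution.
#' @export
footprint <- function(mask, factor) {
  if (factor != round(factor) || factor < 1)
    stop("footprint factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(mask)
  mask[rep(seq_len(nrow(mask)), each = factor),
       rep(seq_len(ncol(mask)), each = factor), drop = FALSE]
}

#' Spatial error between baseline and coarse priority areas
#'
#' Overlap is the baseline-relative shared area
#' `|base & coarse| / |base|`; the error of omission is its complement, so
#' the two always sum to 1.
#'
#' @param mask_base logical baseline top-fraction mask.
#' @param mask_coarse_fp coarse top-fraction mask already expanded to the
#'   baseline grid with [footprint()].
#' @return named numeric vector `c(overlap, omission)`.
#' @export
spatial_error <- function(mask_base, mask_coarse_fp) {
  if (!identical(dim(mask_base), dim(mask_coarse_fp)))
    stop("masks are on different grids")
  nb <- sum(mask_base)
  if (nb == 0L) stop("baseline mask is empty")
  ov <- sum(mask_base & mask_coarse_fp) / nb
  c(overlap = ov, omission = 1 - ov)
}

#' Per-feature conservation error of a coarse solution
#'
#' Evaluated on the baseline data: for each feature j, the protected sum
#' `S_j(mask)` is the total of the baseline layer inside the mask, and the
#' conservation error is the relative change
#' `(S_j(coarse) - S_j(base)) / S_j(base)` — negative when the coarse
#' solution protects less of the feature than the baseline solution,
#' positive when it protects more.  Features absent from the baseline
#' solution's selection (`S_j(base) = 0`) are flagged as undefined rather
#' than propagated as NaN.
#'
#' @param stack16 baseline `feature_stack`.
#' @param mask_base,mask_coarse_fp baseline-grid masks (see
#'   [spatial_error()]).
#' @return data.frame: manifest columns plus `protected_base`,
#'   `protected_coarse`, `conservation_error`, `defined`.
#' @export
conservation_error <- function(stack16, mask_base, mask_coarse_fp) {
  d <- dim(stack16$values)
  if (!identical(d[1:2], dim(mask_base)) ||
      !identical(d[1:2], dim(mask_coarse_fp)))
    stop("masks and baseline stack are on different grids")
  nlay <- d[3]
  sb <- sc <- numeric(nlay)
  for (j in seq_len(nlay)) {
    lay <- stack16$values[, , j]
    sb[j] <- sum(lay[mask_base])
    sc[j] <- sum(lay[mask_coarse_fp])
  }
  defined <- sb > 0
  err <- rep(NA_real_, nlay)
  err[defined] <- (sc[defined] - sb[defined]) / sb[defined]
  cbind(stack16$manifest,
        data.frame(protected_base = sb, protected_coarse = sc,
                   conservation_error = err, defined = defined))
}

#' Run the full multi-resolution prioritization experiment
#'
#' Simulates (or accepts) a baseline feature stack, aggregates it to every
#' configured resolution, ranks each stack independently, and for each
#' top fraction compares the coarse solutions against the baseline
#' solution: spatial overlap/omission and per-feature conservation error
#' evaluated on the baseline data.
#'
#' @param config an experiment configuration from [default_config()] or
#'   [load_config()].
#' @param stack16 optional user-supplied baseline `feature_stack`; when
#'   `NULL` a synthetic landscape is generated from `config$landscape`.
#' @param out_dir optional directory; when given, the report tables are
#'   written as CSV and the rank rasters as ASCII grids, each stamped with
#'   the seed and a hash of the configuration.
#' @return list of class `coarsening_report`: `spatial` (data.frame
#'   resolution_m, top_fraction, overlap, omission, footprint_cells),
#'   `conservation` (data.frame resolution_m, top_fraction + per-feature
#'   rows), `rankings` (per-resolution `priority_ranking`s), `curves`
#'   (per-resolution performance curves at the evaluation fractions),
#'   `config`, and `landscape` (the simulated objects, when generated).
#' @export
run_experiment <- function(config = default_config(), stack16 = NULL,
                           out_dir = NULL) {
  config <- validate_config(config)
  lc <- config$landscape
  landscape <- NULL
  if (is.null(stack16)) {
    sg <- generate_site_classes(lc$extent_x, lc$extent_y, lc$cell_size,
                                lc$shares, lc$smoothness, seed = lc$seed)
    sp <- if (is.null(lc$species)) default_species_params() else
      lapply(lc$species, function(a) do.call(species_params, a))
    trees <- generate_trees(sg, params = sp, seed = lc$seed + 1L)
    ddw <- do.call(generate_ddw,
                   c(list(site_grid = sg, seed = lc$seed + 2L),
                     lc$ddw))
    stack16 <- build_baseline_stack(trees, ddw, sg)
    landscape <- list(site_grid = sg, trees = trees, ddw = ddw)
  }
  an <- config$analysis
  pyramid <- build_pyramid(stack16, an$resolutions)
  base_res <- min(an$resolutions)
  rankings <- lapply(pyramid, function(s)
    suppressWarnings(rank_cells(s, z = an$z, weights = an$weights,
                                warp = an$warp, tie_rule = an$tie_rule,
                                seed = lc$seed)))
  base_rank <- rankings[[as.character(base_res)]]
  base_masks <- lapply(an$fractions, function(p) top_fraction(base_rank, p))
  names(base_masks) <- as.character(an$fractions)

  spatial <- list(); conservation <- list()
  for (res in an$resolutions) {
    rk <- rankings[[as.character(res)]]
    f <- as.integer(res / base_res)
    for (p in an$fractions) {
      fp <- footprint(top_fraction(rk, p), f)
      mb <- base_masks[[as.character(p)]]
      se <- spatial_error(mb, fp)
      spatial[[length(spatial) + 1L]] <- data.frame(
        resolution_m = res, top_fraction = p,
        overlap = se[["overlap"]], omission = se[["omission"]],
        footprint_cells = sum(fp))
      ce <- conservation_error(stack16, mb, fp)
      ce <- cbind(data.frame(resolution_m = res, top_fraction = p), ce)
      conservation[[length(conservation) + 1L]] <- ce
    }
  }
  curves <- lapply(names(pyramid), function(r)
    performance_curve(rankings[[r]], pyramid[[r]],
                      fractions = sort(unique(c(0, an$fractions, 1)))))
  names(curves) <- names(pyramid)
  report <- structure(list(spatial = do.call(rbind, spatial),
                           conservation = do.call(rbind, conservation),
                           rankings = rankings, curves = curves,
                           config = config, landscape = landscape),
                      class = "coarsening_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.coarsening_report <- function(x, ...) {
  cat("Multi-resolution prioritization report\n")
  cat("  resolutions (m):",
      paste(x$config$analysis$resolutions, collapse = ", "), "\n")
  cat("  top fractions:",
      paste(x$config$analysis$fractions, collapse = ", "), "\n")
  cat("  seed:", x$config$landscape$seed, "\n\n")
  cat("Spatial error vs baseline:\n")
  print(x$spatial, row.names = FALSE, digits = 3)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- data.frame(seed = report$config$landscape$seed,
                      config_hash = config_hash(report$config))
  stamped <- function(df) cbind(df, stamp)
  utils::write.csv(stamped(report$spatial),
                   file.path(out_dir, "spatial_error.csv"),
                   row.names = FALSE)
  utils::write.csv(stamped(report$conservation),
                   file.path(out_dir, "conservation_error.csv"),
                   row.names = FALSE)
  for (r in names(report$rankings))
    write_ascii_grid(report$rankings[[r]]$rank,
                     file.path(out_dir, paste0("rank_", r, "m.asc")),
                     cell_size = as.numeric(r))
  for (r in names(report$curves))
    utils::write.csv(report$curves[[r]],
                     file.path(out_dir, paste0("performance_", r, "m.csv")),
                     row.names = FALSE)
  invisible(out_dir)
}
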