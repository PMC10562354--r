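#' Block-aggregate one feature layer to a coarser resolution
#'
#' Each coarse cell's value is the mean, maximum, or sum of the k x k block
#' of fine cells it covers, where k = target / baseline.  The rule is bound
#' to the variable type: mean height aggregates by `mean`, maximum height
#' by `max`, volumes by `sum` (which conserves landscape totals exactly).
#' The plain block mean counts empty (zero) fine cells; `mean_nonzero`
#' averages only over the non-empty fine cells of the block and is exposed
#' as an alternative convention.
#'
#' @param layer numeric matrix at the fine resolution.
#' @param factor integer block edge k (= target resolution / fine
#'   resolution); the layer dimensions must be divisible by it.
#' @param rule one of `"mean"`, `"max"`, `"sum"`, `"mean_nonzero"`.
#' @return coarse matrix of dimension `dim(layer) / factor`.
#' @export
aggregate_layer <- function(layer, factor, rule = c("mean", "max", "sum",
                                                    "mean_nonzero")) {
  rule <- match.arg(rule)
  if (factor != round(factor) || factor < 1)
    stop("aggregation factor must be a positive integer (got ", factor, ")")
  factor <- as.integer(factor)
  if (factor == 1L) return(layer)
  nr <- nrow(layer); nc <- ncol(layer)
  if (nr %% factor || nc %% factor)
    stop("layer of ", nr, " x ", nc,
         " cells is not divisible into blocks of ", factor)
  switch(rule,
         sum = block_sum(layer, factor),
         mean = block_sum(layer, factor) / factor^2,
         mean_nonzero = {
           s <- block_sum(layer, factor)
           n <- block_sum((layer != 0) * 1, factor)
           out <- s / pmax(n, 1)
           out[n == 0] <- 0
           out
         },
         max = block_max(layer, factor))
}

# exact block sum via two rowsum passes
block_sum <- function(m, k) {
  g1 <- rep(seq_len(nrow(m) %/% k), each = k)
  s <- rowsum(m, g1, reorder = TRUE)
  t(rowsum(t(s), rep(seq_len(ncol(m) %/% k), each = k), reorder = TRUE))
}

block_max <- function(m, k) {
  nr <- nrow(m) %/% k; nc <- ncol(m) %/% k
  out <- matrix(-Inf, nr, nc)
  for (i in seq_len(k))
    for (j in seq_len(k))
      out <- pmax(out, m[seq(i, by = k, length.out = nr),
                         seq(j, by = k, length.out = nc), drop = FALSE])
  out
}

aggregation_rule <- function(variable) {
  switch(variable,
         Hmean = "mean",
         Hmax = "max",
         Vol = ,
         DDWVol = "sum",
         stop("no aggregation rule for variable ", variable))
}

#' Aggregate a whole feature stack to a coarser resolution
#'
#' Applies the variable-bound rule (`Hmean` -> mean, `Hmax` -> max,
#' `Vol`/`DDWVol` -> sum) to every layer.  Aggregation always starts from
#' the supplied stack; chaining through intermediate resolutions is never
#' done, so the max rule has no path dependence.
#'
#' @param stack baseline `feature_stack`.
#' @param target_resolution metres; must be an integer multiple of the
#'   stack's resolution, and the extent must tile exactly.
#' @param mean_rule `"mean"` (block mean including empty cells, default)
#'   or `"mean_nonzero"`.
#' @return `feature_stack` at `target_resolution` with the same manifest.
#' @export
aggregate_stack <- function(stack, target_resolution, mean_rule = "mean") {
  f <- target_resolution / stack$resolution
  if (abs(f - round(f)) > 1e-9)
    stop("target resolution ", target_resolution,
         " m is not an integer multiple of the baseline ",
         stack$resolution, " m")
  f <- as.integer(round(f))
  if (f == 1L) return(stack)
  d <- dim(stack$values)
  vals <- array(0, c(d[1] %/% f, d[2] %/% f, d[3]))
  for (j in seq_len(d[3])) {
    rule <- aggregation_rule(stack$manifest$variable[j])
    if (rule == "mean" && mean_rule == "mean_nonzero") rule <- "mean_nonzero"
    vals[, , j] <- aggregate_layer(stack$values[, , j], f, rule)
  }
  feature_stack(vals, stack$manifest, target_resolution)
}

#' Build the multi-resolution stack pyramid
#'
#' Derives every coarser stack directly from the baseline (never chained),
#' producing the six analysis stacks.  With a 52-layer baseline this yields
#' 312 layers in total across the default resolutions.
#'
#' @param stack16 baseline `feature_stack` (16 m).
#' @param resolutions metres (default `c(16, 32, 48, 64, 80, 96)`); each
#'   must be a multiple of the baseline resolution and tile the extent,
#'   which the default extent rule (multiples of 960 m, the least common
#'   multiple of the six cell sizes) guarantees.
#' @param mean_rule see [aggregate_stack()].
#' @return named list of `feature_stack`s, names `"16"`, `"32"`, ...
#' @export
build_pyramid <- function(stack16, resolutions = c(16, 32, 48, 64, 80, 96),
                          mean_rule = "mean") {
  out <- lapply(resolutions, function(r)
    aggregate_stack(stack16, r, mean_rule = mean_rule))
  names(out) <- as.character(resolutions)
  out
}

#' Cell-area ratio between two resolutions
#'
#' Going from 16 m to 32 m cells quadruples the cell area; this helper
#' returns `(res_coarse / res_fine)^2`.
#'
#' @param res_coarse,res_fine cell edge lengths in metres, > 0.
#' @return the areal ratio.
#' @examples
#' cell_area_ratio(32, 16)  # 4
#' @export
cell_area_ratio <- function(res_coarse, res_fine) {
  stopifnot(res_coarse > 0, res_fine > 0)
  (res_coarse / res_fine)^2
}
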