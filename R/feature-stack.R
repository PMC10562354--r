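#' Feature stacks
#'
#' A `feature_stack` holds the raster biodiversity feature layers entering
#' one prioritization run at a single resolution: a 3-D array
#' `values[row, col, layer]` plus a `manifest` data.frame mapping each layer
#' to its `(variable, species, site_class)` identity.  Variables are `Hmax`
#' (height of the tallest tree, m), `Hmean` (mean tree height, m), `Vol`
#' (total stem volume, m3) per species, and `DDWVol` (downed-deadwood
#' volume, m3, species `"none"`).  Empty cells inside the landscape carry 0,
#' not NA, so coarse-block means and sums are well defined.
#'
#' Grid convention: origin top-left, cell `[x0, x0+cs)` half-open, row 1 at
#' the top edge; objects exactly on the far edge are clamped into the last
#' cell.
#'
#' @param values numeric array `nrow x ncol x nlayer`, finite, >= 0.
#' @param manifest data.frame with columns `variable`, `species`,
#'   `site_class` (NA for unstratified layers), one row per layer.
#' @param resolution cell size in metres.
#' @return an object of class `feature_stack`.
#' @export
feature_stack <- function(values, manifest, resolution) {
  stopifnot(length(dim(values)) == 3L, dim(values)[3] == nrow(manifest),
            resolution > 0)
  if (any(!is.finite(values)) || any(values < 0))
    stop("feature values must be finite and non-negative")
  structure(list(values = values, manifest = manifest,
                 resolution = resolution),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$values)
  cat("Feature stack: ", d[3], " layers, ", d[1], " x ", d[2], " cells @ ",
      x$resolution, " m\n", sep = "")
  cat("  variables:", paste(unique(x$manifest$variable), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname feature_stack
#' @param stack a `feature_stack`.
#' @param variable,species,site_class layer identity to extract.
#' @return `get_layer()`: the layer's value matrix.
#' @export
get_layer <- function(stack, variable, species = "none", site_class = NA) {
  m <- stack$manifest
  i <- which(m$variable == variable & m$species == species &
             (is.na(site_class) & is.na(m$site_class) |
              !is.na(site_class) & !is.na(m$site_class) &
              m$site_class %in% site_class))
  if (length(i) != 1L)
    stop("layer (", variable, ", ", species, ", ", site_class,
         ") matches ", length(i), " layers")
  d <- dim(stack$values)
  matrix(stack$values[, , i], d[1], d[2])
}

#' Number of cells in a stack
#' @param stack a `feature_stack`.
#' @export
n_cells <- function(stack) prod(dim(stack$values)[1:2])

SPECIES_LEVELS <- c("spruce", "pine", "birch", "aspen")
TREE_VARIABLES <- c("Hmax", "Hmean", "Vol")

#' Rasterize tree records into per-species canopy layers
#'
#' Bins trees into grid cells and computes, per cell and species, the
#' maximum tree height (`Hmax`), the arithmetic mean height (`Hmean`) and
#' the summed stem volume (`Vol`).  Cells without trees of a species carry
#' 0.  Produces 12 unstratified layers (3 variables x 4 species).
#'
#' @param trees data.frame as returned by [generate_trees()].
#' @param extent_x,extent_y landscape extent in metres.
#' @param cell_size cell edge in metres (default 16).
#' @return `feature_stack` of 12 layers with `site_class = NA`.
#' @export
rasterize_trees <- function(trees, extent_x, extent_y, cell_size = 16) {
  check_divisible(extent_x, cell_size, "extent_x")
  check_divisible(extent_y, cell_size, "extent_y")
  nc <- extent_x / cell_size
  nr <- extent_y / cell_size
  bad <- which(trees$x < 0 | trees$x > extent_x |
               trees$y < 0 | trees$y > extent_y)
  if (length(bad))
    stop("trees outside the extent at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  vals <- array(0, c(nr, nc, 12L))
  manifest <- expand.grid(variable = TREE_VARIABLES,
                          species = SPECIES_LEVELS,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  manifest$site_class <- NA_integer_
  if (nrow(trees)) {
    col <- pmin(floor(trees$x / cell_size) + 1L, nc)
    row <- pmin(floor(trees$y / cell_size) + 1L, nr)
    cell <- (col - 1L) * nr + row             # column-major cell index
    for (s in seq_along(SPECIES_LEVELS)) {
      sel <- trees$species == SPECIES_LEVELS[s]
      if (!any(sel)) next
      cs <- cell[sel]
      hmax <- tapply(trees$height_m[sel], cs, max)
      hmean <- tapply(trees$height_m[sel], cs, mean)
      vol <- tapply(trees$vol_m3[sel], cs, sum)
      idx <- as.integer(names(hmax))
      base <- (s - 1L) * 3L
      vals[idx + (base + 0L) * nr * nc] <- hmax   # Hmax layer
      vals[idx + (base + 1L) * nr * nc] <- hmean  # Hmean layer
      vals[idx + (base + 2L) * nr * nc] <- vol    # Vol layer
    }
  }
  feature_stack(vals, manifest, cell_size)
}

#' Rasterize downed-deadwood segments into a volume layer
#'
#' Each segment's volume is split across the grid cells it crosses in
#' proportion to the clipped within-cell length; a zero-length segment
#' contributes its whole volume to its containing cell.  The cell total is
#' the sum of allocated volumes, so landscape totals are conserved exactly.
#'
#' @param ddw data.frame as returned by [generate_ddw()].
#' @param extent_x,extent_y landscape extent in metres.
#' @param cell_size cell edge in metres (default 16).
#' @return `feature_stack` with the single unstratified `DDWVol` layer.
#' @export
rasterize_ddw <- function(ddw, extent_x, extent_y, cell_size = 16) {
  check_divisible(extent_x, cell_size, "extent_x")
  check_divisible(extent_y, cell_size, "extent_y")
  nc <- extent_x / cell_size
  nr <- extent_y / cell_size
  m <- matrix(0, nr, nc)
  for (i in seq_len(nrow(ddw))) {
    seg <- segment_cell_lengths(ddw$x1[i], ddw$y1[i], ddw$x2[i], ddw$y2[i],
                                cell_size, nr, nc)
    if (seg$total == 0) {
      m[seg$rows[1], seg$cols[1]] <- m[seg$rows[1], seg$cols[1]] + ddw$vol_m3[i]
    } else {
      w <- seg$len / seg$total
      for (k in seq_along(w))
        m[seg$rows[k], seg$cols[k]] <- m[seg$rows[k], seg$cols[k]] +
          ddw$vol_m3[i] * w[k]
    }
  }
  manifest <- data.frame(variable = "DDWVol", species = "none",
                         site_class = NA_integer_)
  feature_stack(array(m, c(nr, nc, 1L)), manifest, cell_size)
}

# Parametric clipping of one segment against the cell lattice: split the
# parameter range [0,1] at every crossing of a vertical or horizontal cell
# boundary; each sub-interval lies in exactly one cell.
segment_cell_lengths <- function(x1, y1, x2, y2, cs, nr, nc) {
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  cell_of <- function(x, y) {
    c(row = min(floor(y / cs) + 1, nr), col = min(floor(x / cs) + 1, nc))
  }
  if (len == 0) {
    rc <- cell_of(x1, y1)
    return(list(rows = rc[["row"]], cols = rc[["col"]], len = 0, total = 0))
  }
  tx <- if (x1 != x2) (cs * seq_len(nc - 1) - x1) / (x2 - x1) else numeric(0)
  ty <- if (y1 != y2) (cs * seq_len(nr - 1) - y1) / (y2 - y1) else numeric(0)
  ts <- sort(unique(c(0, 1, tx[tx > 0 & tx < 1], ty[ty > 0 & ty < 1])))
  mid <- (ts[-length(ts)] + ts[-1]) / 2
  sub <- (ts[-1] - ts[-length(ts)]) * len
  mx <- x1 + mid * (x2 - x1)
  my <- y1 + mid * (y2 - y1)
  rows <- pmin(floor(my / cs) + 1, nr)
  cols <- pmin(floor(mx / cs) + 1, nc)
  list(rows = rows, cols = cols, len = sub, total = len)
}

#' Stratify feature layers by site-fertility class
#'
#' Splits every unstratified layer into four layers, one per site class:
#' the class-c layer equals the input where the cell's site class is c and
#' 0 elsewhere.  12 tree layers + 1 DDW layer become the 52-layer baseline
#' stack (13 variables x 4 classes).
#'
#' @param stack unstratified `feature_stack` at the baseline resolution.
#' @param site_grid a [generate_site_classes()] grid on the same lattice.
#' @return stratified `feature_stack`.
#' @export
stratify <- function(stack, site_grid) {
  d <- dim(stack$values)
  if (d[1] != nrow(site_grid) || d[2] != ncol(site_grid) ||
      stack$resolution != attr(site_grid, "cell_size"))
    stop("feature stack and site grid are on different lattices")
  nlay <- d[3]
  vals <- array(0, c(d[1], d[2], nlay * 4L))
  rows <- vector("list", nlay * 4L)
  k <- 0L
  for (j in seq_len(nlay)) {
    lay <- stack$values[, , j]
    for (cls in 1:4) {
      k <- k + 1L
      vals[, , k] <- lay * (unclass(site_grid) == cls)
      rows[[k]] <- data.frame(variable = stack$manifest$variable[j],
                              species = stack$manifest$species[j],
                              site_class = cls)
    }
  }
  feature_stack(vals, do.call(rbind, rows), stack$resolution)
}

#' Combine feature stacks at one resolution
#' @param ... `feature_stack`s sharing grid and resolution.
#' @return a single `feature_stack` with the layers concatenated.
#' @export
c_stacks <- function(...) {
  stacks <- list(...)
  d1 <- dim(stacks[[1]]$values)[1:2]
  res <- stacks[[1]]$resolution
  for (s in stacks)
    if (!identical(dim(s$values)[1:2], d1) || s$resolution != res)
      stop("stacks are on different lattices")
  vals <- array(unlist(lapply(stacks, function(s) s$values)),
                c(d1, sum(vapply(stacks, function(s) dim(s$values)[3], 0L))))
  feature_stack(vals, do.call(rbind, lapply(stacks, `[[`, "manifest")), res)
}

#' Build the stratified baseline feature stack from object records
#'
#' Convenience wrapper: rasterizes trees and DDW at the baseline cell size
#' and stratifies by site class, yielding the 52-layer analysis input.
#'
#' @param trees,ddw object record tables.
#' @param site_grid site-class grid defining extent and cell size.
#' @return stratified `feature_stack` (52 layers for 4 species + DDW).
#' @export
build_baseline_stack <- function(trees, ddw, site_grid) {
  ext <- attr(site_grid, "extent")
  cs <- attr(site_grid, "cell_size")
  tr <- rasterize_trees(trees, ext[["x"]], ext[["y"]], cs)
  dw <- rasterize_ddw(ddw, ext[["x"]], ext[["y"]], cs)
  stratify(c_stacks(tr, dw), site_grid)
}
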