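#' Raster and object-table I/O
#'
#' Feature stacks are persisted as a directory of ESRI ASCII grids (one per
#' layer, diff-friendly plain text) plus a JSON `manifest.json` mapping
#' each file to its `(variable, species, site_class)` identity and
#' recording the resolution.  Values are written with full double
#' precision, so a write/read round trip reproduces the stack exactly.
#'
#' @param stack a [feature_stack()].
#' @param path directory to create/write.
#' @return `write_stack()`: the path, invisibly; `read_stack()`: the
#'   `feature_stack`.
#' @name stack_io
NULL

#' @rdname stack_io
#' @export
write_stack <- function(stack, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  m <- stack$manifest
  files <- sprintf("layer_%03d_%s_%s_%s.asc", seq_len(nrow(m)),
                   m$variable, m$species,
                   ifelse(is.na(m$site_class), "all",
                          paste0("f", m$site_class)))
  for (j in seq_len(nrow(m)))
    write_ascii_grid(stack$values[, , j], file.path(path, files[j]),
                     cell_size = stack$resolution)
  manifest <- list(resolution = stack$resolution,
                   layers = cbind(m, data.frame(file = files)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname stack_io
#' @export
read_stack <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json in ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  lay <- manifest$layers
  mats <- lapply(file.path(path, lay$file), read_ascii_grid)
  d <- dim(mats[[1]])
  vals <- array(unlist(mats), c(d[1], d[2], length(mats)))
  m <- lay[c("variable", "species", "site_class")]
  m$site_class <- suppressWarnings(as.integer(m$site_class))
  feature_stack(vals, m, manifest$resolution)
}

#' Write / read a single raster layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows
#' from the top of the grid down.  Values are printed with 17 significant
#' digits, which round-trips doubles exactly.
#'
#' @param m numeric matrix (row 1 = top edge).
#' @param path output file.
#' @param cell_size cell edge in metres.
#' @param nodata sentinel for missing cells (default -1).
#' @return the path (write) or the matrix with attribute `cell_size`
#'   (read), NoData cells as `NA`.
#' @export
write_ascii_grid <- function(m, path, cell_size = 16, nodata = -1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)),
               paste("nrows", nrow(m)),
               "xllcorner 0",
               "yllcorner 0",
               paste("cellsize", cell_size),
               paste("NODATA_value", nodata)), con)
  mm <- m
  mm[is.na(mm)] <- nodata
  writeLines(apply(mm, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[`, "", 1L)
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  nodata <- vals[["nodata_value"]]
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != nr * nc)
    stop("ASCII grid body has ", length(body), " values, expected ", nr * nc)
  m <- matrix(body, nr, nc, byrow = TRUE)
  m[m == nodata] <- NA
  attr(m, "cell_size") <- vals[["cellsize"]]
  m
}

#' Write / read object record tables as CSV
#'
#' Tree tables use columns `(x, y, species, height_m, dbh_cm, vol_m3)`,
#' DDW tables `(x1, y1, x2, y2, diameter_cm, length_m, vol_m3)`.
#'
#' @param records a tree or DDW data.frame.
#' @param path CSV file path.
#' @return the path (write) or the data.frame (read).
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_tree_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "species", "height_m", "dbh_cm", "vol_m3")
  if (!all(need %in% names(df)))
    stop("tree table must have columns: ", paste(need, collapse = ", "))
  df$species <- factor(df$species, levels = SPECIES_LEVELS)
  df
}

#' @rdname write_records
#' @export
read_ddw_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x1", "y1", "x2", "y2", "diameter_cm", "length_m", "vol_m3")
  if (!all(need %in% names(df)))
    stop("DDW table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write / read a site-class grid as an ESRI ASCII grid
#' @param grid a [generate_site_classes()] grid.
#' @param path file path.
#' @export
write_site_grid <- function(grid, path) {
  write_ascii_grid(unclass(grid), path,
                   cell_size = attr(grid, "cell_size"), nodata = -1)
}

#' @rdname write_site_grid
#' @export
read_site_grid <- function(path) {
  m <- read_ascii_grid(path)
  cs <- attr(m, "cell_size")
  g <- matrix(as.integer(m), nrow(m), ncol(m))
  structure(g, class = c("site_class_grid", "matrix", "array"),
            cell_size = cs,
            extent = c(x = ncol(g) * cs, y = nrow(g) * cs),
            shares = tabulate(g, 4L) / length(g))
}
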