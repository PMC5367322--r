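#' Write a raster matrix as an ESRI ASCII grid
#'
#' Rasters in this package are plain numeric matrices on a square grid
#' (row 1 = northern edge). The ASCII grid format keeps every exported
#' layer human-readable and diff-able; integer-coded layers (severity,
#' vegetation type) round-trip exactly.
#'
#' @param x Numeric matrix.
#' @param path Output file path.
#' @param cell_size_m Cell size in metres (default 30).
#' @param xll,yll Lower-left corner coordinates in metres.
#' @param nodata Value used to encode `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(x, path, cell_size_m = 30, xll = 0, yll = 0, nodata = -9999) {
  stopifnot(is.matrix(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(x)),
    paste("nrows", nrow(x)),
    paste("xllcorner", xll),
    paste("yllcorner", yll),
    paste("cellsize", cell_size_m),
    paste("NODATA_value", nodata)
  ), con)
  xx <- x
  xx[is.na(xx)] <- nodata
  for (i in seq_len(nrow(xx)))
    writeLines(paste(format(xx[i, ], trim = TRUE, scientific = FALSE, digits = 15),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_asc()]
#'
#' @param path File path.
#' @return A numeric matrix with attributes `cell_size_m`, `xll`, `yll`.
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2]); names(vals) <- tolower(kv[, 1])
  body <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(body, nrow = vals[["nrows"]], ncol = vals[["ncols"]], byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  attr(m, "cell_size_m") <- vals[["cellsize"]]
  attr(m, "xll") <- vals[["xllcorner"]]
  attr(m, "yll") <- vals[["yllcorner"]]
  m
}

#' Write a point-cloud tile as gzipped XYZ text
#'
#' Columns: `x y z intensity range return` (whitespace separated, one
#' return per line), the documented text serialization for height
#' normalized point clouds with per-return intensity and sensor range.
#'
#' @param tile A point-cloud tile (see [simulate_point_cloud()]).
#' @param path Output path; a `.gz` suffix is honoured.
#' @return `path`, invisibly.
#' @export
write_tile_xyz <- function(tile, path) {
  df <- data.frame(
    x = tile$x %||% rep(0, length(tile$height_m)),
    y = tile$y %||% rep(0, length(tile$height_m)),
    z = tile$height_m,
    intensity = tile$intensity,
    range = tile$range_m,
    return_number = tile$return_number
  )
  con <- gzfile(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a gzipped XYZ point-cloud tile written by [write_tile_xyz()]
#'
#' @param path File path.
#' @param cell_id Cell identifier to attach.
#' @param area_m2 Tile area in square metres.
#' @return A point-cloud tile list.
#' @export
read_tile_xyz <- function(path, cell_id = NA_integer_, area_m2 = 900) {
  df <- utils::read.table(gzfile(path), header = TRUE)
  new_tile(height_m = df$z, intensity = df$intensity, range_m = df$range,
           return_number = df$return_number, cell_id = cell_id,
           area_m2 = area_m2, x = df$x, y = df$y)
}

#' Write field plots as CSV
#'
#' Header: `plot_id,x,y,agb_Mg_ha,fc,gps_error_m`.
#'
#' @param plots Field-plot data frame (see [generate_field_plots()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plots_csv <- function(plots, path) {
  df <- data.frame(plot_id = plots$plot_id, x = plots$x, y = plots$y,
                   agb_Mg_ha = plots$plot_agb_Mg_ha, fc = plots$fractional_cover,
                   gps_error_m = plots$gps_error_m)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
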