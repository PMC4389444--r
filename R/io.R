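#' Read and write rasters as Esri ASCII grids
#'
#' Plain-text single-band raster exchange: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' the rows of the grid from the top row down — the same row order as
#' [rr_raster()].
#'
#' @param r An [rr_raster] (writing).
#' @param path File path.
#' @param nodata Value written for `NA` cells.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   an [rr_raster].
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "rr_raster"))
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", format(r$xmin, digits = 15)),
    paste("yllcorner", format(r$ymin, digits = 15)),
    paste("cellsize", format(r$cellsize, digits = 15)),
    paste("NODATA_value", nodata)
  )
  body <- apply(v, 1, function(row) paste(format(row, digits = 15, trim = TRUE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[[`, character(1), 2))
  names(vals) <- keys
  v <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  v[v == vals[["nodata_value"]]] <- NA
  rr_raster(v, xmin = vals[["xllcorner"]], ymin = vals[["yllcorner"]],
            cellsize = vals[["cellsize"]])
}
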