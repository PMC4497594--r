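# Esri ASCII grid I/O and a minimal in-memory grid container.
#
# A grid is a list with class "ascii_grid": fields `data` (numeric matrix,
# row 1 = northern-most row, as in the file format), `cellsize` (km),
# `xll`, `yll` (lower-left corner coordinates, km) and `nodata`.

#' Create an in-memory raster grid
#'
#' @param data numeric matrix; row 1 is the top (northern) row, matching the
#'   Esri ASCII on-disk layout.
#' @param cellsize cell edge length in km.
#' @param xll,yll coordinates (km) of the lower-left corner of the grid.
#' @param nodata value standing for missing cells.
#' @return an object of class `ascii_grid`.
#' @export
ascii_grid <- function(data, cellsize, xll = 0, yll = 0, nodata = -9999) {
  stopifnot(is.matrix(data), is.numeric(data), cellsize > 0)
  structure(list(data = data, cellsize = cellsize, xll = xll, yll = yll,
                 nodata = nodata),
            class = "ascii_grid")
}

#' @export
print.ascii_grid <- function(x, ...) {
  cat(sprintf("<ascii_grid> %d rows x %d cols, cellsize %g km, origin (%g, %g)\n",
              nrow(x$data), ncol(x$data), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' Read an Esri ASCII grid file
#'
#' @param path file path.
#' @return an `ascii_grid`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[k]])) stopf("malformed ASCII grid header: missing %s", k)
  }
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stopf("ASCII grid body has %d values, expected %d", length(vals),
          hdr$ncols * hdr$nrows)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA_real_
  ascii_grid(m, cellsize = hdr$cellsize,
             xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0,
             nodata = nodata)
}

#' Write an Esri ASCII grid file
#'
#' @param grid an `ascii_grid`.
#' @param path destination path.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "ascii_grid"))
  m <- grid$data
  m[is.na(m)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# x/y coordinates (km) of every cell centre; returned as matrices shaped
# like grid$data.
grid_cell_centers <- function(grid) {
  nr <- nrow(grid$data); nc <- ncol(grid$data); cs <- grid$cellsize
  x <- matrix(rep(grid$xll + (seq_len(nc) - 0.5) * cs, each = nr), nr, nc)
  # row 1 is the top row
  y <- matrix(rep(grid$yll + (nr - seq_len(nr) + 0.5) * cs, times = nc), nr, nc)
  list(x = x, y = y)
}

# Row/column of the cell containing point (x, y).
grid_cell_of <- function(grid, x, y) {
  nr <- nrow(grid$data); cs <- grid$cellsize
  col <- pmin(pmax(floor((x - grid$xll) / cs) + 1L, 1L), ncol(grid$data))
  row <- pmin(pmax(nr - floor((y - grid$yll) / cs), 1L), nr)
  cbind(row = row, col = col)
}
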