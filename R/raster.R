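#' Lightweight in-memory grid raster
#'
#' A minimal regular-grid raster: a numeric matrix with row 1 at the northern
#' edge, plus the lower-left corner and square cell size in map units (metres
#' throughout this package). This is the container used for climate surfaces,
#' the binary forest land-cover mask, and the derived forest-proportion layer.
#'
#' @param values numeric matrix; `values[1, 1]` is the north-west cell.
#' @param xll,yll coordinates of the lower-left corner of the grid (m).
#' @param cellsize square cell edge length (m).
#' @param nodata value used for missing cells on disk.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll = 0, yll = 0, cellsize = 1, nodata = -9999) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), cellsize > 0)
  structure(
    list(values = values, xll = xll, yll = yll,
         cellsize = cellsize, nodata = nodata),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d rows x %d cols, cellsize %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' @rdname grid_raster
#' @param r a `grid_raster`.
#' @export
raster_extent <- function(r) {
  c(xmin = r$xll, xmax = r$xll + ncol(r$values) * r$cellsize,
    ymin = r$yll, ymax = r$yll + nrow(r$values) * r$cellsize)
}

#' Extract raster values at point locations (nearest cell)
#'
#' Points are mapped to the cell containing them, which for a regular grid is
#' the nearest cell centre. Points outside the extent return `NA`.
#'
#' @param r a [grid_raster()].
#' @param x,y point coordinates (m).
#' @return Numeric vector of cell values (`NA` outside the extent).
#' @export
raster_extract <- function(r, x, y) {
  stopifnot(inherits(r, "grid_raster"), length(x) == length(y))
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- floor((x - r$xll) / r$cellsize) + 1L
  row_from_bottom <- floor((y - r$yll) / r$cellsize) + 1L
  ## points exactly on the top/right edge belong to the last cell
  col[x == r$xll + nc * r$cellsize] <- nc
  row_from_bottom[y == r$yll + nr * r$cellsize] <- nr
  row <- nr - row_from_bottom + 1L
  out <- rep(NA_real_, length(x))
  ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

#' Block-aggregate a raster by averaging
#'
#' Each coarse cell is the mean of a `fact` x `fact` block of fine cells;
#' partial blocks at the south/east edges average the cells available.
#'
#' @param r a [grid_raster()].
#' @param fact integer aggregation factor (>= 1).
#' @return A coarser [grid_raster()] with cellsize `fact * r$cellsize`.
#' @export
raster_aggregate_mean <- function(r, fact) {
  stopifnot(inherits(r, "grid_raster"), fact >= 1)
  fact <- as.integer(fact)
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  nrc <- ceiling(nr / fact); ncc <- ceiling(nc / fact)
  out <- matrix(NA_real_, nrc, ncc)
  ## blocks are anchored at the lower-left origin, so row blocks are counted
  ## from the bottom and any partial block ends up along the northern edge
  rb_bottom <- (seq_len(nr) - 1L) %/% fact   # block id of each bottom-counted row
  cb <- (seq_len(nc) - 1L) %/% fact
  rows_bottom <- nr:1
  for (i in seq_len(nrc)) {
    rsel <- rows_bottom[rb_bottom == (i - 1L)]   # matrix rows in block i from bottom
    for (j in seq_len(ncc)) {
      csel <- which(cb == (j - 1L))
      out[nrc - i + 1L, j] <- mean(v[rsel, csel, drop = FALSE], na.rm = TRUE)
    }
  }
  grid_raster(out, r$xll, r$yll, r$cellsize * fact, r$nodata)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text `.asc` interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows from
#' north to south.
#'
#' @param path file path.
#' @return `read_asc` returns a [grid_raster()]; `write_asc` returns `path`
#'   invisibly.
#' @export
read_asc <- function(path) {
  head <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(head), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  vals <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(vals, nrow = val[["nrows"]], ncol = val[["ncols"]], byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA_real_
  grid_raster(m, val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]],
              val[["nodata_value"]])
}

#' @rdname read_asc
#' @param r a [grid_raster()].
#' @export
write_asc <- function(r, path) {
  stopifnot(inherits(r, "grid_raster"))
  v <- r$values
  v[is.na(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", r$nodata)
  ), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
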