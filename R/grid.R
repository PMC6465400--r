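#' Gridded covariate container
#'
#' A minimal raster-stack container used throughout the package: one or more
#' named layers stored as `nx x ny` matrices on a shared regular grid in
#' projected meters.  Cell `(ix, iy)` covers the half-open square
#' `[x0 + (ix-1)*cs, x0 + ix*cs) x [y0 + (iy-1)*cs, y0 + iy*cs)` and its
#' center is at `(x0 + (ix - 0.5)*cs, y0 + (iy - 0.5)*cs)`.
#'
#' @param origin numeric length-2, lower-left corner `(x0, y0)` in meters.
#' @param cellsize cell edge length in meters (30 m for all analysis grids).
#' @param nx,ny number of columns/rows of cells along x and y.
#' @param layers named list of `nx x ny` numeric matrices (may be empty).
#' @return An object of class `cov_grid`.
#' @export
cov_grid <- function(origin, cellsize, nx, ny, layers = list()) {
  stopifnot(length(origin) == 2, cellsize > 0, nx >= 1, ny >= 1)
  for (nm in names(layers)) {
    m <- layers[[nm]]
    stopifnot(is.matrix(m), nrow(m) == nx, ncol(m) == ny)
  }
  structure(
    list(origin = as.numeric(origin), cellsize = as.numeric(cellsize),
         nx = as.integer(nx), ny = as.integer(ny), layers = layers),
    class = "cov_grid"
  )
}

#' @export
print.cov_grid <- function(x, ...) {
  cat(sprintf("<cov_grid> %d x %d cells @ %g m, origin (%g, %g)\n",
              x$nx, x$ny, x$cellsize, x$origin[1], x$origin[2]))
  cat("layers:", if (length(x$layers)) paste(names(x$layers), collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Cell-center coordinates of a grid
#' @param grid a [cov_grid()].
#' @return list with vectors `x` (length nx) and `y` (length ny).
#' @export
grid_centers <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$cellsize,
       y = grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$cellsize)
}

#' Map point coordinates to cell indices (half-open membership)
#'
#' Points on a cell's lower/left edge belong to that cell; points on the
#' grid's upper/right outer edge are outside.
#'
#' @param grid a [cov_grid()].
#' @param x,y point coordinates (m), vectorized.
#' @return data.frame with integer columns `ix`, `iy` (NA outside the grid).
#' @export
cell_index <- function(grid, x, y) {
  ix <- floor((x - grid$origin[1]) / grid$cellsize) + 1L
  iy <- floor((y - grid$origin[2]) / grid$cellsize) + 1L
  bad <- ix < 1L | ix > grid$nx | iy < 1L | iy > grid$ny
  ix[bad] <- NA_integer_
  iy[bad] <- NA_integer_
  data.frame(ix = as.integer(ix), iy = as.integer(iy))
}

#' Extract mean covariate values around points
#'
#' For each point, each layer is averaged over all grid cells whose centers
#' lie within `radius` of the point, ignoring no-data cells.  The default
#' 150 m radius matches the mean triangulation error of the telemetry
#' locations, so extracted covariates describe the neighborhood an estimated
#' location could plausibly occupy.  If every cell within the radius is
#' no-data for a layer the extracted value is `NA`.
#'
#' @param grid a [cov_grid()].
#' @param x,y point coordinates (m), vectorized.
#' @param radius extraction radius in meters.
#' @param layers character vector of layer names (default: all layers).
#' @return data.frame, one row per point, one column per layer.
#' @export
extract_mean <- function(grid, x, y, radius = 150, layers = names(grid$layers)) {
  stopifnot(length(x) == length(y), radius > 0, length(layers) > 0)
  n <- length(x)
  cs <- grid$cellsize
  r_cells <- ceiling(radius / cs)
  offs <- expand.grid(dx = -r_cells:r_cells, dy = -r_cells:r_cells)
  ix0 <- floor((x - grid$origin[1]) / cs) + 1L
  iy0 <- floor((y - grid$origin[2]) / cs) + 1L
  sums <- matrix(0, n, length(layers), dimnames = list(NULL, layers))
  cnts <- matrix(0L, n, length(layers))
  mats <- grid$layers[layers]
  for (k in seq_len(nrow(offs))) {
    ix <- ix0 + offs$dx[k]
    iy <- iy0 + offs$dy[k]
    cxx <- grid$origin[1] + (ix - 0.5) * cs
    cyy <- grid$origin[2] + (iy - 0.5) * cs
    ok <- ix >= 1L & ix <= grid$nx & iy >= 1L & iy <= grid$ny &
      (cxx - x)^2 + (cyy - y)^2 <= radius^2
    if (!any(ok)) next
    lin <- ix[ok] + (iy[ok] - 1L) * grid$nx
    for (j in seq_along(layers)) {
      v <- mats[[j]][lin]
      use <- !is.na(v)
      idx <- which(ok)[use]
      sums[idx, j] <- sums[idx, j] + v[use]
      cnts[idx, j] <- cnts[idx, j] + 1L
    }
  }
  out <- sums / cnts
  out[cnts == 0L] <- NA_real_
  as.data.frame(out)
}

# Dilate a logical mask by a Euclidean radius (meters): a cell is TRUE in the
# result iff any TRUE cell center lies within `radius` of its center.
dilate_mask <- function(mask, cellsize, radius) {
  stopifnot(is.matrix(mask), radius >= 0)
  if (radius == 0) return(mask)
  storage.mode(mask) <- "integer"
  out <- cpp_dilate(mask, as.numeric(cellsize), as.numeric(radius))
  out == 1L
}

#' Write / read a single grid layer as ESRI ASCII raster
#'
#' Plain-text exchange format for the 30 m metric grids (readable by GIS
#' software and by [read_ascii_grid()]).
#'
#' @param grid a [cov_grid()].
#' @param layer layer name to write.
#' @param path output file path.
#' @param na_value NODATA sentinel written for `NA` cells.
#' @return `path`, invisibly (writer); a one-layer `cov_grid` (reader).
#' @export
write_ascii_grid <- function(grid, layer, path, na_value = -9999) {
  m <- grid$layers[[layer]]
  stopifnot(!is.null(m))
  hdr <- c(
    sprintf("ncols %d", grid$nx),
    sprintf("nrows %d", grid$ny),
    sprintf("xllcorner %.6f", grid$origin[1]),
    sprintf("yllcorner %.6f", grid$origin[2]),
    sprintf("cellsize %.6f", grid$cellsize),
    sprintf("NODATA_value %g", na_value)
  )
  m2 <- m
  m2[is.na(m2)] <- na_value
  # ASCII grids are written top row first
  rows <- vapply(rev(seq_len(grid$ny)), function(iy) {
    paste(format(m2[, iy], trim = TRUE, scientific = FALSE), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param name layer name to give the data read from `path`.
#' @export
read_ascii_grid <- function(path, name = "layer") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nx <- as.integer(val("ncols")); ny <- as.integer(val("nrows"))
  nodata <- val("NODATA_value")
  dat <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(dat) == nx * ny)
  m <- matrix(dat, nrow = nx)          # row-major text -> columns of each row
  m <- m[, rev(seq_len(ny)), drop = FALSE]
  m[m == nodata] <- NA_real_
  cov_grid(c(val("xllcorner"), val("yllcorner")), val("cellsize"), nx, ny,
           setNames(list(m), name))
}
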