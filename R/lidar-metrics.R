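#' Assign lidar returns to 30 m grid cells
#'
#' Half-open membership: a return at `(x, y)` belongs to the cell whose
#' lower-left corner is `(floor(x/cs)*cs, floor(y/cs)*cs)` relative to the
#' grid origin, so a return on a shared edge belongs to exactly one cell.
#'
#' @param cloud data.frame with columns x, y, z (z = height above ground, m).
#' @param grid a [cov_grid()] defining the target cells, or `NULL` to derive
#'   a grid spanning the cloud.
#' @param cellsize cell size (m) when deriving the grid.
#' @return list: `grid` (the [cov_grid()]) and `cell` (integer vector, linear
#'   cell index `ix + (iy-1)*nx` per return; NA outside the grid).
#' @export
grid_returns <- function(cloud, grid = NULL, cellsize = 30) {
  stopifnot(all(c("x", "y", "z") %in% names(cloud)), cellsize > 0)
  if (is.null(grid)) {
    x0 <- floor(min(cloud$x) / cellsize) * cellsize
    y0 <- floor(min(cloud$y) / cellsize) * cellsize
    nx <- max(1L, ceiling((max(cloud$x) - x0) / cellsize))
    ny <- max(1L, ceiling((max(cloud$y) - y0) / cellsize))
    # returns exactly on the upper edge still need a cell
    if (max(cloud$x) >= x0 + nx * cellsize) nx <- nx + 1L
    if (max(cloud$y) >= y0 + ny * cellsize) ny <- ny + 1L
    grid <- cov_grid(c(x0, y0), cellsize, nx, ny)
  }
  idx <- cell_index(grid, cloud$x, cloud$y)
  cell <- ifelse(is.na(idx$ix), NA_integer_, idx$ix + (idx$iy - 1L) * grid$nx)
  list(grid = grid, cell = as.integer(cell))
}

#' Per-cell canopy metrics from return heights
#'
#' `canopy_height` is the height below which 95% of the returns taller than
#' 2 m fall (dominant canopy height, HEIGHT); 0 if no return exceeds 2 m.
#' `canopy_cover` (CANCOV) is the fraction of all returns above 2 m.
#' `strata_cover` is the count of returns in `[lo, hi)` divided by the count
#' below `hi` (no-data when the denominator is 0): D4to8 uses (4, 8); S2to4
#' uses (2, 4) and is only defined where HEIGHT > 4 m.
#'
#' @param z numeric vector of return heights (m) in one cell.
#' @param prob percentile used for the dominant height (0.95).
#' @return scalar metric value (`NA` for no-data).
#' @export
canopy_height <- function(z, prob = 0.95) {
  if (length(z) == 0) return(NA_real_)
  zz <- z[z > 2]
  if (length(zz) == 0) return(0)
  # linear interpolation between order statistics (quantile type 7)
  unname(quantile(zz, prob, type = 7))
}

#' @rdname canopy_height
#' @export
canopy_cover <- function(z) {
  if (length(z) == 0) return(NA_real_)
  mean(z > 2)
}

#' @rdname canopy_height
#' @param lo,hi stratum bounds (m), half-open `[lo, hi)`.
#' @export
strata_cover <- function(z, lo, hi) {
  stopifnot(lo < hi)
  if (length(z) == 0) return(NA_real_)
  denom <- sum(z < hi)
  if (denom == 0) return(NA_real_)
  sum(z >= lo & z < hi) / denom
}

#' Rumple index of one 30 m cell
#'
#' Builds a 1 m canopy surface model (maximum return height per 1 m subcell,
#' empty subcells filled from the nearest occupied subcell), smooths it with
#' a 3 x 3 mean filter (edge replication), and returns the ratio of the
#' triangulated 3-D surface area (two triangles per 1 m facet) to the planar
#' area.  1 for a flat canopy, increasing with structural complexity.
#'
#' @param x,y,z return coordinates relative to the cell (x, y in `[0, cs)`).
#' @param cellsize cell edge (m).
#' @param csm_res canopy surface model resolution (m).
#' @param min_returns minimum number of returns for the cell to be defined.
#' @return rumple ratio (>= 1), or `NA` for a too-sparse cell.
#' @export
rumple <- function(x, y, z, cellsize = 30, csm_res = 1, min_returns = 5) {
  n <- cellsize / csm_res
  if (length(z) < min_returns) return(NA_real_)
  ix <- pmin(pmax(floor(x / csm_res), 0), n - 1) + 1L
  iy <- pmin(pmax(floor(y / csm_res), 0), n - 1) + 1L
  csm <- matrix(NA_real_, n, n)
  ord <- order(z)  # later (higher) writes win
  csm[cbind(ix[ord], iy[ord])] <- z[ord]
  empty <- which(is.na(csm))
  if (length(empty)) {
    filled <- which(!is.na(csm))
    fi <- ((filled - 1L) %% n) + 1L
    fj <- ((filled - 1L) %/% n) + 1L
    ei <- ((empty - 1L) %% n) + 1L
    ej <- ((empty - 1L) %/% n) + 1L
    # nearest occupied subcell (ties broken by first index)
    nn <- vapply(seq_along(empty), function(k) {
      which.min((fi - ei[k])^2 + (fj - ej[k])^2)
    }, integer(1))
    csm[empty] <- csm[filled[nn]]
  }
  # 3x3 mean low-pass filter with replicated edges
  pad <- csm[c(1, seq_len(n), n), c(1, seq_len(n), n)]
  sm <- matrix(0, n, n)
  for (di in 0:2) for (dj in 0:2) {
    sm <- sm + pad[di + seq_len(n), dj + seq_len(n)]
  }
  sm <- sm / 9
  # planar projection of the triangulated node grid (n x n nodes span n-1
  # subcell widths), so a flat canopy gives exactly 1
  surface_area(sm, csm_res) / ((n - 1)^2 * csm_res^2)
}

# Triangulated 3-D area of a gridded surface: each facet between 4 adjacent
# nodes is split into two triangles.
surface_area <- function(zm, res) {
  n1 <- nrow(zm) - 1L; n2 <- ncol(zm) - 1L
  z00 <- zm[seq_len(n1), seq_len(n2)]
  z10 <- zm[seq_len(n1) + 1L, seq_len(n2)]
  z01 <- zm[seq_len(n1), seq_len(n2) + 1L]
  z11 <- zm[seq_len(n1) + 1L, seq_len(n2) + 1L]
  tri <- function(dz1x, dz1y, dz1z, dz2x, dz2y, dz2z) {
    cx <- dz1y * dz2z - dz1z * dz2y
    cy <- dz1z * dz2x - dz1x * dz2z
    cz <- dz1x * dz2y - dz1y * dz2x
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  # triangle 1: (0,0) (1,0) (0,1); triangle 2: (1,0) (1,1) (0,1)
  a1 <- tri(res, 0, z10 - z00, 0, res, z01 - z00)
  a2 <- tri(0, res, z11 - z10, -res, res, z01 - z10)
  sum(a1) + sum(a2)
}

#' Terrain metrics from a DEM
#'
#' SLOPE (degrees) and aspect from central finite differences; SRI, a solar
#' radiation index describing insolation near noon on the equinox,
#' `SRI = 1 + cos(lat) cos(slope) + sin(lat) sin(slope) cos(aspect - 180)`
#' (range `[0, 2]`, south-facing slopes maximal in the northern hemisphere);
#' and TPI at one or more window sizes, the cell elevation minus the mean
#' elevation within a circular window of radius `window/2` (negative in
#' drainages, positive on ridges).
#'
#' @param dem a [cov_grid()] with layer `dem`.
#' @param lat latitude in degrees (scalar) for SRI.
#' @param tpi_windows numeric vector of TPI window diameters (m).
#' @return the input grid with layers `SLOPE`, `SRI`, `TPI<w>` for each
#'   window, and `TPI` aliased to the largest window.
#' @export
terrain_metrics <- function(dem, lat = 44, tpi_windows = c(200, 500, 1000, 2000)) {
  z <- dem$layers$dem
  stopifnot(!is.null(z), all(is.finite(z)))
  nx <- dem$nx; ny <- dem$ny; cs <- dem$cellsize
  ip <- pmin(seq_len(nx) + 1L, nx); im <- pmax(seq_len(nx) - 1L, 1L)
  jp <- pmin(seq_len(ny) + 1L, ny); jm <- pmax(seq_len(ny) - 1L, 1L)
  span_x <- matrix(pmax(ip - im, 1L) * cs, nx, ny)
  span_y <- matrix(pmax(jp - jm, 1L) * cs, nx, ny, byrow = TRUE)
  dzdx <- (z[ip, , drop = FALSE] - z[im, , drop = FALSE]) / span_x
  dzdy <- (z[, jp, drop = FALSE] - z[, jm, drop = FALSE]) / span_y
  slope_rad <- atan(sqrt(dzdx^2 + dzdy^2))
  # aspect: downslope direction, degrees clockwise from north (+y)
  aspect_rad <- atan2(-dzdx, -dzdy)
  latr <- lat * pi / 180
  sri <- 1 + cos(latr) * cos(slope_rad) +
    sin(latr) * sin(slope_rad) * cos(aspect_rad - pi)
  out <- dem
  out$layers$SLOPE <- slope_rad * 180 / pi
  out$layers$SRI <- sri
  for (w in tpi_windows) {
    out$layers[[paste0("TPI", w)]] <- tpi(z, cs, w)
  }
  out$layers$TPI <- out$layers[[paste0("TPI", max(tpi_windows))]]
  out
}

# TPI at one window: elevation minus the mean within a circular window of
# radius window/2 (cell centers, center cell included).
tpi <- function(z, cellsize, window) {
  r <- window / 2
  rc <- floor(r / cellsize)
  nx <- nrow(z); ny <- ncol(z)
  if (2 * rc + 1 > min(nx, ny)) {
    stop("TPI window (", window, " m) larger than the grid")
  }
  offs <- expand.grid(dx = -rc:rc, dy = -rc:rc)
  offs <- offs[(offs$dx^2 + offs$dy^2) * cellsize^2 <= r^2, ]
  sum_m <- matrix(0, nx, ny)
  cnt_m <- matrix(0, nx, ny)
  for (k in seq_len(nrow(offs))) {
    dx <- offs$dx[k]; dy <- offs$dy[k]
    sx <- max(1, 1 - dx):min(nx, nx - dx)
    sy <- max(1, 1 - dy):min(ny, ny - dy)
    sum_m[sx, sy] <- sum_m[sx, sy] + z[sx + dx, sy + dy]
    cnt_m[sx, sy] <- cnt_m[sx, sy] + 1
  }
  z - sum_m / cnt_m
}

#' Distance from each grid cell center to the nearest stream
#'
#' Exact Euclidean point-to-segment distance, minimized over every segment
#' of every polyline.
#'
#' @param grid a [cov_grid()].
#' @param streams list of polylines (2-column coordinate matrices).
#' @return `nx x ny` matrix of distances (m).
#' @export
dist_to_stream <- function(grid, streams) {
  if (!length(streams)) stop("empty stream network")
  cen <- grid_centers(grid)
  px <- rep(cen$x, times = grid$ny)
  py <- rep(cen$y, each = grid$nx)
  matrix(dist_point_segments(px, py, streams), grid$nx, grid$ny)
}

# Minimum distance from points to a set of polylines.
dist_point_segments <- function(px, py, streams) {
  dmin <- rep(Inf, length(px))
  for (line in streams) {
    nseg <- nrow(line) - 1L
    if (nseg < 1L) next
    for (s in seq_len(nseg)) {
      ax <- line[s, 1]; ay <- line[s, 2]
      bx <- line[s + 1L, 1]; by <- line[s + 1L, 2]
      vx <- bx - ax; vy <- by - ay
      len2 <- vx^2 + vy^2
      t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
      dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
      dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
    }
  }
  dmin
}

#' Compute the full 30 m covariate grid
#'
#' Canopy metrics (HEIGHT, CANCOV, RUMPLE, D4to8, S2to4) from the return
#' cloud, terrain metrics (SLOPE, SRI, TPI at all windows) from the DEM, and
#' STREAM from the stream network, all on the DEM's grid.  S2to4 is only
#' defined where HEIGHT > 4 m.
#'
#' @param cloud data.frame x, y, z (height above ground).
#' @param dem a [cov_grid()] with layer `dem`.
#' @param streams list of polylines.
#' @param lat latitude (degrees) for SRI.
#' @param tpi_windows TPI window diameters (m).
#' @param rumple_min_returns sparsity threshold for RUMPLE.
#' @return a [cov_grid()] with all metric layers.
#' @export
compute_metric_grids <- function(cloud, dem, streams, lat = 44,
                                 tpi_windows = c(200, 500, 1000, 2000),
                                 rumple_min_returns = 5) {
  g <- terrain_metrics(dem, lat = lat, tpi_windows = tpi_windows)
  g$layers$STREAM <- dist_to_stream(dem, streams)
  gr <- grid_returns(cloud, grid = dem)
  ncell <- dem$nx * dem$ny
  cs <- dem$cellsize
  dt <- data.table::data.table(
    cell = gr$cell,
    z = cloud$z,
    rx = (cloud$x - dem$origin[1]) %% cs,
    ry = (cloud$y - dem$origin[2]) %% cs
  )
  dt <- dt[!is.na(cell)]
  mk <- function() matrix(NA_real_, dem$nx, dem$ny)
  HEIGHT <- mk(); CANCOV <- mk(); D4to8 <- mk(); S2to4 <- mk(); RUMPLE <- mk()
  cellstats <- dt[, list(
    height = canopy_height(z),
    cancov = canopy_cover(z),
    d4to8 = strata_cover(z, 4, 8),
    s2to4 = strata_cover(z, 2, 4),
    rumple = rumple(rx, ry, z, cellsize = cs,
                    min_returns = rumple_min_returns)
  ), by = "cell"]
  idx <- cellstats$cell
  HEIGHT[idx] <- cellstats$height
  CANCOV[idx] <- cellstats$cancov
  D4to8[idx] <- cellstats$d4to8
  S2to4[idx] <- cellstats$s2to4
  RUMPLE[idx] <- cellstats$rumple
  S2to4[!is.na(HEIGHT) & HEIGHT <= 4] <- NA_real_
  g$layers$HEIGHT <- HEIGHT
  g$layers$CANCOV <- CANCOV
  g$layers$D4to8 <- D4to8
  g$layers$S2to4 <- S2to4
  g$layers$RUMPLE <- RUMPLE
  g
}
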