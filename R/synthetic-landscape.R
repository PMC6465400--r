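#' Synthetic landscape generators
#'
#' These functions build an artificial forested landscape whose statistical
#' structure matches everything the downstream analysis assumes: a DEM with
#' ridge/valley relief, a steepest-descent stream network, a Voronoi stand
#' mosaic with per-stand canopy parameters, a lidar-like return cloud, and
#' dated harvest polygons for censoring.  All generators are deterministic
#' under a fixed seed.
#'
#' @name synthetic_landscape
NULL

# Separable Gaussian blur with replicated edges, used to turn white noise
# into a smooth random field.
gauss_blur <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_cells))
  w <- dnorm(-r:r, sd = sigma_cells)
  w <- w / sum(w)
  pad_apply <- function(mat) {
    n <- nrow(mat)
    padded <- rbind(mat[rep(1L, r), , drop = FALSE], mat,
                    mat[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(mat))
    for (k in seq_along(w)) {
      out <- out + w[k] * padded[(k - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(pad_apply(t(pad_apply(m))))
}

#' Generate a synthetic DEM
#'
#' Smooth filtered-noise elevation surface with ridge and valley structure.
#'
#' @param extent numeric length-2 `(width, height)` of the landscape in
#'   meters; at least 3000 x 3000 m.
#' @param relief list with `amplitude` (m; approximate total relief, may be 0)
#'   and `wavelength` (m; horizontal scale of ridges/valleys).
#' @param cellsize grid resolution in meters.
#' @param base_elev mean elevation (m).
#' @param seed integer RNG seed.
#' @return A [cov_grid()] with layer `dem`, origin at `(0, 0)`.
#' @export
gen_terrain <- function(extent, relief = list(amplitude = 200, wavelength = 800),
                        cellsize = 30, base_elev = 400, seed = 1) {
  stopifnot(length(extent) == 2)
  if (any(extent < 3000)) stop("extent must be at least 3000 x 3000 m")
  nx <- ceiling(extent[1] / cellsize)
  ny <- ceiling(extent[2] / cellsize)
  with_seed(seed, {
    z <- matrix(rnorm(nx * ny), nx, ny)
    z <- gauss_blur(z, relief$wavelength / (2 * cellsize))
    s <- sd(as.vector(z))
    z <- if (s > 0 && relief$amplitude > 0) {
      z / s * (relief$amplitude / 4)
    } else {
      matrix(0, nx, ny)
    }
    cov_grid(c(0, 0), cellsize, nx, ny, list(dem = z + base_elev))
  })
}

#' Derive a stream network from a DEM by flow accumulation
#'
#' Single-direction (D8) steepest-descent routing: each cell drains to its
#' lowest neighbor; cells whose accumulated upslope area (in cells) meets
#' `accumulation_threshold` form the permanent stream network, connected into
#' downstream segments.
#'
#' @param dem a [cov_grid()] with layer `dem`.
#' @param accumulation_threshold minimum upslope cell count for a cell to be
#'   mapped as stream.
#' @return list of polylines, each a 2-column matrix of `(x, y)` vertices
#'   (individual downslope segments); empty list (with a warning) on a flat
#'   DEM.
#' @export
gen_streams <- function(dem, accumulation_threshold = 50) {
  z <- dem$layers$dem
  stopifnot(!is.null(z), all(is.finite(z)))
  nx <- dem$nx; ny <- dem$ny; cs <- dem$cellsize
  nbr <- expand.grid(dx = -1:1, dy = -1:1)
  nbr <- nbr[!(nbr$dx == 0 & nbr$dy == 0), ]
  ddist <- sqrt(nbr$dx^2 + nbr$dy^2)
  # steepest-descent receiver of every cell (0 = pit/flat/edge outflow)
  recv <- matrix(0L, nx, ny)
  best <- matrix(0, nx, ny)    # steepest descent slope found so far
  lin <- function(ix, iy) ix + (iy - 1L) * nx
  for (k in seq_len(nrow(nbr))) {
    ix <- seq_len(nx) + nbr$dx[k]
    iy <- seq_len(ny) + nbr$dy[k]
    okx <- ix >= 1L & ix <= nx
    oky <- iy >= 1L & iy <= ny
    drop_m <- matrix(-Inf, nx, ny)
    drop_m[okx, oky] <- (z[okx, oky, drop = FALSE] -
                         z[ix[okx], iy[oky], drop = FALSE]) / (ddist[k] * cs)
    upd <- drop_m > best
    if (any(upd)) {
      idx <- which(upd)
      best[idx] <- drop_m[idx]
      tgt_ix <- ((idx - 1L) %% nx) + 1L + nbr$dx[k]
      tgt_iy <- ((idx - 1L) %/% nx) + 1L + nbr$dy[k]
      recv[idx] <- lin(tgt_ix, tgt_iy)
    }
  }
  if (all(best <= 0)) {
    warning("flat DEM: no convergent flow, empty stream network")
    return(list())
  }
  # accumulate upslope area in decreasing elevation order
  acc <- rep(1, nx * ny)
  ord <- order(as.vector(z), decreasing = TRUE)
  for (i in ord) {
    r <- recv[i]
    if (r > 0L) acc[r] <- acc[r] + acc[i]
  }
  is_stream <- acc >= accumulation_threshold
  segs <- list()
  cen <- grid_centers(dem)
  for (i in which(is_stream)) {
    r <- recv[i]
    if (r > 0L && is_stream[r]) {
      ix1 <- ((i - 1L) %% nx) + 1L; iy1 <- ((i - 1L) %/% nx) + 1L
      ix2 <- ((r - 1L) %% nx) + 1L; iy2 <- ((r - 1L) %/% nx) + 1L
      segs[[length(segs) + 1L]] <- cbind(x = cen$x[c(ix1, ix2)],
                                         y = cen$y[c(iy1, iy2)])
    }
  }
  if (!length(segs)) warning("no stream segments above accumulation threshold")
  segs
}

#' Generate a Voronoi stand mosaic with canopy parameters
#'
#' Stands are the Voronoi cells of `n_stands` random seed points, which
#' yields an irregular patchy mosaic like managed forest.  Each stand gets a
#' dominant top height, a canopy cover fraction, and an understory density
#' fraction controlling the lidar return-height mixture.
#'
#' @param dem a [cov_grid()] defining the landscape grid.
#' @param n_stands number of stands.
#' @param seed integer RNG seed.
#' @return list with `stand_id` (nx x ny integer matrix) and `stands`
#'   (data.frame: id, seed_x, seed_y, top_height m, cover, under_frac).
#' @export
gen_stands <- function(dem, n_stands = 60, seed = 1) {
  with_seed(seed, {
    nx <- dem$nx; ny <- dem$ny
    cen <- grid_centers(dem)
    sx <- runif(n_stands, min(cen$x), max(cen$x))
    sy <- runif(n_stands, min(cen$y), max(cen$y))
    gx <- matrix(cen$x, nx, ny)
    gy <- matrix(cen$y, nx, ny, byrow = TRUE)
    id <- matrix(1L, nx, ny)
    d2min <- (gx - sx[1])^2 + (gy - sy[1])^2
    for (s in seq_len(n_stands)[-1]) {
      d2 <- (gx - sx[s])^2 + (gy - sy[s])^2
      upd <- d2 < d2min
      id[upd] <- s
      d2min[upd] <- d2[upd]
    }
    stands <- data.frame(
      id = seq_len(n_stands), seed_x = sx, seed_y = sy,
      top_height = runif(n_stands, 5, 35),
      cover = rbeta(n_stands, 2.5, 1.5),
      under_frac = runif(n_stands, 0.1, 0.5)
    )
    list(stand_id = id, stands = stands)
  })
}

#' Assemble a synthetic landscape
#'
#' Convenience wrapper tying the terrain, stand, stream and harvest
#' generators together with a shared seed.
#'
#' @inheritParams gen_terrain
#' @param n_stands number of Voronoi stands.
#' @param harvest_fraction fraction of the extent harvested between the
#'   telemetry and lidar epochs (paper-scale default 0.06).
#' @param telemetry_date,lidar_date Date bounds for harvest-event dates.
#' @param accumulation_threshold stream mapping threshold (cells).
#' @return list of class `landscape`: `dem` ([cov_grid()]), `streams`,
#'   `stand_id`, `stands`, `harvest`, `extent`, `lidar_date`.
#' @export
gen_landscape <- function(extent = c(4000, 4000),
                          relief = list(amplitude = 250, wavelength = 900),
                          cellsize = 30, n_stands = 60,
                          harvest_fraction = 0.06,
                          telemetry_date = as.Date("2008-06-01"),
                          lidar_date = as.Date("2012-06-01"),
                          accumulation_threshold = 50, seed = 1) {
  dem <- gen_terrain(extent, relief, cellsize, seed = seed)
  streams <- gen_streams(dem, accumulation_threshold)
  mosaic <- gen_stands(dem, n_stands, seed = seed + 1L)
  harvest <- gen_harvest(extent, harvest_fraction,
                         telemetry_date = telemetry_date,
                         lidar_date = lidar_date, seed = seed + 2L)
  structure(list(dem = dem, streams = streams, stand_id = mosaic$stand_id,
                 stands = mosaic$stands, harvest = harvest,
                 extent = extent, lidar_date = lidar_date),
            class = "landscape")
}

#' Generate dated harvest polygons
#'
#' Pairwise-disjoint axis-aligned harvest blocks covering approximately
#' `fraction` of the extent, dated between the telemetry and lidar epochs so
#' they trigger censoring.  Individual blocks are 1-50 ha, matching the size
#' range of observed harvest units.
#'
#' @param extent `(width, height)` in meters.
#' @param fraction target covered fraction of the extent, in `[0, 0.2]`.
#' @param telemetry_date,lidar_date Date bounds for the harvest dates.
#' @param seed integer RNG seed.
#' @return data.frame with columns xmin, xmax, ymin, ymax, date.
#' @export
gen_harvest <- function(extent, fraction = 0.06,
                        telemetry_date = as.Date("2008-06-01"),
                        lidar_date = as.Date("2012-06-01"), seed = 1) {
  stopifnot(fraction >= 0, fraction <= 0.2)
  empty <- data.frame(xmin = numeric(0), xmax = numeric(0),
                      ymin = numeric(0), ymax = numeric(0),
                      date = as.Date(character(0)))
  if (fraction == 0) return(empty)
  with_seed(seed, {
    target <- fraction * prod(extent)
    rects <- empty
    covered <- 0
    tries <- 0L
    while (covered < target * 0.999 && tries < 10000L) {
      tries <- tries + 1L
      w <- runif(1, 100, 600)
      h <- runif(1, 100, 600)
      remaining <- target - covered
      if (w * h > remaining) {         # trim the final block to land on target
        scl <- sqrt(remaining / (w * h))
        w <- w * scl; h <- h * scl
      }
      x0 <- runif(1, 0, extent[1] - w)
      y0 <- runif(1, 0, extent[2] - h)
      # require disjoint (with a 30 m gap so blocks stay clearly separate)
      if (nrow(rects) > 0) {
        overlap <- x0 < rects$xmax + 30 & x0 + w > rects$xmin - 30 &
                   y0 < rects$ymax + 30 & y0 + h > rects$ymin - 30
        if (any(overlap)) next
      }
      rects <- rbind(rects, data.frame(
        xmin = x0, xmax = x0 + w, ymin = y0, ymax = y0 + h,
        date = telemetry_date + round(
          runif(1, 1, as.numeric(lidar_date - telemetry_date) - 1))))
      covered <- covered + w * h
    }
    rects
  })
}

#' Simulate a lidar return cloud over a landscape
#'
#' Per 30 m cell, the return count is Poisson with mean
#' `density_per_m2 * cellsize^2` and return heights follow the stand's
#' three-component mixture: ground returns at 0 m with probability
#' `1 - cover`; understory returns uniform on (2, 8) m with probability
#' `cover * under_frac`; canopy returns around the stand top height with
#' probability `cover * (1 - under_frac)`.  Heights are height-above-ground
#' directly, as consumed by the metric engine.
#'
#' @param landscape a [gen_landscape()] result (or any list with `dem`,
#'   `stand_id`, `stands`).
#' @param density_per_m2 mean return density (returns per square meter).
#' @param seed integer RNG seed.
#' @return data.frame with columns x, y, z (meters; z = height above ground).
#' @export
gen_returns <- function(landscape, density_per_m2 = 0.3, seed = 1) {
  stopifnot(density_per_m2 > 0)
  dem <- landscape$dem
  cs <- dem$cellsize
  with_seed(seed, {
    ncell <- dem$nx * dem$ny
    counts <- rpois(ncell, density_per_m2 * cs^2)
    n <- sum(counts)
    cell <- rep.int(seq_len(ncell), counts)
    ix <- ((cell - 1L) %% dem$nx)
    iy <- ((cell - 1L) %/% dem$nx)
    x <- dem$origin[1] + (ix + runif(n)) * cs
    y <- dem$origin[2] + (iy + runif(n)) * cs
    sid <- as.vector(landscape$stand_id)[cell]
    st <- landscape$stands[sid, ]
    u <- runif(n)
    p_ground <- 1 - st$cover
    p_under <- st$cover * st$under_frac
    z <- numeric(n)
    is_under <- u >= p_ground & u < p_ground + p_under
    is_canopy <- u >= p_ground + p_under
    z[is_under] <- runif(sum(is_under), 2.05, 8)
    if (any(is_canopy)) {
      top <- st$top_height[is_canopy]
      zc <- rnorm(sum(is_canopy), mean = top, sd = 0.08 * top)
      z[is_canopy] <- pmin(pmax(zc, 2.05), 1.1 * top)
    }
    data.frame(x = x, y = y, z = z)
  })
}

#' Write / read lidar returns as XYZ CSV
#' @param cloud data.frame with columns x, y, z.
#' @param path file path.
#' @return `path` invisibly (writer); the cloud data.frame (reader).
#' @export
write_xyz <- function(cloud, path) {
  write.csv(cloud[, c("x", "y", "z")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  df[, c("x", "y", "z")]
}
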