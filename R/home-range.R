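#' Minimum-relocation rule for kernel home ranges
#'
#' Kernel estimates are unstable at small sample sizes, so seasonal home
#' ranges are only built for animals with more than 27 relocations in that
#' season.
#'
#' @param points 2-column matrix (or data.frame with x, y) of relocations.
#' @return `TRUE` iff the season has at least 28 relocations.
#' @export
check_min_relocations <- function(points) {
  n <- if (is.null(dim(points))) length(points) else nrow(points)
  n >= 28L
}

as_pts <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  stopifnot(is.matrix(points), ncol(points) == 2)
  storage.mode(points) <- "double"
  points
}

#' Likelihood cross-validation bandwidth for a fixed Gaussian kernel
#'
#' Selects the scalar smoothing parameter `h` of an isotropic bivariate
#' Gaussian kernel by maximizing the leave-one-out log-likelihood
#' `sum_i log f_{-i}(x_i; h)`.  A log-spaced grid search brackets the
#' optimum, which is then refined with [stats::optimize()].
#'
#' @param points relocations (matrix or data.frame with x, y), in meters.
#' @param ngrid size of the initial log-spaced search grid.
#' @return bandwidth `h` in meters (Gaussian kernel SD).
#' @export
select_bandwidth_lcv <- function(points, ngrid = 30) {
  pts <- as_pts(points)
  n <- nrow(pts)
  stopifnot(n >= 3)
  d2 <- as.matrix(dist(pts))^2
  if (all(d2 == 0)) stop("all points identical: LCV likelihood is degenerate")
  diag(d2) <- Inf
  loo_ll <- function(h) {
    k <- exp(-d2 / (2 * h^2))
    f <- rowSums(k) / ((n - 1) * 2 * pi * h^2)
    if (any(f == 0)) return(-Inf)
    sum(log(f))
  }
  s <- sqrt(mean(apply(pts, 2, var)))
  if (s == 0) s <- sqrt(mean(d2[is.finite(d2)])) / 2
  hs <- exp(seq(log(0.02 * s), log(2.5 * s), length.out = ngrid))
  lls <- vapply(hs, loo_ll, numeric(1))
  i <- which.max(lls)
  lo <- hs[max(1, i - 1)]; hi <- hs[min(ngrid, i + 1)]
  opt <- optimize(loo_ll, c(lo, hi), maximum = TRUE, tol = 1e-3 * s)
  opt$maximum
}

# Evaluate the kernel UD on a regular grid.  MASS::kde2d's bandwidth
# argument is 4x the Gaussian SD of the kernel it applies, so `4 * h`
# yields the isotropic Gaussian KDE with SD h.
kde_ud <- function(pts, h, cellsize = 30, pad = 0) {
  ex <- range(pts[, 1]) + c(-1, 1) * (4 * h + pad)
  ey <- range(pts[, 2]) + c(-1, 1) * (4 * h + pad)
  nx <- max(20L, ceiling(diff(ex) / cellsize) + 1L)
  ny <- max(20L, ceiling(diff(ey) / cellsize) + 1L)
  k <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * h, n = c(nx, ny),
                   lims = c(ex, ey))
  cellarea <- diff(k$x[1:2]) * diff(k$y[1:2])
  mass <- k$z * cellarea
  list(x = k$x, y = k$y, z = k$z, mass = mass / sum(mass),
       raw_total = sum(mass), cellarea = cellarea)
}

# Smallest-density region holding `level` of the UD mass.
ud_threshold <- function(ud, level) {
  o <- order(ud$z, decreasing = TRUE)
  cum <- cumsum(ud$mass[o])
  ud$z[o[which(cum >= level)[1]]]
}

#' Kernel density isopleth
#'
#' The smallest-density-threshold contour containing at least `level` of the
#' utilization-distribution mass on the evaluation grid; may be multi-part.
#'
#' @param points relocations (matrix or data.frame with x, y).
#' @param h Gaussian kernel SD (m), e.g. from [select_bandwidth_lcv()].
#' @param level UD mass fraction in (0, 1); 0.95 for the standard home range.
#' @param cellsize evaluation grid resolution (m).
#' @return list: `polygons` ([grDevices::contourLines()] rings), `area` (m^2,
#'   from grid cells at/above the threshold), `mass` (UD mass enclosed),
#'   `threshold`, `ud`, `mask`.
#' @export
kde_isopleth <- function(points, h, level = 0.95, cellsize = 30) {
  stopifnot(h > 0)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  pts <- as_pts(points)
  ud <- kde_ud(pts, h, cellsize = cellsize)
  thr <- ud_threshold(ud, level)
  mask <- ud$z >= thr
  polys <- grDevices::contourLines(ud$x, ud$y, ud$z, levels = thr * (1 - 1e-9))
  list(polygons = polys, area = sum(mask) * ud$cellarea,
       mass = sum(ud$mass[mask]), threshold = thr, ud = ud, mask = mask)
}

#' Seasonal fixed-kernel home range
#'
#' 95% fixed-kernel home range with an LCV bandwidth, evaluated on a 30 m
#' grid, with the availability region extended outward by the species'
#' average daily movement rate (see [buffer_range()]).  Fails when the
#' season has fewer than 28 relocations.
#'
#' @param points relocations (matrix or data.frame with x, y), meters.
#' @param species `"spotted"` or `"barred"` (sets the buffer distance).
#' @param owl_ids character vector (length 1, or 2 for a joint pair range).
#' @param season season label carried on the object.
#' @param level isopleth level.
#' @param cellsize UD grid resolution (m).
#' @param h optional fixed bandwidth (default: LCV).
#' @return object of class `home_range`: bandwidth `h`, UD grid, isopleth
#'   polygons/mask, buffered mask, areas, grid geometry.
#' @export
home_range <- function(points, species, owl_ids = "owl", season = "breeding",
                       level = 0.95, cellsize = 30, h = NULL) {
  pts <- as_pts(points)
  if (!check_min_relocations(pts)) {
    stop("home range requires >27 relocations (got ", nrow(pts), ")")
  }
  buffer <- movement_buffer(species)
  if (is.null(h)) h <- select_bandwidth_lcv(pts)
  ud <- kde_ud(pts, h, cellsize = cellsize, pad = buffer + 2 * cellsize)
  thr <- ud_threshold(ud, level)
  mask <- ud$z >= thr
  polys <- grDevices::contourLines(ud$x, ud$y, ud$z, levels = thr * (1 - 1e-9))
  cellsize_x <- diff(ud$x[1:2])
  buffered <- dilate_mask(mask, cellsize_x, buffer)
  structure(list(
    owl_ids = owl_ids, species = species, season = season, h = h,
    level = level, ud = ud, threshold = thr, mask = mask,
    polygons = polys, buffered = buffered, buffer = buffer,
    n_points = nrow(pts),
    area = sum(mask) * ud$cellarea,
    buffered_area = sum(buffered) * ud$cellarea
  ), class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf(
    "<home_range> %s [%s, %s] n=%d h=%.0f m area=%.0f ha (buffered %.0f ha)\n",
    paste(x$owl_ids, collapse = "+"), x$species, x$season, x$n_points, x$h,
    x$area / 1e4, x$buffered_area / 1e4))
  invisible(x)
}

#' Average daily movement-rate buffer by species
#'
#' 520 m for spotted owls and 350 m for barred owls.
#'
#' @param species `"spotted"` or `"barred"`.
#' @return buffer distance in meters.
#' @export
movement_buffer <- function(species) {
  switch(as.character(species),
         spotted = 520,
         barred = 350,
         stop("unknown species: ", species))
}

#' Joint breeding-season range for a monitored pair
#'
#' Relocations of both pair members are pooled and a single bandwidth and
#' isopleth computed.  If one member has no relocations the other member's
#' individual range is returned (with a message).
#'
#' @param points_a,points_b relocations of the two pair members.
#' @inheritParams home_range
#' @return a [home_range()] object with both owl ids.
#' @export
joint_pair_range <- function(points_a, points_b, species,
                             owl_ids = c("a", "b"), season = "breeding", ...) {
  na <- if (is.null(points_a)) 0L else nrow(as_pts(points_a))
  nb <- if (is.null(points_b)) 0L else nrow(as_pts(points_b))
  if (na == 0L || nb == 0L) {
    message("one pair member has no relocations; using single-owl range")
    pts <- if (na > 0L) points_a else points_b
    ids <- owl_ids[if (na > 0L) 1L else 2L]
    return(home_range(pts, species, owl_ids = ids, season = season, ...))
  }
  pooled <- rbind(as_pts(points_a), as_pts(points_b))
  home_range(pooled, species, owl_ids = owl_ids, season = season, ...)
}

#' Test whether points fall inside a home range
#'
#' Grid-mask membership on the range's UD grid (cells are centered on the
#' UD evaluation nodes).
#'
#' @param hr a [home_range()].
#' @param x,y point coordinates (m).
#' @param buffered use the movement-rate-buffered region (default) or the
#'   bare 95% isopleth.
#' @return logical vector.
#' @export
point_in_range <- function(hr, x, y, buffered = TRUE) {
  m <- if (buffered) hr$buffered else hr$mask
  gx <- hr$ud$x; gy <- hr$ud$y
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  ix <- round((x - gx[1]) / dx) + 1L
  iy <- round((y - gy[1]) / dy) + 1L
  ok <- ix >= 1L & ix <= length(gx) & iy >= 1L & iy <= length(gy)
  out <- rep(FALSE, length(x))
  out[ok] <- m[cbind(ix[ok], iy[ok])]
  out
}

#' Build qualifying seasonal home ranges for a telemetry table
#'
#' One range per owl and season with more than 27 relocations.  For owls
#' with a `pair_id`, the breeding-season range is built jointly from both
#' pair members' relocations (the >27 rule applies to the pooled count) and
#' shared by both members.  Nonbreeding ranges are always per-individual.
#'
#' @param telemetry data.frame with owl_id, species, season, x, y and
#'   optionally pair_id (or supply `owls` to look pair membership up).
#' @param owls optional [gen_owls()] table with id and pair_id.
#' @param cellsize UD grid resolution (m).
#' @return named list of [home_range()] objects keyed `"<owl_id>.<season>"`;
#'   owls without a qualifying range are absent.
#' @export
build_home_ranges <- function(telemetry, owls = NULL, cellsize = 30) {
  pair_of <- function(id) {
    if (!is.null(owls) && "pair_id" %in% names(owls)) {
      owls$pair_id[match(id, owls$id)]
    } else if ("pair_id" %in% names(telemetry)) {
      telemetry$pair_id[match(id, telemetry$owl_id)]
    } else {
      NA_character_
    }
  }
  ranges <- list()
  for (se in unique(telemetry$season)) {
    tel_s <- telemetry[telemetry$season == se, ]
    done <- character(0)
    for (id in unique(tel_s$owl_id)) {
      if (id %in% done) next
      sp <- tel_s$species[tel_s$owl_id == id][1]
      pid <- pair_of(id)
      mate <- if (se == "breeding" && !is.na(pid)) {
        setdiff(unique(telemetry$owl_id[pair_of(telemetry$owl_id) %in% pid]), id)
      } else {
        character(0)
      }
      pts_a <- tel_s[tel_s$owl_id == id, c("x", "y")]
      if (length(mate) == 1L) {
        pts_b <- tel_s[tel_s$owl_id == mate, c("x", "y")]
        if (!check_min_relocations(rbind(pts_a, pts_b))) {
          warning("skipping ", id, "/", mate, " ", se,
                  ": <28 pooled relocations")
          done <- c(done, id, mate)
          next
        }
        hr <- joint_pair_range(pts_a, pts_b, species = sp,
                               owl_ids = c(id, mate), season = se,
                               cellsize = cellsize)
        ranges[[paste0(id, ".", se)]] <- hr
        ranges[[paste0(mate, ".", se)]] <- hr
        done <- c(done, id, mate)
      } else {
        if (!check_min_relocations(pts_a)) {
          warning("skipping ", id, " ", se, ": <28 relocations")
          done <- c(done, id)
          next
        }
        ranges[[paste0(id, ".", se)]] <-
          home_range(pts_a, species = sp, owl_ids = id, season = se,
                     cellsize = cellsize)
        done <- c(done, id)
      }
    }
  }
  ranges
}
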