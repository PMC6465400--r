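test_that("returns are assigned to cells by the half-open rule", {
  g <- cov_grid(c(0, 0), 30, 4, 4)
  # a return on an interior cell corner belongs to the cell it is the
  # lower-left corner of
  corner <- grid_returns(data.frame(x = 30, y = 60, z = 1), grid = g)
  expect_equal(corner$cell, 2L + 2L * 4L)   # cell (2, 3)

  set.seed(1)
  cloud <- data.frame(x = runif(1e4, 0, 120), y = runif(1e4, 0, 120),
                      z = runif(1e4, 0, 30))
  gr <- grid_returns(cloud, grid = g)
  expect_equal(sum(tabulate(gr$cell, 16)), nrow(cloud))   # conservation
  # brute-force point-in-rectangle oracle
  oracle <- integer(nrow(cloud))
  for (ix in 1:4) for (iy in 1:4) {
    inside <- cloud$x >= (ix - 1) * 30 & cloud$x < ix * 30 &
              cloud$y >= (iy - 1) * 30 & cloud$y < iy * 30
    oracle[inside] <- ix + (iy - 1L) * 4L
  }
  expect_identical(gr$cell, oracle)
})

test_that("canopy height and cover match their definitions", {
  expect_equal(canopy_height(rep(10, 7)), 10)
  expect_equal(canopy_height(c(1, 1, 1)), 0)
  expect_true(is.na(canopy_height(numeric(0))))
  set.seed(2)
  z <- runif(100, 2.001, 20)
  # sort-based percentile oracle (linear interpolation between order stats)
  zz <- sort(z[z > 2])
  h <- (length(zz) - 1) * 0.95
  lo <- floor(h)
  expected <- zz[lo + 1] * (1 - (h - lo)) + zz[lo + 2] * (h - lo)
  expect_equal(canopy_height(z), expected, tolerance = 1e-12)

  expect_equal(canopy_cover(c(0, 1, 3, 5)), 0.5)
  expect_equal(canopy_cover(c(3, 4, 5)), 1)
  set.seed(3)
  for (i in 1:20) {
    z <- runif(sample(5:60, 1), 0, 25)
    expect_equal(canopy_cover(z), sum(z > 2) / length(z), tolerance = 1e-12)
  }
})

test_that("strata cover uses within-and-below denominators", {
  expect_equal(strata_cover(c(1, 1, 1, 5, 5, 5), 4, 8), 0.5)
  expect_true(is.na(strata_cover(c(9, 10, 12), 2, 4)))  # zero denominator
  set.seed(4)
  for (i in 1:20) {
    z <- runif(sample(10:80, 1), 0, 12)
    expect_equal(strata_cover(z, 4, 8),
                 sum(z >= 4 & z < 8) / sum(z < 8), tolerance = 1e-12)
    expect_equal(strata_cover(z, 2, 4),
                 sum(z >= 2 & z < 4) / sum(z < 4), tolerance = 1e-12)
  }
})

test_that("S2to4 is no-data where dominant canopy is 4 m or less", {
  # one low cell (HEIGHT = 3) and one tall cell (HEIGHT > 4), full coverage
  sub <- expand.grid(x = seq(0.5, 29.5, 1), y = seq(0.5, 29.5, 1))
  cloud <- rbind(
    data.frame(x = sub$x, y = sub$y, z = 3),           # low cell
    data.frame(x = sub$x + 30, y = sub$y, z = 3),
    data.frame(x = sub$x + 30, y = sub$y, z = 10)      # tall cell
  )
  dem <- cov_grid(c(0, 0), 30, 2, 1, list(dem = matrix(200, 2, 1)))
  streams <- list(cbind(x = c(0, 60), y = c(0, 0)))
  g <- compute_metric_grids(cloud, dem, streams, tpi_windows = 30)
  expect_equal(g$layers$HEIGHT[1, 1], 3)
  expect_true(is.na(g$layers$S2to4[1, 1]))
  expect_gt(g$layers$HEIGHT[2, 1], 4)
  expect_false(is.na(g$layers$S2to4[2, 1]))
})

test_that("rumple is exact on analytic canopy surfaces", {
  sub <- expand.grid(x = seq(0.5, 29.5, 1), y = seq(0.5, 29.5, 1))
  expect_equal(rumple(sub$x, sub$y, rep(12, 900)), 1, tolerance = 1e-6)
  th <- 10 * pi / 180
  expect_equal(rumple(sub$x, sub$y, 5 + tan(th) * sub$x), 1 / cos(th),
               tolerance = 1e-3)
  set.seed(5)
  for (i in 1:10) {
    z <- runif(900, 0, 30)
    expect_gte(rumple(sub$x, sub$y, z), 1)
  }
  expect_true(is.na(rumple(c(1, 2), c(1, 2), c(5, 6))))  # too sparse
})

test_that("terrain metrics have the right flat-limit and analytic values", {
  n <- 40
  flat <- cov_grid(c(0, 0), 30, n, n, list(dem = matrix(100, n, n)))
  tm <- terrain_metrics(flat, lat = 44, tpi_windows = c(200, 500))
  expect_equal(max(abs(tm$layers$SLOPE)), 0)
  expect_equal(max(abs(tm$layers$TPI)), 0)
  expect_equal(unique(as.vector(tm$layers$SRI)), 1 + cos(44 * pi / 180),
               tolerance = 1e-12)

  cen <- ((1:n) - 0.5) * 30
  tilted <- cov_grid(c(0, 0), 30, n, n,
                     list(dem = matrix(tan(10 * pi / 180) * cen, n, n)))
  tt <- terrain_metrics(tilted, tpi_windows = 200)
  expect_equal(mean(tt$layers$SLOPE[5:(n - 5), 5:(n - 5)]), 10,
               tolerance = 0.1)

  peak <- matrix(0, n, n); peak[20, 20] <- 50
  tp <- terrain_metrics(cov_grid(c(0, 0), 30, n, n, list(dem = peak)),
                        tpi_windows = 200)$layers$TPI200
  expect_gt(tp[20, 20], 0)
  ring <- rbind(c(19, 19), c(19, 20), c(19, 21), c(20, 19), c(20, 21),
                c(21, 19), c(21, 20), c(21, 21))
  expect_true(all(tp[ring] < 0))

  expect_error(terrain_metrics(flat, tpi_windows = 1e5), "larger")
})

test_that("TPI averages to zero over full periods of a periodic surface", {
  nx <- 120
  z <- matrix(50 * sin(2 * pi * (1:nx) / 12), nx, nx)
  for (w in c(200, 500)) {
    tp <- terrain_metrics(cov_grid(c(0, 0), 30, nx, nx, list(dem = z)),
                          tpi_windows = w)$layers[[paste0("TPI", w)]]
    rc <- floor(w / 2 / 30)
    cols <- (rc + 1):(rc + 96)     # 8 full periods, windows fully interior
    expect_lt(abs(mean(tp[cols, ])), 1e-6 * 50)
  }
})

test_that("stream distance is exact against a densified brute force", {
  g <- cov_grid(c(0, 0), 30, 20, 20)
  axis <- list(cbind(x = c(0, 600), y = c(0, 0)))
  d <- dist_to_stream(g, axis)
  expect_equal(d[5, 10], 285)   # center y = 285 above the x-axis line
  on_line <- dist_to_stream(g, list(cbind(x = c(0, 600), y = c(15, 15))))
  expect_equal(min(on_line[, 1]), 0)

  set.seed(6)
  streams <- lapply(1:3, function(i) {
    cbind(x = cumsum(runif(5, 0, 200)), y = cumsum(runif(5, -100, 100)) + 300)
  })
  d2 <- dist_to_stream(g, streams)
  dense <- do.call(rbind, lapply(streams, function(m) {
    do.call(rbind, lapply(seq_len(nrow(m) - 1), function(s) {
      t <- seq(0, 1, length.out = 1000)
      cbind(m[s, 1] + t * (m[s + 1, 1] - m[s, 1]),
            m[s, 2] + t * (m[s + 1, 2] - m[s, 2]))
    }))
  }))
  cen <- grid_centers(g)
  for (k in sample(400, 25)) {
    ix <- ((k - 1) %% 20) + 1; iy <- ((k - 1) %/% 20) + 1
    brute <- min(sqrt((dense[, 1] - cen$x[ix])^2 + (dense[, 2] - cen$y[iy])^2))
    expect_lt(abs(d2[ix, iy] - brute), 1)
  }
  expect_error(dist_to_stream(g, list()), "empty")
})

test_that("point extraction averages cells within the radius", {
  g <- cov_grid(c(0, 0), 30, 20, 20,
                list(A = matrix(7, 20, 20),
                     B = matrix(rep(c(0, 1), length.out = 400), 20, 20)))
  expect_equal(extract_mean(g, 300, 300, radius = 150)$A, 7)
  # checkerboard-ish alternating field averages to ~0.5
  expect_equal(extract_mean(g, 300, 285, radius = 150)$B, 0.5,
               tolerance = 0.05)
  # radius smaller than half a cell: the containing cell only
  expect_equal(extract_mean(g, 290, 290, radius = 10)$B,
               g$layers$B[10, 10])
  # missing data ignored; all-missing flagged NA
  g$layers$A[8:12, 8:12] <- NA
  expect_true(is.na(extract_mean(g, 300, 300, radius = 40)$A))
  v <- extract_mean(g, 300, 300, radius = 150)$A
  expect_equal(v, 7)
})

test_that("gridded metrics equal brute-force recomputation on random cells", {
  set.seed(7)
  n <- 6
  cloud <- data.frame(x = runif(20000, 0, n * 30), y = runif(20000, 0, n * 30),
                      z = pmax(0, runif(20000, -2, 25)))
  dem <- cov_grid(c(0, 0), 30, n, n,
                  list(dem = matrix(rnorm(n * n, 100, 5), n, n)))
  streams <- list(cbind(x = c(0, 180), y = c(90, 90)))
  g <- compute_metric_grids(cloud, dem, streams, tpi_windows = 60)
  for (k in sample(n * n, 12)) {
    ix <- ((k - 1) %% n) + 1; iy <- ((k - 1) %/% n) + 1
    inside <- cloud$x >= (ix - 1) * 30 & cloud$x < ix * 30 &
              cloud$y >= (iy - 1) * 30 & cloud$y < iy * 30
    z <- cloud$z[inside]
    expect_equal(g$layers$HEIGHT[ix, iy], canopy_height(z), tolerance = 1e-9)
    expect_equal(g$layers$CANCOV[ix, iy], sum(z > 2) / length(z),
                 tolerance = 1e-9)
    expect_equal(g$layers$D4to8[ix, iy], sum(z >= 4 & z < 8) / sum(z < 8),
                 tolerance = 1e-9)
  }
  expect_true(all(g$layers$CANCOV >= 0 & g$layers$CANCOV <= 1))
  expect_true(all(g$layers$D4to8 >= 0 & g$layers$D4to8 <= 1, na.rm = TRUE))
  expect_true(all(g$layers$RUMPLE >= 1, na.rm = TRUE))

  # permutation invariance: metric grids don't depend on return order
  per <- sample(nrow(cloud))
  g2 <- compute_metric_grids(cloud[per, ], dem, streams, tpi_windows = 60)
  expect_equal(g2$layers$HEIGHT, g$layers$HEIGHT, tolerance = 1e-12)
  expect_equal(g2$layers$RUMPLE, g$layers$RUMPLE, tolerance = 1e-12)
})

test_that("dominant canopy height is monotone in appended tall returns", {
  set.seed(8)
  for (i in 1:25) {
    z <- runif(sample(5:50, 1), 0, 25)
    h0 <- canopy_height(z)
    z_new <- max(h0, 2.01) + runif(1, 0.01, 10)
    expect_gte(canopy_height(c(z, z_new)), h0)
  }
})
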