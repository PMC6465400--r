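# Shared fixture builders.  Everything is generated in code at test time.

# Flat-terrain covariate grid with spatially autocorrelated canopy layers
# (like real metric surfaces; a smooth field also survives the 150 m
# extraction mean).  No missing cells, so choice-set construction never
# loses sets to covariates.
make_test_grid <- function(nx = 110, ny = nx, cellsize = 30, seed = 1,
                           layers = c("HEIGHT", "CANCOV", "SLOPE")) {
  set.seed(seed)
  specs <- list(HEIGHT = c(20, 6), CANCOV = c(0.6, 0.15), SLOPE = c(15, 5),
                SRI = c(1, 0.3), TPI = c(0, 20), STREAM = c(300, 150))
  lay <- lapply(layers, function(nm) {
    p <- specs[[nm]] %||% c(0, 1)
    z <- strixsel:::gauss_blur(matrix(rnorm(nx * ny), nx, ny), 5)
    p[1] + z / sd(as.vector(z)) * p[2]
  })
  cov_grid(c(0, 0), cellsize, nx, ny, setNames(lay, layers))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small spatial study: owls, truth, telemetry, ranges on a shared grid.
make_test_study <- function(n_per_species = c(spotted = 2, barred = 2),
                            n_locs = 120, extent = c(4000, 4000),
                            radius = 1200, terms = c("HEIGHT", "CANCOV", "SLOPE"),
                            mu = c(1, 0.5, -0.5), sigma = 0.3,
                            paired = TRUE, seed = 1, margin = radius + 300) {
  grid <- make_test_grid(nx = ceiling(extent[1] / 30),
                         ny = ceiling(extent[2] / 30),
                         seed = seed, layers = terms)
  owls <- gen_owls(n_per_species, extent = extent, margin = margin,
                   paired = paired, seed = seed + 1)
  truth <- make_truth(terms, mu = mu, sigma = sigma, owls = owls,
                      seed = seed + 2)
  telemetry <- gen_telemetry_all(owls, grid, truth, n_locs = n_locs,
                                 radius = radius, seed = seed + 3)
  list(grid = grid, owls = owls, truth = truth, telemetry = telemetry,
       terms = terms)
}

# Brute-force conditional-logit log-likelihood (independent oracle).
oracle_choice_loglik <- function(beta, X, nalt) {
  total <- 0
  for (s in seq_len(nrow(X) / nalt)) {
    rows <- (s - 1) * nalt + seq_len(nalt)
    u <- as.vector(X[rows, , drop = FALSE] %*% beta)
    total <- total + log(exp(u[1]) / sum(exp(u)))
  }
  total
}

# Brute-force WAIC from a draws x sets pointwise log-likelihood matrix.
oracle_waic <- function(ll) {
  lppd <- 0; p_waic <- 0
  for (s in seq_len(ncol(ll))) {
    lppd <- lppd + log(mean(exp(ll[, s])))
    p_waic <- p_waic + var(ll[, s])
  }
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}
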