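#' Season of a date
#'
#' Breeding season is March 1 - August 31; the nonbreeding season
#' (September 1 - February 28/29) spans the year boundary, so season is
#' assigned from month alone.
#'
#' @param dates Date (or coercible) vector.
#' @return character vector, `"breeding"` or `"nonbreeding"`.
#' @export
season_of <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  ifelse(m >= 3L & m <= 8L, "breeding", "nonbreeding")
}

#' Generate a set of territorial owls
#'
#' Centers are placed uniformly inside the extent minus a margin so home
#' ranges stay on the covariate grid.  Within each species, owls are grouped
#' into male/female pairs sharing a `pair_id` (odd remainder unpaired).
#'
#' @param n_per_species named integer vector, e.g. `c(spotted = 4, barred = 4)`.
#' @param extent `(width, height)` of the landscape (m).
#' @param margin minimum distance of a center from the landscape edge (m).
#' @param paired logical; assign breeding pairs within species.
#' @param seed integer RNG seed.
#' @return data.frame: id, species, sex, x, y, pair_id (NA if unpaired).
#' @export
gen_owls <- function(n_per_species = c(spotted = 4, barred = 4),
                     extent = c(4000, 4000), margin = 1600,
                     paired = TRUE, seed = 1) {
  stopifnot(all(extent > 2 * margin))
  with_seed(seed, {
    out <- do.call(rbind, lapply(names(n_per_species), function(sp) {
      n <- n_per_species[[sp]]
      if (n == 0) return(NULL)
      pair_id <- if (paired) paste0(sp, "_p", (seq_len(n) + 1L) %/% 2L)
                 else rep(NA_character_, n)
      if (paired && n %% 2L == 1L) pair_id[n] <- NA_character_
      data.frame(
        id = paste0(sp, "_", seq_len(n)),
        species = sp,
        sex = rep_len(c("F", "M"), n),
        x = runif(n, margin, extent[1] - margin),
        y = runif(n, margin, extent[2] - margin),
        pair_id = pair_id
      )
    }))
    rownames(out) <- NULL
    out
  })
}

#' Ground-truth selection parameters
#'
#' Species-by-season hyper-means and SDs for the selection coefficients, and
#' realized individual-by-season coefficient vectors drawn from
#' `Normal(mu, sigma)`, mirroring the hierarchy of the fitted model.
#'
#' @param terms character vector of covariate (layer) names the selection
#'   surface uses.
#' @param mu named list `mu[[species]][[season]]`, each a numeric vector of
#'   length `length(terms)`; or a single numeric vector recycled to all four
#'   species x season cells.
#' @param sigma positive scalar or vector like `mu`: coefficient SDs.
#' @param owls data.frame from [gen_owls()].
#' @param seed integer RNG seed.
#' @return object of class `truth_params`: list with `terms`, `mu`, `sigma`,
#'   `beta` (named list `beta[[owl_id]][[season]]`).
#' @export
make_truth <- function(terms, mu, sigma = 0.3, owls, seed = 1) {
  species <- unique(owls$species)
  seasons <- c("breeding", "nonbreeding")
  expand_hyper <- function(h) {
    if (is.numeric(h)) {
      h <- setNames(lapply(species, function(sp) {
        setNames(lapply(seasons, function(se) rep_len(h, length(terms))), seasons)
      }), species)
    }
    h
  }
  mu <- expand_hyper(mu)
  sigma <- expand_hyper(sigma)
  for (sp in species) for (se in seasons) {
    stopifnot(length(mu[[sp]][[se]]) == length(terms),
              all(sigma[[sp]][[se]] > 0))
  }
  with_seed(seed, {
    beta <- setNames(lapply(seq_len(nrow(owls)), function(i) {
      sp <- owls$species[i]
      setNames(lapply(seasons, function(se) {
        rnorm(length(terms), mu[[sp]][[se]], sigma[[sp]][[se]])
      }), seasons)
    }), owls$id)
    structure(list(terms = terms, mu = mu, sigma = sigma, beta = beta,
                   species = species, seasons = seasons),
              class = "truth_params")
  })
}

#' Generate telemetry relocations from a known selection surface
#'
#' Used locations are drawn from the 30 m cells within `radius` of the owl's
#' center, with probability proportional to `exp(x' beta)` where `x` is the
#' standardized covariate vector of the cell (standardization over the whole
#' grid) and `beta` is the owl's season-specific coefficient vector from
#' `truth`.  Locations are jittered uniformly within their cell.  Dates are
#' uniform within each season (nonbreeding dates span the year boundary) and
#' carry the derived season label.
#'
#' @param owl one row of [gen_owls()] output.
#' @param grid a [cov_grid()] holding the covariate layers named in
#'   `truth$terms`.
#' @param truth a [make_truth()] object.
#' @param n_locs total relocations (split between seasons).
#' @param radius candidate-disc radius around the owl center (m).
#' @param breeding_frac fraction of relocations in the breeding season.
#' @param p_night probability a relocation is nocturnal.
#' @param year calendar year anchoring the timestamps.
#' @param seed integer RNG seed.
#' @return data.frame: owl_id, species, sex, timestamp (Date), x, y, season,
#'   is_night.
#' @export
gen_telemetry <- function(owl, grid, truth, n_locs = 120, radius = 1500,
                          breeding_frac = 0.5, p_night = 0.78,
                          year = 2008, seed = 1) {
  stopifnot(nrow(owl) == 1)
  terms <- truth$terms
  std <- standardize_grid(grid, terms)
  cen <- grid_centers(grid)
  gx <- matrix(cen$x, grid$nx, grid$ny)
  gy <- matrix(cen$y, grid$nx, grid$ny, byrow = TRUE)
  in_disc <- (gx - owl$x)^2 + (gy - owl$y)^2 <= radius^2
  X <- sapply(terms, function(tm) std[[tm]][in_disc])
  ok <- complete.cases(X)
  if (!any(ok)) stop("no candidate cells with complete covariates in the disc")
  X <- X[ok, , drop = FALSE]
  cand <- which(in_disc)[ok]
  cand_ix <- ((cand - 1L) %% grid$nx)
  cand_iy <- ((cand - 1L) %/% grid$nx)
  n_b <- round(n_locs * breeding_frac)
  n_n <- n_locs - n_b
  beta <- truth$beta[[owl$id]]
  with_seed(seed, {
    sample_season <- function(n, season) {
      if (n == 0) return(NULL)
      u <- as.vector(X %*% beta[[season]])
      p <- exp(u - max(u))
      idx <- sample.int(length(cand), n, replace = TRUE, prob = p)
      x <- grid$origin[1] + (cand_ix[idx] + runif(n)) * grid$cellsize
      y <- grid$origin[2] + (cand_iy[idx] + runif(n)) * grid$cellsize
      dates <- if (season == "breeding") {
        as.Date(sprintf("%d-03-01", year)) +
          floor(runif(n, 0, as.numeric(as.Date(sprintf("%d-09-01", year)) -
                                       as.Date(sprintf("%d-03-01", year)))))
      } else {
        as.Date(sprintf("%d-09-01", year)) +
          floor(runif(n, 0, as.numeric(as.Date(sprintf("%d-03-01", year + 1L)) -
                                       as.Date(sprintf("%d-09-01", year)))))
      }
      data.frame(owl_id = owl$id, species = owl$species, sex = owl$sex,
                 timestamp = dates, x = x, y = y,
                 season = season_of(dates),
                 is_night = runif(n) < p_night)
    }
    out <- rbind(sample_season(n_b, "breeding"),
                 sample_season(n_n, "nonbreeding"))
    rownames(out) <- NULL
    out
  })
}

# Standardize the named layers of a grid over all non-missing cells.
standardize_grid <- function(grid, terms) {
  out <- list()
  for (tm in terms) {
    m <- grid$layers[[tm]]
    if (is.null(m)) stop("grid is missing layer: ", tm)
    mu <- mean(m, na.rm = TRUE)
    s <- sd(as.vector(m), na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero-variance layer: ", tm)
    out[[tm]] <- (m - mu) / s
  }
  out
}

#' Generate telemetry for every owl in a study
#'
#' @inheritParams gen_telemetry
#' @param owls data.frame from [gen_owls()].
#' @return data.frame of pooled relocations for all owls.
#' @export
gen_telemetry_all <- function(owls, grid, truth, n_locs = 120, radius = 1500,
                              breeding_frac = 0.5, p_night = 0.78,
                              year = 2008, seed = 1) {
  out <- do.call(rbind, lapply(seq_len(nrow(owls)), function(i) {
    gen_telemetry(owls[i, ], grid, truth, n_locs = n_locs, radius = radius,
                  breeding_frac = breeding_frac, p_night = p_night,
                  year = year, seed = seed + i)
  }))
  rownames(out) <- NULL
  out
}

#' Write / read telemetry as CSV
#' @param telemetry data.frame as produced by [gen_telemetry()].
#' @param path file path.
#' @return `path` invisibly (writer); the telemetry data.frame (reader).
#' @export
write_telemetry_csv <- function(telemetry, path) {
  out <- telemetry
  out$timestamp <- format(as.Date(out$timestamp), "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_telemetry_csv
#' @export
read_telemetry_csv <- function(path) {
  df <- read.csv(path)
  need <- c("owl_id", "species", "timestamp", "x", "y")
  stopifnot(all(need %in% names(df)))
  df$timestamp <- as.Date(df$timestamp)
  if (is.null(df$season)) df$season <- season_of(df$timestamp)
  df
}

#' Simulate choice-set designs directly in covariate space
#'
#' Model-space companion to the spatial generator, used for sampler
#' calibration and WAIC-ranking experiments: covariates of the 6 locations in
#' each set are iid standard normal, individual-by-season coefficient vectors
#' are drawn from the species-by-season hyper-distribution, and the used
#' location is the softmax choice among the 6.
#'
#' @param n_units_per_group number of individual-season units in each
#'   species x season group.
#' @param sets_per_unit choice sets per unit.
#' @param terms character vector of term names.
#' @param mu matrix `G x T` of hyper-means (G = 4 groups in the order
#'   spotted.breeding, spotted.nonbreeding, barred.breeding,
#'   barred.nonbreeding), or a single vector recycled to all groups.
#' @param sigma hyper-SD scalar, vector of length T, or `G x T` matrix.
#' @param nalt alternatives per set (1 used + nalt-1 available).
#' @param seed integer RNG seed.
#' @return a `dcm_design` (see [dcm_design()]) with attribute `truth`
#'   (list mu, sigma, beta, terms).
#' @export
gen_choice_design <- function(n_units_per_group = 4, sets_per_unit = 30,
                              terms = c("HEIGHT", "CANCOV", "SLOPE"),
                              mu = c(1, 0.5, -0.5), sigma = 0.3,
                              nalt = 6, seed = 1) {
  groups <- c("spotted.breeding", "spotted.nonbreeding",
              "barred.breeding", "barred.nonbreeding")
  G <- length(groups); T_ <- length(terms)
  if (!is.matrix(mu)) mu <- matrix(rep_len(mu, T_), G, T_, byrow = TRUE)
  if (!is.matrix(sigma)) {
    sigma <- matrix(rep_len(sigma, T_), G, T_, byrow = TRUE)
  }
  stopifnot(nrow(mu) == G, ncol(mu) == T_, all(sigma > 0))
  with_seed(seed, {
    U <- G * n_units_per_group
    unit_group <- rep(seq_len(G), each = n_units_per_group)
    beta <- matrix(rnorm(U * T_, mean = mu[unit_group, ],
                         sd = sigma[unit_group, ]), U, T_)
    nsets <- U * sets_per_unit
    X <- matrix(rnorm(nsets * nalt * T_), nsets * nalt, T_)
    colnames(X) <- terms
    set_unit <- rep(seq_len(U), each = sets_per_unit)
    # choose the used alternative per set and move it into slot 1
    for (s in seq_len(nsets)) {
      rows <- (s - 1L) * nalt + seq_len(nalt)
      u <- X[rows, , drop = FALSE] %*% beta[set_unit[s], ]
      p <- exp(u - max(u))
      pick <- sample.int(nalt, 1, prob = p)
      if (pick != 1L) {
        X[rows[c(1L, pick)], ] <- X[rows[c(pick, 1L)], ]
      }
    }
    sp_season <- do.call(rbind, strsplit(groups, ".", fixed = TRUE))
    unit_table <- data.frame(
      unit = seq_len(U),
      owl_id = paste0("u", seq_len(U)),
      species = sp_season[unit_group, 1],
      season = sp_season[unit_group, 2],
      group = unit_group
    )
    des <- new_dcm_design(X = X, nalt = nalt,
                          set_unit = set_unit, unit_table = unit_table,
                          groups = groups, terms = terms)
    attr(des, "truth") <- list(mu = mu, sigma = sigma, beta = beta,
                               terms = terms, groups = groups)
    des
  })
}
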