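# Distance from points to the nearest harvest rectangle (0 inside).
dist_to_rects <- function(x, y, rects) {
  if (is.null(rects) || nrow(rects) == 0) return(rep(Inf, length(x)))
  d <- rep(Inf, length(x))
  for (r in seq_len(nrow(rects))) {
    dx <- pmax(rects$xmin[r] - x, x - rects$xmax[r], 0)
    dy <- pmax(rects$ymin[r] - y, y - rects$ymax[r], 0)
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  d
}

#' Censor used locations near recent harvest
#'
#' A used location is censored when it lies within `buffer` meters of a
#' harvest unit cut after its telemetry date and no later than the lidar
#' acquisition date (forest structure at such points changed between
#' observation and measurement).
#'
#' @param used data.frame with x, y and `timestamp` (Date).
#' @param harvest data.frame from [gen_harvest()] (xmin..ymax, date); may be
#'   empty or NULL.
#' @param lidar_date Date of the lidar acquisition.
#' @param buffer censoring distance (m).
#' @return `used` with added logical column `censored`.
#' @export
censor_harvest <- function(used, harvest, lidar_date, buffer = 150) {
  used$censored <- FALSE
  if (is.null(harvest) || nrow(harvest) == 0) return(used)
  t_date <- as.Date(used$timestamp)
  for (r in seq_len(nrow(harvest))) {
    applies <- harvest$date[r] > t_date & harvest$date[r] <= as.Date(lidar_date)
    if (!any(applies)) next
    dx <- pmax(harvest$xmin[r] - used$x, used$x - harvest$xmax[r], 0)
    dy <- pmax(harvest$ymin[r] - used$y, used$y - harvest$ymax[r], 0)
    used$censored <- used$censored |
      (applies & sqrt(dx^2 + dy^2) <= buffer)
  }
  used
}

# Censored-area test for available points: inside the buffer of any harvest
# unit cut between the used location's telemetry date and the lidar date.
in_censored_area <- function(x, y, t_date, harvest, lidar_date, buffer = 150) {
  if (is.null(harvest) || nrow(harvest) == 0) return(rep(FALSE, length(x)))
  act <- harvest[harvest$date > as.Date(t_date) &
                 harvest$date <= as.Date(lidar_date), , drop = FALSE]
  if (nrow(act) == 0) return(rep(FALSE, length(x)))
  dist_to_rects(x, y, act) <= buffer
}

#' Sample the available alternatives of one choice set
#'
#' Rejection-samples `k` points uniformly over the buffered seasonal home
#' range, outside censored areas, with every point of the choice set (the
#' used location and each accepted available point) at least `minsep` apart.
#'
#' @param x0,y0 the used location.
#' @param hr the owl's seasonal [home_range()].
#' @param harvest harvest table (may be NULL).
#' @param t_date telemetry date of the used location (for censor dating).
#' @param lidar_date lidar acquisition date.
#' @param k number of available points.
#' @param minsep minimum pairwise separation (m).
#' @param censor_buffer censored-area half-width (m).
#' @param max_reject consecutive-rejection cap before the set is declared
#'   unconstructible.
#' @return `k x 2` matrix of points, or `NULL` if unconstructible.
#' @export
sample_available <- function(x0, y0, hr, harvest = NULL,
                             t_date = NULL, lidar_date = NULL,
                             k = 5, minsep = 300, censor_buffer = 150,
                             max_reject = 1e4) {
  cells <- which(hr$buffered)
  if (!length(cells)) return(NULL)
  gx <- hr$ud$x; gy <- hr$ud$y
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  nxg <- length(gx)
  accx <- x0; accy <- y0
  rejected <- 0L
  batch <- max(4L * k, 32L)
  while (length(accx) < k + 1L && rejected < max_reject) {
    pick <- sample(cells, batch, replace = TRUE)
    cx <- gx[((pick - 1L) %% nxg) + 1L] + (runif(batch) - 0.5) * dx
    cy <- gy[((pick - 1L) %/% nxg) + 1L] + (runif(batch) - 0.5) * dy
    if (!is.null(harvest) && nrow(harvest) > 0 && !is.null(t_date)) {
      cens <- in_censored_area(cx, cy, t_date, harvest, lidar_date,
                               censor_buffer)
    } else {
      cens <- rep(FALSE, batch)
    }
    for (j in seq_len(batch)) {
      if (length(accx) >= k + 1L) break
      if (cens[j]) { rejected <- rejected + 1L; next }
      if (all((accx - cx[j])^2 + (accy - cy[j])^2 >= minsep^2)) {
        accx <- c(accx, cx[j]); accy <- c(accy, cy[j])
        rejected <- 0L
      } else {
        rejected <- rejected + 1L
      }
    }
  }
  if (length(accx) < k + 1L) return(NULL)
  cbind(x = accx[-1L], y = accy[-1L])
}

#' Build use-availability choice sets
#'
#' For every retained used location of every owl with a qualifying seasonal
#' home range: censor by recent harvest, pair the used location with `k`
#' available points sampled under the spacing/containment/censoring
#' constraints, and attach covariates extracted as 150 m means from the
#' metric grid.  Used locations outside the buffered range, unconstructible
#' sets, and sets with any missing covariate are dropped (counted in the
#' `dropped` attribute).
#'
#' @param telemetry relocation table (owl_id, species, season, timestamp,
#'   x, y, optionally sex / pair_id).
#' @param ranges named list from [build_home_ranges()].
#' @param grid covariate [cov_grid()].
#' @param harvest harvest table or NULL.
#' @param lidar_date lidar acquisition date.
#' @param layers covariate layers to attach (default: all).
#' @param k available points per set.
#' @param minsep minimum pairwise separation (m).
#' @param radius covariate extraction radius (m).
#' @param night_only keep only nocturnal relocations (default FALSE: all
#'   relocations enter, as in the source analysis).
#' @param seed integer RNG seed for the availability sampler.
#' @return long-format data.frame, 6 rows per set: set_id, alt (0 = used,
#'   1..k = available), owl_id, species, sex, season, x, y, and one column
#'   per covariate layer.  Attribute `dropped` tabulates losses.
#' @export
build_choice_sets <- function(telemetry, ranges, grid, harvest = NULL,
                              lidar_date = NULL, layers = names(grid$layers),
                              k = 5, minsep = 300, radius = 150,
                              night_only = FALSE, seed = 1) {
  if (night_only && "is_night" %in% names(telemetry)) {
    telemetry <- telemetry[telemetry$is_night, ]
  }
  dropped <- c(no_range = 0L, censored = 0L, outside_range = 0L,
               unconstructible = 0L, missing_covariate = 0L)
  rows <- list()
  with_seed(seed, {
    set_id <- 0L
    for (key in names(ranges)) {
      hr <- ranges[[key]]
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      id <- parts[1]; se <- parts[2]
      tel <- telemetry[telemetry$owl_id == id & telemetry$season == se, ]
      if (!nrow(tel)) next
      tel <- censor_harvest(tel, harvest, lidar_date)
      dropped["censored"] <- dropped["censored"] + sum(tel$censored)
      tel <- tel[!tel$censored, ]
      if (!nrow(tel)) next
      inside <- point_in_range(hr, tel$x, tel$y, buffered = TRUE)
      dropped["outside_range"] <- dropped["outside_range"] + sum(!inside)
      tel <- tel[inside, ]
      for (i in seq_len(nrow(tel))) {
        av <- sample_available(tel$x[i], tel$y[i], hr, harvest,
                               t_date = tel$timestamp[i],
                               lidar_date = lidar_date,
                               k = k, minsep = minsep)
        if (is.null(av)) {
          dropped["unconstructible"] <- dropped["unconstructible"] + 1L
          next
        }
        set_id <- set_id + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          set_id = set_id, alt = 0:k,
          owl_id = id, species = tel$species[i],
          sex = if ("sex" %in% names(tel)) tel$sex[i] else NA_character_,
          season = se,
          timestamp = tel$timestamp[i],
          x = c(tel$x[i], av[, 1]), y = c(tel$y[i], av[, 2])
        )
      }
    }
  })
  no_range_ids <- setdiff(
    unique(paste0(telemetry$owl_id, ".", telemetry$season)), names(ranges))
  if (length(no_range_ids)) {
    n_lost <- sum(paste0(telemetry$owl_id, ".", telemetry$season)
                  %in% no_range_ids)
    dropped["no_range"] <- n_lost
    warning(length(no_range_ids),
            " owl-season(s) without a qualifying home range skipped")
  }
  if (!length(rows)) {
    out <- data.frame()
    attr(out, "dropped") <- dropped
    return(out)
  }
  out <- do.call(rbind, rows)
  cov <- extract_mean(grid, out$x, out$y, radius = radius, layers = layers)
  keep_set <- !(out$set_id %in% unique(out$set_id[!complete.cases(cov)]))
  dropped["missing_covariate"] <- (nrow(out) - sum(keep_set)) %/% (k + 1L)
  out <- cbind(out[keep_set, ], cov[keep_set, , drop = FALSE])
  out$set_id <- match(out$set_id, unique(out$set_id))  # renumber densely
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Standardize covariates and form model terms
#'
#' Main-effect covariates are centered and scaled over *all* locations (used
#' and available, both species and seasons pooled), so one standard
#' deviation has a single meaning across every reported coefficient.
#' Quadratic (`TPI2`) and interaction terms (`A:B`) are formed from the
#' standardized parents and not re-standardized.
#'
#' @param choice_sets long-format table from [build_choice_sets()].
#' @param terms model terms; main effects must match covariate columns,
#'   interactions written `"A:B"`, quadratics `"<name>2"` (e.g. `"TPI2"`).
#' @return list of class `std_design`: `data` (choice_sets plus standardized
#'   term columns prefixed `std_`), `terms`, `means`, `sds`.
#' @export
standardize_design <- function(choice_sets, terms) {
  mains <- unique(unlist(lapply(terms, function(tm) {
    if (grepl(":", tm, fixed = TRUE)) {
      strsplit(tm, ":", fixed = TRUE)[[1]]
    } else {
      sub("2$", "", tm)
    }
  })))
  means <- numeric(0); sds <- numeric(0)
  std <- list()
  for (v in mains) {
    col <- choice_sets[[v]]
    if (is.null(col)) stop("covariate column missing: ", v)
    if (length(unique(col)) < 2) stop("zero-variance covariate: ", v)
    mu <- mean(col); s <- sd(col)
    if (s == 0) stop("zero-variance covariate: ", v)
    means[v] <- mu; sds[v] <- s
    std[[v]] <- (col - mu) / s
  }
  out <- choice_sets
  for (tm in terms) {
    val <- if (grepl(":", tm, fixed = TRUE)) {
      p <- strsplit(tm, ":", fixed = TRUE)[[1]]
      std[[p[1]]] * std[[p[2]]]
    } else if (grepl("2$", tm) && !tm %in% mains) {
      std[[sub("2$", "", tm)]]^2
    } else {
      std[[tm]]
    }
    out[[paste0("std_", tm)]] <- val
  }
  structure(list(data = out, terms = terms, means = means, sds = sds),
            class = "std_design")
}

#' Independent constraint audit of emitted choice sets
#'
#' Re-verifies every emitted set from the raw coordinates, independently of
#' the builder's bookkeeping: exactly `k` available per used location (1:k
#' location ratio), all pairwise separations >= `minsep`, all points inside
#' the owl's buffered seasonal range, and no point inside a censored harvest
#' area for the set's telemetry date.
#'
#' @param choice_sets long-format table from [build_choice_sets()].
#' @param ranges named list from [build_home_ranges()].
#' @param harvest harvest table or NULL.
#' @param lidar_date lidar acquisition date.
#' @param k,minsep,censor_buffer audited constraint constants.
#' @return data.frame, one row per set, with logical columns `ratio_ok`,
#'   `spacing_ok`, `containment_ok`, `censor_ok`, `all_ok`.
#' @export
audit_choice_sets <- function(choice_sets, ranges, harvest = NULL,
                              lidar_date = NULL, k = 5, minsep = 300,
                              censor_buffer = 150) {
  sets <- split(choice_sets, choice_sets$set_id)
  res <- lapply(sets, function(s) {
    ratio_ok <- nrow(s) == k + 1L && sum(s$alt == 0) == 1L &&
      all(sort(s$alt) == 0:k)
    dmat <- as.matrix(dist(cbind(s$x, s$y)))
    spacing_ok <- min(dmat[upper.tri(dmat)]) >= minsep
    hr <- ranges[[paste0(s$owl_id[1], ".", s$season[1])]]
    containment_ok <- !is.null(hr) &&
      all(point_in_range(hr, s$x, s$y, buffered = TRUE))
    censor_ok <- if (is.null(harvest) || nrow(harvest) == 0) TRUE else {
      !any(in_censored_area(s$x, s$y, s$timestamp[1], harvest, lidar_date,
                            censor_buffer))
    }
    data.frame(set_id = s$set_id[1], ratio_ok = ratio_ok,
               spacing_ok = spacing_ok, containment_ok = containment_ok,
               censor_ok = censor_ok,
               all_ok = ratio_ok && spacing_ok && containment_ok && censor_ok)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write choice sets as long-format CSV
#' @param choice_sets table from [build_choice_sets()] (optionally after
#'   [standardize_design()], pass `std$data`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_choice_sets_csv <- function(choice_sets, path) {
  write.csv(choice_sets, path, row.names = FALSE)
  invisible(path)
}
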