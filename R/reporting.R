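#' Posterior coefficient summaries
#'
#' Per species-season group and term: posterior mean of the hyper-mean
#' `mu`, equal-tailed 95% credible interval, the sign-support statistic `f`
#' (fraction of the posterior sharing the sign of the mean; `f >= 0.9`
#' denotes a strongly supported effect), and the per-SD selection ratio
#' `exp(mean)`.
#'
#' @param fit a `dcm_fit`.
#' @return data.frame: species, season, term, mean, lo, hi, f,
#'   selection_ratio, supported.
#' @export
summarize_coefficients <- function(fit) {
  design <- fit$design
  G <- length(design$groups); T_ <- length(design$terms)
  nd <- fit$draws * fit$chains
  rows <- list()
  for (g in seq_len(G)) {
    sp_se <- strsplit(design$groups[g], ".", fixed = TRUE)[[1]]
    for (t in seq_len(T_)) {
      d <- as.vector(fit$mu[, , g, t])
      m <- mean(d)
      q <- unname(quantile(d, c(0.025, 0.975)))
      f <- if (m == 0) 0.5 else mean(sign(d) == sign(m))
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp_se[1], season = sp_se[2], term = design$terms[t],
        mean = m, lo = q[1], hi = q[2], f = f,
        selection_ratio = exp(m), supported = f >= 0.9)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap of two posterior samples
#'
#' Histogram overlap coefficient: both samples are binned on a shared
#' Freedman-Diaconis grid spanning the pooled range and the overlap is
#' `sum_bins min(p_a, p_b) * binwidth * 100` (identical distributions give
#' ~100, disjoint ones 0).
#'
#' @param draws_a,draws_b numeric samples (>= 500 draws each recommended).
#' @return overlap percentage in `[0, 100]`.
#' @export
posterior_overlap <- function(draws_a, draws_b) {
  a <- as.vector(draws_a); b <- as.vector(draws_b)
  if (sd(a) == 0 && sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 100 else 0)
  }
  pooled <- c(a, b)
  bw <- 2 * IQR(pooled) / length(pooled)^(1 / 3)
  if (bw <= 0) bw <- diff(range(pooled)) / 100
  breaks <- seq(min(pooled) - bw, max(pooled) + bw, by = bw)
  pa <- graphics::hist(a, breaks = breaks, plot = FALSE)$density
  pb <- graphics::hist(b, breaks = breaks, plot = FALSE)$density
  100 * sum(pmin(pa, pb)) * bw
}

#' Seasonal posterior overlap for every term of a fit
#'
#' @param fit a `dcm_fit` with both seasons present.
#' @return data.frame: species, term, overlap (%).
#' @export
seasonal_overlap <- function(fit) {
  design <- fit$design
  sp_se <- do.call(rbind, strsplit(design$groups, ".", fixed = TRUE))
  rows <- list()
  for (sp in unique(sp_se[, 1])) {
    gb <- which(sp_se[, 1] == sp & sp_se[, 2] == "breeding")
    gn <- which(sp_se[, 1] == sp & sp_se[, 2] == "nonbreeding")
    if (!length(gb) || !length(gn)) next
    for (t in seq_along(design$terms)) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, term = design$terms[t],
        overlap = posterior_overlap(fit$mu[, , gb, t], fit$mu[, , gn, t]))
    }
  }
  do.call(rbind, rows)
}

#' Relative-probability response curve for one covariate
#'
#' The relative probability of selection `P(x)` is computed for a
#' hypothetical choice set of the focal location plus `nalt - 1`
#' alternatives held at covariate means:
#' `P(x) = exp(u(x)) / (exp(u(x)) + (nalt-1) * exp(u_ref))`, with the focal
#' covariate swept across its observed 5th-95th percentile range (on the
#' standardized scale) and all other covariates at their means (standardized
#' 0).  Quadratic terms of the focal covariate track it; interaction terms
#' vanish because the partner covariate sits at its mean.  At the all-means
#' point `P = 1/nalt` by construction.
#'
#' @param fit a `dcm_fit`.
#' @param term focal main-effect term (must be in the model).
#' @param group species-season group label (e.g. `"spotted.breeding"`).
#' @param observed optional numeric vector of observed standardized values
#'   of the focal covariate (defaults to the design column).
#' @param percentiles range of the sweep.
#' @param n_points curve resolution.
#' @return data.frame of class `response_curve`: x (standardized focal
#'   value), P.
#' @export
response_curve <- function(fit, term, group = fit$design$groups[1],
                           observed = NULL, percentiles = c(5, 95),
                           n_points = 50) {
  design <- fit$design
  if (!term %in% design$terms) stop("term not in the fitted model: ", term)
  g <- match(group, design$groups)
  stopifnot(!is.na(g))
  mu_hat <- vapply(seq_along(design$terms), function(t) {
    mean(fit$mu[, , g, t])
  }, numeric(1))
  names(mu_hat) <- design$terms
  if (is.null(observed)) observed <- design$X[, term]
  qq <- quantile(observed, percentiles / 100)
  xs <- seq(qq[1], qq[2], length.out = n_points)
  quad <- paste0(term, "2")
  u <- mu_hat[term] * xs +
    if (quad %in% design$terms) mu_hat[quad] * xs^2 else 0
  P <- exp(u) / (exp(u) + (design$nalt - 1))
  structure(data.frame(term = term, group = group, x = xs, P = P),
            class = c("response_curve", "data.frame"))
}

#' Rank covariates by relative importance
#'
#' Terms are ordered by the absolute change in relative selection
#' probability across their observed 5th-95th percentile range,
#' `|P(q95) - P(q5)|`, all other covariates at their means.
#'
#' @param fit a `dcm_fit`.
#' @param group species-season group label.
#' @param terms main-effect terms to rank (default: all non-derived terms).
#' @return data.frame: term, delta_P, rank (1 = most influential).
#' @export
relative_importance <- function(fit, group = fit$design$groups[1],
                                terms = NULL) {
  design <- fit$design
  if (is.null(terms)) {
    terms <- design$terms[!grepl(":", design$terms) &
                          !design$terms %in% paste0(design$terms, "2")]
    terms <- setdiff(terms, paste0(sub("2$", "", terms[grepl("2$", terms)]), "2"))
  }
  dp <- vapply(terms, function(tm) {
    rc <- response_curve(fit, tm, group = group, n_points = 2)
    abs(rc$P[nrow(rc)] - rc$P[1])
  }, numeric(1))
  out <- data.frame(term = terms, delta_P = dp)
  out <- out[order(-out$delta_P), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Welch two-sample comparisons of used vs available conditions
#'
#' For each metric: each species' used locations against the pooled
#' available sample, and the two species against each other, using Welch's
#' unequal-variance t-test (Welch-Satterthwaite df).
#'
#' @param choice_sets long-format table from [build_choice_sets()].
#' @param metrics covariate columns to test (default: all numeric covariate
#'   columns present).
#' @return data.frame: metric, comparison, t, df, p, mean_1, mean_2.
#' @export
used_vs_available_tests <- function(choice_sets, metrics = NULL) {
  if (is.null(metrics)) {
    skip <- c("set_id", "alt", "x", "y")
    metrics <- names(choice_sets)[vapply(choice_sets, is.numeric, logical(1))]
    metrics <- setdiff(metrics, skip)
    metrics <- metrics[!grepl("^std_", metrics)]
  }
  used <- choice_sets[choice_sets$alt == 0, ]
  avail <- choice_sets[choice_sets$alt != 0, ]
  species <- sort(unique(choice_sets$species))
  rows <- list()
  add <- function(metric, comparison, a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return()
    if (sd(a) == 0 && sd(b) == 0) {
      rows[[length(rows) + 1L]] <<- data.frame(
        metric = metric, comparison = comparison, t = NA_real_,
        df = NA_real_, p = NA_real_, mean_1 = mean(a), mean_2 = mean(b))
      return()
    }
    tt <- t.test(a, b)
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, comparison = comparison,
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, mean_1 = mean(a), mean_2 = mean(b))
  }
  for (m in metrics) {
    for (sp in species) {
      add(m, paste0(sp, "_vs_available"),
          used[[m]][used$species == sp], avail[[m]])
    }
    if (length(species) == 2) {
      add(m, paste(species, collapse = "_vs_"),
          used[[m]][used$species == species[1]],
          used[[m]][used$species == species[2]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
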