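#' Fit the hierarchical discrete-choice model by MCMC
#'
#' Adaptive random-walk Metropolis-within-Gibbs sampler for the conditional
#' multinomial-logit model with individual-by-season coefficient vectors
#' drawn from species-by-season normal distributions:
#' `beta_u[t] ~ Normal(mu_g[t], sigma_g[t])`, `mu_g[t] ~ Normal(0, 100)`
#' (the vague `N(0, 0.01)`-precision prior of the source analysis), and
#' `sigma_g[t] ~ half-Normal(2)`.  Three chains are run from dispersed
#' initial values; if any hyper-parameter's split-chain R-hat exceeds 1.1
#' the warmup is doubled and the fit repeated (up to `max_extensions`
#' times).  After warmup, `draws` draws per chain are retained.
#'
#' @param design a `dcm_design`.
#' @param chains number of chains.
#' @param warmup adaptation iterations discarded per chain.
#' @param draws retained draws per chain.
#' @param seed integer seed; chain `c` uses `seed + c`.
#' @param mu_prior_var prior variance of the hyper-means.
#' @param sigma_prior_scale half-Normal scale of the coefficient SDs.
#' @param rhat_max convergence certification threshold.
#' @param max_extensions warmup doublings allowed before giving up.
#' @return object of class `dcm_fit`: arrays `mu` and `sigma`
#'   (draws x chains x groups x terms), `beta` (draws x chains x units x
#'   terms), `rhat` table for all hyper-parameters, `certified` flag, and
#'   the design.
#' @export
fit_hierarchical <- function(design, chains = 3, warmup = 1500, draws = 2000,
                             seed = 1, mu_prior_var = 100,
                             sigma_prior_scale = 2, rhat_max = 1.1,
                             max_extensions = 2) {
  stopifnot(inherits(design, "dcm_design"), length(design$terms) >= 1)
  ut <- design$unit_table
  stopifnot(all(table(ut$species) >= 2))
  U <- nrow(ut); G <- length(design$groups); T_ <- length(design$terms)
  # sampler expects sets grouped contiguously by unit
  ord <- order(design$set_unit)
  rows <- rep((ord - 1L) * design$nalt, each = design$nalt) +
    seq_len(design$nalt)
  X <- design$X[rows, , drop = FALSE]
  unit_nsets <- as.integer(tabulate(design$set_unit, nbins = U))
  stopifnot(all(unit_nsets > 0))

  run_all <- function(wu) {
    out <- vector("list", chains)
    for (ch in seq_len(chains)) {
      out[[ch]] <- with_seed(seed + ch, {
        beta0 <- matrix(rnorm(U * T_, 0, 1), U, T_)
        mu0 <- matrix(rnorm(G * T_, 0, 1), G, T_)
        sigma0 <- matrix(runif(G * T_, 0.5, 1.5), G, T_)
        cpp_run_chain(X, unit_nsets, ut$group - 1L, design$nalt, G,
                      beta0, mu0, sigma0, wu, draws,
                      mu_prior_var, sigma_prior_scale)
      })
    }
    out
  }

  wu <- warmup
  for (attempt in seq_len(max_extensions + 1L)) {
    res <- run_all(wu)
    # assemble draws x chains x G x T arrays
    mu_a <- array(NA_real_, c(draws, chains, G, T_))
    sg_a <- array(NA_real_, c(draws, chains, G, T_))
    bt_a <- array(NA_real_, c(draws, chains, U, T_))
    for (ch in seq_len(chains)) {
      mu_a[, ch, , ] <- aperm(res[[ch]]$mu, c(3, 1, 2))
      sg_a[, ch, , ] <- aperm(res[[ch]]$sigma, c(3, 1, 2))
      bt_a[, ch, , ] <- aperm(res[[ch]]$beta, c(3, 1, 2))
    }
    rh <- hyper_rhat(mu_a, sg_a, design)
    if (max(rh$rhat) <= rhat_max || attempt > max_extensions) break
    wu <- wu * 2L
  }
  structure(list(
    mu = mu_a, sigma = sg_a, beta = bt_a, rhat = rh,
    certified = max(rh$rhat) <= rhat_max,
    warmup_used = wu, draws = draws, chains = chains, seed = seed,
    design = design
  ), class = "dcm_fit")
}

hyper_rhat <- function(mu_a, sg_a, design) {
  G <- length(design$groups); T_ <- length(design$terms)
  out <- do.call(rbind, lapply(seq_len(G), function(g) {
    do.call(rbind, lapply(seq_len(T_), function(t) {
      data.frame(
        param = c(sprintf("mu[%s,%s]", design$groups[g], design$terms[t]),
                  sprintf("sigma[%s,%s]", design$groups[g], design$terms[t])),
        group = design$groups[g], term = design$terms[t],
        rhat = c(rhat(mu_a[, , g, t]), rhat(sg_a[, , g, t]))
      )
    }))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("<dcm_fit> %d terms, %d units, %d chains x %d draws (warmup %d)\n",
              length(x$design$terms), nrow(x$design$unit_table), x$chains,
              x$draws, x$warmup_used))
  cat(sprintf("max split R-hat (hyper-parameters): %.3f [%s]\n",
              max(x$rhat$rhat),
              if (x$certified) "certified" else "NOT certified"))
  invisible(x)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the classic between/within variance-ratio
#' diagnostic computed over the resulting `2 * chains` sequences; values at
#' or below 1.1 are taken as adequate convergence.
#'
#' @param draws matrix of posterior draws, iterations x chains.
#' @return scalar R-hat.
#' @export
rhat <- function(draws) {
  stopifnot(is.matrix(draws), ncol(draws) >= 2)
  n <- nrow(draws) %/% 2L
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(ch) {
    cbind(draws[seq_len(n), ch], draws[n + seq_len(n), ch])
  }))
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Pointwise log predictive density: draws x nsets matrix of
# log p(used_s | beta draw), using individual-level coefficients.
pointwise_loglik <- function(fit, design = fit$design) {
  nd <- fit$draws * fit$chains
  U <- nrow(design$unit_table)
  T_ <- length(design$terms)
  ll <- matrix(NA_real_, nd, design$nsets)
  for (u in seq_len(U)) {
    sets_u <- which(design$set_unit == u)
    if (!length(sets_u)) next
    rows <- rep((sets_u - 1L) * design$nalt, each = design$nalt) +
      seq_len(design$nalt)
    Xu <- design$X[rows, , drop = FALSE]
    bu <- matrix(fit$beta[, , u, ], nd, T_)
    util <- Xu %*% t(bu)                      # (nalt*ns) x nd
    dim(util) <- c(design$nalt, length(sets_u), nd)
    mx <- apply(util, c(2, 3), max)
    num <- matrix(util[1, , ], length(sets_u), nd) - mx
    den <- log(apply(exp(sweep(util, c(2, 3), mx)), c(2, 3), sum))
    ll[, sets_u] <- t(matrix(num - den, length(sets_u), nd))
  }
  ll
}

#' WAIC of a fitted model
#'
#' `lppd = sum_s log mean_draws p(used_s | draw)`,
#' `p_waic = sum_s var_draws log p(used_s | draw)`,
#' `waic = -2 (lppd - p_waic)`; log-mean-exp is computed in log space.
#'
#' @param fit a `dcm_fit`, or a draws x sets matrix of pointwise
#'   log-likelihoods.
#' @param design design to evaluate on (default: the fitted design).
#' @return list with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(fit, design = NULL) {
  ll <- if (is.matrix(fit)) fit else {
    pointwise_loglik(fit, design %||% fit$design)
  }
  stopifnot(nrow(ll) >= 100 || is.matrix(fit))
  nd <- nrow(ll)
  mx <- apply(ll, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(ll, 2, mx)))))
  p_waic <- sum(apply(ll, 2, var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Fit and rank a candidate model set by WAIC
#'
#' Fits every candidate structure to the same design and reports WAIC,
#' effective-parameter and delta-WAIC columns, sorted by WAIC.  The null
#' model (no covariates: selection uniform over the `nalt` alternatives) has
#' the closed-form `lppd = nsets * log(1/nalt)` and `p_waic = 0`.
#'
#' @param design a `dcm_design` containing every term used by the candidates.
#' @param models data.frame like [candidate_models()] (columns `model`,
#'   `terms`; optional `k_printed`), or a named list of term vectors.
#' @param ... passed to [fit_hierarchical()] (chains, warmup, draws, seed...).
#' @return data.frame: model, K, lppd, p_waic, waic, delta_waic, certified,
#'   ordered by waic.
#' @export
rank_models <- function(design, models = candidate_models(), ...) {
  if (!is.data.frame(models)) {
    models <- data.frame(model = names(models), terms = I(unname(models)))
  }
  rows <- lapply(seq_len(nrow(models)), function(i) {
    terms <- models$terms[[i]]
    K <- if ("k_printed" %in% names(models)) models$k_printed[i]
         else length(terms)
    if (length(terms) == 0) {
      lppd <- design$nsets * log(1 / design$nalt)
      return(data.frame(model = models$model[i], K = K, lppd = lppd,
                        p_waic = 0, waic = -2 * lppd, certified = TRUE))
    }
    fit <- fit_hierarchical(subset_design(design, terms = terms), ...)
    w <- waic(fit)
    data.frame(model = models$model[i], K = K, lppd = w$lppd,
               p_waic = w$p_waic, waic = w$waic, certified = fit$certified)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$waic), ]
  out$delta_waic <- out$waic - out$waic[1]
  rownames(out) <- NULL
  out
}

# Score choice sets given an nsets x nalt matrix of predicted selection
# probabilities (used alternative in column 1): a set scores 1 if the used
# alternative has the strictly highest probability, with ties awarded
# fractional credit 1/(number tied at the maximum).
score_sets <- function(probs, tol = 1e-12) {
  mx <- apply(probs, 1, max)
  at_max <- abs(probs - mx) <= tol
  credit <- ifelse(at_max[, 1], 1 / rowSums(at_max), 0)
  100 * mean(credit)
}

#' k-fold cross-validated predictive score
#'
#' Choice sets are split into `folds` random subsets; for each fold the
#' model is refit on the remainder and each held-out set counted as
#' correctly assigned iff its used location attains the highest
#' posterior-mean selection probability among the `nalt` alternatives (ties
#' give fractional credit).  The score is the mean percentage over folds.
#' A unit absent from a training fold is predicted from its species-season
#' hyper-mean draws.  With `terms = character(0)` (the null model) all
#' probabilities are equal, every set earns `1/nalt` credit, and the score
#' is exactly `100/nalt` (~17% for 6 alternatives).
#'
#' @param design a `dcm_design`.
#' @param terms model terms (default: all in the design); `character(0)`
#'   scores the null model without fitting.
#' @param folds number of folds.
#' @param seed seed for the fold split and the fits.
#' @param by_group also report scores split by species-season group.
#' @param ... passed to [fit_hierarchical()].
#' @return list: `score` (%), `fold_scores`, and (if `by_group`)
#'   `group_scores`.
#' @export
cv_predictive_score <- function(design, terms = design$terms, folds = 10,
                                seed = 1, by_group = FALSE, ...) {
  if (length(terms) == 0) {
    probs <- matrix(1 / design$nalt, design$nsets, design$nalt)
    sc <- score_sets(probs)
    fold_scores <- rep(sc, folds)
    out <- list(score = sc, fold_scores = fold_scores)
    if (by_group) {
      g <- design$unit_table$group[design$set_unit]
      out$group_scores <- tapply(rep(sc, design$nsets), g, mean)
    }
    return(out)
  }
  design <- subset_design(design, terms = terms)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), design$nsets)))
  T_ <- length(terms)
  set_credit <- numeric(design$nsets)
  for (f in seq_len(folds)) {
    train_sets <- which(fold_id != f)
    test_sets <- which(fold_id == f)
    if (!length(test_sets)) next
    tr <- subset_design(design, sets = train_sets)
    # units can drop out of the training fold: refit on those present
    present <- sort(unique(tr$set_unit))
    tr$unit_table <- tr$unit_table[present, , drop = FALSE]
    tr$set_unit <- match(tr$set_unit, present)
    tr$unit_table$unit <- seq_len(nrow(tr$unit_table))
    fit <- fit_hierarchical(tr, seed = seed + f, ...)
    nd <- fit$draws * fit$chains
    for (s in test_sets) {
      u <- design$set_unit[s]
      u_tr <- match(u, present)
      bdraws <- if (!is.na(u_tr)) {
        matrix(fit$beta[, , u_tr, ], nd, T_)
      } else {
        g <- design$unit_table$group[u]
        matrix(fit$mu[, , g, ], nd, T_)
      }
      rows <- (s - 1L) * design$nalt + seq_len(design$nalt)
      util <- design$X[rows, , drop = FALSE] %*% t(bdraws)  # nalt x nd
      util <- sweep(util, 2, apply(util, 2, max))
      e <- exp(util)
      p <- rowMeans(sweep(e, 2, colSums(e), "/"))
      mx <- max(p)
      at_max <- abs(p - mx) <= 1e-12
      set_credit[s] <- if (at_max[1]) 1 / sum(at_max) else 0
    }
  }
  fold_scores <- vapply(seq_len(folds), function(f) {
    100 * mean(set_credit[fold_id == f])
  }, numeric(1))
  out <- list(score = mean(fold_scores), fold_scores = fold_scores)
  if (by_group) {
    g <- design$unit_table$group[design$set_unit]
    out$group_scores <- tapply(100 * set_credit, design$groups[g], mean)
  }
  out
}

#' Choose linear vs quadratic form for a covariate by cross-validation
#'
#' Compares the 10-fold predictive score of the model with the covariate
#' entered linearly against the model with its quadratic term added; equal
#' scores prefer the linear (parsimonious) form.
#'
#' @param design a `dcm_design` whose terms include `<covariate>` and
#'   `<covariate>2`.
#' @param covariate focal covariate name (e.g. `"TPI"` or `"SRI"`).
#' @param base_terms other terms kept in both variants (default: none).
#' @param folds,seed,... passed to [cv_predictive_score()].
#' @return list: `form` (`"linear"` or `"quadratic"`), `scores`.
#' @export
select_functional_form <- function(design, covariate, base_terms = character(0),
                                   folds = 10, seed = 1, ...) {
  lin <- cv_predictive_score(design, c(base_terms, covariate),
                             folds = folds, seed = seed, ...)
  quad <- cv_predictive_score(design,
                              c(base_terms, covariate, paste0(covariate, "2")),
                              folds = folds, seed = seed, ...)
  scores <- c(linear = lin$score, quadratic = quad$score)
  list(form = if (quad$score > lin$score) "quadratic" else "linear",
       scores = scores)
}

#' Rank TPI neighborhood windows by univariate WAIC
#'
#' Fits a univariate model at each TPI window size and returns the windows
#' ranked by WAIC (in the source analysis the 2,000 m window ranked first
#' and entered all abiotic models).
#'
#' @param design a `dcm_design` with terms `TPI200`, `TPI500`, `TPI1000`,
#'   `TPI2000` (or as given by `windows`).
#' @param windows window term names.
#' @param ... passed to [fit_hierarchical()].
#' @return data.frame: window, waic, delta_waic, ordered by waic.
#' @export
tpi_window_select <- function(design,
                              windows = c("TPI200", "TPI500", "TPI1000",
                                          "TPI2000"), ...) {
  rows <- lapply(windows, function(w) {
    fit <- fit_hierarchical(subset_design(design, terms = w), ...)
    data.frame(window = w, waic = waic(fit)$waic)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$waic), ]
  out$delta_waic <- out$waic - out$waic[1]
  rownames(out) <- NULL
  out
}
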