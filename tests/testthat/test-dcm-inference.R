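test_that("choice log-likelihood matches brute-force softmax arithmetic", {
  des <- gen_choice_design(n_units_per_group = 1, sets_per_unit = 5,
                           terms = c("A", "B"), mu = c(0.5, -1), seed = 51)
  # zero coefficients: every set contributes log(1/6)
  expect_equal(choice_loglik(c(0, 0), des), des$nsets * log(1 / 6),
               tolerance = 1e-12)
  # hand/brute-force softmax on the same design
  beta <- c(0.7, -0.3)
  expect_equal(choice_loglik(beta, des),
               oracle_choice_loglik(beta, des$X, 6), tolerance = 1e-12)
  # translation invariance: adding a constant to all 6 utilities of a set
  X2 <- cbind(des$X, intercept = 1)
  expect_equal(choice_loglik(c(beta, 137), X2, nalt = 6),
               choice_loglik(beta, des$X, nalt = 6), tolerance = 1e-9)
  # tiny printed-out case
  Xt <- matrix(c(1, 0.5, 0, -1, 2, 0.3, -0.2, 0.1, 0, 0, 1, 1), 6, 2)
  b <- c(0.4, -0.8)
  u <- Xt %*% b
  expect_equal(choice_loglik(b, Xt, nalt = 6),
               log(exp(u[1]) / sum(exp(u))), tolerance = 1e-12)
  des_bad <- des
  des_bad$X[1, 1] <- NA
  expect_error(choice_loglik(beta, des_bad), "non-finite")
  # softmax probabilities sum to one within every set
  p <- strixsel:::choice_probs(beta, des$X, 6)
  expect_equal(rowSums(p), rep(1, des$nsets), tolerance = 1e-12)
})

test_that("the hierarchical sampler recovers known hyper-means", {
  des <- gen_choice_design(n_units_per_group = 5, sets_per_unit = 75,
                           terms = "HEIGHT", mu = 1, sigma = 0.3, seed = 52)
  expect_equal(des$nsets, 1500)
  fit <- fit_hierarchical(des, chains = 3, warmup = 1000, draws = 2000,
                          seed = 53)
  expect_true(fit$certified)
  expect_lte(max(fit$rhat$rhat), 1.1)
  s <- summarize_coefficients(fit)
  for (g in seq_len(4)) {
    expect_lt(abs(s$mean[g] - 1), 0.25)
    expect_true(s$lo[g] < 1 && 1 < s$hi[g])
  }
  # bit-reproducible under seed
  fit2 <- fit_hierarchical(des, chains = 3, warmup = 1000, draws = 2000,
                           seed = 53)
  expect_identical(fit$mu, fit2$mu)
  expect_true(all(fit$sigma > 0))
})

test_that("uninformative data leave the hyper-means near the prior center", {
  des <- gen_choice_design(n_units_per_group = 3, sets_per_unit = 30,
                           terms = "HEIGHT", mu = 2, seed = 54)
  des$X[, 1] <- rep(rnorm(des$nsets), each = 6)  # constant within sets
  fit <- fit_hierarchical(des, warmup = 1000, draws = 3000, seed = 55)
  s <- summarize_coefficients(fit)
  expect_true(all(abs(s$mean) < 0.5))
})

test_that("split-chain R-hat behaves like a variance-ratio diagnostic", {
  set.seed(56)
  good <- matrix(rnorm(6000), 2000, 3)
  expect_lte(rhat(good), 1.01)
  bad <- cbind(rnorm(1000, 0, 1), rnorm(1000, 10, 1), rnorm(1000, 0, 1))
  expect_gt(rhat(bad), 1.5)
  # hard lower bound of the split formula: sqrt((n-1)/n) with half-chains
  # of n draws (between-chain variance is nonnegative)
  for (i in 1:20) {
    m <- matrix(rnorm(600, sample(0:3, 1)), 100, 6)
    expect_gte(rhat(m), sqrt(49 / 50))
  }
  expect_error(rhat(matrix(1:10, 10, 1)))
})

test_that("WAIC matches hand arithmetic and its invariances", {
  # toy 3-set, 4-draw pointwise log-likelihood table
  ll <- matrix(log(c(0.3, 0.2, 0.25, 0.35,
                     0.1, 0.15, 0.12, 0.2,
                     0.5, 0.45, 0.55, 0.4)), 4, 3)
  w <- waic(ll)
  o <- oracle_waic(ll)
  expect_equal(w$waic, o$waic, tolerance = 1e-10)
  expect_equal(w$lppd, o$lppd, tolerance = 1e-10)
  expect_equal(w$p_waic, o$p_waic, tolerance = 1e-10)
  expect_gte(w$p_waic, 0)
  expect_equal(w$waic, -2 * (w$lppd - w$p_waic), tolerance = 1e-12)

  # point-mass posterior: p_waic = 0, waic = -2 sum log p
  ll_pm <- matrix(rep(log(c(0.2, 0.4, 0.1)), each = 4), 4, 3)
  w_pm <- waic(ll_pm)
  expect_equal(w_pm$p_waic, 0, tolerance = 1e-12)
  expect_equal(w_pm$waic, -2 * sum(log(c(0.2, 0.4, 0.1))), tolerance = 1e-10)

  # duplicating the data doubles all three components
  w2 <- waic(cbind(ll, ll))
  expect_equal(w2$lppd, 2 * w$lppd, tolerance = 1e-10)
  expect_equal(w2$p_waic, 2 * w$p_waic, tolerance = 1e-10)
  expect_equal(w2$waic, 2 * w$waic, tolerance = 1e-10)
})

test_that("model ranking puts the generating structure first", {
  des <- gen_choice_design(n_units_per_group = 3, sets_per_unit = 50,
                           terms = c("HEIGHT", "CANCOV"), mu = c(1.2, -0.8),
                           sigma = 0.3, seed = 57)
  tab <- rank_models(des, models = list(
    generating = c("HEIGHT", "CANCOV"),
    height_only = "HEIGHT",
    null = character(0)
  ), warmup = 600, draws = 800, seed = 58)
  expect_equal(tab$model[1], "generating")
  expect_equal(tab$delta_waic[1], 0)
  null_row <- tab[tab$model == "null", ]
  expect_equal(null_row$lppd, des$nsets * log(1 / 6), tolerance = 1e-12)
  expect_equal(null_row$p_waic, 0)
  expect_true(all(diff(tab$waic) >= 0))
})

test_that("the candidate set mirrors the published model structures", {
  cm <- candidate_models()
  expect_equal(nrow(cm), 12)
  expect_equal(cm$model[1], "full_height")
  expect_equal(cm$k_printed,
               c(11L, 10L, 8L, 8L, 6L, 7L, 6L, 3L, 3L, 5L, 2L, 0L))
  expect_length(cm$terms[[12]], 0)
  # HEIGHT and RUMPLE never co-occur (rank-collinearity screen)
  for (tm in cm$terms) {
    mains <- unique(unlist(strsplit(tm, ":")))
    expect_false(all(c("HEIGHT", "RUMPLE") %in% mains))
  }
  # quadratic/interaction terms always bring their parents
  for (tm in cm$terms) {
    if ("TPI2" %in% tm) expect_true("TPI" %in% tm)
    for (x in tm[grepl(":", tm)]) {
      expect_true(all(strsplit(x, ":")[[1]] %in% tm))
    }
  }
})

test_that("the Spearman screen flags rank-correlated covariate pairs", {
  set.seed(59)
  n <- 1e4
  u <- runif(n)
  tab <- data.frame(a = u, b = runif(n), mono = exp(3 * u))
  out <- spearman_screen(tab, threshold = 0.7)
  expect_true(any(out$var1 == "a" & out$var2 == "mono"))
  expect_equal(out$rho[out$var1 == "a" & out$var2 == "mono"], 1,
               tolerance = 1e-12)
  expect_false(any(out$var1 == "a" & out$var2 == "b"))
  expect_lt(abs(cor(tab$a, tab$b, method = "spearman")), 0.05)
  dup <- data.frame(x = u, x_copy = u)
  expect_equal(nrow(spearman_screen(dup)), 1)
})

test_that("cross-validated prediction scores behave across regimes", {
  # all-zero coefficients: exact fractional-tie credit of 100/6
  des0 <- gen_choice_design(n_units_per_group = 2, sets_per_unit = 20,
                            seed = 60)
  sc0 <- cv_predictive_score(des0, terms = character(0))
  expect_equal(sc0$score, 100 / 6, tolerance = 1e-12)
  expect_equal(round(sc0$score), 17)

  # strongly separated data predicts far above the random baseline
  des <- gen_choice_design(n_units_per_group = 3, sets_per_unit = 40,
                           terms = "HEIGHT", mu = 3, sigma = 0.3, seed = 61)
  sc <- cv_predictive_score(des, folds = 10, seed = 62, warmup = 400,
                            draws = 400)
  expect_gt(sc$score, 60)
  expect_true(all(sc$fold_scores >= 0 & sc$fold_scores <= 100))
})

test_that("functional-form selection identifies quadratic and linear truth", {
  make_form_design <- function(beta_lin, beta_quad, seed,
                               n_units = 8, sets = 40) {
    set.seed(seed)
    nalt <- 6
    nsets <- n_units * sets
    x <- rnorm(nsets * nalt)
    X <- cbind(TPI = x, TPI2 = x^2)
    for (s in seq_len(nsets)) {
      rows <- (s - 1) * nalt + seq_len(nalt)
      u <- X[rows, ] %*% c(beta_lin, beta_quad)
      pick <- sample.int(nalt, 1, prob = exp(u - max(u)))
      if (pick != 1) X[rows[c(1, pick)], ] <- X[rows[c(pick, 1)], ]
    }
    ut <- data.frame(unit = seq_len(n_units), owl_id = paste0("u", 1:n_units),
                     species = rep(c("spotted", "barred"), each = n_units / 2),
                     season = "breeding")
    ut$group <- match(paste0(ut$species, ".breeding"),
                      c("spotted.breeding", "barred.breeding"))
    strixsel:::new_dcm_design(X = X, nalt = nalt,
                              set_unit = rep(seq_len(n_units), each = sets),
                              unit_table = ut,
                              groups = c("spotted.breeding", "barred.breeding"),
                              terms = c("TPI", "TPI2"))
  }
  wins_quad <- 0; wins_lin <- 0
  for (r in 1:10) {
    dq <- make_form_design(beta_lin = 0.2, beta_quad = -1, seed = 70 + r)
    fq <- select_functional_form(dq, "TPI", folds = 5, seed = r,
                                 warmup = 300, draws = 300)
    if (fq$form == "quadratic") wins_quad <- wins_quad + 1
    dl <- make_form_design(beta_lin = 1.2, beta_quad = 0, seed = 90 + r)
    fl <- select_functional_form(dl, "TPI", folds = 5, seed = r,
                                 warmup = 300, draws = 300)
    if (fl$form == "linear") wins_lin <- wins_lin + 1
  }
  expect_gte(wins_quad, 8)
  expect_gte(wins_lin, 8)
})

test_that("TPI window ranking finds the generating scale", {
  hits <- 0
  for (r in 1:5) {
    des <- gen_choice_design(n_units_per_group = 2, sets_per_unit = 40,
                             terms = c("TPI200", "TPI500", "TPI1000", "TPI2000"),
                             mu = c(0, 0, 0, -1.2), sigma = 0.2,
                             seed = 110 + r)
    tab <- tpi_window_select(des, warmup = 400, draws = 400, seed = r)
    if (tab$window[1] == "TPI2000") hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("the sampler posterior agrees with an independent JAGS fit", {
  des <- gen_choice_design(n_units_per_group = 3, sets_per_unit = 40,
                           terms = "HEIGHT", mu = 1, sigma = 0.3, seed = 120)
  fit <- fit_hierarchical(des, warmup = 1000, draws = 2000, seed = 121)
  s <- summarize_coefficients(fit)

  model_str <- "
  model {
    for (s in 1:S) {
      y[s] ~ dcat(p[s, 1:6])
      for (j in 1:6) {
        eu[s, j] <- exp(inprod(X[s, j, ], beta[unit[s], ]))
        p[s, j] <- eu[s, j] / sum(eu[s, ])
      }
    }
    for (u in 1:U) {
      for (t in 1:T) {
        beta[u, t] ~ dnorm(mu[group[u], t], pow(sigma[group[u], t], -2))
      }
    }
    for (g in 1:G) {
      for (t in 1:T) {
        mu[g, t] ~ dnorm(0, 0.01)
        sigma[g, t] ~ dnorm(0, pow(2, -2)) T(0,)
      }
    }
  }"
  Xarr <- array(NA_real_, c(des$nsets, 6, 1))
  for (k in seq_len(des$nsets)) {
    Xarr[k, , 1] <- des$X[(k - 1) * 6 + 1:6, 1]
  }
  jd <- list(S = des$nsets, U = nrow(des$unit_table), T = 1, G = 4,
             y = rep(1L, des$nsets), X = Xarr, unit = des$set_unit,
             group = des$unit_table$group)
  jm <- rjags::jags.model(textConnection(model_str), data = jd,
                          n.chains = 2, n.adapt = 500, quiet = TRUE)
  samp <- rjags::coda.samples(jm, c("mu", "sigma"), n.iter = 3000)
  jpost <- colMeans(as.matrix(samp[[1]]))
  for (g in 1:4) {
    expect_equal(s$mean[s$species == strsplit(des$groups[g], ".", fixed = TRUE)[[1]][1] &
                        s$season == strsplit(des$groups[g], ".", fixed = TRUE)[[1]][2]],
                 unname(jpost[sprintf("mu[%d,1]", g)]), tolerance = 0.2)
  }
})
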