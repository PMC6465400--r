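# Internal constructor shared by standardize-based and simulated designs.
new_dcm_design <- function(X, nalt, set_unit, unit_table, groups, terms,
                           meta = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(set_unit) * nalt,
            ncol(X) == length(terms))
  structure(list(
    X = X, nalt = as.integer(nalt), set_unit = as.integer(set_unit),
    unit_table = unit_table, groups = groups, terms = terms,
    nsets = length(set_unit), meta = meta
  ), class = "dcm_design")
}

#' @export
print.dcm_design <- function(x, ...) {
  cat(sprintf("<dcm_design> %d sets x %d alternatives, %d units, %d groups\n",
              x$nsets, x$nalt, nrow(x$unit_table), length(x$groups)))
  cat("terms:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a fitting-ready design from standardized choice sets
#'
#' Converts a [standardize_design()] result into the matrix layout the
#' sampler consumes: one row per location, `nalt` consecutive rows per set
#' with the used location first; one sampling unit per individual owl and
#' season, grouped into species-by-season hyper-groups.
#'
#' @param std a `std_design` from [standardize_design()].
#' @param terms model terms (default: all terms in `std`); every term must
#'   have a `std_<term>` column.
#' @return object of class `dcm_design`.
#' @export
dcm_design <- function(std, terms = std$terms) {
  stopifnot(inherits(std, "std_design"))
  d <- std$data
  ord <- order(d$owl_id, d$season, d$set_id, d$alt)
  d <- d[ord, ]
  stopifnot(all(d$alt[!duplicated(d$set_id)] == 0))
  nalt <- sum(d$set_id == d$set_id[1])
  ukey <- paste0(d$owl_id, ".", d$season)
  first <- !duplicated(d$set_id)
  set_ukey <- ukey[first]
  units <- unique(set_ukey)
  unit_table <- data.frame(
    unit = seq_along(units),
    owl_id = sub("\\.[^.]+$", "", units),
    species = d$species[first][match(units, set_ukey)],
    season = sub("^.*\\.", "", units)
  )
  groups <- sort(unique(paste0(unit_table$species, ".", unit_table$season)))
  unit_table$group <- match(paste0(unit_table$species, ".", unit_table$season),
                            groups)
  X <- sapply(terms, function(tm) {
    col <- d[[paste0("std_", tm)]]
    if (is.null(col)) stop("standardized column missing for term: ", tm)
    col
  })
  new_dcm_design(X = X, nalt = nalt, set_unit = match(set_ukey, units),
                 unit_table = unit_table, groups = groups, terms = terms,
                 meta = d[first, intersect(c("set_id", "owl_id", "species",
                                             "season"), names(d))])
}

# Restrict a design to a subset of terms (columns) and/or sets.
subset_design <- function(design, terms = design$terms, sets = NULL) {
  keep_t <- match(terms, design$terms)
  stopifnot(!anyNA(keep_t))
  if (is.null(sets)) {
    X <- design$X[, keep_t, drop = FALSE]
    su <- design$set_unit
  } else {
    rows <- rep((sets - 1L) * design$nalt, each = design$nalt) +
      seq_len(design$nalt)
    X <- design$X[rows, keep_t, drop = FALSE]
    su <- design$set_unit[sets]
  }
  new_dcm_design(X = X, nalt = design$nalt, set_unit = su,
                 unit_table = design$unit_table, groups = design$groups,
                 terms = terms, meta = design$meta)
}

#' Conditional multinomial-logit log-likelihood of one coefficient vector
#'
#' For each choice set, the probability that the used location is selected
#' is the softmax of the location utilities `x'beta` over the `nalt`
#' alternatives, computed with max-subtraction for numerical stability.
#'
#' @param beta numeric coefficient vector (length = number of terms).
#' @param design a `dcm_design` (all sets are assumed to share `beta`), or
#'   any matrix with `nalt` consecutive rows per set, used row first.
#' @param nalt alternatives per set when `design` is a bare matrix.
#' @return total log-likelihood (scalar).
#' @export
choice_loglik <- function(beta, design, nalt = NULL) {
  if (inherits(design, "dcm_design")) {
    X <- design$X
    nalt <- design$nalt
  } else {
    X <- design
    stopifnot(!is.null(nalt))
  }
  if (!all(is.finite(X))) stop("non-finite covariates in design")
  u <- as.vector(X %*% beta)
  um <- matrix(u, nrow = nalt)
  m <- apply(um, 2, max)
  sum(um[1, ] - m - log(colSums(exp(sweep(um, 2, m)))))
}

# Per-set softmax probabilities (nsets x nalt) for one beta.
choice_probs <- function(beta, X, nalt) {
  u <- matrix(as.vector(X %*% beta), nrow = nalt)
  u <- sweep(u, 2, apply(u, 2, max))
  e <- exp(u)
  t(sweep(e, 2, colSums(e), "/"))
}

#' Screen covariate pairs by Spearman rank correlation
#'
#' Covariate pairs with `|rho_s| >= threshold` are flagged and must not
#' co-occur in a candidate model (in the standard candidate set this
#' excludes HEIGHT and RUMPLE from sharing a model).
#'
#' @param covariates data.frame or matrix of covariate columns (locations in
#'   rows).
#' @param threshold absolute rank-correlation cutoff.
#' @return data.frame of excluded pairs: `var1`, `var2`, `rho`.
#' @export
spearman_screen <- function(covariates, threshold = 0.7) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) >= 3)
  nms <- names(covariates)
  rho <- cor(covariates, method = "spearman")
  out <- data.frame(var1 = character(0), var2 = character(0),
                    rho = numeric(0))
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    if (abs(rho[i, j]) >= threshold) {
      out <- rbind(out, data.frame(var1 = nms[i], var2 = nms[j],
                                   rho = rho[i, j]))
    }
  }
  out
}

#' The candidate model set
#'
#' The twelve a priori model structures ranked in the analysis, from the
#' full canopy-structure models (with either HEIGHT or RUMPLE as the canopy
#' axis, which are rank-collinear and never co-occur) down to the null model
#' of random selection.  `k_printed` is the variable count as reported;
#' for `rumple_vertical` it exceeds the term-list length by one.
#'
#' @return data.frame with columns `model`, `explanation`, `k_printed`, and
#'   a list-column `terms`.
#' @export
candidate_models <- function() {
  tm <- list(
    full_height = c("HEIGHT", "CANCOV", "HEIGHT:CANCOV", "D4to8", "S2to4",
                    "HEIGHT:D4to8", "SRI", "TPI", "TPI2", "SLOPE", "STREAM"),
    full_rumple = c("RUMPLE", "CANCOV", "RUMPLE:CANCOV", "D4to8", "S2to4",
                    "SRI", "TPI", "TPI2", "SLOPE", "STREAM"),
    height_abiotic = c("HEIGHT", "CANCOV", "HEIGHT:CANCOV", "SRI", "TPI",
                       "TPI2", "SLOPE", "STREAM"),
    rumple_abiotic = c("RUMPLE", "CANCOV", "RUMPLE:CANCOV", "SRI", "TPI",
                       "TPI2", "SLOPE", "STREAM"),
    height_vertical = c("HEIGHT", "CANCOV", "HEIGHT:CANCOV", "D4to8",
                        "S2to4", "HEIGHT:D4to8"),
    vertical_abiotic = c("D4to8", "S2to4", "SRI", "TPI", "TPI2", "SLOPE",
                         "STREAM"),
    rumple_vertical = c("RUMPLE", "CANCOV", "RUMPLE:CANCOV", "D4to8",
                        "S2to4"),
    height_canopy = c("HEIGHT", "CANCOV", "HEIGHT:CANCOV"),
    rumple_canopy = c("RUMPLE", "CANCOV", "RUMPLE:CANCOV"),
    abiotic = c("SRI", "TPI", "TPI2", "SLOPE", "STREAM"),
    vertical = c("D4to8", "S2to4"),
    null = character(0)
  )
  data.frame(
    model = names(tm),
    explanation = c(
      "full model with canopy structure HEIGHT",
      "full model with canopy structure RUMPLE",
      "canopy structure HEIGHT and abiotic",
      "canopy structure RUMPLE and abiotic",
      "canopy structure HEIGHT and vertical variation",
      "vertical variation and abiotic",
      "canopy structure RUMPLE and vertical variation",
      "canopy structure HEIGHT",
      "canopy structure RUMPLE",
      "abiotic features",
      "vertical variation",
      "selection is random"),
    k_printed = c(11L, 10L, 8L, 8L, 6L, 7L, 6L, 3L, 3L, 5L, 2L, 0L),
    terms = I(unname(tm))
  )
}
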