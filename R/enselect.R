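#' Elastic-net hyperparameter grids
#'
#' The default search space: 10 evenly spaced mixing ratios alpha on
#' \[0.2, 1\] and 200 penalty weights lambda = exp(tau) with tau evenly
#' spaced on \[-5, 5\], tuned by 10-fold cross-validation.
#'
#' @param alpha_grid Ascending vector of elastic-net mixing ratios.
#' @param lam_grid Ascending vector of penalty weights.
#' @param cv_folds Number of cross-validation folds.
#' @return An `en_hyperparams` list.
#' @export
en_hyperparams <- function(alpha_grid = seq(0.2, 1, length.out = 10),
                           lam_grid = exp(seq(-5, 5, length.out = 200)),
                           cv_folds = 10) {
  if (is.unsorted(alpha_grid) || is.unsorted(lam_grid))
    stopf("grids must be sorted ascending")
  if (any(alpha_grid <= 0 | alpha_grid > 1)) stopf("alpha must be in (0, 1]")
  if (any(lam_grid <= 0)) stopf("lambda must be > 0")
  structure(list(alpha_grid = alpha_grid, lam_grid = lam_grid,
                 cv_folds = as.integer(cv_folds)),
            class = "en_hyperparams")
}

# Fit glmnet at a single fixed (alpha, lambda). A short geometric path down
# to the target lambda keeps the coordinate-descent warm starts stable; the
# coefficient at exactly `lam` is extracted.
glmnet_at <- function(X, y, alpha, lam) {
  path <- sort(unique(lam * c(16, 8, 4, 2, 1)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = path,
                        standardize = FALSE, thresh = 1e-10)
  cf <- as.numeric(stats::coef(fit, s = lam, exact = FALSE))
  list(intercept = cf[1], beta = cf[-1])
}

#' Tune elastic-net hyperparameters by cross-validated MSE
#'
#' Exhaustive search over the alpha x lambda grid minimizing the mean
#' 10-fold cross-validation MSE with a seeded fold assignment shared across
#' alphas. Ties are broken toward larger lambda, then larger alpha (the
#' sparser model).
#'
#' @param X Numeric matrix (samples x features), already normalized.
#' @param y Response vector with no missing values.
#' @param grids An [en_hyperparams()].
#' @param seed Integer seed for the fold assignment.
#' @return A list with `alpha`, `lam`, `cv_mse` (the winning mean CV MSE)
#'   and the full `cv_table`.
#' @export
tune_hyperparams <- function(X, y, grids = en_hyperparams(), seed = 1L) {
  X <- as_fm_matrix(X)
  if (anyNA(y)) stopf("missing response values; drop them upstream")
  n <- length(y)
  if (n < grids$cv_folds) stopf("need at least cv_folds observations")
  foldid <- with_seed(seed, sample(rep_len(seq_len(grids$cv_folds), n)))
  lam_desc <- rev(grids$lam_grid)
  rows <- lapply(grids$alpha_grid, function(a) {
    cv <- glmnet::cv.glmnet(X, y, alpha = a, lambda = lam_desc,
                            foldid = foldid, standardize = FALSE,
                            type.measure = "mse")
    data.frame(alpha = a, lam = cv$lambda, cv_mse = cv$cvm)
  })
  tab <- do.call(rbind, rows)
  best <- tab[order(tab$cv_mse, -tab$lam, -tab$alpha), ][1, ]
  list(alpha = best$alpha, lam = best$lam, cv_mse = best$cv_mse,
       cv_table = tab)
}

# Predictive score from a bootstrap coefficient matrix: the fraction of
# replicates in which a feature's coefficient is nonzero (|beta| > tol).
ps_from_coefficients <- function(beta_bs, tol = 1e-8) {
  colMeans(abs(beta_bs) > tol)
}

#' Bootstrap predictive scores
#'
#' The pipeline's core statistic. Having fixed `(alpha, lam)` once on the
#' full panel, `B` bootstrap resamples of the cell lines are drawn with
#' replacement, the elastic net is refit on each, and the predictive score
#' of feature u is the fraction of replicates with a nonzero coefficient:
#' `PS_u = (1/B) sum_b I(beta_ub != 0)`. Replicates whose resampled
#' response is constant cannot be fit and are skipped (reducing the
#' effective B).
#'
#' @param X Numeric matrix (samples x features), already normalized.
#' @param y Response vector.
#' @param alpha,lam Tuned hyperparameters, fixed across replicates.
#' @param B Number of bootstrap replicates (default 200).
#' @param seed Integer seed for the resampling stream.
#' @return A `bootstrap_ps` list: `coefficients` (B_eff x p), `intercepts`,
#'   `ps` (named predictive-score vector), `B` (effective), `B_requested`,
#'   `seeds`.
#' @export
bootstrap_ps <- function(X, y, alpha, lam, B = 200, seed = 1L) {
  X <- as_fm_matrix(X)
  n <- length(y)
  seeds <- derive_seeds(seed, B)
  keep <- logical(B)
  betas <- matrix(0, B, ncol(X), dimnames = list(NULL, colnames(X)))
  b0 <- numeric(B)
  for (b in seq_len(B)) {
    idx <- with_seed(seeds[[b]], sample.int(n, n, replace = TRUE))
    yb <- y[idx]
    if (stats::var(yb) == 0) {
      noticef("bootstrap replicate %d has constant response; skipped", b)
      next
    }
    fit <- glmnet_at(X[idx, , drop = FALSE], yb, alpha, lam)
    betas[b, ] <- fit$beta
    b0[b] <- fit$intercept
    keep[b] <- TRUE
  }
  betas <- betas[keep, , drop = FALSE]
  structure(list(coefficients = betas, intercepts = b0[keep],
                 ps = ps_from_coefficients(betas),
                 B = sum(keep), B_requested = B,
                 seeds = unlist(seeds)),
            class = "bootstrap_ps")
}

#' Define lncRNA-drug predictive pairs
#'
#' Thresholds predictive scores at `cutoff` (inclusive: PS >= cutoff) and
#' annotates each retained pair with the sign of its mean nonzero bootstrap
#' coefficient and the univariate Spearman correlation of feature
#' expression with the response.
#'
#' @param bs A [bootstrap_ps()] result.
#' @param X,y The panel the scores were computed on.
#' @param agent_id Agent label for the output rows.
#' @param cutoff Predictive-score cutoff in (0, 1\]; default 0.25.
#' @return A data frame (feature, agent, ps, sign, spearman_rho); zero rows
#'   when nothing passes.
#' @export
define_pairs <- function(bs, X, y, agent_id = "agent", cutoff = 0.25) {
  if (cutoff <= 0 || cutoff > 1) stopf("cutoff must be in (0, 1]")
  X <- as_fm_matrix(X)
  keep <- which(bs$ps >= cutoff)
  if (!length(keep))
    return(data.frame(feature = character(), agent = character(),
                      ps = numeric(), sign = integer(),
                      spearman_rho = numeric()))
  sgn <- vapply(keep, function(j) {
    cf <- bs$coefficients[, j]
    nz <- cf[abs(cf) > 1e-8]
    if (!length(nz)) 0L else as.integer(sign(mean(nz)))
  }, integer(1))
  rho <- vapply(keep, function(j)
    stats::cor(X[, j], y, method = "spearman"), numeric(1))
  data.frame(feature = colnames(X)[keep], agent = agent_id,
             ps = unname(bs$ps[keep]), sign = sgn, spearman_rho = rho,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run pair selection for every agent of a panel
#'
#' Convenience driver: per agent, drops cell lines with missing response,
#' tunes `(alpha, lam)`, runs the bootstrap and thresholds pairs.
#'
#' @param X Normalized expression [feature_matrix()].
#' @param response ln-IC50 (or AUC) matrix, cell lines x agents.
#' @param grids An [en_hyperparams()].
#' @param B,cutoff,seed See [bootstrap_ps()] and [define_pairs()].
#' @return A list with `pairs` (row-bound pair table), `ps` (feature x
#'   agent predictive-score matrix) and per-agent `fits`.
#' @export
select_pairs <- function(X, response, grids = en_hyperparams(), B = 200,
                         cutoff = 0.25, seed = 1L) {
  Xm <- as_fm_matrix(X)
  agents <- colnames(response)
  seeds <- derive_seeds(seed, 2L * length(agents))
  ps_mat <- matrix(NA_real_, ncol(Xm), length(agents),
                   dimnames = list(colnames(Xm), agents))
  fits <- list()
  pair_list <- list()
  for (i in seq_along(agents)) {
    a <- agents[i]
    ok <- !is.na(response[, a])
    Xa <- Xm[ok, , drop = FALSE]
    ya <- response[ok, a]
    tuned <- tune_hyperparams(Xa, ya, grids, seed = seeds[[2 * i - 1]])
    bs <- bootstrap_ps(Xa, ya, tuned$alpha, tuned$lam, B = B,
                       seed = seeds[[2 * i]])
    ps_mat[, a] <- bs$ps
    fits[[a]] <- list(tuned = tuned, bootstrap = bs)
    pair_list[[a]] <- define_pairs(bs, Xa, ya, agent_id = a, cutoff = cutoff)
  }
  list(pairs = rbind_rows(pair_list),
       ps = ps_mat, fits = fits, cutoff = cutoff)
}

#' Specificity curve for the predictive-score cutoff
#'
#' For each candidate cutoff, pairs are split into predictive
#' (PS >= cutoff) and non-predictive, and the two-sample Kolmogorov-
#' Smirnov statistic between the absolute Spearman correlations of the two
#' groups — computed on an *independent* panel — measures how well the
#' cutoff separates real signal from background. The returned knee (largest
#' discrete second difference of the curve) is advisory; the pipeline
#' default stays at 0.25.
#'
#' @param ps Feature x agent predictive-score matrix.
#' @param X_ext Independent normalized expression matrix (same features).
#' @param response_ext Independent response matrix (same agents).
#' @param cutoffs Candidate cutoffs.
#' @param min_pairs Minimum group size on each side; cutoffs failing it are
#'   skipped.
#' @return A list with `curve` (data frame cutoff, ks, n_pred, n_nonpred)
#'   and `knee`.
#' @export
calibrate_cutoff <- function(ps, X_ext, response_ext,
                             cutoffs = seq(0.05, 0.95, by = 0.05),
                             min_pairs = 10) {
  X_ext <- as_fm_matrix(X_ext)
  agents <- intersect(colnames(ps), colnames(response_ext))
  feats <- intersect(rownames(ps), colnames(X_ext))
  if (!length(agents) || !length(feats)) stopf("no shared agents/features")
  rho <- vapply(agents, function(a) {
    ok <- !is.na(response_ext[, a])
    abs(suppressWarnings(stats::cor(X_ext[ok, feats, drop = FALSE],
                                    response_ext[ok, a],
                                    method = "spearman")))[, 1]
  }, numeric(length(feats)))
  psm <- ps[feats, agents, drop = FALSE]
  rows <- lapply(cutoffs, function(ct) {
    pred <- psm >= ct
    n1 <- sum(pred); n0 <- sum(!pred)
    if (n1 < min_pairs || n0 < min_pairs) return(NULL)
    ks <- suppressWarnings(stats::ks.test(rho[pred], rho[!pred]))$statistic
    data.frame(cutoff = ct, ks = unname(ks), n_pred = n1, n_nonpred = n0)
  })
  curve <- do.call(rbind, rows)
  knee <- NA_real_
  if (!is.null(curve) && nrow(curve) >= 3) {
    d2 <- diff(curve$ks, differences = 2)
    knee <- curve$cutoff[which.max(-d2) + 1L]
  }
  list(curve = curve, knee = knee)
}

#' Overlap of two pair tables against a shared universe
#'
#' Builds the 2x2 table (in both / A only / B only / neither) over the
#' universe of all feature x agent combinations and reports the overlap
#' count, the sample odds ratio (Haldane 0.5 correction when a margin is
#' zero) and the two-sided Fisher exact p.
#'
#' @param pairs_a,pairs_b Pair tables from [define_pairs()].
#' @param features Feature universe (character vector or count).
#' @param agents Shared agent universe (character vector or count).
#' @return A list: `n_both`, `pct_a_in_b`, `odds_ratio`, `p`, `table`,
#'   `corrected` flag.
#' @export
replication_overlap <- function(pairs_a, pairs_b, features, agents) {
  n_feat <- if (is.numeric(features)) features else length(features)
  n_agent <- if (is.numeric(agents)) agents else length(agents)
  universe <- n_feat * n_agent
  key <- function(p) paste(p$feature, p$agent)
  a <- unique(key(pairs_a)); b <- unique(key(pairs_b))
  n11 <- length(intersect(a, b))
  n10 <- length(a) - n11
  n01 <- length(b) - n11
  n00 <- universe - n11 - n10 - n01
  if (n00 < 0) stopf("universe smaller than observed pair counts")
  tab <- matrix(c(n11, n10, n01, n00), 2, 2, byrow = TRUE)
  corrected <- any(tab == 0)
  or_tab <- if (corrected) tab + 0.5 else tab
  or <- (or_tab[1, 1] * or_tab[2, 2]) / (or_tab[1, 2] * or_tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(n_both = n11,
       pct_a_in_b = if (length(a)) 100 * n11 / length(a) else NA_real_,
       odds_ratio = or, p = p, table = tab, corrected = corrected)
}
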