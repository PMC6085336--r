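#' Select the top-k features by predictive score
#'
#' Features ordered by descending predictive score; ties at the rank-k
#' boundary are broken by larger absolute mean bootstrap coefficient, then
#' by feature identifier.
#'
#' @param ps Named predictive-score vector.
#' @param coefficients Bootstrap coefficient matrix (replicates x features)
#'   used for tie-breaking; optional.
#' @param k Number of features to keep (default 20).
#' @return Character vector of feature identifiers, length <= k.
#' @export
select_top_features <- function(ps, coefficients = NULL, k = 20) {
  mean_abs <- if (is.null(coefficients)) rep(0, length(ps)) else
    colMeans(abs(coefficients))[names(ps)]
  ord <- order(-ps, -mean_abs, names(ps))
  names(ps)[ord][seq_len(min(k, length(ps)))]
}

#' Train a top-k elastic-net drug-response model (LENP)
#'
#' Restricts the panel to the top-k predictive features of one agent,
#' re-tunes `(alpha, lam)` on that reduced matrix and refits the elastic
#' net on all training rows. Column means/sds of the training data are
#' stored so new samples are scored on the same scale.
#'
#' @param X Normalized expression matrix (samples x features).
#' @param y Response vector (no missing values).
#' @param features Selected feature identifiers (see
#'   [select_top_features()]).
#' @param agent_id Agent label.
#' @param grids An [en_hyperparams()].
#' @param seed Integer seed for fold assignment.
#' @param scope `"pan"` or a cancer-type label for cancer-specific models.
#' @param response_metric `"ic50"` or `"auc"`, recorded for provenance.
#' @return An object of class `lenp_model`.
#' @export
train_lenp <- function(X, y, features, agent_id = "agent",
                       grids = en_hyperparams(), seed = 1L, scope = "pan",
                       response_metric = "ic50") {
  X <- as_fm_matrix(X)
  miss <- setdiff(features, colnames(X))
  if (length(miss)) stopf("features absent from X: %s",
                          paste(miss, collapse = ", "))
  Xk <- X[, features, drop = FALSE]
  center <- colMeans(Xk)
  scale_ <- apply(Xk, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- scale(Xk, center = center, scale = scale_)
  tuned <- tune_hyperparams(Xs, y, grids, seed = seed)
  fit <- glmnet_at(Xs, y, tuned$alpha, tuned$lam)
  structure(list(agent_id = agent_id, scope = scope,
                 response_metric = response_metric,
                 features = features,
                 coefficients = stats::setNames(fit$beta, features),
                 intercept = fit$intercept,
                 alpha = tuned$alpha, lam = tuned$lam,
                 center = center, scale = scale_),
            class = "lenp_model")
}

#' Build an LENP model from bootstrap selection results
#'
#' @param X,y Training panel.
#' @param bs A [bootstrap_ps()] result for the agent.
#' @param k Number of top features (default 20).
#' @param ... Passed to [train_lenp()].
#' @return An `lenp_model`, or `NULL` (with a notice) when fewer than two
#'   features have positive predictive score.
#' @export
build_lenp <- function(X, y, bs, k = 20, ...) {
  ps <- bs$ps
  if (sum(ps > 0) < 2) {
    noticef("fewer than 2 features with PS > 0; model untrainable")
    return(NULL)
  }
  feats <- select_top_features(ps, bs$coefficients, k = k)
  train_lenp(X, y, feats, ...)
}

#' @export
print.lenp_model <- function(x, ...) {
  cat(sprintf("lenp_model [%s, %s, %s]: %d features, alpha=%.3g lambda=%.3g\n",
              x$agent_id, x$scope, x$response_metric, length(x$features),
              x$alpha, x$lam))
  invisible(x)
}

#' Predict drug response with an LENP model
#'
#' Deterministic linear scoring; the new matrix is re-standardized with the
#' model's stored training means and sds. All model features must be
#' present — missing features are an error, never a silent zero.
#'
#' @param object An `lenp_model`.
#' @param newdata A [feature_matrix()] or plain matrix containing the model
#'   features.
#' @param ... Unused.
#' @return Named numeric vector of predicted response.
#' @export
predict.lenp_model <- function(object, newdata, ...) {
  X <- as_fm_matrix(newdata)
  miss <- setdiff(object$features, colnames(X))
  if (length(miss)) stopf("newdata is missing model features: %s",
                          paste(miss, collapse = ", "))
  Xs <- scale(X[, object$features, drop = FALSE],
              center = object$center, scale = object$scale)
  drop(Xs %*% object$coefficients) + object$intercept
}

#' Serialize / deserialize an LENP model
#'
#' Versioned JSON with full-precision floating point, so a round trip
#' reproduces predictions exactly.
#'
#' @param model An `lenp_model`.
#' @param path JSON file path.
#' @name lenp-io
NULL

#' @rdname lenp-io
#' @export
write_lenp <- function(model, path) {
  payload <- c(list(format = "lncgx.lenp", version = 1L), unclass(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname lenp-io
#' @export
read_lenp <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "lncgx.lenp")) stopf("not an LENP model file")
  m <- p[setdiff(names(p), c("format", "version"))]
  m$coefficients <- stats::setNames(as.numeric(m$coefficients), m$features)
  m$center <- stats::setNames(as.numeric(m$center), m$features)
  m$scale <- stats::setNames(as.numeric(m$scale), m$features)
  structure(m, class = "lenp_model")
}

#' Cross-validated performance of an LENP model specification
#'
#' 10 iterations of 10-fold cross-validation at fixed hyperparameters:
#' each iteration re-randomizes the fold assignment, refits the elastic
#' net on every training fold, pools the out-of-fold predictions, and
#' records Pearson's r and Kendall's tau between pooled predictions and
#' observations.
#'
#' @param X Normalized expression matrix restricted to the model features.
#' @param y Response vector.
#' @param alpha,lam Fixed hyperparameters.
#' @param iterations,folds CV layout (defaults 10 x 10-fold).
#' @param seed Integer seed.
#' @return A `cv_report` data frame (iteration, pearson_r, kendall_tau)
#'   with a `summary` attribute (means and sds).
#' @export
evaluate_cv <- function(X, y, alpha, lam, iterations = 10, folds = 10,
                        seed = 1L) {
  X <- as_fm_matrix(X)
  n <- length(y)
  if (n < folds) stopf("need at least 'folds' observations")
  seeds <- derive_seeds(seed, iterations)
  rows <- lapply(seq_len(iterations), function(it) {
    foldid <- with_seed(seeds[[it]], sample(rep_len(seq_len(folds), n)))
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- foldid != f
      fit <- glmnet_at(X[tr, , drop = FALSE], y[tr], alpha, lam)
      pred[!tr] <- drop(X[!tr, , drop = FALSE] %*% fit$beta) + fit$intercept
    }
    flag <- stats::sd(pred) == 0
    if (flag) noticef("iteration %d produced constant predictions", it)
    data.frame(iteration = it,
               pearson_r = if (flag) 0 else stats::cor(pred, y),
               kendall_tau = if (flag) 0 else
                 stats::cor(pred, y, method = "kendall"),
               constant = flag)
  })
  rep_ <- do.call(rbind, rows)
  attr(rep_, "summary") <- c(
    mean_r = mean(rep_$pearson_r), sd_r = stats::sd(rep_$pearson_r),
    mean_tau = mean(rep_$kendall_tau), sd_tau = stats::sd(rep_$kendall_tau))
  class(rep_) <- c("cv_report", "data.frame")
  rep_
}

#' Validate LENP models on an external panel
#'
#' Applies each model to an independent panel and reports Pearson r,
#' Spearman rho and the Spearman p-value of predicted vs observed
#' response; agents with p < 0.05 are flagged validated. Agents with fewer
#' than `min_shared` non-missing shared cell lines are skipped with a
#' notice.
#'
#' @param models Named list of `lenp_model`s (one per agent).
#' @param X_ext External normalized expression matrix.
#' @param response_ext External response matrix (cell lines x agents).
#' @param min_shared Minimum shared cell lines per agent (default 10).
#' @return Data frame (agent, n, pearson_r, spearman_rho, p, validated).
#' @export
validate_external <- function(models, X_ext, response_ext, min_shared = 10) {
  X_ext <- as_fm_matrix(X_ext)
  rows <- lapply(names(models), function(a) {
    if (!a %in% colnames(response_ext)) return(NULL)
    ok <- rownames(X_ext)[!is.na(response_ext[rownames(X_ext), a])]
    if (length(ok) < min_shared) {
      noticef("agent %s: only %d shared cell lines; skipped", a, length(ok))
      return(NULL)
    }
    pred <- stats::predict(models[[a]], X_ext[ok, , drop = FALSE])
    obs <- response_ext[ok, a]
    sp <- suppressWarnings(stats::cor.test(pred, obs, method = "spearman"))
    data.frame(agent = a, n = length(ok),
               pearson_r = stats::cor(pred, obs),
               spearman_rho = unname(sp$estimate), p = sp$p.value,
               validated = sp$p.value < 0.05,
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}
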