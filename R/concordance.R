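#' Bootstrap fold-changes of one cancer type against the rest
#'
#' Per feature: mean over the target type's samples minus the mean over a
#' background resampled from all other types (without replacement, size
#' equal to the target group).
#'
#' @param fm A [feature_matrix()] (log-scale or z-scale values).
#' @param labels Named cancer-type vector covering the samples of `fm`.
#' @param target_type Type to contrast.
#' @param seed Integer seed for the background draw.
#' @return Named per-feature fold-change vector.
#' @export
fold_changes <- function(fm, labels, target_type, seed = NULL) {
  X <- as_fm_matrix(fm)
  labels <- labels[rownames(X)]
  tgt <- rownames(X)[labels == target_type]
  if (!length(tgt)) stopf("target type '%s' not present", target_type)
  bg_pool <- rownames(X)[labels != target_type]
  if (length(bg_pool) < length(tgt))
    stopf("background pool smaller than the target group")
  bg <- with_seed(seed, sample(bg_pool, length(tgt)))
  colMeans(X[tgt, , drop = FALSE]) - colMeans(X[bg, , drop = FALSE])
}

retained_types <- function(labels, min_n) {
  tab <- table(labels)
  names(tab)[tab > min_n]
}

#' Tumor vs cell-line concordance matrix
#'
#' For every retained cancer type (more than `min_tumors` tumors and
#' `min_cells` cell lines), fold-change vectors are computed in both panels
#' and the pairwise Pearson correlation between tumor-type and
#' cell-line-type fold-changes is averaged over `n_iter` background
#' resamplings.
#'
#' @param tumor_fm,tumor_labels Tumor panel and its cancer-type labels.
#' @param cell_fm,cell_labels Cell-line panel and labels.
#' @param n_iter Resampling iterations (default 10).
#' @param seed Integer seed.
#' @param min_tumors,min_cells Retention thresholds (defaults 15 and 20;
#'   types at or below are dropped with a notice).
#' @param feature_name Label stored on the result.
#' @return A `concordance_matrix`: tumor types x cell-line types, with
#'   attributes `feature_name` and `n_iterations`.
#' @export
concordance_matrix <- function(tumor_fm, tumor_labels, cell_fm, cell_labels,
                               n_iter = 10, seed = 1L, min_tumors = 15,
                               min_cells = 20, feature_name = "expression") {
  shared_feats <- intersect(colnames(as_fm_matrix(tumor_fm)),
                            colnames(as_fm_matrix(cell_fm)))
  if (length(shared_feats) < 2) stopf("fewer than 2 shared features")
  types <- intersect(retained_types(tumor_labels, min_tumors),
                     retained_types(cell_labels, min_cells))
  dropped <- setdiff(union(unique(tumor_labels), unique(cell_labels)), types)
  if (length(dropped))
    noticef("types below retention thresholds dropped: %s",
            paste(sort(dropped), collapse = ", "))
  if (length(types) < 2) stopf("fewer than 2 retained types")
  types <- sort(types)
  seeds <- derive_seeds(seed, n_iter)
  acc <- matrix(0, length(types), length(types),
                dimnames = list(types, types))
  for (it in seq_len(n_iter)) {
    it_seeds <- derive_seeds(seeds[[it]], 2L * length(types))
    t_fc <- vapply(seq_along(types), function(i)
      fold_changes(tumor_fm, tumor_labels, types[i],
                   seed = it_seeds[[2 * i - 1]])[shared_feats],
      numeric(length(shared_feats)))
    c_fc <- vapply(seq_along(types), function(i)
      fold_changes(cell_fm, cell_labels, types[i],
                   seed = it_seeds[[2 * i]])[shared_feats],
      numeric(length(shared_feats)))
    acc <- acc + stats::cor(t_fc, c_fc)
  }
  out <- acc / n_iter
  structure(out, feature_name = feature_name, n_iterations = n_iter,
            class = c("concordance_matrix", class(out)))
}

#' Integrate concordance matrices across genomic features
#'
#' Rank-sum integration: within each feature's matrix every cell is ranked
#' by descending correlation (rank 1 = most concordant) and ranks are
#' summed across features. The result is negated so that higher remains
#' more concordant; rank-sum ties are broken by the mean correlation
#' (added at epsilon scale 1e-4, far below the minimum rank-sum gap of
#' 0.5).
#'
#' @param matrices List of `concordance_matrix` objects over the same type
#'   set.
#' @return A `concordance_matrix` of integrated scores.
#' @export
integrate_features <- function(matrices) {
  if (!length(matrices)) stopf("no matrices supplied")
  dn <- dimnames(matrices[[1]])
  for (m in matrices)
    if (!identical(dimnames(m), dn)) stopf("type sets differ across matrices")
  ranks <- lapply(matrices, function(m) {
    r <- matrix(rank(-as.numeric(m), ties.method = "average"),
                nrow(m), ncol(m), dimnames = dn)
    r
  })
  rank_sum <- Reduce(`+`, ranks)
  mean_cor <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  out <- -rank_sum + 1e-4 * mean_cor
  structure(out, feature_name = "integrated",
            n_iterations = attr(matrices[[1]], "n_iterations"),
            class = c("concordance_matrix", "matrix", "array"))
}

#' Nearest-neighbor tissue-of-origin matching
#'
#' Each tumor type (row) queries cell-line types sorted by descending
#' concordance score; a match at k means its own type is among the top k
#' neighbors. Ties at the k boundary are broken lexicographically by type
#' name. The random expectation per k is estimated by permuting each row's
#' scores `n_perm` times.
#'
#' @param cm A `concordance_matrix` (square; rows = tumor types).
#' @param ks Neighborhood sizes (default 1..7, capped at the type count).
#' @param n_perm Permutations for the random expectation (default 1000).
#' @param seed Integer seed.
#' @param transpose If `TRUE`, cell-line types query tumor types instead.
#' @return A `matching_result` data frame (k, match_pct,
#'   random_expectation, perm_sd).
#' @export
nn_matching <- function(cm, ks = 1:7, n_perm = 1000, seed = 1L,
                        transpose = FALSE) {
  m <- unclass(cm)
  if (transpose) m <- t(m)
  if (nrow(m) != ncol(m)) stopf("matrix must be square over the type set")
  ks <- ks[ks <= ncol(m)]
  types <- colnames(m)
  neighbor_order <- function(scores)
    types[order(-scores, types)]
  match_pct <- function(mat) {
    hits <- vapply(rownames(mat), function(t) {
      nb <- neighbor_order(mat[t, ])
      match(t, nb)
    }, numeric(1))
    vapply(ks, function(k) 100 * mean(hits <= k), numeric(1))
  }
  obs <- match_pct(m)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pm <- t(apply(m, 1, sample))
      dimnames(pm) <- dimnames(m)
      match_pct(pm)
    }, numeric(length(ks)))
  })
  perm <- matrix(perm, nrow = length(ks))
  structure(data.frame(k = ks, match_pct = obs,
                       random_expectation = rowMeans(perm),
                       perm_sd = apply(perm, 1, stats::sd)),
            class = c("matching_result", "data.frame"))
}
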