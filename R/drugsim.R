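#' Dichotomize predictive scores into selection vectors
#'
#' @param ps Feature x agent predictive-score matrix.
#' @param cutoff Predictive-pair cutoff (inclusive; default 0.25).
#' @return Binary matrix of the same shape.
#' @export
selection_vectors <- function(ps, cutoff = 0.25) {
  (ps >= cutoff) * 1L
}

# One-sided (enrichment) Fisher exact p and Haldane-corrected sample OR
# for a 2x2 table given as counts.
fisher_enrichment <- function(n11, n10, n01, n00) {
  tab <- matrix(c(n11, n10, n01, n00), 2, 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  corrected <- any(tab == 0)
  ot <- if (corrected) tab + 0.5 else tab
  or <- (ot[1, 1] * ot[2, 2]) / (ot[1, 2] * ot[2, 1])
  list(p = p, or = or, corrected = corrected)
}

#' Drug-drug similarity by shared predictive features
#'
#' For every agent pair, a 2x2 table over the feature universe (selected by
#' both / only A / only B / neither) is tested with a one-sided
#' (enrichment) Fisher exact test; the similarity score is -log10 p,
#' capped at `cap` so downstream Euclidean distances stay finite. The
#' diagonal is set to the maximum finite off-diagonal value.
#'
#' @param selections Binary feature x agent matrix (see
#'   [selection_vectors()]).
#' @param cap Cap on -log10 p (default 300).
#' @return A list of class `drug_similarity` with `neglog10p` and
#'   `odds_ratio` agent x agent matrices.
#' @export
pairwise_fisher <- function(selections, cap = 300) {
  agents <- colnames(selections)
  n_a <- length(agents)
  p_mat <- matrix(0, n_a, n_a, dimnames = list(agents, agents))
  or_mat <- matrix(NA_real_, n_a, n_a, dimnames = list(agents, agents))
  for (i in seq_len(n_a)) {
    for (j in seq_len(n_a)) {
      if (j <= i) next
      a <- selections[, i] == 1
      b <- selections[, j] == 1
      ft <- fisher_enrichment(sum(a & b), sum(a & !b), sum(!a & b),
                              sum(!a & !b))
      s <- min(-log10(ft$p), cap)
      p_mat[i, j] <- p_mat[j, i] <- s
      or_mat[i, j] <- or_mat[j, i] <- ft$or
    }
  }
  diag_val <- max(p_mat[upper.tri(p_mat)], 0)
  diag(p_mat) <- diag_val
  diag(or_mat) <- Inf
  structure(list(neglog10p = p_mat, odds_ratio = or_mat),
            class = "drug_similarity")
}

#' Cluster agents by predictive-feature similarity
#'
#' Average-linkage hierarchical clustering on Euclidean distances between
#' the rows of the similarity matrix (-log10 Fisher p by default, odds
#' ratio behind the `score` switch). Agents are ordered by name before
#' clustering so the tree is invariant to input order.
#'
#' @param sim A `drug_similarity` from [pairwise_fisher()].
#' @param score `"neglog10p"` (default) or `"odds_ratio"`.
#' @param k Number of flat clusters to cut (optional).
#' @return A list with `hclust`, `newick` string and, if `k` given,
#'   `clusters`.
#' @export
cluster_agents <- function(sim, score = c("neglog10p", "odds_ratio"),
                           k = NULL) {
  score <- match.arg(score)
  m <- sim[[score]]
  if (nrow(m) < 2) stopf("need at least 2 agents to cluster")
  if (any(!is.finite(m))) {
    noticef("non-finite similarity values capped")
    fin <- max(m[is.finite(m)], 0)
    m[!is.finite(m)] <- fin
  }
  m <- m[order(rownames(m)), order(colnames(m))]
  hc <- stats::hclust(stats::dist(m), method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  out <- list(hclust = hc, newick = nwk)
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}

#' Lineage effect on drug response
#'
#' One-way ANOVA of response against cancer type, per agent: a small p
#' indicates that inter-type variance dominates intra-type variance, i.e.
#' response to the agent is lineage-driven. Lineages with a single cell
#' line are dropped with a notice.
#'
#' @param response Cell line x agent response matrix.
#' @param lineages Named cancer-type vector for the cell lines.
#' @return Data frame (agent, f, p, neglog10p, n_lineages).
#' @export
lineage_anova <- function(response, lineages) {
  rows <- lapply(colnames(response), function(a) {
    y <- response[, a]
    ok <- !is.na(y)
    g <- factor(lineages[rownames(response)][ok])
    y <- y[ok]
    sizes <- table(g)
    if (any(sizes < 2)) {
      noticef("agent %s: dropping %d singleton lineage(s)", a,
              sum(sizes < 2))
      keep <- g %in% names(sizes)[sizes >= 2]
      y <- y[keep]
      g <- droplevels(g[keep])
    }
    if (nlevels(g) < 2) stopf("agent %s: fewer than 2 usable lineages", a)
    av <- stats::anova(stats::lm(y ~ g))
    data.frame(agent = a, f = av$`F value`[1], p = av$`Pr(>F)`[1],
               neglog10p = -log10(av$`Pr(>F)`[1]), n_lineages = nlevels(g),
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}
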