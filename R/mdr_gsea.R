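#' Target-pathway vectors of predictive lncRNAs
#'
#' For each lncRNA appearing in at least one predictive pair, the multiset
#' of target-pathway labels of the agents it predicts (one element per
#' agent; two agents hitting the same pathway contribute two elements).
#'
#' @param pairs Pair table from [define_pairs()] / [select_pairs()].
#' @param agent_pathway Named character vector mapping agent -> target
#'   pathway; every agent in `pairs` must be mapped.
#' @return Named list of character vectors (pathway multisets).
#' @export
pathway_vectors <- function(pairs, agent_pathway) {
  unmapped <- setdiff(unique(pairs$agent), names(agent_pathway))
  if (length(unmapped))
    stopf("agents without a pathway mapping: %s",
          paste(unmapped, collapse = ", "))
  split(unname(agent_pathway[pairs$agent]), pairs$feature)
}

#' Shannon entropy of a pathway multiset
#'
#' Base-2 entropy of the label frequencies, `H = -sum p_k log2 p_k` with
#' `0 * log 0 = 0`. Zero for a single-pathway lncRNA, `log2(n)` for one
#' spread uniformly over n pathways.
#'
#' @param v Character vector (pathway labels, duplicates meaningful).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(v) {
  if (!length(v)) stopf("empty pathway vector")
  p <- table(v) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Flag multi-drug-resistance lncRNAs by entropy z-score
#'
#' Entropies are standardized over all predictive lncRNAs; those with
#' z > 1 (strictly) — more than one sd to the right of the mean — are
#' flagged as MDR-related. With zero entropy variance nothing is flagged.
#'
#' @param vectors Output of [pathway_vectors()], or a named numeric vector
#'   of precomputed entropies.
#' @return Data frame (feature, m, entropy, z, mdr) sorted by feature.
#' @export
flag_mdr <- function(vectors) {
  if (is.numeric(vectors)) {
    h <- vectors
    m <- rep(NA_integer_, length(h))
  } else {
    h <- vapply(vectors, shannon_entropy, numeric(1))
    m <- lengths(vectors)
  }
  if (length(h) < 3) stopf("need at least 3 predictive lncRNAs")
  sdv <- stats::sd(h)
  if (sdv == 0) {
    noticef("zero entropy variance; no lncRNA flagged")
    z <- rep(0, length(h))
  } else {
    z <- (h - mean(h)) / sdv
  }
  out <- data.frame(feature = names(h), m = m, entropy = unname(h),
                    z = unname(z), mdr = unname(z > 1),
                    stringsAsFactors = FALSE)
  out[order(out$feature), , drop = FALSE]
}

#' Co-expression profile of one lncRNA against protein-coding genes
#'
#' Pearson correlation of every protein-coding gene with the lncRNA,
#' sorted descending; ties are broken by gene identifier so the ranking is
#' deterministic. Constant genes get r = 0 and are flagged.
#'
#' @param lnc Named numeric vector (lncRNA expression across samples).
#' @param pcg_fm Protein-coding [feature_matrix()] over the same samples.
#' @return Data frame (gene, r, rank, constant), ordered by rank.
#' @export
correlation_profile <- function(lnc, pcg_fm) {
  P <- as_fm_matrix(pcg_fm)
  samples <- intersect(names(lnc), rownames(P))
  if (length(samples) < 3) stopf("fewer than 3 shared samples")
  r <- suppressWarnings(stats::cor(P[samples, , drop = FALSE],
                                   lnc[samples]))[, 1]
  const <- is.na(r)
  r[const] <- 0
  ord <- order(-r, names(r))
  data.frame(gene = names(r)[ord], r = unname(r[ord]),
             rank = seq_along(r), constant = unname(const[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Weighted (exponent 1) running-sum enrichment score from the sorted
# positions of set members in a ranked list. `w` = |score| in rank order,
# `pos` = sorted member positions. Returns the signed maximum deviation.
gsea_es <- function(w, pos, n_genes) {
  k <- length(pos)
  wh <- w[pos]
  denom <- sum(wh)
  if (denom == 0) return(0)
  cum_hit <- cumsum(wh) / denom
  miss_after <- (pos - seq_len(k)) / (n_genes - k)
  after <- cum_hit - miss_after
  before <- c(0, cum_hit[-k]) - (pos - 1 - (seq_len(k) - 1)) / (n_genes - k)
  cand <- c(after, before)
  unname(cand[which.max(abs(cand))])
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted running-sum GSEA on a ranked, scored gene list. The
#' enrichment score is the maximum deviation of the running sum (hit
#' increments proportional to |score|, weight exponent 1); the null is
#' gene-label permutation (equivalent to random member positions), the
#' normalized enrichment score is ES divided by the mean |null ES| of
#' matching sign, the nominal p uses the (b + 1) / (n + 1) estimator, and
#' FDR q follows the standard pooled positive/negative NES procedure.
#' Sets with fewer than `min_size` members in the ranked universe are
#' skipped.
#'
#' @param scores Named numeric vector (gene -> ranking score), any order.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param n_perm Permutations (default 1000).
#' @param seed Integer seed.
#' @param min_size Minimum surviving set size (default 5).
#' @param fdr_cutoff Significance threshold recorded in the `significant`
#'   column (default 0.25).
#' @return Data frame (set, size, es, nes, p, fdr, significant).
#' @export
gsea_preranked <- function(scores, sets, n_perm = 1000, seed = 1L,
                           min_size = 5, fdr_cutoff = 0.25) {
  if (!length(scores)) stopf("empty ranked universe")
  ord <- order(-scores, names(scores))
  genes <- names(scores)[ord]
  w <- abs(scores[ord])
  n <- length(genes)
  sets <- lapply(sets, intersect, genes)
  sizes <- lengths(sets)
  skip <- sizes < min_size
  if (any(skip))
    noticef("%d set(s) below min_size skipped", sum(skip))
  sets <- sets[!skip]
  if (!length(sets))
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), fdr = numeric(),
                      significant = logical()))
  es_obs <- vapply(sets, function(s)
    gsea_es(w, sort(match(s, genes)), n), numeric(1))
  sizes <- lengths(sets)

  # Null ES by set size: under gene-label permutation the null depends only
  # on the member count, so equal-size sets share one null sample.
  usizes <- sort(unique(sizes))
  seeds <- derive_seeds(seed, length(usizes))
  null_by_size <- lapply(seq_along(usizes), function(i) {
    k <- usizes[i]
    with_seed(seeds[[i]], {
      vapply(seq_len(n_perm), function(b)
        gsea_es(w, sort.int(sample.int(n, k)), n), numeric(1))
    })
  })
  names(null_by_size) <- as.character(usizes)
  null_es <- null_by_size[as.character(sizes)]

  # normalize by the mean |null ES| of matching sign (precomputed per null)
  norm_null <- function(null) {
    pos_mean <- mean(null[null >= 0])
    neg_mean <- mean(abs(null[null < 0]))
    norm1 <- function(es) {
      m <- if (es >= 0) pos_mean else neg_mean
      if (!is.finite(m) || m == 0) 0 else es / m
    }
    list(one = norm1,
         all = {
      out <- numeric(length(null))
      pos <- null >= 0
      out[pos] <- if (is.finite(pos_mean) && pos_mean > 0)
        null[pos] / pos_mean else 0
      out[!pos] <- if (is.finite(neg_mean) && neg_mean > 0)
        null[!pos] / neg_mean else 0
      out
    })
  }
  normed_by_size <- lapply(null_by_size, norm_null)
  nes_obs <- vapply(seq_along(sets), function(i)
    normed_by_size[[as.character(sizes[i])]]$one(es_obs[i]), numeric(1))
  p_nom <- vapply(seq_along(sets), function(i) {
    null <- null_es[[i]]
    if (es_obs[i] >= 0) {
      b <- sum(null[null >= 0] >= es_obs[i])
      (b + 1) / (sum(null >= 0) + 1)
    } else {
      b <- sum(null[null < 0] <= es_obs[i])
      (b + 1) / (sum(null < 0) + 1)
    }
  }, numeric(1))

  # Pooled null NES (each null ES normalized by its own size's null means)
  null_nes <- unlist(lapply(seq_along(sets), function(i)
    normed_by_size[[as.character(sizes[i])]]$all), use.names = FALSE)
  fdr <- vapply(nes_obs, function(nv) {
    if (nv >= 0) {
      num_null <- sum(null_nes >= 0)
      num <- if (num_null) sum(null_nes >= nv) / num_null else 0
      den_obs <- sum(nes_obs >= 0)
      den <- if (den_obs) sum(nes_obs >= nv) / den_obs else 1
    } else {
      num_null <- sum(null_nes < 0)
      num <- if (num_null) sum(null_nes <= nv) / num_null else 0
      den_obs <- sum(nes_obs < 0)
      den <- if (den_obs) sum(nes_obs <= nv) / den_obs else 1
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  data.frame(set = names(sets), size = sizes, es = unname(es_obs),
             nes = nes_obs, p = p_nom, fdr = fdr,
             significant = fdr <= fdr_cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pathway enrichment of top predictive lncRNAs
#'
#' Crosses each agent's top-k predictive lncRNAs with a dichotomized
#' enrichment matrix (lncRNA x pathway, 1 = significantly enriched at
#' FDR <= 0.25): reports the count of top predictors enriched in each
#' pathway and a one-sided Fisher exact p against the selection /
#' enrichment margins over the scored lncRNA universe.
#'
#' @param top_sets Named list: agent -> character vector of its top-k
#'   predictive lncRNAs. Agents with fewer than k scored lncRNAs simply
#'   contribute what they have.
#' @param enrichment Binary lncRNA x pathway matrix.
#' @return A list with `counts` and `p` (pathway x agent matrices).
#' @export
top_predictor_pathway_enrichment <- function(top_sets, enrichment) {
  universe <- rownames(enrichment)
  pathways <- colnames(enrichment)
  counts <- matrix(0L, length(pathways), length(top_sets),
                   dimnames = list(pathways, names(top_sets)))
  pmat <- counts + 1
  for (a in names(top_sets)) {
    top <- intersect(top_sets[[a]], universe)
    for (pw in pathways) {
      enr <- enrichment[, pw] == 1
      in_top <- universe %in% top
      n11 <- sum(in_top & enr)
      ft <- fisher_enrichment(n11, sum(in_top & !enr),
                              sum(!in_top & enr), sum(!in_top & !enr))
      counts[pw, a] <- n11
      pmat[pw, a] <- ft$p
    }
  }
  list(counts = counts, p = pmat)
}
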