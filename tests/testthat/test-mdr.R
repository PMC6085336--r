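test_that("pathway vectors preserve multiplicity and reject unmapped agents", {
  pairs <- data.frame(
    feature = c("L1", "L1", "L1", "L2"),
    agent = c("d1", "d2", "d3", "d1"))
  map <- c(d1 = "mitosis", d2 = "mitosis", d3 = "mitosis")
  pv <- pathway_vectors(pairs, map)
  expect_equal(pv$L1, rep("mitosis", 3))   # duplicates preserved
  expect_equal(lengths(pv), c(L1 = 3L, L2 = 1L))  # counts match pair rows
  expect_false("L9" %in% names(pv))
  expect_error(pathway_vectors(pairs, map[1:2]), "d3")
})

test_that("Shannon entropy matches direct formula evaluation", {
  expect_equal(shannon_entropy(rep("a", 5)), 0)
  expect_equal(shannon_entropy(c("a", "b", "c", "d")), 2)
  expect_equal(shannon_entropy(c("a", "a", "b")), 0.9183, tolerance = 1e-4)
  # all multisets of size <= 4 over 3 labels vs the brute-force oracle
  labs <- c("x", "y", "z")
  for (m in 1:4) {
    grids <- do.call(expand.grid, rep(list(labs), m))
    for (i in seq_len(nrow(grids))) {
      v <- as.character(unlist(grids[i, ]))
      expect_equal(shannon_entropy(v), entropy_oracle(v), tolerance = 1e-12)
    }
  }
})

test_that("entropy respects its bounds with equality at uniformity", {
  withr::with_seed(61, {
    for (i in 1:50) {
      m <- sample(1:6, 1)
      v <- sample(letters[1:4], m, replace = TRUE)
      h <- shannon_entropy(v)
      expect_gte(h, 0)
      expect_lte(h, log2(length(unique(v))) + 1e-12)
    }
  })
  expect_equal(shannon_entropy(c("a", "b")), log2(2))
})

test_that("MDR flagging uses a strict z > 1 rule and ignores ordering", {
  h <- c(A = 0, B = 0, C = 0, D = 0, E = 3)
  out <- flag_mdr(h)
  expect_identical(out$feature[out$mdr], "E")
  out_rev <- flag_mdr(rev(h))
  expect_identical(out_rev$mdr, out$mdr)
  # all-equal entropies: zero variance, nothing flagged
  expect_message(none <- flag_mdr(c(A = 1, B = 1, C = 1)), "variance")
  expect_false(any(none$mdr))
  expect_error(flag_mdr(c(A = 1, B = 2)), "at least 3")
})

test_that("a broad-pathway lncRNA among narrow peers is flagged", {
  vecs <- c(list(BROAD = paste0("P", 1:8)),
            setNames(lapply(1:9, function(i) rep("P1", 2)),
                     paste0("NARROW", 1:9)))
  out <- flag_mdr(vecs)
  expect_true(out$mdr[out$feature == "BROAD"])
  expect_false(any(out$mdr[out$feature != "BROAD"]))
})

test_that("correlation profiles rank perfect and inverted genes at the ends", {
  withr::with_seed(62, {
    n <- 30
    lnc <- setNames(rnorm(n), sprintf("s%02d", 1:n))
    P <- cbind(same = lnc, anti = -lnc,
               noise = rnorm(n), const = rep(1, n))
    rownames(P) <- names(lnc)
  })
  prof <- correlation_profile(lnc, feature_matrix(P))
  expect_equal(prof$gene[1], "same")
  expect_equal(prof$r[1], 1, tolerance = 1e-12)
  expect_equal(prof$gene[nrow(prof)], "anti")
  expect_equal(prof$r[nrow(prof)], -1, tolerance = 1e-12)
  expect_true(prof$constant[prof$gene == "const"])
  expect_equal(prof$r[prof$gene == "const"], 0)
})

test_that("GSEA: extreme sets, antisymmetry, and conservation of the running sum", {
  # strictly positive, gently decreasing scores: no single gene dominates
  # the weighting, so a random set cannot rival the true top block
  scores <- setNames(seq(2, 0.01, length.out = 1000),
                     sprintf("g%04d", 1:1000))
  sets <- list(top = names(scores)[1:20],
               mid = names(scores)[withr::with_seed(63, sample(1000, 20))])
  res <- gsea_preranked(scores, sets, n_perm = 200, seed = 1)
  top <- res[res$set == "top", ]
  expect_gt(top$es, 0.9)
  # minimal attainable nominal p: no same-sign null reaches the observed ES,
  # so p = 1/(n_pos_null + 1) <= 2/(n_perm + 1)
  expect_lte(top$p, 2 / (200 + 1))

  # reversing the ranking negates every ES
  res_rev <- gsea_preranked(-scores, sets, n_perm = 200, seed = 1)
  expect_equal(res_rev$es[match(res$set, res_rev$set)], -res$es,
               tolerance = 1e-10)

  # conservation: at the end of the list the running sum returns to zero
  # (all hit weight and all miss weight have been spent)
  w <- unname(abs(scores))
  for (pos in list(c(1L, 500L, 1000L), sort(sample(1000, 30)))) {
    k <- length(pos)
    end_val <- cumsum(w[pos])[k] / sum(w[pos]) -
      (1000 - k) / (1000 - k)
    expect_equal(end_val, 0, tolerance = 1e-12)
  }
  # sets smaller than min_size are skipped
  expect_message(
    skipped <- gsea_preranked(scores, list(tiny = names(scores)[1:2]),
                              n_perm = 50, seed = 2),
    "skipped")
  expect_equal(nrow(skipped), 0)
})

test_that("our enrichment score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(64, {
    scores <- setNames(rnorm(500), sprintf("g%03d", 1:500))
    sets <- lapply(1:5, function(i) sample(names(scores), 25))
    names(sets) <- paste0("S", 1:5)
  })
  ord <- order(-scores, names(scores))
  ranked <- scores[ord]
  for (nm in names(sets)) {
    ours <- lncgx:::gsea_es(abs(ranked),
                            sort(match(sets[[nm]], names(ranked))),
                            length(ranked))
    theirs <- fgsea::calcGseaStat(ranked,
                                  sort(match(sets[[nm]], names(ranked))),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("top-predictor pathway enrichment counts and saturates correctly", {
  lncs <- sprintf("L%03d", 1:100)
  enr <- matrix(0L, 100, 2, dimnames = list(lncs, c("PW1", "PW2")))
  enr[1:20, "PW1"] <- 1L
  top_sets <- list(agentA = lncs[1:20],    # saturated in PW1
                   agentB = lncs[81:100])  # disjoint from PW1
  res <- top_predictor_pathway_enrichment(top_sets, enr)
  expect_equal(res$counts["PW1", "agentA"], 20L)
  expect_lt(res$p["PW1", "agentA"], 1e-10)
  expect_equal(res$counts["PW1", "agentB"], 0L)
  expect_equal(res$p["PW1", "agentB"], 1, tolerance = 1e-6)
  # Fisher p equals brute-force enumeration on a small configuration
  small_enr <- matrix(0L, 12, 1, dimnames = list(sprintf("x%02d", 1:12), "PW"))
  small_enr[1:4, 1] <- 1L
  res_s <- top_predictor_pathway_enrichment(
    list(a = sprintf("x%02d", c(1, 2, 5, 6, 7))), small_enr)
  expect_equal(res_s$p["PW", "a"],
               enumerate_fisher_greater(2, 3, 2, 5), tolerance = 1e-10)
})
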