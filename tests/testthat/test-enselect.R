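test_that("default grids match the tuned search space", {
  g <- en_hyperparams()
  expect_length(g$alpha_grid, 10)
  expect_length(g$lam_grid, 200)
  expect_equal(range(g$alpha_grid), c(0.2, 1))
  expect_equal(range(log(g$lam_grid)), c(-5, 5), tolerance = 1e-12)
  expect_equal(g$cv_folds, 10L)
  expect_error(en_hyperparams(alpha_grid = c(1, 0.5)), "sorted")
})

test_that("predictive scores are bootstrap selection frequencies", {
  # construct a coefficient matrix directly: PS is pure counting
  beta_bs <- rbind(matrix(1, 180, 1), matrix(0, 20, 1))
  beta_bs <- cbind(beta_bs, 0)
  ps <- lncgx:::ps_from_coefficients(beta_bs)
  expect_equal(unname(ps), c(0.9, 0))
  # PS granularity: multiples of 1/B
  expect_true(all(abs(ps * 200 - round(ps * 200)) < 1e-12))
})

test_that("noiseless response is recovered by tuning + refit", {
  withr::with_seed(11, {
    n <- 200; p <- 50
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%03d", 1:n), sprintf("f%02d", 1:p)))
    beta <- numeric(p); beta[1:5] <- c(1, -1, 0.8, -0.8, 0.6)
    y <- drop(X %*% beta)
  })
  tuned <- tune_hyperparams(X, y, seed = 1)
  fit <- lncgx:::glmnet_at(X, y, tuned$alpha, tuned$lam)
  r2 <- 1 - sum((y - X %*% fit$beta - fit$intercept)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.95)
})

test_that("pure-noise response tunes to the null ceiling", {
  withr::with_seed(12, {
    X <- matrix(rnorm(100 * 30), 100, 30,
                dimnames = list(sprintf("s%03d", 1:100), sprintf("f%02d", 1:30)))
    y <- rnorm(100)
  })
  tuned <- tune_hyperparams(X, y, seed = 2)
  expect_lt(tuned$cv_mse, 1.25 * var(y))
  expect_gt(tuned$cv_mse, 0.75 * var(y))
})

test_that("an extreme penalty drives every predictive score to zero", {
  fx <- planted_xy()
  bs <- bootstrap_ps(as.matrix(fx$X), fx$y, alpha = 1, lam = 1e6, B = 20,
                     seed = 1)
  expect_true(all(bs$ps == 0))
})

test_that("pair definition is inclusive at the cutoff and tolerates empty results", {
  bs <- structure(list(
    coefficients = matrix(c(1, 1, 1, 0, 0,   0, 1, 0, 0, 0,  1, 0, 1, 1, 1),
                          5, 3, dimnames = list(NULL, c("f1", "f2", "f3"))),
    intercepts = numeric(5),
    ps = c(f1 = 0.30, f2 = 0.20, f3 = 0.25), B = 5),
    class = "bootstrap_ps")
  X <- matrix(rnorm(30), 10, 3,
              dimnames = list(sprintf("s%02d", 1:10), c("f1", "f2", "f3")))
  y <- rnorm(10)
  pairs <- define_pairs(bs, X, y, cutoff = 0.25)
  expect_setequal(pairs$feature, c("f1", "f3"))
  none <- define_pairs(bs, X, y, cutoff = 0.5)
  expect_equal(nrow(none), 0)
  all_sel <- define_pairs(bs, X, y, cutoff = 1)
  expect_equal(nrow(all_sel), 0)  # nothing selected in every replicate
  expect_error(define_pairs(bs, X, y, cutoff = 0), "cutoff")
})

test_that("predictive scores are invariant to feature order and die under permuted response", {
  fx <- planted_xy()
  X <- as.matrix(fx$X)
  tuned <- tune_hyperparams(X, fx$y, seed = 3)
  bs <- bootstrap_ps(X, fx$y, tuned$alpha, tuned$lam, B = 30, seed = 4)
  perm <- withr::with_seed(5, sample(ncol(X)))
  bs_p <- bootstrap_ps(X[, perm], fx$y, tuned$alpha, tuned$lam, B = 30,
                       seed = 4)
  # coordinate-descent convergence can flip a coefficient sitting exactly at
  # the zero threshold in a stray replicate; planted features must agree
  # exactly and the remainder within one replicate's worth of PS
  expect_lte(max(abs(bs$ps[colnames(X)[perm]] - bs_p$ps)), 1 / bs$B)
  planted <- colnames(X)[fx$truth_idx]
  expect_equal(bs$ps[planted], bs_p$ps[planted], tolerance = 1e-12)

  y_perm <- withr::with_seed(6, sample(fx$y))
  tuned_p <- tune_hyperparams(X, y_perm, seed = 3)
  bs_null <- bootstrap_ps(X, y_perm, tuned_p$alpha, tuned_p$lam, B = 30,
                          seed = 4)
  expect_lt(median(bs_null$ps[fx$truth_idx]), 0.25)
})

test_that("cutoff calibration returns KS extremes for trivial distributions", {
  # identical distributions -> KS 0; disjoint support -> KS 1
  expect_equal(unname(ks.test(1:50, 1:50)$statistic), 0, tolerance = 1e-12)
  expect_equal(unname(ks.test(1:50, 51:100)$statistic), 1)

  # on simulated twin panels the curve separates predictive from background
  cfg <- small_cfg(seed = 21)
  p1 <- simulate_cell_line_panel(cfg)
  p2 <- simulate_cell_line_panel(small_cfg(seed = 22))
  # same truth: rebuild response of p2's X under p1's coefficients
  X2 <- as.matrix(p2$expression)
  y2 <- X2 %*% t(p1$truth$true_coefficients) +
    withr::with_seed(23,
      matrix(rnorm(nrow(X2) * nrow(p1$truth$true_coefficients), sd = 0.5),
             nrow(X2), nrow(p1$truth$true_coefficients)))
  ps <- abs(t(p1$truth$true_coefficients)) / max(abs(p1$truth$true_coefficients))
  ps <- ps * 0.8 + 0.1 * (ps > 0)  # planted features get high PS
  cal <- calibrate_cutoff(ps, feature_matrix(X2, normalized = TRUE), y2,
                          cutoffs = seq(0.1, 0.9, 0.2))
  expect_true(all(cal$curve$ks >= 0 & cal$curve$ks <= 1))
  expect_gt(max(cal$curve$ks), 0.3)
})

test_that("replication overlap reproduces counts, percentage and OR behavior", {
  mk_pairs <- function(feats, agent = "d1")
    data.frame(feature = feats, agent = agent)
  # 512 pairs in A, 90 shared with B
  a <- mk_pairs(sprintf("f%04d", 1:512))
  b <- mk_pairs(sprintf("f%04d", c(1:90, 2000:2421)))
  ov <- replication_overlap(a, b, features = 5000, agents = 1)
  expect_equal(ov$n_both, 90)
  expect_equal(round(ov$pct_a_in_b, 1), 17.6)

  # identical sets: corrected finite OR with flag
  same <- replication_overlap(a, a, features = 5000, agents = 1)
  expect_true(same$corrected)
  expect_true(is.finite(same$odds_ratio) && same$odds_ratio > 1000)

  # independent random sets: OR near 1 across replicates
  ors <- vapply(1:10, function(s) withr::with_seed(s, {
    u <- sprintf("f%04d", 1:1000)
    replication_overlap(mk_pairs(sample(u, 200)), mk_pairs(sample(u, 200)),
                        features = 1000, agents = 1)$odds_ratio
  }), numeric(1))
  expect_lt(abs(mean(ors) - 1), 0.3)
  expect_error(replication_overlap(a, b, features = 10, agents = 1),
               "universe")
})
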