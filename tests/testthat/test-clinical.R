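# Deterministic patient-prediction fixture: a cohort plus simple models.
.clin_fix <- local({
  cfg <- small_cfg(n_tumors = 200, seed = 51)
  panel <- simulate_cell_line_panel(cfg)
  cohort <- simulate_tumor_cohort(cfg, panel$truth)
  X <- as.matrix(panel$expression)
  models <- lapply(colnames(panel$response$ln_ic50), function(a) {
    y <- panel$response$ln_ic50[, a]
    feats <- colnames(X)[panel$truth$true_coefficients[a, ] != 0]
    train_lenp(X, y, feats, agent_id = a, seed = 52)
  })
  names(models) <- colnames(panel$response$ln_ic50)
  list(panel = panel, cohort = cohort, models = models)
})

test_that("stage-I patients are filtered except for exempt types", {
  cl <- .clin_fix$cohort$clinical
  cl$cancer_type[cl$cancer_type == "TYPE001"] <- "LAML"
  res <- predict_patients(.clin_fix$models, .clin_fix$cohort$expression, cl)
  kept <- res$clinical
  expect_false(any(kept$stage == "I" & kept$cancer_type != "LAML"))
  expect_true(any(kept$stage == "I" & kept$cancer_type == "LAML"))
  expect_identical(rownames(res$predictions), kept$patient_id)
  # deterministic: repeated call identical
  res2 <- predict_patients(.clin_fix$models, .clin_fix$cohort$expression, cl)
  expect_identical(res$predictions, res2$predictions)
  # all-stage-I non-exempt cohort empties out with a notice
  cl_i <- cl[cl$cancer_type != "LAML", ][1:5, ]
  cl_i$stage <- "I"
  expect_message(
    empty <- predict_patients(.clin_fix$models,
                              .clin_fix$cohort$expression, cl_i),
    "no patients")
  expect_null(empty$predictions)
})

test_that("sensitive labeling takes the lowest quartile, inclusive of ties", {
  P <- matrix(1:8, 8, 1, dimnames = list(paste0("p", 1:8), "d"))
  lab <- label_sensitive(P)
  expect_equal(sum(lab), 2)
  expect_equal(which(lab[, 1] == 1), c(p1 = 1L, p2 = 2L))
  # monotone transform leaves labels unchanged
  P2 <- exp(P)
  expect_equal(unname(label_sensitive(P2)), unname(lab))
  # all-equal predictions: everyone tied at the quartile, flagged
  P3 <- matrix(5, 8, 1, dimnames = list(paste0("p", 1:8), "d"))
  expect_warning(lab3 <- label_sensitive(P3), "all-equal")
  expect_true(all(lab3 == 1))
})

test_that("sensitivity summary percentages and KS shift detection", {
  withr::with_seed(53, {
    n <- 80
    ids <- sprintf("p%03d", 1:n)
    types <- setNames(rep(c("T1", "T2"), each = n / 2), ids)
    # T1 stochastically more sensitive (lower predicted IC50) for d1
    P <- cbind(d1 = c(rnorm(n / 2, -2), rnorm(n / 2, 0)),
               d2 = rnorm(n))
    rownames(P) <- ids
  })
  lab <- label_sensitive(P)
  ss <- sensitivity_summary(P, lab, types)
  expect_true(all(ss$percent >= 0 & ss$percent <= 100))
  expect_equal(sum(ss$counts[, "d1"]), sum(lab[, "d1"]))
  ks_d1 <- ss$ks[ss$ks$type == "T1" & ss$ks$agent == "d1", ]
  expect_lt(ks_d1$p, 0.001)
  expect_equal(ks_d1$direction, "sensitive")
  # identical distributions: statistic small, p large
  ks_d2 <- ss$ks[ss$ks$type == "T1" & ss$ks$agent == "d2", ]
  expect_gt(ks_d2$p, 0.01)
  # the pooled sensitive count per agent is about a quarter of patients
  expect_equal(sum(ss$counts[, "d1"]), ceiling(n / 4), tolerance = 1)
})

test_that("univariate Cox recovers planted hazard and is scale-invariant per sd", {
  co <- .clin_fix$cohort
  x <- setNames(co$clinical$true_score, co$clinical$patient_id)
  fit <- univariate_cox(x, co$clinical)
  expect_gt(fit$hr, 1.4); expect_lt(fit$hr, 2.9)  # true HR 2 per sd
  fit2 <- univariate_cox(2 * x, co$clinical)
  expect_equal(fit$hr, fit2$hr, tolerance = 1e-8)  # standardized predictor
  expect_error(univariate_cox(x, transform(co$clinical, os_event = 0)),
               "events")
})

test_that("consensus rank formula, categories and degenerate cases", {
  # hand case: first-line rank 10, second-line rank 20 -> 13.33
  expect_equal((1 * 10 + 0.5 * 20) / 1.5, 13.33, tolerance = 1e-3)
  ids <- sprintf("p%02d", 1:10)
  P <- cbind(dA = 1:10, dB = c(2:10, 1))
  rownames(P) <- ids
  types <- setNames(rep("T1", 10), ids)
  approved <- list(T1 = list(first_line = "dA", second_line = "dB"))
  cr <- consensus_rank(P, types, approved)
  expect_equal(cr$consensus_rank,
               (1 * rank(P[, "dA"]) + 0.5 * rank(P[, "dB"])) / 1.5,
               ignore_attr = TRUE)
  expect_equal(sum(cr$category == "sensitive"), 3)      # nearest-rank 30%
  expect_equal(sum(cr$category == "resistance"), 3)
  # single drug: consensus equals its rank
  cr1 <- consensus_rank(P[, "dA", drop = FALSE], types,
                        list(T1 = list(first_line = "dA",
                                       second_line = character())))
  expect_equal(cr1$consensus_rank, rank(P[, "dA"]), ignore_attr = TRUE)
  # rank-based: monotone transform of P changes nothing
  cr_exp <- consensus_rank(exp(P / 3), types, approved)
  expect_equal(cr_exp$consensus_rank, cr$consensus_rank, ignore_attr = TRUE)
  # no approved drugs -> type skipped with notice
  expect_message(
    none <- consensus_rank(P, types, list(T2 = list(first_line = "dA"))),
    "skipped")
  expect_null(none)
})

test_that("multivariate Cox isolates the resistance effect and drops degenerate covariates", {
  co <- .clin_fix$cohort
  cl <- co$clinical
  P <- matrix(rep(cl$true_score, 2), ncol = 2,
              dimnames = list(cl$patient_id, c("AGENT001", "AGENT002")))
  types <- setNames(cl$cancer_type, cl$patient_id)
  approved <- setNames(
    rep(list(list(first_line = "AGENT001", second_line = "AGENT002")),
        length(unique(cl$cancer_type))), sort(unique(cl$cancer_type)))
  cr <- consensus_rank(P, types, approved)
  mv <- multivariate_cox(cr, cl)
  res <- mv[mv$term == "resistance", ]
  expect_gt(res$hr, 1)
  expect_lt(res$p, 0.05)
  # stage and age were simulated independent of hazard: CIs cover 1
  for (t in c("stage", "old_age")) {
    row <- mv[mv$term == t, ]
    expect_true(row$ci_lo <= 1 && row$ci_hi >= 1)
  }
  # all patients one stage -> stage dropped with a notice
  cl1 <- cl; cl1$stage <- "II"
  expect_message(mv1 <- multivariate_cox(cr, cl1), "degenerate")
  expect_false("stage" %in% mv1$term)
  # age-65 boundary goes to 'old'
  d65 <- data.frame(age = c(64, 65, 66))
  expect_equal(as.integer(d65$age >= 65), c(0L, 1L, 1L))
})

test_that("treated-patient KM split is balanced and detects planted hazard", {
  cfg <- small_cfg(n_tumors = 200, log_hr_resistance = log(3), seed = 54)
  co <- simulate_tumor_cohort(cfg, fixture_panel()$truth)
  cl <- co$clinical
  drug <- strsplit(cl$treatments[1], ";")[[1]][1]
  x <- setNames(cl$true_score, cl$patient_id)
  km <- treated_km(x, cl, drug)
  grp_sizes <- table(km$groups)
  expect_lte(abs(diff(grp_sizes)), 1)
  expect_lt(km$logrank_p, 0.05)
  expect_gt(km$hr, 1)
  # odd n: the median patient lands in the resistant group
  cl_odd <- cl[cl$patient_id %in% names(km$groups), ][1:15, ]
  x_odd <- x[cl_odd$patient_id]
  km_odd <- treated_km(x_odd, transform(cl_odd, treatments = drug), drug,
                       min_treated = 5, min_events = 1)
  expect_equal(unname(table(km_odd$groups)["resistant"]), 8L)
  # eligibility guards
  expect_error(treated_km(x, cl[1:5, ], drug), "treated")
})
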