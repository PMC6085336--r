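#' Predict drug response for a tumor cohort
#'
#' Applies trained LENP models to tumor expression. Stage-I patients are
#' excluded before prediction — chemotherapy response modeling targets
#' advanced disease — except for cancer types in `keep_stage1_types`
#' (acute myeloid leukemia by default, which has no stage system). Unknown
#' stages are retained with a warning.
#'
#' @param models Named list of `lenp_model`s.
#' @param tumor_fm Tumor [feature_matrix()].
#' @param clinical Clinical table (see [validate_clinical()]).
#' @param keep_stage1_types Cancer types exempt from the stage-I filter.
#' @return A list with `predictions` (patient x agent matrix) and
#'   `clinical` (the retained rows); attribute `filter` records the rule.
#' @export
predict_patients <- function(models, tumor_fm, clinical,
                             keep_stage1_types = "LAML") {
  clinical <- validate_clinical(clinical)
  known <- clinical$stage %in% c("I", "II", "III", "IV")
  if (any(!known))
    warnf("%d patient(s) with unknown stage retained", sum(!known))
  drop_ <- known & clinical$stage == "I" &
    !(clinical$cancer_type %in% keep_stage1_types)
  kept <- clinical[!drop_, , drop = FALSE]
  if (!nrow(kept)) {
    noticef("no patients left after the stage filter")
    return(list(predictions = NULL, clinical = kept))
  }
  X <- as_fm_matrix(tumor_fm)[kept$patient_id, , drop = FALSE]
  P <- vapply(models, function(m) stats::predict(m, X),
              numeric(nrow(kept)))
  P <- matrix(P, nrow = nrow(kept),
              dimnames = list(kept$patient_id, names(models)))
  out <- list(predictions = P, clinical = kept)
  attr(out, "filter") <- sprintf("stage I removed except types: %s",
                                 paste(keep_stage1_types, collapse = ", "))
  out
}

# Nearest-rank quantile: the smallest observed value with ecdf >= q.
nearest_rank_quantile <- function(x, q) {
  stats::quantile(x, q, type = 1, names = FALSE)
}

#' Label sensitive patients per agent
#'
#' Patients whose predicted response is at or below the nearest-rank 25th
#' percentile — the lowest predicted IC50 quartile — are labeled sensitive.
#' Ties at the threshold are all included; being rank-based, the labeling
#' is invariant to monotone transforms of the predictions.
#'
#' @param P Patient x agent predicted-response matrix.
#' @return Binary matrix of the same shape (1 = sensitive); degenerate
#'   all-equal agents are flagged via the `degenerate` attribute.
#' @export
label_sensitive <- function(P) {
  if (nrow(P) < 4) stopf("need at least 4 patients per agent")
  out <- apply(P, 2, function(x) as.integer(x <= nearest_rank_quantile(x, 0.25)))
  dimnames(out) <- dimnames(P)
  degen <- apply(P, 2, function(x) length(unique(x)) == 1)
  if (any(degen))
    warnf("all-equal predictions for agent(s): %s",
          paste(colnames(P)[degen], collapse = ", "))
  attr(out, "degenerate") <- degen
  out
}

#' Sensitive-percentage summary per cancer type
#'
#' The sensitive percentage for agent i in type j is
#' `100 * n_sensitive / C_j`. For each (type, agent), a two-sided
#' Kolmogorov-Smirnov test compares the type's predicted-response
#' distribution against all other types (skipped for singleton types), and
#' the direction (whether the type is shifted toward sensitivity) is
#' annotated.
#'
#' @param P Patient x agent predicted-response matrix.
#' @param labels A [label_sensitive()] matrix.
#' @param types Named cancer-type vector for the patients.
#' @return A list with `percent` (type x agent), `counts`, `type_sizes`
#'   and `ks` (long data frame: type, agent, statistic, p, direction).
#' @export
sensitivity_summary <- function(P, labels, types) {
  types <- types[rownames(P)]
  tys <- sort(unique(types))
  pct <- matrix(NA_real_, length(tys), ncol(P),
                dimnames = list(tys, colnames(P)))
  cnt <- pct
  for (t in tys) {
    idx <- types == t
    cnt[t, ] <- colSums(labels[idx, , drop = FALSE])
    pct[t, ] <- 100 * cnt[t, ] / sum(idx)
  }
  ks_rows <- list()
  for (t in tys) {
    idx <- types == t
    if (sum(idx) < 2 || sum(!idx) < 2) {
      noticef("type %s too small for the KS comparison; skipped", t)
      next
    }
    for (a in colnames(P)) {
      kt <- suppressWarnings(stats::ks.test(P[idx, a], P[!idx, a]))
      ks_rows[[paste(t, a)]] <- data.frame(
        type = t, agent = a, statistic = unname(kt$statistic),
        p = kt$p.value,
        direction = if (stats::median(P[idx, a]) < stats::median(P[!idx, a]))
          "sensitive" else "resistant",
        stringsAsFactors = FALSE)
    }
  }
  list(percent = pct, counts = cnt,
       type_sizes = as.integer(table(types)[tys]),
       ks = rbind_rows(ks_rows))
}

#' Univariate Cox regression on a continuous predictor
#'
#' Proportional-hazards partial-likelihood fit of survival on the
#' standardized predictor; the hazard ratio is the exponentiated
#' coefficient (per sd of the predictor).
#'
#' @param x Numeric predictor (e.g. one column of predicted response),
#'   named by patient.
#' @param clinical Clinical table.
#' @param endpoint `"os"` (default) or `"pfi"`.
#' @param min_events Minimum required events (default 10).
#' @return A list: `hr`, `ci` (95%), `p`, `coef`, `n`, `n_events`.
#' @export
univariate_cox <- function(x, clinical, endpoint = c("os", "pfi"),
                           min_events = 10) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  cl <- clinical[match(names(x) %||% clinical$patient_id,
                       clinical$patient_id), ]
  time <- cl[[tcol]]; event <- cl[[ecol]]
  if (sum(event) == 0) stopf("no events")
  if (sum(event) < min_events)
    stopf("fewer than %d events", min_events)
  z <- as.numeric(scale(x))
  fit <- survival::coxph(survival::Surv(time, event) ~ z)
  s <- summary(fit)
  list(hr = unname(s$conf.int[1, "exp(coef)"]),
       ci = unname(s$conf.int[1, c("lower .95", "upper .95")]),
       p = unname(s$coefficients[1, "Pr(>|z|)"]),
       coef = unname(s$coefficients[1, "coef"]),
       n = length(time), n_events = sum(event))
}

#' Consensus drug-response rank per patient
#'
#' Within each cancer type, patients are ranked per approved drug by
#' ascending predicted response (rank 1 = most sensitive; ties get average
#' ranks) and the weighted average rank is
#' `R' = sum(w_i R_i) / sum(w_i)` with weight 1.0 for first-line and 0.5
#' for second-line agents. Patients are then categorized by nearest-rank
#' percentile of R': sensitive response (top 30%), partial response
#' (30-50%), partial resistance (50-70%), resistance (bottom 30%).
#'
#' @param P Patient x agent predicted-response matrix.
#' @param types Named cancer-type vector for the patients.
#' @param approved Named list: cancer type -> list(first_line, second_line)
#'   of agent ids.
#' @return Data frame (patient_id, cancer_type, consensus_rank, category,
#'   n_drugs); types without approved drugs are skipped with a notice.
#' @export
consensus_rank <- function(P, types, approved) {
  types <- types[rownames(P)]
  rows <- list()
  for (ty in sort(unique(types))) {
    ap <- approved[[ty]]
    drugs <- intersect(c(ap$first_line, ap$second_line), colnames(P))
    if (!length(drugs)) {
      noticef("type %s has no approved drugs configured; skipped", ty)
      next
    }
    w <- ifelse(drugs %in% ap$first_line, 1.0, 0.5)
    idx <- which(types == ty)
    R <- vapply(drugs, function(d) rank(P[idx, d]), numeric(length(idx)))
    R <- matrix(R, nrow = length(idx))
    rprime <- drop(R %*% w) / sum(w)
    cat_ <- categorize_consensus(rprime)
    rows[[ty]] <- data.frame(
      patient_id = rownames(P)[idx], cancer_type = ty,
      consensus_rank = rprime, category = cat_, n_drugs = length(drugs),
      stringsAsFactors = FALSE)
  }
  out <- rbind_rows(rows)
  if (!is.null(out))
    out$category <- factor(out$category,
                           levels = c("sensitive", "partial_response",
                                      "partial_resistance", "resistance"))
  out
}

# 30 / 20 / 20 / 30 percent bins of ascending consensus rank, nearest-rank
# boundaries: positions 1..ceil(.3n) sensitive, ..ceil(.5n) partial
# response, ..ceil(.7n) partial resistance, rest resistance.
categorize_consensus <- function(rprime) {
  n <- length(rprime)
  pos <- rank(rprime, ties.method = "first")
  cut_s <- ceiling(0.3 * n); cut_pr <- ceiling(0.5 * n)
  cut_px <- ceiling(0.7 * n)
  ifelse(pos <= cut_s, "sensitive",
         ifelse(pos <= cut_pr, "partial_response",
                ifelse(pos <= cut_px, "partial_resistance", "resistance")))
}

#' Multivariate Cox regression on consensus response, stage and age
#'
#' Covariates: response category coded ordinally 0-3 (resistance high) —
#' or the continuous consensus rank via `covariate = "rank"` — disease
#' stage coded ordinally I-IV, and age dichotomized at 65 years (age >= 65
#' is 'old'). Degenerate (constant) covariates are dropped with a notice.
#'
#' @param consensus A [consensus_rank()] data frame.
#' @param clinical Clinical table.
#' @param endpoint `"os"` or `"pfi"`.
#' @param covariate `"category"` (default) or `"rank"`.
#' @return Data frame (term, hr, ci_lo, ci_hi, p, coef).
#' @export
multivariate_cox <- function(consensus, clinical,
                             endpoint = c("os", "pfi"),
                             covariate = c("category", "rank")) {
  endpoint <- match.arg(endpoint)
  covariate <- match.arg(covariate)
  cl <- clinical[match(consensus$patient_id, clinical$patient_id), ]
  d <- data.frame(
    time = cl[[paste0(endpoint, "_time")]],
    event = cl[[paste0(endpoint, "_event")]],
    resistance = if (covariate == "category")
      as.integer(consensus$category) - 1L else consensus$consensus_rank,
    stage = match(cl$stage, c("I", "II", "III", "IV")),
    old_age = as.integer(cl$age >= 65))
  terms <- c("resistance", "stage", "old_age")
  keep <- vapply(terms, function(t)
    length(unique(stats::na.omit(d[[t]]))) > 1, logical(1))
  if (any(!keep))
    noticef("dropping degenerate covariate(s): %s",
            paste(terms[!keep], collapse = ", "))
  terms <- terms[keep]
  if (!length(terms)) stopf("no usable covariates")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = d)
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             hr = s$conf.int[, "exp(coef)"],
             ci_lo = s$conf.int[, "lower .95"],
             ci_hi = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             coef = s$coefficients[, "coef"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Survival of treated patients split by predicted response
#'
#' Restricts to patients whose treatment record includes the drug,
#' splits them at the median predicted response (upper half = predicted
#' resistant; with odd n the median patient goes to the resistant group),
#' and reports the log-rank test, the Cox hazard ratio of the split and
#' the Kaplan-Meier tables.
#'
#' @param p_drug Named predicted-response vector for one drug.
#' @param clinical Clinical table with a `treatments` column
#'   (semicolon-separated drug names).
#' @param drug Drug name to match in the treatment records.
#' @param min_treated,min_events Eligibility thresholds (defaults 10 and
#'   5).
#' @return A list: `logrank_p`, `hr`, `ci`, `n`, `groups` (per-patient
#'   assignment), `km` (survfit summary table).
#' @export
treated_km <- function(p_drug, clinical, drug, min_treated = 10,
                       min_events = 5) {
  treated <- vapply(strsplit(clinical$treatments %||% "", ";"),
                    function(v) drug %in% v, logical(1))
  cl <- clinical[treated, , drop = FALSE]
  if (nrow(cl) < min_treated)
    stopf("only %d treated patients (< %d)", nrow(cl), min_treated)
  if (sum(cl$os_event) < min_events)
    stopf("only %d events among treated patients (< %d)", sum(cl$os_event),
          min_events)
  p <- p_drug[cl$patient_id]
  ord <- order(p, cl$patient_id)
  n <- length(p)
  grp <- character(n)
  grp[ord[seq_len(floor(n / 2))]] <- "sensitive"
  grp[ord[(floor(n / 2) + 1):n]] <- "resistant"
  grp <- factor(grp, levels = c("sensitive", "resistant"))
  sv <- survival::Surv(cl$os_time, cl$os_event)
  lr <- survival::survdiff(sv ~ grp)
  cx <- summary(survival::coxph(sv ~ grp))
  km <- summary(survival::survfit(sv ~ grp))
  list(logrank_p = stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE),
       hr = unname(cx$conf.int[1, "exp(coef)"]),
       ci = unname(cx$conf.int[1, c("lower .95", "upper .95")]),
       n = n,
       groups = stats::setNames(as.character(grp), cl$patient_id),
       km = data.frame(time = km$time, n_risk = km$n.risk,
                       n_event = km$n.event, surv = km$surv,
                       group = as.character(km$strata)))
}
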