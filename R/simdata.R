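#' Simulation configuration
#'
#' Defines the study conditions of the synthetic pharmacogenomic panel:
#' dimensions, planted effect sizes and noise levels. Defaults are sized so
#' that planted lncRNA-drug effects are recoverable by the bootstrapped
#' elastic net at realistic noise (effect 0.8 ln-IC50 units per z-unit of
#' expression against residual noise sd 0.5), with per-cancer-type
#' expression mean shifts large enough to make tissue-of-origin matching
#' informative but not trivial.
#'
#' @param n_cell_lines,n_tumors,n_lncRNAs,n_pcgs,n_agents,n_cancer_types,n_pathways
#'   Panel dimensions.
#' @param k_true_per_agent Number of planted predictive lncRNAs per agent;
#'   must be below `n_lncRNAs`.
#' @param effect_size Magnitude of planted coefficients (ln-IC50 units per
#'   z-unit of expression).
#' @param noise_sd Residual sd of the drug-response model.
#' @param type_shift Per-cancer-type mean shift (z-units) applied to that
#'   type's signature features.
#' @param lineage_effect_sd Sd of per-(type, agent) response offsets.
#' @param baseline_hazard Events per time unit of the exponential survival
#'   baseline.
#' @param log_hr_resistance Log hazard ratio per sd of the true resistance
#'   score.
#' @param censoring_rate Expected fraction of censored patients, in \[0, 1).
#' @param seed Integer seed; the whole generator is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cell_lines = 120, n_tumors = 300, n_lncRNAs = 500,
                       n_pcgs = 1000, n_agents = 6, n_cancer_types = 6,
                       n_pathways = 3, k_true_per_agent = 10,
                       effect_size = 0.8, noise_sd = 0.5, type_shift = 1,
                       lineage_effect_sd = 0.3, baseline_hazard = 0.001,
                       log_hr_resistance = log(2), censoring_rate = 0.3,
                       seed = 1L) {
  cfg <- list(n_cell_lines = n_cell_lines, n_tumors = n_tumors,
              n_lncRNAs = n_lncRNAs, n_pcgs = n_pcgs, n_agents = n_agents,
              n_cancer_types = n_cancer_types, n_pathways = n_pathways,
              k_true_per_agent = k_true_per_agent, effect_size = effect_size,
              noise_sd = noise_sd, type_shift = type_shift,
              lineage_effect_sd = lineage_effect_sd,
              baseline_hazard = baseline_hazard,
              log_hr_resistance = log_hr_resistance,
              censoring_rate = censoring_rate, seed = as.integer(seed))
  for (f in c("n_cell_lines", "n_tumors", "n_lncRNAs", "n_pcgs", "n_agents",
              "n_cancer_types", "n_pathways", "k_true_per_agent"))
    assert_count(cfg[[f]], f)
  if (cfg$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    stopf("censoring_rate must be in [0, 1)")
  if (cfg$k_true_per_agent >= cfg$n_lncRNAs)
    stopf("k_true_per_agent must be < n_lncRNAs")
  if (cfg$n_pathways > cfg$n_agents)
    stopf("n_pathways must be <= n_agents")
  structure(cfg, class = "sim_config")
}

sim_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

# Per-type signature features and their mean shifts; each type shifts its
# own random 10% of lncRNA features by +type_shift.
make_type_signatures <- function(cfg) {
  types <- sim_ids("TYPE", cfg$n_cancer_types)
  sig <- matrix(0, cfg$n_cancer_types, cfg$n_lncRNAs,
                dimnames = list(types, sim_ids("LNC", cfg$n_lncRNAs)))
  n_sig <- max(5L, ceiling(0.1 * cfg$n_lncRNAs))
  for (t in types)
    sig[t, sample.int(cfg$n_lncRNAs, n_sig)] <- cfg$type_shift
  sig
}

# Sparse agent x lncRNA coefficient matrix. Agents are assigned to target
# pathways round-robin; agents in the same pathway share a common core of
# ceil(k/2) predictive lncRNAs so that pathway structure is recoverable
# from selection overlap.
make_true_coefficients <- function(cfg) {
  agents <- sim_ids("AGENT", cfg$n_agents)
  lncs <- sim_ids("LNC", cfg$n_lncRNAs)
  pathways <- sim_ids("PATH", cfg$n_pathways)
  agent_pathway <- stats::setNames(
    pathways[(seq_len(cfg$n_agents) - 1L) %% cfg$n_pathways + 1L], agents)
  k <- cfg$k_true_per_agent
  core_k <- ceiling(k / 2)
  core <- lapply(stats::setNames(pathways, pathways), function(p)
    sample.int(cfg$n_lncRNAs, core_k))
  beta <- matrix(0, cfg$n_agents, cfg$n_lncRNAs,
                 dimnames = list(agents, lncs))
  for (a in agents) {
    shared <- core[[agent_pathway[[a]]]]
    pool <- setdiff(seq_len(cfg$n_lncRNAs), shared)
    own <- sample(pool, k - core_k)
    idx <- c(shared, own)
    beta[a, idx] <- cfg$effect_size * sample(c(-1, 1), k, replace = TRUE)
  }
  list(beta = beta, agent_pathway = agent_pathway)
}

# Approved-drug map: each cancer type gets two first-line and up to two
# second-line agents (round-robin so every agent is approved somewhere).
make_approved_drugs <- function(cfg) {
  agents <- sim_ids("AGENT", cfg$n_agents)
  types <- sim_ids("TYPE", cfg$n_cancer_types)
  out <- list()
  for (i in seq_along(types)) {
    idx <- ((i - 1L) * 2L + 0:3) %% cfg$n_agents + 1L
    out[[types[i]]] <- list(first_line = agents[unique(idx[1:2])],
                            second_line = setdiff(agents[unique(idx[3:4])],
                                                  agents[unique(idx[1:2])]))
  }
  out
}

#' Simulate a cell-line pharmacogenomic panel
#'
#' Generates z-scale lncRNA expression with per-cancer-type signature mean
#' shifts, and drug response per agent from a sparse linear model over the
#' planted predictive lncRNAs plus a per-(type, agent) lineage offset and
#' Gaussian noise: `lnIC50_j = X beta_j + lineage + N(0, noise_sd)`. AUC is
#' a logistic transform of lnIC50 plus small noise. The same seed yields
#' bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with `expression` ([feature_matrix()]), `response`
#'   (list with `ln_ic50`, `auc` matrices and `agent_meta`), `lineages`
#'   (named cancer-type factor) and `truth` (planted ground truth:
#'   coefficients, pathways, type signatures, approved drugs).
#' @export
simulate_cell_line_panel <- function(config) {
  cfg <- config
  if (!inherits(cfg, "sim_config")) stopf("config must be a sim_config")
  with_seed(cfg$seed, {
    cells <- sim_ids("CL", cfg$n_cell_lines)
    types <- sim_ids("TYPE", cfg$n_cancer_types)
    lineages <- stats::setNames(
      types[(seq_len(cfg$n_cell_lines) - 1L) %% cfg$n_cancer_types + 1L],
      cells)
    sig <- make_type_signatures(cfg)
    X <- matrix(stats::rnorm(cfg$n_cell_lines * cfg$n_lncRNAs),
                cfg$n_cell_lines, cfg$n_lncRNAs,
                dimnames = list(cells, colnames(sig)))
    X <- X + sig[lineages, , drop = FALSE]
    tc <- make_true_coefficients(cfg)
    agents <- rownames(tc$beta)
    lineage_off <- matrix(stats::rnorm(cfg$n_cancer_types * cfg$n_agents,
                                       sd = cfg$lineage_effect_sd),
                          cfg$n_cancer_types, cfg$n_agents,
                          dimnames = list(types, agents))
    ln_ic50 <- X %*% t(tc$beta) +
      lineage_off[lineages, , drop = FALSE] +
      matrix(stats::rnorm(cfg$n_cell_lines * cfg$n_agents, sd = cfg$noise_sd),
             cfg$n_cell_lines, cfg$n_agents)
    med <- apply(ln_ic50, 2, stats::median)
    auc <- 1 / (1 + exp(-sweep(ln_ic50, 2, med))) +
      matrix(stats::rnorm(length(ln_ic50), sd = 0.01),
             nrow(ln_ic50), ncol(ln_ic50))
    agent_meta <- data.frame(
      agent_id = agents,
      pathway = unname(tc$agent_pathway[agents]),
      clinical_status = rep_len(c("clinical", "development", "experimental"),
                                cfg$n_agents),
      stringsAsFactors = FALSE)
    truth <- list(true_coefficients = tc$beta,
                  agent_pathway = tc$agent_pathway,
                  type_signatures = sig,
                  approved_drugs = make_approved_drugs(cfg),
                  true_log_hr = cfg$log_hr_resistance,
                  config = unclass(cfg))
    list(expression = feature_matrix(X, normalized = TRUE),
         response = list(ln_ic50 = ln_ic50, auc = auc,
                         agent_meta = agent_meta),
         lineages = lineages,
         truth = truth)
  })
}

# Standardized mean planted linear predictor across agents: the "true
# resistance score" that survival is tied to.
true_resistance_score <- function(X, truth) {
  lp <- X %*% t(truth$true_coefficients)
  s <- rowMeans(lp)
  as.numeric(scale(s))
}

#' Simulate a tumor cohort with clinical outcomes
#'
#' Tumor expression reuses the cell-line panel's cancer-type signatures so
#' that tumor/cell-line concordance is recoverable. Survival follows an
#' exponential proportional-hazards model whose log hazard is
#' `log_hr_resistance` times the standardized true resistance score (the
#' planted linear predictor averaged over agents); censoring is an
#' independent exponential calibrated so that a `censoring_rate` fraction
#' of patients is censored under the null.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_cell_line_panel()].
#' @return A list with `expression` (tumor [feature_matrix()]) and
#'   `clinical` (data frame; includes a `true_score` column for recovery
#'   testing, a synthetic quantity with no real-data counterpart).
#' @export
simulate_tumor_cohort <- function(config, truth) {
  cfg <- config
  if (is.null(truth$type_signatures)) stopf("truth is missing type_signatures")
  with_seed(cfg$seed + 1L, {
    pts <- sim_ids("PT", cfg$n_tumors)
    types <- rownames(truth$type_signatures)
    pt_type <- stats::setNames(
      types[(seq_len(cfg$n_tumors) - 1L) %% length(types) + 1L], pts)
    E <- matrix(stats::rnorm(cfg$n_tumors * cfg$n_lncRNAs),
                cfg$n_tumors, cfg$n_lncRNAs,
                dimnames = list(pts, colnames(truth$type_signatures)))
    E <- E + truth$type_signatures[pt_type, , drop = FALSE]
    score <- true_resistance_score(E, truth)
    haz <- cfg$baseline_hazard * exp(cfg$log_hr_resistance * score)
    t_event <- stats::rexp(cfg$n_tumors, rate = haz)
    if (cfg$censoring_rate > 0) {
      c_rate <- cfg$baseline_hazard * cfg$censoring_rate /
        (1 - cfg$censoring_rate)
      t_cens <- stats::rexp(cfg$n_tumors, rate = c_rate)
    } else {
      t_cens <- rep(Inf, cfg$n_tumors)
    }
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
    approved <- truth$approved_drugs
    treatments <- vapply(pt_type, function(ty) {
      drugs <- unlist(approved[[ty]], use.names = FALSE)
      n_rx <- sample.int(min(3L, length(drugs)), 1L)
      paste(sample(drugs, n_rx), collapse = ";")
    }, character(1))
    clinical <- data.frame(
      patient_id = pts,
      cancer_type = unname(pt_type),
      stage = sample(c("I", "II", "III", "IV"), cfg$n_tumors, replace = TRUE),
      age = sample(30:90, cfg$n_tumors, replace = TRUE),
      os_time = os_time,
      os_event = os_event,
      treatments = unname(treatments),
      true_score = score,
      stringsAsFactors = FALSE)
    list(expression = feature_matrix(E, normalized = TRUE),
         clinical = validate_clinical(clinical))
  })
}

#' Simulate multi-omic panels and gene sets
#'
#' Produces copy-number segments and methylation beta values that carry the
#' same cancer-type signatures as expression (so cross-modality
#' concordance holds), a protein-coding expression matrix in which each
#' planted gene set's members are generated from a partner lncRNA
#' (`pcg = loading * lncRNA + sqrt(1 - loading^2) * noise`, so the set is
#' enriched at the top of that lncRNA's co-expression ranking), and a
#' GMT-writable gene-set collection of the planted sets plus random decoys.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_cell_line_panel()].
#' @param samples Sample identifiers to generate omics for; defaults to the
#'   cell-line panel layout of `config`.
#' @param lineages Named cancer-type vector for `samples`.
#' @param loading Co-expression loading of planted set members, in \[0, 1\].
#' @param set_size Members per planted set.
#' @param n_decoy_sets Random gene sets added alongside the planted ones.
#' @return A list with `segments` (SEG-like data frame), `regions` (lncRNA
#'   interval table), `betas` (samples x probes matrix), `probe_map`,
#'   `pcg_expression` ([feature_matrix()]), `gene_sets` (named list) and
#'   `planted_gene_sets` (set -> members + partner lncRNA).
#' @export
simulate_multiomics_and_genesets <- function(config, truth,
                                             samples = NULL, lineages = NULL,
                                             loading = 0.8, set_size = 30,
                                             n_decoy_sets = 10) {
  cfg <- config
  if (cfg$n_pathways > cfg$n_pcgs) stopf("n_pathways must be <= n_pcgs")
  if (set_size * cfg$n_pathways > cfg$n_pcgs)
    stopf("planted sets exceed the protein-coding universe")
  with_seed(cfg$seed + 2L, {
    if (is.null(samples)) {
      samples <- sim_ids("CL", cfg$n_cell_lines)
      types <- rownames(truth$type_signatures)
      lineages <- stats::setNames(
        types[(seq_along(samples) - 1L) %% length(types) + 1L], samples)
    }
    lncs <- colnames(truth$type_signatures)
    shift <- truth$type_signatures[lineages[samples], , drop = FALSE]

    # lncRNA genomic regions on one synthetic chromosome, 0-based half-open
    regions <- data.frame(feature_id = lncs, chrom = "chrS",
                          start = (seq_along(lncs) - 1L) * 1000L,
                          end = (seq_along(lncs) - 1L) * 1000L + 500L,
                          stringsAsFactors = FALSE)
    cnv <- 0.5 * shift +
      matrix(stats::rnorm(length(samples) * length(lncs), sd = 0.2),
             length(samples), length(lncs))
    segments <- data.frame(
      sample = rep(samples, each = length(lncs)),
      chrom = "chrS",
      start = rep(regions$start, length(samples)),
      end = rep(regions$end, length(samples)),
      value = as.numeric(t(cnv)),
      stringsAsFactors = FALSE)

    probes <- sprintf("cg%05d", seq_along(lncs))
    probe_map <- data.frame(probe_id = probes, feature_id = lncs,
                            stringsAsFactors = FALSE)
    betas <- stats::plogis(0.3 * shift +
      matrix(stats::rnorm(length(samples) * length(lncs), sd = 0.3),
             length(samples), length(lncs)))
    dimnames(betas) <- list(samples, probes)

    pcgs <- sim_ids("PCG", cfg$n_pcgs)
    P <- matrix(stats::rnorm(length(samples) * cfg$n_pcgs),
                length(samples), cfg$n_pcgs, dimnames = list(samples, pcgs))
    # one planted co-expressed set per pathway, partnered with a predictive
    # lncRNA of an agent in that pathway
    planted <- list()
    lnc_expr <- matrix(stats::rnorm(length(samples) * length(lncs)),
                       length(samples), length(lncs),
                       dimnames = list(samples, lncs)) + shift
    free <- seq_len(cfg$n_pcgs)
    for (i in seq_len(cfg$n_pathways)) {
      pw <- sim_ids("PATH", cfg$n_pathways)[i]
      ag <- names(truth$agent_pathway)[truth$agent_pathway == pw][1]
      partner <- colnames(truth$true_coefficients)[
        which(truth$true_coefficients[ag, ] != 0)[1]]
      members <- pcgs[free[seq_len(set_size)]]
      free <- free[-seq_len(set_size)]
      z <- lnc_expr[, partner]
      P[, members] <- loading * z +
        sqrt(max(0, 1 - loading^2)) *
          matrix(stats::rnorm(length(samples) * set_size),
                 length(samples), set_size)
      planted[[sprintf("PLANTED_%s", pw)]] <-
        list(members = members, partner = partner, loading = loading)
    }
    sets <- lapply(planted, `[[`, "members")
    for (i in seq_len(n_decoy_sets))
      sets[[sprintf("DECOY_%02d", i)]] <- sample(pcgs, set_size)
    list(segments = segments, regions = regions,
         betas = betas, probe_map = probe_map,
         lnc_expression = feature_matrix(lnc_expr, normalized = TRUE),
         pcg_expression = feature_matrix(P, normalized = TRUE),
         gene_sets = sets, planted_gene_sets = planted)
  })
}

#' Write a simulated study to disk
#'
#' Emits the TSV/GMT/JSON files of a simulated panel + cohort so the
#' pipeline can be driven from files (and from the command line).
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @return Invisibly, the named vector of files written.
#' @export
write_simulation <- function(dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_cell_line_panel(config)
  cohort <- simulate_tumor_cohort(config, panel$truth)
  omics <- simulate_multiomics_and_genesets(config, panel$truth)
  p <- function(f) file.path(dir, f)
  write_feature_matrix(panel$expression, p("cell_expression.tsv"))
  write_feature_matrix(cohort$expression, p("tumor_expression.tsv"))
  ic <- data.frame(cell_line = rownames(panel$response$ln_ic50),
                   panel$response$ln_ic50, check.names = FALSE)
  write_tsv(ic, p("ln_ic50.tsv"))
  au <- data.frame(cell_line = rownames(panel$response$auc),
                   panel$response$auc, check.names = FALSE)
  write_tsv(au, p("auc.tsv"))
  write_tsv(panel$response$agent_meta, p("agent_meta.tsv"))
  write_tsv(data.frame(sample = names(panel$lineages),
                       cancer_type = unname(panel$lineages)),
            p("cell_lineages.tsv"))
  write_tsv(cohort$clinical, p("clinical.tsv"))
  write_tsv(omics$segments, p("cnv_segments.seg"))
  write_tsv(omics$regions, p("lnc_regions.tsv"))
  write_gmt(omics$gene_sets, p("gene_sets.gmt"))
  truth <- panel$truth
  truth$type_signatures <- NULL  # large; regenerable from config
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c("cell_expression.tsv", "tumor_expression.tsv", "ln_ic50.tsv",
             "auc.tsv", "agent_meta.tsv", "cell_lineages.tsv",
             "clinical.tsv", "cnv_segments.seg", "lnc_regions.tsv",
             "gene_sets.gmt", "ground_truth.json")
  invisible(stats::setNames(file.path(dir, files), files))
}
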