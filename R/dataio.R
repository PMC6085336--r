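#' Construct a feature matrix
#'
#' Samples-by-features container used throughout the pipeline for lncRNA or
#' protein-coding expression, mapped copy-number values and summarized
#' methylation. Rows are samples, columns are features; both must carry
#' unique identifiers.
#'
#' @param values Numeric matrix, samples x features, with row and column
#'   names set to sample and feature identifiers.
#' @param normalized Logical flag; `TRUE` marks a matrix that has already
#'   been log-transformed and per-feature z-scored.
#' @return An object of class `feature_matrix` (a numeric matrix with a
#'   `normalized` attribute).
#' @export
feature_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stopf("feature matrix requires sample (row) and feature (column) names")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate sample identifiers")
  if (anyDuplicated(colnames(values)))
    stopf("duplicate feature identifiers")
  structure(values, normalized = isTRUE(normalized),
            class = c("feature_matrix", class(values)))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (%s)\n",
              nrow(x), ncol(x),
              if (is_normalized(x)) "normalized" else "raw"))
  invisible(x)
}

#' @rdname feature_matrix
#' @param x Object to test / query.
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

as_fm_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "normalized") <- NULL
  y
}

#' Log-transform and z-score an expression matrix
#'
#' Applies `ln(x + pseudocount)` and then z-scores each feature across
#' samples using the sample standard deviation (n - 1 denominator), the
#' normalization applied to every expression panel before modeling.
#' Constant features cannot be scaled and are set to all-zero with a
#' warning.
#'
#' @param raw A non-negative [feature_matrix()] of raw expression.
#' @param pseudocount Value added before the log; default 1.
#' @return A normalized `feature_matrix`.
#' @export
normalize_expression <- function(raw, pseudocount = 1) {
  if (is_normalized(raw))
    stopf("matrix is already normalized; refusing to normalize twice")
  v <- as_fm_matrix(raw)
  if (anyNA(v)) stopf("raw expression contains missing values")
  if (any(v < 0)) stopf("raw expression must be non-negative")
  lg <- log(v + pseudocount)
  mu <- colMeans(lg)
  sdv <- apply(lg, 2, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  z <- sweep(lg, 2, mu)
  z[, !const] <- sweep(z[, !const, drop = FALSE], 2, sdv[!const], "/")
  if (any(const)) {
    z[, const] <- 0
    warnf("%d constant feature(s) set to zero: %s", sum(const),
          paste(utils::head(colnames(v)[const], 5), collapse = ", "))
  }
  feature_matrix(z, normalized = TRUE)
}

#' Map copy-number segments onto feature regions
#'
#' Computes, for every (sample, region) pair, the overlap-length-weighted
#' mean of segment values across the region, the standard reduction of
#' SNP-array segmentations to per-gene copy-number calls. Coordinates are
#' 0-based half-open in both inputs. Regions with no overlapping segment
#' for a sample are `NA`.
#'
#' @param segments Data frame with columns `sample`, `chrom`, `start`,
#'   `end`, `value`.
#' @param regions Data frame with columns `feature_id`, `chrom`, `start`,
#'   `end`.
#' @return A `feature_matrix` (samples x regions) with a `coverage`
#'   attribute holding the fraction of each region covered by segments.
#' @export
map_segments_to_regions <- function(segments, regions) {
  need_s <- c("sample", "chrom", "start", "end", "value")
  need_r <- c("feature_id", "chrom", "start", "end")
  if (!all(need_s %in% names(segments))) stopf("segments missing columns")
  if (!all(need_r %in% names(regions))) stopf("regions missing columns")
  if (any(segments$start >= segments$end) || any(regions$start >= regions$end))
    stopf("malformed interval: start must be < end (0-based half-open)")
  samples <- unique(segments$sample)
  feats <- as.character(regions$feature_id)
  # 0-based half-open -> 1-based closed for IRanges
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start + 1L, segments$end))
  hits <- GenomicRanges::findOverlaps(seg_gr, reg_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ow <- GenomicRanges::width(GenomicRanges::pintersect(seg_gr[qh], reg_gr[sh]))
  out <- matrix(NA_real_, length(samples), length(feats),
                dimnames = list(samples, feats))
  cov <- matrix(0, length(samples), length(feats),
                dimnames = list(samples, feats))
  si <- match(segments$sample[qh], samples)
  key <- paste(si, sh)
  wsum <- tapply(ow, key, sum)
  vsum <- tapply(ow * segments$value[qh], key, sum)
  idx <- do.call(rbind, lapply(strsplit(names(wsum), " "), as.integer))
  out[idx] <- as.numeric(vsum / wsum)
  rw <- regions$end - regions$start
  cov[idx] <- as.numeric(wsum) / rw[idx[, 2]]
  fm <- feature_matrix(out)
  attr(fm, "coverage") <- cov
  fm
}

#' Summarize methylation probes to features
#'
#' Unweighted mean of the beta values of all probes mapped to a feature;
#' features with no mapped probe are absent from the result.
#'
#' @param betas Numeric matrix of beta values, samples x probes, all in
#'   \[0, 1\].
#' @param probe_map Data frame with columns `probe_id`, `feature_id`.
#' @return A `feature_matrix` (samples x features).
#' @export
summarize_probes <- function(betas, probe_map) {
  if (anyNA(betas) || any(betas < 0 | betas > 1))
    stopf("beta values must lie in [0, 1]")
  probe_map <- probe_map[probe_map$probe_id %in% colnames(betas), , drop = FALSE]
  feats <- unique(as.character(probe_map$feature_id))
  out <- matrix(NA_real_, nrow(betas), length(feats),
                dimnames = list(rownames(betas), feats))
  for (f in feats) {
    pr <- probe_map$probe_id[probe_map$feature_id == f]
    out[, f] <- rowMeans(betas[, pr, drop = FALSE])
  }
  feature_matrix(out)
}

# ---- TSV / GMT / JSON io ----------------------------------------------------

#' Read and write pipeline file formats
#'
#' Expression matrices are stored features x samples with a header row of
#' sample identifiers; drug-response and clinical tables as plain TSV; gene
#' sets as standard GMT (name, description, members); ground truth and
#' models as JSON.
#'
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @name lncgx-io
NULL

#' @rdname lncgx-io
#' @export
write_feature_matrix <- function(fm, path) {
  m <- t(as_fm_matrix(fm))
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname lncgx-io
#' @param normalized Flag to set on the matrix read back.
#' @export
read_feature_matrix <- function(path, normalized = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  feature_matrix(t(m), normalized = normalized)
}

#' @rdname lncgx-io
#' @param df A data frame (clinical table, pair table, segments, ...).
#' @export
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  lc <- vapply(df, is.list, logical(1))
  df[lc] <- lapply(df[lc], function(col)
    vapply(col, paste, character(1), collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname lncgx-io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname lncgx-io
#' @param sets Named list of character vectors (gene sets).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname lncgx-io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  validate_gene_sets(sets)
}

#' Validate a gene-set collection
#'
#' @param sets Named list of character vectors.
#' @return The validated list, members de-duplicated within each set.
#' @export
validate_gene_sets <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("gene sets must be named")
  if (any(lengths(sets) == 0)) stopf("empty gene set")
  lapply(sets, unique)
}

#' Validate a clinical table
#'
#' Checks the column contract shared by the survival and patient-prediction
#' stages: non-negative times, 0/1 event indicators.
#'
#' @param clinical Data frame with columns `patient_id`, `cancer_type`,
#'   `stage`, `age`, `os_time`, `os_event` and optionally `treatments`
#'   (semicolon-separated drug names).
#' @return The validated data frame.
#' @export
validate_clinical <- function(clinical) {
  need <- c("patient_id", "cancer_type", "stage", "age", "os_time", "os_event")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) stopf("clinical table missing: %s", paste(miss, collapse = ", "))
  if (any(clinical$os_time < 0)) stopf("negative survival times")
  if (!all(clinical$os_event %in% c(0, 1))) stopf("os_event must be 0/1")
  if (anyDuplicated(clinical$patient_id)) stopf("duplicate patient identifiers")
  clinical
}
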