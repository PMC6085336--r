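# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. A NULL seed leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of child seeds from a master seed so independent stages do
# not share RNG streams. Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

noticef <- function(fmt, ...) message(sprintf(fmt, ...))

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x <= 0 || x != round(x))
    stopf("'%s' must be a single positive integer, got %s", name,
          paste(x, collapse = ","))
  invisible(as.integer(x))
}

# Row-bind a list of data frames, tolerating NULL entries; NULL when empty.
rbind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Pearson AUROC via the rank-sum (Mann-Whitney) identity; used for planted
# vs null feature discrimination checks.
rank_auroc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  n1 <- length(scores_pos)
  n2 <- length(scores_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
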