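# Small shared helpers. None exported.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cumulative bp offset per chromosome, so that multi-chromosome coordinates
# can be collapsed onto a single sorted axis for findInterval() lookups.
chrom_offsets <- function(chrom_lengths) {
  offs <- cumsum(c(0, as.numeric(chrom_lengths[-length(chrom_lengths)])))
  names(offs) <- names(chrom_lengths)
  offs
}

stopifnot_scalar_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", what), call. = FALSE)
  invisible(x)
}

# Stratified fold assignment: each class is split as evenly as possible.
# Errors if any fold ends up without both classes.
stratified_folds <- function(labels, n_folds) {
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  tab <- table(fold, labels)
  if (any(tab == 0))
    stop("stratification error: a fold lacks one of the classes", call. = FALSE)
  fold
}

# Draw from a beta distribution parameterized by mean and concentration.
rbeta_mc <- function(n, mean, concentration) {
  stats::rbeta(n, shape1 = mean * concentration,
               shape2 = (1 - mean) * concentration)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
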