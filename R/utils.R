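# Internal helpers shared across modules.

#' @noRd
stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# Deterministic per-stage seed derivation: all randomness in the package
# flows from one user-supplied seed; sub-seeds for folds/specimens are
# derived with a fixed affine step modulo 2^31 - 1 so they stay valid
# 32-bit integers and never collide for offsets < 104729.
#' @noRd
derive_seed <- function(seed, offset) {
  stop_if(!is.numeric(seed) || length(seed) != 1L || !is.finite(seed),
          "`seed` must be a single finite number")
  as.integer((abs(seed) + 104729 * offset) %% 2147483647)
}

# Evaluate `code` under a local RNG state; the caller's .Random.seed is
# untouched.
#' @noRd
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' @noRd
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

# Stratified index split: returns logical vector, TRUE = second part
# (e.g. calibration), with ceiling(fraction * n_class) per class.
#' @noRd
stratified_holdout <- function(labels, fraction, seed) {
  labels <- as.factor(labels)
  take <- logical(length(labels))
  local_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_take <- floor(fraction * length(idx))
      if (n_take > 0L) take[sample(idx, n_take)] <- TRUE
    }
  })
  take
}

# Split the feature columns from the label column of a feature table.
#' @noRd
feature_matrix <- function(table) {
  stopifnot(is.data.frame(table))
  cols <- setdiff(names(table), "label")
  as.matrix(table[, cols, drop = FALSE])
}

#' @noRd
has_labels <- function(table) "label" %in% names(table)
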