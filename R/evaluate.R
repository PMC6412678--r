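# Evaluation protocol: stratified k-fold cross-validation over conformal
# predictors, forced-prediction accuracy, calibration (validity) and
# efficiency curves, confidence/credibility summaries, and a PCA view
# of the feature space.

#' Stratified cross-validation of a conformal predictor
#'
#' Splits the labelled feature table into \code{n_folds} stratified
#' folds (per-class fold sizes differ by at most 1), and for each fold
#' fits an ICP or ACP on the remaining folds and computes conformal
#' p-values for the held-out test fold. Every sample is a test case
#' exactly once.
#'
#' @param table labelled feature table.
#' @param framework \code{"icp"} or \code{"acp"}.
#' @param spec an \code{\link{underlying_spec}}.
#' @param n_folds number of CV folds (default 10).
#' @param seed integer seed for fold assignment and per-fold models.
#' @param calib_fraction ICP calibration fraction (ignored for ACP).
#' @param K ACP fold count (ignored for ICP).
#' @return An object of class \code{cv_result}: \code{pvalues} (matrix
#'   [samples x labels], original row order), \code{label} (true
#'   labels), \code{fold} (test-fold index per sample), and metadata.
#' @export
cross_validate <- function(table, framework = c("icp", "acp"),
                           spec = underlying_spec(), n_folds = 10,
                           seed = 1, calib_fraction = 1 / 3, K = 5) {
  framework <- match.arg(framework)
  stopifnot(is.data.frame(table))
  stop_if(!has_labels(table), "feature table has no `label` column")
  stop_if(!is_count(n_folds, 2L), "`n_folds` must be an integer >= 2")
  y <- droplevels(factor(table$label))
  counts <- base::table(y)
  stop_if(any(counts < n_folds),
          "class(es) with fewer samples than folds: ",
          paste(names(counts)[counts < n_folds], collapse = ", "))
  # stratified fold assignment: within each class, shuffle then deal
  # round-robin so per-class fold sizes differ by <= 1
  fold_of <- integer(nrow(table))
  local_seed(derive_seed(seed, 0L), {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  pvals <- matrix(NA_real_, nrow = nrow(table), ncol = nlevels(y),
                  dimnames = list(NULL, levels(y)))
  for (f in seq_len(n_folds)) {
    test <- fold_of == f
    train_tab <- table[!test, , drop = FALSE]
    fold_seed <- derive_seed(seed, f)
    model <- if (framework == "icp") {
      icp_fit(train_tab, spec, calib_fraction = calib_fraction,
              seed = fold_seed)
    } else {
      acp_fit(train_tab, spec, K = K, seed = fold_seed)
    }
    pv <- if (framework == "icp") {
      icp_pvalues(model, table[test, , drop = FALSE])
    } else {
      acp_pvalues(model, table[test, , drop = FALSE])
    }
    pvals[test, colnames(pv)] <- pv
  }
  structure(list(pvalues = pvals, label = y, fold = fold_of,
                 framework = framework, spec = spec, n_folds = n_folds,
                 seed = as.integer(seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV result: %s-%s, %d folds, %d samples, %d labels\n",
              toupper(x$framework), x$spec$kind, x$n_folds,
              nrow(x$pvalues), ncol(x$pvalues)))
  invisible(x)
}

# forced label per row: argmax p, ties to the lowest label index
forced_labels <- function(pvalues) {
  colnames(pvalues)[max.col(pvalues, ties.method = "first")]
}

#' Forced-prediction accuracy
#'
#' Fraction of test samples whose forced prediction (highest p-value)
#' equals the true label, overall and per CV fold.
#'
#' @param result a \code{\link{cross_validate}} result.
#' @return List with \code{accuracy} (overall fraction),
#'   \code{per_fold} (named vector), and \code{fold_mean} (mean of the
#'   per-fold accuracies).
#' @export
accuracy_forced <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  stop_if(nrow(result$pvalues) == 0L, "empty result")
  hit <- forced_labels(result$pvalues) == as.character(result$label)
  per_fold <- vapply(split(hit, result$fold), mean, numeric(1))
  list(accuracy = mean(hit),
       per_fold = per_fold,
       fold_mean = mean(per_fold))
}

#' Calibration (validity) curve
#'
#' For each significance level epsilon on the grid, the error rate is
#' the fraction of test samples whose prediction region excludes the
#' true label, i.e. whose true-label p-value is <= epsilon. A valid
#' predictor keeps the curve at or below the diagonal (up to sampling
#' noise).
#'
#' @param result a \code{\link{cross_validate}} result.
#' @param epsilon_grid significance levels in (0, 1); default
#'   0.01..0.99 step 0.01.
#' @return data.frame with columns \code{epsilon} and \code{error_rate}.
#' @export
calibration_curve <- function(result, epsilon_grid = seq(0.01, 0.99, 0.01)) {
  stopifnot(inherits(result, "cv_result"))
  stop_if(any(epsilon_grid <= 0 | epsilon_grid >= 1),
          "epsilon grid must lie in (0, 1)")
  p_true <- result$pvalues[cbind(seq_len(nrow(result$pvalues)),
                                 match(as.character(result$label),
                                       colnames(result$pvalues)))]
  err <- vapply(epsilon_grid, function(eps) mean(p_true <= eps), numeric(1))
  data.frame(epsilon = epsilon_grid, error_rate = err)
}

#' Efficiency curve (mean prediction-set size)
#'
#' For each significance level, the mean number of labels in the
#' prediction region over all test samples. By region nesting the curve
#' is non-increasing in epsilon; below every p-value floor it equals
#' the number of classes.
#'
#' @inheritParams calibration_curve
#' @return data.frame with columns \code{epsilon} and
#'   \code{mean_set_size}.
#' @export
efficiency_curve <- function(result, epsilon_grid = seq(0.01, 0.99, 0.01)) {
  stopifnot(inherits(result, "cv_result"))
  stop_if(any(epsilon_grid <= 0 | epsilon_grid >= 1),
          "epsilon grid must lie in (0, 1)")
  sizes <- vapply(epsilon_grid,
                  function(eps) mean(rowSums(result$pvalues > eps)),
                  numeric(1))
  data.frame(epsilon = epsilon_grid, mean_set_size = sizes)
}

#' Summarise confidence and credibility over a CV run
#'
#' Per-sample confidence (1 minus the second-highest p-value) and
#' credibility (highest p-value) are computed for every test case and
#' summarised as mean and standard deviation.
#'
#' @param result a \code{\link{cross_validate}} result.
#' @return data.frame with rows \code{confidence} and
#'   \code{credibility} and columns \code{mean}, \code{sd}.
#' @export
summarize_indicators <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  n <- nrow(result$pvalues)
  stop_if(n == 0L, "empty result")
  top2 <- t(apply(result$pvalues, 1L, function(p)
    sort(p, decreasing = TRUE)[1:2]))
  conf <- 1 - top2[, 2L]
  cred <- top2[, 1L]
  sd0 <- function(x) {
    if (length(x) < 2L) {
      message("summarize_indicators: single sample, reporting SD = 0")
      return(0)
    }
    sd(x)
  }
  data.frame(indicator = c("confidence", "credibility"),
             mean = c(mean(conf), mean(cred)),
             sd = c(sd0(conf), sd0(cred)))
}

#' PCA projection of a feature table
#'
#' Mean-centred (optionally standardised) principal-component scores of
#' the feature columns, with per-component variance and explained
#' variance fractions, for visualising class structure in 2D.
#'
#' @param table feature table (label column, if any, carried through).
#' @param n_components number of components to keep (default 2).
#' @param standardize z-score features before the decomposition.
#' @return List with \code{scores} (data.frame, PC columns plus
#'   \code{label} if present), \code{variance} (per-component), and
#'   \code{variance_fraction} (per-component share of total variance).
#' @export
pca_projection <- function(table, n_components = 2, standardize = FALSE) {
  stopifnot(is.data.frame(table))
  stop_if(nrow(table) == 0L, "empty table")
  x <- feature_matrix(table)
  stop_if(n_components > ncol(x),
          "`n_components` exceeds the number of features")
  if (standardize) {
    keep_sd <- apply(x, 2L, sd)
    x[, keep_sd == 0] <- 0          # constant columns contribute nothing
    keep_sd[keep_sd == 0] <- 1
    x <- scale(x, scale = keep_sd)
  }
  pc <- prcomp(x, center = !standardize, scale. = FALSE)
  scores <- as.data.frame(pc$x[, seq_len(n_components), drop = FALSE])
  if (has_labels(table)) scores$label <- table$label
  variance <- pc$sdev^2
  list(scores = scores,
       variance = variance[seq_len(n_components)],
       variance_fraction = (variance / sum(variance))[seq_len(n_components)])
}
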