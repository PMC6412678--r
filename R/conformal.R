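# Inductive and aggregated conformal prediction.
#
# An inductive conformal predictor (ICP) splits the available data into
# a proper-training part, used to fit the underlying scorer, and a
# calibration part, whose nonconformity scores under their true labels
# give the reference distribution for rank-based p-values. For a test
# object and candidate label c with nonconformity alpha_c,
#
#   p_c = (#{calibration alpha_j >= alpha_c} + 1) / (n_cal + 1),
#
# ties counted inclusively. The aggregated conformal predictor (ACP)
# repeats this K times on stratified bootstrap resamples (duplicates
# retained for fitting, out-of-bag examples as calibration) and reports
# the arithmetic mean of the K fold p-values per label.

#' Rank-based conformal p-value
#'
#' The building block shared by ICP and ACP folds: given the
#' calibration nonconformity scores and a test score alpha, returns
#' (#\{calibration scores >= alpha\} + 1) / (n_cal + 1), counting ties
#' inclusively. The smoothed variant splits ties uniformly at random,
#' trading determinism for exact (rather than conservative) validity.
#'
#' @param calib_scores numeric vector of calibration nonconformity
#'   scores (non-empty, finite).
#' @param alpha test nonconformity score(s); vectorised.
#' @param smoothed use random tie-splitting; default \code{FALSE}.
#' @return Numeric vector of p-values in (0, 1], one per alpha.
#' @export
#' @examples
#' conformal_pvalue(c(0.1, 0.2, 0.3), 0.25)  # (1 + 1) / 4 = 0.5
conformal_pvalue <- function(calib_scores, alpha, smoothed = FALSE) {
  stop_if(length(calib_scores) == 0L || any(!is.finite(calib_scores)),
          "calibration scores must be non-empty and finite")
  n <- length(calib_scores)
  vapply(alpha, function(a) {
    if (smoothed) {
      gt <- sum(calib_scores > a)
      eq <- sum(calib_scores == a)
      (gt + runif(1) * (eq + 1)) / (n + 1)
    } else {
      (sum(calib_scores >= a) + 1) / (n + 1)
    }
  }, numeric(1))
}

#' Fit an inductive conformal predictor
#'
#' Splits the labelled feature table (stratified by class) into a
#' proper-training part and a calibration part, fits the underlying
#' scorer on the former, and stores the calibration examples'
#' nonconformity scores under their true labels.
#'
#' @param table labelled feature table (numeric columns + \code{label}).
#' @param spec an \code{\link{underlying_spec}}.
#' @param calib_fraction fraction of each class held out for
#'   calibration; default 1/3 (2/3 proper training).
#' @param seed integer seed governing the split and the model fit.
#' @return An object of class \code{icp_model} with fields
#'   \code{scorer}, \code{calib_scores}, \code{label_set},
#'   \code{calib_idx}.
#' @export
icp_fit <- function(table, spec = underlying_spec(),
                    calib_fraction = 1 / 3, seed = 1) {
  stopifnot(is.data.frame(table))
  stop_if(!has_labels(table), "feature table has no `label` column")
  stop_if(calib_fraction <= 0 || calib_fraction >= 1,
          "`calib_fraction` must lie in (0, 1)")
  y <- droplevels(factor(table$label))
  stop_if(nlevels(y) < 2L, "need at least 2 classes")
  is_cal <- stratified_holdout(y, calib_fraction, seed)
  stop_if(sum(is_cal) < 1L, "degenerate split: empty calibration set")
  stop_if(nlevels(droplevels(y[!is_cal])) < 2L,
          "degenerate split: fewer than 2 classes in proper training set")
  spec$seed <- derive_seed(seed, 1L)
  scorer <- fit_underlying(table[!is_cal, , drop = FALSE], spec)
  calib_scores <- nonconformity(scorer, table[is_cal, , drop = FALSE],
                                as.character(y[is_cal]))
  stop_if(any(!is.finite(calib_scores)), "non-finite calibration scores")
  structure(list(scorer = scorer, calib_scores = unname(calib_scores),
                 label_set = levels(y), calib_idx = which(is_cal),
                 spec = spec, calib_fraction = calib_fraction,
                 seed = as.integer(seed)),
            class = "icp_model")
}

#' @export
print.icp_model <- function(x, ...) {
  cat(sprintf("ICP (%s): %d calibration scores, %d labels\n",
              x$spec$kind, length(x$calib_scores), length(x$label_set)))
  invisible(x)
}

#' Conformal p-values of test objects under an ICP
#'
#' For every candidate label, computes the rank of the object's
#' nonconformity score within the calibration scores (inclusive ties,
#' +1 smoothing in numerator and denominator). Every p-value lies in
#' (0, 1] with floor 1/(n_cal + 1).
#'
#' @param model an \code{\link{icp_fit}} result.
#' @param objects feature rows (data.frame or matrix); a \code{label}
#'   column is ignored.
#' @param smoothed break score ties uniformly at random (exact-validity
#'   variant); default \code{FALSE}, matching the deterministic
#'   inclusive-tie rule.
#' @return Matrix [objects x labels] of p-values, columns named by the
#'   label set.
#' @export
icp_pvalues <- function(model, objects, smoothed = FALSE) {
  stopifnot(inherits(model, "icp_model"))
  prob <- predict_scores(model$scorer, objects)
  out <- matrix(NA_real_, nrow = nrow(prob), ncol = length(model$label_set),
                dimnames = list(NULL, model$label_set))
  for (c_idx in seq_along(model$label_set)) {
    alpha_c <- 1 - prob[, model$label_set[c_idx]]
    out[, c_idx] <- conformal_pvalue(model$calib_scores, alpha_c, smoothed)
  }
  out
}

#' Fit an aggregated conformal predictor
#'
#' Repeats ICP fitting on K stratified bootstrap resamples of the data:
#' each fold's training set is a with-replacement draw of the full size
#' (class proportions preserved, duplicates retained for fitting) and
#' its calibration set is the out-of-bag examples never drawn. A fold
#' whose out-of-bag set is empty or misses a training class is redrawn
#' (bounded retries).
#'
#' @param table labelled feature table.
#' @param spec an \code{\link{underlying_spec}}.
#' @param K number of bootstrap folds; default 5.
#' @param seed integer seed; per-fold seeds are derived from it.
#' @param max_retries redraw budget per fold before failing.
#' @return An object of class \code{acp_model}: \code{folds} (list of
#'   \code{icp_model}-like fold objects), \code{K}, \code{label_set}.
#' @export
acp_fit <- function(table, spec = underlying_spec(), K = 5, seed = 1,
                    max_retries = 20L) {
  stopifnot(is.data.frame(table))
  stop_if(!has_labels(table), "feature table has no `label` column")
  stop_if(!is_count(K), "`K` must be a positive integer")
  y <- droplevels(factor(table$label))
  stop_if(nlevels(y) < 2L, "need at least 2 classes")
  n <- nrow(table)
  folds <- vector("list", K)
  for (k in seq_len(K)) {
    fold <- NULL
    for (try in 0:max_retries) {
      fold_seed <- derive_seed(seed, k * (max_retries + 1L) + try)
      boot_idx <- local_seed(fold_seed, {
        unlist(lapply(levels(y), function(cl) {
          idx <- which(y == cl)
          sample(idx, length(idx), replace = TRUE)
        }), use.names = FALSE)
      })
      oob_idx <- setdiff(seq_len(n), unique(boot_idx))
      if (length(oob_idx) == 0L) next
      if (nlevels(droplevels(y[boot_idx])) < 2L) next
      fold_spec <- spec
      fold_spec$seed <- derive_seed(fold_seed, 1L)
      scorer <- fit_underlying(table[boot_idx, , drop = FALSE], fold_spec)
      calib_scores <- nonconformity(
        scorer, table[oob_idx, , drop = FALSE], as.character(y[oob_idx]))
      fold <- structure(
        list(scorer = scorer, calib_scores = unname(calib_scores),
             label_set = levels(y), calib_idx = oob_idx,
             boot_idx = boot_idx, spec = fold_spec, seed = fold_seed),
        class = "icp_model")
      break
    }
    stop_if(is.null(fold),
            "fold ", k, ": no valid bootstrap resample after ",
            max_retries, " retries")
    folds[[k]] <- fold
  }
  structure(list(folds = folds, K = K, label_set = levels(y),
                 spec = spec, seed = as.integer(seed)),
            class = "acp_model")
}

#' @export
print.acp_model <- function(x, ...) {
  cat(sprintf("ACP (%s): K = %d bootstrap folds, %d labels\n",
              x$spec$kind, x$K, length(x$label_set)))
  invisible(x)
}

#' Aggregated conformal p-values
#'
#' The ACP p-value for each candidate label is the arithmetic mean of
#' the K fold ICP p-values.
#'
#' @param model an \code{\link{acp_fit}} result.
#' @inheritParams icp_pvalues
#' @return Matrix [objects x labels] of aggregated p-values.
#' @export
acp_pvalues <- function(model, objects, smoothed = FALSE) {
  stopifnot(inherits(model, "acp_model"))
  per_fold <- lapply(model$folds, icp_pvalues, objects = objects,
                     smoothed = smoothed)
  Reduce(`+`, per_fold) / model$K
}

#' Prediction region at significance level epsilon
#'
#' The region contains exactly the labels whose p-value strictly
#' exceeds \code{epsilon}. Regions are nested: raising epsilon can only
#' shrink the set.
#'
#' @param pvals named numeric vector of per-label p-values (one row of
#'   an \code{\link{icp_pvalues}} / \code{\link{acp_pvalues}} matrix).
#' @param epsilon significance level in (0, 1).
#' @return Character vector of labels in the region (possibly empty).
#' @export
#' @examples
#' prediction_region(c(C1 = 0.007, C2 = 0.009, C3 = 0.813), 0.05)
prediction_region <- function(pvals, epsilon) {
  stop_if(!is.numeric(epsilon) || length(epsilon) != 1L ||
            epsilon <= 0 || epsilon >= 1,
          "`epsilon` must lie in (0, 1)")
  pvals <- drop_pvals(pvals)
  names(pvals)[pvals > epsilon]
}

# Accept a 1-row p-value matrix or a plain named vector.
drop_pvals <- function(pvals) {
  if (is.matrix(pvals)) {
    stop_if(nrow(pvals) != 1L, "supply one object's p-values at a time")
    pvals <- pvals[1L, ]
  }
  stop_if(length(pvals) == 0L, "empty p-value vector")
  if (is.null(names(pvals))) names(pvals) <- paste0("L", seq_along(pvals))
  pvals
}

#' Forced (point) prediction
#'
#' Returns the single label with the highest p-value, the forced
#' prediction used when a point decision is required regardless of the
#' significance level. Ties are broken towards the lowest label index
#' and reported via a message.
#'
#' @param pvals named numeric vector of per-label p-values.
#' @return The winning label (character scalar).
#' @export
forced_prediction <- function(pvals) {
  pvals <- drop_pvals(pvals)
  win <- which(pvals == max(pvals))
  if (length(win) > 1L) {
    message("forced_prediction: tie among {",
            paste(names(pvals)[win], collapse = ", "),
            "}; choosing the lowest index")
  }
  names(pvals)[win[1L]]
}

#' Confidence and credibility of one prediction
#'
#' Credibility is the highest p-value: near zero it flags a test object
#' atypical of every class. Confidence is 1 minus the second-highest
#' p-value: high confidence means every rival label is implausible, so
#' the forced prediction is informative.
#'
#' @param pvals named numeric vector of p-values for >= 2 labels.
#' @return List with elements \code{confidence} and \code{credibility}.
#' @export
#' @examples
#' confidence_credibility(c(A = 0.1, B = 0.8, C = 0.05))
confidence_credibility <- function(pvals) {
  pvals <- drop_pvals(pvals)
  stop_if(length(pvals) < 2L, "need at least 2 candidate labels")
  sorted <- sort(pvals, decreasing = TRUE)
  list(confidence = 1 - sorted[[2L]], credibility = sorted[[1L]])
}
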