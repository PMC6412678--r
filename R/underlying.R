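# Underlying scorers for conformal prediction.
#
# The nonconformity measure used throughout is 1 minus the scorer's
# estimated class probability, the standard choice for classification.
# Two scorers are provided: an RBF-kernel SVM with Platt-calibrated
# probabilities and a random forest using vote fractions. Both expose a
# common probability interface, so the conformal layer is agnostic to
# the underlying model.

#' Underlying model specification
#'
#' @param kind \code{"svm_rbf"} or \code{"random_forest"}.
#' @param cost SVM penalty parameter C (default 6000).
#' @param gamma SVM RBF kernel width (default 0.001).
#' @param ntree random-forest tree count (default 500).
#' @param standardize z-score the features (fit on the training portion
#'   only) before the model. Defaults to \code{TRUE} for the SVM, whose
#'   fixed kernel width assumes comparable feature scales, and
#'   \code{FALSE} for the scale-invariant random forest.
#' @param seed integer seed for the model fit (Platt-scaling folds,
#'   bootstrap draws of the forest).
#' @return An object of class \code{underlying_spec}.
#' @export
#' @examples
#' underlying_spec("svm_rbf")
#' underlying_spec("random_forest", ntree = 250)
underlying_spec <- function(kind = c("svm_rbf", "random_forest"),
                            cost = 6000, gamma = 0.001, ntree = 500,
                            standardize = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(standardize)) standardize <- kind == "svm_rbf"
  stop_if(cost <= 0 || gamma <= 0, "`cost` and `gamma` must be positive")
  stop_if(!is_count(ntree), "`ntree` must be a positive integer")
  structure(list(kind = kind, cost = cost, gamma = gamma, ntree = ntree,
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "underlying_spec")
}

#' @export
print.underlying_spec <- function(x, ...) {
  detail <- if (x$kind == "svm_rbf") {
    sprintf("C = %g, gamma = %g", x$cost, x$gamma)
  } else {
    sprintf("%d trees", x$ntree)
  }
  cat(sprintf("Underlying model: %s (%s)%s\n", x$kind, detail,
              if (x$standardize) ", standardized features" else ""))
  invisible(x)
}

#' Fit an underlying scorer
#'
#' Fits the model named by \code{spec} on a labelled feature table and
#' returns a scorer whose \code{\link{predict_scores}} method yields a
#' probability-like vector (non-negative, summing to 1) over the label
#' set for any object. Fits are deterministic given \code{spec$seed}.
#'
#' @param train_table data.frame of numeric features with a factor
#'   \code{label} column containing at least 2 classes.
#' @param spec an \code{\link{underlying_spec}}.
#' @return An object of class \code{fitted_scorer}.
#' @export
fit_underlying <- function(train_table, spec = underlying_spec()) {
  stopifnot(is.data.frame(train_table), inherits(spec, "underlying_spec"))
  stop_if(!has_labels(train_table), "training table has no `label` column")
  y <- droplevels(factor(train_table$label))
  stop_if(nlevels(y) < 2L, "training set must contain at least 2 classes")
  x <- feature_matrix(train_table)
  center <- rep(0, ncol(x))
  scale <- rep(1, ncol(x))
  if (spec$standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2L, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    x <- scale(x, center = center, scale = scale)
  }
  fit <- local_seed(spec$seed, {
    if (spec$kind == "svm_rbf") {
      e1071::svm(x, y, kernel = "radial", cost = spec$cost,
                 gamma = spec$gamma, probability = TRUE, scale = FALSE)
    } else {
      randomForest::randomForest(x, y, ntree = spec$ntree)
    }
  })
  structure(list(fit = fit, spec = spec, label_set = levels(y),
                 center = center, scale = scale,
                 feature_names = colnames(x)),
            class = "fitted_scorer")
}

#' Class-probability estimates from a fitted scorer
#'
#' @param scorer a \code{\link{fit_underlying}} result.
#' @param newdata data.frame or matrix of feature rows (a \code{label}
#'   column, if present, is ignored).
#' @return Matrix [objects x labels] of probability estimates, columns
#'   ordered as \code{scorer$label_set}, rows summing to 1.
#' @export
predict_scores <- function(scorer, newdata) {
  stopifnot(inherits(scorer, "fitted_scorer"))
  if (is.data.frame(newdata)) newdata <- feature_matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  stop_if(ncol(newdata) != length(scorer$feature_names),
          "newdata has ", ncol(newdata), " features; scorer expects ",
          length(scorer$feature_names))
  newdata <- scale(newdata, center = scorer$center, scale = scorer$scale)
  colnames(newdata) <- scorer$feature_names
  prob <- if (scorer$spec$kind == "svm_rbf") {
    pred <- predict(scorer$fit, newdata, probability = TRUE)
    attr(pred, "probabilities")
  } else {
    predict(scorer$fit, newdata, type = "prob")
  }
  prob <- prob[, scorer$label_set, drop = FALSE]
  rownames(prob) <- NULL
  prob
}

#' Nonconformity score of a labelled object
#'
#' The nonconformity measure is alpha = 1 - P(label | object) under the
#' fitted scorer, so alpha lies in [0, 1]: 0 for an object the scorer
#' assigns the label with certainty, 1 for an impossible label.
#'
#' @param scorer a \code{\link{fit_underlying}} result.
#' @param object one feature row (data.frame row, named vector, or
#'   matrix with one row per object).
#' @param label candidate label(s), recycled against the rows of
#'   \code{object}.
#' @return Numeric vector of nonconformity scores in [0, 1].
#' @export
nonconformity <- function(scorer, object, label) {
  prob <- predict_scores(scorer, object)
  label <- as.character(label)
  stop_if(!all(label %in% scorer$label_set),
          "unknown label(s): ",
          paste(setdiff(label, scorer$label_set), collapse = ", "))
  label <- rep_len(label, nrow(prob))
  1 - prob[cbind(seq_len(nrow(prob)), match(label, scorer$label_set))]
}
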