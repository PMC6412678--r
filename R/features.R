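# Per-sensor transient features.
#
# Five features summarise each sensor's baseline-corrected response
# R(t): the maximum absolute response, the integral of the response
# over the recorded window, and the maximum absolute exponential moving
# average (EMA) of the first difference at three smoothing factors
# (0.005, 0.05, 0.5). With 16 sensors this yields an 80-dimensional
# feature vector per specimen.

#' Maximum absolute response
#'
#' @param series numeric response series R(t); non-empty.
#' @return \code{max(|R|)}.
#' @export
#' @examples
#' feature_rmax(c(-1, 2, -3))  # 3
feature_rmax <- function(series) {
  stop_if(length(series) == 0L, "empty series")
  max(abs(series))
}

#' Integral response (trapezoid rule)
#'
#' Approximates the signed area between the response curve and the time
#' axis over the full recorded window using the trapezoid rule on a
#' uniform grid with spacing \code{dt}.
#'
#' @param series numeric response series; non-empty.
#' @param dt sample spacing in seconds; > 0.
#' @return Approximate integral of R over the window.
#' @export
#' @examples
#' feature_rint(rep(2, 11), dt = 0.1)  # 2 * 1 s = 2
feature_rint <- function(series, dt) {
  stop_if(length(series) == 0L, "empty series")
  stop_if(!is.numeric(dt) || dt <= 0, "`dt` must be > 0")
  n <- length(series)
  if (n == 1L) return(0)
  dt * (sum(series) - (series[1L] + series[n]) / 2)
}

#' Maximum EMA-smoothed derivative
#'
#' Smooths the first difference d(k) = R(k) - R(k-1) with an exponential
#' moving average y(k) = (1 - a) y(k-1) + a d(k), starting from
#' y(0) = 0, and returns max |y(k)|. Small smoothing factors emphasise
#' the sustained injection transient; a = 1 reduces to the maximum
#' absolute first difference. The recurrence runs over the full series;
#' \code{decimate_to} optionally subsamples the series to a fixed
#' length first (evenly spaced, endpoints kept).
#'
#' @param series numeric response series of length >= 2.
#' @param a smoothing factor in (0, 1].
#' @param decimate_to optional target length for pre-decimation;
#'   \code{NULL} (default) uses the full series.
#' @return \code{max(|y(k)|)} over the smoothed derivative.
#' @export
#' @examples
#' feature_ema_max(c(0, 1, 1), a = 0.5)  # y = (0.5, 0.25) -> 0.5
feature_ema_max <- function(series, a, decimate_to = NULL) {
  stop_if(length(series) < 2L, "series must have at least 2 samples")
  stop_if(!is.numeric(a) || length(a) != 1L || a <= 0 || a > 1,
          "`a` must lie in (0, 1]")
  if (!is.null(decimate_to) && length(series) > decimate_to) {
    stop_if(!is_count(decimate_to, 2L), "`decimate_to` must be >= 2")
    idx <- unique(round(seq(1L, length(series), length.out = decimate_to)))
    series <- series[idx]
  }
  d <- diff(series)
  # y(k) = (1-a) y(k-1) + a d(k) is a first-order IIR filter
  y <- stats::filter(a * d, 1 - a, method = "recursive")
  max(abs(as.numeric(y)))
}

#' Extract the per-sensor feature vector of one recording
#'
#' For each sensor of a baseline-corrected recording, computes the five
#' features in the fixed order rmax, rint, ema_a0.005, ema_a0.05,
#' ema_a0.5, and concatenates them sensor-major (all five features of
#' S1, then S2, ...). A 16-sensor recording therefore yields 80
#' features.
#'
#' @param recording a \code{sensor_recording} with
#'   \code{units = "relative"} (see \code{\link{baseline_correct}}).
#' @param integration_window \code{"full"} (default) integrates over the
#'   whole recorded window; \code{"reaction"} restricts the integral to
#'   the reaction phase.
#' @param decimate_to optional decimation length for the EMA features
#'   (see \code{\link{feature_ema_max}}).
#' @return A named numeric vector of length \code{5 * n_sensors} with
#'   names \code{S<i>_rmax, S<i>_rint, S<i>_ema_a0.005, ...}, carrying
#'   the recording's label as attribute \code{"label"}.
#' @export
extract_features <- function(recording,
                             integration_window = c("full", "reaction"),
                             decimate_to = NULL) {
  stopifnot(inherits(recording, "sensor_recording"))
  stop_if(!identical(recording$units, "relative"),
          "recording must be baseline-corrected first (units 'relative')")
  integration_window <- match.arg(integration_window)
  timing <- recording$timing
  dt <- 1 / timing$sampling_rate
  int_idx <- seq_len(ncol(recording$signal))
  if (integration_window == "reaction") {
    i0 <- floor(timing$sampling_rate * timing$baseline_duration) + 1L
    i1 <- floor(timing$sampling_rate *
                  (timing$baseline_duration + timing$reaction_duration))
    int_idx <- i0:i1
  }
  feats <- lapply(seq_len(nrow(recording$signal)), function(s) {
    r <- recording$signal[s, ]
    c(rmax = feature_rmax(r),
      rint = feature_rint(r[int_idx], dt),
      ema_a0.005 = feature_ema_max(r, 0.005, decimate_to),
      ema_a0.05 = feature_ema_max(r, 0.05, decimate_to),
      ema_a0.5 = feature_ema_max(r, 0.5, decimate_to))
  })
  sensors <- rownames(recording$signal) %||%
    paste0("S", seq_len(nrow(recording$signal)))
  out <- unlist(feats)
  names(out) <- as.vector(t(outer(sensors, names(feats[[1L]]),
                                  paste, sep = "_")))
  stop_if(any(!is.finite(out)), "non-finite feature value")
  attr(out, "label") <- recording$label
  out
}

#' Build a feature table from a list of recordings
#'
#' Applies \code{\link{baseline_correct}} (if needed) and
#' \code{\link{extract_features}} to every recording and assembles the
#' results into a feature table: one row per specimen, uniform feature
#' columns, and a final \code{label} factor column when labels are
#' present.
#'
#' @param recordings list of \code{sensor_recording} objects.
#' @param ... passed to \code{\link{extract_features}}.
#' @return A data.frame of features (plus \code{label} if available).
#' @export
extract_feature_table <- function(recordings, ...) {
  stop_if(length(recordings) == 0L, "no recordings supplied")
  rows <- lapply(recordings, function(rec) {
    if (!identical(rec$units, "relative")) rec <- baseline_correct(rec)
    extract_features(rec, ...)
  })
  nm <- names(rows[[1L]])
  stop_if(!all(vapply(rows, function(r) identical(names(r), nm), logical(1))),
          "recordings produced inconsistent feature names")
  out <- as.data.frame(do.call(rbind, rows))
  labels <- vapply(rows, function(r) attr(r, "label") %||% NA_character_,
                   character(1))
  if (!anyNA(labels)) out$label <- factor(labels)
  rownames(out) <- NULL
  out
}
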