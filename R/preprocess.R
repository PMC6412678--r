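# Preprocessing: voltage-divider readout conversion and baseline
# normalisation of raw sensor traces.

#' Convert voltage readout to sensor resistance
#'
#' MOS sensors are typically read through a voltage divider: the
#' recorded voltage V across a load resistor RL in series with the
#' sensor under supply voltage Vc gives sensor resistance
#' Rs = RL * (Vc - V) / V. Inputs already expressed as resistance can
#' skip this step (see \code{\link{baseline_correct}}).
#'
#' @param recording a \code{sensor_recording} with \code{units = "voltage"}
#'   (a recording without a units field is assumed to be voltage).
#' @param supply_voltage divider supply voltage in volts.
#' @param load_resistance load resistor in ohms.
#' @return The recording with \code{signal} in ohms and
#'   \code{units = "resistance"}.
#' @export
#' @examples
#' rec <- structure(list(signal = matrix(2.5, 1, 4), units = "voltage"),
#'                  class = "sensor_recording")
#' voltage_to_resistance(rec, 5, 10000)$signal[1, 1]  # 10000 ohms
voltage_to_resistance <- function(recording, supply_voltage,
                                  load_resistance) {
  stopifnot(inherits(recording, "sensor_recording"))
  stop_if(!is.null(recording$units) && recording$units != "voltage",
          "recording is already in '", recording$units, "' units")
  stop_if(supply_voltage <= 0 || load_resistance <= 0,
          "supply voltage and load resistance must be positive")
  v <- recording$signal
  bad <- which(v <= 0 | v >= supply_voltage, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "voltage out of (0, %g) V at sensor %s, sample index %d (value %g V)",
      supply_voltage, rownames(v)[bad[1L, 1L]] %||% bad[1L, 1L],
      bad[1L, 2L], v[bad[1L, , drop = FALSE]]), call. = FALSE)
  }
  recording$signal <- load_resistance * (supply_voltage - v) / v
  recording$units <- "resistance"
  recording
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline-normalise a recording
#'
#' Converts each sensor trace to the dimensionless relative response
#' R(t) = (Rsample(t) - Rbaseline) / Rbaseline, where Rbaseline is that
#' sensor's mean over the pre-injection baseline window (the first
#' \code{baseline_duration} seconds declared in the recording's timing).
#' This removes unit and baseline-level differences between sensors and
#' measurement sessions; no further drift compensation is applied.
#'
#' @param recording a \code{sensor_recording} in resistance (or any
#'   positive signal) units, with a \code{timing_config} attached.
#' @return A \code{sensor_recording} with \code{units = "relative"}; the
#'   baseline-window mean of every corrected trace is ~0.
#' @export
#' @examples
#' sig <- make_signatures(2, 2, seed = 1, noise_sd = 0)
#' rec <- simulate_recording(sig, 1, timing_config(sampling_rate = 1), seed = 1)
#' cor <- baseline_correct(rec)
#' range(cor$signal[, 1:20])  # ~0 during the baseline window
baseline_correct <- function(recording) {
  stopifnot(inherits(recording, "sensor_recording"),
            inherits(recording$timing, "timing_config"))
  stop_if(identical(recording$units, "relative"),
          "recording is already baseline-corrected")
  n_base <- floor(recording$timing$sampling_rate *
                    recording$timing$baseline_duration)
  stop_if(n_base < 1L, "baseline window contains no samples")
  base <- rowMeans(recording$signal[, seq_len(n_base), drop = FALSE])
  zero <- which(base == 0)
  stop_if(length(zero) > 0L,
          "zero baseline mean for sensor ",
          paste(rownames(recording$signal)[zero] %||% zero, collapse = ", "),
          "; cannot normalise")
  recording$signal <- sweep(sweep(recording$signal, 1L, base, "-"),
                            1L, base, "/")
  recording$units <- "relative"
  recording
}
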