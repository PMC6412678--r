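# Synthetic e-nose data generator.
#
# Emulates the measurement cycle of a metal-oxide-semiconductor (MOS)
# sensor array: a pre-injection baseline phase, a reaction phase in
# which each sensor's resistance rises saturatingly towards a
# class-specific relative amplitude, and a cleaning phase in which it
# decays back to baseline. First-order exponential kinetics are used for
# both rise and decay; within-class variability is multiplicative
# lognormal on the amplitudes, and each recording carries additive
# Gaussian noise plus a random linear baseline drift.

#' Measurement-cycle timing
#'
#' Defines the three phases of one e-nose measurement: a pre-injection
#' baseline window, a reaction window after sample-gas injection, and
#' the start of the cleaning window. The defaults mirror a typical MOS
#' array protocol (20 s baseline, 200 s reaction, 120 s cleaning) but at
#' a reduced 10 Hz sampling rate; the transient features extracted
#' downstream depend on curve shape, not on raw sample density, so a
#' lower rate keeps simulated datasets small. Set
#' \code{sampling_rate = 100} to reproduce the full-rate protocol.
#'
#' @param sampling_rate samples per second (Hz); > 0.
#' @param baseline_duration pre-injection phase length in seconds; > 0.
#' @param reaction_duration reaction phase length in seconds; > 0.
#' @param cleaning_duration recorded cleaning phase length in seconds; > 0.
#' @return An object of class \code{timing_config}.
#' @export
#' @examples
#' timing_config()                  # 340 s cycle at 10 Hz
#' timing_config(sampling_rate = 1) # coarse grid for quick tests
timing_config <- function(sampling_rate = 10,
                          baseline_duration = 20,
                          reaction_duration = 200,
                          cleaning_duration = 120) {
  vals <- c(sampling_rate, baseline_duration, reaction_duration,
            cleaning_duration)
  stop_if(any(!is.finite(vals)) || any(vals <= 0),
          "all timing parameters must be strictly positive")
  structure(
    list(sampling_rate = sampling_rate,
         baseline_duration = baseline_duration,
         reaction_duration = reaction_duration,
         cleaning_duration = cleaning_duration,
         total_duration = baseline_duration + reaction_duration +
           cleaning_duration),
    class = "timing_config")
}

#' @export
print.timing_config <- function(x, ...) {
  cat(sprintf("Timing: %g + %g + %g s (baseline/reaction/cleaning) at %g Hz\n",
              x$baseline_duration, x$reaction_duration, x$cleaning_duration,
              x$sampling_rate))
  invisible(x)
}

#' Class-specific sensor response signatures
#'
#' Draws a set of per-class, per-sensor relative response amplitudes
#' together with sensor kinetics and noise parameters. Each sensor gets
#' a common base amplitude; class rows are offset from it by Gaussian
#' deviates scaled by \code{separation}, so the mean pairwise distance
#' between class rows grows linearly with \code{separation} and
#' \code{separation = 0} makes all classes identical (the exchangeable
#' null used by validity tests).
#'
#' @param n_classes number of classes (>= 2).
#' @param n_sensors number of sensors (>= 1).
#' @param separation non-negative scale of between-class amplitude
#'   differences, in units of the within-sensor base amplitude spread.
#' @param seed integer seed; the signature set is fully reproducible.
#' @param within_class_cv coefficient of variation of the lognormal
#'   specimen-to-specimen amplitude perturbation.
#' @param noise_sd additive measurement-noise SD, in signal units.
#' @param drift_slope_sd SD of the per-recording linear baseline drift
#'   slope, in signal units per second.
#' @return An object of class \code{signature_set} with fields
#'   \code{amplitude} (class x sensor matrix), \code{rise_tau} and
#'   \code{decay_tau} (per-sensor time constants, seconds), and the
#'   noise parameters above.
#' @export
#' @examples
#' sig <- make_signatures(10, 16, separation = 1, seed = 7)
#' dim(sig$amplitude)
make_signatures <- function(n_classes, n_sensors, separation = 1, seed = 1,
                            within_class_cv = 0.08,
                            noise_sd = 0.005,
                            drift_slope_sd = 1e-4) {
  stop_if(!is_count(n_classes, 2L), "`n_classes` must be an integer >= 2")
  stop_if(!is_count(n_sensors, 1L), "`n_sensors` must be an integer >= 1")
  stop_if(!is.numeric(separation) || separation < 0,
          "`separation` must be >= 0")
  stop_if(within_class_cv < 0 || noise_sd < 0 || drift_slope_sd < 0,
          "variability parameters must be >= 0")
  local_seed(seed, {
    base <- runif(n_sensors, 0.5, 1.5)
    delta <- matrix(rnorm(n_classes * n_sensors, sd = 0.25),
                    nrow = n_classes)
    amplitude <- sweep(separation * delta, 2L, base, "+")
    rise_tau <- runif(n_sensors, 5, 20)
    decay_tau <- runif(n_sensors, 20, 60)
    dimnames(amplitude) <- list(paste0("C", seq_len(n_classes)),
                                paste0("S", seq_len(n_sensors)))
    structure(
      list(n_classes = n_classes, n_sensors = n_sensors,
           amplitude = amplitude, rise_tau = rise_tau,
           decay_tau = decay_tau, within_class_cv = within_class_cv,
           noise_sd = noise_sd, drift_slope_sd = drift_slope_sd,
           separation = separation, seed = as.integer(seed)),
      class = "signature_set")
  })
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf(
    "Signature set: %d classes x %d sensors, separation %g, cv %g\n",
    x$n_classes, x$n_sensors, x$separation, x$within_class_cv))
  invisible(x)
}

# Noiseless phase response (relative units, 0 at baseline) for one
# sensor: saturating exponential rise during reaction, exponential decay
# during cleaning, continuous at the phase boundary.
phase_response <- function(t, timing, amplitude, rise_tau, decay_tau) {
  t0 <- timing$baseline_duration
  t1 <- t0 + timing$reaction_duration
  resp <- numeric(length(t))
  react <- t >= t0 & t < t1
  resp[react] <- amplitude * (1 - exp(-(t[react] - t0) / rise_tau))
  clean <- t >= t1
  peak <- amplitude * (1 - exp(-timing$reaction_duration / rise_tau))
  resp[clean] <- peak * exp(-(t[clean] - t1) / decay_tau)
  resp
}

#' Simulate one sensor-array recording
#'
#' Produces the raw multichannel time series for one specimen of a given
#' class: per-sensor baseline level times (1 + relative response), plus
#' linear drift and additive Gaussian noise. The specimen's effective
#' amplitudes are the class amplitudes perturbed by a mean-one lognormal
#' factor with coefficient of variation \code{within_class_cv}.
#'
#' @param signatures a \code{\link{make_signatures}} object.
#' @param class_id class index in \code{1:n_classes} or a class label
#'   such as \code{"C3"}.
#' @param timing a \code{\link{timing_config}}.
#' @param seed integer seed for this recording.
#' @param baseline per-sensor baseline signal level (recycled); the
#'   baseline normalisation step divides it out.
#' @param specimen_id optional identifier stored on the recording.
#' @return An object of class \code{sensor_recording}: \code{signal}
#'   (sensor x time matrix), \code{time} (seconds), \code{timing},
#'   \code{units} (\code{"resistance"}), \code{label}, \code{specimen_id}.
#' @export
#' @examples
#' sig <- make_signatures(3, 4, seed = 1)
#' rec <- simulate_recording(sig, 2, timing_config(sampling_rate = 1), seed = 9)
#' dim(rec$signal)
simulate_recording <- function(signatures, class_id,
                               timing = timing_config(), seed = 1,
                               baseline = 1, specimen_id = NULL) {
  stopifnot(inherits(signatures, "signature_set"),
            inherits(timing, "timing_config"))
  if (is.character(class_id)) {
    class_id <- match(class_id, rownames(signatures$amplitude))
  }
  stop_if(is.na(class_id) || !is_count(class_id) ||
            class_id > signatures$n_classes,
          "unknown `class_id`")
  ns <- signatures$n_sensors
  n <- round(timing$sampling_rate * timing$total_duration)
  t <- (seq_len(n) - 1L) / timing$sampling_rate
  baseline <- rep_len(baseline, ns)
  cv <- signatures$within_class_cv
  sdlog <- sqrt(log(1 + cv^2))
  local_seed(seed, {
    # mean-one lognormal amplitude perturbation per sensor
    a_eff <- signatures$amplitude[class_id, ] *
      exp(rnorm(ns, mean = -sdlog^2 / 2, sd = sdlog))
    drift <- rnorm(ns, sd = signatures$drift_slope_sd)
    signal <- matrix(0, nrow = ns, ncol = n,
                     dimnames = list(paste0("S", seq_len(ns)), NULL))
    for (s in seq_len(ns)) {
      resp <- phase_response(t, timing, a_eff[s],
                             signatures$rise_tau[s],
                             signatures$decay_tau[s])
      signal[s, ] <- baseline[s] * (1 + resp) + drift[s] * t +
        rnorm(n, sd = signatures$noise_sd)
    }
    structure(
      list(signal = signal, time = t, timing = timing,
           units = "resistance",
           label = rownames(signatures$amplitude)[class_id],
           specimen_id = specimen_id),
      class = "sensor_recording")
  })
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("Sensor recording (%s): %d sensors x %d samples, label %s\n",
              x$units, nrow(x$signal), ncol(x$signal),
              if (is.null(x$label)) "<none>" else x$label))
  invisible(x)
}

#' Simulate a balanced labelled dataset of recordings
#'
#' Generates \code{per_class} recordings for every class in
#' \code{signatures} and shuffles their order deterministically from the
#' seed (mimicking randomised measurement order).
#'
#' @inheritParams simulate_recording
#' @param per_class recordings per class (>= 1).
#' @return A list of \code{sensor_recording} objects of length
#'   \code{n_classes * per_class}, with exactly balanced labels.
#' @export
simulate_dataset <- function(signatures, per_class,
                             timing = timing_config(), seed = 1) {
  stopifnot(inherits(signatures, "signature_set"))
  stop_if(!is_count(per_class), "`per_class` must be an integer >= 1")
  grid <- expand.grid(rep = seq_len(per_class),
                      class = seq_len(signatures$n_classes))
  recs <- lapply(seq_len(nrow(grid)), function(i) {
    simulate_recording(
      signatures, grid$class[i], timing,
      seed = derive_seed(seed, i),
      specimen_id = sprintf("C%d_r%d", grid$class[i], grid$rep[i]))
  })
  order_idx <- local_seed(derive_seed(seed, 0L), sample.int(length(recs)))
  recs[order_idx]
}

#' Simulate a Gaussian class-conditional feature table
#'
#' Fast fixture that bypasses signal simulation: each class has a mean
#' vector drawn as \code{separation} times standard-normal deviates, and
#' specimens are that mean plus unit-variance Gaussian noise. At
#' \code{separation = 0} all rows are exchangeable across labels; large
#' \code{separation} makes classes perfectly separable.
#'
#' @param n_classes number of classes (>= 2).
#' @param per_class rows per class (>= 1).
#' @param n_features feature dimension (>= 1); 80 matches a 16-sensor
#'   array with 5 features per sensor.
#' @param separation non-negative between-class mean scale, in units of
#'   the within-class noise SD (1). The default 0.3 gives the moderate
#'   class overlap regime (multi-class accuracy well above chance but
#'   below 1) in 80 dimensions.
#' @param seed integer seed.
#' @return A data.frame with \code{n_features} numeric columns
#'   \code{F1..Fn} and a final factor column \code{label}.
#' @export
#' @examples
#' tab <- simulate_feature_table(3, 5, n_features = 4, seed = 2)
#' table(tab$label)
simulate_feature_table <- function(n_classes, per_class, n_features = 80,
                                   separation = 0.3, seed = 1) {
  stop_if(!is_count(n_classes, 2L), "`n_classes` must be an integer >= 2")
  stop_if(!is_count(per_class), "`per_class` must be an integer >= 1")
  stop_if(!is_count(n_features), "`n_features` must be an integer >= 1")
  stop_if(!is.numeric(separation) || separation < 0,
          "`separation` must be >= 0")
  local_seed(seed, {
    means <- matrix(rnorm(n_classes * n_features), nrow = n_classes) *
      separation
    x <- matrix(rnorm(n_classes * per_class * n_features),
                ncol = n_features)
    labs <- rep(seq_len(n_classes), each = per_class)
    x <- x + means[labs, , drop = FALSE]
    out <- as.data.frame(x)
    names(out) <- paste0("F", seq_len(n_features))
    out$label <- factor(paste0("C", labs),
                        levels = paste0("C", seq_len(n_classes)))
    out
  })
}
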