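# File formats and the end-to-end pipeline.
#
# Recordings are stored as wide CSV (time_s, S1..Sn) with a JSON
# sidecar holding the label, phase boundaries and sampling rate;
# feature tables as CSV with one row per specimen and a final `label`
# column. Curves and summaries are written as CSV so results are
# plain-text diffable.

#' Write / read a feature table
#'
#' Feature tables round-trip losslessly through CSV: numeric feature
#' columns in order, final \code{label} column when labels are present.
#'
#' @param table feature table (data.frame).
#' @param path CSV file path.
#' @return \code{write_feature_table} returns \code{path} invisibly;
#'   \code{read_feature_table} returns the table with \code{label}
#'   restored as a factor (absent for unlabelled tables).
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (has_labels(table)) {
    stop_if(!identical(names(table)[ncol(table)], "label"),
            "`label` must be the final column")
  }
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param require_label reject files without a \code{label} column.
#' @export
read_feature_table <- function(path, require_label = FALSE) {
  stop_if(!file.exists(path), "no such file: ", path)
  widths <- count.fields(path, sep = ",", quote = "\"")
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged CSV: row ", bad - 1L, " of ", path, " has ", widths[bad],
         " fields, expected ", widths[1L], call. = FALSE)
  }
  tab <- read.csv(path, check.names = FALSE)
  labelled <- identical(names(tab)[ncol(tab)], "label")
  stop_if(require_label && !labelled, "missing `label` column in ", path)
  feat_cols <- setdiff(names(tab), "label")
  numeric_ok <- vapply(tab[feat_cols], is.numeric, logical(1))
  stop_if(!all(numeric_ok), "non-numeric feature column(s): ",
          paste(feat_cols[!numeric_ok], collapse = ", "))
  if (labelled) tab$label <- factor(tab$label)
  tab
}

#' Write / read a sensor recording
#'
#' One recording becomes a wide CSV (\code{time_s, S1..Sn}) plus a JSON
#' sidecar (\code{<path>.json}) holding units, label, timing and
#' specimen id.
#'
#' @param recording a \code{sensor_recording}.
#' @param path CSV file path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{write_recording} returns \code{path} invisibly;
#'   \code{read_recording} reconstructs the \code{sensor_recording}.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "sensor_recording"))
  df <- data.frame(time_s = recording$time, t(recording$signal),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  meta <- list(units = recording$units, label = recording$label,
               specimen_id = recording$specimen_id,
               timing = unclass(recording$timing))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  meta_path <- paste0(path, ".json")
  stop_if(!file.exists(meta_path), "missing sidecar: ", meta_path)
  df <- read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  timing <- do.call(timing_config, meta$timing[c(
    "sampling_rate", "baseline_duration", "reaction_duration",
    "cleaning_duration")])
  structure(
    list(signal = t(as.matrix(df[, -1L, drop = FALSE])),
         time = df$time_s, timing = timing, units = meta$units,
         label = meta$label, specimen_id = meta$specimen_id),
    class = "sensor_recording")
}

#' Pipeline configuration
#'
#' Bundles every tunable of the simulate -> featurize -> evaluate
#' pipeline. Unknown keys passed via \code{...} are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @param n_classes,per_class,n_sensors,separation synthetic-data scale.
#' @param timing a \code{\link{timing_config}}.
#' @param model \code{"svm_rbf"} or \code{"random_forest"}.
#' @param framework \code{"icp"} or \code{"acp"}.
#' @param K ACP bootstrap fold count.
#' @param calib_fraction ICP calibration fraction.
#' @param n_folds CV fold count.
#' @param epsilon_grid significance-level grid for the curves.
#' @param standardize feature standardisation flag for the underlying
#'   model (\code{NULL} = model default).
#' @param seed master seed; every random stage derives from it.
#' @param ... must be empty (strict).
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_classes = 10, per_class = 50,
                            n_sensors = 16, separation = 1,
                            timing = timing_config(),
                            model = "svm_rbf", framework = "acp",
                            K = 5, calib_fraction = 1 / 3, n_folds = 10,
                            epsilon_grid = seq(0.01, 0.99, 0.01),
                            standardize = NULL, seed = 1, ...) {
  extra <- list(...)
  stop_if(length(extra) > 0L, "unknown config key(s): ",
          paste(names(extra), collapse = ", "))
  cfg <- list(n_classes = n_classes, per_class = per_class,
              n_sensors = n_sensors, separation = separation,
              timing = timing, model = model, framework = framework,
              K = K, calib_fraction = calib_fraction, n_folds = n_folds,
              epsilon_grid = epsilon_grid, standardize = standardize,
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

config_to_json <- function(config, path) {
  out <- unclass(config)
  out$timing <- unclass(out$timing)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the full pipeline
#'
#' Simulates a labelled recording set, baseline-corrects and
#' featurizes it, cross-validates the configured conformal predictor,
#' and writes every artifact to \code{out_dir}: \code{features.csv},
#' \code{pvalues.csv} (per-sample p-values with truth and fold),
#' \code{calibration_curve.csv}, \code{efficiency_curve.csv},
#' \code{indicators.csv}, \code{accuracy.csv}, \code{pca_scores.csv},
#' and the resolved \code{config.json} with its md5 hash in
#' \code{summary.json}. Identical configs (including seed) reproduce
#' byte-identical CSVs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage-boundary messages.
#' @return Invisibly, a list with the in-memory results (feature table,
#'   cv result, curves, indicators, accuracy, pca).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  sig <- make_signatures(config$n_classes, config$n_sensors,
                         separation = config$separation,
                         seed = derive_seed(config$seed, 1L))
  recs <- simulate_dataset(sig, config$per_class, config$timing,
                           seed = derive_seed(config$seed, 2L))
  say("simulate: %d recordings (%d classes x %d/class, %d sensors)",
      length(recs), config$n_classes, config$per_class, config$n_sensors)

  feats <- extract_feature_table(recs)
  say("featurize: %d x %d feature table", nrow(feats), ncol(feats) - 1L)
  write_feature_table(feats, file.path(out_dir, "features.csv"))

  spec <- underlying_spec(config$model, standardize = config$standardize,
                          seed = derive_seed(config$seed, 3L))
  cv <- cross_validate(feats, framework = config$framework, spec = spec,
                       n_folds = config$n_folds,
                       seed = derive_seed(config$seed, 4L),
                       calib_fraction = config$calib_fraction,
                       K = config$K)
  say("evaluate: %s-%s over %d folds", toupper(config$framework),
      config$model, config$n_folds)

  pv_df <- data.frame(specimen = seq_len(nrow(cv$pvalues)),
                      label = as.character(cv$label), fold = cv$fold,
                      cv$pvalues, check.names = FALSE)
  write.csv(pv_df, file.path(out_dir, "pvalues.csv"), row.names = FALSE)

  calib <- calibration_curve(cv, config$epsilon_grid)
  eff <- efficiency_curve(cv, config$epsilon_grid)
  ind <- summarize_indicators(cv)
  acc <- accuracy_forced(cv)
  pca <- pca_projection(feats, 2)
  write.csv(calib, file.path(out_dir, "calibration_curve.csv"),
            row.names = FALSE)
  write.csv(eff, file.path(out_dir, "efficiency_curve.csv"),
            row.names = FALSE)
  write.csv(ind, file.path(out_dir, "indicators.csv"), row.names = FALSE)
  write.csv(data.frame(fold = c(names(acc$per_fold), "mean", "overall"),
                       accuracy = c(unname(acc$per_fold), acc$fold_mean,
                                    acc$accuracy)),
            file.path(out_dir, "accuracy.csv"), row.names = FALSE)
  pca_df <- pca$scores
  write.csv(pca_df, file.path(out_dir, "pca_scores.csv"),
            row.names = FALSE)

  cfg_path <- config_to_json(config, file.path(out_dir, "config.json"))
  cfg_hash <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(
    list(seed = config$seed, config_md5 = cfg_hash,
         n_specimens = nrow(feats),
         accuracy_forced = acc$fold_mean,
         mean_confidence = ind$mean[ind$indicator == "confidence"],
         mean_credibility = ind$mean[ind$indicator == "credibility"],
         pca_variance_fraction = pca$variance_fraction),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  say("accuracy (mean over folds): %.3f", acc$fold_mean)

  invisible(list(features = feats, cv = cv, calibration = calib,
                 efficiency = eff, indicators = ind, accuracy = acc,
                 pca = pca, config = config))
}
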