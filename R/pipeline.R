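# Pipeline plumbing: nested configuration with full defaulting and YAML
# round-trip, and the end-to-end run (denoise -> interpretability gate ->
# segment -> featurize -> classify -> evaluate).

pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulator = list(per_class_count = 20,
                     heart_rate_bpm = c(50, 110),
                     murmur_intensity = c(0.3, 0.8),
                     snr_db = c(15, 30),
                     af_frac = 0,
                     duration_s = 10,
                     sample_rate_hz = 2000),
    preprocess = list(low_cut_hz = 20, high_cut_hz = 100, order = 4,
                      denoise = TRUE, frame_ms = 256, hop_frac = 0.5,
                      noise_percentile = 0.1, over_subtraction = 1.5,
                      spectral_floor = 0.05,
                      min_snr_db = 5, min_peak = 0.01,
                      include_uninterpretable = FALSE),
    segmentation = list(window_ms = 20, hop_ms = 5, peak_threshold = 0.5,
                        min_gap_ms = 120, recovery = TRUE),
    features = list(canonical_s = 0.8, working_rate_hz = 1000,
                    window_ms = 64, overlap = 0.75, nfft = 256,
                    freq_range_hz = c(10, 200), size = 40),
    classifier = list(dense_units = 128, learning_rate = 0.001,
                      batch_size = 32, epochs = 30, early_stop = TRUE,
                      train_per_class = 80, train_cycle_cap = 6),
    evaluation = list(level = 0.95)
  )
}

merge_checked <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults)) {
      abort_config(sprintf("unknown configuration key '%s%s'", path, nm),
                   nm)
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_checked(defaults[[nm]],
                                      as.list(user[[nm]]),
                                      paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Pipeline configuration
#'
#' Every field has a documented default (see the vignette); unknown keys
#' are rejected. Pass either a named list of overrides or a YAML file
#' path.
#'
#' @param overrides Named list of (possibly nested) overrides, or a
#'   length-one character path to a YAML file.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  if (is.character(overrides) && length(overrides) == 1) {
    overrides <- yaml::read_yaml(overrides)
  }
  cfg <- merge_checked(pipeline_defaults(), overrides)
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#'
#' `pipeline_config(save_config(cfg, path))` round-trips.
#'
#' @param cfg A `pipeline_config`.
#' @param path Output YAML path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

preprocess_recording <- function(rec, pp) {
  rec <- bandpass(rec, pp$low_cut_hz, pp$high_cut_hz, pp$order)
  if (isTRUE(pp$denoise)) {
    rec <- spectral_subtract(rec, denoise_params(pp$frame_ms, pp$hop_frac,
                                                 pp$noise_percentile,
                                                 pp$over_subtraction,
                                                 pp$spectral_floor))
  }
  rec
}

featurize_trainset <- function(recs, labels, cfg, cycle_cap = Inf) {
  ep <- do.call(envelope_params, cfg$segmentation)
  sc <- do.call(spectrogram_config, cfg$features)
  feats <- list(); labs <- character()
  for (i in seq_along(recs)) {
    rec <- preprocess_recording(recs[[i]], cfg$preprocess)
    fts <- tryCatch({
      seg <- segment(rec, ep)
      featurize_recording(rec, seg, sc)
    }, pcgdx_data_error = function(e) NULL)
    if (is.null(fts)) next
    if (length(fts) > cycle_cap) fts <- fts[seq_len(cycle_cap)]
    feats <- c(feats, fts)
    labs <- c(labs, rep(labels[i], length(fts)))
  }
  list(features = feats, labels = labs)
}

#' Train the pipeline's classifier on simulated recordings
#'
#' Simulates a balanced labeled training set, runs it through the same
#' preprocessing/segmentation/feature path used at evaluation time, and
#' trains the CNN.
#'
#' @param cfg A [pipeline_config()].
#' @return A trained `pcg_cnn`.
#' @export
train_pipeline_model <- function(cfg = pipeline_config()) {
  sim <- cfg$simulator
  ds <- generate_dataset(cfg$classifier$train_per_class,
                         sim[setdiff(names(sim), "per_class_count")],
                         seed = cfg$seed + 1000L)
  tr <- featurize_trainset(ds$recordings, ds$labels, cfg,
                           cycle_cap = cfg$classifier$train_cycle_cap)
  ccfg <- classifier_config(dense_units = cfg$classifier$dense_units,
                            learning_rate = cfg$classifier$learning_rate,
                            batch_size = cfg$classifier$batch_size,
                            epochs = cfg$classifier$epochs,
                            early_stop = cfg$classifier$early_stop,
                            seed = cfg$seed)
  model <- build_model(ccfg)
  train_cnn(model, tr$features, tr$labels)
}

#' Run the full diagnostic pipeline
#'
#' Each input recording is band-passed and denoised, gated for
#' interpretability, segmented into cardiac cycles, featurized and
#' diagnosed; aggregate diagnostic metrics are computed over the
#' interpretable, segmentable recordings (mirroring an analysis set
#' restricted to interpretable sounds), unless
#' `preprocess$include_uninterpretable` is set. Deterministic given
#' `(config, inputs, model)`.
#'
#' @param cfg A [pipeline_config()].
#' @param inputs One of: `NULL` (simulate an evaluation set per
#'   `cfg$simulator`), a list of [pcg_recording()]s, or a character
#'   vector of WAV paths.
#' @param model A trained `pcg_cnn`, or `NULL` to train one via
#'   [train_pipeline_model()] (only needed if any recording passes the
#'   gate).
#' @return List of class `pcg_report`: `per_recording` (data frame),
#'   `metrics` (an `evaluation_table`, or `NULL` with `note` when no
#'   recording was evaluable), `model`, `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), inputs = NULL,
                         model = NULL) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  if (is.null(inputs)) {
    sim <- cfg$simulator
    ds <- generate_dataset(sim$per_class_count,
                           sim[setdiff(names(sim), "per_class_count")],
                           seed = cfg$seed)
    recs <- ds$recordings
  } else if (is.character(inputs)) {
    recs <- lapply(inputs, read_wav)
  } else {
    recs <- inputs
  }
  truths <- vapply(recs, function(r) {
    if (!is.null(r$annotation)) r$annotation$label else NA_character_
  }, character(1))

  pp <- cfg$preprocess
  ep <- do.call(envelope_params, cfg$segmentation)
  sc <- do.call(spectrogram_config, cfg$features)

  pre <- vector("list", length(recs))
  gates <- vector("list", length(recs))
  any_evaluable <- FALSE
  for (i in seq_along(recs)) {
    # the gate judges acquisition quality on the band-passed signal,
    # before spectral subtraction reshapes the noise statistics
    bp <- bandpass(recs[[i]], pp$low_cut_hz, pp$high_cut_hz, pp$order)
    gates[[i]] <- assess_interpretability(bp, pp$min_snr_db, pp$min_peak)
    pre[[i]] <- if (isTRUE(pp$denoise)) {
      spectral_subtract(bp, denoise_params(pp$frame_ms, pp$hop_frac,
                                           pp$noise_percentile,
                                           pp$over_subtraction,
                                           pp$spectral_floor))
    } else bp
    if (gates[[i]]$interpretable) any_evaluable <- TRUE
  }
  if (is.null(model) && (any_evaluable || pp$include_uninterpretable)) {
    model <- train_pipeline_model(cfg)
  }

  rows <- list()
  for (i in seq_along(recs)) {
    gate <- gates[[i]]
    entry <- data.frame(
      source_id = recs[[i]]$source_id, truth = truths[i],
      interpretable = gate$interpretable,
      gate_reasons = paste(gate$reasons, collapse = "+"),
      estimated_snr_db = gate$estimated_snr_db,
      segmented = FALSE, n_cycles = NA_integer_, quality = NA_real_,
      predicted = NA_character_, p_truth = NA_real_, correct = NA,
      stringsAsFactors = FALSE)
    use <- gate$interpretable || pp$include_uninterpretable
    if (use) {
      diag <- tryCatch({
        seg <- segment(pre[[i]], ep)
        fts <- featurize_recording(pre[[i]], seg, sc)
        d <- diagnose_recording(model, fts,
                                if (!is.na(truths[i])) truths[i] else NULL)
        entry$segmented <- TRUE
        entry$n_cycles <- nrow(seg$cycles)
        entry$quality <- seg$quality
        entry$predicted <- d$predicted_class
        if (!is.na(truths[i])) {
          entry$p_truth <- unname(d$aggregate[truths[i]])
          entry$correct <- d$correct_given_truth
        }
        d
      }, pcgdx_data_error = function(e) {
        entry$gate_reasons <<- paste(c(entry$gate_reasons, "UNSEGMENTABLE"),
                                     collapse = "+")
        NULL
      })
    }
    rows[[i]] <- entry
  }
  per_rec <- do.call(rbind, rows)

  eval_mask <- per_rec$segmented & !is.na(per_rec$truth) &
    (per_rec$interpretable | pp$include_uninterpretable)
  if (any(eval_mask)) {
    # the >=50% rule: a recording counts as detected-positive when its
    # predicted class is abnormal; metric denominators use only the
    # evaluable analysis set
    metrics <- evaluate_dataset(per_rec$predicted[eval_mask],
                                per_rec$truth[eval_mask],
                                level = cfg$evaluation$level)
    note <- NULL
  } else {
    metrics <- NULL
    note <- "no interpretable, segmentable, labeled recordings: metrics table empty"
  }
  structure(list(per_recording = per_rec, metrics = metrics, note = note,
                 model = model, config = cfg),
            class = "pcg_report")
}

#' @export
print.pcg_report <- function(x, ...) {
  n <- nrow(x$per_recording)
  ni <- sum(x$per_recording$interpretable)
  cat(sprintf("<pcg_report> %d recordings; %d interpretable (%.0f%%)\n",
              n, ni, 100 * ni / n))
  if (!is.null(x$metrics)) print(x$metrics) else cat(x$note, "\n")
  invisible(x)
}

#' Write a report's tables to an output directory
#'
#' `per_recording.csv`, `metrics.csv` and `report.json` (per-recording
#' entries plus run parameters).
#'
#' @param report A `pcg_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_recording,
                   file.path(dir, "per_recording.csv"), row.names = FALSE)
  if (!is.null(report$metrics)) {
    utils::write.csv(report$metrics$metrics, file.path(dir, "metrics.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(per_recording = report$per_recording,
         note = report$note,
         config = unclass(report$config)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(dir)
}
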