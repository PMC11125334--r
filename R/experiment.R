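#' Default experiment configuration
#'
#' Nested configuration for an end-to-end synthetic experiment: cohort
#' generation, preprocessing, classifier, training, and output options.
#' [read_experiment_config()] loads the same structure from YAML with strict
#' key checking; unknown keys are rejected.
#'
#' @return A named list (class `experiment_config`).
#' @export
default_experiment_config <- function() {
  structure(list(
    seed = 1L,
    n_subjects = 5L,
    algorithms = c("lstm", "icgn", "bilstm"),
    synthetic = list(
      n_channels = 20L, fs = 10.1725,
      n_trials = 10L, activity = 10, rest = 20,
      initial_rest = 30, final_rest = 30,
      hrf_amplitude = 1, white_sd = 0.1,
      emit = "hemoglobin"
    ),
    preprocessing = list(low = 0.01, high = 0.2, order = 4L,
                         features = "hbo",
                         fractions = c(0.8, 0.1, 0.1),
                         balance_classes = TRUE),
    network = list(recurrent_units = 64L, dropout_rate = 0.2,
                   dense_units = 64L, output_activation = "softmax",
                   window_length = 20L),
    training = list(learning_rate = 0.001, epochs = 100L, batch_size = 32L,
                    loss = "categorical_crossentropy", optimizer = "adam",
                    clip_norm = 5)
  ), class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_experiment_config()]; unknown keys at the top level or within a
#' section raise an error.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_experiment_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      bad <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
      if (length(bad))
        stop(sprintf("unknown keys in section '%s': %s", nm,
                     paste(bad, collapse = ", ")))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], user[[nm]])
    } else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

.subject_config_from <- function(cfg, seed) {
  syn <- cfg$synthetic
  synthetic_subject_config(
    paradigm = build_paradigm(initial_rest = syn$initial_rest,
                              n_trials = syn$n_trials,
                              activity = syn$activity, rest = syn$rest,
                              final_rest = syn$final_rest),
    fs = syn$fs, n_channels = syn$n_channels,
    hrf = hrf_params(amplitude = syn$hrf_amplitude),
    noise = noise_params(white_sd = syn$white_sd),
    emit = syn$emit, seed = seed)
}

#' Preprocess one subject and build windowed partitions
#'
#' Runs the standard path: optional absorbance-to-hemoglobin conversion,
#' zero-phase band-pass filtering, paradigm segmentation and labeling, the
#' balanced 80/10/10 split, and windowing.
#'
#' @param series A [hemoglobin_series()] or [absorbance_series()].
#' @param schedule A `paradigm_schedule`.
#' @param cfg An `experiment_config` (preprocessing/network sections used).
#' @param seed Split seed.
#' @return A list with `train`, `val`, `test` window sets and the `labeled`
#'   dataset.
#' @export
preprocess_subject <- function(series, schedule,
                               cfg = default_experiment_config(),
                               seed = 1L) {
  if (inherits(series, "absorbance_series")) series <- mbll_convert(series)
  pp <- cfg$preprocessing
  filtered <- bandpass_filter(series, low = pp$low, high = pp$high,
                              order = pp$order)
  labeled <- segment_and_label(filtered, schedule, features = pp$features)
  parts <- split_dataset(labeled, fractions = pp$fractions, seed = seed,
                         balance_classes = isTRUE(pp$balance_classes))
  W <- cfg$network$window_length
  list(train = windowed_samples(labeled, parts$train, W),
       val = windowed_samples(labeled, parts$val, W),
       test = windowed_samples(labeled, parts$test, W),
       labeled = labeled)
}

.train_one <- function(algo, sets, cfg, seed) {
  k <- length(unique(sets$train$y))
  net <- network_config(algo,
                        recurrent_units = cfg$network$recurrent_units,
                        dropout_rate = cfg$network$dropout_rate,
                        dense_units = cfg$network$dense_units,
                        n_classes = max(2L, k),
                        output_activation = cfg$network$output_activation,
                        window_length = cfg$network$window_length)
  model <- build_classifier(net, input_dim = dim(sets$train$x)[3L],
                            seed = seed)
  tc <- training_config(learning_rate = cfg$training$learning_rate,
                        epochs = cfg$training$epochs,
                        batch_size = cfg$training$batch_size,
                        loss = cfg$training$loss,
                        optimizer = cfg$training$optimizer,
                        clip_norm = cfg$training$clip_norm, seed = seed)
  fit <- train_classifier(model, sets$train, val = sets$val, config = tc)
  list(model = fit$model, history = fit$history,
       test = evaluate_classifier(fit$model, sets$test,
                                  loss = cfg$training$loss))
}

#' Run a full synthetic cohort experiment
#'
#' Generates a synthetic cohort, preprocesses each subject, trains every
#' requested classifier on each subject's training partition, evaluates test
#' accuracy, and (for two or more algorithms) compares the algorithms across
#' subjects with [summarize_cohort()], [one_way_anova()] and [tukey_hsd()].
#'
#' @param cfg An `experiment_config`.
#' @param out_dir Optional directory; when given, the per-subject results
#'   table, summary, statistics and a reproducibility manifest (seeds,
#'   configuration) are written there as CSV/JSON.
#' @param verbose Print per-subject progress.
#' @return A list with `results` (subject x algorithm accuracy data.frame),
#'   `summary`, `anova`, `tukey` (the latter two `NULL` for a single
#'   algorithm) and `histories`.
#' @export
run_experiment <- function(cfg = default_experiment_config(), out_dir = NULL,
                           verbose = FALSE) {
  algos <- match.arg(cfg$algorithms, c("lstm", "icgn", "bilstm"),
                     several.ok = TRUE)
  template <- .subject_config_from(cfg, seed = cfg$seed)
  cohort <- generate_cohort(cfg$n_subjects, template,
                            master_seed = cfg$seed)
  results <- data.frame(subject = seq_len(cfg$n_subjects))
  for (a in algos) results[[a]] <- NA_real_
  histories <- list()
  for (s in seq_len(cfg$n_subjects)) {
    subj <- cohort[[s]]
    sets <- preprocess_subject(subj$series, subj$config$paradigm, cfg,
                               seed = cfg$seed + s)
    for (a in algos) {
      fit <- .train_one(a, sets, cfg, seed = cfg$seed + s)
      results[s, a] <- fit$test$accuracy
      histories[[sprintf("subject%d_%s", s, a)]] <- fit$history
      if (verbose)
        message(sprintf("subject %d %s: test accuracy %.2f%%",
                        s, a, fit$test$accuracy))
    }
  }
  summary <- anova <- tukey <- NULL
  if (length(algos) >= 2L && cfg$n_subjects >= 2L) {
    summary <- summarize_cohort(results)
    groups <- lapply(algos, function(a) results[[a]])
    names(groups) <- algos
    anova <- one_way_anova(groups)
    tukey <- tukey_hsd(groups, names = algos)
  } else if (length(algos) < 2L) {
    warning("a single algorithm was run; cohort statistics skipped")
  }
  out <- list(results = results, summary = summary, anova = anova,
              tukey = tukey, histories = histories)
  if (!is.null(out_dir)) .write_experiment(out, cfg, out_dir)
  out
}

.write_experiment <- function(out, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$results, file.path(out_dir, "subject_results.csv"),
                   row.names = FALSE)
  if (!is.null(out$summary))
    utils::write.csv(out$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  if (!is.null(out$tukey))
    utils::write.csv(as.data.frame(out$tukey),
                     file.path(out_dir, "tukey.csv"), row.names = FALSE)
  stats_json <- list(anova = if (!is.null(out$anova))
    list(F = out$anova$F, p = out$anova$p,
         df_between = out$anova$df_between,
         df_within = out$anova$df_within))
  manifest <- list(config = unclass(cfg),
                   config_hash = .config_hash(cfg),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(c(stats_json, manifest = list(manifest)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Simulate a cohort and write it to disk
#'
#' Writes one series file pair per subject (CSV + JSON sidecar), the
#' ground-truth labels, and a manifest recording the configuration and every
#' derived seed, sufficient to regenerate the files bit-for-bit.
#'
#' @param cfg An `experiment_config`.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
simulate_cohort_files <- function(cfg = default_experiment_config(),
                                  out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  template <- .subject_config_from(cfg, seed = cfg$seed)
  cohort <- generate_cohort(cfg$n_subjects, template,
                            master_seed = cfg$seed)
  seeds <- integer(cfg$n_subjects)
  for (s in seq_along(cohort)) {
    base <- file.path(out_dir, sprintf("subject%02d", s))
    if (inherits(cohort[[s]]$series, "absorbance_series"))
      write_absorbance_series(cohort[[s]]$series, base)
    else
      write_hemoglobin_series(cohort[[s]]$series, base)
    write_labeled_dataset(cohort[[s]]$labeled, paste0(base, "_truth"))
    seeds[s] <- cohort[[s]]$config$seed
  }
  manifest <- list(master_seed = cfg$seed, subject_seeds = seeds,
                   n_subjects = cfg$n_subjects,
                   config_hash = .config_hash(cfg),
                   config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
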