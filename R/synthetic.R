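#' Canonical hemodynamic response parameters
#'
#' Parameters of a double-gamma hemodynamic response function (HRF): a
#' positive gamma peak followed by a scaled undershoot gamma. Defaults are
#' the conventional canonical values (peak at 6 s, undershoot at 16 s,
#' undershoot one sixth of the peak).
#'
#' @param peak_delay Time to peak in seconds (gamma mode).
#' @param undershoot_delay Time to undershoot trough in seconds.
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions (s).
#' @param undershoot_ratio Undershoot amplitude as a fraction of the peak.
#' @param amplitude Peak amplitude in uM.
#' @return An `hrf_params` object.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_dispersion = 1, undershoot_dispersion = 1,
                       undershoot_ratio = 1 / 6, amplitude = 1) {
  stopifnot(peak_delay > 0, undershoot_delay > 0,
            peak_dispersion > 0, undershoot_dispersion > 0,
            is.finite(amplitude))
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio,
                 amplitude = amplitude),
            class = "hrf_params")
}

#' Sampled canonical HRF kernel
#'
#' Difference-of-gammas kernel sampled at `fs`, truncated at `duration`
#' seconds, with the gamma shapes chosen so that each gamma's mode equals
#' its configured delay, and the kernel peak rescaled to `amplitude`.
#'
#' @param params An [hrf_params()].
#' @param fs Sampling frequency in Hz.
#' @param duration Kernel support in seconds (default 32).
#' @return Numeric kernel vector of length `floor(duration * fs) + 1`.
#' @export
canonical_hrf <- function(params = hrf_params(), fs, duration = 32) {
  stopifnot(inherits(params, "hrf_params"), fs > 0)
  t <- seq(0, duration, by = 1 / fs)
  shape1 <- 1 + params$peak_delay / params$peak_dispersion
  shape2 <- 1 + params$undershoot_delay / params$undershoot_dispersion
  g1 <- stats::dgamma(t, shape = shape1, rate = 1 / params$peak_dispersion)
  g2 <- stats::dgamma(t, shape = shape2,
                      rate = 1 / params$undershoot_dispersion)
  h <- g1 - params$undershoot_ratio * g2
  if (params$amplitude == 0 || max(abs(h)) == 0) return(h * 0)
  h / max(h) * params$amplitude
}

#' Physiological noise parameters
#'
#' White sensor noise, sinusoidal physiological components with random
#' per-channel phases, and a slow linear drift. The default oscillations sit
#' at the conventional Mayer-wave (~0.1 Hz), respiratory (~0.3 Hz) and
#' cardiac (~1.0 Hz) frequencies; the latter two lie outside the 0.01-0.2 Hz
#' passband and are removed by filtering.
#'
#' @param white_sd White-noise standard deviation (uM).
#' @param oscillations A list of `c(frequency_hz, amplitude_um)` pairs.
#' @param drift_slope Linear drift in uM per second.
#' @return A `noise_params` object.
#' @export
noise_params <- function(white_sd = 0.1,
                         oscillations = list(c(0.1, 0.2), c(0.3, 0.2),
                                             c(1.0, 0.3)),
                         drift_slope = 0.001) {
  stopifnot(white_sd >= 0,
            all(vapply(oscillations, function(o) o[2L] >= 0, TRUE)))
  structure(list(white_sd = white_sd, oscillations = oscillations,
                 drift_slope = drift_slope),
            class = "noise_params")
}

#' Synthetic subject configuration
#'
#' Everything needed to simulate one subject's block-design fNIRS run:
#' paradigm, sampling rate, channel layout with per-class activation
#' weights, HRF, noise, and the emitted representation.
#'
#' @param paradigm A `paradigm_schedule` (default: the 360 s two-class
#'   design).
#' @param fs Sampling frequency (default 10.1725 Hz).
#' @param n_channels Number of measurement channels (default 20).
#' @param channel_weights `n_channels x n_classes` matrix of activation
#'   weights (how strongly each task class drives each channel). Default:
#'   for each class, half of the channels respond with weights tapering from
#'   1, the rest are silent. For the two-class rest/activity design only the
#'   activity class carries activation.
#' @param hrf An [hrf_params()].
#' @param noise A [noise_params()].
#' @param hbr_ratio Deoxyhemoglobin response as a fraction of the oxy
#'   response (default -1/3, the typical empirical inversion).
#' @param emit `"hemoglobin"` (default) or `"absorbance"` (passes the
#'   generated concentrations through [inverse_mbll()] so the full
#'   conversion path is exercised).
#' @param seed Integer seed.
#' @return A `synthetic_subject_config` object.
#' @export
synthetic_subject_config <- function(paradigm = build_paradigm(),
                                     fs = 10.1725,
                                     n_channels = 20L,
                                     channel_weights = NULL,
                                     hrf = hrf_params(),
                                     noise = noise_params(),
                                     hbr_ratio = -1 / 3,
                                     emit = c("hemoglobin", "absorbance"),
                                     seed = 1L) {
  emit <- match.arg(emit)
  stopifnot(inherits(paradigm, "paradigm_schedule"), fs > 0, n_channels >= 1)
  cls_map <- .condition_classes(paradigm$condition)
  task_conds <- names(cls_map)[!is.na(cls_map)]
  # activation-bearing conditions: activity / taskK, not inter-trial rest
  active_conds <- setdiff(task_conds, "rest")
  if (is.null(channel_weights)) {
    k <- length(active_conds)
    channel_weights <- matrix(0, n_channels, k,
                              dimnames = list(NULL, active_conds))
    n_active <- max(1L, floor(n_channels / 2))
    for (j in seq_len(k)) {
      chans <- ((seq_len(n_active) - 1L + (j - 1L) * n_active) %%
                  n_channels) + 1L
      channel_weights[chans, j] <- seq(1, 0.5, length.out = n_active)
    }
  }
  if (nrow(channel_weights) != n_channels)
    stop("`channel_weights` must have one row per channel")
  if (all(colSums(abs(channel_weights)) == 0))
    stop("at least one active channel per task class is required")
  structure(list(paradigm = paradigm, fs = fs,
                 n_channels = as.integer(n_channels),
                 channel_weights = channel_weights,
                 hrf = hrf, noise = noise, hbr_ratio = hbr_ratio,
                 emit = emit, seed = as.integer(seed)),
            class = "synthetic_subject_config")
}

.noise_matrix <- function(noise, n, n_channels, fs) {
  t_sec <- (seq_len(n) - 1) / fs
  out <- matrix(stats::rnorm(n * n_channels, 0, noise$white_sd),
                n, n_channels)
  for (o in noise$oscillations) {
    phase <- stats::runif(n_channels, 0, 2 * pi)
    for (ch in seq_len(n_channels))
      out[, ch] <- out[, ch] + o[2L] * sin(2 * pi * o[1L] * t_sec + phase[ch])
  }
  out + noise$drift_slope * t_sec
}

#' Generate one synthetic subject
#'
#' Builds the noiseless activation by convolving each task class's boxcar
#' (1 during that class's segments) with the canonical HRF kernel and
#' projecting it onto channels via the class weights; deoxyhemoglobin is the
#' oxy signal scaled by `hbr_ratio`. Physiological noise is then added to
#' both chromophores, and with `emit = "absorbance"` the result is converted
#' to two-wavelength absorbance via [inverse_mbll()]. Ground-truth labels
#' are obtained from [segment_and_label()] on the same schedule, so they are
#' consistent with the preprocessing path by construction.
#'
#' @param config A [synthetic_subject_config()].
#' @return A list with `series` (a [hemoglobin_series()] or
#'   [absorbance_series()]), `labeled` (ground-truth `labeled_dataset` built
#'   from the noiseless-labeled schedule), `clean` (noiseless hemoglobin
#'   series), and `config`.
#' @export
generate_subject <- function(config) {
  stopifnot(inherits(config, "synthetic_subject_config"))
  set.seed(config$seed)
  fs <- config$fs
  sched <- config$paradigm
  n <- floor(attr(sched, "total_duration") * fs)
  C <- config$n_channels

  counts <- .segment_counts(sched, fs)
  seg_id <- rep(seq_len(nrow(sched)), counts)
  cond_per_sample <- sched$condition[seg_id]

  kern <- canonical_hrf(config$hrf, fs)
  signal_m <- matrix(0, n, C)
  for (cond in colnames(config$channel_weights)) {
    box <- as.numeric(cond_per_sample == cond)
    box <- c(box, rep(0, n - length(box)))
    conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(n)]
    signal_m <- signal_m + outer(conv, config$channel_weights[, cond])
  }
  hbo_clean <- signal_m
  hbr_clean <- config$hbr_ratio * signal_m
  clean <- hemoglobin_series(hbo_clean, hbr_clean, fs = fs)

  hbo <- hbo_clean + .noise_matrix(config$noise, n, C, fs)
  hbr <- hbr_clean + abs(config$hbr_ratio) *
    .noise_matrix(config$noise, n, C, fs)
  hemo <- hemoglobin_series(hbo, hbr, fs = fs)

  series <- if (config$emit == "absorbance") inverse_mbll(hemo) else hemo
  labeled <- segment_and_label(hemo, sched)
  list(series = series, labeled = labeled, clean = clean, config = config)
}

#' Generate a synthetic cohort
#'
#' Repeats [generate_subject()] with per-subject seeds derived
#' deterministically from a master seed and multiplicative log-normal jitter
#' (sigma = 0.2) on the HRF amplitude and white-noise SD to create
#' inter-subject variability.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config Template [synthetic_subject_config()].
#' @param master_seed Integer master seed.
#' @param jitter_sd Log-normal sigma of the between-subject jitter.
#' @return A list of [generate_subject()] results, one per subject.
#' @export
generate_cohort <- function(n_subjects, config = synthetic_subject_config(),
                            master_seed = 1L, jitter_sd = 0.2) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1")
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max, n_subjects)
  amp_jit <- exp(stats::rnorm(n_subjects, 0, jitter_sd))
  sd_jit <- exp(stats::rnorm(n_subjects, 0, jitter_sd))
  lapply(seq_len(n_subjects), function(i) {
    cfg <- config
    cfg$hrf$amplitude <- cfg$hrf$amplitude * amp_jit[i]
    cfg$noise$white_sd <- cfg$noise$white_sd * sd_jit[i]
    cfg$seed <- seeds[i]
    generate_subject(cfg)
  })
}
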