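#' Extinction coefficient table
#'
#' The 2x2 matrix of molar extinction coefficients used by the modified
#' Beer-Lambert law, in uM^-1 cm^-1, laid out as
#' `rbind(c(eHbO(l1), eHbR(l1)), c(eHbO(l2), eHbR(l2)))`. The defaults are
#' widely used literature values for 760 and 850 nm; measured systems should
#' supply their own table. A warning is emitted when the matrix is
#' ill-conditioned (condition number above 1e6).
#'
#' @param hbo Extinction coefficients of oxyhemoglobin at the two
#'   wavelengths.
#' @param hbr Extinction coefficients of deoxyhemoglobin at the two
#'   wavelengths.
#' @param wavelengths Wavelengths in nm (metadata only).
#' @return An `extinction_table` object wrapping the 2x2 matrix.
#' @export
extinction_table <- function(hbo = c(0.0014866, 0.0025264),
                             hbr = c(0.0038437, 0.0017798),
                             wavelengths = c(760, 850)) {
  stopifnot(length(hbo) == 2L, length(hbr) == 2L)
  e <- cbind(HbO = as.numeric(hbo), HbR = as.numeric(hbr))
  rownames(e) <- paste0("lambda", seq_len(2L))
  if (abs(det(e)) < .Machine$double.eps * max(abs(e)))
    stop("extinction matrix is singular")
  cn <- kappa(e, exact = TRUE)
  if (cn > 1e6)
    warning(sprintf("extinction matrix is ill-conditioned (kappa = %.3g)", cn))
  structure(list(matrix = e, wavelengths = wavelengths,
                 condition_number = cn),
            class = "extinction_table")
}

#' Two-wavelength absorbance series
#'
#' @param delta_a A `T x C x 2` array of absorbance changes (time x channel
#'   x wavelength), or a list of two `T x C` matrices.
#' @param fs Sampling frequency in Hz (default 10.1725).
#' @param wavelengths The two wavelengths in nm.
#' @param distance Source-detector separation l in cm (default 3).
#' @param dpf Differential path-length factor d (dimensionless, default 6).
#' @param channels Optional channel labels.
#' @return An `absorbance_series` object.
#' @export
absorbance_series <- function(delta_a, fs = 10.1725,
                              wavelengths = c(760, 850),
                              distance = 3, dpf = 6, channels = NULL) {
  if (is.list(delta_a) && length(delta_a) == 2L) {
    a1 <- as.matrix(delta_a[[1L]]); a2 <- as.matrix(delta_a[[2L]])
    stopifnot(all(dim(a1) == dim(a2)))
    delta_a <- array(c(a1, a2), dim = c(nrow(a1), ncol(a1), 2L))
  }
  stopifnot(length(dim(delta_a)) == 3L, dim(delta_a)[3L] == 2L,
            fs > 0, distance > 0, dpf > 0)
  if (any(!is.finite(delta_a))) stop("non-finite absorbance values")
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(delta_a)[2L]))
  structure(list(delta_a = delta_a, fs = fs, wavelengths = wavelengths,
                 distance = distance, dpf = dpf, channels = channels),
            class = "absorbance_series")
}

#' Hemoglobin concentration-change series
#'
#' Per-channel oxy- and deoxyhemoglobin concentration changes in uM.
#'
#' @param hbo,hbr `T x C` numeric matrices (uM).
#' @param fs Sampling frequency in Hz.
#' @param channels Optional channel labels.
#' @return A `hemoglobin_series` object.
#' @export
hemoglobin_series <- function(hbo, hbr, fs = 10.1725, channels = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  stopifnot(all(dim(hbo) == dim(hbr)), fs > 0)
  if (any(!is.finite(hbo)) || any(!is.finite(hbr)))
    stop("non-finite concentration values")
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(hbo)))
  structure(list(hbo = hbo, hbr = hbr, fs = fs, channels = channels),
            class = "hemoglobin_series")
}

#' @export
print.hemoglobin_series <- function(x, ...) {
  cat(sprintf("<hemoglobin_series> %d samples x %d channels at %.4f Hz (%.1f s)\n",
              nrow(x$hbo), ncol(x$hbo), x$fs, nrow(x$hbo) / x$fs))
  invisible(x)
}

#' Modified Beer-Lambert conversion
#'
#' Converts two-wavelength absorbance changes to hemoglobin concentration
#' changes by inverting the extinction matrix:
#' \deqn{[\Delta HbO_t, \Delta HbR_t]^T = E^{-1} [\Delta A_{t,\lambda_1},
#'   \Delta A_{t,\lambda_2}]^T / (l \cdot d)}
#' with `E` the 2x2 extinction matrix, `l` the source-detector distance (cm)
#' and `d` the differential path-length factor.
#'
#' @param absorbance An [absorbance_series()].
#' @param extinction An [extinction_table()].
#' @return A [hemoglobin_series()] in uM.
#' @export
mbll_convert <- function(absorbance, extinction = extinction_table()) {
  stopifnot(inherits(absorbance, "absorbance_series"),
            inherits(extinction, "extinction_table"))
  ld <- absorbance$distance * absorbance$dpf
  if (ld <= 0) stop("distance * dpf must be positive")
  einv <- solve(extinction$matrix)
  a1 <- absorbance$delta_a[, , 1L, drop = TRUE]
  a2 <- absorbance$delta_a[, , 2L, drop = TRUE]
  a1 <- matrix(a1, dim(absorbance$delta_a)[1L])
  a2 <- matrix(a2, dim(absorbance$delta_a)[1L])
  hbo <- (einv[1L, 1L] * a1 + einv[1L, 2L] * a2) / ld
  hbr <- (einv[2L, 1L] * a1 + einv[2L, 2L] * a2) / ld
  hemoglobin_series(hbo, hbr, fs = absorbance$fs,
                    channels = absorbance$channels)
}

#' Inverse modified Beer-Lambert conversion
#'
#' Exact algebraic inverse of [mbll_convert()]: maps hemoglobin
#' concentration changes back to the two-wavelength absorbance changes that
#' would have produced them. Used by the synthetic generator to emit
#' raw-style absorbance inputs.
#'
#' @param hemo A [hemoglobin_series()].
#' @param extinction An [extinction_table()].
#' @param distance Source-detector separation l in cm.
#' @param dpf Differential path-length factor d.
#' @return An [absorbance_series()].
#' @export
inverse_mbll <- function(hemo, extinction = extinction_table(),
                         distance = 3, dpf = 6) {
  stopifnot(inherits(hemo, "hemoglobin_series"),
            inherits(extinction, "extinction_table"))
  ld <- distance * dpf
  if (ld <= 0) stop("distance * dpf must be positive")
  e <- extinction$matrix
  a1 <- (e[1L, 1L] * hemo$hbo + e[1L, 2L] * hemo$hbr) * ld
  a2 <- (e[2L, 1L] * hemo$hbo + e[2L, 2L] * hemo$hbr) * ld
  absorbance_series(array(c(a1, a2), dim = c(nrow(a1), ncol(a1), 2L)),
                    fs = hemo$fs, wavelengths = extinction$wavelengths,
                    distance = distance, dpf = dpf,
                    channels = hemo$channels)
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass (default 4th order, passband 0.01-0.2 Hz) applied
#' forward and backward ([signal::filtfilt()]) for zero phase distortion,
#' independently per channel. The passband retains the slow hemodynamic
#' response while suppressing drift, Mayer waves' harmonics, respiration and
#' cardiac pulsation.
#'
#' @param series A [hemoglobin_series()], or a numeric matrix/vector (then
#'   `fs` must be given).
#' @param low,high Band edges in Hz (defaults 0.01 and 0.2).
#' @param order Butterworth order (default 4).
#' @param fs Sampling frequency, required for plain matrices.
#' @return The filtered object, same type as the input.
#' @export
bandpass_filter <- function(series, low = 0.01, high = 0.2, order = 4L,
                            fs = NULL) {
  if (inherits(series, "hemoglobin_series")) {
    fs <- series$fs
    out <- series
    out$hbo <- bandpass_filter(series$hbo, low, high, order, fs = fs)
    out$hbr <- bandpass_filter(series$hbr, low, high, order, fs = fs)
    return(out)
  }
  if (is.null(fs)) stop("`fs` is required for matrix input")
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  x <- as.matrix(series)
  y <- apply(x, 2L, function(col) signal::filtfilt(flt, col))
  y <- matrix(y, nrow(x), ncol(x), dimnames = dimnames(x))
  if (is.null(dim(series))) drop(y) else y
}

#' Block-design experimental paradigm
#'
#' Builds the ordered segment schedule of a block-design run: an initial
#' baseline rest, `n_trials` repetitions of an activity block followed by an
#' inter-trial rest block, and a final baseline rest. The defaults describe
#' a 360 s hand-gripping run: 30 s rest, 10 x (10 s activity + 20 s rest),
#' 30 s rest.
#'
#' @param initial_rest,final_rest Baseline durations in seconds.
#' @param n_trials Number of activity/rest trial pairs.
#' @param activity,rest Durations (s) of the activity and inter-trial rest
#'   blocks.
#' @return A `paradigm_schedule`: a data.frame with columns `condition`,
#'   `duration` (s) and `trial`, with the total duration as an attribute.
#' @examples
#' p <- build_paradigm()
#' attr(p, "total_duration")  # 360
#' @export
build_paradigm <- function(initial_rest = 30, n_trials = 10,
                           activity = 10, rest = 20, final_rest = 30) {
  stopifnot(initial_rest >= 0, final_rest >= 0, n_trials >= 0,
            activity >= 0, rest >= 0)
  seg <- data.frame(condition = character(), duration = numeric(),
                    trial = integer())
  if (initial_rest > 0)
    seg <- rbind(seg, data.frame(condition = "baseline",
                                 duration = initial_rest, trial = NA))
  for (i in seq_len(n_trials)) {
    if (activity > 0)
      seg <- rbind(seg, data.frame(condition = "activity",
                                   duration = activity, trial = i))
    if (rest > 0)
      seg <- rbind(seg, data.frame(condition = "rest",
                                   duration = rest, trial = i))
  }
  if (final_rest > 0)
    seg <- rbind(seg, data.frame(condition = "baseline",
                                 duration = final_rest, trial = NA))
  if (nrow(seg) == 0L) stop("schedule has no segments")
  rownames(seg) <- NULL
  attr(seg, "total_duration") <- sum(seg$duration)
  class(seg) <- c("paradigm_schedule", "data.frame")
  seg
}

#' Multi-class block-design paradigm
#'
#' Like [build_paradigm()] but with `n_classes` distinct task conditions
#' (`task1`, `task2`, ...) whose trials are interleaved cyclically, each
#' followed by an inter-trial rest. Inter-trial rest is treated as baseline
#' (excluded from classing), mirroring multi-task finger/foot-tapping
#' designs in which the classes are the tasks themselves.
#'
#' @param n_classes Number of task conditions.
#' @param trials_per_class Trials per task.
#' @inheritParams build_paradigm
#' @return A `paradigm_schedule`.
#' @export
build_multiclass_paradigm <- function(n_classes = 3, trials_per_class = 25,
                                      activity = 10, rest = 20,
                                      initial_rest = 30, final_rest = 30) {
  stopifnot(n_classes >= 2, trials_per_class >= 1)
  seg <- data.frame(condition = "baseline", duration = initial_rest,
                    trial = NA)
  trial <- 0L
  for (r in seq_len(trials_per_class)) {
    for (k in seq_len(n_classes)) {
      trial <- trial + 1L
      seg <- rbind(seg,
                   data.frame(condition = paste0("task", k),
                              duration = activity, trial = trial),
                   data.frame(condition = "rest_baseline", duration = rest,
                              trial = trial))
    }
  }
  seg <- rbind(seg, data.frame(condition = "baseline",
                               duration = final_rest, trial = NA))
  rownames(seg) <- NULL
  attr(seg, "total_duration") <- sum(seg$duration)
  class(seg) <- c("paradigm_schedule", "data.frame")
  seg
}

# Condition -> class mapping. Baseline-like conditions are excluded (NA);
# inter-trial rest is class 1 and activity class 2 in the two-class design;
# taskK conditions map to class K.
.condition_classes <- function(conditions) {
  u <- unique(conditions)
  cls <- rep(NA_integer_, length(u))
  names(cls) <- u
  if ("rest" %in% u) cls["rest"] <- 1L
  if ("activity" %in% u) cls["activity"] <- 2L
  tasks <- grep("^task[0-9]+$", u, value = TRUE)
  for (tk in tasks) cls[tk] <- as.integer(sub("^task", "", tk))
  cls
}

# Per-condition sample counts floor(total duration x fs), apportioned over
# that condition's segments by largest remainder (ties broken by schedule
# order).
.segment_counts <- function(schedule, fs) {
  cond_tot <- tapply(schedule$duration, schedule$condition, sum)
  n_cond <- floor(as.numeric(cond_tot) * fs)
  names(n_cond) <- names(cond_tot)
  counts <- integer(nrow(schedule))
  for (cond in names(n_cond)) {
    idx <- which(schedule$condition == cond)
    quota <- schedule$duration[idx] / sum(schedule$duration[idx]) *
      n_cond[[cond]]
    base <- floor(quota)
    rem <- n_cond[[cond]] - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    counts[idx] <- as.integer(base)
  }
  counts
}

#' Segment a series by the paradigm and label samples
#'
#' Assigns consecutive samples (0-based, half-open segments) to the
#' schedule's segments. Per condition, the sample count is
#' `floor(total condition duration x fs)` distributed over that condition's
#' segments by largest-remainder apportionment; trailing samples beyond the
#' schedule are dropped. Baseline segments are flagged excluded (class
#' `NA`); the remaining conditions map to integer classes (two-class
#' design: inter-trial rest = class 1, activity = class 2; multi-class:
#' `taskK` = class K).
#'
#' For the default 360 s paradigm at 10.1725 Hz this yields 610 baseline,
#' 1017 activity and 2034 rest samples (3661 in total).
#'
#' @param hemo A [hemoglobin_series()] (or a plain feature matrix plus `fs`).
#' @param schedule A `paradigm_schedule`.
#' @param features Which signal feeds the classifier: `"hbo"` (default),
#'   `"hbr"`, or `"both"` (column-bound).
#' @param fs Sampling frequency when `hemo` is a plain matrix.
#' @return A `labeled_dataset`: list with `x` (feature matrix, one row per
#'   kept sample), `condition`, `class` (integer, `NA` = excluded baseline),
#'   `segment`, `trial`, `counts` (per-condition totals), `fs`.
#' @export
segment_and_label <- function(hemo, schedule, features = c("hbo", "hbr", "both"),
                              fs = NULL) {
  features <- match.arg(features)
  stopifnot(inherits(schedule, "paradigm_schedule"))
  if (inherits(hemo, "hemoglobin_series")) {
    fs <- hemo$fs
    x <- switch(features, hbo = hemo$hbo, hbr = hemo$hbr,
                both = cbind(hemo$hbo, hemo$hbr))
  } else {
    if (is.null(fs)) stop("`fs` is required for matrix input")
    x <- as.matrix(hemo)
  }
  counts <- .segment_counts(schedule, fs)
  total <- sum(counts)
  if (nrow(x) < total)
    stop(sprintf("series has %d samples but the schedule needs %d",
                 nrow(x), total))
  seg_id <- rep(seq_len(nrow(schedule)), counts)
  condition <- schedule$condition[seg_id]
  trial <- schedule$trial[seg_id]
  cls_map <- .condition_classes(schedule$condition)
  # baseline-like conditions stay NA (excluded)
  class_int <- unname(cls_map[condition])
  cond_counts <- tapply(counts, schedule$condition, sum)
  structure(list(x = x[seq_len(total), , drop = FALSE],
                 condition = condition,
                 class = class_int,
                 segment = seg_id,
                 trial = trial,
                 counts = as.integer(cond_counts),
                 condition_levels = names(cond_counts),
                 fs = fs),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d features at %.4f Hz\n",
              nrow(x$x), ncol(x$x), x$fs))
  cnt <- stats::setNames(x$counts, x$condition_levels)
  cat("  per-condition counts:",
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  invisible(x)
}

# Largest-remainder integer apportionment of `total` over weights.
.largest_remainder <- function(weights, total) {
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Split labeled samples into train/validation/test partitions
#'
#' Splits the non-baseline samples of a [segment_and_label()] dataset into
#' disjoint partitions (default 80/10/10), drawing samples from every trial
#' of every class. With `balance_classes = TRUE` (default) the majority
#' class is first subsampled (evenly across its trials) so that every
#' partition holds equally many samples of each class, matching protocols
#' that pick equal numbers of rest and activity samples at random; with
#' `FALSE` all labeled samples are kept and each class is split
#' proportionally (partitions exhaust the labeled samples but inherit the
#' class imbalance).
#'
#' @param labeled A `labeled_dataset`.
#' @param fractions Length-3 positive vector summing to 1.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param balance_classes See above.
#' @return A list of integer row-index vectors `train`, `val`, `test`
#'   (indices into `labeled$x`).
#' @export
split_dataset <- function(labeled, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                          balance_classes = TRUE) {
  stopifnot(inherits(labeled, "labeled_dataset"),
            length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  set.seed(as.integer(seed))
  classes <- sort(unique(labeled$class[!is.na(labeled$class)]))
  if (length(classes) < 2L) stop("need at least two labeled classes")
  pools <- lapply(classes, function(k) which(!is.na(labeled$class) &
                                               labeled$class == k))
  names(pools) <- classes

  if (balance_classes) {
    m <- min(lengths(pools))
    pools <- lapply(pools, function(idx) {
      if (length(idx) == m) return(idx)
      seg <- labeled$segment[idx]
      keep_per_seg <- .largest_remainder(as.numeric(table(seg)), m)
      segs <- sort(unique(seg))
      unlist(lapply(seq_along(segs), function(j) {
        cand <- idx[seg == segs[j]]
        sort(sample(cand, keep_per_seg[j]))
      }), use.names = FALSE)
    })
  }

  out <- list(train = integer(), val = integer(), test = integer())
  for (k in seq_along(pools)) {
    idx <- pools[[k]]
    sizes_k <- .largest_remainder(rep(1, 3) * fractions, length(idx))
    # draw val and test stratified by trial segment; remainder is train
    seg <- labeled$segment[idx]
    segs <- sort(unique(seg))
    remaining <- split(idx, factor(seg, levels = segs))
    take <- function(n_needed) {
      per_seg <- .largest_remainder(lengths(remaining), n_needed)
      got <- integer(0)
      for (j in seq_along(remaining)) {
        nj <- min(per_seg[j], length(remaining[[j]]))
        if (nj > 0) {
          sel <- sample(seq_along(remaining[[j]]), nj)
          got <- c(got, remaining[[j]][sel])
          remaining[[j]] <<- remaining[[j]][-sel]
        }
      }
      got
    }
    out$test <- c(out$test, take(sizes_k[3L]))
    out$val <- c(out$val, take(sizes_k[2L]))
    out$train <- c(out$train, unlist(remaining, use.names = FALSE))
  }
  lapply(out, sort)
}

#' Two-tailed t-test between activity and rest samples
#'
#' Compares the per-sample channel-mean feature between the two classes of a
#' labeled dataset with a pooled-variance two-sample t-test (see
#' [two_sample_ttest()]).
#'
#' @param labeled A two-class `labeled_dataset`.
#' @return A list with `t` and `p`.
#' @export
class_difference_ttest <- function(labeled) {
  stopifnot(inherits(labeled, "labeled_dataset"))
  cls <- labeled$class
  classes <- sort(unique(cls[!is.na(cls)]))
  if (length(classes) != 2L) stop("expected exactly two classes")
  v <- rowMeans(labeled$x)
  a <- v[!is.na(cls) & cls == classes[2L]]  # activity
  b <- v[!is.na(cls) & cls == classes[1L]]  # rest
  two_sample_ttest(a, b)
}

#' Build windowed training samples from a labeled dataset
#'
#' Each selected labeled time point becomes one training sample: the window
#' of `window_length` consecutive samples ending at it, confined to the time
#' point's own segment (windows never cross a condition boundary; at a
#' segment start the first in-segment sample is replicated to pad the
#' window). Labels are re-coded to `0..k-1` in increasing class order.
#'
#' @param labeled A `labeled_dataset`.
#' @param indices Row indices (e.g. one partition from [split_dataset()]).
#' @param window_length Window length W.
#' @return A list with `x` (`B x W x D` array), `y` (integer labels
#'   `0..k-1`) and `classes` (original class values in label order).
#' @export
windowed_samples <- function(labeled, indices, window_length = 20L) {
  stopifnot(inherits(labeled, "labeled_dataset"), window_length >= 1)
  W <- as.integer(window_length)
  indices <- indices[!is.na(labeled$class[indices])]
  B <- length(indices)
  D <- ncol(labeled$x)
  seg_start <- c(1L, which(diff(labeled$segment) != 0L) + 1L)
  start_of <- seg_start[findInterval(indices, seg_start)]
  X <- array(0, dim = c(B, W, D))
  for (b in seq_len(B)) {
    i <- indices[b]; s <- start_of[b]
    rows <- pmax(seq.int(i - W + 1L, i), s)
    X[b, , ] <- labeled$x[rows, , drop = FALSE]
  }
  classes <- sort(unique(labeled$class[!is.na(labeled$class)]))
  y <- match(labeled$class[indices], classes) - 1L
  list(x = X, y = y, classes = classes)
}
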