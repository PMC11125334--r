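test_that("MBLL conversion inverts the extinction system", {
  # identity extinction matrix, unit path length: channels pass through
  E <- extinction_table(hbo = c(1, 0), hbr = c(0, 1))
  a <- absorbance_series(array(rnorm(40), dim = c(10, 2, 2)),
                         distance = 1, dpf = 1)
  h <- mbll_convert(a, E)
  expect_equal(h$hbo, matrix(a$delta_a[, , 1], 10, 2), ignore_attr = TRUE)
  expect_equal(h$hbr, matrix(a$delta_a[, , 2], 10, 2), ignore_attr = TRUE)

  # hand-inverted 2x2 system: E = [[2,1],[1,2]], dA = (3,3) -> (1,1)
  E2 <- extinction_table(hbo = c(2, 1), hbr = c(1, 2))
  a2 <- absorbance_series(array(3, dim = c(4, 1, 2)), distance = 1, dpf = 1)
  h2 <- mbll_convert(a2, E2)
  expect_equal(h2$hbo, matrix(1, 4, 1), ignore_attr = TRUE)
  expect_equal(h2$hbr, matrix(1, 4, 1), ignore_attr = TRUE)

  # zero absorbance -> zero concentrations
  a0 <- absorbance_series(array(0, dim = c(5, 3, 2)))
  h0 <- mbll_convert(a0)
  expect_equal(max(abs(h0$hbo)), 0)

  # linearity
  mk <- function(m) absorbance_series(array(m, dim = c(6, 2, 2)),
                                      distance = 2, dpf = 5)
  x <- rnorm(24); y <- rnorm(24)
  hx <- mbll_convert(mk(x)); hy <- mbll_convert(mk(y))
  hxy <- mbll_convert(mk(2 * x - 3 * y))
  expect_equal(hxy$hbo, 2 * hx$hbo - 3 * hy$hbo, tolerance = 1e-12)
})

test_that("MBLL round trip is exact to 1e-10 and warns when ill-conditioned", {
  set.seed(2)
  hemo <- hemoglobin_series(matrix(rnorm(60), 20, 3),
                            matrix(rnorm(60), 20, 3))
  back <- mbll_convert(inverse_mbll(hemo, distance = 3, dpf = 6),
                       extinction_table())
  expect_equal(back$hbo, hemo$hbo, tolerance = 1e-10)
  expect_equal(back$hbr, hemo$hbr, tolerance = 1e-10)

  expect_warning(extinction_table(hbo = c(1, 1), hbr = c(1, 1 + 1e-8)),
                 "ill-conditioned")
  bad <- suppressWarnings(extinction_table(hbo = c(1, 1),
                                           hbr = c(1, 1 + 1e-8)))
  expect_true(is.finite(bad$condition_number))
  expect_error(extinction_table(hbo = c(1, 1), hbr = c(1, 1)), "singular")
})

test_that("band-pass filter has the designed frequency response, zero phase", {
  fs <- 10.1725
  n <- 20000
  t <- (0:(n - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))

  hi <- sin(2 * pi * 1 * t)             # cardiac-band tone: stop band
  expect_lt(rms(bandpass_filter(hi, fs = fs)) / rms(hi), 0.05)

  lo <- sin(2 * pi * 0.05 * t)          # hemodynamic band: pass band
  ratio <- rms(bandpass_filter(lo, fs = fs)) / rms(lo)
  expect_gte(ratio, 0.80)
  expect_lte(ratio, 1.10)

  dc <- rep(2, n)                       # DC removed
  ydc <- bandpass_filter(dc, fs = fs)
  expect_lt(abs(mean(ydc[2000:(n - 2000)])), 0.02)

  # zero phase: in-band sinusoid peak lag at most one sample
  y <- bandpass_filter(lo, fs = fs)
  cc <- stats::ccf(y[3000:17000], lo[3000:17000], lag.max = 10, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 1)

  expect_error(bandpass_filter(lo, low = 0.2, high = 0.01, fs = fs), "band")
  expect_error(bandpass_filter(lo, low = 0.01, high = 6, fs = fs), "band")
})

test_that("paradigm schedules account for every second", {
  p <- build_paradigm()
  expect_equal(attr(p, "total_duration"), 360)
  expect_equal(sum(p$condition == "activity"), 10)
  expect_equal(sum(p$condition == "rest"), 10)

  p0 <- build_paradigm(n_trials = 0)
  expect_equal(attr(p0, "total_duration"), 60)
  expect_equal(p0$condition, c("baseline", "baseline"))

  p2 <- build_paradigm(initial_rest = 10, n_trials = 2, activity = 5,
                       rest = 5, final_rest = 10)
  expect_equal(attr(p2, "total_duration"), 40)

  mc <- build_multiclass_paradigm(n_classes = 3, trials_per_class = 4,
                                  activity = 10, rest = 20)
  expect_equal(attr(mc, "total_duration"), 30 + 3 * 4 * 30 + 30)
})

test_that("segmentation reproduces the block-design sample counts", {
  fs <- 10.1725
  x <- matrix(0, 3662, 4)
  lab <- segment_and_label(x, build_paradigm(), fs = fs)
  counts <- stats::setNames(lab$counts, lab$condition_levels)
  expect_equal(counts[["baseline"]], 610)
  expect_equal(counts[["activity"]], 1017)
  expect_equal(counts[["rest"]], 2034)
  expect_equal(sum(lab$counts), 3661)
  expect_equal(sum(is.na(lab$class)), 610)
  expect_equal(sum(lab$class == 2, na.rm = TRUE), 1017)  # activity
  expect_equal(sum(lab$class == 1, na.rm = TRUE), 2034)  # trial rest

  # integer sampling rate: counts equal durations in seconds
  lab1 <- segment_and_label(matrix(0, 360, 1), build_paradigm(), fs = 1)
  expect_equal(stats::setNames(lab1$counts, lab1$condition_levels),
               c(activity = 100, baseline = 60, rest = 200))

  # fractional counts floor per condition: fs = 2.5, 3 s activity + 2 s rest
  sched <- build_paradigm(initial_rest = 0, n_trials = 1, activity = 3,
                          rest = 2, final_rest = 0)
  lab2 <- segment_and_label(matrix(0, 13, 1), sched, fs = 2.5)
  expect_equal(stats::setNames(lab2$counts, lab2$condition_levels),
               c(activity = 7, rest = 5))

  expect_error(segment_and_label(matrix(0, 100, 1), build_paradigm(),
                                 fs = fs), "needs")
})

test_that("counts sum identity holds for arbitrary schedules", {
  set.seed(55)
  for (r in 1:20) {
    fs <- runif(1, 1, 12)
    sched <- build_paradigm(initial_rest = sample(5:40, 1),
                            n_trials = sample(1:8, 1),
                            activity = runif(1, 3, 12),
                            rest = runif(1, 3, 25),
                            final_rest = sample(5:40, 1))
    n <- ceiling(attr(sched, "total_duration") * fs) + 2
    lab <- segment_and_label(matrix(0, n, 1), sched, fs = fs)
    cond_tot <- tapply(sched$duration, sched$condition, sum)
    expect_equal(sort(lab$counts),
                 sort(unname(floor(as.numeric(cond_tot) * fs))))
  }
})

test_that("dataset splits are disjoint, seeded, and class-balanced", {
  lab <- segment_and_label(matrix(rnorm(3662 * 2), 3662, 2),
                           build_paradigm(), fs = 10.1725)

  # balanced mode: every partition has equal class counts
  pb <- split_dataset(lab, seed = 4, balance_classes = TRUE)
  for (part in pb) {
    tab <- table(lab$class[part])
    expect_equal(unname(diff(range(tab))), 0)
  }
  expect_equal(length(unlist(pb)), 2 * 1017)
  expect_equal(length(intersect(pb$train, c(pb$val, pb$test))), 0)
  expect_equal(length(intersect(pb$val, pb$test)), 0)
  # samples drawn from every trial
  expect_equal(length(unique(lab$trial[pb$test])), 10)

  # exhaustive mode: all labeled samples covered, test partition 305/306
  pe <- split_dataset(lab, seed = 4, balance_classes = FALSE)
  expect_equal(sort(unname(unlist(pe))), which(!is.na(lab$class)))
  expect_true(length(pe$test) %in% c(305L, 306L))

  # reproducibility
  expect_identical(split_dataset(lab, seed = 9),
                   split_dataset(lab, seed = 9))

  # simple balanced case: 100 samples 50/50 -> 80/10/10 at 40/40, 5/5, 5/5
  sched <- build_paradigm(initial_rest = 0, n_trials = 1, activity = 50,
                          rest = 50, final_rest = 0)
  lab2 <- segment_and_label(matrix(0, 100, 1), sched, fs = 1)
  ps <- split_dataset(lab2, seed = 1)
  expect_equal(lengths(ps), c(train = 80L, val = 10L, test = 10L))
  expect_equal(unname(table(lab2$class[ps$train])), c(40L, 40L),
               ignore_attr = TRUE)
  expect_equal(unname(table(lab2$class[ps$test])), c(5L, 5L),
               ignore_attr = TRUE)
})

test_that("windowed samples are causal, segment-confined and padded", {
  sched <- build_paradigm(initial_rest = 0, n_trials = 1, activity = 5,
                          rest = 5, final_rest = 0)
  x <- matrix(seq_len(10), 10, 1)
  lab <- segment_and_label(x, sched, fs = 1)
  w <- windowed_samples(lab, indices = c(1, 3, 6, 7), window_length = 3)
  expect_equal(dim(w$x), c(4, 3, 1))
  expect_equal(w$x[1, , 1], c(1, 1, 1))   # segment start: replicated pad
  expect_equal(w$x[2, , 1], c(1, 2, 3))   # fully inside activity
  expect_equal(w$x[3, , 1], c(6, 6, 6))   # rest segment start at row 6
  expect_equal(w$x[4, , 1], c(6, 6, 7))
  expect_equal(w$y, c(1L, 1L, 0L, 0L))    # activity = class 2 -> label 1
})

test_that("class-difference t-test behaves like a pooled two-sample test", {
  sched <- build_paradigm(initial_rest = 0, n_trials = 1, activity = 4,
                          rest = 4, final_rest = 0)
  mk <- function(act, rst) {
    lab <- segment_and_label(matrix(c(act, rst), ncol = 1), sched, fs = 1)
    lab
  }
  # identical classes: t = 0, p = 1
  r <- class_difference_ttest(mk(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # well-separated classes with tiny jitter: p < 0.001
  set.seed(1)
  r2 <- class_difference_ttest(mk(1 + rnorm(4, 0, 1e-3),
                                  rnorm(4, 0, 1e-3)))
  expect_lt(r2$p, 0.001)

  # swapping the class roles negates t, keeps p
  r3 <- class_difference_ttest(mk(rnorm(4, 0, 1e-3),
                                  1 + rnorm(4, 0, 1e-3)))
  expect_lt(r3$t, 0)
})
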