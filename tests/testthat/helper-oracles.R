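# Independent oracles used across the suite. These deliberately avoid the
# package's unroll/backward code paths: scalar recurrences are written out
# in plain arithmetic, gradients come from central finite differences, and
# classifier sanity bounds come from a logistic model on summary features.

sig <- function(x) 1 / (1 + exp(-x))

# Scalar (D = H = 1) LSTM recurrence with every weight = w, biases = 0.
scalar_lstm_oracle <- function(x_seq, w = 1, c0 = 0, h0 = 0) {
  c_ <- c0; h <- h0
  out <- matrix(NA_real_, length(x_seq), 2)
  for (t in seq_along(x_seq)) {
    pre <- w * x_seq[t] + w * h
    i <- sig(pre); f <- sig(pre); o <- sig(pre); g <- tanh(pre)
    c_ <- f * c_ + i * g
    h <- o * tanh(c_)
    out[t, ] <- c(c_, h)
  }
  colnames(out) <- c("c", "h")
  out
}

# Scalar ICGN recurrence, all weights = w, biases = 0: every gate and the
# candidate see w*x + w*h + w*c, and c_t = (i+f+o)*g with no carry term.
scalar_icgn_oracle <- function(x_seq, w = 1, c0 = 0, h0 = 0) {
  c_ <- c0; h <- h0
  out <- matrix(NA_real_, length(x_seq), 2)
  for (t in seq_along(x_seq)) {
    pre <- w * x_seq[t] + w * h + w * c_
    i <- sig(pre); f <- sig(pre); o <- sig(pre); g <- tanh(pre)
    c_ <- (i + f + o) * g
    h <- o * tanh(c_)
    out[t, ] <- c(c_, h)
  }
  colnames(out) <- c("c", "h")
  out
}

# Central finite-difference gradient of a sequence loss w.r.t. every
# parameter array, compared against cell_gradients(); returns the max
# relative error. The denominator floor (1e-4) keeps entries whose true
# gradient is at the finite-difference noise floor (~1e-10 absolute) from
# reporting spurious relative error.
fd_gradient_max_rel_err <- function(params, X, target, eps = 1e-6) {
  ls <- loss_spec(target, "final")
  an <- cell_gradients(params, X, ls)
  loss_of <- function(p) {
    h <- unroll(p, X)$hidden
    0.5 * sum((h[nrow(h), ] - target)^2)
  }
  max_rel <- 0
  for (nm in names(an$gradients)) {
    for (j in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - eps
      fd <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      a <- an$gradients[[nm]][j]
      max_rel <- max(max_rel, abs(fd - a) / max(abs(fd), abs(a), 1e-4))
    }
  }
  max_rel
}

# Linear separability oracle: logistic regression on per-window channel
# means and slopes. Returns test accuracy in percent.
logistic_window_oracle <- function(train, test) {
  feats <- function(S) {
    mu <- apply(S$x, c(1, 3), mean)
    W <- dim(S$x)[2]
    tt <- seq_len(W) - mean(seq_len(W))
    sl <- apply(S$x, c(1, 3), function(v) sum(v * tt) / sum(tt^2))
    cbind(1, mu, sl)
  }
  fit <- suppressWarnings(
    stats::glm.fit(feats(train), train$y, family = stats::binomial()))
  pred <- as.numeric(feats(test) %*% fit$coefficients > 0)
  100 * mean(pred == test$y)
}

# Small random cell parameters with optionally inflated weight scales (to
# probe the ICGN state bound far from the origin).
random_cell <- function(kind, D, H, seed, scale = 1, ...) {
  p <- init_cell_parameters(kind, D, H, "normal_scaled", seed = seed, ...)
  if (scale != 1) {
    for (nm in grep("^w_", names(p), value = TRUE))
      p[[nm]] <- p[[nm]] * scale
  }
  p
}

# Two-class toy sequence set: class-dependent mean trajectories plus noise.
# Linearly separable at high SNR.
toy_sequences <- function(n = 200, T_len = 10, D = 2, sd = 0.3, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- array(stats::rnorm(n * T_len * D, 0, sd), dim = c(n, T_len, D))
  ramp <- seq(0, 1, length.out = T_len)
  for (b in seq_len(n))
    X[b, , 1] <- X[b, , 1] + if (y[b] == 1) ramp else -ramp
  list(x = X, y = y)
}

# One preprocessed high-SNR synthetic subject: filtered, labeled, split,
# windowed. Shared by network/synthetic/acceptance tests.
prepared_subject <- function(seed = 11, n_channels = 10,
                             window_length = 20L) {
  cfg <- synthetic_subject_config(
    n_channels = n_channels,
    noise = noise_params(white_sd = 0.1),
    seed = seed)
  subj <- generate_subject(cfg)
  filtered <- bandpass_filter(subj$series)
  labeled <- segment_and_label(filtered, cfg$paradigm)
  parts <- split_dataset(labeled, seed = seed)
  list(train = windowed_samples(labeled, parts$train, window_length),
       val = windowed_samples(labeled, parts$val, window_length),
       test = windowed_samples(labeled, parts$test, window_length),
       labeled = labeled, subject = subj)
}
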