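#' Network architecture configuration
#'
#' Describes the sequence classifier used throughout the package: a recurrent
#' layer (LSTM, ICGN, or bidirectional LSTM), a dropout layer on its final
#' hidden representation, a dense ReLU layer, and a dense output layer. The
#' same head is used for every cell kind so that accuracy comparisons between
#' cells reflect the recurrent layer alone.
#'
#' @param cell_kind `"lstm"`, `"icgn"`, or `"bilstm"`.
#' @param recurrent_units Hidden units H of the recurrent cell (per direction
#'   for `"bilstm"`). Default 64.
#' @param dropout_rate Dropout probability in `[0, 1)` applied to the
#'   recurrent output during training only. Default 0.2.
#' @param dense_units Units of the intermediate dense ReLU layer. Default 64.
#' @param n_classes Number of output classes (>= 2). Default 2.
#' @param output_activation `"softmax"` (default) or `"sigmoid"`.
#' @param window_length Timesteps W per classified window. Each labeled time
#'   point is classified from the window of W consecutive samples ending at
#'   it. Default 20 (about 2 s at 10.1725 Hz).
#' @return A `network_config` object.
#' @export
network_config <- function(cell_kind = c("lstm", "icgn", "bilstm"),
                           recurrent_units = 64L,
                           dropout_rate = 0.2,
                           dense_units = 64L,
                           n_classes = 2L,
                           output_activation = c("softmax", "sigmoid"),
                           window_length = 20L) {
  cell_kind <- match.arg(cell_kind)
  output_activation <- match.arg(output_activation)
  stopifnot(recurrent_units >= 1, dense_units >= 1, n_classes >= 2,
            dropout_rate >= 0, dropout_rate < 1, window_length >= 1)
  structure(list(cell_kind = cell_kind,
                 recurrent_units = as.integer(recurrent_units),
                 dropout_rate = dropout_rate,
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 output_activation = output_activation,
                 window_length = as.integer(window_length)),
            class = "network_config")
}

#' Training configuration
#'
#' @param learning_rate Step size (default 0.001).
#' @param epochs Full passes over the training set (default 100).
#' @param batch_size Mini-batch size (default 32).
#' @param loss `"categorical_crossentropy"` (default) or
#'   `"mean_squared_error"`, both on one-hot targets.
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param clip_norm Global gradient-norm clipping threshold; batch gradients
#'   whose overall L2 norm exceeds it are rescaled to it. The standard guard
#'   against the exploding-gradient instabilities of recurrent training;
#'   `Inf` disables clipping. Default 5.
#' @param seed Integer seed controlling shuffling and dropout masks.
#' @return A `training_config` object.
#' @export
training_config <- function(learning_rate = 0.001,
                            epochs = 100L,
                            batch_size = 32L,
                            loss = c("categorical_crossentropy",
                                     "mean_squared_error"),
                            optimizer = c("adam", "sgd"),
                            clip_norm = 5,
                            seed = 1L) {
  loss <- match.arg(loss)
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1, clip_norm > 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 optimizer = optimizer, clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "training_config")
}

.dense_init <- function(nrow, ncol) {
  matrix(stats::runif(nrow * ncol, -1 / sqrt(ncol), 1 / sqrt(ncol)),
         nrow, ncol)
}

#' Build a recurrent sequence classifier
#'
#' Instantiates the architecture of [network_config()] with seeded random
#' initial weights: recurrent cell(s), dense ReLU layer, and output layer.
#'
#' @param config A [network_config()].
#' @param input_dim Features per timestep D (e.g. number of fNIRS channels).
#' @param seed Integer seed; the same seed and config yield bitwise-identical
#'   initial weights.
#' @return A `recurrent_classifier` object.
#' @export
build_classifier <- function(config, input_dim, seed = 1L) {
  stopifnot(inherits(config, "network_config"), input_dim >= 1)
  set.seed(as.integer(seed))
  H <- config$recurrent_units
  kind <- if (config$cell_kind == "bilstm") "lstm" else config$cell_kind
  cell <- init_cell_parameters(kind, input_dim, H, "uniform_scaled")
  cell_bwd <- NULL
  feat_dim <- H
  if (config$cell_kind == "bilstm") {
    cell_bwd <- init_cell_parameters("lstm", input_dim, H, "uniform_scaled")
    feat_dim <- 2L * H
  }
  model <- list(config = config, input_dim = as.integer(input_dim),
                cell = cell, cell_bwd = cell_bwd,
                w1 = .dense_init(config$dense_units, feat_dim),
                b1 = rep(0, config$dense_units),
                w2 = .dense_init(config$n_classes, config$dense_units),
                b2 = rep(0, config$n_classes))
  class(model) <- "recurrent_classifier"
  model
}

#' Number of trainable parameters of a classifier
#'
#' @param model A `recurrent_classifier`.
#' @return Integer parameter count (recurrent cell(s) plus dense layers).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "recurrent_classifier"))
  count_cell <- function(p)
    sum(vapply(.param_array_names(p), function(nm) length(p[[nm]]), 0))
  n <- count_cell(model$cell)
  if (!is.null(model$cell_bwd)) n <- n + count_cell(model$cell_bwd)
  n + length(model$w1) + length(model$b1) + length(model$w2) +
    length(model$b2)
}

#' @export
print.recurrent_classifier <- function(x, ...) {
  cat(sprintf("<recurrent_classifier> %s, D = %d, H = %d, %d classes, %d parameters\n",
              x$config$cell_kind, x$input_dim, x$config$recurrent_units,
              x$config$n_classes, n_parameters(x)))
  invisible(x)
}

# Forward pass to the recurrent feature (final hidden state; for bilstm the
# concatenation of both directions' final states). X: B x T x D.
.recurrent_features <- function(model, X) {
  fwd <- .cell_forward_batch(model$cell, X)
  feat <- fwd$h[[fwd$T_len]]
  cache <- list(fwd = fwd)
  if (!is.null(model$cell_bwd)) {
    Xr <- X[, rev(seq_len(dim(X)[2L])), , drop = FALSE]
    bwd <- .cell_forward_batch(model$cell_bwd, Xr)
    feat <- cbind(feat, bwd$h[[bwd$T_len]])
    cache$bwd <- bwd
  }
  cache$feat <- feat
  cache
}

.head_forward <- function(model, feat) {
  z1 <- feat %*% t(model$w1) + rep(model$b1, each = nrow(feat))
  r1 <- pmax(z1, 0)
  z2 <- r1 %*% t(model$w2) + rep(model$b2, each = nrow(feat))
  if (model$config$output_activation == "softmax") {
    z2m <- z2 - apply(z2, 1L, max)
    e <- exp(z2m)
    probs <- e / rowSums(e)
  } else {
    probs <- sigmoid(z2)
  }
  list(z1 = z1, r1 = r1, z2 = z2, probs = probs)
}

# Loss value and gradient w.r.t. the output pre-activations z2.
.loss_and_dz2 <- function(probs, onehot, loss, activation) {
  B <- nrow(probs)
  eps <- 1e-12
  if (loss == "categorical_crossentropy") {
    if (activation == "softmax") {
      value <- -mean(rowSums(onehot * log(probs + eps)))
      dz2 <- (probs - onehot) / B
    } else {
      value <- -mean(rowSums(onehot * log(probs + eps) +
                               (1 - onehot) * log(1 - probs + eps)))
      dz2 <- (probs - onehot) / (B * ncol(probs))
    }
  } else {  # mean_squared_error on the activated outputs
    value <- mean((probs - onehot)^2)
    dp <- 2 * (probs - onehot) / (B * ncol(probs))
    if (activation == "softmax") {
      dz2 <- probs * (dp - rowSums(dp * probs))
    } else {
      dz2 <- dp * probs * (1 - probs)
    }
  }
  list(value = value, dz2 = dz2)
}

.adam_state <- function(shapes) {
  lapply(shapes, function(s) list(m = s * 0, v = s * 0))
}

# Flatten the trainable tensors of a model into a named list.
.model_tensors <- function(model) {
  out <- list()
  for (nm in .param_array_names(model$cell))
    out[[paste0("cell.", nm)]] <- model$cell[[nm]]
  if (!is.null(model$cell_bwd))
    for (nm in .param_array_names(model$cell_bwd))
      out[[paste0("cell_bwd.", nm)]] <- model$cell_bwd[[nm]]
  out$w1 <- model$w1; out$b1 <- model$b1
  out$w2 <- model$w2; out$b2 <- model$b2
  out
}

.apply_tensors <- function(model, tensors) {
  for (nm in names(tensors)) {
    if (startsWith(nm, "cell_bwd.")) {
      model$cell_bwd[[sub("^cell_bwd\\.", "", nm)]] <- tensors[[nm]]
    } else if (startsWith(nm, "cell.")) {
      model$cell[[sub("^cell\\.", "", nm)]] <- tensors[[nm]]
    } else model[[nm]] <- tensors[[nm]]
  }
  model
}

# Full-model gradient for one batch. Returns loss, accuracy and named
# gradient list aligned with .model_tensors().
.model_batch_gradient <- function(model, X, onehot, dropout_mask = NULL) {
  cfg <- model$config
  rc <- .recurrent_features(model, X)
  feat <- rc$feat
  if (!is.null(dropout_mask)) feat <- feat * dropout_mask
  hd <- .head_forward(model, feat)
  ld <- .loss_and_dz2(hd$probs, onehot, attr(onehot, "loss"),
                      cfg$output_activation)
  dz2 <- ld$dz2
  g <- list()
  g$w2 <- crossprod(dz2, hd$r1)
  g$b2 <- colSums(dz2)
  dr1 <- dz2 %*% model$w2
  dz1 <- dr1 * (hd$z1 > 0)
  g$w1 <- crossprod(dz1, feat)
  g$b1 <- colSums(dz1)
  dfeat <- dz1 %*% model$w1
  if (!is.null(dropout_mask)) dfeat <- dfeat * dropout_mask

  H <- cfg$recurrent_units
  T_len <- dim(X)[2L]
  mk_inj <- function(d_final) {
    inj <- vector("list", T_len)
    zero <- matrix(0, nrow(d_final), ncol(d_final))
    for (t in seq_len(T_len)) inj[[t]] <- zero
    inj[[T_len]] <- d_final
    inj
  }
  bw <- .cell_backward_batch(model$cell, rc$fwd,
                             mk_inj(dfeat[, seq_len(H), drop = FALSE]))
  for (nm in names(bw$gradients)) g[[paste0("cell.", nm)]] <- bw$gradients[[nm]]
  if (!is.null(model$cell_bwd)) {
    bwb <- .cell_backward_batch(model$cell_bwd, rc$bwd,
                                mk_inj(dfeat[, H + seq_len(H), drop = FALSE]))
    for (nm in names(bwb$gradients))
      g[[paste0("cell_bwd.", nm)]] <- bwb$gradients[[nm]]
  }
  pred <- max.col(hd$probs, ties.method = "first") - 1L
  list(loss = ld$value, gradients = g, predicted = pred)
}

#' Train a recurrent classifier
#'
#' Mini-batch gradient descent (Adam by default) on windowed labeled
#' sequences, with seeded shuffling, seeded inverted-dropout masks on the
#' recurrent output, and a per-epoch history of training and validation loss
#' and accuracy.
#'
#' @param model A `recurrent_classifier` from [build_classifier()].
#' @param train A list with `x` (`B x T x D` array) and `y` (integer class
#'   labels in `0..n_classes-1`).
#' @param val Optional validation list of the same shape.
#' @param config A [training_config()].
#' @param verbose Print per-epoch progress every `verbose` epochs (0 = quiet).
#' @return A list with `model` (trained) and `history` (a data.frame with
#'   columns epoch, loss, accuracy, val_loss, val_accuracy), the latter of
#'   class `training_history`.
#' @export
train_classifier <- function(model, train, val = NULL, config = training_config(),
                             verbose = 0L) {
  stopifnot(inherits(model, "recurrent_classifier"),
            inherits(config, "training_config"))
  X <- train$x; y <- as.integer(train$y)
  if (length(dim(X)) != 3L) stop("`train$x` must be a B x T x D array")
  n <- dim(X)[1L]
  if (n < 1L) stop("empty training set")
  k <- model$config$n_classes
  if (any(y < 0L | y >= k)) stop("labels must lie in 0..n_classes-1")
  if (length(y) != n) stop("labels do not match the number of samples")

  set.seed(config$seed)
  tensors <- .model_tensors(model)
  opt <- .adam_state(tensors)
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  drop_p <- model$config$dropout_rate
  feat_dim <- ncol(model$w1)

  hist <- data.frame(epoch = integer(), loss = numeric(),
                     accuracy = numeric(), val_loss = numeric(),
                     val_accuracy = numeric())
  onehot_all <- diag(k)[y + 1L, , drop = FALSE]

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_correct <- 0L
    for (b in batches) {
      Xb <- X[b, , , drop = FALSE]
      oh <- onehot_all[b, , drop = FALSE]
      attr(oh, "loss") <- config$loss
      mask <- NULL
      if (drop_p > 0) {
        mask <- matrix(stats::rbinom(length(b) * feat_dim, 1L, 1 - drop_p),
                       length(b), feat_dim) / (1 - drop_p)
      }
      res <- .model_batch_gradient(model, Xb, oh, mask)
      step <- step + 1L
      if (is.finite(config$clip_norm)) {
        gnorm <- sqrt(sum(vapply(res$gradients,
                                 function(g) sum(g^2), 0)))
        if (gnorm > config$clip_norm) {
          scl <- config$clip_norm / gnorm
          res$gradients <- lapply(res$gradients, function(g) g * scl)
        }
      }
      for (nm in names(res$gradients)) {
        gr <- res$gradients[[nm]]
        if (config$optimizer == "adam") {
          st <- opt[[nm]]
          st$m <- beta1 * st$m + (1 - beta1) * gr
          st$v <- beta2 * st$v + (1 - beta2) * gr^2
          opt[[nm]] <- st
          mhat <- st$m / (1 - beta1^step)
          vhat <- st$v / (1 - beta2^step)
          tensors[[nm]] <- tensors[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        } else {
          tensors[[nm]] <- tensors[[nm]] - lr * gr
        }
      }
      model <- .apply_tensors(model, tensors)
      ep_loss <- ep_loss + res$loss * length(b)
      ep_correct <- ep_correct + sum(res$predicted == y[b])
    }
    row <- data.frame(epoch = epoch, loss = ep_loss / n,
                      accuracy = 100 * ep_correct / n,
                      val_loss = NA_real_, val_accuracy = NA_real_)
    if (!is.null(val)) {
      ev <- evaluate_classifier(model, val, loss = config$loss)
      row$val_loss <- ev$loss
      row$val_accuracy <- ev$accuracy
    }
    hist <- rbind(hist, row)
    if (verbose > 0 && epoch %% verbose == 0)
      message(sprintf("epoch %d/%d loss %.4f acc %.2f%%",
                      epoch, config$epochs, row$loss, row$accuracy))
  }
  class(hist) <- c("training_history", "data.frame")
  list(model = model, history = hist)
}

#' Predict class probabilities and labels
#'
#' Dropout is disabled at inference, so predictions are deterministic
#' functions of the model and inputs. With a softmax output the probability
#' rows sum to one.
#'
#' @param object A `recurrent_classifier`.
#' @param x A `B x T x D` array (or `T x D` matrix for a single sample).
#' @param ... Unused.
#' @return A list with `probabilities` (`B x n_classes` matrix) and `labels`
#'   (integer vector in `0..n_classes-1`).
#' @export
predict.recurrent_classifier <- function(object, x, ...) {
  if (length(dim(x)) == 2L)
    x <- array(x, dim = c(1L, nrow(x), ncol(x)))
  rc <- .recurrent_features(object, x)
  hd <- .head_forward(object, rc$feat)
  list(probabilities = hd$probs,
       labels = max.col(hd$probs, ties.method = "first") - 1L)
}

#' Evaluate a classifier on a labeled set
#'
#' @param model A `recurrent_classifier`.
#' @param data List with `x` (`B x T x D`) and `y` (labels in
#'   `0..n_classes-1`).
#' @param loss Loss to report (defaults to categorical crossentropy).
#' @return List with `loss`, `accuracy` (percent), `confusion`
#'   (k x k matrix) and `predicted`.
#' @export
evaluate_classifier <- function(model, data,
                                loss = "categorical_crossentropy") {
  pr <- predict(model, data$x)
  k <- model$config$n_classes
  y <- as.integer(data$y)
  onehot <- diag(k)[y + 1L, , drop = FALSE]
  ld <- .loss_and_dz2(pr$probabilities, onehot, loss,
                      model$config$output_activation)
  ca <- confusion_and_accuracy(y, pr$labels, k)
  list(loss = ld$value, accuracy = ca$accuracy, confusion = ca$confusion,
       predicted = pr$labels)
}

#' @export
plot.training_history <- function(x, ...) {
  graphics::plot(x$epoch, x$loss, type = "l", xlab = "epoch", ylab = "loss",
                 main = "training history", ...)
  if (any(!is.na(x$val_loss)))
    graphics::lines(x$epoch, x$val_loss, lty = 2)
  invisible(x)
}

#' Hyperparameter grid sweep
#'
#' Trains one classifier per unique combination of the supplied grid values
#' and reports the final validation accuracy of each. Duplicate combinations
#' are collapsed before training.
#'
#' @param grid A named list with any of `recurrent_units`, `dropout_rate`,
#'   `learning_rate`, `loss`, `batch_size`; each entry a vector of values to
#'   cross.
#' @param train,val Labeled window sets as in [train_classifier()].
#' @param cell_kind Recurrent cell for every run.
#' @param epochs Training epochs per combination.
#' @param seed Base seed (same for every combination, so rows differ only by
#'   hyperparameters).
#' @return A data.frame with one row per unique combination and a
#'   `val_accuracy` column (percent).
#' @export
hyperparameter_sweep <- function(grid, train, val,
                                 cell_kind = "icgn", epochs = 20L,
                                 seed = 1L) {
  defaults <- list(recurrent_units = 64L, dropout_rate = 0.2,
                   learning_rate = 0.001,
                   loss = "categorical_crossentropy", batch_size = 32L)
  unknown <- setdiff(names(grid), names(defaults))
  if (length(unknown))
    stop("unknown grid dimensions: ", paste(unknown, collapse = ", "))
  if (!length(grid)) stop("empty grid")
  full <- utils::modifyList(defaults, lapply(grid, unique))
  combos <- expand.grid(full, stringsAsFactors = FALSE)
  combos <- unique(combos)
  n_classes <- length(unique(as.integer(train$y)))
  D <- dim(train$x)[3L]
  combos$val_accuracy <- NA_real_
  for (r in seq_len(nrow(combos))) {
    cfg <- network_config(cell_kind,
                          recurrent_units = combos$recurrent_units[r],
                          dropout_rate = combos$dropout_rate[r],
                          n_classes = max(2L, n_classes),
                          window_length = dim(train$x)[2L])
    model <- build_classifier(cfg, D, seed = seed)
    tc <- training_config(learning_rate = combos$learning_rate[r],
                          epochs = epochs,
                          batch_size = combos$batch_size[r],
                          loss = combos$loss[r], seed = seed)
    fit <- train_classifier(model, train, val = NULL, config = tc)
    combos$val_accuracy[r] <- evaluate_classifier(fit$model, val)$accuracy
  }
  rownames(combos) <- NULL
  combos
}
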