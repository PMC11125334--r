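#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize recurrent cell parameters
#'
#' Allocates and initializes the weight matrices and bias vectors of a single
#' recurrent cell, either a standard LSTM or an integrated contextual gate
#' network (ICGN) cell. An ICGN cell extends the LSTM gate pre-activations
#' with cell-context ("peephole") terms: every gate, and by default also the
#' candidate activation, receives the previous cell state \eqn{c_{t-1}}
#' through its own `H x H` context matrix.
#'
#' Parameter naming follows the gate it serves: `w_x*` multiplies the input
#' \eqn{x_t} (`H x D`), `w_h*` the previous hidden state (`H x H`), `w_c*`
#' the previous cell state (`H x H`, ICGN only), and `b_*` is the bias
#' (length `H`); the suffixes are `i` (input gate), `f` (forget gate),
#' `o` (output gate) and `c` (candidate).
#'
#' @param cell_kind `"lstm"` or `"icgn"`.
#' @param input_dim Input dimension D (positive integer).
#' @param hidden_dim Hidden dimension H (positive integer).
#' @param init_scheme One of `"uniform_scaled"` (uniform on
#'   `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`), `"normal_scaled"`
#'   (`N(0, 1/fan_in)`), or `"zeros"`.
#' @param seed Optional integer; when supplied the initialization is
#'   reproducible (bitwise) for the same arguments.
#' @param forget_bias Constant added to the forget-gate bias at
#'   initialization (default 0).
#' @param share_candidate_with_forget If `TRUE` the candidate activation
#'   reuses the forget-gate weights and bias instead of owning separate
#'   `w_xc`/`w_hc`/`w_cc`/`b_c` parameters (the literal reading of the cell
#'   equations, in which the candidate is written with the forget-gate
#'   symbols). Default `FALSE`: separate candidate parameters, the standard
#'   recurrent-network convention.
#' @param candidate_uses_cell_context ICGN only. If `TRUE` (default) the
#'   candidate pre-activation includes a `w_cc c_{t-1}` context term, as the
#'   cell equations state; `FALSE` drops it so the candidate depends on the
#'   input and previous hidden state only.
#' @param output_context_shared_with_forget ICGN only. If `TRUE` the output
#'   gate reuses the forget gate's context matrix `w_cf` instead of owning a
#'   separate `w_co` (a literal reading of the printed output-gate equation,
#'   most plausibly a typo). Default `FALSE`.
#' @param diagonal_context ICGN only. If `TRUE` the context matrices are
#'   constrained to be diagonal, the classic peephole-LSTM convention;
#'   default `FALSE` (full `H x H` matrices, matching the cell equations'
#'   matrix products).
#'
#' @return An object of class `cell_parameters`: a named list of matrices
#'   and vectors plus the structural flags above.
#' @examples
#' p <- init_cell_parameters("icgn", input_dim = 2, hidden_dim = 3,
#'                           init_scheme = "uniform_scaled", seed = 1)
#' dim(p$w_ci)
#' @export
init_cell_parameters <- function(cell_kind = c("lstm", "icgn"),
                                 input_dim, hidden_dim,
                                 init_scheme = c("uniform_scaled",
                                                 "normal_scaled", "zeros"),
                                 seed = NULL,
                                 forget_bias = 0,
                                 share_candidate_with_forget = FALSE,
                                 candidate_uses_cell_context = TRUE,
                                 output_context_shared_with_forget = FALSE,
                                 diagonal_context = FALSE) {
  cell_kind <- match.arg(cell_kind)
  init_scheme <- match.arg(init_scheme)
  if (length(input_dim) != 1L || input_dim < 1 || input_dim != round(input_dim))
    stop("`input_dim` must be a positive integer")
  if (length(hidden_dim) != 1L || hidden_dim < 1 ||
      hidden_dim != round(hidden_dim))
    stop("`hidden_dim` must be a positive integer")
  D <- as.integer(input_dim)
  H <- as.integer(hidden_dim)
  if (!is.null(seed)) set.seed(as.integer(seed))

  draw <- function(nrow, ncol) {
    fan_in <- ncol
    switch(init_scheme,
      zeros = matrix(0, nrow, ncol),
      uniform_scaled = matrix(
        stats::runif(nrow * ncol, -1 / sqrt(fan_in), 1 / sqrt(fan_in)),
        nrow, ncol),
      normal_scaled = matrix(
        stats::rnorm(nrow * ncol, 0, 1 / sqrt(fan_in)), nrow, ncol))
  }
  draw_ctx <- function() {
    m <- draw(H, H)
    if (diagonal_context) m <- diag(diag(as.matrix(m)), H, H)
    m
  }

  p <- list(
    cell_kind = cell_kind, input_dim = D, hidden_dim = H,
    share_candidate_with_forget = isTRUE(share_candidate_with_forget),
    candidate_uses_cell_context = isTRUE(candidate_uses_cell_context),
    output_context_shared_with_forget =
      isTRUE(output_context_shared_with_forget),
    diagonal_context = isTRUE(diagonal_context)
  )
  p$w_xi <- draw(H, D); p$w_xf <- draw(H, D); p$w_xo <- draw(H, D)
  p$w_hi <- draw(H, H); p$w_hf <- draw(H, H); p$w_ho <- draw(H, H)
  p$b_i <- rep(0, H)
  p$b_f <- rep(forget_bias, H)
  p$b_o <- rep(0, H)
  if (!p$share_candidate_with_forget) {
    p$w_xc <- draw(H, D); p$w_hc <- draw(H, H); p$b_c <- rep(0, H)
  }
  if (cell_kind == "icgn") {
    p$w_ci <- draw_ctx(); p$w_cf <- draw_ctx()
    if (!p$output_context_shared_with_forget) p$w_co <- draw_ctx()
    if (p$candidate_uses_cell_context && !p$share_candidate_with_forget)
      p$w_cc <- draw_ctx()
  }
  class(p) <- "cell_parameters"
  p
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat(sprintf("<cell_parameters> %s cell, input_dim = %d, hidden_dim = %d\n",
              toupper(x$cell_kind), x$input_dim, x$hidden_dim))
  cat("  arrays:", paste(names(x)[vapply(x, is.numeric, TRUE)],
                         collapse = ", "), "\n")
  invisible(x)
}

#' Initial (or explicit) cell state
#'
#' @param hidden_dim Hidden dimension H.
#' @param c,h Optional numeric vectors of length H (default zeros).
#' @return A list with elements `c` (cell state) and `h` (hidden state),
#'   class `cell_state`.
#' @export
cell_state <- function(hidden_dim, c = NULL, h = NULL) {
  H <- as.integer(hidden_dim)
  if (is.null(c)) c <- rep(0, H)
  if (is.null(h)) h <- rep(0, H)
  stopifnot(length(c) == H, length(h) == H)
  structure(list(c = as.numeric(c), h = as.numeric(h)), class = "cell_state")
}

.check_step_input <- function(params, x_t, prev_state) {
  if (length(x_t) != params$input_dim)
    stop(sprintf("input has length %d, expected %d",
                 length(x_t), params$input_dim))
  if (any(!is.finite(x_t))) stop("non-finite input")
  if (length(prev_state$c) != params$hidden_dim ||
      length(prev_state$h) != params$hidden_dim)
    stop("state dimension does not match `hidden_dim`")
}

# Effective candidate weights: either the cell's own candidate parameters or
# (under the sharing flag) aliases of the forget-gate parameters.
.cand <- function(p) {
  if (p$share_candidate_with_forget)
    list(wx = p$w_xf, wh = p$w_hf, wc = p$w_cf, b = p$b_f)
  else
    list(wx = p$w_xc, wh = p$w_hc, wc = p$w_cc, b = p$b_c)
}

.octx <- function(p) if (p$output_context_shared_with_forget) p$w_cf else p$w_co

#' One LSTM step
#'
#' Applies the standard LSTM recurrence for a single timestep:
#' gates \eqn{i_t, f_t, o_t = \sigma(W_x x_t + W_h h_{t-1} + b)}, candidate
#' \eqn{\tilde c_t = \tanh(\cdot)}, cell state
#' \eqn{c_t = f_t \odot c_{t-1} + i_t \odot \tilde c_t}, hidden state
#' \eqn{h_t = o_t \odot \tanh(c_t)}.
#'
#' @param params A `cell_parameters` object with `cell_kind = "lstm"`.
#' @param x_t Numeric input vector of length `input_dim`.
#' @param prev_state A `cell_state` (defaults to zeros).
#' @return A list with `state` (the new `cell_state`) and `gates` (a list
#'   `i`, `f`, `o`, `candidate`, each length H).
#' @export
lstm_step <- function(params, x_t, prev_state = NULL) {
  stopifnot(inherits(params, "cell_parameters"))
  if (params$cell_kind != "lstm") stop("`params` is not an LSTM cell")
  if (is.null(prev_state)) prev_state <- cell_state(params$hidden_dim)
  .check_step_input(params, x_t, prev_state)
  h0 <- prev_state$h; c0 <- prev_state$c
  cw <- .cand(params)
  i <- sigmoid(drop(params$w_xi %*% x_t + params$w_hi %*% h0) + params$b_i)
  f <- sigmoid(drop(params$w_xf %*% x_t + params$w_hf %*% h0) + params$b_f)
  o <- sigmoid(drop(params$w_xo %*% x_t + params$w_ho %*% h0) + params$b_o)
  g <- tanh(drop(cw$wx %*% x_t + cw$wh %*% h0) + cw$b)
  c1 <- f * c0 + i * g
  h1 <- o * tanh(c1)
  list(state = cell_state(params$hidden_dim, c = c1, h = h1),
       gates = list(i = i, f = f, o = o, candidate = g))
}

#' One ICGN step
#'
#' Applies the integrated contextual gate network recurrence for a single
#' timestep. All three gates receive the previous cell state through their
#' context matrices,
#' \eqn{i_t = \sigma(w_{xi} x_t + w_{hi} h_{t-1} + w_{ci} c_{t-1} + b_i)}
#' (forget and output gates analogous), the candidate is
#' \eqn{\tilde c_t = \tanh(w_{xc} x_t + w_{hc} h_{t-1} + w_{cc} c_{t-1} + b_c)},
#' and the memory cell is the candidate scaled by the *sum* of the gate
#' activations,
#' \deqn{c_t = (f_t + i_t + o_t) \odot \tilde c_t,}
#' with no direct \eqn{c_{t-1}} carry term: the previous cell state enters
#' only through the gates and candidate. Consequently \eqn{|c_t| < 3}
#' elementwise and \eqn{|h_t| < \tanh(3)} always hold. The hidden state is
#' \eqn{h_t = o_t \odot \tanh(c_t)}.
#'
#' @inheritParams lstm_step
#' @param params A `cell_parameters` object with `cell_kind = "icgn"`.
#' @return As [lstm_step()].
#' @export
icgn_step <- function(params, x_t, prev_state = NULL) {
  stopifnot(inherits(params, "cell_parameters"))
  if (params$cell_kind != "icgn") stop("`params` is not an ICGN cell")
  if (is.null(prev_state)) prev_state <- cell_state(params$hidden_dim)
  .check_step_input(params, x_t, prev_state)
  h0 <- prev_state$h; c0 <- prev_state$c
  cw <- .cand(params)
  i <- sigmoid(drop(params$w_xi %*% x_t + params$w_hi %*% h0 +
                      params$w_ci %*% c0) + params$b_i)
  f <- sigmoid(drop(params$w_xf %*% x_t + params$w_hf %*% h0 +
                      params$w_cf %*% c0) + params$b_f)
  o <- sigmoid(drop(params$w_xo %*% x_t + params$w_ho %*% h0 +
                      .octx(params) %*% c0) + params$b_o)
  a_c <- drop(cw$wx %*% x_t + cw$wh %*% h0) + cw$b
  if (params$candidate_uses_cell_context && !is.null(cw$wc))
    a_c <- a_c + drop(cw$wc %*% c0)
  g <- tanh(a_c)
  c1 <- (f + i + o) * g
  h1 <- o * tanh(c1)
  list(state = cell_state(params$hidden_dim, c = c1, h = h1),
       gates = list(i = i, f = f, o = o, candidate = g))
}

#' Unroll a recurrent cell over a sequence
#'
#' Applies [lstm_step()] or [icgn_step()] (chosen by `params$cell_kind`)
#' sequentially over the rows of `sequence`.
#'
#' @param params A `cell_parameters` object.
#' @param sequence A `T x D` numeric matrix (rows are timesteps), or a
#'   numeric vector when `D = 1`.
#' @param initial_state Optional `cell_state` (defaults to zeros).
#' @return A list with `hidden` (a `T x H` matrix whose row t is \eqn{h_t})
#'   and `final_state` (a `cell_state`).
#' @export
unroll <- function(params, sequence, initial_state = NULL) {
  stopifnot(inherits(params, "cell_parameters"))
  sequence <- .as_sequence(sequence, params$input_dim)
  T_len <- nrow(sequence)
  if (T_len < 1L) stop("empty sequence")
  step <- if (params$cell_kind == "lstm") lstm_step else icgn_step
  state <- if (is.null(initial_state)) cell_state(params$hidden_dim)
           else initial_state
  hidden <- matrix(0, T_len, params$hidden_dim)
  for (t in seq_len(T_len)) {
    out <- step(params, sequence[t, ], state)
    state <- out$state
    hidden[t, ] <- state$h
  }
  list(hidden = hidden, final_state = state)
}

.as_sequence <- function(sequence, input_dim) {
  if (is.null(dim(sequence))) {
    if (input_dim == 1L) sequence <- matrix(sequence, ncol = 1L)
    else stop("`sequence` must be a T x D matrix")
  }
  sequence <- as.matrix(sequence)
  if (ncol(sequence) != input_dim)
    stop(sprintf("sequence has %d columns, expected input_dim = %d",
                 ncol(sequence), input_dim))
  if (nrow(sequence) < 1L) stop("empty sequence")
  if (any(!is.finite(sequence))) stop("non-finite values in sequence")
  sequence
}

#' Bidirectional unroll
#'
#' Runs one cell forward over the sequence and a second cell over the
#' time-reversed sequence, re-reverses the backward outputs to forward time
#' order, and concatenates the two hidden sequences column-wise.
#'
#' @param forward_params,backward_params `cell_parameters` sharing
#'   `input_dim` and `hidden_dim` (their `cell_kind` may differ).
#' @param sequence A `T x D` matrix.
#' @return A `T x 2H` matrix; columns `1..H` are the forward pass, columns
#'   `H+1..2H` the backward pass mapped back to forward time order.
#' @export
bidirectional_unroll <- function(forward_params, backward_params, sequence) {
  if (forward_params$input_dim != backward_params$input_dim ||
      forward_params$hidden_dim != backward_params$hidden_dim)
    stop("forward and backward cells must share input_dim and hidden_dim")
  sequence <- .as_sequence(sequence, forward_params$input_dim)
  fwd <- unroll(forward_params, sequence)$hidden
  rev_idx <- rev(seq_len(nrow(sequence)))
  bwd <- unroll(backward_params, sequence[rev_idx, , drop = FALSE])$hidden
  cbind(fwd, bwd[rev_idx, , drop = FALSE])
}

#' Specify a differentiable loss on unrolled hidden states
#'
#' Currently a squared-error loss: `L = 0.5 * sum((h - target)^2)` over the
#' final hidden state (`steps = "final"`) or the whole hidden sequence
#' (`steps = "all"`).
#'
#' @param targets Numeric vector of length H (`steps = "final"`) or `T x H`
#'   matrix (`steps = "all"`).
#' @param steps `"final"` or `"all"`.
#' @return A `loss_spec` object.
#' @export
loss_spec <- function(targets, steps = c("final", "all")) {
  steps <- match.arg(steps)
  structure(list(type = "squared_error", targets = targets, steps = steps),
            class = "loss_spec")
}

# Names of the trainable arrays present in a parameter object.
.param_array_names <- function(p) {
  nm <- c("w_xi", "w_xf", "w_xo", "w_hi", "w_hf", "w_ho",
          "b_i", "b_f", "b_o",
          "w_xc", "w_hc", "b_c", "w_ci", "w_cf", "w_co", "w_cc")
  nm[nm %in% names(p)]
}

#' Gradients of a sequence loss with respect to cell parameters
#'
#' Computes the loss of [loss_spec()] on the unrolled hidden states and its
#' exact gradient with respect to every weight matrix and bias of the cell by
#' backpropagation through time. Gradients match central finite differences
#' to high relative accuracy in double precision (a contract exercised by the
#' test suite).
#'
#' @param params A `cell_parameters` object (LSTM or ICGN).
#' @param sequence A `T x D` matrix.
#' @param loss A [loss_spec()].
#' @param initial_state Optional `cell_state`.
#' @return A list with `loss` (scalar) and `gradients` (named list matching
#'   the parameter arrays of `params`).
#' @export
cell_gradients <- function(params, sequence, loss, initial_state = NULL) {
  stopifnot(inherits(params, "cell_parameters"), inherits(loss, "loss_spec"))
  sequence <- .as_sequence(sequence, params$input_dim)
  X <- array(sequence, dim = c(1L, nrow(sequence), ncol(sequence)))
  fwd <- .cell_forward_batch(params, X, initial_state = initial_state)
  T_len <- nrow(sequence); H <- params$hidden_dim
  hidden <- matrix(0, T_len, H)
  for (t in seq_len(T_len)) hidden[t, ] <- fwd$h[[t]]

  d_hidden <- vector("list", T_len)
  if (loss$steps == "final") {
    target <- as.numeric(loss$targets)
    stopifnot(length(target) == H)
    resid <- hidden[T_len, ] - target
    loss_val <- 0.5 * sum(resid^2)
    for (t in seq_len(T_len)) d_hidden[[t]] <- matrix(0, 1L, H)
    d_hidden[[T_len]] <- matrix(resid, 1L, H)
  } else {
    target <- as.matrix(loss$targets)
    stopifnot(all(dim(target) == c(T_len, H)))
    resid <- hidden - target
    loss_val <- 0.5 * sum(resid^2)
    for (t in seq_len(T_len)) d_hidden[[t]] <- matrix(resid[t, ], 1L, H)
  }
  grads <- .cell_backward_batch(params, fwd, d_hidden)$gradients
  list(loss = loss_val, gradients = grads)
}
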