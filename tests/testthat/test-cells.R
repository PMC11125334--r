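const_cell <- function(kind, value = 1, D = 1, H = 1, ...) {
  p <- init_cell_parameters(kind, D, H, "zeros", ...)
  for (nm in grep("^w_", names(p), value = TRUE)) p[[nm]][] <- value
  p
}

test_that("parameter initialization respects scheme, shapes and seed", {
  p0 <- init_cell_parameters("lstm", 3, 2, "zeros", seed = 1)
  arrays <- grep("^(w_|b_)", names(p0), value = TRUE)
  expect_true(all(vapply(arrays, function(nm) all(p0[[nm]] == 0), TRUE)))
  expect_equal(dim(p0$w_xi), c(2L, 3L))
  expect_equal(dim(p0$w_hf), c(2L, 2L))

  p1 <- init_cell_parameters("icgn", 1, 1, "uniform_scaled", seed = 7)
  expect_equal(dim(p1$w_ci), c(1L, 1L))
  expect_equal(dim(p1$w_cf), c(1L, 1L))
  expect_equal(dim(p1$w_co), c(1L, 1L))

  p2 <- init_cell_parameters("icgn", 4, 3, "normal_scaled", seed = 42)
  p3 <- init_cell_parameters("icgn", 4, 3, "normal_scaled", seed = 42)
  expect_identical(p2, p3)
  expect_false(identical(
    p2, init_cell_parameters("icgn", 4, 3, "normal_scaled", seed = 43)))

  expect_error(init_cell_parameters("lstm", 0, 2), "positive")
  expect_error(init_cell_parameters("lstm", 2, 2, "bogus"))
  # LSTM carries no cell-context matrices
  p_lstm <- init_cell_parameters("lstm", 2, 2, "uniform_scaled", seed = 1)
  expect_false(any(c("w_ci", "w_cf", "w_co", "w_cc") %in% names(p_lstm)))
})

test_that("lstm_step matches the scalar arithmetic oracle", {
  # all-zero parameters: gates sit at sigmoid(0) = 0.5, state stays at 0
  z <- init_cell_parameters("lstm", 2, 2, "zeros")
  s <- lstm_step(z, c(0, 0))
  expect_equal(s$gates$i, rep(0.5, 2))
  expect_equal(s$gates$f, rep(0.5, 2))
  expect_equal(s$gates$o, rep(0.5, 2))
  expect_equal(s$gates$candidate, rep(0, 2))
  expect_equal(s$state$c, rep(0, 2))
  expect_equal(s$state$h, rep(0, 2))

  # zero weights, nonzero previous cell state: pure forget-gate decay
  c0 <- c(1, -2)
  s2 <- lstm_step(z, c(0, 0), cell_state(2, c = c0))
  expect_equal(s2$state$c, 0.5 * c0)
  expect_equal(s2$state$h, 0.5 * tanh(0.5 * c0))

  # scalar cell, every weight 1, x = 1
  oracle <- scalar_lstm_oracle(1)
  s3 <- lstm_step(const_cell("lstm"), 1)
  expect_equal(s3$state$c, oracle[1, "c"], ignore_attr = TRUE)
  expect_equal(s3$state$h, oracle[1, "h"], ignore_attr = TRUE)
  expect_equal(s3$gates$i, sig(1))
  expect_equal(s3$gates$candidate, tanh(1))

  expect_error(lstm_step(z, c(1, 2, 3)), "length")
  expect_error(lstm_step(z, c(1, NA)), "finite")
})

test_that("icgn_step matches the scalar arithmetic oracle", {
  z <- init_cell_parameters("icgn", 2, 2, "zeros")
  s <- icgn_step(z, c(0, 0))
  expect_equal(s$gates$i, rep(0.5, 2))
  expect_equal(s$state$c, rep(0, 2))
  expect_equal(s$state$h, rep(0, 2))

  oracle <- scalar_icgn_oracle(1)
  s2 <- icgn_step(const_cell("icgn"), 1)
  expect_equal(s2$state$c, oracle[1, "c"], ignore_attr = TRUE)
  expect_equal(s2$state$h, oracle[1, "h"], ignore_attr = TRUE)
  # c_1 = (i+f+o) * g = 3 sigma(1) tanh(1)
  expect_equal(s2$state$c, 3 * sig(1) * tanh(1), ignore_attr = TRUE)
})

test_that("gate activations stay strictly inside their open intervals", {
  set.seed(31)
  for (r in 1:50) {
    kind <- sample(c("lstm", "icgn"), 1)
    p <- random_cell(kind, 3, 4, seed = r, scale = sample(c(1, 3, 5), 1))
    st <- cell_state(4, c = rnorm(4), h = tanh(rnorm(4)))
    step <- if (kind == "lstm") lstm_step else icgn_step
    out <- step(p, rnorm(3), st)
    for (g in c("i", "f", "o"))
      expect_true(all(out$gates[[g]] > 0 & out$gates[[g]] < 1))
    expect_true(all(abs(out$gates$candidate) < 1))
  }
})

test_that("ICGN cell state is bounded: |c| < 3 and |h| < tanh(3)", {
  set.seed(77)
  worst_c <- 0
  ok_c <- ok_h <- TRUE
  for (r in 1:1000) {
    p <- random_cell("icgn", 2, 3, seed = r, scale = sample(c(0.5, 2, 5), 1))
    st <- cell_state(3, c = rnorm(3), h = rnorm(3))
    out <- icgn_step(p, rnorm(2), st)
    worst_c <- max(worst_c, max(abs(out$state$c)))
    ok_c <- ok_c && all(abs(out$state$c) < 3)
    ok_h <- ok_h && all(abs(out$state$h) < tanh(3))
  }
  expect_true(ok_c)
  expect_true(ok_h)
  # the bound is approached but never reached
  expect_gt(worst_c, 1)

  # fully saturated gates in floating point still respect the closed bound
  p <- random_cell("icgn", 2, 3, seed = 1, scale = 1000)
  out <- icgn_step(p, c(50, -50), cell_state(3, c = rnorm(3, 0, 10)))
  expect_true(all(abs(out$state$c) <= 3))
  expect_true(all(abs(out$state$h) <= tanh(3)))
})

test_that("ICGN with zeroed context weights reduces to LSTM gate-wise", {
  set.seed(5)
  q <- init_cell_parameters("icgn", 3, 4, "normal_scaled", seed = 9)
  for (nm in c("w_ci", "w_cf", "w_co", "w_cc")) q[[nm]][] <- 0
  l <- init_cell_parameters("lstm", 3, 4, "zeros")
  for (nm in c("w_xi", "w_xf", "w_xo", "w_xc",
               "w_hi", "w_hf", "w_ho", "w_hc", "b_i", "b_f", "b_o", "b_c"))
    l[[nm]] <- q[[nm]]
  x <- rnorm(3)
  st <- cell_state(4, c = rnorm(4), h = rnorm(4))
  gi <- icgn_step(q, x, st)$gates
  gl <- lstm_step(l, x, st)$gates
  expect_equal(gi, gl, tolerance = 1e-12)
})

test_that("unroll iterates the step and matches a hand-iterated oracle", {
  p <- const_cell("icgn")
  x <- c(1, 0.5, -1)
  res <- unroll(p, x)
  oracle <- scalar_icgn_oracle(x)
  expect_equal(drop(res$hidden), unname(oracle[, "h"]))
  expect_equal(res$final_state$c, unname(oracle[3, "c"]))

  # T = 1 equals one step call
  one <- unroll(p, 1)
  stp <- icgn_step(p, 1)
  expect_equal(drop(one$hidden), stp$state$h)

  # zero parameters give all-zero hidden rows for both cell kinds
  for (kind in c("lstm", "icgn")) {
    z <- init_cell_parameters(kind, 2, 3, "zeros")
    expect_equal(unroll(z, matrix(rnorm(10), 5, 2))$hidden,
                 matrix(0, 5, 3))
  }
  expect_error(unroll(p, matrix(numeric(0), 0, 1)), "empty")
})

test_that("bidirectional unroll concatenates independent passes", {
  set.seed(8)
  fp <- init_cell_parameters("lstm", 1, 1, "uniform_scaled", seed = 2)
  # T = 2 scalar: explicit two-sided construction
  x <- matrix(c(0.3, -0.7), 2, 1)
  out <- bidirectional_unroll(fp, fp, x)
  fwd <- unroll(fp, x)$hidden
  bwd <- unroll(fp, x[2:1, , drop = FALSE])$hidden
  expect_equal(out, cbind(fwd, bwd[2:1, , drop = FALSE]))

  # palindromic input with identical cells: backward half mirrors forward
  fp2 <- init_cell_parameters("lstm", 1, 2, "uniform_scaled", seed = 3)
  pal <- matrix(c(1, 2, 5, 2, 1), 5, 1)
  o2 <- bidirectional_unroll(fp2, fp2, pal)
  H <- 2L
  for (t in 1:5)
    expect_equal(o2[t, 1:H], o2[6 - t, H + 1:H], ignore_attr = TRUE)

  # zero parameters: all-zero output
  z <- init_cell_parameters("lstm", 1, 2, "zeros")
  expect_equal(bidirectional_unroll(z, z, pal), matrix(0, 5, 4))

  z3 <- init_cell_parameters("lstm", 1, 3, "zeros")
  expect_error(bidirectional_unroll(z, z3, pal), "share")
})

test_that("forward passes are deterministic given seed and inputs", {
  X <- matrix(seq(-1, 1, length.out = 12), 6, 2)
  h1 <- unroll(init_cell_parameters("icgn", 2, 3, "uniform_scaled",
                                    seed = 123), X)$hidden
  h2 <- unroll(init_cell_parameters("icgn", 2, 3, "uniform_scaled",
                                    seed = 123), X)$hidden
  expect_identical(h1, h2)
})

test_that("structural flags alias weights as documented", {
  # shared candidate: candidate pre-activation reuses forget weights
  p <- init_cell_parameters("lstm", 1, 1, "zeros",
                            share_candidate_with_forget = TRUE)
  expect_false("w_xc" %in% names(p))
  p$w_xf[] <- 2
  out <- lstm_step(p, 1)
  expect_equal(out$gates$candidate, tanh(2))
  expect_equal(out$gates$f, sig(2))

  # output gate context aliased to the forget context matrix
  q <- init_cell_parameters("icgn", 1, 1, "zeros",
                            output_context_shared_with_forget = TRUE)
  expect_false("w_co" %in% names(q))
  q$w_cf[] <- 3
  out2 <- icgn_step(q, 0, cell_state(1, c = 1))
  expect_equal(out2$gates$o, sig(3))

  # candidate cell-context disabled: candidate ignores c_{t-1}
  r <- init_cell_parameters("icgn", 1, 1, "zeros",
                            candidate_uses_cell_context = FALSE)
  expect_false("w_cc" %in% names(r))
  r$w_hc[] <- 1
  out3 <- icgn_step(r, 0, cell_state(1, c = 5, h = 1))
  expect_equal(out3$gates$candidate, tanh(1))  # c_{t-1} = 5 ignored

  # diagonal context constraint
  d <- init_cell_parameters("icgn", 2, 3, "uniform_scaled", seed = 4,
                            diagonal_context = TRUE)
  expect_equal(d$w_ci[upper.tri(d$w_ci)], rep(0, 3))
  expect_equal(d$w_cf[lower.tri(d$w_cf)], rep(0, 3))
})
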