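# Batched forward/backward passes for a recurrent cell. A batch of B
# sequences of length T is processed timestep by timestep with B x H state
# matrices, so the inner loop is dense matrix algebra. All caches needed for
# backpropagation through time are kept per timestep. Used by
# cell_gradients() (B = 1) and by the network trainer.

.add_bias <- function(a, b) {
  # a: B x H matrix (column-major), b: length-H bias
  a + rep(b, each = nrow(a))
}

.cell_forward_batch <- function(params, X, initial_state = NULL,
                                h0 = NULL, c0 = NULL) {
  B <- dim(X)[1L]; T_len <- dim(X)[2L]; D <- dim(X)[3L]
  H <- params$hidden_dim
  stopifnot(D == params$input_dim)
  if (!is.null(initial_state)) {
    h0 <- matrix(initial_state$h, B, H, byrow = TRUE)
    c0 <- matrix(initial_state$c, B, H, byrow = TRUE)
  }
  if (is.null(h0)) h0 <- matrix(0, B, H)
  if (is.null(c0)) c0 <- matrix(0, B, H)

  p <- params
  cw <- .cand(p)
  icgn <- p$cell_kind == "icgn"
  t_wxi <- t(p$w_xi); t_wxf <- t(p$w_xf); t_wxo <- t(p$w_xo)
  t_whi <- t(p$w_hi); t_whf <- t(p$w_hf); t_who <- t(p$w_ho)
  t_wxc <- t(cw$wx); t_whc <- t(cw$wh)
  if (icgn) {
    t_wci <- t(p$w_ci); t_wcf <- t(p$w_cf); t_wco <- t(.octx(p))
    use_cc <- p$candidate_uses_cell_context && !is.null(cw$wc)
    if (use_cc) t_wcc <- t(cw$wc)
  } else use_cc <- FALSE

  xs <- is_ <- fs <- os <- gs <- cs <- tcs <- hs <- cprev <- hprev <-
    vector("list", T_len)
  h <- h0; cc <- c0
  for (t in seq_len(T_len)) {
    x <- matrix(X[, t, ], B, D)
    a_i <- x %*% t_wxi + h %*% t_whi
    a_f <- x %*% t_wxf + h %*% t_whf
    a_o <- x %*% t_wxo + h %*% t_who
    a_c <- x %*% t_wxc + h %*% t_whc
    if (icgn) {
      a_i <- a_i + cc %*% t_wci
      a_f <- a_f + cc %*% t_wcf
      a_o <- a_o + cc %*% t_wco
      if (use_cc) a_c <- a_c + cc %*% t_wcc
    }
    i <- sigmoid(.add_bias(a_i, p$b_i))
    f <- sigmoid(.add_bias(a_f, p$b_f))
    o <- sigmoid(.add_bias(a_o, p$b_o))
    g <- tanh(.add_bias(a_c, cw$b))
    cprev[[t]] <- cc; hprev[[t]] <- h
    cc <- if (icgn) (f + i + o) * g else f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    xs[[t]] <- x; is_[[t]] <- i; fs[[t]] <- f; os[[t]] <- o; gs[[t]] <- g
    cs[[t]] <- cc; tcs[[t]] <- tc; hs[[t]] <- h
  }
  list(params = params, B = B, T_len = T_len,
       x = xs, i = is_, f = fs, o = os, g = gs,
       c = cs, tc = tcs, h = hs, c_prev = cprev, h_prev = hprev,
       use_cc = use_cc)
}

.zero_grads <- function(params) {
  g <- lapply(.param_array_names(params), function(nm) {
    a <- params[[nm]]
    if (is.matrix(a)) matrix(0, nrow(a), ncol(a)) else rep(0, length(a))
  })
  names(g) <- .param_array_names(params)
  g
}

.cell_backward_batch <- function(params, fwd, d_hidden, d_final_c = NULL) {
  p <- params
  B <- fwd$B; T_len <- fwd$T_len; H <- p$hidden_dim
  icgn <- p$cell_kind == "icgn"
  shared <- p$share_candidate_with_forget
  cw <- .cand(p)
  G <- .zero_grads(p)

  dh_rec <- matrix(0, B, H)
  dc_rec <- if (is.null(d_final_c)) matrix(0, B, H) else d_final_c
  dx <- vector("list", T_len)

  for (t in rev(seq_len(T_len))) {
    i <- fwd$i[[t]]; f <- fwd$f[[t]]; o <- fwd$o[[t]]; g <- fwd$g[[t]]
    tc <- fwd$tc[[t]]; c_prev <- fwd$c_prev[[t]]; h_prev <- fwd$h_prev[[t]]
    x <- fwd$x[[t]]
    dh <- d_hidden[[t]] + dh_rec
    dc <- dc_rec + dh * o * (1 - tc^2)
    if (icgn) {
      dcommon <- dc * g
      dg <- dc * (i + f + o)
      di <- dcommon; df <- dcommon
      do_ <- dh * tc + dcommon
      dc_rec <- matrix(0, B, H)      # no direct carry; refilled via contexts
    } else {
      di <- dc * g
      df <- dc * c_prev
      do_ <- dh * tc
      dg <- dc * i
      dc_rec <- dc * f
    }
    da_i <- di * i * (1 - i)
    da_f <- df * f * (1 - f)
    da_o <- do_ * o * (1 - o)
    da_c <- dg * (1 - g^2)

    G$w_xi <- G$w_xi + crossprod(da_i, x)
    G$w_xf <- G$w_xf + crossprod(da_f, x)
    G$w_xo <- G$w_xo + crossprod(da_o, x)
    G$w_hi <- G$w_hi + crossprod(da_i, h_prev)
    G$w_hf <- G$w_hf + crossprod(da_f, h_prev)
    G$w_ho <- G$w_ho + crossprod(da_o, h_prev)
    G$b_i <- G$b_i + colSums(da_i)
    G$b_f <- G$b_f + colSums(da_f)
    G$b_o <- G$b_o + colSums(da_o)
    if (shared) {
      G$w_xf <- G$w_xf + crossprod(da_c, x)
      G$w_hf <- G$w_hf + crossprod(da_c, h_prev)
      G$b_f <- G$b_f + colSums(da_c)
    } else {
      G$w_xc <- G$w_xc + crossprod(da_c, x)
      G$w_hc <- G$w_hc + crossprod(da_c, h_prev)
      G$b_c <- G$b_c + colSums(da_c)
    }

    dh_rec <- da_i %*% p$w_hi + da_f %*% p$w_hf + da_o %*% p$w_ho +
      da_c %*% cw$wh
    dx[[t]] <- da_i %*% p$w_xi + da_f %*% p$w_xf + da_o %*% p$w_xo +
      da_c %*% cw$wx

    if (icgn) {
      G$w_ci <- G$w_ci + crossprod(da_i, c_prev)
      dc_rec <- dc_rec + da_i %*% p$w_ci + da_f %*% p$w_cf
      if (p$output_context_shared_with_forget) {
        G$w_cf <- G$w_cf + crossprod(da_f + da_o, c_prev)
        dc_rec <- dc_rec + da_o %*% p$w_cf
      } else {
        G$w_cf <- G$w_cf + crossprod(da_f, c_prev)
        G$w_co <- G$w_co + crossprod(da_o, c_prev)
        dc_rec <- dc_rec + da_o %*% p$w_co
      }
      if (fwd$use_cc) {
        if (shared) G$w_cf <- G$w_cf + crossprod(da_c, c_prev)
        else G$w_cc <- G$w_cc + crossprod(da_c, c_prev)
        dc_rec <- dc_rec + da_c %*% cw$wc
      }
    }
  }

  if (isTRUE(p$diagonal_context)) {
    for (nm in intersect(c("w_ci", "w_cf", "w_co", "w_cc"), names(G)))
      G[[nm]] <- diag(diag(G[[nm]]), H, H)
  }
  list(gradients = G, d_x = dx, d_h0 = dh_rec, d_c0 = dc_rec)
}
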