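# Shared fixtures and independent oracles. Oracles are deliberately written
# in the most naive way possible (scalar loops, per-entry arithmetic) so they
# share no code path with the implementation they check.

# Naive per-entry evaluation of the synaptic current sum.
oracle_synaptic_current <- function(theta_in, theta_hid, W_ih, W_hh) {
  M <- nrow(W_ih)
  I <- numeric(M)
  for (m in seq_len(M)) {
    for (i in seq_along(theta_in)) I[m] <- I[m] + W_ih[m, i] * theta_in[i]
    for (j in seq_along(theta_hid)) I[m] <- I[m] + W_hh[m, j] * theta_hid[j]
  }
  I
}

# Forward-mode chain-rule expansion of the readout gradient: for each weight
# individually, propagate d(v)/d(w) forward through the membrane recursion
# with the rectangular surrogate at each threshold crossing and the reset
# factor held constant. Independent of the trainer's backward recursion.
oracle_readout_grad <- function(H, y, W, params, a) {
  T_ <- nrow(H)
  C <- nrow(W)
  d <- exp(-params$dt / params$tau_m)
  g <- params$gain
  grad <- matrix(0, C, ncol(W))
  for (cc in seq_len(C)) for (mm in seq_len(ncol(W))) {
    v <- rep(0, C)
    dvk <- 0
    dth_sum <- 0
    r <- rep(0, C)
    for (k in seq_len(T_)) {
      th <- as.numeric(v >= params$u_th)
      sur <- if (abs(v[cc] - params$u_th) < a / 2) 1 / a else 0
      dth_sum <- dth_sum + sur * dvk
      vnew <- v * d * (1 - th) + g * as.vector(W %*% H[k, ])
      dvk <- d * (1 - th[cc]) * dvk + g * H[k, mm]
      r <- r + th / T_
      v <- vnew
    }
    grad[cc, mm] <- -2 * (y[cc] - r[cc]) * dth_sum / T_
  }
  grad
}

# Independent bit-packing of one AER event record, written directly against
# the 5-byte format description using base bit operations.
oracle_pack_event <- function(x, y, p, t) {
  as.raw(c(x, y,
           bitwOr(p * 128L, bitwAnd(bitwShiftR(t, 16L), 127L)),
           bitwAnd(bitwShiftR(t, 8L), 255L),
           bitwAnd(t, 255L)))
}

# Random valid event stream for codec property tests.
random_stream <- function(n, width = 12, height = 9, max_t = 2^23 - 1) {
  t <- sort(sample.int(max_t, n, replace = TRUE)) - 1L
  event_stream(data.frame(
    x = sample.int(width, n, replace = TRUE) - 1L,
    y = sample.int(height, n, replace = TRUE) - 1L,
    t = t,
    p = sample(c(0L, 1L), n, replace = TRUE)), width, height)
}

# A small labelled raster batch with linearly separable classes: class 1
# drives the first half of the input channels, class 2 the second half.
separable_rasters <- function(n_per_class = 10, T_ = 12, N = 16, seed = 99) {
  set.seed(seed)
  S <- 2 * n_per_class
  x <- array(0, dim = c(T_, N, S))
  y <- rep(1:2, each = n_per_class)
  half <- seq_len(N / 2)
  for (s in seq_len(S)) {
    ch <- if (y[s] == 1) half else setdiff(seq_len(N), half)
    x[, ch, s] <- rbinom(T_ * length(ch), 1, 0.6)
  }
  list(x = x, y = y)
}
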