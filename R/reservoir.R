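# Frozen Elman reservoir: weight initialization, synaptic currents, and the
# full spiking rollout that turns input spike rasters into hidden and readout
# spike trains.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package route
# through this so results are pure functions of their seed arguments.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Spike raster container
#'
#' A T x K binary matrix of spikes (rows = timesteps, columns = channels)
#' with the step length attached. The raster is the common currency between
#' event binning, reservoir simulation and readout training.
#'
#' @param data binary matrix (timesteps x channels); entries must be 0 or 1.
#' @param dt time per step (ms).
#' @return the matrix with class `spike_raster` and a `dt` attribute.
#' @export
spike_raster <- function(data, dt = 1.0) {
  data <- as.matrix(data)
  if (nrow(data) < 1) stop("a raster needs at least one timestep", call. = FALSE)
  if (!all(data %in% c(0, 1)))
    stop("raster entries must be binary", call. = FALSE)
  structure(data, dt = dt, class = c("spike_raster", class(data)))
}

#' Initialize frozen reservoir weights
#'
#' Draws the input-to-hidden (`W_ih`, M x N) and hidden-to-hidden (`W_hh`,
#' M x M, all-to-all including self-connections) weight matrices i.i.d.
#' uniform on `[-1/N, 1/N]`, where N is the number of input channels. These
#' matrices are frozen: training never touches them.
#'
#' @param n_input number of input channels N.
#' @param n_hidden number of hidden (liquid) neurons M.
#' @param seed integer seed; the same seed always yields the same matrices.
#' @return list with elements `W_ih` and `W_hh`.
#' @export
init_weights <- function(n_input, n_hidden, seed = 1L) {
  if (n_input < 1 || n_hidden < 1)
    stop("n_input and n_hidden must be positive", call. = FALSE)
  bound <- 1 / n_input
  with_local_seed(seed, {
    W_ih <- matrix(stats::runif(n_hidden * n_input, -bound, bound),
                   nrow = n_hidden, ncol = n_input)
    W_hh <- matrix(stats::runif(n_hidden * n_hidden, -bound, bound),
                   nrow = n_hidden, ncol = n_hidden)
    list(W_ih = W_ih, W_hh = W_hh)
  })
}

#' Synaptic current into the hidden layer for one step
#'
#' `I = W_ih %*% theta_in + W_hh %*% theta_hid`: the weighted sum of input
#' spikes plus the weighted sum of lateral (recurrent) spikes.
#'
#' @param theta_in binary N-vector of input spikes.
#' @param theta_hid binary M-vector of hidden spikes.
#' @param W_ih M x N input weight matrix.
#' @param W_hh M x M recurrent weight matrix.
#' @return numeric M-vector of currents.
#' @export
synaptic_current <- function(theta_in, theta_hid, W_ih, W_hh) {
  if (length(theta_in) != ncol(W_ih) || length(theta_hid) != ncol(W_hh) ||
      nrow(W_ih) != nrow(W_hh))
    stop("spike vectors and weight matrices are not conformable", call. = FALSE)
  drop(W_ih %*% theta_in + W_hh %*% theta_hid)
}

#' Construct a Liquid State Machine
#'
#' Builds an LSM with N input channels fully connected to a liquid of M
#' leaky integrate-and-fire neurons with all-to-all recurrence, read out by
#' C output neurons with identical dynamics but no lateral connections and
#' no feedback into the liquid. Input and recurrent weights are drawn
#' uniform on `[-1/N, 1/N]` and frozen; readout weights are drawn uniform on
#' `[-1/M, 1/M]` (by analogy with the reservoir rule) and are the only
#' trainable parameters. The network has no bias terms.
#'
#' @param n_input number of input channels N.
#' @param n_hidden number of liquid neurons M.
#' @param n_class number of readout neurons C (one per class).
#' @param params a [neuron_params()] object shared by liquid and readout.
#' @param seed integer seed for weight initialization.
#' @return an object of class `lsm` with fields `W_ih`, `W_hh`, `W_ho`,
#'   `params`, `seed` and a `history` field filled in by [train_readout()].
#' @examples
#' m <- lsm(n_input = 8, n_hidden = 16, n_class = 2, seed = 42)
#' m
#' @export
lsm <- function(n_input, n_hidden, n_class,
                params = neuron_params(), seed = 1L) {
  stopifnot(inherits(params, "neuron_params"))
  if (n_class < 1) stop("n_class must be positive", call. = FALSE)
  w <- init_weights(n_input, n_hidden, seed = seed)
  W_ho <- with_local_seed(seed + 1L, {
    b <- 1 / n_hidden
    matrix(stats::runif(n_class * n_hidden, -b, b),
           nrow = n_class, ncol = n_hidden)
  })
  structure(list(W_ih = w$W_ih, W_hh = w$W_hh, W_ho = W_ho,
                 params = params, seed = as.integer(seed),
                 history = NULL),
            class = "lsm")
}

#' @export
print.lsm <- function(x, ...) {
  cat("Liquid State Machine\n")
  cat(sprintf("  input channels : %d\n", ncol(x$W_ih)))
  cat(sprintf("  liquid neurons : %d (frozen, all-to-all recurrent)\n",
              nrow(x$W_hh)))
  cat(sprintf("  readout neurons: %d (trainable)\n", nrow(x$W_ho)))
  cat(sprintf("  decay d = %.4f (tau_m = %.4f ms, dt = %g ms), u_th = %g, gain = %g\n",
              decay_factor(x$params$tau_m, x$params$dt),
              x$params$tau_m, x$params$dt, x$params$u_th, x$params$gain))
  if (!is.null(x$history))
    cat(sprintf("  trained: %d epochs, final rate loss %.5f\n",
                length(x$history), x$history[length(x$history)]))
  else cat("  readout untrained\n")
  invisible(x)
}

#' @export
summary.lsm <- function(object, ...) {
  s <- list(
    n_input = ncol(object$W_ih),
    n_hidden = nrow(object$W_hh),
    n_class = nrow(object$W_ho),
    params = object$params,
    w_range = list(W_ih = range(object$W_ih), W_hh = range(object$W_hh),
                   W_ho = range(object$W_ho)),
    spectral_radius_hh = max(Mod(eigen(object$params$gain * object$W_hh,
                                       only.values = TRUE)$values)),
    history = object$history
  )
  class(s) <- "summary.lsm"
  s
}

#' @export
print.summary.lsm <- function(x, ...) {
  cat(sprintf("LSM: %d -> %d -> %d\n", x$n_input, x$n_hidden, x$n_class))
  cat(sprintf("  effective recurrent spectral radius (gain * W_hh): %.3f\n",
              x$spectral_radius_hh))
  for (nm in names(x$w_range))
    cat(sprintf("  %s in [%.5f, %.5f]\n", nm, x$w_range[[nm]][1],
                x$w_range[[nm]][2]))
  if (!is.null(x$history))
    cat(sprintf("  loss history: %s\n",
                paste(sprintf("%.4f", x$history), collapse = " ")))
  invisible(x)
}

#' @export
coef.lsm <- function(object, ...) object$W_ho

# Batched liquid rollout.
#
# X: T x N x S binary array (S samples simulated in parallel).
# Spike timing convention: theta[k] = 1{u[k-1] >= u_th}, so spikes recorded
# at step k announce threshold crossings of the previous step; the current at
# step k combines input raster row k with hidden spikes theta[k]. Together
# with the membrane update this realizes a synaptic delay of one step: a
# spike can first influence other neurons' recorded spikes one step later.
# extra_current: optional length-T vector of externally injected current, in
# membrane-potential units, applied identically to every hidden neuron (the
# rhythmic inhibitory pulse); it bypasses the synaptic gain.
hidden_rollout <- function(model, X, record_membrane = FALSE,
                           init_u = NULL, extra_current = NULL) {
  dims <- dim(X)
  T_ <- dims[1]; N <- dims[2]; S <- dims[3]
  if (N != ncol(model$W_ih))
    stop("input channel count does not match W_ih", call. = FALSE)
  M <- nrow(model$W_hh)
  p <- model$params
  d <- decay_factor(p$tau_m, p$dt)
  U <- if (is.null(init_u)) matrix(p$u_rest, M, S) else init_u
  H <- array(0, dim = c(T_, M, S))
  Umem <- if (record_membrane) array(NA_real_, dim = c(T_, M, S)) else NULL
  for (k in seq_len(T_)) {
    Theta <- (U >= p$u_th) + 0
    Xk <- matrix(X[k, , ], nrow = N, ncol = S)
    I <- model$W_ih %*% Xk + model$W_hh %*% Theta
    U <- U * (d * (1 - Theta)) + p$gain * I
    if (!is.null(extra_current)) U <- U + extra_current[k]
    H[k, , ] <- Theta
    if (record_membrane) Umem[k, , ] <- U
  }
  list(spikes = H, membrane = Umem, final_u = U)
}

# Batched readout rollout over precomputed hidden spikes.
# H: T x M x S. Returns readout spikes (T x C x S) and, when record_v, the
# pre-step membrane V_prev[k,,] = v[k-1] needed by the surrogate gradient.
readout_rollout <- function(W_ho, H, params, record_v = FALSE,
                            init_v = NULL) {
  dims <- dim(H)
  T_ <- dims[1]; M <- dims[2]; S <- dims[3]
  C <- nrow(W_ho)
  d <- decay_factor(params$tau_m, params$dt)
  V <- if (is.null(init_v)) matrix(params$u_rest, C, S) else init_v
  O <- array(0, dim = c(T_, C, S))
  Vprev <- if (record_v) array(NA_real_, dim = c(T_, C, S)) else NULL
  for (k in seq_len(T_)) {
    if (record_v) Vprev[k, , ] <- V
    Theta <- (V >= params$u_th) + 0
    Hk <- matrix(H[k, , ], nrow = M, ncol = S)
    V <- V * (d * (1 - Theta)) + params$gain * (W_ho %*% Hk)
    O[k, , ] <- Theta
  }
  list(spikes = O, v_prev = Vprev, final_v = V)
}

#' Simulate the full network on one input raster
#'
#' Rolls the liquid and the readout forward over an input spike raster from
#' a resting initial state, honouring the one-step synaptic delay: spikes
#' recorded at step k depend only on inputs and network spikes at earlier
#' steps, so with a resting start the first step is always silent.
#'
#' @param input_raster T x N binary matrix (or [spike_raster()]).
#' @param model an [lsm()] object with `ncol(W_ih) == N`.
#' @param record_membrane also record hidden membrane trajectories
#'   (T x M matrix) — off by default to save memory.
#' @return a list of class `lsm_rollout` with `hidden_spikes` (T x M),
#'   `readout_spikes` (T x C), `readout_counts` (C-vector of per-class spike
#'   counts) and, optionally, `hidden_membrane`.
#' @export
run_reservoir <- function(input_raster, model, record_membrane = FALSE) {
  Xm <- unclass(as.matrix(input_raster))
  T_ <- nrow(Xm); N <- ncol(Xm)
  X <- array(Xm, dim = c(T_, N, 1))
  hid <- hidden_rollout(model, X, record_membrane = record_membrane)
  out <- readout_rollout(model$W_ho, hid$spikes, model$params)
  hs <- matrix(hid$spikes, nrow = T_)
  os <- matrix(out$spikes, nrow = T_)
  structure(list(
    hidden_spikes = hs,
    readout_spikes = os,
    hidden_membrane = if (record_membrane) matrix(hid$membrane, nrow = T_) else NULL,
    readout_counts = colSums(os)
  ), class = "lsm_rollout")
}

#' @export
print.lsm_rollout <- function(x, ...) {
  cat(sprintf("LSM rollout: %d steps, %d hidden neurons, %d readout neurons\n",
              nrow(x$hidden_spikes), ncol(x$hidden_spikes),
              ncol(x$readout_spikes)))
  cat(sprintf("  hidden spikes: %d (rate %.3f/neuron/step)\n",
              sum(x$hidden_spikes), mean(x$hidden_spikes)))
  cat("  readout counts:", paste(x$readout_counts, collapse = " "), "\n")
  invisible(x)
}

#' Raster plot of network activity on one input
#'
#' Runs the model on an input raster and draws spike rasters of the input,
#' liquid and readout populations (base graphics).
#'
#' @param x an [lsm()] object.
#' @param input_raster T x N binary input raster.
#' @param ... passed to [graphics::plot()].
#' @return the [run_reservoir()] record, invisibly.
#' @export
plot.lsm <- function(x, input_raster, ...) {
  rec <- run_reservoir(input_raster, x)
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  draw <- function(mat, main) {
    idx <- which(mat == 1, arr.ind = TRUE)
    graphics::plot(idx[, 1], idx[, 2], pch = ".", cex = 2,
                   xlim = c(1, nrow(mat)), ylim = c(1, max(2, ncol(mat))),
                   xlab = "step", ylab = "neuron", main = main, ...)
  }
  draw(unclass(as.matrix(input_raster)), "input")
  draw(rec$hidden_spikes, "liquid")
  draw(rec$readout_spikes, "readout")
  invisible(rec)
}

#' Save / load an LSM model archive
#'
#' Serializes the full model (weights, neuron parameters, seed, training
#' history) to a single file with an exact, bit-level round trip.
#'
#' @param model an [lsm()] object.
#' @param path file path for the archive.
#' @return `save_lsm` returns `path` invisibly; `load_lsm` returns the model.
#' @export
save_lsm <- function(model, path) {
  stopifnot(inherits(model, "lsm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_lsm
#' @export
load_lsm <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "lsm")) stop("not an LSM archive", call. = FALSE)
  model
}
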