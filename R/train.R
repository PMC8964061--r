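# Training of the readout weights by spatio-temporal backpropagation (STBP):
# backpropagation through time over the readout membrane recursion, with a
# rectangular surrogate in place of the spike derivative. The liquid is
# frozen, so hidden spike trains are computed once and treated as constants.

#' Training configuration for the readout layer
#'
#' @param learning_rate positive step size. Default 0.001 (stable for
#'   liquids driven at the package's reference operating point; larger
#'   rates can push the spiking readout into dead or saturated regimes).
#' @param epochs number of passes over the training set. Default 20.
#' @param batch_size minibatch size. Default 64.
#' @param surrogate_width width `a` of the rectangular surrogate derivative,
#'   in membrane-potential (threshold) units. Default 1.
#' @param seed integer seed controlling minibatch shuffling.
#' @param optimizer `"sgd"` (plain minibatch SGD, default) or `"adam"`.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 20L, batch_size = 64L,
                         surrogate_width = 1.0, seed = 1L,
                         optimizer = c("sgd", "adam")) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (surrogate_width <= 0) stop("surrogate_width must be positive", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be at least 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 surrogate_width = surrogate_width, seed = as.integer(seed),
                 optimizer = optimizer),
            class = "train_config")
}

# Coerce a batch of rasters (list of T x K matrices, a single matrix, or a
# T x K x S array) to a T x K x S array.
as_raster_array <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.matrix(x)) return(array(unclass(x), dim = c(nrow(x), ncol(x), 1)))
  if (is.list(x)) {
    mats <- lapply(x, function(m) unclass(as.matrix(m)))
    T_ <- nrow(mats[[1]]); K <- ncol(mats[[1]])
    ok <- vapply(mats, function(m) nrow(m) == T_ && ncol(m) == K, logical(1))
    if (!all(ok)) stop("all rasters in a batch must share the same shape",
                       call. = FALSE)
    return(array(unlist(mats), dim = c(T_, K, length(mats))))
  }
  stop("cannot interpret input as a raster batch", call. = FALSE)
}

# Class labels (1-based integers or factor) -> one-hot C x S matrix.
one_hot <- function(y, n_class) {
  y <- as.integer(y)
  if (any(y < 1) || any(y > n_class)) stop("labels out of range", call. = FALSE)
  Y <- matrix(0, n_class, length(y))
  Y[cbind(y, seq_along(y))] <- 1
  Y
}

#' Spike-rate loss
#'
#' Mean squared distance, averaged over samples, between each sample's label
#' vector and its readout firing-rate vector: for S samples over a window of
#' T steps, `loss = (1/S) * sum_s || y_s - (1/T) sum_t theta_{s,t} ||^2`.
#' The loss is zero exactly when every correct-class neuron fires on every
#' step and all others stay silent.
#'
#' @param readout_spikes batch of readout rasters: T x C x S array, list of
#'   T x C matrices, or a single matrix.
#' @param labels one-hot C x S matrix, or a vector of 1-based class indices.
#' @return list of class `rate_loss` with `value` (scalar) and `per_sample`
#'   (length-S vector).
#' @export
rate_loss <- function(readout_spikes, labels) {
  O <- as_raster_array(readout_spikes)
  T_ <- dim(O)[1]; C <- dim(O)[2]; S <- dim(O)[3]
  Y <- if (is.matrix(labels)) labels else one_hot(labels, C)
  if (nrow(Y) != C || ncol(Y) != S)
    stop("labels do not match the readout batch", call. = FALSE)
  rates <- apply(O, c(2, 3), sum) / T_          # C x S
  per_sample <- colSums((Y - rates)^2)
  structure(list(value = mean(per_sample), per_sample = per_sample),
            class = "rate_loss")
}

#' Rectangular surrogate spike derivative
#'
#' The spike function is a hard threshold with zero derivative almost
#' everywhere; STBP substitutes a compact window of unit area:
#' `(1/a) * 1{|u - u_th| < a/2}`.
#'
#' @param u membrane potentials (any shape).
#' @param u_th firing threshold.
#' @param a window width, positive.
#' @return surrogate derivative values, same shape as `u`.
#' @export
surrogate_grad <- function(u, u_th, a) {
  if (a <= 0) stop("surrogate width must be positive", call. = FALSE)
  (abs(u - u_th) < a / 2) / a
}

#' STBP gradient of the rate loss with respect to the readout weights
#'
#' Unrolls the readout membrane recursion over the time window, propagating
#' the rate-loss error backwards through time with the rectangular surrogate
#' standing in for the spike derivative. Two standard STBP conventions are
#' used: the reset factor `(1 - theta)` is held constant during
#' differentiation, and hidden spike trains are constants (the liquid is
#' frozen), so the only gradient produced is for `W_ho`.
#'
#' @param batch_hidden hidden spike batch: T x M x S array (or list/matrix).
#' @param labels one-hot C x S matrix or vector of 1-based class indices.
#' @param model an [lsm()] object.
#' @param config a [train_config()] (supplies the surrogate width).
#' @return list with `grad` (C x M matrix, d loss / d W_ho) and `loss`
#'   (the [rate_loss()] of the forward pass).
#' @export
stbp_readout_gradients <- function(batch_hidden, labels, model,
                                   config = train_config()) {
  H <- as_raster_array(batch_hidden)
  T_ <- dim(H)[1]; M <- dim(H)[2]; S <- dim(H)[3]
  C <- nrow(model$W_ho)
  p <- model$params
  d <- decay_factor(p$tau_m, p$dt)
  Y <- if (is.matrix(labels)) labels else one_hot(labels, C)
  out <- readout_rollout(model$W_ho, H, p, record_v = TRUE)
  O <- out$spikes
  rates <- apply(O, c(2, 3), sum) / T_           # C x S
  per_sample <- colSums((Y - rates)^2)
  # d loss_s / d rate = -2 (y - r); each spike contributes 1/T to the rate
  dtheta <- -2 * (Y - rates) / T_                # C x S
  delta <- matrix(0, C, S)                       # d loss / d v[k], k = T..0
  grad <- matrix(0, C, M)
  for (k in T_:1) {
    if (k < T_) {
      Hk <- matrix(H[k, , ], nrow = M, ncol = S)
      grad <- grad + p$gain * (delta %*% t(Hk))
    }
    vprev <- matrix(out$v_prev[k, , ], nrow = C, ncol = S)
    thk <- matrix(O[k, , ], nrow = C, ncol = S)
    g <- surrogate_grad(vprev, p$u_th, config$surrogate_width)
    delta <- delta * (d * (1 - thk)) + dtheta * g
  }
  list(grad = grad / S,
       loss = structure(list(value = mean(per_sample),
                             per_sample = per_sample),
                        class = "rate_loss"))
}

#' Train the readout layer
#'
#' Fits the hidden-to-readout weights by minibatch gradient descent on the
#' spike-rate loss, with gradients from [stbp_readout_gradients()]. The
#' liquid is rolled out once per sample before training starts — its spike
#' trains are constants of the optimization — and the frozen matrices
#' `W_ih` and `W_hh` are returned bitwise unchanged. Readout membrane state
#' is reset at every sample boundary, matching the independent-sample form
#' of the loss.
#'
#' @param model an [lsm()] object.
#' @param x batch of input rasters: T x N x S array or list of T x N
#'   matrices.
#' @param y class labels: 1-based integer vector (or factor) of length S.
#' @param config a [train_config()].
#' @param hidden optional precomputed hidden spike batch (T x M x S array)
#'   to reuse across calls; computed from `x` when missing.
#' @return the trained `lsm` model; `model$history` holds the mean minibatch
#'   loss of each epoch.
#' @examples
#' m <- lsm(n_input = 4, n_hidden = 8, n_class = 2, seed = 3)
#' x <- array(rbinom(6 * 4 * 10, 1, 0.3), dim = c(6, 4, 10))
#' y <- rep(1:2, 5)
#' m2 <- train_readout(m, x, y, train_config(epochs = 2, batch_size = 5))
#' m2$history
#' @export
train_readout <- function(model, x, y, config = train_config(),
                          hidden = NULL) {
  stopifnot(inherits(model, "lsm"), inherits(config, "train_config"))
  if (is.null(hidden)) {
    X <- as_raster_array(x)
    if (dim(X)[3] < 1) stop("empty training set", call. = FALSE)
    hidden <- hidden_rollout(model, X)$spikes
  }
  S <- dim(hidden)[3]
  if (S < 1) stop("empty training set", call. = FALSE)
  y <- as.integer(y)
  if (length(y) != S) stop("labels do not match the sample count", call. = FALSE)
  C <- nrow(model$W_ho)
  W <- model$W_ho
  history <- numeric(0)
  if (config$epochs > 0) {
    adam_m <- matrix(0, C, ncol(W)); adam_v <- matrix(0, C, ncol(W))
    adam_t <- 0
    with_local_seed(config$seed, {
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(S)
        starts <- seq(1, S, by = config$batch_size)
        batch_losses <- numeric(length(starts))
        for (bi in seq_along(starts)) {
          idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1, S)]
          Hb <- hidden[, , idx, drop = FALSE]
          mb <- model; mb$W_ho <- W
          res <- stbp_readout_gradients(Hb, one_hot(y[idx], C), mb, config)
          if (config$optimizer == "sgd") {
            W <- W - config$learning_rate * res$grad
          } else {
            adam_t <- adam_t + 1
            adam_m <- 0.9 * adam_m + 0.1 * res$grad
            adam_v <- 0.999 * adam_v + 0.001 * res$grad^2
            mhat <- adam_m / (1 - 0.9^adam_t)
            vhat <- adam_v / (1 - 0.999^adam_t)
            W <- W - config$learning_rate * mhat / (sqrt(vhat) + 1e-8)
          }
          batch_losses[bi] <- res$loss$value
        }
        history[ep] <- mean(batch_losses)
      }
    })
  }
  model$W_ho <- W
  model$history <- history
  model
}
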