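# Inference engines: batch mode (hard state reset between samples) and
# streaming mode, which feeds samples back to back through a persistent
# network state and quenches reverberating liquid activity with a rhythmic
# inhibitory pulse, emulating a one-neuron inhibitory population with
# one-to-all connectivity that fires once per presentation period.

#' Streaming inference schedule
#'
#' Timing of sequential presentation: each sample occupies
#' `stim_ms + relax_ms` of simulated time. During the relaxation the input
#' is silent and, at `inh_step` (default: the first step after the stimulus
#' ends), a strong negative current is injected simultaneously into every
#' hidden neuron — the scheduled equivalent of a rhythmic inhibitory neuron
#' firing once per period.
#'
#' @param stim_ms stimulus duration per sample (ms). Default 25.
#' @param relax_ms relaxation after each stimulus (ms). Default 25.
#' @param inh_weight injected current (membrane-potential units),
#'   nonpositive; 0 disables inhibition. Default -10.
#' @param inh_step 1-based step offset of the pulse within each period;
#'   default `stim_ms/dt + 1`.
#' @param dt simulation resolution (ms). Default 1.
#' @return an object of class `streaming_schedule`.
#' @export
streaming_schedule <- function(stim_ms = 25, relax_ms = 25,
                               inh_weight = -10, inh_step = NULL, dt = 1.0) {
  stopifnot(stim_ms > 0, relax_ms >= 0, dt > 0)
  if (inh_weight > 0) stop("inh_weight must be nonpositive", call. = FALSE)
  stim_steps <- as.integer(round(stim_ms / dt))
  relax_steps <- as.integer(round(relax_ms / dt))
  if (is.null(inh_step)) inh_step <- stim_steps + 1L
  period <- stim_steps + relax_steps
  if (inh_step < 1 || inh_step > period)
    stop("inh_step must fall inside the period", call. = FALSE)
  structure(list(stim_ms = stim_ms, relax_ms = relax_ms,
                 inh_weight = inh_weight, inh_step = as.integer(inh_step),
                 dt = dt, stim_steps = stim_steps,
                 relax_steps = relax_steps, period = period),
            class = "streaming_schedule")
}

#' Spike-count classification rule
#'
#' The predicted class is the readout neuron with the highest spike count
#' during the stimulus window; ties break to the lowest class index, and an
#' all-silent readout is flagged.
#'
#' @param counts nonnegative C-vector of readout spike counts.
#' @return list of class `lsm_prediction` with `counts`, `label` (1-based),
#'   `tie` and `silent` flags.
#' @export
classify_counts <- function(counts) {
  if (length(counts) < 1) stop("empty count vector", call. = FALSE)
  label <- which.max(counts)   # lowest index wins ties
  structure(list(counts = counts, label = label,
                 tie = sum(counts == max(counts)) > 1,
                 silent = all(counts == 0)),
            class = "lsm_prediction")
}

# Predictions for an S x C count matrix -> data.frame + counts attribute.
predictions_from_counts <- function(counts) {
  preds <- apply(counts, 1, classify_counts)
  structure(data.frame(
    label = vapply(preds, `[[`, integer(1), "label"),
    tie = vapply(preds, `[[`, logical(1), "tie"),
    silent = vapply(preds, `[[`, logical(1), "silent")
  ), counts = counts)
}

#' Batch inference
#'
#' Classifies each sample independently: all membrane state is zeroed
#' before every sample and readout spike counts are taken over the full
#' raster duration.
#'
#' @param samples input rasters: T x N x S array or list of T x N matrices.
#' @param model an [lsm()] object.
#' @return data.frame with columns `label`, `tie`, `silent` (one row per
#'   sample) and an S x C `counts` attribute.
#' @export
infer_batch <- function(samples, model) {
  X <- as_raster_array(samples)
  hid <- hidden_rollout(model, X)
  out <- readout_rollout(model$W_ho, hid$spikes, model$params)
  counts <- t(apply(out$spikes, c(2, 3), sum))   # S x C
  predictions_from_counts(counts)
}

#' Streaming inference with a rhythmic inhibitory reset
#'
#' Feeds the samples through the network back to back: membrane state
#' persists across samples, each period consists of `stim_steps` of input
#' followed by `relax_steps` of silence, and the inhibitory pulse of the
#' schedule is injected into every hidden neuron once per period. Spike
#' counts for classification are taken only inside each sample's stimulus
#' window — never the relaxation. The readout is not inhibited; its
#' membrane decays naturally between samples.
#'
#' @param samples input rasters (T x N x S array or list); every raster
#'   must span exactly `schedule$stim_steps` steps.
#' @param model an [lsm()] object.
#' @param schedule a [streaming_schedule()].
#' @return as [infer_batch()], with additional attributes
#'   `relax_hidden_counts` (hidden spikes inside each sample's relaxation
#'   window) and `stim_hidden_counts`.
#' @export
infer_streaming <- function(samples, model, schedule = streaming_schedule()) {
  X <- as_raster_array(samples)
  T_ <- dim(X)[1]; N <- dim(X)[2]; S <- dim(X)[3]
  if (T_ != schedule$stim_steps)
    stop(sprintf("sample rasters span %d steps but the stimulus window is %d",
                 T_, schedule$stim_steps), call. = FALSE)
  M <- nrow(model$W_hh); C <- nrow(model$W_ho)
  period <- schedule$period
  extra <- numeric(period)
  extra[schedule$inh_step] <- schedule$inh_weight
  u <- NULL; v <- NULL
  counts <- matrix(0, S, C)
  relax_hidden <- numeric(S); stim_hidden <- numeric(S)
  for (s in seq_len(S)) {
    Xp <- array(0, dim = c(period, N, 1))
    Xp[seq_len(T_), , 1] <- X[, , s]
    hid <- hidden_rollout(model, Xp, init_u = u, extra_current = extra)
    u <- hid$final_u
    out <- readout_rollout(model$W_ho, hid$spikes, model$params, init_v = v)
    v <- out$final_v
    ospk <- matrix(out$spikes, nrow = period)
    counts[s, ] <- colSums(ospk[seq_len(schedule$stim_steps), , drop = FALSE])
    hspk <- matrix(hid$spikes, nrow = period)
    stim_hidden[s] <- sum(hspk[seq_len(schedule$stim_steps), ])
    if (schedule$relax_steps > 0)
      relax_hidden[s] <- sum(hspk[(schedule$stim_steps + 1):period, ])
  }
  res <- predictions_from_counts(counts)
  attr(res, "relax_hidden_counts") <- relax_hidden
  attr(res, "stim_hidden_counts") <- stim_hidden
  res
}

#' Predict classes for input rasters
#'
#' @param object a trained [lsm()] model.
#' @param newdata input rasters (T x N x S array or list of matrices).
#' @param type `"class"` for a label vector, `"counts"` for the spike-count
#'   matrix, `"table"` for the full prediction data.frame.
#' @param mode `"batch"` (state reset per sample) or `"streaming"`.
#' @param schedule a [streaming_schedule()] for streaming mode.
#' @param ... unused.
#' @return per `type`: integer labels, S x C count matrix, or data.frame.
#' @export
predict.lsm <- function(object, newdata,
                        type = c("class", "counts", "table"),
                        mode = c("batch", "streaming"),
                        schedule = streaming_schedule(), ...) {
  type <- match.arg(type); mode <- match.arg(mode)
  res <- if (mode == "batch") infer_batch(newdata, object)
         else infer_streaming(newdata, object, schedule)
  switch(type,
         class = res$label,
         counts = attr(res, "counts"),
         table = res)
}

#' Evaluate a model on a labelled raster set
#'
#' @param model a trained [lsm()] model.
#' @param x input rasters (T x N x S array or list).
#' @param y true 1-based labels.
#' @param mode `"batch"` or `"streaming"`.
#' @param schedule a [streaming_schedule()] for streaming mode.
#' @return list with `accuracy` (fraction correct) and `table` (one row per
#'   sample: true and predicted label, tie/silent flags, per-class counts).
#' @export
evaluate_model <- function(model, x, y, mode = c("batch", "streaming"),
                           schedule = streaming_schedule()) {
  mode <- match.arg(mode)
  res <- if (mode == "batch") infer_batch(x, model)
         else infer_streaming(x, model, schedule)
  counts <- attr(res, "counts")
  colnames(counts) <- paste0("count_", seq_len(ncol(counts)))
  tab <- cbind(data.frame(sample = seq_along(y), true = as.integer(y),
                          predicted = res$label, tie = res$tie,
                          silent = res$silent),
               as.data.frame(counts))
  list(accuracy = mean(res$label == as.integer(y)), table = tab)
}
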