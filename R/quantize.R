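# Uniform quantization of the frozen reservoir weights. Because the liquid
# is never trained, quantizing before or after readout training gives
# literally identical reservoir weights; only the memory footprint changes.

#' Fit the quantization scale to a weight distribution
#'
#' The scale anchors the quantization lattice to the weight distribution.
#' The default is the maximum absolute weight; a percentile of the absolute
#' weights can be used instead to ignore outliers.
#'
#' @param W weight matrix (nonempty).
#' @param percentile optional value in (0, 1]: use this quantile of `|W|`
#'   instead of the maximum.
#' @return the scale `s >= 0`, with attribute `degenerate = TRUE` when all
#'   weights are zero (quantization then maps everything to zero).
#' @export
fit_scale <- function(W, percentile = NULL) {
  if (length(W) == 0) stop("empty weight matrix", call. = FALSE)
  aw <- abs(W)
  s <- if (is.null(percentile)) max(aw)
       else stats::quantile(aw, percentile, names = FALSE)
  structure(s, degenerate = (s == 0))
}

#' Quantize weights to a b-bit uniform lattice
#'
#' Rounds each weight to the nearest multiple of the lattice step
#' `step = s * 2^(1 - b)` (ties to even). With the scale fitted to the
#' maximum absolute weight this places `2^b + 1` symmetric levels
#' (including zero) across `[-s, s]`, and the rounding error is at most
#' `step / 2` for any weight inside that range. Values outside `[-s, s]`
#' are still rounded to the lattice, not clipped.
#'
#' With `mode = "sign"` and `b = 1` the map is `s * sign(w)` instead — a
#' strict two-level (binarized) scheme with no zero level.
#'
#' @param W weight matrix.
#' @param bits number of bits `b >= 1`.
#' @param scale lattice scale `s >= 0`; defaults to [fit_scale()] of `W`.
#' @param mode `"round"` (default) or `"sign"` (only meaningful at
#'   `b = 1`).
#' @return the quantized matrix, with attributes `scale`, `step` and
#'   `bits`.
#' @export
quantize_weights <- function(W, bits, scale = fit_scale(W),
                             mode = c("round", "sign")) {
  mode <- match.arg(mode)
  if (bits < 1) stop("bits must be at least 1", call. = FALSE)
  s <- as.numeric(scale)
  if (s < 0) stop("scale must be nonnegative", call. = FALSE)
  if (s == 0) {
    Wq <- W * 0
    step <- 0
  } else if (mode == "sign") {
    if (bits != 1) stop("sign mode is a two-level scheme; use bits = 1",
                        call. = FALSE)
    Wq <- s * sign(W)
    step <- 2 * s
  } else {
    step <- s * 2^(1 - bits)
    Wq <- step * round(W / step)   # round() is ties-to-even
  }
  structure(Wq, scale = s, step = step, bits = as.integer(bits))
}

#' Quantize a model's reservoir weights
#'
#' Returns a copy of the model with `W_ih` and `W_hh` quantized to `bits`
#' bits, each with its own scale fitted to its weight distribution. The
#' trained readout weights and the neuron parameters are untouched: only
#' the frozen reservoir is reduced in precision.
#'
#' @param model an [lsm()] object.
#' @param bits number of bits per reservoir weight.
#' @param mode passed to [quantize_weights()].
#' @return the quantized `lsm` model, with a `quantization` field recording
#'   per-matrix scale, step, distinct-level count and maximum absolute
#'   rounding error.
#' @export
quantized_model <- function(model, bits, mode = "round") {
  stopifnot(inherits(model, "lsm"))
  report <- list()
  out <- model
  for (nm in c("W_ih", "W_hh")) {
    W <- model[[nm]]
    s <- fit_scale(W)
    Wq <- quantize_weights(W, bits, s, mode = mode)
    report[[nm]] <- list(scale = as.numeric(s),
                         step = attr(Wq, "step"),
                         n_levels = length(unique(as.numeric(Wq))),
                         max_error = max(abs(W - Wq)))
    attributes(Wq) <- list(dim = dim(W))
    out[[nm]] <- Wq
  }
  out$quantization <- c(list(bits = as.integer(bits), mode = mode), report)
  out
}

#' One-line text report of a quantization
#'
#' @param model a model returned by [quantized_model()].
#' @return character vector (one line per quantized matrix), invisibly;
#'   also printed.
#' @export
quantization_report <- function(model) {
  q <- model$quantization
  if (is.null(q)) stop("model has not been quantized", call. = FALSE)
  lines <- vapply(c("W_ih", "W_hh"), function(nm) {
    r <- q[[nm]]
    sprintf("%s: bits=%d scale=%.6g step=%.6g levels=%d max_error=%.3g",
            nm, q$bits, r$scale, r$step, r$n_levels, r$max_error)
  }, character(1))
  cat(lines, sep = "\n")
  invisible(lines)
}
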