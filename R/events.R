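# Address-event-representation (AER) I/O in the N-MNIST 5-byte binary
# dialect, binning of event streams into spike rasters, and a seeded
# generator of synthetic labelled event streams (moving-front stimuli with
# Poisson event emission and uniform background noise).

#' Event stream container
#'
#' A time-ordered set of DVS events. Each event carries a pixel location
#' (0-based `x` column, `y` row), a timestamp `t` in microseconds
#' (nondecreasing), and a polarity `p` (0 = OFF/darkening, 1 = ON/
#' brightening).
#'
#' @param events data frame with integer columns `x`, `y`, `t`, `p`.
#' @param width,height pixel grid dimensions.
#' @param duration recording duration in microseconds; defaults to the last
#'   timestamp + 1.
#' @return an object of class `event_stream`.
#' @export
event_stream <- function(events, width, height, duration = NULL) {
  events <- as.data.frame(events)
  stopifnot(all(c("x", "y", "t", "p") %in% names(events)))
  if (nrow(events) > 0) {
    if (any(events$x < 0 | events$x >= width) ||
        any(events$y < 0 | events$y >= height))
      stop("event coordinates outside the pixel grid", call. = FALSE)
    if (any(events$p != 0 & events$p != 1))
      stop("polarity must be 0 or 1", call. = FALSE)
    if (any(diff(events$t) < 0))
      stop("timestamps must be nondecreasing", call. = FALSE)
    if (any(events$t < 0)) stop("timestamps must be nonnegative", call. = FALSE)
  }
  if (is.null(duration))
    duration <- if (nrow(events) > 0) max(events$t) + 1 else 0
  structure(list(events = events, width = as.integer(width),
                 height = as.integer(height), duration = as.numeric(duration)),
            class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("event stream: %d events, %dx%d px, %.1f ms\n",
              nrow(x$events), x$width, x$height, x$duration / 1000))
  invisible(x)
}

#' Read / write the N-MNIST binary AER dialect
#'
#' Each event is 5 bytes: byte 0 = x, byte 1 = y, byte 2 bit 7 = polarity
#' and bits 6-0 = timestamp bits 22-16, bytes 3-4 = timestamp bits 15-0.
#' Timestamps are microseconds and must fit in 23 bits (~8.4 s).
#'
#' @param input a file path or a raw vector.
#' @param width,height pixel grid dimensions; inferred from the events when
#'   omitted.
#' @return `read_aer` returns an [event_stream()]; `write_aer` returns the
#'   raw encoding invisibly (and writes it to `path` when given).
#' @export
read_aer <- function(input, width = NULL, height = NULL) {
  bytes <- if (is.raw(input)) input
           else readBin(input, what = "raw", n = file.info(input)$size)
  nb <- length(bytes)
  if (nb %% 5 != 0)
    stop(sprintf("truncated AER record: %d trailing byte(s) at offset %d",
                 nb %% 5, nb - nb %% 5), call. = FALSE)
  n <- nb %/% 5
  if (n == 0) {
    ev <- data.frame(x = integer(0), y = integer(0), t = integer(0),
                     p = integer(0))
    return(event_stream(ev, width %||% 1L, height %||% 1L, duration = 0))
  }
  b <- matrix(as.integer(bytes), nrow = 5)
  x <- b[1, ]; y <- b[2, ]
  p <- b[3, ] %/% 128L
  t <- (b[3, ] %% 128L) * 65536L + b[4, ] * 256L + b[5, ]
  event_stream(data.frame(x = x, y = y, t = t, p = p),
               width = width %||% (max(x) + 1L),
               height = height %||% (max(y) + 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_aer
#' @param stream an [event_stream()].
#' @param path optional output file path.
#' @export
write_aer <- function(stream, path = NULL) {
  ev <- stream$events
  if (nrow(ev) > 0 && any(ev$t >= 2^23))
    stop("timestamps exceed the 23-bit range of the on-disk dialect",
         call. = FALSE)
  t <- as.integer(ev$t)
  bytes <- as.raw(rbind(ev$x, ev$y,
                        ev$p * 128L + t %/% 65536L,
                        (t %/% 256L) %% 256L,
                        t %% 256L))
  if (!is.null(path)) writeBin(bytes, path)
  invisible(bytes)
}

# (p, y, x) -> 1-based flat channel index, polarity-major then row-major.
channel_index <- function(p, y, x, width, height) {
  p * height * width + y * width + x + 1L
}

#' Bin an event stream into a spike raster
#'
#' Divides `[0, window)` ms into `T` equal half-open bins and maps each
#' event to the raster cell for its bin and its flattened channel
#' `p * H * W + y * W + x` (0-based, polarity-major, row-major). In
#' `"binary"` mode a cell is 1 iff at least one event fell in it (one spike
#' per timestep per channel); `"count"` mode keeps event counts for
#' diagnostics. Events at `t >= window` are dropped and counted.
#'
#' @param stream an [event_stream()].
#' @param n_bins number of time bins T.
#' @param window total binning window in ms; defaults to the stream
#'   duration (time-compressing the whole recording into T steps).
#' @param mode `"binary"` (default) or `"count"`.
#' @return a T x (2*H*W) [spike_raster()] (or count matrix) with attributes
#'   `dropped_events` and `dt` (= `window / n_bins`, ms).
#' @export
bin_to_raster <- function(stream, n_bins, window = stream$duration / 1000,
                          mode = c("binary", "count")) {
  mode <- match.arg(mode)
  stopifnot(n_bins >= 1, window > 0)
  ev <- stream$events
  K <- 2L * stream$height * stream$width
  window_us <- window * 1000
  keep <- ev$t < window_us
  dropped <- sum(!keep)
  ev <- ev[keep, , drop = FALSE]
  out <- matrix(0, nrow = n_bins, ncol = K)
  if (nrow(ev) > 0) {
    # t * T / window_us keeps the boundary t = window/T exactly on bin 1
    bin <- floor(ev$t * n_bins / window_us) + 1L
    ch <- channel_index(ev$p, ev$y, ev$x, stream$width, stream$height)
    tab <- table(factor(bin, levels = seq_len(n_bins)),
                 factor(ch, levels = seq_len(K)))
    out[] <- as.numeric(tab)
    if (mode == "binary") out <- (out > 0) + 0
  }
  structure(out, dropped_events = dropped, dt = window / n_bins,
            class = if (mode == "binary") c("spike_raster", "matrix"))
}

#' Synthetic event dataset configuration
#'
#' Describes a seeded generator of labelled DVS-like recordings emulating
#' the statistics of saccade-style event data: a bright front sweeping the
#' pixel grid along a class-specific direction, emitting ON events while it
#' covers a pixel and OFF events just after it leaves, over uniform
#' background noise on both polarities.
#'
#' @param n_classes number of classes (each gets a sweep direction spaced
#'   evenly on the circle). Default 4 (left, up, right, down sweeps).
#' @param grid `c(height, width)` of the pixel array. Default 16 x 16.
#' @param duration recording length in ms. Default 300 (saccade-scale).
#' @param base_rate ON/OFF event rate of a pixel being crossed by the
#'   front, events per ms. Default 0.5.
#' @param noise_rate background event rate per pixel per polarity,
#'   events per ms. Default 0.005.
#' @param jitter standard deviation (ms) of per-pixel timing jitter of the
#'   front crossing. Default 5.
#' @param samples_per_class recordings per class. Default 100.
#' @param seed integer seed; the full dataset is a pure function of the
#'   configuration.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 4L, grid = c(16L, 16L), duration = 300,
                         base_rate = 0.5, noise_rate = 0.005, jitter = 5,
                         samples_per_class = 100L, seed = 1L) {
  stopifnot(n_classes >= 2, length(grid) == 2, all(grid >= 1), duration > 0,
            base_rate >= 0, noise_rate >= 0, jitter >= 0,
            samples_per_class >= 1)
  structure(list(n_classes = as.integer(n_classes),
                 grid = as.integer(grid), duration = duration,
                 base_rate = base_rate, noise_rate = noise_rate,
                 jitter = jitter,
                 samples_per_class = as.integer(samples_per_class),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# One synthetic recording for class `cls` (1-based). RNG state is managed by
# the caller.
synth_one <- function(config, cls) {
  H <- config$grid[1]; W <- config$grid[2]
  dur <- config$duration
  phi <- 2 * pi * (cls - 1) / config$n_classes
  px <- expand.grid(x = 0:(W - 1), y = 0:(H - 1))
  proj <- cos(phi) * px$x + sin(phi) * px$y
  rng <- range(proj)
  q <- if (rng[2] > rng[1]) (proj - rng[1]) / (rng[2] - rng[1]) else proj * 0
  dwell <- dur / (rng[2] - rng[1] + 1)
  entry <- q * (dur - 2 * dwell) +
    stats::rnorm(nrow(px), sd = config$jitter)
  entry <- pmin(pmax(entry, 0), dur - dwell)
  exit <- entry + dwell
  emit <- function(t0, span, pol) {
    n <- stats::rpois(length(t0), config$base_rate * span)
    idx <- rep.int(seq_along(t0), n)
    if (length(idx) == 0)
      return(data.frame(x = integer(0), y = integer(0), t = numeric(0),
                        p = integer(0)))
    data.frame(x = px$x[idx], y = px$y[idx],
               t = t0[idx] + stats::runif(length(idx)) * span,
               p = pol)
  }
  on_ev <- emit(entry, dwell, 1L)
  off_ev <- emit(exit, dwell, 0L)
  n_noise <- stats::rpois(1, 2 * config$noise_rate * dur * H * W)
  noise <- data.frame(
    x = sample.int(W, n_noise, replace = TRUE) - 1L,
    y = sample.int(H, n_noise, replace = TRUE) - 1L,
    t = stats::runif(n_noise) * dur,
    p = sample(c(0L, 1L), n_noise, replace = TRUE))
  ev <- rbind(on_ev, off_ev, noise)
  ev <- ev[ev$t >= 0 & ev$t < dur, , drop = FALSE]
  ev$t <- as.integer(floor(ev$t * 1000))      # ms -> us
  ev <- ev[order(ev$t), , drop = FALSE]
  rownames(ev) <- NULL
  event_stream(ev, width = W, height = H, duration = dur * 1000)
}

#' Generate a labelled synthetic event dataset
#'
#' Produces `n_classes * samples_per_class` recordings according to a
#' [synth_config()]. Class c sweeps a one-pixel-wide front across the grid
#' in direction `2*pi*(c-1)/n_classes`; pixels emit ON events (Poisson at
#' `base_rate` per ms) while the front covers them and OFF events for an
#' equal span after it leaves, with per-pixel Gaussian timing jitter, plus
#' uniform background noise on both polarities. Identical configurations
#' (including the seed) yield identical datasets.
#'
#' @param config a [synth_config()].
#' @return a list with `streams` (list of [event_stream()]) and `labels`
#'   (1-based integer class vector).
#' @examples
#' d <- synth_generate(synth_config(samples_per_class = 2, seed = 7))
#' table(d$labels)
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, {
    labels <- rep(seq_len(config$n_classes), each = config$samples_per_class)
    streams <- lapply(labels, function(cls) synth_one(config, cls))
    list(streams = streams, labels = labels)
  })
}

#' Convert a list of event streams to a raster batch
#'
#' Bins every stream with [bin_to_raster()] into a common T x K x S array.
#' `time_mode = "compress"` maps each full recording onto the T steps
#' (every event is used); `"truncate"` keeps only the first `n_bins * dt`
#' ms at the simulation resolution.
#'
#' @param streams list of [event_stream()] objects with equal grid sizes.
#' @param n_bins number of timesteps T.
#' @param time_mode `"compress"` (default) or `"truncate"`.
#' @param dt simulation resolution in ms (used by `"truncate"`).
#' @return T x K x S binary array, K = 2 * H * W.
#' @export
rasters_from_streams <- function(streams, n_bins,
                                 time_mode = c("compress", "truncate"),
                                 dt = 1.0) {
  time_mode <- match.arg(time_mode)
  mats <- lapply(streams, function(s) {
    win <- if (time_mode == "compress") s$duration / 1000 else n_bins * dt
    unclass(bin_to_raster(s, n_bins, window = win))
  })
  as_raster_array(mats)
}

#' Write / read an event dataset directory
#'
#' Lays out streams on disk as `<dir>/<label>/<index>.bin` in the binary
#' AER dialect (labels written 0-based, as in the N-MNIST distribution).
#'
#' @param dataset list with `streams` and `labels` as from
#'   [synth_generate()].
#' @param dir directory to create/read.
#' @return `write_event_dataset` returns `dir` invisibly;
#'   `read_event_dataset` returns a `list(streams, labels)` with 1-based
#'   labels, ordered by label then file name.
#' @export
write_event_dataset <- function(dataset, dir) {
  for (cls in sort(unique(dataset$labels))) {
    sub <- file.path(dir, cls - 1L)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    idx <- which(dataset$labels == cls)
    for (i in seq_along(idx))
      write_aer(dataset$streams[[idx[i]]],
                file.path(sub, sprintf("%05d.bin", i)))
  }
  invisible(dir)
}

#' @rdname write_event_dataset
#' @param width,height grid dimensions passed to [read_aer()].
#' @export
read_event_dataset <- function(dir, width = NULL, height = NULL) {
  subs <- sort(list.dirs(dir, recursive = FALSE))
  streams <- list(); labels <- integer(0)
  for (sub in subs) {
    cls <- as.integer(basename(sub)) + 1L
    files <- sort(list.files(sub, pattern = "\\.bin$", full.names = TRUE))
    for (f in files) {
      streams[[length(streams) + 1L]] <- read_aer(f, width, height)
      labels <- c(labels, cls)
    }
  }
  list(streams = streams, labels = labels)
}
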