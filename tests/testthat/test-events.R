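test_that("AER codec matches the 5-byte format and round-trips", {
  # hand-packed single record against the independent packer
  bytes <- oracle_pack_event(5L, 7L, 1L, 1000L)
  s <- read_aer(bytes, width = 16, height = 16)
  expect_equal(s$events$x, 5)
  expect_equal(s$events$y, 7)
  expect_equal(s$events$p, 1)
  expect_equal(s$events$t, 1000)
  expect_identical(write_aer(s), bytes)
  # timestamps above 16 bits exercise the 7 high bits in byte 2
  big <- oracle_pack_event(1L, 2L, 0L, 2^23 - 1L)
  sb <- read_aer(big, 4, 4)
  expect_equal(sb$events$t, 2^23 - 1)
  expect_equal(sb$events$p, 0)
  # empty input
  expect_equal(nrow(read_aer(raw(0))$events), 0)
  # trailing partial record names the offset
  expect_error(read_aer(c(bytes, as.raw(1:2))), "offset 5")
})

test_that("codec round-trip is the identity on random streams", {
  set.seed(77)
  for (trial in 1:10) {
    s <- random_stream(sample(1:200, 1))
    bytes <- write_aer(s)
    back <- read_aer(bytes, s$width, s$height)
    expect_equal(back$events, s$events)
    expect_identical(write_aer(back), bytes)
  }
  # file round trip
  s <- random_stream(50)
  f <- tempfile(fileext = ".bin")
  write_aer(s, f)
  expect_equal(read_aer(f, s$width, s$height)$events, s$events)
  unlink(f)
})

test_that("binning uses half-open bins and the documented channel order", {
  s <- event_stream(data.frame(x = 0L, y = 0L, t = 0L, p = 0L), 3, 2,
                    duration = 10000)
  r <- bin_to_raster(s, 5, window = 10)
  expect_equal(dim(r), c(5, 12))
  expect_equal(sum(r), 1)
  expect_equal(r[1, 1], 1)
  # boundary event t = window/T lands in the second bin (0-based bin 1)
  s2 <- event_stream(data.frame(x = 0L, y = 0L, t = 2000L, p = 0L), 3, 2,
                     duration = 10000)
  r2 <- bin_to_raster(s2, 5, window = 10)
  expect_equal(which(r2[, 1] == 1), 2)
  # channel flattening p*H*W + y*W + x is a bijection onto 0..2HW-1
  grid <- expand.grid(x = 0:2, y = 0:1, p = 0:1)
  idx <- grid$p * 6 + grid$y * 3 + grid$x
  expect_setequal(idx, 0:11)
  ev <- data.frame(x = grid$x, y = grid$y, t = seq(0, 110, by = 10), p = grid$p)
  s3 <- event_stream(ev[order(ev$t), ], 3, 2, duration = 1000)
  r3 <- bin_to_raster(s3, 1, window = 1)
  expect_equal(as.numeric(r3), rep(1, 12))
})

test_that("binning conserves events and reports drops", {
  set.seed(13)
  s <- random_stream(300, width = 6, height = 5, max_t = 40000)
  win <- 30 # ms: some events beyond the window
  rc <- bin_to_raster(s, 10, window = win, mode = "count")
  in_window <- sum(s$events$t < win * 1000)
  expect_equal(sum(rc), in_window)
  expect_equal(attr(rc, "dropped_events"), nrow(s$events) - in_window)
  # per-event independent bin computation
  ev <- s$events[s$events$t < win * 1000, ]
  for (i in sample(nrow(ev), 20)) {
    bin <- floor(ev$t[i] * 10 / (win * 1000)) + 1
    ch <- ev$p[i] * 30 + ev$y[i] * 6 + ev$x[i] + 1
    expect_gte(rc[bin, ch], 1)
  }
  # binarized raster never exceeds the counting raster
  rb <- bin_to_raster(s, 10, window = win)
  expect_true(all(rb <= rc))
  expect_true(all(rb %in% c(0, 1)))
})

test_that("synthetic generation is seeded and respects rate switches", {
  cfg <- synth_config(samples_per_class = 2, duration = 80, seed = 5)
  d1 <- synth_generate(cfg)
  d2 <- synth_generate(cfg)
  expect_identical(d1, d2)
  expect_equal(length(d1$streams), 8)
  expect_equal(d1$labels, rep(1:4, each = 2))
  for (s in d1$streams) {
    expect_true(all(diff(s$events$t) >= 0))
    expect_true(all(s$events$t < 80 * 1000))
    expect_true(all(s$events$x >= 0 & s$events$x < 16))
  }
  # zero rates produce empty streams
  quiet <- synth_generate(synth_config(samples_per_class = 1, base_rate = 0,
                                       noise_rate = 0, seed = 5))
  expect_true(all(vapply(quiet$streams,
                         function(s) nrow(s$events) == 0, logical(1))))
})

test_that("event datasets round-trip through the on-disk layout", {
  cfg <- synth_config(samples_per_class = 2, duration = 50,
                      grid = c(8, 8), seed = 9)
  d <- synth_generate(cfg)
  dir <- tempfile("aerds")
  write_event_dataset(d, dir)
  expect_setequal(basename(list.dirs(dir, recursive = FALSE)),
                  as.character(0:3))
  back <- read_event_dataset(dir, width = 8, height = 8)
  expect_equal(back$labels, d$labels)
  for (i in seq_along(d$streams))
    expect_equal(back$streams[[i]]$events, d$streams[[i]]$events)
  unlink(dir, recursive = TRUE)
})

test_that("raster batches stack streams consistently", {
  cfg <- synth_config(samples_per_class = 1, duration = 60, grid = c(8, 8),
                      seed = 2)
  d <- synth_generate(cfg)
  x <- rasters_from_streams(d$streams, 12)
  expect_equal(dim(x), c(12, 2 * 64, 4))
  expect_equal(as.numeric(x[, , 2]),
               as.numeric(bin_to_raster(d$streams[[2]], 12,
                                        window = d$streams[[2]]$duration / 1000)))
  # truncate mode keeps only the first n_bins * dt ms
  xt <- rasters_from_streams(d$streams, 12, time_mode = "truncate", dt = 1)
  expect_equal(dim(xt), dim(x))
  first12 <- d$streams[[1]]$events$t < 12000
  expect_equal(sum(xt[, , 1] > 0) <= sum(first12), TRUE)
})
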