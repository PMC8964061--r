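test_that("spike-count classification breaks ties low and flags silence", {
  p <- classify_counts(c(3, 1, 0))
  expect_equal(p$label, 1)
  expect_false(p$tie)
  expect_false(p$silent)
  p2 <- classify_counts(c(2, 2))
  expect_equal(p2$label, 1)
  expect_true(p2$tie)
  p3 <- classify_counts(c(0, 0, 0))
  expect_equal(p3$label, 1)
  expect_true(p3$silent)
  expect_error(classify_counts(numeric(0)), "empty")
})

test_that("batch inference is stateless across samples", {
  set.seed(3)
  m <- lsm(6, 16, 3, neuron_params(gain = 8), seed = 2)
  x <- array(rbinom(10 * 6 * 7, 1, 0.4), dim = c(10, 6, 7))
  res <- infer_batch(x, m)
  expect_equal(nrow(res), 7)
  # permuting the samples permutes the predictions identically
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  res_p <- infer_batch(x[, , perm], m)
  expect_equal(res_p$label, res$label[perm])
  expect_equal(attr(res_p, "counts"), attr(res, "counts")[perm, ])
  # a duplicated sample gets the same prediction twice
  dup <- infer_batch(x[, , c(1, 1)], m)
  expect_equal(dup$label[1], dup$label[2])
  # single sample equals run_reservoir + classify_counts
  rec <- run_reservoir(matrix(x[, , 3], 10), m)
  expect_equal(as.numeric(attr(res, "counts")[3, ]), rec$readout_counts)
  expect_equal(res$label[3], classify_counts(rec$readout_counts)$label)
})

test_that("streaming with no prior activity equals batch on one sample", {
  set.seed(8)
  m <- lsm(6, 16, 3, neuron_params(gain = 8), seed = 2)
  x <- array(rbinom(25 * 6, 1, 0.4), dim = c(25, 6, 1))
  sched <- streaming_schedule() # inhibition after the stimulus window
  sres <- infer_streaming(x, m, sched)
  bres <- infer_batch(x, m)
  expect_equal(sres$label, bres$label)
  expect_equal(attr(sres, "counts"), attr(bres, "counts"))
  expect_error(infer_streaming(array(0, c(10, 6, 1)), m, sched), "stimulus")
})

test_that("overwhelming inhibition plus a long relaxation recovers batch mode", {
  set.seed(12)
  m <- lsm(8, 24, 3, neuron_params(gain = 10), seed = 4)
  x <- array(rbinom(25 * 8 * 6, 1, 0.35), dim = c(25, 8, 6))
  sched <- streaming_schedule(relax_ms = 300, inh_weight = -1000)
  sres <- infer_streaming(x, m, sched)
  bres <- infer_batch(x, m)
  expect_equal(sres$label, bres$label)
  expect_equal(attr(sres, "counts"), attr(bres, "counts"))
})

test_that("the inhibitory pulse quenches relaxation-window activity", {
  set.seed(19)
  m <- lsm(8, 32, 2, neuron_params(gain = 12), seed = 4)
  x <- array(rbinom(25 * 8 * 8, 1, 0.4), dim = c(25, 8, 8))
  on <- infer_streaming(x, m, streaming_schedule(inh_weight = -10))
  off <- infer_streaming(x, m, streaming_schedule(inh_weight = 0))
  expect_lt(sum(attr(on, "relax_hidden_counts")),
            sum(attr(off, "relax_hidden_counts")))
})

test_that("evaluation tables line up with predictions", {
  set.seed(30)
  m <- lsm(6, 16, 3, neuron_params(gain = 8), seed = 2)
  x <- array(rbinom(10 * 6 * 9, 1, 0.4), dim = c(10, 6, 9))
  y <- rep(1:3, 3)
  ev <- evaluate_model(m, x, y)
  expect_equal(nrow(ev$table), 9)
  expect_equal(ev$accuracy, mean(ev$table$predicted == y))
  expect_equal(ev$table$predicted, predict(m, x))
  counts <- predict(m, x, type = "counts")
  expect_equal(unname(as.matrix(ev$table[, 6:8])), unname(counts))
})

test_that("config files round-trip through YAML", {
  cfg <- list(neuron = neuron_params(u_th = 0.25, gain = 16),
              training = train_config(learning_rate = 0.005, epochs = 7),
              synthetic = synth_config(samples_per_class = 3, seed = 44),
              schedule = streaming_schedule(relax_ms = 30, inh_weight = -5),
              network = list(n_hidden = 128L, seed = 2L))
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back$neuron, cfg$neuron)
  expect_equal(back$training, cfg$training)
  expect_equal(back$synthetic, cfg$synthetic)
  expect_equal(back$schedule, cfg$schedule)
  expect_equal(back$network$n_hidden, 128)
  unlink(f)
})
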