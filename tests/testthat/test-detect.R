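# Derivative-threshold event detection: hand-computed examples, oracle
# equivalence, and the algebraic invariants of the detector.

test_that("smoothing averages neighbouring points", {
  expect_equal(smooth_trace(c(1, 3)), 2)
  expect_equal(smooth_trace(rep(7, 10)), rep(7, 9))
  expect_equal(smooth_trace(c(0, 2, 4, 10)), c(1, 3, 7))
  expect_error(smooth_trace(5), "samples")
})

test_that("derivative is the first difference", {
  expect_equal(trace_derivative(c(2, 2, 2)), c(0, 0))
  expect_equal(trace_derivative(c(0, 1, 3)), c(1, 2))
  expect_equal(trace_derivative(smooth_trace(c(0, 0, 4, 4))), c(2, 2))
  expect_error(trace_derivative(1), "2 samples")
})

test_that("threshold is k times the derivative SD", {
  p <- detection_params(accuracy_coefficient = 0.45)
  expect_equal(detection_threshold(c(1, -1, 1, -1), p), 0.45)
  expect_equal(detection_threshold(rep(3, 5), p), 0)
  p2 <- detection_params(accuracy_coefficient = 0.9)
  expect_equal(detection_threshold(c(1, -1, 1, -1), p2), 0.9)
  ps <- detection_params(sd_mode = "sample")
  expect_equal(detection_threshold(c(0, 1), ps), 0.45 * sd(c(0, 1)))
})

test_that("flat and too-short traces are handled", {
  expect_equal(nrow(detect_events(rep(5, 20), 4)), 0)
  expect_error(detect_events(c(1, 2, 3), 4), "4 samples")
  expect_error(detect_events(c(1, NA, 3, 4, 5), 4), "finite")
})

test_that("the 16-sample toy transient yields exactly the oracle's event", {
  x <- c(rep(100, 8), 140, 180, 180, 180, 140, 100, 100, 100)
  ev <- detect_events(x, frame_rate = 4)
  orc <- oracle_detect(x)
  expect_equal(nrow(ev), 1)
  expect_equal(nrow(orc), 1)
  expect_equal(ev$onset_frame, unname(orc[, 1]))
  expect_equal(ev$offset_frame, unname(orc[, 2]))
  expect_equal(ev$onset_s, (ev$onset_frame - 1) / 4)
  expect_equal(ev$duration_s, ev$offset_s - ev$onset_s)
})

test_that("detector matches the straight-line oracle on random traces", {
  set.seed(101)
  for (rep in 1:500) {
    n <- sample(4:64, 1)
    x <- random_trace(n)
    ev <- detect_events(x, 4)
    orc <- oracle_detect(x)
    expect_identical(ev$onset_frame, as.integer(orc[, 1]))
    expect_identical(ev$offset_frame, as.integer(orc[, 2]))
  }
})

test_that("detection is invariant under affine rescaling a*F + b, a > 0", {
  set.seed(202)
  for (rep in 1:100) {
    x <- random_trace(sample(10:120, 1))
    a <- runif(1, 0.1, 10); b <- runif(1, -50, 50)
    e1 <- detect_events(x, 4)
    e2 <- detect_events(a * x + b, 4)
    expect_equal(e1$onset_frame, e2$onset_frame)
    expect_equal(e1$offset_frame, e2$offset_frame)
  }
})

test_that("event count is non-increasing in k", {
  set.seed(303)
  for (rep in 1:30) {
    x <- random_trace(80)
    ks <- c(0.2, 0.45, 0.9, 1.8, 3.6)
    counts <- vapply(ks, function(k)
      nrow(detect_events(x, 4, detection_params(accuracy_coefficient = k))),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("events are sorted, non-overlapping, with offset after onset", {
  set.seed(404)
  for (rep in 1:50) {
    ev <- detect_events(random_trace(100), 4)
    if (!nrow(ev)) next
    expect_true(all(ev$offset_s > ev$onset_s))
    expect_true(!is.unsorted(ev$onset_frame))
    if (nrow(ev) > 1)
      expect_true(all(ev$onset_frame[-1] > ev$offset_frame[-nrow(ev)]))
  }
})

test_that("min_event_samples discards short events", {
  set.seed(77)
  x <- random_trace(200)
  all_ev <- detect_events(x, 4, detection_params(min_event_samples = 1))
  long_ev <- detect_events(x, 4, detection_params(min_event_samples = 10))
  expect_lte(nrow(long_ev), nrow(all_ev))
  if (nrow(long_ev))
    expect_true(all(long_ev$offset_frame - long_ev$onset_frame + 1 >= 10))
})

test_that("noise-free well-separated transients are recovered exactly", {
  cfg <- sim_config(n_cells = 20, duration = 120, event_rate = 1,
                    network_event_rate = 0, noise_sd = 0, seed = 55)
  sim <- simulate_traces(cfg)
  ev <- detect_all(sim$traces)
  for (j in seq_along(sim$truth)) {
    id <- names(sim$truth)[j]
    expect_equal(sum(ev$cell_id == id), nrow(sim$truth[[j]]))
  }
})

test_that("noisy recordings keep sensitivity and FDR within bounds", {
  cfg <- sim_config(n_cells = 200, duration = 300, event_rate = 2,
                    network_event_rate = 0, seed = 66)
  perf <- detection_performance(simulate_traces(cfg))
  expect_gte(perf$sensitivity, 0.95)
  expect_lte(perf$fdr, 0.05)
})
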