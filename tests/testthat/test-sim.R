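# Synthetic-data generators: contracts, determinism, event statistics.

test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(noise_sd = -1), "negative")
  expect_error(sim_config(sync_fraction = 1.5), "sync_fraction")
  expect_error(sim_config(duration = 0))
  expect_error(sim_config(amplitude = NaN), "non-finite")
})

test_that("no signal sources yields constant baseline traces", {
  cfg <- sim_config(n_cells = 4, duration = 30, baseline = 77,
                    noise_sd = 0, event_rate = 0, network_event_rate = 0,
                    seed = 5)
  sim <- simulate_traces(cfg)
  expect_equal(dim(sim$traces$values), c(30 * 4, 4))
  expect_true(all(sim$traces$values == 77))
  expect_true(all(vapply(sim$truth, nrow, integer(1)) == 0))
})

test_that("traces have duration x frame_rate samples and valid ground truth", {
  cfg <- sim_config(n_cells = 3, duration = 45, frame_rate = 8, seed = 2)
  sim <- simulate_traces(cfg)
  expect_equal(nrow(sim$traces$values), 45 * 8)
  for (tr in sim$truth) {
    expect_true(all(tr$offset_s > tr$onset_s))
    expect_true(all(tr$onset_s >= 0 & tr$offset_s <= 45))
  }
})

test_that("identical seed and config give bitwise-identical output", {
  cfg <- sim_config(n_cells = 6, duration = 40, seed = 11)
  a <- simulate_traces(cfg)
  b <- simulate_traces(cfg)
  expect_identical(a$traces$values, b$traces$values)
  expect_identical(a$truth, b$truth)
  expect_identical(a$network_events$time_s, b$network_events$time_s)
})

test_that("adding a cell does not perturb existing cells' traces", {
  base <- simulate_traces(sim_config(n_cells = 4, duration = 40, seed = 9))
  more <- simulate_traces(sim_config(n_cells = 7, duration = 40, seed = 9))
  expect_identical(base$traces$values, more$traces$values[, 1:4])
})

test_that("total event count obeys the Poisson law", {
  # 10 cells x 5 min x 2/min -> Poisson mean 100, sd 10
  cfg <- sim_config(n_cells = 10, duration = 300, event_rate = 2,
                    network_event_rate = 0, noise_sd = 0, seed = 21)
  sim <- simulate_traces(cfg)
  total <- sum(lengths(sim$onsets))
  expect_gt(total, 100 - 3 * 10)
  expect_lt(total, 100 + 3 * 10)
  # merged ground-truth intervals can only reduce the count
  expect_lte(sum(vapply(sim$truth, nrow, integer(1))), total)
})

test_that("per-cell event counts pass a chi-square goodness-of-fit", {
  cfg <- sim_config(n_cells = 1000, duration = 30, event_rate = 2,
                    network_event_rate = 0, noise_sd = 0, amplitude = 0,
                    seed = 33)
  sim <- simulate_traces(cfg)
  counts <- lengths(sim$onsets)
  lambda <- 2 / 60 * 30
  kmax <- max(counts, 5)
  obs <- tabulate(counts + 1L, kmax + 1L)
  p <- dpois(0:kmax, lambda)
  p[kmax + 1L] <- p[kmax + 1L] + ppois(kmax, lambda, lower.tail = FALSE)
  keep <- p * 1000 >= 5
  obs2 <- c(obs[keep], sum(obs[!keep]))
  p2 <- c(p[keep], sum(p[!keep]))
  chisq <- sum((obs2 - 1000 * p2)^2 / (1000 * p2))
  expect_lt(chisq, qchisq(0.99, df = length(p2) - 1))
})

test_that("quantized traces are integers within 0-255", {
  cfg <- sim_config(n_cells = 3, duration = 20, quantize = TRUE,
                    baseline = 240, amplitude = 60, seed = 4)
  v <- simulate_traces(cfg)$traces$values
  expect_true(all(v == round(v)))
  expect_true(all(v >= 0 & v <= 255))
})

test_that("simulate_stack realises traces exactly at zero noise", {
  cfg <- sim_config(n_cells = 2, duration = 15, noise_sd = 0, seed = 6)
  lab <- matrix(0L, 20, 20)
  lab[3:6, 3:6] <- 1L
  lab[12:16, 10:15] <- 2L
  out <- simulate_stack(cfg, lab)
  tr <- extract_traces(out$stack, lab, cfg$frame_rate)
  expect_equal(unname(tr$values), unname(out$traces$values))
})

test_that("simulate_stack rejects overlapping masks and wrong cell counts", {
  cfg <- sim_config(n_cells = 2, duration = 5, seed = 1)
  m1 <- matrix(FALSE, 10, 10); m1[1:4, 1:4] <- TRUE
  m2 <- matrix(FALSE, 10, 10); m2[3:6, 3:6] <- TRUE
  expect_error(simulate_stack(cfg, list(m1, m2)), "overlapping")
  lab <- matrix(0L, 10, 10); lab[1:3, 1:3] <- 1L
  expect_error(simulate_stack(cfg, lab), "n_cells")
})

test_that("empty ROI map gives pure background", {
  cfg <- sim_config(n_cells = 1, duration = 5, noise_sd = 0, baseline = 50,
                    event_rate = 0, network_event_rate = 0, seed = 1)
  lab <- matrix(0L, 8, 8)
  lab[2, 2] <- 1L   # single-pixel ROI keeps n_cells consistent
  out <- simulate_stack(cfg, lab)
  expect_true(all(out$stack == 50))
})

test_that("simulate_respirometry: sd = 0 reproduces group means, seeded", {
  gm <- data.frame(group = c("Sham", "Hypoxia"), V4_gm = c(73.99, 88.8),
                   V3 = c(281.2, 151), V4_succ = c(120, 140))
  tab <- simulate_respirometry(gm, sd = 0, n = 4, seed = 2)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$V4_gm, rep(gm$V4_gm, each = 4))
  t1 <- simulate_respirometry(gm, sd = 5, n = 1, seed = 7)
  t2 <- simulate_respirometry(gm, sd = 5, n = 1, seed = 7)
  expect_identical(t1, t2)
  expect_true(all(t1[c("V4_gm", "V3", "V4_succ")] > 0))
  expect_error(simulate_respirometry(gm, n = 0), "positive")
  gm$V3[1] <- -1
  expect_error(simulate_respirometry(gm), "positive")
})

test_that("simulate_ct_table encodes folds in Ct space", {
  tf <- data.frame(group = c("Sham", "Hyp"), gene = "Hif1a", fold = c(1, 4))
  ct <- simulate_ct_table(tf, base_ct = 25, noise_sd = 0, n = 2, seed = 3)
  hyp_t <- ct$Ct[ct$group == "Hyp" & ct$gene == "Hif1a"]
  expect_equal(hyp_t, rep(23, 2))          # log2(4) = 2 cycles below base
  sham_t <- ct$Ct[ct$group == "Sham" & ct$gene == "Hif1a"]
  expect_equal(sham_t, rep(25, 2))
  expect_error(simulate_ct_table(data.frame(group = "a", gene = "g",
                                            fold = 0)), "positive")
})

test_that("trace CSV and truth JSON round-trip", {
  sim <- simulate_traces(sim_config(n_cells = 3, duration = 20, seed = 8))
  tf <- tempfile(fileext = ".csv"); jf <- tempfile(fileext = ".json")
  write_traces_csv(sim$traces, tf)
  back <- read_traces_csv(tf)
  expect_equal(back$values, sim$traces$values, tolerance = 1e-12)
  expect_equal(back$frame_rate, 4)
  write_truth_json(sim$truth, jf)
  truth2 <- read_truth_json(jf)
  for (i in seq_along(sim$truth))
    expect_equal(truth2[[i]], sim$truth[[i]], tolerance = 1e-9)
  unlink(c(tf, jf))
})
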