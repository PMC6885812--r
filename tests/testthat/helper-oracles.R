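# Independent straight-line oracles used to pin down expected values.

# Brute-force re-implementation of the detection pipeline: materialises the
# smoothed series, derivative and threshold sample by sample and scans runs
# with an explicit state machine. Returns 1-based (onset_frame, offset_frame)
# pairs. Kept deliberately naive and separate from the package code path.
oracle_detect <- function(x, k = 0.45, sd_mode = "population") {
  n <- length(x)
  s <- numeric(n - 1)
  for (i in seq_len(n - 1)) s[i] <- (x[i] + x[i + 1]) / 2
  d <- numeric(n - 2)
  for (i in seq_len(n - 2)) d[i] <- s[i + 1] - s[i]
  mu <- sum(d) / length(d)
  ss <- 0
  for (v in d) ss <- ss + (v - mu)^2
  sdv <- if (sd_mode == "population") sqrt(ss / length(d))
         else sqrt(ss / (length(d) - 1))
  theta <- k * sdv
  if (theta <= 0) return(matrix(integer(0), ncol = 2))
  onsets <- integer(0); offsets <- integer(0)
  open <- NA
  i <- 1
  while (i <= length(d)) {
    if (is.na(open) && d[i] > theta) {
      open <- i                       # first sample of a positive run
      while (i <= length(d) && d[i] > theta) i <- i + 1
    } else if (!is.na(open) && d[i] < -theta) {
      while (i <= length(d) && d[i] < -theta) i <- i + 1
      onsets <- c(onsets, open)
      offsets <- c(offsets, i - 1)    # last sample of the negative run
      open <- NA
    } else i <- i + 1
  }
  if (!is.na(open)) {                 # trailing open event -> trace end
    onsets <- c(onsets, open)
    offsets <- c(offsets, n - 1)      # maps to raw frame n after +1 below
  }
  cbind(onset_frame = onsets + 1, offset_frame = pmin(offsets + 1, n))
}

# Brute-force connected components by iterative neighbour propagation.
oracle_label_count <- function(mask, connectivity = 8) {
  m <- which(mask, arr.ind = TRUE)
  if (!nrow(m)) return(0L)
  comp <- seq_len(nrow(m))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(nrow(m))) {
        dr <- abs(m[i, 1] - m[j, 1]); dc <- abs(m[i, 2] - m[j, 2])
        adj <- if (connectivity == 8) max(dr, dc) == 1
               else dr + dc == 1
        if (adj && comp[j] != comp[i]) {
          lo <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- lo
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# Random traces for property tests: mixtures of noise, drifts and transients.
random_trace <- function(n, baseline = 100) {
  kind <- sample(3, 1)
  t <- seq_len(n)
  x <- baseline + rnorm(n, 0, runif(1, 0.1, 3))
  if (kind >= 2) {
    for (e in seq_len(sample(3, 1))) {
      on <- runif(1, 0, n)
      x <- x + runif(1, 5, 60) * pmax(0, exp(-(t - on) / runif(1, 4, 15)) -
                                        exp(-(t - on) / runif(1, 0.5, 3))) *
        (t >= on)
    }
  }
  if (kind == 3) x <- x + cumsum(rnorm(n, 0, 0.5))
  x
}

# Draw a small disk into a matrix (for viability fixtures).
add_disk <- function(img, r0, c0, radius, value = 255) {
  for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img)))
    if ((r - r0)^2 + (cc - c0)^2 <= radius^2) img[r, cc] <- value
  img
}

# Overlap-based matching of detected events against ground-truth intervals
# for one cell; returns c(n_true, n_detected, n_true_matched, n_det_matched).
match_events <- function(det, truth) {
  if (is.null(det)) det <- data.frame(onset_s = numeric(0),
                                      offset_s = numeric(0))
  tm <- 0L
  if (nrow(truth)) for (i in seq_len(nrow(truth))) {
    hit <- any(det$onset_s <= truth$offset_s[i] &
               det$offset_s >= truth$onset_s[i])
    tm <- tm + hit
  }
  dm <- 0L
  if (nrow(det)) for (i in seq_len(nrow(det))) {
    hit <- any(truth$onset_s <= det$offset_s[i] &
               truth$offset_s >= det$onset_s[i])
    dm <- dm + hit
  }
  c(n_true = nrow(truth), n_det = nrow(det), true_matched = tm,
    det_matched = dm)
}

# Detection sensitivity / false-discovery rate of a simulated recording.
detection_performance <- function(sim, params = detection_params()) {
  ev <- detect_all(sim$traces, params = params)
  tot <- c(0, 0, 0, 0)
  for (j in seq_along(sim$truth)) {
    id <- names(sim$truth)[j]
    det <- ev[ev$cell_id == id, c("onset_s", "offset_s")]
    tot <- tot + match_events(det, sim$truth[[j]])
  }
  list(sensitivity = tot[3] / max(tot[1], 1),
       fdr = 1 - tot[4] / max(tot[2], 1),
       n_true = tot[1], n_det = tot[2], events = ev)
}
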