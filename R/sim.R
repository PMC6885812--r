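# Synthetic recordings with known ground truth: fluorescence traces and image
# stacks, respirometry state tables, and qPCR Ct tables.

#' Simulation configuration for synthetic calcium recordings
#'
#' Bundles every knob of the trace/stack generator. Defaults describe a
#' healthy culture imaged with a high-affinity calcium indicator on an 8-bit
#' confocal at 4 Hz: a baseline around 60 relative units (r.u.), transients of
#' comparable peak height (ROI-mean traces of bright somatic indicators show
#' relative changes near 100%), about 2 oscillations per minute per cell, and
#' trace noise of 0.5 r.u. — small because averaging over the ~10^2 pixels of
#' a soma ROI suppresses per-pixel shot noise by an order of magnitude.
#'
#' @param n_cells number of cells (ROIs).
#' @param duration recording length, seconds.
#' @param frame_rate acquisition rate, Hz.
#' @param baseline resting fluorescence, r.u. on the 0-255 scale.
#' @param amplitude transient peak height above baseline, r.u.
#' @param rise_tau,decay_tau transient kinetics, seconds. The transient is a
#'   difference of exponentials `A * (exp(-t/decay_tau) - exp(-t/rise_tau))`
#'   rescaled so its peak equals `amplitude`.
#' @param event_rate per-cell rate of independent oscillations, events/min.
#' @param sync_fraction expected fraction of cells recruited by each network
#'   event, in `[0, 1]`.
#' @param sync_jitter SD of the Gaussian onset jitter of recruited cells,
#'   seconds.
#' @param network_event_rate rate of network-wide events, events/min.
#' @param noise_sd additive Gaussian noise on each trace sample, r.u.
#' @param quantize if `TRUE`, round trace/stack values to integers and clip to
#'   the 8-bit range 0-255.
#' @param seed integer seed; drives per-cell substreams so that adding a cell
#'   leaves all other traces unchanged.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 5, duration = 60, seed = 1)
#' sim <- simulate_traces(cfg)
#' dim(sim$traces$values)
sim_config <- function(n_cells = 50, duration = 300, frame_rate = 4,
                       baseline = 60, amplitude = 60,
                       rise_tau = 0.5, decay_tau = 3,
                       event_rate = 2, sync_fraction = 0.6,
                       sync_jitter = 0.2, network_event_rate = 0.5,
                       noise_sd = 0.5, quantize = FALSE, seed = 1L) {
  cfg <- list(n_cells = n_cells, duration = duration, frame_rate = frame_rate,
              baseline = baseline, amplitude = amplitude,
              rise_tau = rise_tau, decay_tau = decay_tau,
              event_rate = event_rate, sync_fraction = sync_fraction,
              sync_jitter = sync_jitter,
              network_event_rate = network_event_rate,
              noise_sd = noise_sd, quantize = isTRUE(quantize),
              seed = as.integer(seed))
  num <- cfg[!(names(cfg) %in% c("quantize", "seed"))]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad))
    stop("non-finite or non-scalar config values: ", paste(bad, collapse = ", "))
  stopifnot(cfg$n_cells >= 1, cfg$duration > 0, cfg$frame_rate > 0,
            cfg$rise_tau > 0, cfg$decay_tau > cfg$rise_tau)
  if (cfg$amplitude < 0 || cfg$noise_sd < 0 || cfg$event_rate < 0 ||
      cfg$network_event_rate < 0 || cfg$sync_jitter < 0 || cfg$baseline < 0)
    stop("negative config values are not allowed")
  if (cfg$sync_fraction < 0 || cfg$sync_fraction > 1)
    stop("sync_fraction must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d cells, %.0f s @ %.3g Hz; baseline %.3g, amplitude %.3g r.u.\n",
    x$n_cells, x$duration, x$frame_rate, x$baseline, x$amplitude))
  cat(sprintf(
    "  events %.3g/min/cell; network %.3g/min (fraction %.3g, jitter %.3g s)\n",
    x$event_rate, x$network_event_rate, x$sync_fraction, x$sync_jitter))
  cat(sprintf("  noise sd %.3g r.u.; quantize %s; seed %d\n",
              x$noise_sd, x$quantize, x$seed))
  invisible(x)
}

# Unit-peak transient shape: exp(-t/decay) - exp(-t/rise), rescaled so the
# maximum is 1. Returns a function of time-since-onset (vectorised, 0 for t<0).
transient_kernel <- function(rise_tau, decay_tau) {
  tpk <- log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
  norm <- exp(-tpk / decay_tau) - exp(-tpk / rise_tau)
  function(t) {
    y <- exp(-t / decay_tau) - exp(-t / rise_tau)
    y[t < 0] <- 0
    y / norm
  }
}

# Half-maximum crossing times (relative to onset) of the unit-peak transient.
transient_halfmax_window <- function(rise_tau, decay_tau) {
  ker <- transient_kernel(rise_tau, decay_tau)
  tpk <- log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
  lo <- uniroot(function(t) ker(t) - 0.5, c(1e-9, tpk))$root
  hi <- uniroot(function(t) ker(t) - 0.5,
                c(tpk, tpk + 20 * decay_tau))$root
  c(lo, hi)
}

# Deterministic substream seeds: arithmetic on the base seed, kept < 2^31, so
# cell i's stream never depends on n_cells.
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 + (i + 1) * 1000003) %% 2147483647)
}

merge_intervals <- function(onset, offset) {
  if (!length(onset))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  o <- order(onset)
  onset <- onset[o]; offset <- offset[o]
  ks <- 1L
  for (j in seq_along(onset)[-1]) {
    k <- ks[length(ks)]
    if (onset[j] <= offset[k]) {
      offset[k] <- max(offset[k], offset[j])
    } else ks <- c(ks, j)
  }
  data.frame(onset_s = onset[ks], offset_s = offset[ks])
}

new_trace_set <- function(values, frame_rate) {
  stopifnot(is.matrix(values), frame_rate > 0)
  structure(list(values = values, frame_rate = frame_rate,
                 time = (seq_len(nrow(values)) - 1) / frame_rate),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d cells x %d frames @ %.3g Hz (%.1f s)\n",
              ncol(x$values), nrow(x$values), x$frame_rate,
              nrow(x$values) / x$frame_rate))
  invisible(x)
}

#' Simulate per-cell fluorescence traces with ground-truth events
#'
#' Each cell receives independent oscillations from a Poisson process at
#' `event_rate` plus network-event onsets shared across a recruited subset of
#' cells; transients superpose linearly on the baseline, Gaussian noise is
#' added, and values are optionally quantized to the 8-bit range. Ground truth
#' records, per cell, the merged intervals during which a transient exceeds
#' half of its peak, plus the network-event times and participants.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   * `traces`: a `trace_set` (matrix `frames x cells`, columns
#'     `cell_0 ...`, plus `frame_rate` and `time`),
#'   * `truth`: per-cell `data.frame(onset_s, offset_s)` of true events
#'     (overlapping transients merged),
#'   * `onsets`: per-cell numeric vector of raw transient onset times before
#'     merging,
#'   * `network_events`: `data.frame(time_s)` with a list-column `cells` of
#'     participating cell indices (1-based).
#' @export
simulate_traces <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n <- as.integer(round(cf$duration * cf$frame_rate))
  stopifnot(n >= 2)
  tgrid <- (seq_len(n) - 1) / cf$frame_rate
  ker <- transient_kernel(cf$rise_tau, cf$decay_tau)
  hm <- transient_halfmax_window(cf$rise_tau, cf$decay_tau)

  # network stream: event times only; recruitment is decided per cell below
  with_seed(substream_seed(cf$seed, -1L), {
    n_net <- rpois(1L, cf$network_event_rate / 60 * cf$duration)
    net_times <- sort(runif(n_net, 0, cf$duration))
  })

  vals <- matrix(0, n, cf$n_cells,
                 dimnames = list(NULL, paste0("cell_", seq_len(cf$n_cells) - 1)))
  truth <- onset_list <- vector("list", cf$n_cells)
  names(truth) <- names(onset_list) <- colnames(vals)
  part <- matrix(FALSE, length(net_times), cf$n_cells)

  for (i in seq_len(cf$n_cells)) {
    with_seed(substream_seed(cf$seed, i), {
      k <- rpois(1L, cf$event_rate / 60 * cf$duration)
      own <- runif(k, 0, cf$duration)
      joins <- runif(length(net_times)) < cf$sync_fraction
      jit <- rnorm(length(net_times), 0, cf$sync_jitter)
      noise <- rnorm(n, 0, cf$noise_sd)
    })
    net_on <- (net_times + jit)[joins]
    net_on <- net_on[net_on >= 0 & net_on < cf$duration]
    part[, i] <- joins
    onsets <- sort(c(own, net_on))
    sig <- rep(cf$baseline, n)
    for (on in onsets) sig <- sig + cf$amplitude * ker(tgrid - on)
    vals[, i] <- sig + noise
    onset_list[[i]] <- onsets
    truth[[i]] <- merge_intervals(pmax(onsets + hm[1], 0),
                                  pmin(onsets + hm[2], cf$duration))
  }
  if (cf$quantize) vals[] <- pmin(pmax(round(vals), 0), 255)
  net <- data.frame(time_s = net_times)
  net$cells <- lapply(seq_len(nrow(net)), function(e) which(part[e, ]))
  list(traces = new_trace_set(vals, cf$frame_rate), truth = truth,
       onsets = onset_list, network_events = net)
}

# Run code under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Simulate an image stack realising a set of traces over an ROI layout
#'
#' Pixels inside ROI `r` carry cell `r`'s trace value plus independent pixel
#' noise; background pixels carry the baseline plus pixel noise. The number of
#' nonzero ROI labels must equal `config$n_cells`.
#'
#' @param config a [sim_config()].
#' @param rois either an integer label matrix (0 = background) or a list of
#'   logical mask matrices, one per cell. Masks must be pairwise disjoint.
#' @param pixel_noise_sd per-pixel Gaussian noise, r.u.; defaults to
#'   `config$noise_sd`.
#' @return list with `stack` (array `rows x cols x frames`), and the
#'   `traces`/`truth`/`network_events` of the underlying [simulate_traces()]
#'   call.
#' @export
simulate_stack <- function(config, rois, pixel_noise_sd = config$noise_sd) {
  stopifnot(inherits(config, "sim_config"))
  lab <- as_label_matrix(rois)
  labels <- sort(unique(lab[lab > 0L]))
  if (length(labels) != config$n_cells)
    stop("ROI layout has ", length(labels), " labels but config$n_cells = ",
         config$n_cells)
  sim <- simulate_traces(config)
  n <- nrow(sim$traces$values)
  h <- nrow(lab); w <- ncol(lab)
  stack <- array(config$baseline, c(h, w, n))
  flat <- matrix(stack, h * w, n)
  for (j in seq_along(labels)) {
    idx <- which(lab == labels[j])
    flat[idx, ] <- matrix(sim$traces$values[, j], length(idx), n, byrow = TRUE)
  }
  with_seed(substream_seed(config$seed, -2L), {
    if (pixel_noise_sd > 0)
      flat <- flat + matrix(rnorm(length(flat), 0, pixel_noise_sd), nrow(flat))
  })
  if (config$quantize) flat[] <- pmin(pmax(round(flat), 0), 255)
  list(stack = array(flat, c(h, w, n)), traces = sim$traces,
       truth = sim$truth, network_events = sim$network_events)
}

# Accept a label matrix or a list of logical masks; reject overlapping masks.
as_label_matrix <- function(rois) {
  if (is.matrix(rois) && !is.list(rois)) {
    if (any(rois < 0) || any(rois != round(rois)))
      stop("ROI labels must be non-negative integers")
    return(matrix(as.integer(rois), nrow(rois)))
  }
  if (is.list(rois)) {
    stopifnot(length(rois) >= 1)
    dims <- dim(rois[[1]])
    lab <- matrix(0L, dims[1], dims[2])
    for (j in seq_along(rois)) {
      m <- rois[[j]]
      stopifnot(is.logical(m) || all(m %in% c(0, 1)))
      if (any(lab[m > 0] != 0L)) stop("overlapping ROI labels")
      lab[m > 0] <- j
    }
    return(lab)
  }
  stop("rois must be a label matrix or a list of masks")
}

#' Simulate a respirometry state table
#'
#' Draws Gaussian replicates around per-group means for the three measured
#' oxygen-consumption states, truncated at zero.
#'
#' @param group_means `data.frame` with columns `group`, `V4_gm`, `V3`,
#'   `V4_succ` (rates in pmol/s per mg protein).
#' @param sd Gaussian SD applied to every state (scalar).
#' @param n replicates per group.
#' @param seed integer seed.
#' @return long replicate table: `group`, `replicate`, `V4_gm`, `V3`,
#'   `V4_succ`.
#' @export
simulate_respirometry <- function(group_means, sd = 0, n = 3, seed = 1L) {
  stopifnot(is.data.frame(group_means),
            all(c("group", "V4_gm", "V3", "V4_succ") %in% names(group_means)))
  if (!is.numeric(n) || n < 1) stop("n must be a positive integer")
  n <- as.integer(n)
  states <- c("V4_gm", "V3", "V4_succ")
  if (any(as.matrix(group_means[states]) <= 0))
    stop("all group means must be positive")
  if (sd < 0) stop("sd must be non-negative")
  out <- do.call(rbind, lapply(seq_len(nrow(group_means)), function(g) {
    data.frame(group = group_means$group[g], replicate = seq_len(n),
               V4_gm = NA_real_, V3 = NA_real_, V4_succ = NA_real_)
  }))
  with_seed(seed, {
    for (s in states) {
      mu <- rep(group_means[[s]], each = n)
      x <- rnorm(length(mu), mu, sd)
      while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mu[x <= 0], sd)
      out[[s]] <- x
    }
  })
  out
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Target-gene Ct values are `base_ct - log2(fold) + noise`; the reference
#' gene sits at `base_ct + noise`. Running [delta_ct()] and [fold_change()]
#' on the output recovers `fold` up to noise.
#'
#' @param true_folds `data.frame` with columns `group`, `gene`, `fold`
#'   (fold > 0; the calibrator group should carry fold 1).
#' @param base_ct nominal Ct of an unregulated well, cycles.
#' @param reference_gene name of the housekeeping gene added to every sample.
#' @param noise_sd Gaussian Ct noise, cycles.
#' @param n biological samples per group.
#' @param seed integer seed.
#' @return long Ct table: `sample`, `group`, `gene`, `Ct`.
#' @export
simulate_ct_table <- function(true_folds, base_ct = 25,
                              reference_gene = "Oaz1",
                              noise_sd = 0.2, n = 6, seed = 1L) {
  stopifnot(is.data.frame(true_folds),
            all(c("group", "gene", "fold") %in% names(true_folds)))
  if (any(true_folds$fold <= 0)) stop("fold values must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  groups <- unique(true_folds$group)
  rows <- list()
  with_seed(seed, {
    for (g in groups) {
      sub <- true_folds[true_folds$group == g, ]
      for (r in seq_len(n)) {
        id <- paste0(g, "_s", r)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = id, group = g, gene = reference_gene,
          Ct = base_ct + rnorm(1, 0, noise_sd))
        for (j in seq_len(nrow(sub))) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = id, group = g, gene = sub$gene[j],
            Ct = base_ct - log2(sub$fold[j]) + rnorm(1, 0, noise_sd))
        }
      }
    }
  })
  do.call(rbind, rows)
}
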