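# Derivative-threshold detection of calcium oscillations.
#
# Pipeline per trace F (N frames): pairwise smoothing S[i] = (F[i]+F[i+1])/2,
# first difference D[i] = S[i+1]-S[i], threshold theta = k * SD(D). Runs of
# D > +theta open an oscillation (fluorescence rising), the first subsequent
# run of D < -theta closes it at the run's last sample (decay tail included).

#' Detection parameters
#'
#' @param accuracy_coefficient `k`, the dimensionless factor multiplying the
#'   SD of the trace derivative to form the detection threshold. The
#'   empirically established value for somatic indicator traces is 0.45.
#' @param smoothing_window number of neighbouring samples averaged before
#'   differencing; 2 = pairwise averaging.
#' @param min_event_samples discard events spanning fewer raw frames than
#'   this (default 1, i.e. keep all).
#' @param sd_mode `"population"` (divide by N) or `"sample"` (divide by N-1)
#'   for the derivative SD.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(accuracy_coefficient = 0.45,
                             smoothing_window = 2L,
                             min_event_samples = 1L,
                             sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(accuracy_coefficient > 0, smoothing_window >= 1,
            min_event_samples >= 1)
  structure(list(accuracy_coefficient = accuracy_coefficient,
                 smoothing_window = as.integer(smoothing_window),
                 min_event_samples = as.integer(min_event_samples),
                 sd_mode = sd_mode),
            class = "detection_params")
}

#' Pairwise-average smoothing of a trace
#'
#' `S[i] = mean(F[i], ..., F[i + w - 1])`; with the default window of 2 this
#' is the average of neighbouring points, giving a series of length `N - 1`.
#'
#' @param x numeric trace.
#' @param window moving-average width in samples.
#' @return numeric vector of length `length(x) - window + 1`.
#' @export
smooth_trace <- function(x, window = 2L) {
  n <- length(x)
  if (n < 2 || n < window) stop("trace must have at least `window` (>= 2) samples")
  if (window == 1L) return(as.numeric(x))
  cs <- c(0, cumsum(as.numeric(x)))
  (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
}

#' First-difference derivative of a smoothed series
#'
#' @param s numeric series (typically the output of [smooth_trace()]).
#' @return `diff(s)`, one sample shorter.
#' @export
trace_derivative <- function(s) {
  if (length(s) < 2) stop("need at least 2 samples to differentiate")
  diff(as.numeric(s))
}

#' Detection threshold from the derivative SD
#'
#' `theta = k * SD(D)` where the SD is taken over the whole derivative
#' series, event epochs included.
#'
#' @param d derivative series.
#' @param params a [detection_params()].
#' @return scalar threshold (r.u. per frame).
#' @export
detection_threshold <- function(d, params = detection_params()) {
  if (!length(d)) stop("empty derivative series")
  s <- if (params$sd_mode == "population") {
    sqrt(mean((d - mean(d))^2))
  } else sd(d)
  params$accuracy_coefficient * s
}

#' Detect calcium oscillations on a single fluorescence trace
#'
#' An event opens at the first sample of a maximal run where the smoothed
#' derivative exceeds `+theta` and closes at the last sample of the first
#' subsequent maximal run below `-theta`; positive runs occurring while an
#' event is open extend it, and an event still open at the end of the trace
#' closes at the final frame. A flat trace (`theta == 0`) yields no events.
#' Derivative indices are mapped to raw frames at the centre of the
#' smoothing/differencing stencil; frame `f` (1-based) occurs at time
#' `(f - 1) / frame_rate` seconds.
#'
#' @param x numeric fluorescence trace (>= 4 samples).
#' @param frame_rate sampling rate, Hz.
#' @param params a [detection_params()].
#' @return `data.frame` with columns `onset_frame`, `offset_frame` (1-based),
#'   `onset_s`, `offset_s`, `duration_s`, sorted by onset.
#' @export
#' @examples
#' x <- c(rep(100, 8), 140, 180, 180, 180, 140, 100, 100, 100)
#' detect_events(x, frame_rate = 4)
detect_events <- function(x, frame_rate = 4, params = detection_params()) {
  x <- as.numeric(x)
  if (length(x) < 4) stop("trace must have at least 4 samples")
  if (any(!is.finite(x))) stop("trace values must be finite")
  w <- params$smoothing_window
  s <- smooth_trace(x, w)
  d <- trace_derivative(s)
  theta <- detection_threshold(d, params)
  empty <- data.frame(onset_frame = integer(0), offset_frame = integer(0),
                      onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0))
  if (theta <= 0) return(empty)

  cat_ <- integer(length(d))           # +1 above +theta, -1 below -theta
  cat_[d > theta] <- 1L
  cat_[d < -theta] <- -1L
  r <- rle(cat_)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  onsets <- integer(0); offsets <- integer(0)
  open_at <- NA_integer_
  for (j in seq_along(r$values)) {
    v <- r$values[j]
    if (v == 1L && is.na(open_at)) {
      open_at <- starts[j]
    } else if (v == -1L && !is.na(open_at)) {
      onsets <- c(onsets, open_at)
      offsets <- c(offsets, ends[j])
      open_at <- NA_integer_
    }
  }
  n <- length(x)
  centre <- w %/% 2L                   # D[i] sits at raw frame i + centre
  if (!is.na(open_at)) {               # trailing event closes at trace end
    onsets <- c(onsets, open_at)
    offsets <- c(offsets, n - centre)  # maps to raw frame n below
  }
  if (!length(onsets)) return(empty)
  onset_frame <- onsets + centre
  offset_frame <- pmin(offsets + centre, n)
  keep <- (offset_frame - onset_frame + 1L) >= params$min_event_samples
  onset_frame <- onset_frame[keep]; offset_frame <- offset_frame[keep]
  data.frame(onset_frame = onset_frame, offset_frame = offset_frame,
             onset_s = (onset_frame - 1) / frame_rate,
             offset_s = (offset_frame - 1) / frame_rate,
             duration_s = (offset_frame - onset_frame) / frame_rate)
}

#' Detect oscillations on every trace of a recording
#'
#' @param traces a `trace_set` (see [simulate_traces()], [extract_traces()])
#'   or a numeric matrix `frames x cells`.
#' @param frame_rate sampling rate, Hz; taken from the `trace_set` if absent.
#' @param params a [detection_params()].
#' @return `data.frame` of events with a leading `cell_id` column (the trace
#'   column name, or `cell_<j>` for bare matrices).
#' @export
detect_all <- function(traces, frame_rate = NULL, params = detection_params()) {
  if (inherits(traces, "trace_set")) {
    vals <- traces$values
    if (is.null(frame_rate)) frame_rate <- traces$frame_rate
  } else {
    vals <- as.matrix(traces)
    if (is.null(frame_rate)) stop("frame_rate required for bare matrices")
  }
  ids <- colnames(vals)
  if (is.null(ids)) ids <- paste0("cell_", seq_len(ncol(vals)) - 1)
  out <- lapply(seq_len(ncol(vals)), function(j) {
    ev <- detect_events(vals[, j], frame_rate, params)
    if (nrow(ev)) cbind(cell_id = ids[j], ev)
    else cbind(data.frame(cell_id = character(0)), ev)
  })
  do.call(rbind, out)
}
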