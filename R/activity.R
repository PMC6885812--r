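# Culture-level activity parameters, raster diagrams and network synchrony.

#' Summarise detected events into the three activity parameters
#'
#' * `pct_working`: percentage of cells with at least one oscillation;
#' * `freq_osc_per_min`: oscillations per minute, averaged by default over
#'   working cells only (cells without events would otherwise drag the mean
#'   of an "oscillation frequency" towards zero; a flag switches to an
#'   all-cell denominator);
#' * `mean_duration_s`: mean onset-to-offset duration over all events.
#'
#' With no active cell, frequency and duration are `NA` and `flagged` is set.
#'
#' @param events event table from [detect_all()] (needs `cell_id`,
#'   `duration_s`).
#' @param n_cells total number of cells examined.
#' @param length_s recording length, seconds.
#' @param denominator `"working"` or `"all"` for the frequency average.
#' @return one-row `data.frame(n_cells, pct_working, freq_osc_per_min,
#'   mean_duration_s, flagged)`.
#' @export
summarize_activity <- function(events, n_cells, length_s,
                               denominator = c("working", "all")) {
  denominator <- match.arg(denominator)
  if (!is.numeric(n_cells) || n_cells < 1) stop("n_cells must be >= 1")
  stopifnot(length_s > 0)
  counts <- if (nrow(events)) table(events$cell_id) else table(character(0))
  n_working <- length(counts)
  if (n_working > n_cells) stop("more working cells than n_cells")
  mins <- length_s / 60
  if (n_working == 0) {
    return(data.frame(n_cells = n_cells, pct_working = 0,
                      freq_osc_per_min = NA_real_,
                      mean_duration_s = NA_real_, flagged = TRUE))
  }
  per_cell <- as.numeric(counts) / mins
  freq <- if (denominator == "working") mean(per_cell)
          else sum(per_cell) / n_cells
  data.frame(n_cells = n_cells,
             pct_working = 100 * n_working / n_cells,
             freq_osc_per_min = freq,
             mean_duration_s = mean(events$duration_s),
             flagged = FALSE)
}

#' Build a raster of oscillation onsets
#'
#' @param events event table with `cell_id` and `onset_s`.
#' @param length_s recording length, seconds.
#' @return `data.frame(cell_id, onset_s)` ordered by cell then onset, of
#'   class `raster_data` with the recording length as attribute.
#' @export
build_raster <- function(events, length_s) {
  stopifnot(length_s > 0)
  r <- if (nrow(events)) {
    stopifnot(all(events$onset_s >= 0), all(events$onset_s <= length_s))
    events[order(events$cell_id, events$onset_s), c("cell_id", "onset_s")]
  } else data.frame(cell_id = character(0), onset_s = numeric(0))
  rownames(r) <- NULL
  structure(r, length_s = length_s, class = c("raster_data", "data.frame"))
}

#' Plot a raster diagram
#'
#' One row per cell, a stroke at each oscillation onset.
#'
#' @param x a `raster_data` from [build_raster()].
#' @param ... passed to [graphics::segments()].
#' @export
plot.raster_data <- function(x, ...) {
  cells <- unique(x$cell_id)
  plot.new()
  plot.window(xlim = c(0, attr(x, "length_s")),
              ylim = c(0, max(length(cells), 1) + 1))
  if (nrow(x)) {
    y <- match(x$cell_id, cells)
    segments(x$onset_s, y - 0.4, x$onset_s, y + 0.4, ...)
  }
  axis(1); axis(2, at = seq_along(cells), labels = cells, las = 1)
  title(xlab = "time (s)", ylab = "cell")
  box()
  invisible(x)
}

#' Call network-synchronous events from an event table
#'
#' The time axis is cut into consecutive bins; a bin qualifies when the
#' fraction of *working* cells with at least one onset inside it reaches the
#' participation threshold, and adjacent qualifying bins are merged. This is
#' an operational definition chosen for this package (binning at the scale of
#' the onset jitter); it is not a published procedure.
#'
#' @param events event table with `cell_id` and `onset_s`.
#' @param length_s recording length, seconds.
#' @param bin_width bin width, seconds.
#' @param threshold minimum participating fraction of working cells, in
#'   `(0, 1]`.
#' @return `data.frame(start_s, end_s, n_cells, participation)`, one row per
#'   merged synchronous event; `participation` is the largest per-bin
#'   fraction inside the merged window.
#' @export
find_sync_events <- function(events, length_s, bin_width = 1, threshold = 0.3) {
  stopifnot(bin_width > 0, threshold > 0, threshold <= 1, length_s > 0)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_cells = integer(0), participation = numeric(0))
  if (!nrow(events)) return(empty)
  working <- unique(events$cell_id)
  nw <- length(working)
  nbins <- ceiling(length_s / bin_width)
  bin <- pmin(floor(events$onset_s / bin_width) + 1L, nbins)
  # fraction of working cells represented in each bin
  per_bin <- vapply(seq_len(nbins), function(b)
    length(unique(events$cell_id[bin == b])), integer(1))
  frac <- per_bin / nw
  qual <- frac >= threshold
  if (!any(qual)) return(empty)
  r <- rle(qual)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start_s = (starts[keep] - 1) * bin_width,
    end_s = pmin(ends[keep] * bin_width, length_s),
    n_cells = vapply(keep, function(j)
      length(unique(events$cell_id[bin >= starts[j] & bin <= ends[j]])),
      integer(1)),
    participation = vapply(keep, function(j)
      max(frac[starts[j]:ends[j]]), numeric(1)))
}
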