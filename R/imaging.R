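# ROI-mean trace extraction from image stacks and two-channel nucleus
# counting for the viability assay. Stacks are plain numeric arrays
# (rows x cols x frames); ROI maps are integer label matrices (0 = background).

#' Extract per-cell mean-fluorescence traces from an image stack
#'
#' The trace value of cell `r` at frame `t` is the arithmetic mean of the
#' stack over the pixels labelled `r` in the ROI map.
#'
#' @param stack numeric array `rows x cols x frames`.
#' @param rois integer label matrix (or list of masks, see
#'   [simulate_stack()]) matching the stack's spatial dimensions.
#' @param frame_rate sampling rate, Hz.
#' @param labels which labels to extract; defaults to every nonzero label.
#'   Requesting a label with no pixels is an error naming the label.
#' @return a `trace_set`; column `j` is labelled `cell_<label_j>`.
#' @export
extract_traces <- function(stack, rois, frame_rate = 4, labels = NULL) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  lab <- as_label_matrix(rois)
  if (!identical(dim(stack)[1:2], dim(lab)))
    stop("stack frames (", paste(dim(stack)[1:2], collapse = "x"),
         ") do not match the ROI map (", paste(dim(lab), collapse = "x"), ")")
  present <- sort(unique(lab[lab > 0L]))
  if (is.null(labels)) labels <- present
  missing_ <- setdiff(labels, present)
  if (length(missing_))
    stop("ROI label(s) with zero pixels: ", paste(missing_, collapse = ", "))
  nfr <- dim(stack)[3]
  flat <- matrix(stack, prod(dim(stack)[1:2]), nfr)
  vals <- vapply(labels, function(l) {
    idx <- which(lab == l)
    if (length(idx) == 1L) flat[idx, ] else colMeans(flat[idx, , drop = FALSE])
  }, numeric(nfr))
  colnames(vals) <- paste0("cell_", labels)
  new_trace_set(vals, frame_rate)
}

#' Otsu's threshold
#'
#' Maximises between-class variance on a 256-bin histogram of the image's
#' intensity range.
#'
#' @param img numeric matrix.
#' @return scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(img) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  # empty bins between classes give a plateau of maxima; split in its middle
  best <- round(mean(which(between == max(between))))
  breaks[best + 1]   # upper edge of the best split bin
}

#' Label connected components of a binary mask
#'
#' Flood-fill labelling with 8-connectivity (default) or 4-connectivity.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 8 or 4.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in scan order.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- matrix(as.logical(mask), nrow(mask))
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  nextlab <- 0L
  for (start in which(m & lab == 0L)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      px <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r0 <- ((px - 1L) %% h) + 1L
      c0 <- ((px - 1L) %/% h) + 1L
      rr <- r0 + dr; cc <- c0 + dc
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      nb <- (cc[ok] - 1L) * h + rr[ok]
      nb <- nb[m[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- nextlab
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

count_objects <- function(img, threshold, min_object_area, connectivity = 8) {
  lab <- label_components(img > threshold, connectivity)
  if (!max(lab)) return(0L)
  sizes <- tabulate(lab[lab > 0L], max(lab))
  sum(sizes >= min_object_area)
}

#' Two-channel nucleus-counting viability ratio
#'
#' Counts above-threshold connected components (8-connectivity, area filter)
#' in a dead-cell stain channel and a total-nuclei stain channel and reports
#' the dead fraction `100 * n_dead / n_total`.
#'
#' @param dead_channel,total_channel numeric matrices of identical shape.
#' @param intensity_threshold per-channel scalar threshold(s); `NULL` (the
#'   default) uses [otsu_threshold()] independently per channel. A length-2
#'   vector gives (dead, total) thresholds.
#' @param min_object_area smallest pixel count accepted as a nucleus.
#' @return one-row `data.frame(n_dead, n_total, dead_fraction)`. When no
#'   nuclei are found in the total channel the fraction is `NA` with a
#'   warning, not 0; a raw dead count exceeding the total count is capped
#'   with a warning.
#' @export
count_viability <- function(dead_channel, total_channel,
                            intensity_threshold = NULL,
                            min_object_area = 10) {
  stopifnot(is.matrix(dead_channel), is.matrix(total_channel))
  if (!identical(dim(dead_channel), dim(total_channel)))
    stop("channel images must share dimensions")
  thr <- if (is.null(intensity_threshold)) {
    c(otsu_threshold(dead_channel), otsu_threshold(total_channel))
  } else rep_len(intensity_threshold, 2)
  n_dead <- count_objects(dead_channel, thr[1], min_object_area)
  n_total <- count_objects(total_channel, thr[2], min_object_area)
  if (n_total == 0) {
    warning("no nuclei detected in the total channel; dead_fraction undefined")
    return(data.frame(n_dead = 0L, n_total = 0L, dead_fraction = NA_real_))
  }
  if (n_dead > n_total) {
    warning("dead-channel count (", n_dead, ") exceeds total-channel count (",
            n_total, "); capping")
    n_dead <- n_total
  }
  frac <- 100 * n_dead / n_total
  data.frame(n_dead = n_dead, n_total = n_total, dead_fraction = frac)
}

#' Convenience ROI segmentation from a stack
#'
#' Otsu threshold on the temporal-mean image, connected components, area
#' filter. Intended as a starting point only; analyses asserting published
#' behaviour should use curated label maps.
#'
#' @param stack numeric array `rows x cols x frames`.
#' @param min_area smallest component kept, pixels.
#' @return integer label matrix.
#' @export
segment_rois <- function(stack, min_area = 20) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  avg <- apply(stack, c(1, 2), mean)
  lab <- label_components(avg > otsu_threshold(avg), 8)
  if (max(lab)) {
    sizes <- tabulate(lab[lab > 0L], max(lab))
    drop <- which(sizes < min_area)
    lab[lab %in% drop] <- 0L
    old <- sort(unique(lab[lab > 0L]))
    lab[] <- match(lab, old, nomatch = 0L)
  }
  lab
}
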