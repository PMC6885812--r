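# Mitochondrial respirometry summaries: state rates, respiratory control
# index, and the derived percent-change reporting.

#' Respiratory control index
#'
#' `RCI = V3 / V4`: ADP-stimulated (phosphorylating) over basal respiration,
#' a measure of coupling between oxidation and phosphorylation. The V4 rate
#' in the denominator is the glutamate/malate state measured before ADP
#' addition.
#'
#' @param v3 ADP-stimulated rate (state V3), pmol/s per mg protein.
#' @param v4 basal rate (state V4, glutamate + malate), same units.
#' @return `v3 / v4` (vectorised).
#' @export
#' @examples
#' respiratory_control_index(10, 5)   # 2: coupled
#' respiratory_control_index(5, 5)    # 1: coupling lost
respiratory_control_index <- function(v3, v4) {
  if (any(v4 <= 0)) stop("V4 must be positive")
  v3 / v4
}

#' Percent change relative to a reference rate
#'
#' `100 * (reference - treated) / reference`; positive for a reduction.
#'
#' @param reference reference-group rate (> 0).
#' @param treated treated-group rate.
#' @return percent (vectorised).
#' @export
#' @examples
#' percent_change(88.8, 50.2)   # 43.5% reduction
percent_change <- function(reference, treated) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (reference - treated) / reference
}

#' Per-group summary of respirometry states and RCI
#'
#' The RCI is computed per replicate (`V3 / V4_gm`) before averaging, so the
#' group RCI carries its own SEM.
#'
#' @param table replicate table with columns `group`, `V4_gm`, `V3`,
#'   `V4_succ` (see [simulate_respirometry()]).
#' @return long `data.frame(group, measure, mean, sem, n)`; `sem` is `NA`
#'   for single-replicate groups.
#' @export
group_respiration_summary <- function(table) {
  states <- c("V4_gm", "V3", "V4_succ")
  stopifnot(is.data.frame(table), all(c("group", states) %in% names(table)))
  if (!nrow(table)) stop("empty respirometry table")
  if (any(as.matrix(table[states]) <= 0))
    stop("respiration rates must be positive")
  tab <- table
  tab$RCI <- respiratory_control_index(tab$V3, tab$V4_gm)
  out <- do.call(rbind, lapply(split(tab, tab$group), function(g) {
    if (!nrow(g)) stop("empty group: ", g$group[1])
    do.call(rbind, lapply(c(states, "RCI"), function(m) {
      x <- g[[m]]
      data.frame(group = g$group[1], measure = m, mean = mean(x),
                 sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_,
                 n = length(x))
    }))
  }))
  rownames(out) <- NULL
  out
}
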