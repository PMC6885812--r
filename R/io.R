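# Plain-text interchange: traces CSV (time + one column per cell), events
# CSV, ground-truth JSON, and the bundled table of published group values.

#' Write / read a trace CSV
#'
#' One row per frame; first column `time_s`, remaining columns one per cell
#' (`cell_0`, `cell_1`, ...).
#'
#' @param traces a `trace_set`.
#' @param path output file.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  df <- data.frame(time_s = traces$time, traces$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param frame_rate override the rate inferred from the time column.
#' @return `read_traces_csv`: a `trace_set`.
#' @export
read_traces_csv <- function(path, frame_rate = NULL) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(names(df)[1] == "time_s", nrow(df) >= 2)
  if (is.null(frame_rate))
    frame_rate <- 1 / stats::median(diff(df$time_s))
  new_trace_set(as.matrix(df[-1]), frame_rate)
}

#' Write / read ground-truth events as JSON
#'
#' @param truth per-cell list of `data.frame(onset_s, offset_s)` as produced
#'   by [simulate_traces()].
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x)
    data.frame(onset_s = as.numeric(x$onset_s),
               offset_s = as.numeric(x$offset_s)))
}

#' Published group-level values bundled with the package
#'
#' Printed mean/SEM tables from the source study (dead-cell percentages,
#' mature-synapse densities, mitochondrial V4 glutamate/malate rates,
#' respiratory control indices, and the three spontaneous-activity
#' parameters) for the groups Sham, Hypoxia and Hypoxia+GDNF. These are
#' *inputs* for derived-ratio reporting, not values the package computes.
#'
#' @return `data.frame(measure, group, mean, sem, n)` (`n` is `NA` where the
#'   replicate count was not printed).
#' @export
published_group_values <- function() {
  path <- system.file("extdata", "published_group_values.csv",
                      package = "calosc", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
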