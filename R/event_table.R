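#' Event-level flow cytometry data for one well or one acquisition stream
#'
#' An `event_table` holds a numeric matrix of per-event channel measurements
#' (scatter and fluorescence, arbitrary instrument units), an optional
#' per-event timestamp in seconds, a source identifier, and an optional
#' ground-truth label table (attached by the simulator, never by readers).
#'
#' @param exprs numeric matrix, one row per event, columns named by channel
#'   (e.g. `"FSC-A"`, `"SSC-A"`, `"VL1-A"`).
#' @param time optional numeric vector of per-event timestamps in seconds;
#'   must be non-decreasing.
#' @param source character scalar identifying the file / stream / simulation.
#' @param labels optional `data.frame` of per-event ground-truth labels with
#'   `nrow(labels) == nrow(exprs)`.
#' @return an object of class `event_table`.
#' @export
event_table <- function(exprs, time = NULL, source = "", labels = NULL) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stopf("`exprs` must be a numeric matrix")
  if (is.null(colnames(exprs)) || anyDuplicated(colnames(exprs)))
    stopf("`exprs` must have unique column (channel) names")
  if (!is.null(time)) {
    if (length(time) != nrow(exprs))
      stopf("`time` length (%d) != number of events (%d)",
            length(time), nrow(exprs))
    if (length(time) > 1L && any(diff(time) < 0))
      stopf("`time` must be non-decreasing")
  }
  if (!is.null(labels)) {
    if (!is.data.frame(labels) || nrow(labels) != nrow(exprs))
      stopf("`labels` must be a data.frame with one row per event")
  }
  structure(
    list(exprs = exprs, time = time, source = as.character(source)[1L],
         labels = labels),
    class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events x %d channels\n",
              nrow(x$exprs), ncol(x$exprs)))
  cat("  channels:", paste(colnames(x$exprs), collapse = ", "), "\n")
  if (!is.null(x$time))
    cat(sprintf("  time: %.3f .. %.3f s\n", min(x$time), max(x$time)))
  if (!is.null(x$labels))
    cat("  labels:", paste(names(x$labels), collapse = ", "), "\n")
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' @rdname event_table
#' @param x an `event_table`.
#' @export
n_events <- function(x) nrow(x$exprs)

#' @rdname event_table
#' @export
channels <- function(x) colnames(x$exprs)

#' Subset an event table by a logical or integer event index
#'
#' Labels and timestamps are carried along.
#'
#' @param x an `event_table`.
#' @param i logical mask or integer indices of events to keep.
#' @return an `event_table` with the selected events.
#' @export
subset_events <- function(x, i) {
  event_table(x$exprs[i, , drop = FALSE],
              time = if (!is.null(x$time)) x$time[i],
              source = x$source,
              labels = if (!is.null(x$labels)) x$labels[i, , drop = FALSE])
}

#' Concatenate event tables sharing the same channels
#'
#' @param tables list of `event_table`s with identical channel sets.
#' @param source source label for the result.
#' @return a single `event_table`; label tables are row-bound when present in
#'   every input, dropped otherwise; time is kept only if present in every
#'   input and globally non-decreasing after concatenation.
#' @export
bind_events <- function(tables, source = "") {
  stopifnot(length(tables) >= 1L)
  chans <- channels(tables[[1L]])
  for (t in tables)
    if (!identical(channels(t), chans))
      stopf("all event tables must share identical channel sets")
  exprs <- do.call(rbind, lapply(tables, `[[`, "exprs"))
  have_time <- all(vapply(tables, function(t) !is.null(t$time), logical(1)))
  time <- if (have_time) unlist(lapply(tables, `[[`, "time"), use.names = FALSE)
  have_lab <- all(vapply(tables, function(t) !is.null(t$labels), logical(1)))
  labels <- if (have_lab) do.call(rbind, lapply(tables, `[[`, "labels"))
  event_table(exprs, time = time, source = source, labels = labels)
}

channel_values <- function(x, channel) {
  if (!channel %in% colnames(x$exprs))
    stopf("channel '%s' not present (have: %s)", channel,
          paste(colnames(x$exprs), collapse = ", "))
  x$exprs[, channel]
}
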