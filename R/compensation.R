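#' Spillover matrix
#'
#' Square matrix of spill fractions between fluorescence detectors. Row
#' `i`, column `j` gives the fraction of channel `i`'s true signal that
#' appears in detector `j`; the diagonal is 1.
#'
#' @param mat square numeric matrix with identical row/column channel names.
#' @return object of class `spillover_matrix` (a named matrix).
#' @export
spillover_matrix <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stopf("spillover matrix must be square")
  if (is.null(colnames(mat)) || !identical(rownames(mat), colnames(mat)))
    stopf("spillover matrix needs identical row and column channel names")
  if (any(abs(diag(mat) - 1) > 1e-12))
    stopf("spillover matrix diagonal must be 1")
  det_ok <- tryCatch(abs(det(mat)) > .Machine$double.eps, error = function(e) FALSE)
  if (!det_ok) stopf("spillover matrix is singular")
  structure(mat, class = c("spillover_matrix", "matrix"))
}

#' Read / write a spillover matrix as CSV
#'
#' The CSV has a header row of channel names and the channel names again in
#' the first column.
#'
#' @param path CSV path.
#' @return a [spillover_matrix()].
#' @export
read_spillover <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  rownames(m) <- rownames(df)
  spillover_matrix(m)
}

#' @rdname read_spillover
#' @param spill a [spillover_matrix()].
#' @export
write_spillover <- function(spill, path) {
  df <- data.frame(channel = rownames(spill), as.data.frame(unclass(spill),
                   check.names = FALSE), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Apply (or simulate) fluorescence spillover compensation
#'
#' `apply_compensation` replaces the fluorescence columns named in the spill
#' matrix by `observed %*% solve(spill)`; scatter and time channels are left
#' untouched. `mix_spillover` is the forward operation (`truth %*% spill`),
#' used by the simulator to create uncompensated data.
#'
#' Compensated values can be negative; they are deliberately not clipped.
#'
#' @param table an [event_table()].
#' @param spill a [spillover_matrix()] whose channels are a subset of the
#'   table's channels.
#' @return an [event_table()] with the spill channels replaced.
#' @export
apply_compensation <- function(table, spill) {
  comp_channels(table, spill, inverse = TRUE)
}

#' @rdname apply_compensation
#' @export
mix_spillover <- function(table, spill) {
  comp_channels(table, spill, inverse = FALSE)
}

comp_channels <- function(table, spill, inverse) {
  stopifnot(inherits(table, "event_table"))
  if (!inherits(spill, "spillover_matrix")) spill <- spillover_matrix(spill)
  ch <- colnames(spill)
  missing <- setdiff(ch, colnames(table$exprs))
  if (length(missing))
    stopf("spillover channel(s) absent from event table: %s",
          paste(missing, collapse = ", "))
  m <- unclass(spill)
  op <- if (inverse) solve(m) else m
  exprs <- table$exprs
  exprs[, ch] <- exprs[, ch, drop = FALSE] %*% op
  event_table(exprs, time = table$time, source = table$source,
              labels = table$labels)
}
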