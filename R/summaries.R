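#' Per-well derived statistics used by QC and triage
#'
#' Runs the gate tree on one well and extracts the screen's summary
#' statistics: FoxP3% of CD4+, the lymphocyte FSC-H median (toxicity
#' readout) and the V450 medians of the FoxP3+ and FoxP3- populations
#' (autofluorescence readout).
#'
#' @param table an [event_table()] for one well.
#' @param tree a [gate_tree()].
#' @param min_events floor below which the CD4+ population is flagged
#'   insufficient (default 100).
#' @return one-row data.frame.
#' @export
summarize_well <- function(table, tree, min_events = 100) {
  g <- run_gating_tree(table, tree, min_events = min_events)
  st <- g$stats
  pick <- function(pop) st[st$population == pop, , drop = FALSE]
  lym <- pick("lymphocytes"); sng <- pick("singlets"); cd4 <- pick("cd4_pos")
  fp <- pick("foxp3_pos"); fn <- pick("foxp3_neg")
  v450 <- paste0("median_", tree$foxp3_channel)
  data.frame(
    n_events = n_events(table),
    n_lymph = lym$count, n_singlets = sng$count, n_cd4 = cd4$count,
    n_foxp3_pos = fp$count, n_foxp3_neg = fn$count,
    foxp3_pct_cd4 = 100 * fp$fraction_of_parent,
    cd4_pct_singlets = 100 * cd4$fraction_of_parent,
    fsch_mfi = lym[["median_FSC-H"]],
    v450_mfi_pos = fp[[v450]], v450_mfi_neg = fn[[v450]],
    insufficient = cd4$insufficient,
    stringsAsFactors = FALSE)
}

#' Summarize every well of a plate
#'
#' @param wells named list of per-well [event_table()]s.
#' @param layout the `plate_layout` (rows matched to `names(wells)`).
#' @param tree a [gate_tree()], e.g. from [fit_plate_gates()].
#' @param min_events insufficient-events floor, see [summarize_well()].
#' @return a `well_summary` data.frame: layout columns plus the
#'   [summarize_well()] statistics, one row per well.
#' @export
summarize_plate <- function(wells, layout, tree, min_events = 100) {
  layout <- validate_plate_layout(as.data.frame(layout))
  miss <- setdiff(layout$well, names(wells))
  if (length(miss))
    stopf("no event data for layout well(s): %s",
          paste(utils::head(miss, 5L), collapse = ", "))
  rows <- lapply(layout$well, function(w)
    summarize_well(wells[[w]], tree, min_events = min_events))
  out <- cbind(as.data.frame(layout), do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("well_summary", "data.frame")
  out
}

#' Write per-well summaries as CSV
#'
#' @param summaries a `well_summary` data.frame.
#' @param path CSV path.
#' @export
write_well_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}
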