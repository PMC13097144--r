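# Segmentation of a continuous (plate-sampler) acquisition stream into
# wells, using the low-event-rate gaps left by up-time, shakes and rinses.

#' Segment a continuous acquisition stream into wells
#'
#' Event times are binned (`bin_width` seconds); bins whose event count
#' falls below `rate_frac` times the median count of non-empty bins are
#' inactive. Maximal runs of inactive bins lasting at least `min_gap`
#' seconds are gaps; the bursts between gaps are candidate wells, mapped
#' 1:1 onto the layout wells in acquisition order. Events inside gaps are
#' discarded (inter-well background). If the number of bursts differs from
#' the number of layout wells the function stops with diagnostics rather
#' than guessing.
#'
#' @param stream an [event_table()] with a `time` field.
#' @param layout a `plate_layout` giving the expected wells in acquisition
#'   order.
#' @param bin_width histogram bin width in seconds.
#' @param rate_frac inactive-bin threshold as a fraction of the median
#'   non-empty bin count.
#' @param min_gap minimum gap duration in seconds.
#' @param min_burst minimum burst duration in seconds; shorter bursts are
#'   treated as inter-well noise and discarded (sips last many seconds, so
#'   the default 2 s only removes stray background clusters).
#' @return a `segmentation_result`: list with `assignment` (per-event well
#'   name or `NA`), `wells` (data.frame well, t_start, t_end, n_events),
#'   `discarded` (count), `diagnostics`.
#' @export
segment_stream <- function(stream, layout, bin_width = 0.2, rate_frac = 0.1,
                           min_gap = 0.5, min_burst = 2) {
  stopifnot(inherits(stream, "event_table"))
  if (is.null(stream$time)) stopf("stream has no time channel")
  layout <- validate_plate_layout(as.data.frame(layout))
  expected <- nrow(layout)
  tt <- stream$time
  t0 <- 0
  t1 <- max(tt) + bin_width
  breaks <- seq(t0, t1 + bin_width, by = bin_width)
  bin <- findInterval(tt, breaks, rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  med <- stats::median(counts[counts > 0])
  thr <- rate_frac * med
  active <- counts >= thr
  # morphological opening: isolated above-threshold spikes (shorter than
  # min_gap) inside an otherwise quiet stretch are background noise, not
  # wells -- without this a single carry-over event can bridge a gap
  min_bins <- max(1L, ceiling(min_gap / bin_width))
  r0 <- rle(active)
  r0$values[r0$values & r0$lengths < min_bins] <- FALSE
  active <- inverse.rle(r0)

  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # gaps: inactive runs long enough; stream start/end always count as gaps
  is_gap <- !r$values & (r$lengths >= min_bins |
                           starts == 1L | ends == length(counts))
  # bursts: maximal stretches between gaps (short inactive runs inside a
  # burst are kept with it)
  seg_id <- cumsum(is_gap)
  burst_runs <- which(!is_gap)
  if (!length(burst_runs))
    stopf("no wells detected in stream (all bins below threshold)")
  bursts <- split(burst_runs, seg_id[burst_runs])
  windows <- t(vapply(bursts, function(runs) {
    c(breaks[starts[runs[1L]]], breaks[ends[runs[length(runs)]] + 1L])
  }, numeric(2)))
  keep <- windows[, 2L] - windows[, 1L] >= min_burst
  windows <- windows[keep, , drop = FALSE]
  # pad by one bin: partial edge bins of a sip can fall under the rate
  # threshold, and their events belong to the well, not the gap
  windows[, 1L] <- windows[, 1L] - bin_width
  windows[, 2L] <- windows[, 2L] + bin_width
  n_burst <- nrow(windows)
  gap_durs <- r$lengths[is_gap] * bin_width
  if (n_burst != expected) {
    stopf(paste0("segmentation found %d bursts but layout expects %d wells\n",
                 "  gap durations (s): n=%d, quartiles %.2f/%.2f/%.2f\n",
                 "  median active bin count %.1f, threshold %.2f"),
          n_burst, expected, length(gap_durs),
          stats::quantile(gap_durs, 0.25), stats::median(gap_durs),
          stats::quantile(gap_durs, 0.75), med, thr)
  }
  assignment <- rep(NA_character_, length(tt))
  n_assigned <- integer(n_burst)
  for (i in seq_len(n_burst)) {
    in_w <- tt >= windows[i, 1L] & tt < windows[i, 2L]
    assignment[in_w] <- layout$well[i]
    n_assigned[i] <- sum(in_w)
  }
  wells <- data.frame(well = layout$well, t_start = windows[, 1L],
                      t_end = windows[, 2L], n_events = n_assigned,
                      stringsAsFactors = FALSE)
  res <- list(assignment = assignment, wells = wells,
              discarded = sum(is.na(assignment)),
              diagnostics = list(bin_width = bin_width, threshold = thr,
                                 median_bin_count = med,
                                 gap_durations = gap_durs))
  class(res) <- "segmentation_result"
  res
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d wells, %d events assigned, %d discarded\n",
              nrow(x$wells), sum(x$wells$n_events), x$discarded))
  invisible(x)
}

#' Split a segmented stream into per-well event tables
#'
#' @param stream the [event_table()] that was segmented.
#' @param seg a `segmentation_result` from [segment_stream()].
#' @return named list of [event_table()]s, one per well in layout order.
#' @export
split_stream <- function(stream, seg) {
  out <- lapply(seg$wells$well, function(w)
    subset_events(stream, which(seg$assignment == w)))
  names(out) <- seg$wells$well
  out
}

#' Check well identification using the control wells
#'
#' CD4-only wells must show (near-)zero FoxP3+ fraction and unstained wells
#' near-zero CD4+ and FoxP3+ fractions; violations indicate that bursts were
#' mapped to the wrong wells. When violations occur the function also scans
#' circular shifts of the well assignment and reports the shift minimizing
#' the number of violated control checks.
#'
#' @param summaries a `well_summary` data.frame (see [summarize_plate()]).
#' @param layout the `plate_layout` used for segmentation.
#' @param ceiling_pct maximum acceptable control percentage (default 5).
#' @param max_shift shifts `-max_shift..max_shift` scanned on failure.
#' @return list with `per_well` check table, `pass`, `verifiable` and, when
#'   failing, `best_shift`.
#' @export
validate_segmentation <- function(summaries, layout, ceiling_pct = 5,
                                  max_shift = 5) {
  layout <- validate_plate_layout(as.data.frame(layout))
  s <- summaries[match(layout$well, summaries$well), ]
  violations <- function(roles) {
    bad <- 0L; checks <- list()
    for (i in seq_len(nrow(layout))) {
      role <- roles[i]
      if (role == "cd4_only_negative") {
        v <- s$foxp3_pct_cd4[i] <= ceiling_pct
        checks[[length(checks) + 1L]] <- data.frame(
          well = layout$well[i], role = role, check = "foxp3_pct_cd4",
          value = s$foxp3_pct_cd4[i], pass = v)
        bad <- bad + !v
      } else if (role == "unstained") {
        v1 <- s$cd4_pct_singlets[i] <= ceiling_pct
        v2 <- s$foxp3_pct_cd4[i] <= ceiling_pct || is.na(s$foxp3_pct_cd4[i])
        checks[[length(checks) + 1L]] <- data.frame(
          well = layout$well[i], role = role, check = "cd4_pct_singlets",
          value = s$cd4_pct_singlets[i], pass = v1)
        bad <- bad + !v1 + !isTRUE(v2)
      }
    }
    list(bad = bad, checks = if (length(checks)) do.call(rbind, checks))
  }
  base <- violations(layout$role)
  if (is.null(base$checks))
    return(list(per_well = NULL, pass = NA, verifiable = FALSE))
  out <- list(per_well = base$checks, pass = base$bad == 0L,
              verifiable = TRUE)
  if (base$bad > 0L) {
    shifts <- setdiff(seq(-max_shift, max_shift), 0L)
    nb <- vapply(shifts, function(k) {
      roles <- layout$role[((seq_len(nrow(layout)) - 1L + k) %% nrow(layout)) + 1L]
      violations(roles)$bad
    }, integer(1))
    cand <- c(0L, shifts)[which.min(c(base$bad, nb))]
    out$best_shift <- cand
  }
  out
}
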