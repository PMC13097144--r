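# Screen triage: hit calling against DMSO, FSC-H delta-ratio toxicity
# filtering, V450 stain-ratio autofluorescence filtering, open-channel
# interference profiling and ROC evaluation.

#' Call FoxP3 hits at +/-50% of the plate DMSO mean
#'
#' Each well's FoxP3% of CD4+ is divided by the mean FoxP3% of the
#' DMSO-positive wells on the same plate. A compound is an up-hit when its
#' fold is `>= 1 + fold_threshold` and a down-hit when `<= 1 -
#' fold_threshold` (default +/-50%, i.e. folds of 1.5 and 0.5). With
#' `log_scale = TRUE` the rule is applied symmetrically on log10 folds
#' (cutoffs `1.5` and `1/1.5`).
#'
#' @param summaries a `well_summary` data.frame, possibly spanning plates.
#' @param fold_threshold relative change defining a hit (default 0.5).
#' @param log_scale apply the threshold on the log scale (see above).
#' @return `summaries` with columns `foxp3_fold` and `hit_call`
#'   (`"up"`/`"down"`/`"none"`, `NA` for non-compound wells).
#' @export
call_hits <- function(summaries, fold_threshold = 0.5, log_scale = FALSE) {
  out <- summaries
  out$foxp3_fold <- NA_real_
  out$hit_call <- NA_character_
  for (pid in unique(out$plate_id)) {
    on_plate <- out$plate_id == pid
    dmso <- out$foxp3_pct_cd4[on_plate & out$role == "dmso_positive"]
    dmso <- dmso[is.finite(dmso)]
    if (!length(dmso))
      stopf("plate %s has no dmso_positive wells", pid)
    m <- mean(dmso)
    if (m == 0) stopf("plate %s: DMSO mean FoxP3%% is zero", pid)
    out$foxp3_fold[on_plate] <- out$foxp3_pct_cd4[on_plate] / m
  }
  cmp <- out$role == "compound"
  if (log_scale) {
    up <- 1 + fold_threshold
    hi <- log10(up); lo <- -log10(up)
    lf <- log10(out$foxp3_fold)
    out$hit_call[cmp] <- ifelse(lf[cmp] >= hi, "up",
                                ifelse(lf[cmp] <= lo, "down", "none"))
  } else {
    out$hit_call[cmp] <- ifelse(out$foxp3_fold[cmp] >= 1 + fold_threshold,
                                "up",
                                ifelse(out$foxp3_fold[cmp] <= 1 - fold_threshold,
                                       "down", "none"))
  }
  out
}

#' FSC-H delta-ratio: per-well toxicity statistic
#'
#' Each well's lymphocyte FSC-H median is divided by the pooled
#' DMSO-control FSC-H on the same plate. The pool is the median over the
#' plate's DMSO wells' events; at the summary level this is computed as the
#' median of the DMSO wells' FSC-H medians (`pool = "median"`) or their
#' mean (`pool = "mean"`).
#'
#' @param summaries a `well_summary` data.frame.
#' @param pool how DMSO wells are pooled (default `"median"`).
#' @return `summaries` with a `delta_ratio` column (all wells, including
#'   controls, so DMSO wells can be sanity-checked against ~1).
#' @export
delta_ratio <- function(summaries, pool = c("median", "mean")) {
  pool <- match.arg(pool)
  out <- summaries
  out$delta_ratio <- NA_real_
  for (pid in unique(out$plate_id)) {
    on_plate <- out$plate_id == pid
    dmso <- out$fsch_mfi[on_plate & out$role == "dmso_positive"]
    dmso <- dmso[is.finite(dmso)]
    if (!length(dmso))
      stopf("plate %s has no dmso_positive wells", pid)
    ref <- if (pool == "median") stats::median(dmso) else mean(dmso)
    if (!is.finite(ref) || ref == 0)
      stopf("plate %s: pooled DMSO FSC-H median is zero", pid)
    out$delta_ratio[on_plate] <- out$fsch_mfi[on_plate] / ref
  }
  out
}

#' Flag toxicity outliers at +/- k SD of the compound delta-ratios
#'
#' The mean and SD are computed over compound wells only (controls
#' excluded), either over the whole screen (`scope = "screen"`, the
#' default) or per plate (`scope = "plate"`). A compound is toxic when
#' `|z| >= k` (two-sided by default; `side = "lower"`/`"upper"` for
#' one-sided variants).
#'
#' @param summaries output of [delta_ratio()].
#' @param scope `"screen"` or `"plate"`.
#' @param k SD multiple (default 3).
#' @param side `"both"`, `"lower"` or `"upper"`.
#' @param min_wells minimum compound wells required in scope (default 8).
#' @return `summaries` with columns `tox_z` and `toxic` (compound wells
#'   only, `NA` elsewhere).
#' @export
toxicity_outliers <- function(summaries, scope = c("screen", "plate"), k = 3,
                              side = c("both", "lower", "upper"),
                              min_wells = 8) {
  scope <- match.arg(scope)
  side <- match.arg(side)
  out <- summaries
  out$tox_z <- NA_real_
  out$toxic <- NA
  cmp <- out$role == "compound" & is.finite(out$delta_ratio)
  groups <- if (scope == "screen") list(all = which(cmp))
            else split(which(cmp), out$plate_id[cmp])
  for (idx in groups) {
    if (length(idx) < min_wells)
      stopf("toxicity scope has %d compound wells (< %d)", length(idx),
            min_wells)
    mu <- mean(out$delta_ratio[idx])
    sdv <- stats::sd(out$delta_ratio[idx])
    if (sdv == 0) stopf("delta-ratio SD is zero in toxicity scope")
    z <- (out$delta_ratio[idx] - mu) / sdv
    out$tox_z[idx] <- z
    out$toxic[idx] <- switch(side,
                             both = abs(z) >= k,
                             lower = z <= -k,
                             upper = z >= k)
  }
  out
}

#' V450 stain ratio: per-well autofluorescence statistic
#'
#' The V450 (FoxP3 detector) median of the FoxP3+ population divided by
#' that of the FoxP3- population of the same well. Wells whose FoxP3-
#' median is `<= 0` (possible after compensation) or whose populations fall
#' below `min_events` get `NA` and are flagged indeterminate.
#'
#' @param summaries a `well_summary` data.frame.
#' @param min_events per-population event floor (default 20).
#' @return `summaries` with columns `v450_ratio` and
#'   `v450_indeterminate`.
#' @export
v450_stain_ratio <- function(summaries, min_events = 20) {
  out <- summaries
  ok <- is.finite(out$v450_mfi_pos) & is.finite(out$v450_mfi_neg) &
    out$v450_mfi_neg > 0 & out$n_foxp3_pos >= min_events &
    out$n_foxp3_neg >= min_events
  out$v450_ratio <- ifelse(ok, out$v450_mfi_pos / out$v450_mfi_neg, NA_real_)
  out$v450_indeterminate <- !ok
  out
}

#' Grade autofluorescence per plate from the V450 stain ratio
#'
#' z-scores are computed per plate over compound wells. `high` flags are
#' two-sided at `k_high` SD (strong artifacts can push the ratio in either
#' direction); `low_moderate` flags are one-sided negative between
#' `-k_high` and `-k_low` SD, the direction additive compound fluorescence
#' pushes the ratio.
#'
#' @param summaries output of [v450_stain_ratio()].
#' @param k_high SD cut for `high` (default 3).
#' @param k_low SD cut for `low_moderate` (default 1).
#' @param min_wells minimum compound wells per plate (default 8).
#' @return `summaries` with columns `af_z` and `autofluor_level`
#'   (`"none"`, `"low_moderate"`, `"high"`).
#' @export
autofluorescence_flags <- function(summaries, k_high = 3, k_low = 1,
                                   min_wells = 8) {
  out <- summaries
  out$af_z <- NA_real_
  out$autofluor_level <- NA_character_
  cmp <- out$role == "compound" & is.finite(out$v450_ratio)
  for (pid in unique(out$plate_id)) {
    idx <- which(cmp & out$plate_id == pid)
    if (length(idx) < min_wells)
      stopf("plate %s has %d usable compound wells (< %d)", pid,
            length(idx), min_wells)
    mu <- mean(out$v450_ratio[idx])
    sdv <- stats::sd(out$v450_ratio[idx])
    if (sdv == 0) stopf("plate %s: V450 ratio SD is zero", pid)
    z <- (out$v450_ratio[idx] - mu) / sdv
    out$af_z[idx] <- z
    out$autofluor_level[idx] <- ifelse(abs(z) >= k_high, "high",
                                       ifelse(z <= -k_low, "low_moderate",
                                              "none"))
  }
  out
}

#' Open-channel interference profile of a compound
#'
#' Compares unstained compound-treated events against unstained DMSO events
#' on every shared fluorescence channel ("all channels open"): the
#' per-channel median fold change flags channels the compound interferes
#' with and yields the list of channels safe for follow-up staining panels.
#'
#' @param compound_unstained,dmso_unstained [event_table()]s of unstained
#'   cells.
#' @param fold_threshold median fold change above which a channel is
#'   flagged (default 2).
#' @param scatter_channels channels excluded from profiling.
#' @return data.frame channel, median_compound, median_dmso, fold,
#'   interfered; attribute `safe_channels`.
#' @export
channel_interference_profile <- function(compound_unstained, dmso_unstained,
                                         fold_threshold = 2,
                                         scatter_channels = c("FSC-A",
                                                              "FSC-H",
                                                              "SSC-A")) {
  shared <- intersect(channels(compound_unstained), channels(dmso_unstained))
  fluor <- setdiff(shared, scatter_channels)
  if (!length(fluor))
    stopf("no shared fluorescence channels between the two tables")
  med_c <- apply(compound_unstained$exprs[, fluor, drop = FALSE], 2L,
                 stats::median)
  med_d <- apply(dmso_unstained$exprs[, fluor, drop = FALSE], 2L,
                 stats::median)
  fold <- med_c / med_d
  out <- data.frame(channel = fluor, median_compound = med_c,
                    median_dmso = med_d, fold = fold,
                    interfered = fold >= fold_threshold |
                      fold <= 1 / fold_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "safe_channels") <- out$channel[!out$interfered]
  out
}

#' ROC curve of a toxicity (or other) score against ground-truth labels
#'
#' Threshold sweep over the unique score values (ties grouped); the AUC is
#' computed by the trapezoid rule over (FPR, TPR).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (or 0/1) ground truth.
#' @return a `roc_curve` list: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels))
    stopf("ROC needs both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels); nn <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nn, numeric(1))
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, thr, -Inf), tpr = tpr, fpr = fpr,
                 auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Write a ROC curve as CSV plus a JSON AUC sidecar
#'
#' @param roc a `roc_curve`.
#' @param path CSV path; the sidecar is written to `<path>.auc.json`.
#' @export
write_roc <- function(roc, path) {
  utils::write.csv(data.frame(threshold = roc$thresholds, tpr = roc$tpr,
                              fpr = roc$fpr), path, row.names = FALSE)
  jsonlite::write_json(list(auc = roc$auc), paste0(path, ".auc.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Normalize a viability readout to the DMSO control
#'
#' @param live_pct_compound live % of a compound-treated sample.
#' @param live_pct_dmso live % of the DMSO control (> 0).
#' @return `100 * compound / dmso`.
#' @export
normalize_viability <- function(live_pct_compound, live_pct_dmso) {
  if (any(live_pct_dmso <= 0)) stopf("DMSO live%% must be > 0")
  100 * live_pct_compound / live_pct_dmso
}

#' Compile the per-compound triage report
#'
#' One row per compound carrying the hit call and both filter flags. The
#' candidate list is hits minus toxic minus high-autofluorescence, except
#' that *down*-hits flagged only for autofluorescence are retained with a
#' `retest_alt_fluor` flag: compound fluorescence in V450 inflates apparent
#' FoxP3 and so cannot explain a decreased signal, but the call should be
#' confirmed with a different fluorochrome.
#'
#' @param summaries a `well_summary` data.frame that has passed through
#'   [call_hits()], [delta_ratio()], [toxicity_outliers()],
#'   [v450_stain_ratio()] and [autofluorescence_flags()].
#' @return a `screen_triage_report` data.frame (compound wells only) with
#'   attribute `candidates` (character vector of compound ids).
#' @export
compile_triage_report <- function(summaries) {
  need <- c("hit_call", "toxic", "autofluor_level")
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stopf("summaries missing triage column(s): %s",
          paste(miss, collapse = ", "))
  cmp <- summaries[summaries$role == "compound", , drop = FALSE]
  rep_cols <- intersect(
    c("compound_id", "plate_id", "well", "concentration_um",
      "foxp3_pct_cd4", "foxp3_fold", "hit_call", "delta_ratio", "tox_z",
      "toxic", "v450_ratio", "af_z", "autofluor_level",
      "v450_indeterminate"), names(cmp))
  out <- cmp[, rep_cols, drop = FALSE]
  out$retest_alt_fluor <- out$hit_call == "down" &
    out$autofluor_level %in% c("high", "low_moderate") &
    !out$toxic %in% TRUE
  is_hit <- out$hit_call %in% c("up", "down")
  clean <- is_hit & !out$toxic %in% TRUE &
    (!out$autofluor_level %in% "high" |
       (out$hit_call == "down" & !out$toxic %in% TRUE))
  out$candidate <- clean
  rownames(out) <- NULL
  class(out) <- c("screen_triage_report", "data.frame")
  attr(out, "candidates") <- out$compound_id[clean]
  out
}
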