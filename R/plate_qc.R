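# Z'-factor plate quality control.

#' Control-well summary statistics for the Z'-factor
#'
#' @param mu_p,sigma_p mean / SD of the positive-control readout (FoxP3% in
#'   CD4+ of the DMSO wells).
#' @param mu_n,sigma_n mean / SD of the negative controls (CD4-only wells).
#' @param n_p,n_n control well counts (>= 2 each).
#' @return a `control_summary` list.
#' @export
control_summary <- function(mu_p, sigma_p, mu_n, sigma_n, n_p = 2L, n_n = 2L) {
  if (n_p < 2L || n_n < 2L) stopf("need >= 2 wells per control group")
  if (sigma_p < 0 || sigma_n < 0) stopf("SDs must be >= 0")
  structure(list(mu_p = mu_p, sigma_p = sigma_p, mu_n = mu_n,
                 sigma_n = sigma_n, n_p = n_p, n_n = n_n),
            class = "control_summary")
}

#' Z'-factor of a screening plate
#'
#' `Z' = 1 - 3 * (sigma_p + sigma_n) / |mu_p - mu_n|`, the standard
#' screening-window statistic; `Z' >= 0.5` is the customary pass mark.
#'
#' @param controls a [control_summary()].
#' @return the Z'-factor (<= 1).
#' @export
zprime_factor <- function(controls) {
  stopifnot(inherits(controls, "control_summary"))
  if (controls$mu_p == controls$mu_n)
    stopf("Z'-factor undefined: positive and negative control means equal")
  1 - 3 * (controls$sigma_p + controls$sigma_n) /
    abs(controls$mu_p - controls$mu_n)
}

#' Plate pass/fail report from per-well summaries
#'
#' Computes the control summary from the FoxP3% readout of DMSO-positive
#' and CD4-only wells (sample SDs, n-1 denominator), evaluates the
#' Z'-factor and passes the plate iff `zprime >= threshold` (boundary
#' inclusive).
#'
#' @param summaries a `well_summary` data.frame (see [summarize_plate()]).
#' @param threshold pass threshold (default 0.5).
#' @return a `plate_qc_report` list: `plate_id`, `zprime`, `controls`,
#'   `threshold`, `pass`.
#' @export
plate_qc_report <- function(summaries, threshold = 0.5) {
  pos <- summaries$foxp3_pct_cd4[summaries$role == "dmso_positive"]
  neg <- summaries$foxp3_pct_cd4[summaries$role == "cd4_only_negative"]
  pos <- pos[is.finite(pos)]; neg <- neg[is.finite(neg)]
  if (length(pos) < 2L)
    stopf("insufficient dmso_positive control wells (%d, need >= 2)",
          length(pos))
  if (length(neg) < 2L)
    stopf("insufficient cd4_only_negative control wells (%d, need >= 2)",
          length(neg))
  ctrl <- control_summary(mean(pos), stats::sd(pos), mean(neg),
                          stats::sd(neg), length(pos), length(neg))
  z <- zprime_factor(ctrl)
  structure(list(plate_id = summaries$plate_id[1L], zprime = z,
                 controls = ctrl, threshold = threshold,
                 pass = z >= threshold),
            class = "plate_qc_report")
}

#' @export
print.plate_qc_report <- function(x, ...) {
  cat(sprintf("<plate_qc_report> %s: Z' = %.3f (threshold %.2f) -> %s\n",
              x$plate_id, x$zprime, x$threshold,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Write one or more plate QC reports as CSV
#'
#' @param reports a `plate_qc_report` or list of them.
#' @param path CSV path.
#' @export
write_qc_reports <- function(reports, path) {
  if (inherits(reports, "plate_qc_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r)
    data.frame(plate_id = r$plate_id, zprime = r$zprime,
               n_pos = r$controls$n_p, n_neg = r$controls$n_n,
               pass = r$pass)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
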