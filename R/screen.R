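# End-to-end convenience: simulate a whole screen with spiked effects,
# gate it, and run the full triage -- the workhorse behind the package's
# property tests and the acceptance script.

#' Simulate and summarize a complete screen with known spiked effects
#'
#' Compounds are spread across 384-well plates (up to 368 compound wells
#' per plate, controls per [plate_layout_default()]). The listed spiked
#' compounds get the corresponding ground-truth effect; all others are
#' neutral. Each plate is simulated, plate-global gates are fit on its
#' pooled DMSO wells, and per-well summaries are produced.
#'
#' @param n_compounds total compound count (default 300).
#' @param modulators_down,modulators_up compound indices whose FoxP3
#'   positive fraction is multiplied by `mult_down` / `mult_up`.
#' @param toxic compound indices given `tox_dead_fraction` dead cells.
#' @param autofluor compound indices given `autofluor_additive`.
#' @param mult_down,mult_up FoxP3 multipliers for spiked modulators.
#' @param tox_dead_fraction dead fraction for spiked toxic compounds.
#' @param autofluor_additive named per-channel additive signal for spiked
#'   autofluorescent compounds.
#' @param config a [sim_config()]; lower `n_events` for speed.
#' @param seed master seed.
#' @return list with `summaries` (all plates row-bound, gated), `truth`
#'   (per-well injected effects), `layouts`, `trees` (per-plate gate
#'   trees), and `plates` (the raw event data, named by plate id).
#' @export
simulate_screen <- function(n_compounds = 300,
                            modulators_down = integer(0),
                            modulators_up = integer(0),
                            toxic = integer(0),
                            autofluor = integer(0),
                            mult_down = 0.3, mult_up = 2.0,
                            tox_dead_fraction = 0.85,
                            autofluor_additive = c("VL1-A" = 150),
                            config = sim_config(n_events = 1500),
                            seed = 1L) {
  per_plate <- 368L
  n_plates <- ceiling(n_compounds / per_plate)
  ids <- sprintf("C%04d", seq_len(n_compounds))
  effects <- lapply(seq_len(n_compounds), function(i) {
    compound_effect(
      ids[i],
      foxp3_multiplier = if (i %in% modulators_down) mult_down
                         else if (i %in% modulators_up) mult_up else 1,
      dead_fraction = if (i %in% toxic) tox_dead_fraction else 0,
      autofluor_additive = if (i %in% autofluor) autofluor_additive)
  })
  names(effects) <- ids
  seeds <- derive_seeds(seed, n_plates)
  summaries <- list(); truth <- list(); layouts <- list(); trees <- list()
  plates <- list()
  for (p in seq_len(n_plates)) {
    idx <- ((p - 1L) * per_plate + 1L):min(p * per_plate, n_compounds)
    layout <- plate_layout_default(plate_id = sprintf("plate%d", p),
                                   compound_ids = ids[idx])
    plate <- simulate_plate(layout, effects[ids[idx]], config,
                            seed = seeds[p])
    tree <- fit_plate_gates(plate$wells, layout)
    summaries[[p]] <- summarize_plate(plate$wells, layout, tree)
    truth[[p]] <- plate$truth
    layouts[[p]] <- layout
    trees[[p]] <- tree
    plates[[p]] <- plate
  }
  names(trees) <- names(plates) <- sprintf("plate%d", seq_len(n_plates))
  su <- do.call(rbind, summaries)
  class(su) <- c("well_summary", "data.frame")
  list(summaries = su, truth = do.call(rbind, truth), layouts = layouts,
       trees = trees, plates = plates,
       spiked = list(down = ids[modulators_down], up = ids[modulators_up],
                     toxic = ids[toxic], autofluor = ids[autofluor]))
}

#' Run the full triage chain on gated well summaries
#'
#' Convenience wrapper: [call_hits()] -> [delta_ratio()] ->
#' [toxicity_outliers()] -> [v450_stain_ratio()] ->
#' [autofluorescence_flags()] -> [compile_triage_report()].
#'
#' @param summaries a `well_summary` data.frame.
#' @param fold_threshold hit threshold, see [call_hits()].
#' @param tox_scope toxicity outlier scope, see [toxicity_outliers()].
#' @param tox_k,af_k_high,af_k_low SD cutoffs.
#' @return list with `summaries` (all triage columns appended) and
#'   `report` (the `screen_triage_report`).
#' @export
triage_screen <- function(summaries, fold_threshold = 0.5,
                          tox_scope = "screen", tox_k = 3,
                          af_k_high = 3, af_k_low = 1) {
  s <- call_hits(summaries, fold_threshold = fold_threshold)
  s <- delta_ratio(s)
  s <- toxicity_outliers(s, scope = tox_scope, k = tox_k)
  s <- v450_stain_ratio(s)
  s <- autofluorescence_flags(s, k_high = af_k_high, k_low = af_k_low)
  list(summaries = s, report = compile_triage_report(s))
}
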