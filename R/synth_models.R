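# Generative models for the synthetic screening plate.
#
# The screen readout this emulates: human T cells in 384-well plates,
# stained anti-CD4 (PE-Cy7, BL5 detector) and anti-FoxP3 (Horizon V450,
# VL1 detector), acquired on a plate sampler either per-well (FCS per well)
# or as one continuous timed stream. None of the distribution parameters
# below are measured values from a specific instrument; they are declared
# configuration chosen to produce realistic scatter/fluorescence structure
# (a dominant lymphocyte cloud, small debris, ~10% doublets, clearly
# separated stained populations).

#' Scatter population model
#'
#' @param name one of `"lymphocyte"`, `"debris"`, `"doublet"`.
#' @param scatter_location length-2 numeric, mean (FSC-A, SSC-A).
#' @param scatter_spread 2x2 symmetric positive-definite covariance.
#' @param fsch_over_fsca mean FSC-H / FSC-A ratio (~1 singlets, ~0.5
#'   doublets).
#' @param weight fraction of events drawn from this population.
#' @return a `population_model` list.
#' @export
population_model <- function(name, scatter_location, scatter_spread,
                             fsch_over_fsca, weight) {
  stopifnot(length(scatter_location) == 2L,
            is.matrix(scatter_spread), all(dim(scatter_spread) == 2L))
  if (max(abs(scatter_spread - t(scatter_spread))) > 1e-8)
    stopf("scatter_spread must be symmetric")
  ev <- eigen(scatter_spread, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stopf("scatter_spread must be positive-definite")
  if (fsch_over_fsca <= 0) stopf("fsch_over_fsca must be > 0")
  if (weight < 0) stopf("weight must be >= 0")
  structure(list(name = name, scatter_location = as.numeric(scatter_location),
                 scatter_spread = scatter_spread,
                 fsch_over_fsca = fsch_over_fsca, weight = weight),
            class = "population_model")
}

cov2 <- function(sd1, sd2, rho = 0) {
  matrix(c(sd1^2, rho * sd1 * sd2, rho * sd1 * sd2, sd2^2), 2L, 2L)
}

#' Default scatter populations: lymphocytes, debris, doublets
#'
#' @return list of [population_model()]s with weights summing to 1.
#' @export
default_population_models <- function() {
  list(
    lymphocyte = population_model("lymphocyte", c(50000, 30000),
                                  cov2(8000, 6000, 0.4), 1.0, 0.70),
    debris = population_model("debris", c(12000, 8000),
                              cov2(5000, 4000, 0.2), 1.0, 0.18),
    doublet = population_model("doublet", c(100000, 45000),
                               cov2(12000, 8000, 0.4), 0.5, 0.12))
}

#' Antibody stain model (log10-scale mixture on one detector)
#'
#' Fluorescence is generated on the log10 scale and exponentiated; the
#' `positive_fraction` of the parent population draws from the positive
#' component, the rest from the negative (unstained background) component.
#'
#' @param channel detector channel name.
#' @param negative_location,negative_spread log10 location/SD of unstained
#'   signal.
#' @param positive_location,positive_spread log10 location/SD of stained
#'   signal; `positive_location >= negative_location`.
#' @param positive_fraction fraction of the parent population stained, in
#'   `[0, 1]`.
#' @return a `stain_model` list.
#' @export
stain_model <- function(channel, negative_location, negative_spread,
                        positive_location, positive_spread,
                        positive_fraction) {
  if (positive_location < negative_location)
    stopf("positive_location must be >= negative_location")
  if (positive_fraction < 0 || positive_fraction > 1)
    stopf("positive_fraction must be in [0, 1]")
  structure(list(channel = channel,
                 negative_location = negative_location,
                 negative_spread = negative_spread,
                 positive_location = positive_location,
                 positive_spread = positive_spread,
                 positive_fraction = positive_fraction),
            class = "stain_model")
}

#' Default stains: CD4 (BL5-A) and FoxP3 (VL1-A)
#'
#' CD4 marks ~65% of lymphocytes; FoxP3 marks ~6% of CD4+ cells at
#' baseline (the DMSO level the screen normalizes against).
#'
#' @return named list with elements `cd4` and `foxp3`.
#' @export
default_stain_models <- function() {
  list(
    cd4 = stain_model("BL5-A", negative_location = 2.0, negative_spread = 0.25,
                      positive_location = 3.8, positive_spread = 0.15,
                      positive_fraction = 0.65),
    foxp3 = stain_model("VL1-A", negative_location = 1.7, negative_spread = 0.3,
                        positive_location = 3.3, positive_spread = 0.2,
                        positive_fraction = 0.06))
}

#' Injected per-compound ground-truth effect
#'
#' @param compound_id compound label.
#' @param foxp3_multiplier multiplies the FoxP3 stain's positive fraction
#'   (capped at 1); 1 = neutral, 0.3 = strong down-modulator, 2 = up.
#' @param dead_fraction fraction of cell events converted to a dead
#'   population with shifted scatter.
#' @param autofluor_additive named numeric vector of per-channel additive
#'   signal (linear fluorescence units), e.g. `c("VL1-A" = 3000)`.
#' @param event_loss_fraction fraction of events lost outright (cell loss).
#' @param viability_truth logical toxicity label for ROC ground truth.
#' @return a `compound_effect` list.
#' @export
compound_effect <- function(compound_id, foxp3_multiplier = 1,
                            dead_fraction = 0, autofluor_additive = NULL,
                            event_loss_fraction = 0,
                            viability_truth = dead_fraction > 0.25) {
  if (foxp3_multiplier < 0) stopf("foxp3_multiplier must be >= 0")
  if (dead_fraction < 0 || dead_fraction > 1)
    stopf("dead_fraction must be in [0, 1]")
  if (event_loss_fraction < 0 || event_loss_fraction > 1)
    stopf("event_loss_fraction must be in [0, 1]")
  if (!is.null(autofluor_additive)) {
    if (is.null(names(autofluor_additive)) || any(autofluor_additive < 0))
      stopf("autofluor_additive must be a named non-negative vector")
  }
  structure(list(compound_id = compound_id,
                 foxp3_multiplier = foxp3_multiplier,
                 dead_fraction = dead_fraction,
                 autofluor_additive = autofluor_additive,
                 event_loss_fraction = event_loss_fraction,
                 viability_truth = isTRUE(viability_truth)),
            class = "compound_effect")
}

neutral_effect <- function(id = "DMSO") compound_effect(id)

#' Continuous-acquisition timing profile (iQue-style)
#'
#' Defaults mirror the published acquisition protocol: 13.5 s sip per well
#' plus 1 s up time, a 4 s shake every 6 wells, three 1 s rinse cycles
#' every 12 wells, and a 30 s initial plate shake.
#'
#' @param sip_seconds seconds of recording per well.
#' @param up_time_seconds extra per-well travel time after each sip.
#' @param shake_every,shake_seconds wells between shakes; shake duration.
#' @param rinse_every,rinse_cycles,rinse_seconds wells between rinse blocks;
#'   number of cycles; seconds per cycle.
#' @param initial_shake_seconds plate shake before the first sip.
#' @param event_rate nominal events/second during sips (used for simulated
#'   stream diagnostics, not to resample well events).
#' @param inter_well_rate background events/second between sips (carry-over
#'   and debris picked up during travel); must be `< event_rate`.
#' @return an `acquisition_profile` list.
#' @export
acquisition_profile <- function(sip_seconds = 13.5, up_time_seconds = 1,
                                shake_every = 6, shake_seconds = 4,
                                rinse_every = 12, rinse_cycles = 3,
                                rinse_seconds = 1,
                                initial_shake_seconds = 30,
                                event_rate = 150, inter_well_rate = 0.5) {
  durs <- c(sip_seconds, up_time_seconds, shake_seconds, rinse_seconds,
            initial_shake_seconds)
  if (any(durs <= 0)) stopf("all durations must be > 0")
  if (inter_well_rate >= event_rate)
    stopf("inter_well_rate must be < event_rate")
  structure(list(sip_seconds = sip_seconds,
                 up_time_seconds = up_time_seconds,
                 shake_every = shake_every, shake_seconds = shake_seconds,
                 rinse_every = rinse_every, rinse_cycles = rinse_cycles,
                 rinse_seconds = rinse_seconds,
                 initial_shake_seconds = initial_shake_seconds,
                 event_rate = event_rate, inter_well_rate = inter_well_rate),
            class = "acquisition_profile")
}

#' Simulator configuration
#'
#' Bundles population and stain models, the channel set, per-well event
#' count, dead-cell morphology parameters and baseline (autofluorescence)
#' background levels for the open channels.
#'
#' @param populations list of [population_model()]s (weights sum to 1).
#' @param stains named list with `cd4` and `foxp3` [stain_model()]s.
#' @param n_events events recorded per well.
#' @param channels ordered channel names; must contain FSC-A, FSC-H, SSC-A
#'   and the stain channels.
#' @param baseline_log10 named list: log10 `c(location, spread)` of the
#'   unstained background per fluorescence channel not covered by a stain.
#' @param dead_fsca_mult,dead_fsch_mult,dead_ssca_mult multiplicative scatter
#'   shift applied to dead cells (default: shrunken FSC, raised SSC).
#' @param fsch_noise_sd log-normal SD of the per-event FSC-H/FSC-A ratio.
#' @return a `sim_config` list.
#' @export
sim_config <- function(populations = default_population_models(),
                       stains = default_stain_models(),
                       n_events = 5000,
                       channels = c("FSC-A", "FSC-H", "SSC-A", "VL1-A",
                                    "VL2-A", "VL3-A", "BL1-A", "BL5-A"),
                       baseline_log10 = list(
                         `VL1-A` = c(1.7, 0.3), `VL2-A` = c(1.8, 0.3),
                         `VL3-A` = c(1.9, 0.3), `BL1-A` = c(2.0, 0.3),
                         `BL5-A` = c(2.0, 0.25)),
                       dead_fsca_mult = 0.60, dead_fsch_mult = 0.55,
                       dead_ssca_mult = 1.25, fsch_noise_sd = 0.03) {
  w <- vapply(populations, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stopf("population weights must sum to 1")
  need <- c("FSC-A", "FSC-H", "SSC-A",
            vapply(stains, `[[`, character(1), "channel"))
  miss <- setdiff(need, channels)
  if (length(miss))
    stopf("channels missing from config: %s", paste(miss, collapse = ", "))
  fluor <- setdiff(channels, c("FSC-A", "FSC-H", "SSC-A"))
  nobase <- setdiff(fluor, names(baseline_log10))
  if (length(nobase))
    stopf("no baseline_log10 for channel(s): %s",
          paste(nobase, collapse = ", "))
  structure(list(populations = populations, stains = stains,
                 n_events = n_events, channels = channels,
                 baseline_log10 = baseline_log10,
                 dead_fsca_mult = dead_fsca_mult,
                 dead_fsch_mult = dead_fsch_mult,
                 dead_ssca_mult = dead_ssca_mult,
                 fsch_noise_sd = fsch_noise_sd),
            class = "sim_config")
}

#' Read / write a simulator configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_sim_config`: a [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  pops <- lapply(y$populations, function(p)
    population_model(p$name, unlist(p$scatter_location),
                     matrix(unlist(p$scatter_spread), 2L, 2L),
                     p$fsch_over_fsca, p$weight))
  names(pops) <- vapply(pops, `[[`, character(1), "name")
  stains <- lapply(y$stains, function(s)
    stain_model(s$channel, s$negative_location, s$negative_spread,
                s$positive_location, s$positive_spread, s$positive_fraction))
  base <- lapply(y$baseline_log10, unlist)
  sim_config(populations = pops, stains = stains, n_events = y$n_events,
             channels = unlist(y$channels), baseline_log10 = base,
             dead_fsca_mult = y$dead_fsca_mult %||% 0.60,
             dead_fsch_mult = y$dead_fsch_mult %||% 0.55,
             dead_ssca_mult = y$dead_ssca_mult %||% 1.25,
             fsch_noise_sd = y$fsch_noise_sd %||% 0.03)
}

#' @rdname read_sim_config
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  y <- list(
    populations = lapply(unname(config$populations), function(p)
      list(name = p$name, scatter_location = p$scatter_location,
           scatter_spread = as.vector(p$scatter_spread),
           fsch_over_fsca = p$fsch_over_fsca, weight = p$weight)),
    stains = lapply(config$stains, unclass),
    n_events = config$n_events, channels = config$channels,
    baseline_log10 = lapply(config$baseline_log10, as.numeric),
    dead_fsca_mult = config$dead_fsca_mult,
    dead_fsch_mult = config$dead_fsch_mult,
    dead_ssca_mult = config$dead_ssca_mult,
    fsch_noise_sd = config$fsch_noise_sd)
  yaml::write_yaml(y, path)
  invisible(path)
}
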