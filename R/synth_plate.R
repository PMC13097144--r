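# Event-level simulator for a 384-well FoxP3 screen, with ground truth.

rmvn2 <- function(n, mu, sigma) {
  L <- chol(sigma)
  z <- matrix(stats::rnorm(2L * n), ncol = 2L)
  sweep(z %*% L, 2L, mu, `+`)
}

#' Simulate the events recorded from a single well
#'
#' Draws scatter events from the configured lymphocyte/debris/doublet
#' mixture, applies the compound effect (FoxP3 modulation, dead-cell
#' conversion with shrunken forward scatter, additive autofluorescence,
#' event loss), then generates fluorescence per channel on the log10 scale.
#' Staining respects the well role: `unstained` wells draw every
#' fluorescence channel from its negative distribution and
#' `cd4_only_negative` wells draw the FoxP3 channel from its negative
#' distribution.
#'
#' Ground truth is attached as `labels`: `population` (lymphocyte / debris /
#' doublet), `dead`, `cd4`, `foxp3` (antibody-bound truth, independent of
#' any gate).
#'
#' @param role one of `"compound"`, `"dmso_positive"`, `"cd4_only_negative"`,
#'   `"unstained"`.
#' @param effect a [compound_effect()]; controls should pass a neutral
#'   effect (the default).
#' @param config a [sim_config()].
#' @param n_events events to draw before event loss (default from config).
#' @param seed integer seed; identical seeds and inputs give identical
#'   events.
#' @return an [event_table()] with truth labels.
#' @export
simulate_well_events <- function(role, effect = compound_effect("DMSO"),
                                 config = sim_config(),
                                 n_events = config$n_events, seed = 1L) {
  if (!role %in% WELL_ROLES)
    stopf("unknown well role '%s' (allowed: %s)", role,
          paste(WELL_ROLES, collapse = ", "))
  stopifnot(is_count(n_events))
  set.seed(seed)
  pops <- config$populations
  wts <- vapply(pops, `[[`, numeric(1), "weight")
  pop_names <- vapply(pops, `[[`, character(1), "name")

  n <- n_events
  if (effect$event_loss_fraction > 0)
    n <- stats::rbinom(1L, n, 1 - effect$event_loss_fraction)
  if (n == 0L) n <- 1L
  pop_idx <- sample.int(length(pops), n, replace = TRUE, prob = wts)

  fsca <- numeric(n); ssca <- numeric(n); fsch <- numeric(n)
  for (k in seq_along(pops)) {
    sel <- pop_idx == k
    nk <- sum(sel)
    if (!nk) next
    sc <- rmvn2(nk, pops[[k]]$scatter_location, pops[[k]]$scatter_spread)
    fsca[sel] <- pmax(sc[, 1L], 1)
    ssca[sel] <- pmax(sc[, 2L], 1)
    fsch[sel] <- fsca[sel] * pops[[k]]$fsch_over_fsca *
      exp(stats::rnorm(nk, 0, config$fsch_noise_sd))
  }
  population <- pop_names[pop_idx]

  # dead-cell conversion: cells (not debris) shift to low-FSC morphology
  dead <- rep(FALSE, n)
  if (effect$dead_fraction > 0) {
    cell <- population != "debris"
    dead[cell] <- stats::runif(sum(cell)) < effect$dead_fraction
    jit <- function(m) exp(stats::rnorm(m, 0, 0.08))
    nd <- sum(dead)
    fsca[dead] <- fsca[dead] * config$dead_fsca_mult * jit(nd)
    fsch[dead] <- fsch[dead] * config$dead_fsch_mult * jit(nd)
    ssca[dead] <- ssca[dead] * config$dead_ssca_mult * jit(nd)
  }

  # fluorescence: negative baseline everywhere, stain positives by role
  fluor_ch <- setdiff(config$channels, c("FSC-A", "FSC-H", "SSC-A"))
  fl <- matrix(0, n, length(fluor_ch), dimnames = list(NULL, fluor_ch))
  for (ch in fluor_ch) {
    b <- config$baseline_log10[[ch]]
    fl[, ch] <- 10^stats::rnorm(n, b[1L], b[2L])
  }
  cd4 <- rep(FALSE, n)
  foxp3 <- rep(FALSE, n)
  stained <- role != "unstained"
  if (stained) {
    s <- config$stains$cd4
    cell <- population != "debris"
    cd4[cell] <- stats::runif(sum(cell)) < s$positive_fraction
    fl[cd4, s$channel] <- 10^stats::rnorm(sum(cd4), s$positive_location,
                                          s$positive_spread)
    if (role != "cd4_only_negative") {
      f <- config$stains$foxp3
      p <- min(1, f$positive_fraction * effect$foxp3_multiplier)
      foxp3[cd4] <- stats::runif(sum(cd4)) < p
      fl[foxp3, f$channel] <- 10^stats::rnorm(sum(foxp3),
                                              f$positive_location,
                                              f$positive_spread)
    }
  }
  if (!is.null(effect$autofluor_additive)) {
    for (ch in names(effect$autofluor_additive)) {
      if (ch %in% fluor_ch)
        fl[, ch] <- fl[, ch] + effect$autofluor_additive[[ch]]
    }
  }

  exprs <- cbind(`FSC-A` = fsca, `FSC-H` = fsch, `SSC-A` = ssca, fl)
  exprs <- exprs[, config$channels, drop = FALSE]
  labels <- data.frame(population = population, dead = dead, cd4 = cd4,
                       foxp3 = foxp3, stringsAsFactors = FALSE)
  event_table(exprs, source = sprintf("sim:%s", effect$compound_id),
              labels = labels)
}

#' Simulate every well of a screening plate
#'
#' @param layout a `plate_layout` (see [plate_layout_default()]).
#' @param effects named list of [compound_effect()]s keyed by compound id;
#'   every compound well in the layout must have an entry. Control wells use
#'   a neutral effect.
#' @param config a [sim_config()].
#' @param seed master seed; per-well seeds are derived from it.
#' @return list with `wells` (named list of [event_table()]s in layout
#'   order) and `truth` (data.frame of the injected effect per well).
#' @export
simulate_plate <- function(layout, effects = list(), config = sim_config(),
                           seed = 1L) {
  layout <- validate_plate_layout(as.data.frame(layout))
  cmp <- layout$compound_id[layout$role == "compound"]
  miss <- setdiff(cmp, names(effects))
  if (length(miss))
    stopf("no compound_effect for compound well(s): %s",
          paste(utils::head(miss, 5L), collapse = ", "))
  seeds <- derive_seeds(seed, nrow(layout))
  wells <- vector("list", nrow(layout))
  names(wells) <- layout$well
  truth <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    role <- layout$role[i]
    eff <- if (role == "compound") effects[[layout$compound_id[i]]]
           else neutral_effect(role)
    wells[[i]] <- simulate_well_events(role, eff, config, seed = seeds[i])
    truth[[i]] <- data.frame(
      plate_id = layout$plate_id[i], well = layout$well[i], role = role,
      compound_id = if (role == "compound") eff$compound_id else NA_character_,
      foxp3_multiplier = eff$foxp3_multiplier,
      dead_fraction = eff$dead_fraction,
      autofluor = sum(eff$autofluor_additive %||% 0),
      viability_truth = eff$viability_truth, stringsAsFactors = FALSE)
  }
  list(wells = wells, truth = do.call(rbind, truth), layout = layout,
       config = config)
}

#' Fold per-well events into one continuous timed acquisition stream
#'
#' Reproduces the timing structure of plate-sampler acquisition: an initial
#' plate shake, then per-well sips (each followed by an up-time), a shake
#' after every `shake_every` wells and a rinse block after every
#' `rinse_every` wells. Well events receive sorted uniform timestamps inside
#' their sip window; sparse background events (rate
#' `profile$inter_well_rate`) fill the non-sip intervals.
#'
#' @param plate result of [simulate_plate()] (or a compatible list with
#'   `wells` in acquisition order and `config`).
#' @param profile an [acquisition_profile()].
#' @param seed integer seed for timestamps and background events.
#' @return list with `stream` (one [event_table()] with time),
#'   `windows` (data.frame well, t_start, t_end, n_events) and
#'   `truth_well` (per-event well name, `NA` for background events).
#' @export
simulate_acquisition_stream <- function(plate, profile = acquisition_profile(),
                                        seed = 1L) {
  stopifnot(inherits(profile, "acquisition_profile"))
  set.seed(seed)
  wells <- plate$wells
  wn <- names(wells)
  n_wells <- length(wells)
  t <- profile$initial_shake_seconds
  win <- data.frame(well = wn, t_start = NA_real_, t_end = NA_real_,
                    n_events = NA_integer_, stringsAsFactors = FALSE)
  parts <- list(); truth <- list()
  gap_start <- 0
  add_background <- function(t0, t1) {
    ne <- stats::rpois(1L, profile$inter_well_rate * (t1 - t0))
    if (ne == 0L) return(NULL)
    bg <- simulate_well_events("unstained", config = plate$config,
                               n_events = ne,
                               seed = sample.int(2147483646L, 1L))
    bg$time <- sort(stats::runif(ne, t0, t1))
    bg
  }
  for (i in seq_len(n_wells)) {
    bg <- add_background(gap_start, t)
    if (!is.null(bg)) { parts[[length(parts) + 1L]] <- bg
                        truth[[length(truth) + 1L]] <- rep(NA_character_,
                                                           n_events(bg)) }
    tb <- wells[[i]]
    ne <- n_events(tb)
    tb$time <- sort(stats::runif(ne, t, t + profile$sip_seconds))
    win$t_start[i] <- t; win$t_end[i] <- t + profile$sip_seconds
    win$n_events[i] <- ne
    parts[[length(parts) + 1L]] <- tb
    truth[[length(truth) + 1L]] <- rep(wn[i], ne)
    t <- t + profile$sip_seconds
    gap_start <- t
    t <- t + profile$up_time_seconds
    if (i %% profile$shake_every == 0L) t <- t + profile$shake_seconds
    if (i %% profile$rinse_every == 0L)
      t <- t + profile$rinse_cycles * profile$rinse_seconds
  }
  stream_parts <- parts
  truth_flat <- unlist(truth, use.names = FALSE)
  # order the concatenated events by time
  keep_labels <- all(vapply(stream_parts, function(p) !is.null(p$labels),
                            logical(1)))
  exprs <- do.call(rbind, lapply(stream_parts, `[[`, "exprs"))
  time <- unlist(lapply(stream_parts, `[[`, "time"), use.names = FALSE)
  o <- order(time)
  labels <- NULL
  if (keep_labels) {
    labels <- do.call(rbind, lapply(stream_parts, `[[`, "labels"))
    labels <- labels[o, , drop = FALSE]
    rownames(labels) <- NULL
  }
  stream <- event_table(exprs[o, , drop = FALSE], time = time[o],
                        source = "sim:stream", labels = labels)
  list(stream = stream, windows = win, truth_well = truth_flat[o])
}

#' Simulate replicated dose-response readouts from a 4PL curve
#'
#' Responses follow
#' `bottom + (top - bottom) / (1 + 10^((log10(dose) - log10(ic50)) * hill))`
#' (so `hill > 0` is inhibition) plus i.i.d. Gaussian noise.
#'
#' @param ic50 concentration of half-maximal effect (same units as `doses`).
#' @param hill Hill slope.
#' @param top,bottom upper/lower asymptotes (normalized %, DMSO = 100).
#' @param doses positive concentrations.
#' @param noise_sd Gaussian noise SD in response units (%).
#' @param replicates replicates per dose.
#' @param seed integer seed.
#' @param compound_id label carried into the output.
#' @return data.frame `compound_id`, `dose_um`, `replicate`, `response_pct`.
#' @export
simulate_dose_response <- function(ic50, hill = 1, top = 100, bottom = 0,
                                   doses = 30 / 3^(0:7), noise_sd = 5,
                                   replicates = 3, seed = 1L,
                                   compound_id = "cmpd") {
  stopifnot(all(doses > 0), replicates >= 1, ic50 > 0)
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), dose_um = doses,
                      KEEP.OUT.ATTRS = FALSE)
  mu <- fourpl(grid$dose_um, ic50, hill, top, bottom)
  resp <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  data.frame(compound_id = compound_id, dose_um = grid$dose_um,
             replicate = grid$replicate, response_pct = resp,
             stringsAsFactors = FALSE)
}
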