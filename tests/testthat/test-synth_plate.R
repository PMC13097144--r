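test_that("simulate_well_events is deterministic and honors effects", {
  cfg <- fast_config()
  a <- simulate_well_events("compound", compound_effect("X"), cfg, seed = 11)
  b <- simulate_well_events("compound", compound_effect("X"), cfg, seed = 11)
  expect_identical(a$exprs, b$exprs)
  expect_identical(a$labels, b$labels)
  c2 <- simulate_well_events("compound", compound_effect("X"), cfg, seed = 12)
  expect_false(identical(a$exprs, c2$exprs))

  # dead_fraction reduces live-labeled cells by the configured fraction
  d <- simulate_well_events("compound",
                            compound_effect("X", dead_fraction = 0.9),
                            cfg, seed = 5)
  cells <- d$labels$population != "debris"
  p_live <- mean(!d$labels$dead[cells])
  se <- sqrt(0.9 * 0.1 / sum(cells))
  expect_lt(abs(p_live - 0.1), 5 * se)

  # foxp3_multiplier = 0 forces zero FoxP3-stained events
  z <- simulate_well_events("compound",
                            compound_effect("X", foxp3_multiplier = 0),
                            cfg, seed = 5)
  expect_identical(sum(z$labels$foxp3), 0L)

  expect_error(simulate_well_events("mystery_role"), "unknown well role")
})

test_that("role semantics: unstained and CD4-only wells draw negatives", {
  cfg <- fast_config()
  u <- simulate_well_events("unstained", config = cfg, seed = 3)
  expect_false(any(u$labels$cd4))
  expect_false(any(u$labels$foxp3))
  n <- simulate_well_events("cd4_only_negative", config = cfg, seed = 3)
  expect_gt(sum(n$labels$cd4), 0)
  expect_false(any(n$labels$foxp3))
  # stained CD4 events sit far above the unstained background
  s <- cfg$stains$cd4
  expect_gt(median(n$exprs[n$labels$cd4, s$channel]),
            10 * median(u$exprs[, s$channel]))
})

test_that("truth FoxP3 fraction matches configured positive_fraction", {
  cfg <- fast_config(4000)
  w <- simulate_well_events("dmso_positive", config = cfg, seed = 21)
  cd4 <- w$labels$cd4
  p_hat <- mean(w$labels$foxp3[cd4])
  p <- cfg$stains$foxp3$positive_fraction
  se <- sqrt(p * (1 - p) / sum(cd4))
  expect_lt(abs(p_hat - p), 4 * se)
})

test_that("foxp3 multiplier is monotone in the truth labels", {
  cfg <- fast_config()
  fr <- vapply(c(0, 0.3, 1, 2, 5), function(m) {
    w <- simulate_well_events("compound", compound_effect("X", m), cfg,
                              seed = 9)
    mean(w$labels$foxp3[w$labels$cd4])
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("simulate_plate covers the layout and validates effects", {
  lay <- small_plate_layout(6)
  eff <- neutral_effects(lay)
  pl <- simulate_plate(lay, eff, fast_config(400), seed = 2)
  expect_identical(names(pl$wells), lay$well)
  expect_identical(nrow(pl$truth), nrow(lay))
  expect_identical(sum(pl$truth$role == "dmso_positive"), 8L)
  # neutral truth on every control well
  ctrl <- pl$truth$role != "compound"
  expect_true(all(pl$truth$foxp3_multiplier[ctrl] == 1))
  expect_true(all(pl$truth$dead_fraction[ctrl] == 0))
  # different seeds: different events, identical truth table
  pl2 <- simulate_plate(lay, eff, fast_config(400), seed = 3)
  expect_false(identical(pl$wells[[1]]$exprs, pl2$wells[[1]]$exprs))
  expect_identical(pl$truth, pl2$truth)
  expect_error(simulate_plate(lay, eff[-1], fast_config(400)),
               "no compound_effect")
})

test_that("acquisition stream conserves events and respects sip windows", {
  lay <- small_plate_layout(2)
  pl <- simulate_plate(lay, neutral_effects(lay), fast_config(300), seed = 4)
  prof <- acquisition_profile(inter_well_rate = 2)
  st <- simulate_acquisition_stream(pl, prof, seed = 4)
  n_well_events <- sum(vapply(pl$wells, n_events, numeric(1)))
  n_bg <- sum(is.na(st$truth_well))
  expect_identical(n_events(st$stream), as.integer(n_well_events + n_bg))
  expect_true(all(diff(st$stream$time) >= 0))
  # each well's events fall inside its truth window
  for (k in seq_len(nrow(st$windows))) {
    w <- st$windows$well[k]
    tt <- st$stream$time[which(st$truth_well == w)]
    expect_true(all(tt >= st$windows$t_start[k] &
                      tt <= st$windows$t_end[k]))
  }
  # zero background rate -> no events outside windows
  prof0 <- acquisition_profile(inter_well_rate = 1e-12)
  st0 <- simulate_acquisition_stream(pl, prof0, seed = 4)
  expect_identical(sum(is.na(st0$truth_well)), 0L)
})

test_that("stream gap structure reflects shakes and rinses", {
  lay <- small_plate_layout(8)  # 24 wells total -> shakes at 6, rinses at 12
  pl <- simulate_plate(lay, neutral_effects(lay), fast_config(200), seed = 6)
  prof <- acquisition_profile(inter_well_rate = 1e-12)
  st <- simulate_acquisition_stream(pl, prof, seed = 1)
  gaps <- st$windows$t_start[-1] - head(st$windows$t_end, -1)
  base <- prof$up_time_seconds
  after <- seq_len(length(gaps))           # gap i follows well i
  expect_equal(gaps[after %% 12 == 0],
               rep(base + prof$shake_seconds +
                     prof$rinse_cycles * prof$rinse_seconds,
                   sum(after %% 12 == 0)))
  expect_equal(gaps[after %% 6 == 0 & after %% 12 != 0],
               rep(base + prof$shake_seconds,
                   sum(after %% 6 == 0 & after %% 12 != 0)))
  expect_equal(gaps[after %% 6 != 0], rep(base, sum(after %% 6 != 0)))
  expect_equal(st$windows$t_start[1], prof$initial_shake_seconds)
})

test_that("simulate_dose_response matches the 4PL and its noise model", {
  # noiseless: response at dose = ic50 is midway between top and bottom
  d <- simulate_dose_response(ic50 = 2, hill = 1.3, top = 100, bottom = 20,
                              doses = c(2, 0.001, 1e5), noise_sd = 0,
                              replicates = 1, seed = 1)
  expect_equal(d$response_pct[d$dose_um == 2], 60)
  expect_equal(d$response_pct[d$dose_um == 0.001], 100, tolerance = 1e-3)
  expect_equal(d$response_pct[d$dose_um == 1e5], 20, tolerance = 1e-3)
  # replicate scatter ~ noise_sd
  dn <- simulate_dose_response(ic50 = 2, noise_sd = 5, replicates = 200,
                               doses = c(1, 10), seed = 2)
  expect_equal(sd(dn$response_pct[dn$dose_um == 1]), 5, tolerance = 0.15)
})
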