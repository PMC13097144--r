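summary_frame <- function(foxp3, roles = NULL, plate = "p1",
                          fsch = 10000, v450_pos = 2000, v450_neg = 50) {
  n <- length(foxp3)
  if (is.null(roles)) roles <- rep("compound", n)
  data.frame(plate_id = plate, well = paste0("A", seq_len(n)), role = roles,
             compound_id = ifelse(roles == "compound",
                                  paste0("c", seq_len(n)), NA),
             foxp3_pct_cd4 = foxp3, fsch_mfi = fsch,
             v450_mfi_pos = v450_pos, v450_mfi_neg = v450_neg,
             n_foxp3_pos = 100, n_foxp3_neg = 1000,
             stringsAsFactors = FALSE)
}

test_that("call_hits applies the +/-50% rule against the plate DMSO mean", {
  s <- summary_frame(c(8, 2, 6, 5, 5), c(rep("compound", 3),
                                         rep("dmso_positive", 2)))
  h <- call_hits(s)
  expect_equal(h$foxp3_fold[1:3], c(1.6, 0.4, 1.2))
  expect_identical(h$hit_call[1:3], c("up", "down", "none"))
  expect_true(all(is.na(h$hit_call[4:5])))
  # boundary folds are inclusive
  s2 <- summary_frame(c(7.5, 2.5, 5, 5), c("compound", "compound",
                                           "dmso_positive", "dmso_positive"))
  expect_identical(call_hits(s2)$hit_call[1:2], c("up", "down"))
  # log-scale option is symmetric around 1 in log space
  sl <- summary_frame(c(5 / 1.5 - 0.01, 5, 5),
                      c("compound", "dmso_positive", "dmso_positive"))
  expect_identical(call_hits(sl, log_scale = TRUE)$hit_call[1], "down")
  s0 <- summary_frame(c(1, 0, 0), c("compound", "dmso_positive",
                                    "dmso_positive"))
  expect_error(call_hits(s0), "zero")
})

test_that("delta_ratio normalizes to the plate DMSO pool", {
  s <- summary_frame(5, fsch = 20000)
  s <- rbind(s, summary_frame(5, roles = rep("dmso_positive", 3),
                              fsch = 10000))
  s$well <- paste0("A", 1:4)
  d <- delta_ratio(s)
  expect_equal(d$delta_ratio[1], 2)
  expect_equal(d$delta_ratio[2:4], rep(1, 3))  # DMSO wells vs their own pool
})

test_that("toxicity outliers: z-scores match brute force, scopes differ", {
  set.seed(41)
  s <- summary_frame(5, fsch = rnorm(60, 10000, 100))
  s$plate_id <- rep(c("p1", "p2"), each = 30)
  s <- rbind(s, summary_frame(5, roles = rep("dmso_positive", 2),
                              fsch = 10000),
             {x <- summary_frame(5, roles = rep("dmso_positive", 2),
                                 fsch = 10000); x$plate_id <- "p2"; x})
  s$well <- paste0(rep(LETTERS[1:8], each = 8)[seq_len(nrow(s))],
                   seq_len(nrow(s)) %% 24 + 1)
  s$fsch_mfi[3] <- 6000  # one extreme well
  d <- delta_ratio(s)
  t_screen <- toxicity_outliers(d, scope = "screen")
  cmp <- t_screen$role == "compound"
  mu <- mean(t_screen$delta_ratio[cmp]); sdv <- sd(t_screen$delta_ratio[cmp])
  expect_equal(t_screen$tox_z[cmp],
               (t_screen$delta_ratio[cmp] - mu) / sdv, tolerance = 1e-12)
  expect_identical(which(t_screen$toxic), 3L)
  t_plate <- toxicity_outliers(d, scope = "plate")
  expect_identical(which(t_plate$toxic), 3L)
  expect_false(identical(t_screen$tox_z, t_plate$tox_z))
  d0 <- d; d0$delta_ratio[d0$role == "compound"] <- 1
  expect_error(toxicity_outliers(d0), "SD is zero")
})

test_that("v450 stain ratio and autofluorescence grading", {
  s <- summary_frame(rep(5, 20), v450_pos = 5000, v450_neg = 500)
  v <- v450_stain_ratio(s)
  expect_equal(v$v450_ratio, rep(10, 20))
  # equal medians give ratio 1; nonpositive or starved wells: indeterminate
  s$v450_mfi_pos[1] <- s$v450_mfi_neg[1] <- 700
  s$v450_mfi_neg[2] <- -5
  s$n_foxp3_pos[3] <- 5
  v <- v450_stain_ratio(s)
  expect_equal(v$v450_ratio[1], 1)
  expect_true(all(v$v450_indeterminate[2:3]))

  set.seed(43)
  s2 <- summary_frame(rep(5, 40), v450_pos = rnorm(40, 2000, 30),
                      v450_neg = 50)
  s2$v450_mfi_pos[7] <- 2000 + 10 * 30 * sqrt(40)  # >> 3 plate SDs
  v2 <- autofluorescence_flags(v450_stain_ratio(s2))
  expect_identical(v2$autofluor_level[7], "high")
  # a mild negative deviation grades low_moderate
  z <- v2$af_z
  mild <- which(z > -3 & z <= -1)
  expect_true(all(v2$autofluor_level[mild] == "low_moderate"))
  expect_true(all(v2$autofluor_level[z > -1 & z < 3] == "none"))
})

test_that("channel interference profiling flags exactly spiked channels", {
  cfg <- fast_config(2000)
  dmso <- simulate_well_events("unstained", config = cfg, seed = 51)
  one <- simulate_well_events("unstained",
    compound_effect("x", autofluor_additive = c("VL1-A" = 500)),
    cfg, seed = 52)
  p1 <- channel_interference_profile(one, dmso)
  expect_identical(p1$channel[p1$interfered], "VL1-A")
  expect_false("VL1-A" %in% attr(p1, "safe_channels"))

  three <- simulate_well_events("unstained",
    compound_effect("y", autofluor_additive =
                      c("VL1-A" = 500, "VL2-A" = 600, "VL3-A" = 800)),
    cfg, seed = 53)
  p3 <- channel_interference_profile(three, dmso)
  expect_setequal(p3$channel[p3$interfered], c("VL1-A", "VL2-A", "VL3-A"))

  # DMSO vs itself (independent draws): nothing flagged
  dmso2 <- simulate_well_events("unstained", config = cfg, seed = 54)
  p0 <- channel_interference_profile(dmso2, dmso)
  expect_false(any(p0$interfered))
})

test_that("roc_analysis: separation, symmetry, chance level, invariance", {
  perfect <- roc_analysis(c(rep(2, 10), rep(1, 20)),
                          c(rep(TRUE, 10), rep(FALSE, 20)))
  expect_identical(perfect$auc, 1)
  rev <- roc_analysis(-c(rep(2, 10), rep(1, 20)),
                      c(rep(TRUE, 10), rep(FALSE, 20)))
  expect_equal(rev$auc, 0)
  expect_true(all(diff(perfect$tpr) >= 0), all(diff(perfect$fpr) >= 0))

  set.seed(47)
  sc <- rnorm(200); lb <- runif(200) < 0.5
  chance <- roc_analysis(sc, lb)
  expect_lt(abs(chance$auc - 0.5), 0.12)
  # strictly monotone transforms leave the AUC untouched
  expect_equal(roc_analysis(exp(sc), lb)$auc, chance$auc, tolerance = 1e-12)
  expect_error(roc_analysis(sc, rep(TRUE, 200)), "both classes")
})

test_that("viability normalization", {
  expect_equal(normalize_viability(80, 80), 100)
  expect_equal(normalize_viability(40, 80), 50)
  expect_error(normalize_viability(40, 0), "> 0")
})

test_that("triage report compiles candidates and re-test flags", {
  scr <- simulate_screen(n_compounds = 40, modulators_down = 1:2,
                         modulators_up = 3:4, toxic = 5:6, autofluor = 7:8,
                         config = fast_config(1500), seed = 29)
  tr <- triage_screen(scr$summaries, tox_scope = "plate")
  rep <- tr$report
  expect_identical(nrow(rep), 40L)
  cand <- attr(rep, "candidates")
  # all spiked modulators called; spiked toxic/autofluor excluded
  expect_true(all(sprintf("C%04d", 1:4) %in% cand))
  expect_false(any(sprintf("C%04d", 5:6) %in% cand))
  # neutral compounds stay out of the candidate list
  neutral <- sprintf("C%04d", 9:40)
  expect_lte(sum(neutral %in% cand), 1)
  # empty screen -> empty report
  empty <- compile_triage_report(tr$summaries[tr$summaries$role != "compound", ])
  expect_identical(nrow(empty), 0L)
})
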