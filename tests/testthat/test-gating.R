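test_that("polygon gate matches the scalar oracle and keeps boundaries", {
  tb <- tiny_table(300)
  verts <- cbind(c(200, 800, 900, 500, 150), c(100, 150, 700, 900, 600))
  mask <- gate_lymphocytes(tb, verts, channels = c("FSC-A", "SSC-A"))
  oracle <- vapply(seq_len(n_events(tb)), function(i)
    point_in_poly_scalar(tb$exprs[i, "FSC-A"], tb$exprs[i, "SSC-A"],
                         verts[, 1], verts[, 2]), logical(1))
  expect_identical(as.logical(mask), oracle)

  # vertex and edge points are inside; a full-range polygon passes all
  vt <- event_table(cbind(`FSC-A` = c(200, 500), `SSC-A` = c(100, 125)))
  expect_true(all(gate_lymphocytes(vt, verts, c("FSC-A", "SSC-A"))))
  full <- cbind(c(0, 1e6, 1e6, 0), c(0, 0, 1e6, 1e6))
  expect_true(all(gate_lymphocytes(tb, full, c("FSC-A", "SSC-A"))))
  degen <- cbind(c(0, 1, 2), c(0, 1, 2))
  expect_error(gate_lymphocytes(tb, degen, c("FSC-A", "SSC-A")),
               "degenerate")
})

test_that("scatter gates separate simulator populations", {
  w <- simulate_well_events("dmso_positive", config = fast_config(4000),
                            seed = 13)
  lym <- gate_lymphocytes(w)
  deb <- w$labels$population == "debris"
  expect_gte(mean(!lym[deb]), 0.95)            # debris excluded
  sng <- gate_singlets(w)
  single <- w$labels$population == "lymphocyte" & !w$labels$dead
  expect_gte(mean(sng[single]), 0.99)          # singlets retained
  dbl <- w$labels$population == "doublet"
  expect_gte(mean(!sng[dbl]), 0.95)            # doublets excluded
  # an unbounded band is the identity (modulo FSC-A = 0 events)
  expect_true(all(gate_singlets(w, 0, Inf)))
})

test_that("auto_threshold finds the valley and falls back to quantiles", {
  set.seed(31)
  neg <- 10^rnorm(3000, 1.7, 0.3)
  pos <- 10^rnorm(600, 3.3, 0.2)
  lab <- c(rep(FALSE, 3000), rep(TRUE, 600))
  v <- c(neg, pos)
  cut <- auto_threshold(v)
  expect_identical(attr(cut, "method"), "valley")
  miscls <- mean((v >= cut) != lab)
  expect_lte(miscls, 0.02)

  # unimodal input engages the negative-control quantile fall-back
  uni <- 10^rnorm(2000, 2, 0.25)
  cut2 <- auto_threshold(uni, neg_control = neg)
  expect_identical(attr(cut2, "method"), "quantile")
  expect_equal(as.numeric(cut2), quantile(neg, 0.995), ignore_attr = TRUE)
  expect_error(auto_threshold(uni), "negative control")
  expect_error(auto_threshold(rep(5, 500)), "no spread")
  expect_error(auto_threshold(uni[1:50]), ">= 200 events")
})

test_that("gating tree matches per-event brute force exactly", {
  w <- simulate_well_events("dmso_positive", config = fast_config(1000),
                            seed = 17)
  tree <- gate_tree(cd4_cut = 1100, foxp3_cut = 300)
  g <- run_gating_tree(w, tree)
  bf <- brute_force_gate(w, tree)
  for (pop in names(bf)) {
    expect_identical(as.logical(g$masks[[pop]]), bf[[pop]], label = pop)
    # medians agree with a sort-based oracle on the masked events
    st <- g$stats[g$stats$population == pop, ]
    if (st$count > 0)
      expect_identical(unname(st[["median_FSC-H"]]),
                       unname(sorted_median(w$exprs[bf[[pop]], "FSC-H"])))
  }
})

test_that("gate hierarchy invariants hold on simulated wells", {
  for (seed in c(1, 2)) {
    w <- simulate_well_events("dmso_positive", config = fast_config(2000),
                              seed = seed)
    tree <- gate_tree(cd4_cut = 1100, foxp3_cut = 300)
    g <- run_gating_tree(w, tree)
    st <- g$stats
    cnt <- setNames(st$count, st$population)
    expect_true(cnt["lymphocytes"] <= cnt["all"])
    expect_true(cnt["singlets"] <= cnt["lymphocytes"])
    expect_true(cnt["cd4_pos"] <= cnt["singlets"])
    # FoxP3+/- partition CD4+ exactly and disjointly
    expect_identical(cnt[["foxp3_pos"]] + cnt[["foxp3_neg"]],
                     cnt[["cd4_pos"]])
    expect_false(any(g$masks$foxp3_pos & g$masks$foxp3_neg))
    expect_true(all(st$fraction_of_parent >= 0 & st$fraction_of_parent <= 1))
  }
})

test_that("plate-global gates recover the configured truth fractions", {
  lay <- small_plate_layout(4)
  pl <- simulate_plate(lay, neutral_effects(lay), fast_config(3000),
                       seed = 19)
  tree <- fit_plate_gates(pl$wells, lay)
  su <- summarize_plate(pl$wells, lay, tree)
  dm <- su[su$role == "dmso_positive", ]
  p <- fast_config()$stains$foxp3$positive_fraction * 100
  # gated FoxP3% tracks truth within a few binomial SEs (gate bias < 1%)
  expect_lt(abs(mean(dm$foxp3_pct_cd4) - p), 1.0)
  expect_identical(su$n_foxp3_pos + su$n_foxp3_neg, su$n_cd4)
  # insufficient-events flag trips on unstained wells (no CD4+ population)
  expect_true(all(su$insufficient[su$role == "unstained"]))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_gate_tree(tree, f)
  tree2 <- read_gate_tree(f)
  expect_equal(tree2$cd4_cut, tree$cd4_cut)
  expect_equal(tree2$lymph_vertices, tree$lymph_vertices, ignore_attr = TRUE)
})
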