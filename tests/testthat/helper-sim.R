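# Shared fixtures: a down-scaled simulator config for fast unit tests and
# a tiny deterministic event table.

fast_config <- function(n_events = 1500) sim_config(n_events = n_events)

tiny_table <- function(n = 100, seed = 42) {
  set.seed(seed)
  m <- cbind(`FSC-A` = runif(n, 1, 1000), `FSC-H` = runif(n, 1, 1000),
             `SSC-A` = runif(n, 1, 1000), `VL1-A` = rlnorm(n, 4, 1),
             `BL5-A` = rlnorm(n, 5, 1))
  event_table(m, source = "tiny")
}

small_plate_layout <- function(n_compounds = 12) {
  plate_layout_default(compound_ids = sprintf("T%03d", seq_len(n_compounds)))
}

neutral_effects <- function(layout) {
  ids <- layout$compound_id[layout$role == "compound"]
  setNames(lapply(ids, compound_effect), ids)
}

# Brute-force per-event gate evaluation, written independently of
# run_gating_tree: a plain loop over events re-deriving each population.
brute_force_gate <- function(table, tree) {
  n <- n_events(table)
  ex <- table$exprs
  vx <- tree$lymph_vertices[, 1L]; vy <- tree$lymph_vertices[, 2L]
  pops <- list(all = logical(n), lymphocytes = logical(n),
               singlets = logical(n), cd4_pos = logical(n),
               foxp3_pos = logical(n), foxp3_neg = logical(n))
  for (i in seq_len(n)) {
    pops$all[i] <- TRUE
    lym <- point_in_poly_scalar(ex[i, "FSC-A"], ex[i, "SSC-A"], vx, vy)
    pops$lymphocytes[i] <- lym
    r <- ex[i, "FSC-H"] / ex[i, "FSC-A"]
    sng <- lym && ex[i, "FSC-A"] != 0 &&
      r >= tree$singlet_band[1L] && r <= tree$singlet_band[2L]
    pops$singlets[i] <- sng
    cd4 <- sng && ex[i, tree$cd4_channel] >= tree$cd4_cut
    pops$cd4_pos[i] <- cd4
    pops$foxp3_pos[i] <- cd4 && ex[i, tree$foxp3_channel] >= tree$foxp3_cut
    pops$foxp3_neg[i] <- cd4 && ex[i, tree$foxp3_channel] < tree$foxp3_cut
  }
  pops
}

# scalar crossing-number point-in-polygon with boundary-inclusive rule,
# separate from the vectorized implementation under test
point_in_poly_scalar <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cross) <= 1e-9 * (abs(x2 - x1) + abs(y2 - y1) + 1) &&
        px >= min(x1, x2) - 1e-12 && px <= max(x1, x2) + 1e-12 &&
        py >= min(y1, y2) - 1e-12 && py <= max(y1, y2) + 1e-12)
      return(TRUE)
    if ((y1 > py) != (y2 > py) &&
        px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
      inside <- !inside
    j <- i
  }
  inside
}

sorted_median <- function(v) {
  # sort-based median, independent of stats::median internals
  v <- sort(v)
  n <- length(v)
  if (n == 0L) return(NA_real_)
  if (n %% 2L == 1L) v[(n + 1L) / 2L] else mean(v[n / 2L + 0:1])
}
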