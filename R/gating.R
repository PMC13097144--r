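# Hierarchical gating: lymphocytes (scatter polygon) -> singlets
# (FSC-H/FSC-A ratio band) -> CD4+ (1-D threshold) -> FoxP3+/- partition.

#' Point-in-polygon test (boundary counts as inside)
#'
#' Crossing-number algorithm with an explicit on-edge check, vectorized
#' over points.
#'
#' @param x,y point coordinates.
#' @param vx,vy polygon vertices (>= 3, closed implicitly).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  stopifnot(n >= 3L, length(vy) == n)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # collinear and within the segment's bounding box -> on the boundary
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_edge <- on_edge | (abs(cross) <= 1e-9 * (abs(x2 - x1) + abs(y2 - y1) + 1) &
                            x >= pmin(x1, x2) - 1e-12 & x <= pmax(x1, x2) + 1e-12 &
                            y >= pmin(y1, y2) - 1e-12 & y <= pmax(y1, y2) + 1e-12)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < x1 + (y - y1) * (x2 - x1) / (y2 - y1))
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | on_edge
}

check_polygon <- function(vx, vy) {
  if (length(vx) < 3L || length(vx) != length(vy))
    stopf("polygon needs >= 3 (x, y) vertices")
  if (abs(polygon_area(vx, vy)) <= 0)
    stopf("degenerate polygon (zero area)")
  invisible(TRUE)
}

polygon_area <- function(vx, vy) {
  n <- length(vx); j <- c(n, seq_len(n - 1L))
  sum(vx[j] * vy - vx * vy[j]) / 2
}

#' Scatter (lymphocyte) polygon gate
#'
#' @param table an [event_table()].
#' @param vertices 2-column matrix of polygon vertices.
#' @param channels the two channels gated on (default FSC-A vs SSC-A).
#' @return logical event mask (boundary inclusive).
#' @export
gate_lymphocytes <- function(table, vertices = default_lymph_gate(),
                             channels = c("FSC-A", "SSC-A")) {
  vertices <- as.matrix(vertices)
  check_polygon(vertices[, 1L], vertices[, 2L])
  x <- channel_values(table, channels[1L])
  y <- channel_values(table, channels[2L])
  point_in_polygon(x, y, vertices[, 1L], vertices[, 2L])
}

#' Default lymphocyte scatter gate
#'
#' A generous FSC-A/SSC-A polygon that excludes the debris cloud while
#' retaining shrunken (dying) lymphocytes; coordinates are configuration,
#' not measured values.
#'
#' @return 2-column vertex matrix.
#' @export
default_lymph_gate <- function() {
  cbind(c(24000, 140000, 140000, 24000),
        c(4000, 4000, 85000, 85000))
}

#' Singlet gate: FSC-H / FSC-A ratio band
#'
#' Events with `FSC-A == 0` are excluded and counted in the `excluded_zero`
#' attribute of the mask.
#'
#' @param table an [event_table()].
#' @param low,high inclusive ratio bounds (default 0.75..1.25).
#' @return logical event mask with attribute `excluded_zero`.
#' @export
gate_singlets <- function(table, low = 0.75, high = 1.25) {
  if (low >= high) stopf("ratio band requires low < high")
  a <- channel_values(table, "FSC-A")
  h <- channel_values(table, "FSC-H")
  zero <- a == 0
  ratio <- h / a
  mask <- !zero & ratio >= low & ratio <= high
  attr(mask, "excluded_zero") <- sum(zero)
  mask
}

#' Data-driven 1-D threshold between two stained/unstained modes
#'
#' A kernel-density estimate is computed on asinh-transformed values
#' (cofactor `cofactor`, robust to negative post-compensation values). If
#' the density has two clear modes, the cut is the minimum-density valley
#' between the two largest; otherwise the fall-back is a quantile of a
#' designated negative-control sample (default 99.5th percentile).
#'
#' @param values numeric fluorescence values (raw units).
#' @param cofactor asinh cofactor (default 150).
#' @param min_events minimum number of events required (default 200).
#' @param neg_control optional numeric vector of negative-control values
#'   for the quantile fall-back.
#' @param fallback_quantile quantile of `neg_control` used when unimodal.
#' @param min_mode_frac a secondary mode must reach this fraction of the
#'   main mode's density height to count as bimodal (default 0.05).
#' @return the cut value in raw units, with attribute `method`
#'   (`"valley"` or `"quantile"`).
#' @export
auto_threshold <- function(values, cofactor = 150, min_events = 200,
                           neg_control = NULL, fallback_quantile = 0.995,
                           min_mode_frac = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < min_events)
    stopf("auto_threshold needs >= %d events (got %d)", min_events,
          length(values))
  tv <- asinh(values / cofactor)
  if (stats::sd(tv) == 0) stopf("values have no spread")
  d <- stats::density(tv, n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) >= 2L) {
    top2 <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
    if (y[top2[2L]] >= min_mode_frac * y[top2[1L]]) {
      lo <- min(top2); hi <- max(top2)
      valley <- lo + which.min(y[lo:hi]) - 1L
      cut <- sinh(d$x[valley]) * cofactor
      attr(cut, "method") <- "valley"
      return(cut)
    }
  }
  if (is.null(neg_control))
    stopf("density is unimodal and no negative control was supplied")
  cut <- as.numeric(stats::quantile(neg_control, fallback_quantile))
  attr(cut, "method") <- "quantile"
  cut
}

#' Gate tree for the screen's five-population hierarchy
#'
#' Nodes: `all` -> `lymphocytes` (polygon) -> `singlets` (ratio band) ->
#' `cd4_pos` (threshold on the CD4 channel) -> `foxp3_pos` / `foxp3_neg`
#' (threshold partition on the FoxP3/V450 channel).
#'
#' @param lymph_vertices polygon for [gate_lymphocytes()].
#' @param singlet_band length-2 ratio band for [gate_singlets()].
#' @param cd4_cut,foxp3_cut numeric 1-D thresholds (raw units). Events with
#'   value `>= cut` are positive, `< cut` negative, so the FoxP3+/- pair
#'   partitions CD4+ exactly.
#' @param cd4_channel,foxp3_channel channel names.
#' @return a `gate_tree` list.
#' @export
gate_tree <- function(lymph_vertices = default_lymph_gate(),
                      singlet_band = c(0.75, 1.25),
                      cd4_cut, foxp3_cut,
                      cd4_channel = "BL5-A", foxp3_channel = "VL1-A") {
  structure(list(lymph_vertices = as.matrix(lymph_vertices),
                 singlet_band = singlet_band,
                 cd4_cut = as.numeric(cd4_cut),
                 foxp3_cut = as.numeric(foxp3_cut),
                 cd4_channel = cd4_channel, foxp3_channel = foxp3_channel),
            class = "gate_tree")
}

#' Serialize / load a gate tree (YAML)
#'
#' @param tree a [gate_tree()].
#' @param path YAML path.
#' @export
write_gate_tree <- function(tree, path) {
  yaml::write_yaml(list(
    lymph_vertices = apply(tree$lymph_vertices, 1L, as.numeric,
                           simplify = FALSE),
    singlet_band = tree$singlet_band, cd4_cut = tree$cd4_cut,
    foxp3_cut = tree$foxp3_cut, cd4_channel = tree$cd4_channel,
    foxp3_channel = tree$foxp3_channel), path)
  invisible(path)
}

#' @rdname write_gate_tree
#' @export
read_gate_tree <- function(path) {
  y <- yaml::read_yaml(path)
  gate_tree(do.call(rbind, y$lymph_vertices), unlist(y$singlet_band),
            y$cd4_cut, y$foxp3_cut, y$cd4_channel, y$foxp3_channel)
}

#' Evaluate the gate hierarchy and per-population statistics
#'
#' @param table an [event_table()].
#' @param tree a [gate_tree()].
#' @param min_events populations with fewer events than this floor are
#'   flagged `insufficient` (their medians are still reported, `NA` when
#'   empty).
#' @return list with `masks` (named list of logical event masks) and
#'   `stats`: data.frame population, parent, count, fraction_of_parent,
#'   fraction_of_all, insufficient, plus `median_<channel>` columns.
#' @export
run_gating_tree <- function(table, tree, min_events = 100) {
  stopifnot(inherits(tree, "gate_tree"))
  n <- n_events(table)
  masks <- list()
  masks$all <- rep(TRUE, n)
  masks$lymphocytes <- gate_lymphocytes(table, tree$lymph_vertices)
  sing <- gate_singlets(table, tree$singlet_band[1L], tree$singlet_band[2L])
  masks$singlets <- masks$lymphocytes & as.logical(sing)
  cd4v <- channel_values(table, tree$cd4_channel)
  masks$cd4_pos <- masks$singlets & cd4v >= tree$cd4_cut
  fxv <- channel_values(table, tree$foxp3_channel)
  masks$foxp3_pos <- masks$cd4_pos & fxv >= tree$foxp3_cut
  masks$foxp3_neg <- masks$cd4_pos & fxv < tree$foxp3_cut
  parents <- c(all = NA, lymphocytes = "all", singlets = "lymphocytes",
               cd4_pos = "singlets", foxp3_pos = "cd4_pos",
               foxp3_neg = "cd4_pos")
  ch <- channels(table)
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    cnt <- sum(m)
    par <- parents[[nm]]
    pcnt <- if (is.na(par)) cnt else sum(masks[[par]])
    med <- if (cnt > 0)
      apply(table$exprs[m, , drop = FALSE], 2L, stats::median)
    else rep(NA_real_, length(ch))
    row <- data.frame(population = nm, parent = par, count = cnt,
                      fraction_of_parent = if (pcnt > 0) cnt / pcnt else NA_real_,
                      fraction_of_all = cnt / n,
                      insufficient = cnt < min_events,
                      stringsAsFactors = FALSE)
    med_df <- as.data.frame(as.list(med))
    names(med_df) <- paste0("median_", ch)
    cbind(row, med_df)
  })
  list(masks = masks, stats = do.call(rbind, rows))
}

#' Fit plate-global CD4 and FoxP3 thresholds from control wells
#'
#' Mirrors manual plate analysis: one threshold per plate per marker. The
#' CD4 cut is fit on pooled DMSO-positive singlet events; the FoxP3 cut on
#' their CD4+ events, using pooled CD4-only wells as the negative control
#' for the quantile fall-back.
#'
#' @param wells named list of per-well [event_table()]s.
#' @param layout the `plate_layout`.
#' @param lymph_vertices,singlet_band upstream scatter gates.
#' @param cd4_channel,foxp3_channel channel names.
#' @param ... passed to [auto_threshold()].
#' @return a [gate_tree()] with plate-global thresholds.
#' @export
fit_plate_gates <- function(wells, layout,
                            lymph_vertices = default_lymph_gate(),
                            singlet_band = c(0.75, 1.25),
                            cd4_channel = "BL5-A", foxp3_channel = "VL1-A",
                            ...) {
  layout <- validate_plate_layout(as.data.frame(layout))
  pick <- function(role) layout$well[layout$role == role]
  dmso <- pick("dmso_positive")
  if (!length(dmso)) stopf("no dmso_positive wells to fit gates on")
  pool <- bind_events(wells[dmso], source = "pooled_dmso")
  lym <- gate_lymphocytes(pool, lymph_vertices)
  sng <- lym & as.logical(gate_singlets(pool, singlet_band[1L],
                                        singlet_band[2L]))
  cd4v <- channel_values(pool, cd4_channel)[sng]
  cd4_cut <- auto_threshold(cd4v, ...)
  cd4pos <- sng & channel_values(pool, cd4_channel) >= cd4_cut
  fxv <- channel_values(pool, foxp3_channel)[cd4pos]
  neg <- NULL
  cd4only <- pick("cd4_only_negative")
  if (length(cd4only)) {
    npool <- bind_events(wells[cd4only], source = "pooled_cd4only")
    nlym <- gate_lymphocytes(npool, lymph_vertices)
    nsng <- nlym & as.logical(gate_singlets(npool, singlet_band[1L],
                                            singlet_band[2L]))
    ncd4 <- nsng & channel_values(npool, cd4_channel) >= cd4_cut
    neg <- channel_values(npool, foxp3_channel)[ncd4]
  }
  foxp3_cut <- auto_threshold(fxv, neg_control = neg, ...)
  gate_tree(lymph_vertices, singlet_band, cd4_cut, foxp3_cut,
            cd4_channel, foxp3_channel)
}
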