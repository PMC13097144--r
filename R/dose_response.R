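# Dose-response validation: DMSO normalization and log(inhibitor) vs
# normalized-response four-parameter logistic (4PL) fitting.

#' Four-parameter logistic curve
#'
#' `bottom + (top - bottom) / (1 + 10^((log10(dose) - log10(ic50)) * hill))`.
#' With `hill > 0` the response decreases with dose (inhibition) and equals
#' `(top + bottom) / 2` at `dose = ic50`.
#'
#' @param dose positive concentrations.
#' @param ic50,hill,top,bottom curve parameters.
#' @return predicted responses.
#' @export
fourpl <- function(dose, ic50, hill, top, bottom) {
  bottom + (top - bottom) / (1 + 10^((log10(dose) - log10(ic50)) * hill))
}

#' Normalize a FoxP3 readout to the DMSO control (set to 100%)
#'
#' @param foxp3_pct_compound readout of the compound-treated sample(s).
#' @param foxp3_pct_dmso readout of the DMSO control (> 0).
#' @return `100 * compound / dmso`.
#' @export
normalize_response <- function(foxp3_pct_compound, foxp3_pct_dmso) {
  if (any(foxp3_pct_dmso <= 0)) stopf("DMSO readout must be > 0")
  100 * foxp3_pct_compound / foxp3_pct_dmso
}

#' Fit a log(inhibitor) vs normalized-response curve and estimate the IC50
#'
#' Least-squares fit of [fourpl()] on the log10-dose axis by bounded
#' quasi-Newton (L-BFGS-B) from five deterministic starts derived from the
#' data quantiles; the best residual sum of squares wins, ties broken by
#' the smaller IC50. `model = "variable_slope"` (default) frees all four
#' parameters with asymptotes bounded in `asymptote_bounds`;
#' `model = "fixed_asymptotes"` pins `top = 100`, `bottom = 0` (the
#' normalized-response convention).
#'
#' A series with no dose-dependent signal (response range below
#' `flat_tol`, or a fit with `top - bottom` below it) is reported as not
#' converged with an explanatory diagnostic, and no IC50 is returned.
#'
#' @param series data.frame with columns `dose_um` and `response_pct` (one
#'   row per replicate measurement), e.g. from [simulate_dose_response()].
#' @param model `"variable_slope"` or `"fixed_asymptotes"`.
#' @param asymptote_bounds bounds for top and bottom (default `c(0, 120)`).
#' @param hill_bounds bounds for the Hill slope (default `c(0.1, 10)`).
#' @param flat_tol minimal response span treated as signal (default 5, in
#'   response units).
#' @return a `fourpl_fit` list: `ic50`, `hill`, `top`, `bottom`, `rss`,
#'   `converged`, `diagnostics`.
#' @export
fit_log_inhibitor <- function(series,
                              model = c("variable_slope",
                                        "fixed_asymptotes"),
                              asymptote_bounds = c(0, 120),
                              hill_bounds = c(0.1, 10),
                              flat_tol = 5) {
  model <- match.arg(model)
  need <- c("dose_um", "response_pct")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stopf("series missing column(s): %s", paste(miss, collapse = ", "))
  dose <- series$dose_um
  resp <- series$response_pct
  ok <- is.finite(dose) & is.finite(resp) & dose > 0
  dose <- dose[ok]; resp <- resp[ok]
  if (length(unique(dose)) < 4L)
    stopf("need >= 4 distinct positive doses (got %d)",
          length(unique(dose)))
  ld <- log10(dose)
  fail <- function(reason) structure(
    list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
         bottom = NA_real_, rss = NA_real_, converged = FALSE,
         model = model, diagnostics = reason), class = "fourpl_fit")
  if (diff(range(resp)) < flat_tol)
    return(fail("flat response series: no dose-dependent signal"))

  # per-dose means guide the starting values
  mu <- tapply(resp, ld, mean)
  lds <- as.numeric(names(mu))
  top0 <- as.numeric(stats::quantile(resp, 0.95))
  bot0 <- as.numeric(stats::quantile(resp, 0.05))
  half <- (top0 + bot0) / 2
  l50_0 <- lds[which.min(abs(mu - half))]
  l50_starts <- unique(c(l50_0, stats::quantile(ld, c(0.25, 0.5, 0.75)),
                         mean(range(ld))))[1:5]
  l50_starts <- l50_starts[!is.na(l50_starts)]
  l50_bounds <- c(min(ld) - 2, max(ld) + 2)

  obj_var <- function(p)
    sum((resp - fourpl(10^ld, 10^p[1L], p[2L], p[3L], p[4L]))^2)
  obj_fix <- function(p)
    sum((resp - fourpl(10^ld, 10^p[1L], p[2L], 100, 0))^2)
  best <- NULL
  for (s in l50_starts) {
    fit <- tryCatch({
      if (model == "variable_slope")
        stats::optim(c(s, 1, top0, bot0), obj_var, method = "L-BFGS-B",
                     lower = c(l50_bounds[1L], hill_bounds[1L],
                               asymptote_bounds[1L], asymptote_bounds[1L]),
                     upper = c(l50_bounds[2L], hill_bounds[2L],
                               asymptote_bounds[2L], asymptote_bounds[2L]),
                     control = list(maxit = 500L, factr = 1e4))
      else
        stats::optim(c(s, 1), obj_fix, method = "L-BFGS-B",
                     lower = c(l50_bounds[1L], hill_bounds[1L]),
                     upper = c(l50_bounds[2L], hill_bounds[2L]),
                     control = list(maxit = 500L, factr = 1e4))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    take <- is.null(best) || fit$value < best$value - 1e-12 ||
      (abs(fit$value - best$value) <= 1e-12 && fit$par[1L] < best$par[1L])
    if (take) best <- fit
  }
  if (is.null(best)) return(fail("all optimizer starts failed"))
  p <- best$par
  # Gauss-Newton polish from the quasi-Newton optimum (tightens noiseless
  # recovery well below optim's stopping tolerance); kept only on success
  polished <- tryCatch({
    df <- data.frame(ld = ld, resp = resp)
    if (model == "variable_slope") {
      nf <- stats::nls(resp ~ bot + (top - bot) / (1 + 10^((ld - l50) * h)),
                       data = df,
                       start = list(l50 = p[1L], h = p[2L], top = p[3L],
                                    bot = p[4L]),
                       lower = c(l50_bounds[1L], hill_bounds[1L],
                                 asymptote_bounds[1L], asymptote_bounds[1L]),
                       upper = c(l50_bounds[2L], hill_bounds[2L],
                                 asymptote_bounds[2L], asymptote_bounds[2L]),
                       algorithm = "port",
                       control = stats::nls.control(warnOnly = FALSE,
                                                    scaleOffset = 1))
      list(par = as.numeric(stats::coef(nf)),
           value = sum(stats::resid(nf)^2))
    } else {
      nf <- stats::nls(resp ~ 0 + 100 / (1 + 10^((ld - l50) * h)),
                       data = df, start = list(l50 = p[1L], h = p[2L]),
                       lower = c(l50_bounds[1L], hill_bounds[1L]),
                       upper = c(l50_bounds[2L], hill_bounds[2L]),
                       algorithm = "port",
                       control = stats::nls.control(warnOnly = FALSE,
                                                    scaleOffset = 1))
      list(par = as.numeric(stats::coef(nf)),
           value = sum(stats::resid(nf)^2))
    }
  }, error = function(e) NULL)
  if (!is.null(polished) && polished$value <= best$value) {
    best$par <- polished$par
    best$value <- polished$value
    best$convergence <- 0L
  }
  p <- best$par
  top <- if (model == "variable_slope") p[3L] else 100
  bottom <- if (model == "variable_slope") p[4L] else 0
  if (bottom > top) { tmp <- top; top <- bottom; bottom <- tmp }
  if (top - bottom < flat_tol)
    return(fail("fitted span below flat_tol: IC50 indeterminate"))
  structure(list(ic50 = 10^p[1L], hill = p[2L], top = top, bottom = bottom,
                 rss = best$value, converged = best$convergence == 0L,
                 model = model,
                 diagnostics = sprintf("optim convergence code %d",
                                       best$convergence)),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (isTRUE(x$converged))
    cat(sprintf(
      "<fourpl_fit %s> IC50 = %.4g, hill = %.3g, top = %.3g, bottom = %.3g (RSS %.3g)\n",
      x$model, x$ic50, x$hill, x$top, x$bottom, x$rss))
  else
    cat(sprintf("<fourpl_fit %s> not converged: %s\n", x$model,
                x$diagnostics))
  invisible(x)
}

#' Profile-likelihood confidence interval for the IC50
#'
#' Profiles the residual sum of squares over a log10-IC50 grid, refitting
#' the remaining parameters at each point, and inverts the F-test
#' `RSS(ic50) / RSS_min <= 1 + F / (n - p)` at the requested level.
#'
#' @param series the data passed to [fit_log_inhibitor()].
#' @param fit the resulting `fourpl_fit`.
#' @param level confidence level (default 0.95).
#' @param grid_points points on the log10-IC50 grid (default 81).
#' @param ... further arguments passed through to [fit_log_inhibitor()].
#' @return length-2 numeric (lower, upper), possibly infinite at the ends
#'   of the searched grid.
#' @export
ic50_profile_ci <- function(series, fit, level = 0.95, grid_points = 81,
                            ...) {
  stopifnot(inherits(fit, "fourpl_fit"), isTRUE(fit$converged))
  dose <- series$dose_um; resp <- series$response_pct
  ok <- is.finite(dose) & is.finite(resp) & dose > 0
  dose <- dose[ok]; resp <- resp[ok]
  n <- length(resp)
  p_free <- if (fit$model == "variable_slope") 4L else 2L
  ld <- log10(dose)
  grid <- seq(min(ld) - 2, max(ld) + 2, length.out = grid_points)
  crit <- 1 + stats::qf(level, 1L, n - p_free) / (n - p_free)
  rss_at <- vapply(grid, function(l50) {
    obj <- function(q) {
      top <- if (fit$model == "variable_slope") q[2L] else 100
      bot <- if (fit$model == "variable_slope") q[3L] else 0
      sum((resp - fourpl(dose, 10^l50, q[1L], top, bot))^2)
    }
    q0 <- if (fit$model == "variable_slope")
      c(fit$hill, fit$top, fit$bottom) else fit$hill
    o <- stats::optim(q0, obj, method = "L-BFGS-B",
                      lower = if (fit$model == "variable_slope")
                        c(0.1, 0, 0) else 0.1,
                      upper = if (fit$model == "variable_slope")
                        c(10, 120, 120) else 10)
    o$value
  }, numeric(1))
  inside <- rss_at <= crit * fit$rss
  if (!any(inside)) return(c(NA_real_, NA_real_))
  c(10^min(grid[inside]), 10^max(grid[inside]))
}

#' Normalize a Treg-suppression proliferation readout
#'
#' The proliferation readout (% CellTrace-diluted cells among live) of a
#' coculture condition is normalized to the effector-only control.
#'
#' @param pct_proliferated condition readout, in `[0, 100]`.
#' @param teff_only_reference effector-only readout (> 0).
#' @return data.frame `pct_proliferated`, `normalized_to_teff_only`.
#' @export
proliferation_readout <- function(pct_proliferated, teff_only_reference) {
  if (any(teff_only_reference <= 0))
    stopf("Teff-only reference must be > 0")
  if (any(pct_proliferated < 0 | pct_proliferated > 100))
    stopf("pct_proliferated must be in [0, 100]")
  data.frame(pct_proliferated = pct_proliferated,
             normalized_to_teff_only =
               100 * pct_proliferated / teff_only_reference)
}

#' Read a dose-response CSV and fit every compound
#'
#' Input columns: `compound_id`, `dose_um`, `replicate`, `response_pct`.
#'
#' @param path CSV path.
#' @param ... passed to [fit_log_inhibitor()].
#' @return data.frame of fit parameters, one row per compound.
#' @export
fit_dose_response_csv <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$compound_id)
  rows <- lapply(ids, function(id) {
    f <- fit_log_inhibitor(df[df$compound_id == id, , drop = FALSE], ...)
    data.frame(compound_id = id, ic50_um = f$ic50, hill = f$hill,
               top = f$top, bottom = f$bottom, rss = f$rss,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
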