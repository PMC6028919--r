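#' Fit a phosphate standard curve
#'
#' Ordinary least-squares line `absorbance = slope * concentration +
#' intercept` through the calibration points (e.g. an inorganic-phosphate
#' dilution series read at 360 nm), exposing the inverse map used to
#' convert assay absorbances to released-phosphate concentrations.
#'
#' @param concentrations phosphate concentrations (any consistent unit).
#' @param absorbances matched absorbance readings; at least two distinct
#'   concentrations are required.
#' @return A `StandardCurve` with `slope`, `intercept`, `residual_sd`, `n`.
#' @examples
#' sc <- fit_standard_curve(c(0, 100), c(0.1, 1.1))
#' sc$slope                       # 0.01
#' invert_absorbance(sc, 0.6)     # 50
#' @export
fit_standard_curve <- function(concentrations, absorbances) {
  if (length(concentrations) != length(absorbances))
    stopf("concentrations and absorbances must have equal length")
  if (length(unique(concentrations)) < 2)
    stopf("need at least two distinct concentrations")
  fit <- lm(absorbances ~ concentrations)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stopf("standard curve slope must be positive (got %.4g)", slope)
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 residual_sd = sqrt(mean(fit$residuals^2)),
                 n = length(absorbances)),
            class = "StandardCurve")
}

#' @export
print.StandardCurve <- function(x, ...) {
  cat(sprintf("StandardCurve: A = %.4g * conc + %.4g (n = %d, rms = %.3g)\n",
              x$slope, x$intercept, x$n, x$residual_sd))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param curve a `StandardCurve`.
#' @param absorbance absorbance value(s) to invert.
#' @export
invert_absorbance <- function(curve, absorbance) {
  stopifnot(inherits(curve, "StandardCurve"))
  (absorbance - curve$intercept) / curve$slope
}

#' Phosphate-release rate from an absorbance time series
#'
#' Converts absorbances to phosphate concentration via the standard curve
#' and fits an OLS slope over the linear phase, operationalized as a fixed
#' window covering the first `window` seconds (default 600 s = 10 min; no
#' automatic linearity detection). The rate is invariant to a constant
#' absorbance blank, since the curve's intercept shift cancels in the
#' slope.
#'
#' @param time_s strictly increasing sampling times in seconds (the assay
#'   convention is a reading every 30 s for 90 min).
#' @param a360 matched absorbance readings.
#' @param curve a [fit_standard_curve()] result.
#' @param window linear-phase window length in seconds; must contain at
#'   least 3 samples.
#' @param enzyme_conc optional enzyme (complex) concentration in the same
#'   concentration unit; if given, the rate is also returned per enzyme
#'   (unit 1/s).
#' @return List with `rate` (concentration per second), `n_points`, and
#'   `rate_per_enzyme` when `enzyme_conc` is supplied.
#' @export
atpase_rate <- function(time_s, a360, curve, window = 600,
                        enzyme_conc = NULL) {
  stopifnot(inherits(curve, "StandardCurve"))
  if (length(time_s) != length(a360))
    stopf("time_s and a360 must have equal length")
  if (is.unsorted(time_s, strictly = TRUE))
    stopf("time_s must be strictly increasing")
  sel <- time_s <= window
  if (sum(sel) < 3)
    stopf("linear-phase window [0, %g s] contains %d samples; need >= 3",
          window, sum(sel))
  conc <- invert_absorbance(curve, a360[sel])
  t <- time_s[sel]
  fit <- lm(conc ~ t)
  out <- list(rate = unname(coef(fit)[2]), n_points = sum(sel))
  if (!is.null(enzyme_conc)) {
    if (enzyme_conc <= 0) stopf("enzyme_conc must be > 0")
    out$rate_per_enzyme <- out$rate / enzyme_conc
  }
  out
}

#' Rates for a table of kinetics traces, with replicate aggregation
#'
#' Takes long-format trace data (one row per reading) and returns one rate
#' per well plus the per-condition replicate mean and SD.
#'
#' @param traces data frame with columns `well`, `condition`, `time_s`,
#'   `a360`.
#' @param curve a [fit_standard_curve()] result.
#' @param window linear-phase window in seconds (see [atpase_rate()]).
#' @param enzyme_conc optional enzyme concentration (see [atpase_rate()]).
#' @return List with `wells` (data frame `well`, `condition`, `rate`) and
#'   `conditions` (data frame `condition`, `mean_rate`, `sd_rate`, `n`).
#' @export
atpase_rates <- function(traces, curve, window = 600, enzyme_conc = NULL) {
  need <- c("well", "condition", "time_s", "a360")
  if (!all(need %in% names(traces)))
    stopf("traces need columns %s", paste(need, collapse = ", "))
  wells <- do.call(rbind, lapply(split(traces, traces$well), function(tr) {
    tr <- tr[order(tr$time_s), , drop = FALSE]
    r <- atpase_rate(tr$time_s, tr$a360, curve, window, enzyme_conc)
    data.frame(well = tr$well[1], condition = tr$condition[1],
               rate = r$rate, stringsAsFactors = FALSE)
  }))
  rownames(wells) <- NULL
  conditions <- do.call(rbind, lapply(split(wells, wells$condition),
                                      function(w) {
    data.frame(condition = w$condition[1], mean_rate = mean(w$rate),
               sd_rate = if (nrow(w) > 1) sd(w$rate) else NA_real_,
               n = nrow(w), stringsAsFactors = FALSE)
  }))
  rownames(conditions) <- NULL
  list(wells = wells, conditions = conditions)
}
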