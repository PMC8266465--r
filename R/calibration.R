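# External-standard calibration, LOD/LOQ and the method-validation metrics
# (precision, accuracy, stability, repeatability).

#' Relative standard deviation (percent)
#'
#' Uses the n-1 sample standard deviation, the estimator that reproduces the
#' published validation tables.
#'
#' @param x Numeric vector, `n >= 2`.
#' @return `100 * sd(x) / mean(x)`.
#' @export
rsd_pct <- function(x) {
  stopifnot(length(x) >= 2)
  m <- mean(x)
  if (m == 0) {
    stop(structure(
      class = c("gq_undefined_rsd", "error", "condition"),
      list(message = "RSD undefined: mean is zero", call = sys.call())
    ))
  }
  100 * stats::sd(x) / m
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area on concentration (unweighted by
#' default; `weights = "1/x"` weights each point by the inverse
#' concentration). r-squared is the squared Pearson correlation of fitted
#' and observed areas.
#'
#' @param conc Concentrations (ng/mL), at least three distinct values.
#' @param area Peak areas.
#' @param analyte Optional analyte name.
#' @param range Optional `c(low, high)` validated range carried into the
#'   curve (ng/mL) and used by [quantify_esm()] for range flags.
#' @param weights `"none"` or `"1/x"`.
#' @return An object of class `calibration_curve`: list with `analyte`,
#'   `slope`, `intercept`, `r2`, `n`, `range`.
#' @export
fit_curve <- function(conc, area, analyte = NA_character_, range = NULL,
                      weights = c("none", "1/x")) {
  weights <- match.arg(weights)
  stopifnot(length(conc) == length(area))
  if (length(unique(conc)) < 3) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  w <- if (weights == "1/x") 1 / conc else NULL
  fit <- stats::lm(area ~ conc, weights = w)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) warning("fitted calibration slope is not positive")
  r2 <- stats::cor(stats::fitted(fit), area)^2
  structure(
    list(analyte = analyte, slope = slope,
         intercept = unname(stats::coef(fit)[1]), r2 = r2,
         n = length(conc), range = range),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: area = %.4g * C %+.4g, r2 = %.4f (n = %d)\n",
              x$analyte, x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Peak height per unit area for a Gaussian peak
#'
#' A Gaussian of area A and width sigma has apex height
#' `A / (sigma * sqrt(2 * pi))`; this factor converts calibration areas into
#' predicted apex heights for S/N-based detection limits.
#'
#' @param sigma Peak width (minutes).
#' @return Height per unit area (1/minutes).
#' @export
height_per_area <- function(sigma = 0.02) {
  stopifnot(sigma > 0)
  1 / (sigma * sqrt(2 * pi))
}

#' Detection and quantification limits from predicted S/N
#'
#' The LOD is the concentration whose predicted apex height equals 3 times
#' the baseline noise, the LOQ the concentration at 10 times the noise;
#' their ratio is 10/3 by construction. Predicted height uses the
#' proportional part of the calibration law (the peak signal), so
#' `lod = 3 * noise / (height_per_area * slope)`.
#'
#' @param curve A [fit_curve()] result (or any list with `slope`).
#' @param noise Baseline noise level (intensity units).
#' @param hpa Height-per-area factor of the peak model
#'   (see [height_per_area()]).
#' @return List with `lod` and `loq` in ng/mL.
#' @export
lod_loq <- function(curve, noise, hpa = height_per_area()) {
  stopifnot(noise > 0, hpa > 0)
  if (curve$slope <= 0) stop("nonpositive slope", call. = FALSE)
  lod <- 3 * noise / (hpa * curve$slope)
  list(lod = lod, loq = 10 / 3 * lod)
}

#' Simulated S/N at a given concentration
#'
#' Empirical cross-check of the S/N-based limits: generates a
#' single-analyte run at the given concentration (proportional response)
#' with the configured baseline noise and returns the measured peak S/N.
#'
#' @param analyte One-row analyte tibble.
#' @param conc Concentration (ng/mL).
#' @param config A [synthetic_config()] with `baseline_sd > 0`.
#' @param rt_window Integration half-window (minutes).
#' @return Measured S/N of the integrated peak.
#' @export
simulated_snr <- function(analyte, conc, config, rt_window = 0.12) {
  stopifnot(config$baseline_sd > 0)
  config$zero_intercept <- TRUE
  run <- make_sample_run(analyte, stats::setNames(conc, analyte$name), config,
                         tag = paste0("snr", conc))
  pk <- measure_run(run, analyte, rt_window = rt_window)
  pk$snr
}

#' Back-calculate concentration from a calibration curve
#'
#' `(area - intercept) / slope`. Values outside the curve's validated range
#' (when the curve carries one), including negative concentrations, are
#' reported as-is with a warning — never clamped silently.
#'
#' @param area Peak area(s).
#' @param curve A [fit_curve()] result.
#' @return Concentration(s) in ng/mL.
#' @export
quantify_esm <- function(area, curve) {
  conc <- (area - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("negative back-calculated concentration(s)")
  } else if (!is.null(curve$range) &&
             any(conc < curve$range[1] | conc > curve$range[2])) {
    warning("concentration(s) outside the validated range")
  }
  conc
}

#' Precision and accuracy of a replicate series
#'
#' Precision is the percent RSD of the measured values (n-1 denominator);
#' accuracy is the percent relative error of their mean against the target,
#' reported as an absolute value.
#'
#' @param measured Replicate measured concentrations, `n >= 2`.
#' @param target Nominal (true) concentration.
#' @return List with `rsd` and `re` (both percent).
#' @export
precision_accuracy <- function(measured, target) {
  stopifnot(length(measured) >= 2, target > 0)
  list(rsd = rsd_pct(measured), re = 100 * abs(mean(measured) - target) / target)
}

#' Stability of a timepoint series
#'
#' Percent RSD of peak areas across storage timepoints (same estimator as
#' precision).
#'
#' @param areas Areas measured at successive timepoints (e.g. 0, 2, 6, 12,
#'   24, 48 h), at least two.
#' @return RSD in percent.
#' @export
stability_series <- function(areas) {
  if (length(areas) < 2) stop("need at least 2 timepoints", call. = FALSE)
  rsd_pct(areas)
}

#' Simulated method validation
#'
#' Emulates the validation protocol on synthetic data: six replicate
#' injections of a mixed standard for precision/accuracy, six independent
#' preparations for repeatability, and one injection per storage timepoint
#' for stability. Measured concentrations come from an external-standard
#' curve fitted to a simulated serial-dilution series.
#'
#' @param library Analyte library.
#' @param config A [synthetic_config()]; its `area_cv` drives the dispersion.
#' @param sample_frac Fraction of each analyte's range top used as the test
#'   concentration.
#' @param n_rep Replicates for precision and repeatability.
#' @param timepoints Storage timepoints (h) for stability.
#' @param factors Dilution factors of the calibration series.
#' @return A tibble: `name`, `precision_rsd`, `accuracy_re`,
#'   `stability_rsd`, `repeatability_rsd` (all percent).
#' @export
validate_method <- function(library, config = synthetic_config(area_cv = 0.02),
                            sample_frac = 0.2, n_rep = 6,
                            timepoints = c(0, 2, 6, 12, 24, 48),
                            factors = c(0.1, 0.2, 0.4, 0.7, 1)) {
  concs <- stats::setNames(sample_frac * library$range_high, library$name)

  # calibration series (one injection per level)
  series <- make_standard_series(library, dilution_series(library, factors),
                                 config, tag = "val_std")
  areas <- lapply(series, measure_run, library = library)
  curves <- lapply(seq_len(nrow(library)), function(i) {
    fit_curve(
      conc = vapply(series, function(r) r$truth$conc[i], numeric(1)),
      area = vapply(areas, function(a) a$area[i], numeric(1)),
      analyte = library$name[i],
      range = c(library$range_low[i], library$range_high[i])
    )
  })

  measure_concs <- function(tag) {
    run <- make_sample_run(library, concs, config, tag = tag)
    a <- measure_run(run, library)
    vapply(seq_len(nrow(library)),
           function(i) suppressWarnings(quantify_esm(a$area[i], curves[[i]])),
           numeric(1))
  }

  prec <- sapply(seq_len(n_rep), function(r) measure_concs(sprintf("prec%02d", r)))
  repe <- sapply(seq_len(n_rep), function(r) measure_concs(sprintf("repe%02d", r)))
  stab <- sapply(seq_along(timepoints), function(ti) {
    run <- make_sample_run(library, concs, config,
                           tag = sprintf("stab_t%02d", ti))
    measure_run(run, library)$area
  })

  tibble::tibble(
    name = library$name,
    precision_rsd = apply(prec, 1, rsd_pct),
    accuracy_re = vapply(seq_len(nrow(library)), function(i) {
      precision_accuracy(prec[i, ], concs[i])$re
    }, numeric(1)),
    stability_rsd = apply(stab, 1, rsd_pct),
    repeatability_rsd = apply(repe, 1, rsd_pct)
  )
}
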