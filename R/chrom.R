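# Extracted-ion chromatograms, peak integration, noise / signal-to-noise
# estimation and relative-retention-time peak localisation.
#
# Conventions: time in minutes, windows are closed intervals, areas are
# trapezoidal integrals of the baseline-subtracted intensity
# (intensity * minutes). The baseline is the median of the off-peak region;
# noise is its standard deviation. Peak bounds descend from the apex until
# the intensity falls below baseline + k * noise.

#' Construct an extracted ion chromatogram
#'
#' @param time Strictly increasing time vector (minutes).
#' @param intensity Nonnegative intensity vector of equal length.
#' @param mz Target m/z of the channel (Da), or `NA`.
#' @param ppm Extraction tolerance used (ppm), or `NA`.
#' @return An object of class `xic`.
#' @export
xic <- function(time, intensity, mz = NA_real_, ppm = NA_real_) {
  stopifnot(length(time) == length(intensity), length(time) >= 2,
            all(diff(time) > 0), all(intensity >= 0))
  structure(list(time = time, intensity = intensity, mz = mz, ppm = ppm),
            class = "xic")
}

#' @export
print.xic <- function(x, ...) {
  cat(sprintf("<xic> m/z %.4f (%s ppm), %d points, %.2f-%.2f min\n",
              x$mz, format(x$ppm), length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Extract an ion chromatogram from a run
#'
#' For channelised synthetic runs, returns the channel whose m/z lies within
#' `ppm` of the query; when several qualify the nearest is taken. A missing
#' channel raises an error of class `gq_no_channel` rather than returning a
#' silent zero trace.
#'
#' @param run A `synthetic_run` (see [make_sample_run()]).
#' @param mz Query m/z (Da).
#' @param ppm Tolerance in ppm.
#' @return An [xic()].
#' @export
extract_xic <- function(run, mz, ppm = 20) {
  stopifnot(inherits(run, "synthetic_run"), ppm > 0)
  channel_mz <- vapply(run$channels, `[[`, numeric(1), "mz")
  dev <- abs(ppm_error(channel_mz, mz))
  if (all(dev > ppm)) {
    stop(structure(
      class = c("gq_no_channel", "error", "condition"),
      list(message = sprintf("no channel within %g ppm of m/z %.4f", ppm, mz),
           call = sys.call())
    ))
  }
  ch <- run$channels[[which.min(dev)]]
  xic(ch$time, ch$intensity, mz = ch$mz, ppm = ppm)
}

#' Estimate baseline noise
#'
#' Standard deviation of the intensities outside the excluded windows, after
#' subtracting their median (the baseline level).
#'
#' @param x An [xic()].
#' @param exclude A list of `c(t0, t1)` windows (minutes) to exclude, e.g.
#'   around analyte peaks.
#' @param min_points Minimum number of baseline points required.
#' @return Noise level (intensity units).
#' @export
estimate_noise <- function(x, exclude = list(), min_points = 20) {
  keep <- rep(TRUE, length(x$time))
  for (w in exclude) keep[x$time >= w[1] & x$time <= w[2]] <- FALSE
  if (sum(keep) < min_points) {
    stop(structure(
      class = c("gq_insufficient_baseline", "error", "condition"),
      list(message = sprintf(
        "only %d baseline points left after exclusion (need >= %d)",
        sum(keep), min_points), call = sys.call())
    ))
  }
  v <- x$intensity[keep]
  stats::sd(v - stats::median(v))
}

#' Signal-to-noise ratio
#'
#' Apex height over baseline noise. Zero noise with a nonzero height is
#' undefined and raises an error of class `gq_undefined_snr`.
#'
#' @param height Peak apex height above baseline.
#' @param noise Baseline noise level.
#' @return Dimensionless S/N.
#' @export
snr <- function(height, noise) {
  stopifnot(height >= 0, noise >= 0)
  if (height == 0) return(0)
  if (noise == 0) {
    stop(structure(
      class = c("gq_undefined_snr", "error", "condition"),
      list(message = "S/N undefined: noise level is zero", call = sys.call())
    ))
  }
  height / noise
}

#' Integrate a chromatographic peak
#'
#' Locates the apex inside `window`, finds the peak bounds by descending
#' from the apex until the intensity falls to `baseline + k * noise`, and
#' integrates the baseline-subtracted intensity over the bounds with the
#' trapezoidal rule. Baseline (median) and noise (standard deviation) are
#' estimated from the points outside `window` when at least 20 remain;
#' otherwise both are taken as zero and the bounds default to the window
#' edges (adequate for clean, peak-only traces).
#'
#' @param x An [xic()].
#' @param window `c(t0, t1)` search window in minutes; must overlap the XIC.
#' @param k Bound-descent multiple of the noise level.
#' @param analyte Optional analyte name carried into the result.
#' @param exclude Additional `c(t0, t1)` windows excluded (together with
#'   `window`) from the baseline region — e.g. the peaks of co-channel
#'   isomers.
#' @return A one-row tibble: `analyte`, `rt_apex`, `area`, `height`, `snr`,
#'   `t_start`, `t_end`, `baseline`, `noise`. An all-zero window yields a
#'   zero-area, zero-S/N peak.
#' @export
integrate_peak <- function(x, window, k = 3, analyte = NA_character_,
                           exclude = list()) {
  stopifnot(inherits(x, "xic"), length(window) == 2, window[1] < window[2])
  inside <- which(x$time >= window[1] & x$time <= window[2])
  if (length(inside) < 2) {
    stop("window does not overlap the chromatogram", call. = FALSE)
  }
  base_keep <- rep(TRUE, length(x$time))
  base_keep[inside] <- FALSE
  for (w in exclude) base_keep[x$time >= w[1] & x$time <= w[2]] <- FALSE
  outside <- x$intensity[base_keep]
  if (length(outside) >= 20) {
    baseline <- stats::median(outside)
    noise <- stats::sd(outside - baseline)
  } else {
    baseline <- 0
    noise <- 0
  }

  sig <- x$intensity[inside] - baseline
  apex_rel <- which.max(sig)
  # apex height as the mean of the three samples around the apex, which damps
  # the upward selection bias of a single noisy maximum
  height <- mean(sig[max(1, apex_rel - 1):min(length(sig), apex_rel + 1)])
  if (height <= 0 || all(sig == 0)) {
    return(tibble::tibble(
      analyte = analyte, rt_apex = x$time[inside[apex_rel]], area = 0,
      height = 0, snr = 0, t_start = window[1], t_end = window[2],
      baseline = baseline, noise = noise
    ))
  }

  thr <- k * noise
  lo <- apex_rel
  while (lo > 1 && sig[lo - 1] > thr) lo <- lo - 1
  hi <- apex_rel
  while (hi < length(sig) && sig[hi + 1] > thr) hi <- hi + 1

  idx <- inside[lo:hi]
  tt <- x$time[idx]
  yy <- x$intensity[idx] - baseline
  area <- sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  area <- max(area, 0)

  sn <- if (noise > 0) height / noise else NA_real_
  tibble::tibble(
    analyte = analyte, rt_apex = x$time[inside[apex_rel]], area = area,
    height = height, snr = sn, t_start = tt[1], t_end = tt[length(tt)],
    baseline = baseline, noise = noise
  )
}

#' Relative retention time
#'
#' @param rt,rt_ref Retention times (minutes) of the analyte and the internal
#'   reference.
#' @return The dimensionless ratio `rt / rt_ref`.
#' @export
relative_rt <- function(rt, rt_ref) {
  stopifnot(all(rt > 0), rt_ref > 0)
  rt / rt_ref
}

#' Locate a peak by relative retention time
#'
#' Among candidate peaks, returns the one whose retention-time ratio to the
#' reference peak is nearest the expected relative retention time and within
#' `tol`; exact ties are broken by larger area. Relative retention times are
#' invariant under uniform time rescaling (flow-rate-like changes), which is
#' what makes them usable for localisation across conditions.
#'
#' @param candidates Tibble of peaks (needs `rt_apex` and `area`), e.g. rows
#'   from [integrate_peak()] or [measure_run()].
#' @param reference_peak One-row tibble, the located internal-reference peak.
#' @param expected Expected relative retention time (ratio).
#' @param tol Acceptance tolerance on the ratio, in (0, 0.2].
#' @return The selected candidate row.
#' @export
locate_peak_by_rtr <- function(candidates, reference_peak, expected,
                               tol = 0.05) {
  stopifnot(nrow(candidates) >= 1, nrow(reference_peak) == 1,
            expected > 0, tol > 0, tol <= 0.2)
  ratio <- relative_rt(candidates$rt_apex, reference_peak$rt_apex)
  dev <- abs(ratio - expected)
  ok <- which(dev <= tol)
  if (length(ok) == 0) {
    stop(structure(
      class = c("gq_peak_not_found", "error", "condition"),
      list(message = sprintf(
        "no candidate within %.3f of expected RT ratio %.3f (candidates: %s)",
        tol, expected, paste(sprintf("%.3f", ratio), collapse = ", ")),
        call = sys.call())
    ))
  }
  best <- ok[dev[ok] == min(dev[ok])]
  if (length(best) > 1) best <- best[which.max(candidates$area[best])]
  candidates[best, ]
}

#' Measure every library analyte in a run
#'
#' Extracts each analyte's channel at its theoretical `[M-H]-` m/z and
#' integrates the peak in a window around its library retention time
#' (rescaled by the run's `time_scale`, if any).
#'
#' @param run A `synthetic_run`.
#' @param library Analyte library.
#' @param ppm Channel extraction tolerance (ppm).
#' @param rt_window Half-width of the integration window (minutes).
#' @param k Bound-descent noise multiple (see [integrate_peak()]).
#' @return A tibble with one row per analyte (columns as in
#'   [integrate_peak()]).
#' @export
measure_run <- function(run, library, ppm = 20, rt_window = 0.12, k = 3) {
  ts <- run$metadata$config$time_scale
  if (is.null(ts)) ts <- 1
  rows <- lapply(seq_len(nrow(library)), function(i) {
    a <- library[i, ]
    x <- extract_xic(run, a$mz_mh, ppm = ppm)
    rt <- a$rt_min * ts
    # co-channel isomer windows are excluded from the baseline region
    mates <- library$rt_min[library$mz_mh == a$mz_mh & library$name != a$name]
    excl <- lapply(mates * ts, function(m) c(m - rt_window * ts,
                                             m + rt_window * ts))
    integrate_peak(x, c(rt - rt_window * ts, rt + rt_window * ts), k = k,
                   analyte = a$name, exclude = excl)
  })
  dplyr::bind_rows(rows)
}
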