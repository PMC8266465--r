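# Synthetic LC-MS run generator.
#
# Emulates the statistical structure the downstream analysis assumes: one
# extracted-ion channel per analyte at its theoretical [M-H]- m/z, a Gaussian
# elution peak centred at the library retention time whose true area follows
# the analyte's linear calibration law times a multiplicative lognormal
# dispersion factor, and an additive Gaussian baseline riding on a constant
# offset so that intensities stay nonnegative and signal-to-noise can be
# estimated from the flanking baseline.

#' Configuration for synthetic run generation
#'
#' @param peak_sigma_min Gaussian peak width (standard deviation) in minutes.
#' @param baseline_sd Standard deviation of the additive baseline noise
#'   (intensity units).
#' @param area_cv Coefficient of variation of the multiplicative lognormal
#'   peak-area dispersion (fraction, e.g. 0.02 for 2 %).
#' @param sampling_hz Sampling rate in points per second.
#' @param seed Master integer seed; per-analyte, per-run substreams are
#'   derived from it so that adding an analyte or a run never perturbs the
#'   draws of the others.
#' @param zero_intercept If `TRUE`, calibration intercepts are forced to zero
#'   when generating true areas (proportional response; single-marker
#'   quantification is exact in this mode).
#' @param channel_halfwidth_min Half-width of the simulated time window
#'   around each analyte's retention time, in minutes.
#' @param baseline_level Constant baseline offset; defaults to
#'   `10 * baseline_sd` so that noise excursions almost never clip at zero.
#' @param time_scale Multiplies all retention times (and peak widths), which
#'   emulates a uniform flow-rate change; 1 leaves the time axis untouched.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(peak_sigma_min = 0.02, baseline_sd = 0,
                             area_cv = 0, sampling_hz = 5, seed = 1L,
                             zero_intercept = FALSE,
                             channel_halfwidth_min = 1.5,
                             baseline_level = NULL, time_scale = 1) {
  stopifnot(peak_sigma_min > 0, baseline_sd >= 0, area_cv >= 0,
            sampling_hz > 0, channel_halfwidth_min >= 6 * peak_sigma_min,
            time_scale > 0)
  if (is.null(baseline_level)) baseline_level <- 10 * baseline_sd
  structure(
    list(peak_sigma_min = peak_sigma_min, baseline_sd = baseline_sd,
         area_cv = area_cv, sampling_hz = sampling_hz, seed = as.integer(seed),
         zero_intercept = zero_intercept,
         channel_halfwidth_min = channel_halfwidth_min,
         baseline_level = baseline_level, time_scale = time_scale),
    class = "synthetic_config"
  )
}

# Deterministic substream seed from the master seed and a text tag.
# Kept below 2^31 - 1; exact in double arithmetic.
.substream_seed <- function(seed, tag) {
  m <- 2147483647
  h <- seed %% m
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% m
  as.integer((h * 48271) %% m)
}

# True peak area from the calibration law, before dispersion.
.law_area <- function(analyte, conc, zero_intercept) {
  analyte$slope * conc + if (zero_intercept) 0 else analyte$intercept
}

# Per-analyte lognormal area dispersion factor, drawn from a substream
# keyed only by run tag and analyte name, so adding an analyte or channel
# never perturbs the others' true areas.
.area_factor <- function(name, config, tag) {
  if (config$area_cv == 0) return(1)
  sub <- .substream_seed(config$seed, paste(tag, name, sep = "|"))
  withr::with_seed(sub, {
    sdlog <- sqrt(log(1 + config$area_cv^2))
    stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })
}

# Builds the run's channels. Isomeric analytes share the same theoretical
# [M-H]- m/z and therefore share one chromatogram channel, exactly as on the
# instrument; the channel's time grid spans all of its analytes' retention
# windows and each analyte contributes a Gaussian peak at its own time.
.make_run <- function(library, concs, config, run_id) {
  stopifnot(length(concs) == nrow(library))
  sigma <- config$peak_sigma_min * config$time_scale
  hw <- config$channel_halfwidth_min * config$time_scale
  dt <- 1 / (60 * config$sampling_hz)

  true_area <- numeric(nrow(library))
  detectable <- logical(nrow(library))
  key <- sprintf("%.6f", library$mz_mh)
  channels <- lapply(split(seq_len(nrow(library)), key)[unique(key)], function(idx) {
    rts <- library$rt_min[idx] * config$time_scale
    time <- seq(max(0, min(rts) - hw), max(rts) + hw, by = dt)
    sub <- .substream_seed(config$seed,
                           paste(run_id, "channel", key[idx[1]], sep = "|"))
    noise <- withr::with_seed(sub,
                              stats::rnorm(length(time), 0, config$baseline_sd))
    intensity <- config$baseline_level + noise
    for (j in seq_along(idx)) {
      i <- idx[j]
      law <- .law_area(library[i, ], concs[i], config$zero_intercept)
      ta <- law * .area_factor(library$name[i], config, run_id)
      det <- is.finite(ta) && ta > 0 && concs[i] > 0
      if (det) {
        height <- ta / (sigma * sqrt(2 * pi))
        intensity <- intensity + height * exp(-(time - rts[j])^2 / (2 * sigma^2))
      }
      true_area[i] <<- ta
      detectable[i] <<- det
    }
    list(mz = library$mz_mh[idx[1]], time = time,
         intensity = pmax(intensity, 0), analytes = library$name[idx])
  })

  truth <- tibble::tibble(
    name = library$name,
    conc = unname(concs),
    true_area = true_area,
    in_range = concs >= library$range_low & concs <= library$range_high,
    detectable = detectable
  )
  structure(
    list(channels = channels, truth = truth,
         metadata = list(run_id = run_id, seed = config$seed,
                         config = unclass(config))),
    class = "synthetic_run"
  )
}

#' Generate a standard dilution series
#'
#' One synthetic run per calibration level. `levels` is either a numeric
#' vector (the same concentration for every analyte at each level, in ng/mL)
#' or a matrix with one row per level and one named column per analyte, as
#' produced by [dilution_series()]. Levels outside an analyte's validated
#' range are generated anyway and flagged `in_range = FALSE` in the truth
#' block.
#'
#' @param library Analyte library (see [ginsenoside_library()]).
#' @param levels Numeric vector or level-by-analyte matrix of concentrations
#'   (ng/mL).
#' @param config A [synthetic_config()].
#' @param tag Text tag entering the random substream, so replicate series
#'   get independent draws.
#' @return A list of `synthetic_run` objects, one per level.
#' @export
make_standard_series <- function(library, levels, config = synthetic_config(),
                                 tag = "std") {
  if (nrow(library) == 0) stop("empty analyte library", call. = FALSE)
  if (is.matrix(levels)) {
    stopifnot(identical(colnames(levels), library$name))
    conc_mat <- levels
  } else {
    stopifnot(is.numeric(levels), length(levels) >= 1)
    conc_mat <- matrix(rep(levels, each = nrow(library)),
                       nrow = length(levels), byrow = TRUE,
                       dimnames = list(NULL, library$name))
  }
  if (any(conc_mat < 0)) stop("negative concentration", call. = FALSE)
  lapply(seq_len(nrow(conc_mat)), function(l) {
    .make_run(library, conc_mat[l, ], config,
              run_id = sprintf("%s_level%02d", tag, l))
  })
}

#' Serial-dilution concentration matrix
#'
#' Emulates serial dilution of a mixed stock in which each analyte's stock
#' concentration is the top of its own validated range: level `f` puts
#' analyte `x` at `f * range_high[x]` ng/mL.
#'
#' @param library Analyte library.
#' @param factors Dilution factors in (0, 1].
#' @return Matrix with one row per factor, one named column per analyte.
#' @export
dilution_series <- function(library, factors = c(0.1, 0.2, 0.4, 0.7, 1)) {
  stopifnot(all(factors > 0), all(factors <= 1))
  m <- outer(factors, library$range_high)
  dimnames(m) <- list(NULL, library$name)
  m
}

#' Generate a synthetic sample run
#'
#' A single run whose truth block records the supplied per-analyte true
#' concentrations; analytes absent from `true_concs` are generated at zero
#' (baseline-only channel).
#'
#' @param library Analyte library.
#' @param true_concs Named numeric vector of true concentrations (ng/mL).
#' @param config A [synthetic_config()].
#' @param tag Text tag entering the random substream.
#' @return A `synthetic_run`.
#' @export
make_sample_run <- function(library, true_concs, config = synthetic_config(),
                            tag = "sample") {
  if (nrow(library) == 0) stop("empty analyte library", call. = FALSE)
  unknown <- setdiff(names(true_concs), library$name)
  if (length(unknown) > 0) {
    stop("analyte(s) not in library: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(true_concs < 0)) stop("negative concentration", call. = FALSE)
  concs <- stats::setNames(rep(0, nrow(library)), library$name)
  concs[names(true_concs)] <- true_concs
  .make_run(library, concs, config, run_id = tag)
}

#' Generate a synthetic MS2 spectrum
#'
#' Builds the glycosidic neutral-loss ladder of an analyte: the precursor is
#' the theoretical `[M-H]-` of the formula and each fragment removes one more
#' residue of the loss sequence. By default the analyte's library `loss_seq`
#' is used.
#'
#' @param analyte One-row analyte tibble (a row of [ginsenoside_library()]).
#' @param losses Character vector of residue labels (see [residue_masses()]),
#'   applied in order; `NULL` uses the library loss sequence.
#' @param precursor_intensity,fragment_intensity Intensities assigned to the
#'   precursor and to each fragment.
#' @return An object of class `msms_spectrum`: a list with `precursor_mz`,
#'   `rt_min`, `title` and a `fragments` tibble (`mz`, `intensity`).
#' @export
make_msms_spectrum <- function(analyte, losses = NULL,
                               precursor_intensity = 100,
                               fragment_intensity = 50) {
  stopifnot(nrow(analyte) == 1)
  if (is.null(losses)) {
    losses <- strsplit(analyte$loss_seq, ";", fixed = TRUE)[[1]]
    losses <- losses[nzchar(losses)]
  }
  rm_tab <- residue_masses()
  unknown <- setdiff(losses, names(rm_tab))
  if (length(unknown) > 0) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  precursor <- adduct_mz(monoisotopic_mass(analyte$formula), "[M-H]-")
  frag_mz <- precursor - cumsum(rm_tab[losses])
  if (any(frag_mz <= 0)) {
    stop("cumulative residue loss exceeds precursor mass", call. = FALSE)
  }
  fragments <- tibble::tibble(
    mz = unname(c(precursor, frag_mz)),
    intensity = c(precursor_intensity, rep(fragment_intensity, length(frag_mz)))
  )
  structure(
    list(precursor_mz = precursor, rt_min = analyte$rt_min,
         title = analyte$name, fragments = fragments),
    class = "msms_spectrum"
  )
}
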