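# Analyte library and printed reference tables.
#
# The 25-standard ginsenoside library carries, per analyte: molecular formula,
# retention time, aglycone class, the linear calibration law (peak area =
# slope * concentration + intercept, concentrations in ng/mL) with its
# validated range, and the characteristic MS2 glycosidic loss sequence.
# The 43-compound table additionally holds the measured adduct m/z values and
# MS2 fragment lists used by the annotation module.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "ginqams")
  if (path == "") path <- file.path("inst", "extdata", file) # pre-install use
  if (!file.exists(path)) stop("cannot locate extdata file ", file, call. = FALSE)
  path
}

.validate_library <- function(lib) {
  stopifnot(
    all(!is.na(lib$name)), !anyDuplicated(lib$name),
    all(lib$rt_min > 0),
    all(lib$slope > 0),
    all(lib$range_low < lib$range_high),
    all(lib$class %in% c("PPT", "PPD", "OA", "other"))
  )
  invisible(lib)
}

#' The 25-ginsenoside standard library
#'
#' One row per quantified standard: name, molecular formula, retention time
#' (min), aglycone class, calibration slope and intercept (peak area per
#' ng/mL and area offset), validated concentration range (ng/mL), the
#' theoretical `[M-H]-` m/z used as the quantification channel, and the
#' characteristic glycosidic neutral-loss sequence observed in MS2
#' (semicolon-separated residue labels, empty for the bare aglycones).
#'
#' @return A tibble with 25 rows.
#' @examples
#' lib <- ginsenoside_library()
#' lib[lib$name == "Rb1", ]
#' @export
ginsenoside_library <- function() {
  lib <- read_library(.extdata("ginsenoside_library.csv"))
  .validate_library(lib)
}

#' Read / write an analyte library CSV
#'
#' The on-disk format has columns `name, formula, rt_min, class, slope,
#' intercept, range_low, range_high, loss_seq`. [read_library()] adds the
#' derived `mz_mh` column (theoretical `[M-H]-` of the formula).
#'
#' @param path CSV file path.
#' @return [read_library()]: a tibble; [write_library()]: `path`, invisibly.
#' @export
read_library <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "formula", "rt_min", "class", "slope", "intercept",
              "range_low", "range_high", "loss_seq")
  missing <- setdiff(needed, names(lib))
  if (length(missing) > 0) {
    stop("library file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lib$loss_seq[is.na(lib$loss_seq)] <- ""
  lib$mz_mh <- vapply(lib$formula,
                      function(f) adduct_mz(monoisotopic_mass(f), "[M-H]-"),
                      numeric(1), USE.NAMES = FALSE)
  tibble::as_tibble(lib)
}

#' @param lib A library tibble as returned by [read_library()].
#' @rdname read_library
#' @export
write_library <- function(lib, path) {
  cols <- c("name", "formula", "rt_min", "class", "slope", "intercept",
            "range_low", "range_high", "loss_seq")
  utils::write.csv(as.data.frame(lib)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' The 43-compound identification table
#'
#' All compounds characterised in ginseng root extract by full-scan accurate
#' mass plus data-dependent MS2: compound number and name, formula, retention
#' time, the measured `[M+HCOO]-` and `[M-H]-` m/z, and the measured MS2
#' fragment m/z values (list column `ms2`). `is_standard` marks the 25
#' compounds confirmed against authentic standards; `mass_typo` marks two
#' rows whose printed m/z values are inconsistent with their formula and are
#' excluded from mass-accuracy checks. Theoretical adduct m/z are added as
#' `th_mh` / `th_mcooh`.
#'
#' @return A tibble with 43 rows.
#' @export
compound_table <- function() {
  ct <- utils::read.csv(.extdata("compound_table.csv"), stringsAsFactors = FALSE)
  ct$ms2 <- lapply(strsplit(ifelse(is.na(ct$ms2), "", ct$ms2), ";", fixed = TRUE),
                   function(x) as.numeric(x[nzchar(x)]))
  m <- vapply(ct$formula, monoisotopic_mass, numeric(1), USE.NAMES = FALSE)
  ct$th_mh <- adduct_mz(m, "[M-H]-")
  ct$th_mcooh <- adduct_mz(m, "[M+HCOO]-")
  tibble::as_tibble(ct)
}

#' Published per-level relative response factors
#'
#' The reference relative response factor (RCF) table: per-level Fx of each
#' standard against the Rb2 internal marker at the five calibration levels
#' (10, 20, 50, 100 and 200 ng/mL), with the published mean and RSD. Used as
#' the arithmetic input for RCF-averaging checks.
#'
#' @return A tibble with 25 rows and columns `name`, `fx_10` ... `fx_200`,
#'   `mean_fx`, `rsd`.
#' @export
reference_rcf_table <- function() {
  tibble::as_tibble(utils::read.csv(.extdata("reference_rcf.csv"),
                                    stringsAsFactors = FALSE))
}

#' Published ESM vs QAMS comparison table
#'
#' Per-analyte ginseng-root contents (mg/g) quantified by the external
#' standard method (ESM) and by single-marker quantification (QAMS), with
#' the published standard method difference (SMD, %). The internal marker
#' Rb2 has no SMD by construction.
#'
#' @return A tibble with 25 rows and columns `no`, `name`, `esm`, `qams`, `smd`.
#' @export
reference_comparison_table <- function() {
  tibble::as_tibble(utils::read.csv(.extdata("reference_comparison.csv"),
                                    stringsAsFactors = FALSE))
}

#' Round half away from zero
#'
#' Report tables round half-up (0.305 -> 0.31), matching the convention of
#' the published tables; `base::round` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
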