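# Readers and writers: synthetic runs as long-format CSV plus a JSON truth
# sidecar, MS2 spectra as MGF, and rounded report tables mirroring the
# published table layouts.
#
# Writers are deterministic given seed and config: stable row order, full
# precision in machine-readable files, fixed rounding (4 decimals for m/z,
# 2 for concentrations and percentages) in report tables.

#' Write / read a synthetic run
#'
#' The run's channels go to `<basename>.csv` in long format
#' (`channel_mz`, `time_min`, `intensity`) and the truth block, metadata and
#' generating configuration to `<basename>.json`. The truth block
#' round-trips exactly: numbers are serialised at full IEEE precision.
#'
#' @param run A `synthetic_run`.
#' @param basename Output path without extension.
#' @return [write_run()]: `basename`, invisibly; [read_run()]: a
#'   `synthetic_run`.
#' @export
write_run <- function(run, basename) {
  stopifnot(inherits(run, "synthetic_run"))
  tab <- do.call(rbind, lapply(seq_along(run$channels), function(i) {
    ch <- run$channels[[i]]
    data.frame(channel = i, channel_mz = ch$mz, time_min = ch$time,
               intensity = ch$intensity)
  }))
  utils::write.csv(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                   paste0(basename, ".csv"), row.names = FALSE, quote = FALSE)
  side <- list(
    truth = as.data.frame(run$truth),
    metadata = run$metadata,
    channel_analytes = lapply(run$channels, `[[`, "analytes")
  )
  jsonlite::write_json(side, paste0(basename, ".json"), digits = I(17),
                       auto_unbox = TRUE)
  invisible(basename)
}

#' @rdname write_run
#' @export
read_run <- function(basename) {
  tab <- utils::read.csv(paste0(basename, ".csv"))
  side <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  analytes <- side$channel_analytes
  channels <- lapply(seq_along(analytes), function(i) {
    sub <- tab[tab$channel == i, ]
    list(mz = sub$channel_mz[1], time = sub$time_min, intensity = sub$intensity,
         analytes = unlist(analytes[[i]]))
  })
  names(channels) <- names(analytes)
  structure(
    list(channels = channels, truth = tibble::as_tibble(side$truth),
         metadata = side$metadata),
    class = "synthetic_run"
  )
}

#' Write / read MS2 spectra as MGF
#'
#' Minimal Mascot Generic Format: one `BEGIN IONS` block per spectrum with
#' `TITLE`, `PEPMASS` (the `[M-H]-` precursor) and `RTINSECONDS`.
#'
#' @param spectra A list of `msms_spectrum` objects.
#' @param path Output file.
#' @return [write_mgf()]: `path`, invisibly; [read_mgf()]: a list of
#'   `msms_spectrum` objects.
#' @export
write_mgf <- function(spectra, path) {
  lines <- unlist(lapply(spectra, function(sp) {
    c("BEGIN IONS",
      paste0("TITLE=", sp$title),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      sprintf("RTINSECONDS=%.3f", sp$rt_min * 60),
      sprintf("%.6f %.4f", sp$fragments$mz, sp$fragments$intensity),
      "END IONS", "")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mgf
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  stopifnot(length(starts) == length(ends))
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1):(ends[i] - 1)]
    kv <- grepl("=", block, fixed = TRUE)
    fields <- strsplit(block[kv], "=", fixed = TRUE)
    keys <- vapply(fields, `[[`, character(1), 1)
    vals <- vapply(fields, `[[`, character(1), 2)
    peaks <- do.call(rbind, strsplit(block[!kv], " ", fixed = TRUE))
    structure(
      list(
        precursor_mz = as.numeric(vals[keys == "PEPMASS"]),
        rt_min = if ("RTINSECONDS" %in% keys)
          as.numeric(vals[keys == "RTINSECONDS"]) / 60 else NA_real_,
        title = if ("TITLE" %in% keys) vals[keys == "TITLE"] else NA_character_,
        fragments = tibble::tibble(mz = as.numeric(peaks[, 1]),
                                   intensity = as.numeric(peaks[, 2]))
      ),
      class = "msms_spectrum"
    )
  })
}

#' Write a rounded report table
#'
#' Human-readable mirror of the published table layouts: m/z-like columns
#' rounded to 4 decimals, concentration/percentage-like columns rounded
#' half-up to 2 decimals, everything else untouched. Row order is preserved.
#'
#' @param df Data frame or tibble.
#' @param path Output CSV.
#' @param mz_cols,round2_cols Column-name regular expressions selecting the
#'   4-decimal and 2-decimal groups.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(df, path, mz_cols = "mz|mass",
                             round2_cols = "conc|esm|qams|smd|rsd|fx|re|rt") {
  out <- as.data.frame(df)
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) next
    if (grepl(mz_cols, nm, ignore.case = TRUE)) {
      out[[nm]] <- round_half_up(out[[nm]], 4)
    } else if (grepl(round2_cols, nm, ignore.case = TRUE)) {
      out[[nm]] <- round_half_up(out[[nm]], 2)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
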