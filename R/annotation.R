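# Rule-based ginsenoside annotation: glycosidic neutral-loss decomposition
# of precursor masses, aglycone classification (PPT / PPD / OA), isomer
# grouping by nominal mass, and MS2 ladder matching.
#
# A structural degeneracy runs through all of this: PPT differs from PPD by
# one oxygen, exactly as a hexose differs from a deoxyhexose, so
# PPD + n Glc and PPT + (n-1) Glc + Rha are the same elemental composition.
# Precursor mass alone therefore cannot separate PPT from PPD glycosides;
# the MS2 ladder (which aglycone ion the losses terminate at, 475 vs 459)
# settles it, and the classifier uses it the same way.

#' Decompose a precursor mass into glycosyl residue losses
#'
#' Exhaustive search over residue multisets of size up to `max_residues`
#' (optionally extended by one water loss for dehydrated ginsenosides):
#' every multiset whose removal from the precursor lands on an aglycone
#' `[M-H]-` within `ppm_tol` is returned, ranked by absolute ppm error and
#' then by fewer residues. An empty result is a valid outcome — dehydrated
#' ginsenosides match no aglycone unless `allow_h2o` is set.
#'
#' @param precursor_mz Precursor `[M-H]-` m/z (Da).
#' @param residues Residue labels to search over (see [residue_masses()]).
#' @param aglycones Aglycone definitions (see [aglycone_definitions()]).
#' @param max_residues Maximum multiset size (<= 8).
#' @param ppm_tol Match tolerance (ppm).
#' @param allow_h2o Additionally allow a single water loss.
#' @return A tibble, one row per matching path: `class`, `n_residues`,
#'   `n_h2o`, `losses` (label string such as `"2Glc+Rha"`), `counts` (list
#'   column of named residue counts), `terminal_mz`, `ppm_err`.
#' @export
decompose_losses <- function(precursor_mz, residues = c("Glc", "Rha", "Pen", "GlcA"),
                             aglycones = aglycone_definitions(),
                             max_residues = 6, ppm_tol = 5,
                             allow_h2o = FALSE) {
  stopifnot(precursor_mz > 0, ppm_tol > 0, max_residues <= 8)
  rm_tab <- residue_masses()[residues]
  grid <- expand.grid(lapply(rm_tab, function(.) 0:max_residues))
  grid <- grid[rowSums(grid) <= max_residues, , drop = FALSE]
  grid <- grid[rep(seq_len(nrow(grid)), each = if (allow_h2o) 2 else 1), ,
               drop = FALSE]
  n_h2o <- if (allow_h2o) rep(0:1, length.out = nrow(grid)) else
    rep(0L, nrow(grid))
  loss_mass <- as.matrix(grid) %*% rm_tab + n_h2o * residue_masses()[["H2O"]]
  terminal <- precursor_mz - as.vector(loss_mass)

  out <- list()
  for (a in seq_len(nrow(aglycones))) {
    err <- ppm_error(terminal, aglycones$mz_mh[a])
    hit <- which(abs(err) <= ppm_tol)
    if (length(hit) == 0) next
    labels <- vapply(hit, function(i) .loss_label(grid[i, ], n_h2o[i]),
                     character(1))
    counts <- lapply(hit, function(i) {
      stats::setNames(as.integer(grid[i, ]), names(rm_tab))
    })
    out[[length(out) + 1]] <- tibble::tibble(
      class = aglycones$class[a],
      n_residues = as.integer(rowSums(grid[hit, , drop = FALSE])),
      n_h2o = as.integer(n_h2o[hit]),
      losses = labels,
      counts = counts,
      terminal_mz = terminal[hit],
      ppm_err = err[hit]
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      class = character(), n_residues = integer(), n_h2o = integer(),
      losses = character(), counts = list(), terminal_mz = numeric(),
      ppm_err = numeric()
    ))
  }
  res <- dplyr::bind_rows(out)
  res[order(abs(res$ppm_err), res$n_residues), ]
}

.loss_label <- function(counts, n_h2o = 0) {
  counts <- unlist(counts)
  parts <- character(0)
  for (nm in names(counts)) {
    if (counts[[nm]] == 1) parts <- c(parts, nm)
    if (counts[[nm]] > 1) parts <- c(parts, paste0(counts[[nm]], nm))
  }
  if (n_h2o > 0) parts <- c(parts, "H2O")
  if (length(parts) == 0) "none" else paste(parts, collapse = "+")
}

# All distinct sub-multiset loss masses of a residue-count vector (excluding
# the empty subset); used to test which observed fragments a path explains.
.subset_losses <- function(counts, n_h2o = 0) {
  rm_tab <- residue_masses()
  sums <- 0
  for (nm in names(counts)) {
    if (counts[[nm]] > 0) {
      sums <- as.vector(outer(sums, (0:counts[[nm]]) * rm_tab[[nm]], `+`))
    }
  }
  if (n_h2o > 0) sums <- as.vector(outer(sums, c(0, rm_tab[["H2O"]]), `+`))
  sort(unique(sums[sums > 0]))
}

# Residue labels evidenced by single-residue mass differences between
# consecutive observed fragments (precursor included).
.evidenced_residues <- function(precursor_mz, ms2, abs_tol = 0.03) {
  rm_tab <- residue_masses()[c("Glc", "Rha", "Pen", "GlcA")]
  mz <- sort(c(precursor_mz, ms2), decreasing = TRUE)
  d <- -diff(mz)
  ev <- character(0)
  for (x in d) {
    hit <- names(rm_tab)[abs(rm_tab - x) <= abs_tol]
    ev <- c(ev, hit)
  }
  unique(ev)
}

#' Classify one compound by sugar-loss decomposition
#'
#' Decomposes the theoretical `[M-H]-` of `formula` over the residue table.
#' When the decomposition is ambiguous across aglycone classes (the
#' isobaric PPD+Glc / PPT+Rha degeneracy), candidate paths are scored by how
#' many observed MS2 fragments they explain as sub-multiset losses from the
#' precursor; remaining ties prefer the path whose residue types are all
#' evidenced by single-residue neutral-loss differences in the spectrum.
#'
#' @param formula Molecular formula.
#' @param ms2 Observed MS2 fragment m/z values (may be empty).
#' @param ppm_tol Decomposition tolerance (theoretical vs theoretical, ppm).
#' @param frag_tol Fragment match tolerance vs measured m/z (ppm).
#' @param ... Passed to [decompose_losses()].
#' @return A one-row tibble: `class` (`"other"` when nothing matches),
#'   `n_residues`, `losses`, `is_glycoside`.
#' @export
classify_compound <- function(formula, ms2 = numeric(0), ppm_tol = 5,
                              frag_tol = 15, ...) {
  mh <- adduct_mz(monoisotopic_mass(formula), "[M-H]-")
  paths <- decompose_losses(mh, ppm_tol = ppm_tol, ...)
  if (nrow(paths) == 0) {
    return(tibble::tibble(class = "other", n_residues = NA_integer_,
                          losses = NA_character_, is_glycoside = FALSE))
  }
  if (length(unique(paths$class)) > 1 && length(ms2) > 0) {
    score <- vapply(seq_len(nrow(paths)), function(i) {
      expl <- mh - .subset_losses(paths$counts[[i]], paths$n_h2o[i])
      sum(vapply(ms2, function(f) {
        any(abs(ppm_error(f, expl)) <= frag_tol)
      }, logical(1)))
    }, numeric(1))
    ev <- .evidenced_residues(mh, ms2)
    unevidenced <- vapply(seq_len(nrow(paths)), function(i) {
      cnt <- paths$counts[[i]]
      length(setdiff(names(cnt)[cnt > 0], ev))
    }, numeric(1))
    paths <- paths[order(-score, unevidenced, paths$n_residues, paths$class), ]
  }
  best <- paths[1, ]
  tibble::tibble(class = best$class, n_residues = best$n_residues,
                 losses = best$losses, is_glycoside = best$n_residues > 0)
}

#' Classify a compound table by aglycone
#'
#' Row-wise [classify_compound()] over a table of formulas with optional
#' MS2 fragment lists (as in [compound_table()]). The operation is pure per
#' row, hence order-independent and idempotent.
#'
#' @param entries Tibble with a `formula` column and optionally an `ms2`
#'   list column of fragment m/z vectors.
#' @param ... Passed to [classify_compound()].
#' @return `entries` with `class`, `n_residues`, `losses` and
#'   `is_glycoside` columns appended.
#' @export
classify_library <- function(entries, ...) {
  ms2 <- if ("ms2" %in% names(entries)) entries$ms2 else
    rep(list(numeric(0)), nrow(entries))
  res <- dplyr::bind_rows(lapply(seq_len(nrow(entries)), function(i) {
    classify_compound(entries$formula[i], ms2 = ms2[[i]], ...)
  }))
  dplyr::bind_cols(entries[setdiff(names(entries),
                                   c("class", "n_residues", "losses",
                                     "is_glycoside"))], res)
}

#' Glycoside counts per aglycone class
#'
#' Counts classified glycosides (at least one residue) per class; bare
#' aglycones are excluded, unmatched compounds are counted as `other`.
#'
#' @param classified Output of [classify_library()].
#' @return Named integer vector over `PPT`, `PPD`, `OA`, `other`.
#' @export
glycoside_class_counts <- function(classified) {
  cls <- ifelse(classified$class == "other", "other",
                ifelse(classified$is_glycoside, classified$class, "aglycone"))
  out <- c(PPT = 0L, PPD = 0L, OA = 0L, other = 0L)
  tab <- table(cls[cls %in% names(out)])
  out[names(tab)] <- as.integer(tab)
  out
}

#' Group isomeric analytes by nominal ion mass
#'
#' Partitions the library by the integer-rounded theoretical `[M-H]-` and
#' reports groups with at least two members. Isomers must be separated
#' chromatographically, so within-group retention times are required to be
#' distinct.
#'
#' @param library Analyte library (needs `name`, `mz_mh`, `rt_min`).
#' @return A tibble: `nominal_mz`, `name`, `rt_min`, sorted by nominal mass
#'   then retention time; zero rows when no isomers exist.
#' @export
isomer_groups <- function(library) {
  stopifnot(nrow(library) >= 1)
  if (anyDuplicated(library$name)) stop("duplicate analyte names", call. = FALSE)
  nominal <- round(library$mz_mh)
  keep <- nominal %in% nominal[duplicated(nominal)]
  out <- tibble::tibble(nominal_mz = nominal[keep], name = library$name[keep],
                        rt_min = library$rt_min[keep])
  out <- out[order(out$nominal_mz, out$rt_min), ]
  if (nrow(out) > 0) {
    dup_rt <- tapply(out$rt_min, out$nominal_mz, anyDuplicated)
    if (any(dup_rt > 0)) {
      stop("isomer group members must have distinct retention times",
           call. = FALSE)
    }
  }
  out
}

#' Annotate an MS2 spectrum against the library
#'
#' Candidates are analytes whose theoretical `[M-H]-` matches the precursor
#' within `ppm_tol`. Each candidate's expected fragment ladder (precursor
#' plus cumulative losses of its library loss sequence) is matched against
#' the spectrum; candidates are ranked by ladder coverage, then by number of
#' matched ladder ions, then by retention-time proximity when the spectrum
#' carries one, then by precursor ppm error. Coverage below `low_conf`
#' flags the annotation as low confidence.
#'
#' @param spectrum An `msms_spectrum` (see [make_msms_spectrum()]) or a list
#'   with `precursor_mz`, a `fragments` tibble and optionally `rt_min`.
#' @param library Analyte library.
#' @param ppm_tol Match tolerance (ppm).
#' @param low_conf Coverage threshold below which the top annotation is
#'   flagged.
#' @return A tibble of ranked candidates: `name`, `class`, `precursor_ppm`,
#'   `coverage`, `n_matched`, `rt_diff`, `low_confidence`. Zero rows when no
#'   precursor matches.
#' @export
annotate_spectrum <- function(spectrum, library, ppm_tol = 10,
                              low_conf = 0.5) {
  stopifnot(nrow(spectrum$fragments) >= 1)
  prec_ppm <- ppm_error(spectrum$precursor_mz, library$mz_mh)
  cand <- which(abs(prec_ppm) <= ppm_tol)
  if (length(cand) == 0) {
    return(tibble::tibble(
      name = character(), class = character(), precursor_ppm = numeric(),
      coverage = numeric(), n_matched = integer(), rt_diff = numeric(),
      low_confidence = logical()
    ))
  }
  rm_tab <- residue_masses()
  obs <- spectrum$fragments$mz
  rt <- if (!is.null(spectrum$rt_min)) spectrum$rt_min else NA_real_

  rows <- lapply(cand, function(i) {
    losses <- strsplit(library$loss_seq[i], ";", fixed = TRUE)[[1]]
    losses <- losses[nzchar(losses)]
    ladder <- library$mz_mh[i] - cumsum(c(0, rm_tab[losses]))
    matched <- vapply(ladder, function(m) {
      any(abs(ppm_error(obs, m)) <= ppm_tol)
    }, logical(1))
    tibble::tibble(
      name = library$name[i], class = library$class[i],
      precursor_ppm = prec_ppm[i],
      coverage = mean(matched), n_matched = as.integer(sum(matched)),
      rt_diff = if (is.na(rt)) NA_real_ else abs(rt - library$rt_min[i])
    )
  })
  res <- dplyr::bind_rows(rows)
  ord <- order(-res$coverage, -res$n_matched,
               if (all(is.na(res$rt_diff))) rep(0, nrow(res)) else res$rt_diff,
               abs(res$precursor_ppm), res$name)
  res <- res[ord, ]
  res$low_confidence <- res$coverage < low_conf
  res
}
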