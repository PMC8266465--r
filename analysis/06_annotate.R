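#!/usr/bin/env Rscript
# Qualitative analysis: aglycone classification of the 43-compound table by
# glycosidic neutral-loss decomposition, isomer grouping of the standards by
# nominal ion mass, and closed-loop annotation of the generated MS2 spectra.

suppressPackageStartupMessages(library(ginqams))

lib <- ginsenoside_library()
ct <- compound_table()

cl <- classify_library(ct)
counts <- glycoside_class_counts(cl)
cat(sprintf("Classified %d compounds: %d PPT, %d PPD, %d OA glycosides, %d other\n",
            nrow(cl), counts[["PPT"]], counts[["PPD"]], counts[["OA"]],
            counts[["other"]]))
cat("  'other' =", paste(cl$name[cl$class == "other"], collapse = ", "),
    "(dehydrated; recoverable with allow_h2o = TRUE)\n")

g <- isomer_groups(lib)
cat(sprintf("Isomer groups among the %d standards: %d\n", nrow(lib),
            length(unique(g$nominal_mz))))
for (mz in unique(g$nominal_mz)) {
  cat(sprintf("  m/z %4d: %s\n", mz,
              paste(g$name[g$nominal_mz == mz], collapse = ", ")))
}

spectra <- read_mgf("results/runs/standards_ms2.mgf")
ann <- dplyr::bind_rows(lapply(spectra, function(sp) {
  top <- annotate_spectrum(sp, lib)[1, ]
  tibble::tibble(spectrum = sp$title, top_hit = top$name, class = top$class,
                 coverage = top$coverage, precursor_ppm = top$precursor_ppm,
                 low_confidence = top$low_confidence)
}))
cat(sprintf("Closed-loop annotation: %d/%d spectra self-identified top-1, min coverage %.2f\n",
            sum(ann$spectrum == ann$top_hit), nrow(ann), min(ann$coverage)))

write_report_csv(cl[, c("no", "name", "formula", "class", "n_residues",
                        "losses", "is_glycoside")],
                 "results/classification.csv")
write_report_csv(g, "results/isomer_groups.csv")
write_report_csv(ann, "results/annotation.csv")
cat("Wrote results/classification.csv, isomer_groups.csv, annotation.csv\n")
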