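#!/usr/bin/env Rscript
# Generate the synthetic study data: a serial-dilution standard series, a
# ginseng-extract-like sample run, and one MS2 spectrum per standard.
# Everything downstream (02-06) is recomputed from these generator settings;
# runs are also written to results/runs/ for inspection.

suppressPackageStartupMessages(library(ginqams))

seed <- 20260927L
dir.create("results/runs", recursive = TRUE, showWarnings = FALSE)

lib <- ginsenoside_library()
cfg <- synthetic_config(area_cv = 0.02, baseline_sd = 25, baseline_level = 250,
                        seed = seed)

cat(sprintf("Library: %d analytes on %d m/z channels, RT %.2f-%.2f min\n",
            nrow(lib), length(unique(sprintf("%.4f", lib$mz_mh))),
            min(lib$rt_min), max(lib$rt_min)))

# standard series: each analyte diluted over the top decade of its own
# validated range, the same 1:2:4:7:10 ladder for every analyte
conc <- dilution_series(lib, factors = c(0.1, 0.2, 0.4, 0.7, 1))
series <- make_standard_series(lib, conc, cfg)
for (l in seq_along(series)) {
  write_run(series[[l]], sprintf("results/runs/standard_level%02d", l))
}
cat(sprintf("Wrote %d standard-series runs (levels at %s of range top)\n",
            length(series), paste(c(0.1, 0.2, 0.4, 0.7, 1), collapse = "/")))

# sample run: mid-range concentrations patterned on the published contents
concs <- default_sample_concs(lib)
sample_run <- make_sample_run(lib, concs, cfg)
write_run(sample_run, "results/runs/sample")
cat(sprintf("Wrote sample run: %d analytes, %.0f-%.0f ng/mL\n",
            length(concs), min(concs), max(concs)))

# MS2 spectra: the characteristic glycosidic loss ladder of each standard
spectra <- lapply(seq_len(nrow(lib)), function(i) make_msms_spectrum(lib[i, ]))
write_mgf(spectra, "results/runs/standards_ms2.mgf")
cat(sprintf("Wrote %d MS2 spectra (ladders of %d-%d ions)\n", length(spectra),
            min(vapply(spectra, function(s) nrow(s$fragments), integer(1))),
            max(vapply(spectra, function(s) nrow(s$fragments), integer(1)))))

write_library(lib, "results/runs/library.csv")
cat("Done: inputs for 02-06 are reproducible from seed", seed, "\n")
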