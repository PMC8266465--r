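# Neutral-loss decomposition, aglycone classification, isomer grouping and
# MS2 ladder annotation.

# Independent brute-force decomposition oracle: nested loops over residue
# counts, no shared code with decompose_losses.
brute_decompose <- function(precursor, max_res = 6, ppm_tol = 5) {
  rm_tab <- residue_masses()[c("Glc", "Rha", "Pen", "GlcA")]
  agly <- aglycone_definitions()
  hits <- character(0)
  for (g in 0:max_res) for (r in 0:(max_res - g)) {
    for (p in 0:(max_res - g - r)) for (a in 0:(max_res - g - r - p)) {
      term <- precursor - g * rm_tab[["Glc"]] - r * rm_tab[["Rha"]] -
        p * rm_tab[["Pen"]] - a * rm_tab[["GlcA"]]
      for (k in seq_len(nrow(agly))) {
        if (abs(ppm_error(term, agly$mz_mh[k])) <= ppm_tol) {
          hits <- c(hits, sprintf("%s:%d:%d:%d:%d", agly$class[k], g, r, p, a))
        }
      }
    }
  }
  sort(hits)
}

path_keys <- function(paths) {
  sort(vapply(seq_len(nrow(paths)), function(i) {
    v <- paths$counts[[i]]
    sprintf("%s:%d:%d:%d:%d", paths$class[i],
            v[["Glc"]], v[["Rha"]], v[["Pen"]], v[["GlcA"]])
  }, character(1)))
}

test_that("decomposition matches an independent brute-force enumeration", {
  for (f in unique(compound_table()$formula)) {
    mh <- adduct_mz(monoisotopic_mass(f), "[M-H]-")
    expect_identical(path_keys(decompose_losses(mh)), brute_decompose(mh),
                     label = f)
  }
})

test_that("known precursors decompose to their documented residue sets", {
  # Rb1: four hexoses to the PPD aglycone; the isobaric PPT alternative
  # (3 Glc + Rha) is the same elemental composition and is found too
  p <- decompose_losses(1107.5956, ppm_tol = 5)
  expect_setequal(p$losses, c("4Glc", "3Glc+Rha"))
  expect_setequal(p$class, c("PPD", "PPT"))

  # a bare aglycone matches with zero residues
  p0 <- decompose_losses(459.3844)
  expect_equal(p0$n_residues, 0L)
  expect_equal(p0$class, "PPD")

  # oleanolic-acid saponin: one glucose and one glucuronide
  poa <- decompose_losses(793.4395)
  expect_equal(poa$class, "OA")
  expect_equal(poa$losses, "Glc+GlcA")

  # dehydrated ginsenosides match nothing unless a water loss is allowed
  rk3 <- adduct_mz(monoisotopic_mass("C36H60O8"), "[M-H]-")
  expect_equal(nrow(decompose_losses(rk3)), 0)
  expect_gt(nrow(decompose_losses(rk3, allow_h2o = TRUE)), 0)
})

test_that("classification reproduces the published class membership", {
  ct <- compound_table()
  cl <- classify_library(ct)
  counts <- glycoside_class_counts(cl)
  expect_equal(counts[["PPT"]], 9L)
  expect_equal(counts[["PPD"]], 23L)
  expect_equal(counts[["OA"]], 3L)
  expect_equal(cl$no[cl$class == "PPT" & cl$is_glycoside],
               c(1L, 2L, 3L, 4L, 5L, 7L, 8L, 9L, 15L))
  expect_equal(cl$no[cl$class == "PPD" & cl$is_glycoside],
               c(6L, 10L, 11L, 12L, 13L, 16L, 17L, 18L, 19L, 21L, 22L, 23L,
                 24L, 25L, 30L, 33L, 34L, 35L, 36L, 37L, 38L, 39L, 42L))
  expect_equal(cl$no[cl$class == "OA"], c(14L, 20L, 32L))
  # dehydrated compounds (including Rk3) fall out as "other"
  expect_equal(cl$no[cl$class == "other"], c(26L, 27L, 28L, 29L, 40L, 41L))
})

test_that("classification is order-independent and idempotent", {
  ct <- compound_table()[c(4, 21, 39, 27, 20), ]
  cl1 <- classify_library(ct)
  perm <- c(3, 1, 5, 2, 4)
  cl2 <- classify_library(ct[perm, ])
  expect_equal(cl2$class, cl1$class[perm])
  expect_equal(classify_library(cl1)$class, cl1$class)
})

test_that("isomer grouping by nominal ion mass finds the eight pairs/triples", {
  g <- isomer_groups(full_library)
  expect_equal(length(unique(g$nominal_mz)), 8L)
  members <- split(g$name, g$nominal_mz)
  expect_setequal(members[["621"]], c("CK", "Rh2"))
  expect_setequal(members[["637"]], c("Rh1", "F1"))
  expect_setequal(members[["753"]], c("Mc", "CY", "CMx"))
  expect_setequal(members[["783"]], c("Rg2", "F2", "G75", "Rg3"))
  expect_setequal(members[["799"]], c("Rg1", "Rf"))
  expect_setequal(members[["916"]], c("nFe", "CO", "nFd"))
  expect_setequal(members[["946"]], c("Re", "Rd", "GXVII"))
  expect_setequal(members[["1078"]], c("Rc", "Rb2", "Rb3"))

  expect_equal(nrow(isomer_groups(full_library[1, ])), 0)
  dup <- full_library[c(1, 1), ]
  expect_error(isomer_groups(dup), "duplicate")
})

test_that("spectra self-identify against the library", {
  lib <- full_library
  for (nm in c("Rb1", "Re", "Rd", "GXVII", "CK", "Rh2", "PPT")) {
    sp <- make_msms_spectrum(lib[lib$name == nm, ])
    ann <- annotate_spectrum(sp, lib)
    expect_equal(ann$name[1], nm)
    expect_equal(ann$coverage[1], 1)
    expect_false(ann$low_confidence[1])
  }
})

test_that("random fragments give zero ladder coverage, flagged low confidence", {
  lib <- full_library
  sp <- make_msms_spectrum(lib[lib$name == "Rb1", ])
  sp$fragments <- tibble::tibble(mz = c(sp$precursor_mz, 101.1, 333.3, 777.7),
                                 intensity = rep(1, 4))
  ann <- annotate_spectrum(sp, lib)
  # only the precursor matches: coverage 1/(n losses + 1)
  expect_lt(ann$coverage[1], 0.5)
  expect_true(ann$low_confidence[1])

  sp$precursor_mz <- 50.0
  expect_equal(nrow(annotate_spectrum(sp, lib)), 0)
})
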