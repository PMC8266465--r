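# Relative response factors, single-marker quantification, SMD and
# robustness across condition variants.

test_that("single response factors follow their definition and invariances", {
  expect_equal(rcf_single(100, 1, 100, 1), 1)
  # ratio of calibration slopes: marker 20778.7, analyte 64984
  expect_equal(rcf_single(20778.7, 1, 64984, 1), 0.3197, tolerance = 1e-3)
  # scale invariance: doubling an analyte's area and concentration together
  expect_equal(rcf_single(20778.7, 1, 2 * 64984, 2),
               rcf_single(20778.7, 1, 64984, 1))
  # detector-gain invariance: rescaling the whole intensity axis
  g <- 17.3
  expect_equal(rcf_single(g * 20778.7, 1, g * 64984, 1),
               rcf_single(20778.7, 1, 64984, 1))
  expect_error(rcf_single(0, 1, 1, 1))
})

test_that("RCF averaging reproduces the published per-level arithmetic", {
  rows <- list(
    list(fx = c(0.32, 0.30, 0.31, 0.30, 0.30), mean = 0.31, rsd = 2.92),
    list(fx = c(3.45, 3.25, 3.05, 3.18, 3.22), mean = 3.23, rsd = 4.48),
    list(fx = c(0.48, 0.46, 0.47, 0.48, 0.46), mean = 0.47, rsd = 2.13),
    list(fx = c(6.48, 6.95, 6.67, 6.98, 6.45), mean = 6.71, rsd = 3.75)
  )
  for (r in rows) {
    e <- rcf_series(r$fx)
    expect_equal(round_half_up(e$mean_fx, 2), r$mean)
    expect_equal(round_half_up(e$rsd, 2), r$rsd)
  }
  const <- rcf_series(rep(0.42, 3))
  expect_equal(const$mean_fx, 0.42)
  expect_equal(const$rsd, 0)
})

test_that("levels without a detected peak are dropped, not imputed", {
  expect_warning(e <- rcf_series(c(0.3, NA, 0.32, 0.31, NA), analyte = "x"),
                 "dropped 2")
  expect_equal(e$n_levels, 3L)
  expect_error(suppressWarnings(rcf_series(c(0.3, NA, NA, NA, NA))),
               "fewer than 2")
})

test_that("single-marker quantification follows its formula", {
  expect_equal(quantify_qams(100, 100, 50, 1), 50) # marker self-consistency
  expect_equal(quantify_qams(2, 1, 0.2, 0.5), 0.2)
  expect_error(quantify_qams(1, 0, 1, 1))
})

test_that("SMD reproduces the published comparison rows", {
  expect_equal(round_half_up(smd(151.28, 143.83), 2), 4.92)
  expect_equal(round_half_up(smd(324.15, 316.05), 2), 2.50)
  expect_equal(smd(7.7, 7.7), 0)
  expect_error(smd(0, 1), "c_esm")
})

test_that("marker's own factor is identically 1 at every level", {
  lib <- mini_library
  series <- make_standard_series(lib, dilution_series(lib),
                                 quiet_config(area_cv = 0.02))
  areas <- t(vapply(series, function(r) measure_run(r, lib)$area,
                    numeric(nrow(lib))))
  colnames(areas) <- lib$name
  tab <- rcf_table(areas, dilution_series(lib), reference = "Rb2")
  rb2 <- tab[tab$analyte == "Rb2", ]
  expect_equal(rb2$mean_fx, 1)
  expect_equal(rb2$rsd, 0)
  expect_true(all(tab$fx[[which(tab$analyte == "Rb2")]] == 1))
})

test_that("QAMS equals ESM exactly on proportional, dispersion-free data", {
  cmp <- compare_methods(full_library,
                         quiet_config(zero_intercept = TRUE),
                         n_std_rep = 1, n_rep = 1)
  expect_lt(max(cmp$smd), 1e-8)
  expect_equal(cmp$c_qams, cmp$c_true, tolerance = 1e-8)
})

test_that("with printed intercepts and 2% dispersion the two methods agree", {
  cmp <- compare_methods(full_library,
                         synthetic_config(area_cv = 0.02, seed = 202),
                         n_std_rep = 2, n_rep = 3)
  expect_lt(max(cmp$smd[cmp$name != "Rb2"]), 6)
})

test_that("robustness summaries: identical variants give zero RSDs", {
  v <- tibble::tibble(analyte = c("a", "b"), mean_fx = c(0.5, 2),
                      rt_r = c(0.3, 1.4))
  rb <- rcf_robustness(list(v, v, v))
  expect_true(all(rb$fx_rsd == 0))
  expect_true(all(rb$rtr_rsd == 0))
  # an analyte missing from one variant is dropped with a warning
  expect_warning(rb2 <- rcf_robustness(list(v, v[1, ])), "dropped")
  expect_equal(rb2$analyte, "a")
})

test_that("uniform time rescaling leaves relative retention times fixed", {
  lib <- mini_library
  ref_rt <- lib$rt_min[lib$name == "Rb2"]
  variants <- lapply(c(1, 0.8, 1.25), function(gam) {
    cfg <- quiet_config(area_cv = 0.03, time_scale = gam,
                        seed = round(1000 * gam))
    run <- make_sample_run(lib, stats::setNames(0.3 * lib$range_high, lib$name),
                           cfg)
    m <- measure_run(run, lib)
    tibble::tibble(
      analyte = m$analyte,
      mean_fx = rcf_single(m$area[m$analyte == "Rb2"], 1, m$area, 1),
      rt_r = relative_rt(m$rt_apex, m$rt_apex[m$analyte == "Rb2"])
    )
  })
  rb <- rcf_robustness(variants)
  # the ratio itself is exactly invariant; the measured apex adds only
  # sampling-grid discretisation (one time step out of several minutes)
  expect_equal(relative_rt(0.8 * lib$rt_min, 0.8 * ref_rt),
               relative_rt(lib$rt_min, ref_rt))
  expect_true(all(rb$rtr_rsd < 0.1))
})

test_that("area jitter of 3% keeps RCF RSDs under 6% across variants", {
  lib <- full_library
  conc <- dilution_series(lib)
  variants <- lapply(1:3, function(v) {
    cfg <- synthetic_config(area_cv = 0.03, seed = 500 + v)
    series <- make_standard_series(lib, conc, cfg, tag = sprintf("var%d", v))
    areas <- t(vapply(series, function(r) r$truth$true_area,
                      numeric(nrow(lib))))
    colnames(areas) <- lib$name
    rcf_table(areas, conc, reference = "Rb2")[, c("analyte", "mean_fx")]
  })
  rb <- rcf_robustness(variants)
  expect_lt(max(rb$fx_rsd), 6)
})
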