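# XIC extraction, peak integration, noise/SNR estimation and relative
# retention time localisation.

fake_run <- function(mzs) {
  t <- seq(0, 1, by = 0.01)
  channels <- lapply(mzs, function(m) {
    list(mz = m, time = t, intensity = rep(0, length(t)), analytes = "x")
  })
  structure(list(channels = channels,
                 truth = tibble::tibble(),
                 metadata = list(config = list(time_scale = 1))),
            class = "synthetic_run")
}

test_that("XIC extraction picks the channel nearest in ppm, or signals absence", {
  run <- fake_run(c(1107.5956, 500.123))
  expect_equal(extract_xic(run, 1107.60, ppm = 20)$mz, 1107.5956)
  expect_error(extract_xic(run, 800.0, ppm = 5), class = "gq_no_channel")
  # two near channels: only the closer one is returned
  run2 <- fake_run(c(783.49, 783.50))
  got <- extract_xic(run2, 783.4913, ppm = 5)
  ref <- c(783.49, 783.50)
  expect_equal(got$mz, ref[which.min(abs(ppm_error(ref, 783.4913)))])
})

test_that("Gaussian and rectangular peaks integrate to their closed forms", {
  g <- gaussian_xic(height = 1, rt = 5, sigma = 0.05)
  pk <- integrate_peak(g, c(4.5, 5.5))
  expect_equal(pk$area, 0.05 * sqrt(2 * pi), tolerance = 0.005)
  expect_equal(pk$rt_apex, 5, tolerance = 1e-6)

  # rectangular pulse: trapezoid is exact on a constant
  t <- seq(0, 1, by = 0.01)
  y <- ifelse(t >= 0.4 & t <= 0.6, 7, 0)
  pk2 <- integrate_peak(xic(t, y), c(0.395, 0.605))
  expect_equal(pk2$area, 7 * 0.2, tolerance = 1e-9)

  # flat zero trace
  z <- xic(t, rep(0, length(t)))
  pk3 <- integrate_peak(z, c(0.2, 0.8))
  expect_equal(pk3$area, 0)
  expect_equal(pk3$snr, 0)
})

test_that("integration is linear in intensity and invariant to time shifts", {
  g <- gaussian_xic(height = 2, rt = 5, sigma = 0.05)
  pk <- integrate_peak(g, c(4.5, 5.5))
  g3 <- xic(g$time, 3 * g$intensity)
  pk3 <- integrate_peak(g3, c(4.5, 5.5))
  expect_equal(pk3$area, 3 * pk$area)
  expect_equal(pk3$height, 3 * pk$height)

  sh <- xic(g$time + 2.5, g$intensity)
  pks <- integrate_peak(sh, c(7, 8))
  expect_equal(pks$area, pk$area, tolerance = 1e-9)
  expect_equal(pks$rt_apex, pk$rt_apex + 2.5)
})

test_that("noise estimation recovers the generating sigma", {
  t <- seq(0, 10, by = 0.01)
  noise <- withr::with_seed(42, rnorm(length(t), 50, 5))
  x <- xic(t, pmax(noise, 0))
  expect_equal(estimate_noise(x), 5, tolerance = 0.1 * 5)

  # adding an excluded peak does not move the estimate
  peak <- 1000 * exp(-(t - 5)^2 / (2 * 0.05^2))
  xp <- xic(t, pmax(noise + peak, 0))
  n_clean <- estimate_noise(x, exclude = list(c(4.5, 5.5)))
  n_peak <- estimate_noise(xp, exclude = list(c(4.5, 5.5)))
  expect_equal(n_peak, n_clean, tolerance = 1e-9)

  expect_equal(estimate_noise(xic(t, rep(0, length(t)))), 0)
  expect_error(estimate_noise(x, exclude = list(c(-1, 11))),
               class = "gq_insufficient_baseline")
})

test_that("snr follows its definition and flags the degenerate cases", {
  expect_equal(snr(30, 10), 3)
  expect_equal(snr(0, 10), 0)
  expect_equal(snr(0, 0), 0)
  expect_error(snr(5, 0), class = "gq_undefined_snr")
})

test_that("simulated peak at the computed LOD has S/N near 3", {
  rd <- full_library[full_library$name == "Rd", ]
  cfg <- quiet_config(baseline_sd = 40, baseline_level = 400)
  lims <- lod_loq(list(slope = rd$slope), noise = cfg$baseline_sd,
                  hpa = height_per_area(cfg$peak_sigma_min))
  sn <- vapply(1:8, function(s) {
    simulated_snr(rd, lims$lod, quiet_config(baseline_sd = 40,
                                             baseline_level = 400,
                                             seed = 100 + s))
  }, numeric(1))
  expect_lt(abs(mean(sn) / 3 - 1), 0.3)
})

test_that("relative retention time localises peaks and survives rescaling", {
  # candidates patterned on the printed retention times (ratio ~ 0.206)
  cands <- tibble::tibble(rt_apex = c(1.46, 4.08, 9.25), area = c(5, 4, 3))
  ref <- tibble::tibble(rt_apex = 7.09, area = 10)
  hit <- locate_peak_by_rtr(cands, ref, expected = 0.21, tol = 0.05)
  expect_equal(hit$rt_apex, 1.46)
  expect_equal(relative_rt(1.46, 7.09), 0.206, tolerance = 1e-3)

  # reference against itself
  self <- locate_peak_by_rtr(ref, ref, expected = 1, tol = 0.05)
  expect_equal(self$rt_apex, 7.09)

  # nearest-ratio wins between two in-band candidates
  c2 <- tibble::tibble(rt_apex = c(0.20, 0.35) * 7.09, area = c(1, 100))
  expect_equal(locate_peak_by_rtr(c2, ref, 0.21, tol = 0.05)$rt_apex, 0.20 * 7.09)

  # uniform time rescaling leaves every ratio unchanged
  gam <- 1.37
  hit_g <- locate_peak_by_rtr(dplyr::mutate(cands, rt_apex = rt_apex * gam),
                              dplyr::mutate(ref, rt_apex = rt_apex * gam),
                              expected = 0.21, tol = 0.05)
  expect_equal(hit_g$rt_apex / (ref$rt_apex * gam), hit$rt_apex / ref$rt_apex)

  expect_error(locate_peak_by_rtr(cands, ref, expected = 0.5, tol = 0.05),
               class = "gq_peak_not_found")
})

test_that("ties in relative retention time break toward the larger area", {
  ref <- tibble::tibble(rt_apex = 10, area = 1)
  cands <- tibble::tibble(rt_apex = c(1.9, 2.1), area = c(3, 8))
  hit <- locate_peak_by_rtr(cands, ref, expected = 0.2, tol = 0.05)
  expect_equal(hit$rt_apex, 2.1)
})
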