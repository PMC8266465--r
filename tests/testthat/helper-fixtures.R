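# Shared fixtures: the full standard library, a small three-analyte subset
# whose members sit on distinct channels, and a quiet default config.

full_library <- ginsenoside_library()

mini_library <- full_library[full_library$name %in% c("Rg1", "Rb2", "Rb1"), ]

quiet_config <- function(...) {
  args <- list(...)
  if (is.null(args$seed)) args$seed <- 11L
  do.call(synthetic_config, args)
}

# Gaussian trace on its own grid (no baseline), for integration tests.
gaussian_xic <- function(height = 1, rt = 5, sigma = 0.05, halfwidth = 0.5,
                         dt = 1 / 300) {
  t <- seq(rt - halfwidth, rt + halfwidth, by = dt)
  xic(t, height * exp(-(t - rt)^2 / (2 * sigma^2)))
}
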