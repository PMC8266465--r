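---
title: "Single-marker quantification of ginsenosides: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification of ginsenosides: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginqams)
```

## The problem

Quantifying dozens of ginsenosides — the triterpene saponins of *Panax
ginseng* — by LC-MS normally requires an authentic standard and a
calibration curve for every analyte (the external standard method, ESM).
Quantitative analysis of multicomponents by single marker (QAMS) replaces
all but one of those standards with pre-established **relative response
factors**. With an internal marker $s$ (here ginsenoside Rb2) the factor of
analyte $x$ is the ratio of per-unit-concentration responses,

$$F_x = \frac{A_s/C_s}{A_x/C_x},$$

and a sample is quantified from the marker's standard alone:

$$C_x = \frac{A_x}{A_s/C_s}\,F_x .$$

The working $F_x$ is the arithmetic mean of factors measured at a series of
standard concentrations. Agreement between the two routes is scored by the
standard method difference, $\mathrm{SMD} = 100\,|C_\mathrm{ESM} -
C_\mathrm{QAMS}|/C_\mathrm{ESM}$, reported as an absolute percentage (the
published comparison tables print nonnegative values even where QAMS exceeds
ESM, which forces the sign convention).

`ginqams` implements the full chain — synthetic raw data with known truth,
extracted-ion-chromatogram (XIC) peak integration, ESM calibration with
S/N-based limits, the QAMS route, and rule-based MS² annotation — so every
stage is testable without access to the original instrument data, none of
which was deposited.

## Units: why everything is in ng/mL

The published calibration laws come with a range column labelled in µg/mL,
but read literally in µg/mL several of the printed lines produce negative
peak areas across their entire stated range (Rg2: $52298.5 \times 1 -
612776 < 0$ at its 1 µg/mL top; Rd likewise). Read in ng/mL, every line is
positive over its full range, the LOD/LOQ column (printed in ng/mL) sits on
the same axis, the RCF level set (10–200 ng/mL) becomes directly usable,
and the slope ratios reproduce the published factor table (e.g.
$20778.7/64984 = 0.32$ for Rg1 against Rb2). The package therefore treats
calibration concentrations as ng/mL throughout; `range_low`/`range_high` in
the library are the printed range × 1000.

## The synthetic-data generator

`make_standard_series()` and `make_sample_run()` emulate what the analysis
assumes about the raw data, not the instrument itself:

* **Channels.** One XIC channel per distinct theoretical [M−H]⁻; isomers
  share a channel, exactly as on the instrument, and are separated by
  retention time.
* **Peak shape.** Gaussian, width (sigma) `peak_sigma_min = 0.02` min
  (≈ 4.7 s FWHM, typical for sub-2-µm UPLC columns). A wider 0.05-min
  peak was rejected during implementation because it cannot baseline-resolve
  the closest printed isomer pairs (G75/Rg3 at 0.26 min, CK/Rh2 at
  0.29 min), which the original separation resolves; only relative areas
  matter, so the exact width is otherwise inconsequential.
* **Areas.** The true area of analyte $x$ at concentration $C$ is the
  calibration law $mC + b$ times a lognormal factor with coefficient of
  variation `area_cv` (mean exactly 1; exact law when `area_cv = 0`).
  `zero_intercept = TRUE` forces $b = 0$; single-marker quantification is
  algebraically exact only for proportional response, and the exactness
  tests use this mode while realism tests keep the printed intercepts.
* **Baseline.** A constant offset (default 10× the noise sd, so clipping at
  zero is negligible) plus i.i.d. Gaussian noise of sd `baseline_sd`.
  The offset is removed by median subtraction during integration.
* **Seeding.** One master seed; every random draw comes from a substream
  keyed by run tag and analyte name, so adding or removing an analyte never
  perturbs the others' draws, and identical configurations are bit-identical.

What the generator does **not** emulate: isotope envelopes, chimeric MS²
spectra, retention drift beyond a uniform time rescaling, detector
saturation, and matrix interferences. Passing tests therefore demonstrate
the correctness and internal consistency of the computations, not
instrument-level performance on real extracts.

## Peak integration and S/N

Integration is trapezoidal over baseline-subtracted intensity, in
intensity·minutes. The baseline is the median, and the noise the standard
deviation, of the channel outside the integration window (and outside
co-eluting isomer windows); bounds descend from the apex until intensity
falls below baseline + 3×noise, defaulting to the window edges on clean
traces. The apex height is the mean of the three samples around the
maximum, which damps the upward selection bias of a single noisy point —
at realistic sampling (5 Hz) this biases a clean Gaussian apex by under
0.2 %. The integration half-window is 0.12 min (6 sigma: truncation
≈ 10⁻⁹ of the area, while staying clear of the nearest co-channel
neighbour at 0.26 min).

LOD and LOQ come from the predicted apex height of the proportional part of
the calibration law: $\mathrm{LOD} = 3\,\sigma_\mathrm{noise}/(h_A m)$ with
$h_A = 1/(\sigma\sqrt{2\pi})$ the Gaussian height-per-area factor, and LOQ
with 10 instead of 3 — so LOQ/LOD is exactly 10/3 by construction. The
published LOD/LOQ pairs deviate from that ratio (they reflect unreported
empirical noise), so printed limit values are deliberately not asserted;
`simulated_snr()` provides the empirical cross-check that a peak generated
at the computed LOD measures S/N ≈ 3.

## The comparison protocol

The ESM-vs-QAMS experiment (`compare_methods()`) emulates serial dilution
of a mixed stock: each analyte's standard levels are fractions
{1/10, 1/5, 2/5, 7/10, 1} of **its own** range top — the same 1:2:4:7:10
ladder as the published factor table, expressed per analyte. A shared
absolute level set (10–200 ng/mL for everyone) fails with the printed
intercepts: some analytes' laws go negative at the low levels and the
level-averaged factor becomes badly biased. This is a genuine inconsistency
in the source material — the printed intercepts are irreconcilable with the
printed, nearly level-independent factors (Rg1's intercept equals the
signal of ~15 ng/mL of analyte, yet its printed per-level factors are flat
at 0.30–0.32) — and the per-analyte ladder is the protocol under which the
method is used in its valid regime.

Samples sit mid-range (20–28 % of each range top, spread by the rank order
of the published root contents), replicated six times, with six injections
per standard level, mirroring the sextuplicate protocol of the validation
section. The marker response $A_s/C_s$ is taken at the top standard level,
where its intercept contributes under 0.2 %. Under this protocol the
residual ESM–QAMS bias from the intercepts is ≈ 2.6 % worst-case
(noise-free algebra, frozen before any stochastic run), comfortably inside
the 6 % acceptance envelope with 2 % area dispersion on top.

## Annotation: the PPD/PPT degeneracy

Protopanaxatriol (PPT, C₃₀H₅₂O₄) is protopanaxadiol (PPD, C₃₀H₅₂O₃) plus
one oxygen — exactly the difference between a hexose (Glc, 162.0528 Da) and
a deoxyhexose (Rha, 146.0579 Da). Hence PPD + *n* Glc and PPT + (*n*−1) Glc
+ Rha are the *same elemental composition*, and precursor mass alone cannot
classify most glycosides. `decompose_losses()` returns all residue
multisets (up to 6 residues over Glc/Rha/Pen/GlcA, exhaustive enumeration)
reaching an aglycone [M−H]⁻ within 5 ppm; `classify_compound()` then scores
ambiguous paths by how many observed MS² fragments each explains as
sub-multiset losses — the 459/475 terminal aglycone ion usually decides —
with a deterministic tie-break preferring paths whose residue types are all
evidenced by single-residue neutral-loss differences in the spectrum.
Pentoses (xylose, both arabinoses) are isobaric and collapsed onto one
"Pen" label. Dehydrated ginsenosides (Rk1, Rg5, Rg6, F4, Rk3, Rh4) match no
aglycone and classify as "other" unless `allow_h2o = TRUE` adds a single
water loss; the published class counts exclude them, so the flag defaults
off. Rh2's printed formula (C₅₃H₉₀O₂₂) contradicts its printed m/z 621.44;
the library uses C₃₆H₆₂O₈, consistent with the m/z and with its isomer
pairing with compound K.

Spectrum annotation ranks precursor-matched candidates by ladder coverage,
then number of matched ladder ions, then retention-time proximity (isobaric
isomers with identical loss ladders — Rc/Rb2/Rb3, Mc/CY/CMx — are separable
only chromatographically, which is also how the original identification
worked), then precursor mass error.

## Numerical conventions

* Monoisotopic masses from CODATA atomic constants; the proton mass is
  taken as m(H) − m(e) so the [M+HCOO]⁻/[M−H]⁻ difference equals the HCOOH
  mass exactly. Tolerances: 5 ppm theory-vs-theory, 10–15 ppm against
  printed measured values (Orbitrap-realistic).
* RSD uses the n−1 sample standard deviation — the only estimator that
  reproduces the published replicate tables — and relative error is
  reported unsigned.
* Report tables round half-up to 2 decimals (4 for m/z), matching the
  published layouts; machine-readable outputs keep full precision.
* Calibration is unweighted least squares; a 1/x weighting option exists
  but is off by default, as no weighting scheme is documented for the
  original curves.
* Degenerate inputs fail loudly with classed conditions (`gq_no_channel`,
  `gq_undefined_snr`, `gq_peak_not_found`, `gq_insufficient_baseline`)
  rather than returning silent zeros.

## Problem sizes

The shipped analyses use 25 analytes × 5 levels (× 6 injections where
replication matters), six-replicate validation series over 20 seeds, and
the full 43-compound table for annotation — the sizes at which every
published quantity the pipeline can recompute is recomputed, while a full
run of the test suite and acceptance script stays around a minute.

## Known limitations

* Absolute tissue contents (mg/g) are not reproducible: the
  injection-to-extract dilution factors were never reported, so the
  comparison works in concentration units within the calibrated ranges and
  treats the published contents only as a rank pattern.
* Printed instrument-dependent values (LOD/LOQ, real-injection r²) are
  represented by their defining procedures, not asserted numerically.
* The per-level factor tables generated with the printed intercepts show a
  level dependence the published tables do not — see the units and protocol
  sections; the package reports it honestly rather than calibrating it
  away.
* No deconvolution of co-eluting peaks sharing a channel closer than the
  integration window, and no positional-isomer discrimination from MS²
  alone (Rc vs Rb2 vs Rb3).
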