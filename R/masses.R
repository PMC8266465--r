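# Monoisotopic mass calculus for CHO(NS) formulas, negative-mode adducts and
# the glycosyl residue / aglycone constants used throughout the package.

# CODATA/IUPAC monoisotopic atomic masses (Da)
.atomic_masses <- c(
  C = 12.0,
  H = 1.00782503207,
  O = 15.9949146196,
  N = 14.0030740048,
  S = 31.97207100
)

.electron_mass <- 0.00054857990
# proton mass taken as H minus electron, so that the difference between the
# formate adduct and the deprotonated molecule equals the HCOOH mass exactly
.proton_mass <- 1.00782503207 - 0.00054857990

#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula such as `"C54H92O23"` into named
#' element counts. Only C, H, O, N and S are recognised; ginsenosides are
#' CHO-only compounds.
#'
#' @param formula Character scalar, e.g. `"C30H52O3"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C30H52O3")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (!identical(paste(tokens, collapse = ""), formula)) {
    stop("unparseable formula: '", formula, "'", call. = FALSE)
  }
  elements <- gsub("[0-9]", "", tokens)
  counts <- vapply(tokens, function(t) {
    n <- gsub("[A-Za-z]", "", t)
    if (n == "") 1L else as.integer(n)
  }, integer(1), USE.NAMES = FALSE)
  unknown <- setdiff(elements, names(.atomic_masses))
  if (length(unknown) > 0) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(counts <= 0)) stop("element counts must be positive", call. = FALSE)
  out <- tapply(counts, elements, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Molecular formula string (see [parse_formula()]).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")     # 18.0106
#' monoisotopic_mass("C30H52O3") # protopanaxadiol, 460.3916
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(.atomic_masses[names(counts)] * counts)
}

#' m/z of a negative-mode adduct ion
#'
#' Computes the m/z of the deprotonated molecule or the formate adduct as
#' observed in negative-mode ESI. The electron mass is included: `[M-H]-` is
#' the neutral mass minus one proton (1.007276 Da), `[M+HCOO]-` the neutral
#' mass plus the formate anion (44.998201 Da). Their difference is exactly
#' the HCOOH monoisotopic mass, 46.005480 Da.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param adduct One of `"[M-H]-"` or `"[M+HCOO]-"`.
#' @return Ion m/z in Da.
#' @examples
#' adduct_mz(monoisotopic_mass("C30H52O3"), "[M-H]-") # 459.3844
#' @export
adduct_mz <- function(neutral_mass, adduct = c("[M-H]-", "[M+HCOO]-")) {
  stopifnot(is.numeric(neutral_mass), all(neutral_mass > 0))
  adduct <- match.arg(adduct)
  switch(adduct,
    "[M-H]-"    = neutral_mass - .proton_mass,
    "[M+HCOO]-" = neutral_mass + monoisotopic_mass("CHO2") + .electron_mass
  )
}

#' Neutral-loss masses of glycosyl residues
#'
#' Monoisotopic masses of the residues lost as glycosidic units during CID of
#' ginsenosides: hexose (Glc, dehydrated glucose C6H10O5, ~162 Da),
#' deoxyhexose (Rha, C6H10O4, ~146 Da), pentose (Pen, C5H8O4, ~132 Da;
#' xylose and both arabinoses are isobaric and collapsed onto one label) and
#' glucuronosyl (GlcA, C6H8O6, ~176 Da), plus water and formic acid.
#'
#' @return Named numeric vector of residue masses in Da.
#' @export
residue_masses <- function() {
  vapply(
    c(Glc = "C6H10O5", Rha = "C6H10O4", Pen = "C5H8O4",
      GlcA = "C6H8O6", H2O = "H2O", HCOOH = "CH2O2"),
    monoisotopic_mass, numeric(1)
  )
}

#' Aglycone backbone definitions
#'
#' The three triterpene aglycones of Panax ginsenosides: protopanaxatriol
#' (PPT, C30H52O4, aglycone ion near m/z 475), protopanaxadiol (PPD,
#' C30H52O3, near m/z 459) and oleanolic acid (OA, C30H48O3, near m/z 455).
#'
#' @return A tibble with columns `class`, `formula`, `neutral_mass`, `mz_mh`.
#' @export
aglycone_definitions <- function() {
  formulas <- c(PPT = "C30H52O4", PPD = "C30H52O3", OA = "C30H48O3")
  m <- vapply(formulas, monoisotopic_mass, numeric(1))
  tibble::tibble(
    class = names(formulas),
    formula = unname(formulas),
    neutral_mass = unname(m),
    mz_mh = unname(adduct_mz(m, "[M-H]-"))
  )
}

#' Parts-per-million mass deviation
#'
#' @param observed,expected m/z values in Da.
#' @return Signed deviation of `observed` from `expected` in ppm.
#' @export
ppm_error <- function(observed, expected) {
  (observed - expected) / expected * 1e6
}
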