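# Exact-mass and molecular-formula arithmetic for CHO anions.
# All monoisotopic masses are CODATA/IUPAC values to >= 8 decimals; the
# electron mass is included in m/z so that 4-decimal diagnostic masses
# (121.0295, 147.0088, 165.0193) come out of the atomic constants.

.monoisotopic <- c(
  C  = 12,              # 12C, exact by definition
  H  = 1.00782503207,
  O  = 15.99491461956,
  C13 = 13.00335483507
)
.electron_mass <- 0.00054857990

#' CHO elemental formula with optional 13C substitutions
#'
#' The unit of mass and ring-double-bond-equivalent (RDBE) arithmetic in the
#' screening workflow. Formulas are CHO-only; `n_carbon13` of the carbons may
#' be the heavy isotope (isotope-labelled internal standards).
#'
#' @param n_carbon,n_hydrogen,n_oxygen Non-negative integer atom counts.
#' @param n_carbon13 Number of 13C substitutions (`<= n_carbon`).
#' @return An object of class `formula_cho`.
#' @examples
#' formula_cho(7, 5, 2)            # the m/z 121.0295 fragment ion
#' formula_cho(10, 9, 4, n_carbon13 = 4)
#' @export
formula_cho <- function(n_carbon, n_hydrogen, n_oxygen, n_carbon13 = 0L) {
  counts <- c(n_carbon, n_hydrogen, n_oxygen, n_carbon13)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("atom counts must be non-negative integers")
  if (n_carbon13 > n_carbon)
    stop("n_carbon13 cannot exceed n_carbon")
  structure(
    list(n_carbon = as.integer(n_carbon), n_hydrogen = as.integer(n_hydrogen),
         n_oxygen = as.integer(n_oxygen), n_carbon13 = as.integer(n_carbon13)),
    class = "formula_cho"
  )
}

#' @export
format.formula_cho <- function(x, ...) {
  num <- function(n) if (n == 1) "" else as.character(n)
  out <- ""
  c12 <- x$n_carbon - x$n_carbon13
  if (c12 > 0) out <- paste0(out, "C", num(c12))
  if (x$n_carbon13 > 0) out <- paste0(out, "[13C]", num(x$n_carbon13))
  if (x$n_hydrogen > 0) out <- paste0(out, "H", num(x$n_hydrogen))
  if (x$n_oxygen > 0) out <- paste0(out, "O", num(x$n_oxygen))
  out
}

#' @export
print.formula_cho <- function(x, ...) {
  cat("<formula_cho> ", format(x), "  (", sprintf("%.5f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

#' Parse a Hill-notation CHO formula string
#'
#' Accepts strings such as `"C10H10O4"` or `"C6[13C]4H10O4"` (13C substitutions
#' written as `[13C]n`).
#'
#' @param x A formula string.
#' @return A [formula_cho()] object.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  s <- gsub("\\s", "", x)
  n13 <- 0L
  m13 <- regmatches(s, regexec("\\[13C\\]([0-9]*)", s))[[1]]
  if (length(m13)) {
    n13 <- if (m13[2] == "") 1L else as.integer(m13[2])
    s <- sub("\\[13C\\][0-9]*", "", s)
  }
  grab <- function(el) {
    m <- regmatches(s, regexec(paste0(el, "([0-9]*)"), s))[[1]]
    if (!length(m)) return(0L)
    if (m[2] == "") 1L else as.integer(m[2])
  }
  if (grepl("[^CHO0-9]", s))
    stop("formula must contain only C, H, O (and [13C]): ", x)
  formula_cho(grab("C") + n13, grab("H"), grab("O"), n13)
}

.as_formula <- function(x) {
  if (inherits(x, "formula_cho")) x else parse_formula(x)
}

#' Monoisotopic mass of a CHO formula
#'
#' Sum of monoisotopic atomic masses (12C = 12 exactly, 1H = 1.00782503207,
#' 16O = 15.99491461956), each 13C substitution replacing one 12C
#' (13C = 13.00335483507).
#'
#' @param formula A [formula_cho()] or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C7H6O2")  # benzoic acid, 122.03678
#' @export
monoisotopic_mass <- function(formula) {
  f <- .as_formula(formula)
  (f$n_carbon - f$n_carbon13) * .monoisotopic[["C"]] +
    f$n_carbon13 * .monoisotopic[["C13"]] +
    f$n_hydrogen * .monoisotopic[["H"]] +
    f$n_oxygen * .monoisotopic[["O"]]
}

#' m/z of a singly charged anion
#'
#' The formula is the *ionic* composition (e.g. `C7H5O2` for the 121.0295
#' diagnostic fragment): m/z = monoisotopic mass + one electron mass, at
#' charge -1.
#'
#' @inheritParams monoisotopic_mass
#' @return m/z value.
#' @examples
#' round(anion_mz("C7H5O2"), 4)   # 121.0295
#' round(anion_mz("C8H5O4"), 4)   # 165.0193
#' @export
anion_mz <- function(formula) {
  monoisotopic_mass(formula) + .electron_mass
}

#' Neutral monoisotopic mass from an [M-H]- m/z
#'
#' Adds back the proton (H atom minus the electron already on the anion).
#'
#' @param mz Observed m/z of a singly charged deprotonated anion.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass_from_mz <- function(mz) {
  mz + .monoisotopic[["H"]] - .electron_mass
}

#' RDBE of the neutral molecule reconstructed from an [M-H]- composition
#'
#' For a CHO anion `CxHyOz` the neutral is `CxH(y+1)Oz` and
#' RDBE = C - (y + 1)/2 + 1; integer for even-electron neutrals. A
#' monophthalate skeleton (aromatic ring + two carbonyls) gives RDBE 6.
#'
#' @param ion_formula The ionic composition ([formula_cho()] or string).
#' @return RDBE value of the reconstructed neutral.
#' @examples
#' rdbe_neutral("C10H9O4")  # monoethyl phthalate anion -> 6
#' @export
rdbe_neutral <- function(ion_formula) {
  f <- .as_formula(ion_formula)
  f$n_carbon - (f$n_hydrogen + 1) / 2 + 1
}

#' Elemental composition restrictions for monophthalate features
#'
#' The constraint set used during formula enumeration: carbon 8-30, hydrogen
#' 6-60, oxygen 4-10, no other elements, charge -1, even-electron rule, RDBE
#' 6-12, mass tolerance 5 ppm. `snr_min` (S/N threshold 3) and
#' `min_spectral_fit` (an isotope-fit score of the vendor software, value 10)
#' are carried as metadata; the latter is never evaluated here because its
#' algorithm is proprietary.
#'
#' @param c_min,c_max,h_min,h_max,o_min,o_max Element count bounds (H bounds
#'   apply to the ion's hydrogen count).
#' @param rdbe_min,rdbe_max RDBE bounds, evaluated on the reconstructed
#'   neutral.
#' @param mass_tol_ppm Mass tolerance in ppm (closed window).
#' @param snr_min Chromatographic S/N threshold carried to peak detection.
#' @param min_spectral_fit Recorded, not evaluated.
#' @param even_electron Require the ion to be the deprotonation product of an
#'   even-electron neutral (ion hydrogen count odd).
#' @return A `composition_constraints` list.
#' @export
composition_constraints <- function(c_min = 8L, c_max = 30L,
                                    h_min = 6L, h_max = 60L,
                                    o_min = 4L, o_max = 10L,
                                    rdbe_min = 6, rdbe_max = 12,
                                    mass_tol_ppm = 5, snr_min = 3,
                                    min_spectral_fit = 10,
                                    even_electron = TRUE) {
  stopifnot(c_min <= c_max, h_min <= h_max, o_min <= o_max,
            rdbe_min <= rdbe_max, mass_tol_ppm > 0)
  structure(
    list(c_min = c_min, c_max = c_max, h_min = h_min, h_max = h_max,
         o_min = o_min, o_max = o_max, charge = -1L,
         rdbe_min = rdbe_min, rdbe_max = rdbe_max,
         mass_tol_ppm = mass_tol_ppm, snr_min = snr_min,
         min_spectral_fit = min_spectral_fit, even_electron = even_electron),
    class = "composition_constraints"
  )
}

#' Diagnostic fragment ions of the monophthalate skeleton
#'
#' The native trio (m/z 121.0295 C7H5O2-, 147.0088 C8H3O3-, 165.0193 C8H5O4-)
#' drives the two-of-three candidacy rule. m/z 134.0377 is a supplementary ion
#' specific to pure-alkyl-chain monophthalates: it flags the subclass but never
#' counts toward the two-of-three rule. The labelled trio (124.0397, 151.0223,
#' 169.0329) screens isotope-labelled internal standards; these constants are
#' stored as published, not derived from a labelling model.
#'
#' @param match_tol_ppm Fragment matching tolerance in ppm.
#' @return A `diagnostic_ion_set` list.
#' @export
diagnostic_ion_set <- function(match_tol_ppm = 5) {
  structure(
    list(native_trio = c(121.0295, 147.0088, 165.0193),
         supplementary = 134.0377,
         labelled_trio = c(124.0397, 151.0223, 169.0329),
         match_tol_ppm = match_tol_ppm),
    class = "diagnostic_ion_set"
  )
}

#' Enumerate CHO anion formulas matching an observed m/z
#'
#' Exhaustive scan of the (C, H, O) grid inside the elemental composition
#' restrictions. A composition is kept when its anion m/z lies within
#' `mass_tol_ppm` of `observed_mz` (closed window), the RDBE of the
#' reconstructed neutral lies in `[rdbe_min, rdbe_max]`, and (even-electron
#' rule) the ion hydrogen count is odd. Results are sorted by absolute ppm
#' error; ties broken by fewer oxygens, then (C, H) lexicographically.
#'
#' @param observed_mz Observed m/z of a singly charged anion.
#' @param constraints A [composition_constraints()] object.
#' @return A data.frame with columns `formula`, `n_carbon`, `n_hydrogen`,
#'   `n_oxygen`, `mz`, `ppm_error`, `rdbe` (zero rows when nothing matches —
#'   the feature is "filtered out" by the elemental restriction, not an
#'   error).
#' @examples
#' enumerate_formulas(321.1709)  # contains C18H25O5 (neutral C18H26O5)
#' @export
enumerate_formulas <- function(observed_mz,
                               constraints = composition_constraints()) {
  stopifnot(observed_mz > 0)
  cs <- constraints
  h_all <- seq.int(cs$h_min, cs$h_max)
  if (cs$even_electron) h_all <- h_all[h_all %% 2L == 1L]
  grid <- expand.grid(n_carbon = seq.int(cs$c_min, cs$c_max),
                      n_hydrogen = h_all,
                      n_oxygen = seq.int(cs$o_min, cs$o_max),
                      KEEP.OUT.ATTRS = FALSE)
  mz <- grid$n_carbon * .monoisotopic[["C"]] +
    grid$n_hydrogen * .monoisotopic[["H"]] +
    grid$n_oxygen * .monoisotopic[["O"]] + .electron_mass
  ppm <- (mz - observed_mz) / observed_mz * 1e6
  rdbe <- grid$n_carbon - (grid$n_hydrogen + 1) / 2 + 1
  keep <- abs(ppm) <= cs$mass_tol_ppm & rdbe >= cs$rdbe_min & rdbe <= cs$rdbe_max
  out <- grid[keep, , drop = FALSE]
  out$mz <- mz[keep]
  out$ppm_error <- ppm[keep]
  out$rdbe <- rdbe[keep]
  ord <- order(abs(out$ppm_error), out$n_oxygen, out$n_carbon, out$n_hydrogen)
  out <- out[ord, , drop = FALSE]
  out$formula <- vapply(
    seq_len(nrow(out)),
    function(i) format(formula_cho(out$n_carbon[i], out$n_hydrogen[i],
                                   out$n_oxygen[i])),
    character(1)
  )
  rownames(out) <- NULL
  out[, c("formula", "n_carbon", "n_hydrogen", "n_oxygen", "mz",
          "ppm_error", "rdbe")]
}
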