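# Composition and mass arithmetic for LCO structures.
#
# A chitooligosaccharide of n GlcNAc residues is C(8n) H(13n+2) N(n) O(5n+1)
# (n dehydro residues of C8H13NO5 plus one H2O). The N-acyl chain replaces
# the N-acetyl (C2H2O, ketene equivalent, 42 Da nominal) of the
# non-reducing-terminal residue with the fatty acyl moiety
# C(c) H(2c-2-2d) O(1+h). Substituent increments relative to H:
# carbamoyl +CHNO (43), O-acetyl +C2H2O (42), methyl +CH2 (14).

.glcnac_residue <- function() {
  elemental_composition(C = 8, H = 13, N = 1, O = 5)
}

.water <- function() elemental_composition(H = 2, O = 1)

.n_acetyl_delta <- function() elemental_composition(C = 2, H = 2, O = 1)

.carbamoyl_delta <- function() elemental_composition(C = 1, H = 1, N = 1, O = 1)

.o_acetyl_delta <- function() elemental_composition(C = 2, H = 2, O = 1)

.methyl_delta <- function() elemental_composition(C = 1, H = 2)

# neutral acetic acid, lost from O-acetylated ions in CID
.acetic_acid <- function() elemental_composition(C = 2, H = 4, O = 2)

#' Elemental composition of an acyl chain moiety
#'
#' The fatty acyl group as attached to the backbone amine:
#' C(c) H(2c - 2 - 2d) O(1 + h) for c carbons, d double bonds and h chain
#' hydroxyls.
#'
#' @param acyl an [acyl_chain()].
#' @return An [elemental_composition()].
#' @export
acyl_composition <- function(acyl) {
  stopifnot(inherits(acyl, "acyl_chain"))
  h <- 2L * acyl$carbons - 2L - 2L * acyl$double_bonds
  if (h < 0) stop("invalid chemistry: acyl chain ", acyl$carbons, ":",
                  acyl$double_bonds, " has negative hydrogen count",
                  call. = FALSE)
  elemental_composition(C = acyl$carbons, H = h, O = 1L + acyl$hydroxyls)
}

#' Composition of one backbone residue, with its position-specific groups
#'
#' Residue 1 (non-reducing terminus) carries the acyl chain in place of its
#' N-acetyl, plus the carbamoyl when present; residue 2 carries the O-acetyl
#' when present; the reducing-terminal residue carries the methyl when
#' present. All residues are the dehydro (in-chain) form C8H13NO5; the
#' terminal water of the intact molecule is accounted separately.
#'
#' @param s an [lco_structure()].
#' @param k residue index, 1 = non-reducing terminus.
#' @return An [elemental_composition()].
#' @export
residue_composition <- function(s, k) {
  stopifnot(inherits(s, "lco_structure"))
  k <- as.integer(k)
  if (k < 1L || k > s$backbone_length) {
    stop("residue index out of range", call. = FALSE)
  }
  comp <- .glcnac_residue()
  if (k == 1L) {
    comp <- comp_subtract(comp, .n_acetyl_delta())
    comp <- comp_add(comp, acyl_composition(s$acyl))
    if (s$substituents$carbamoyl) comp <- comp_add(comp, .carbamoyl_delta())
  }
  if (k == 2L && s$substituents$o_acetyl) {
    comp <- comp_add(comp, .o_acetyl_delta())
  }
  if (k == s$backbone_length && s$substituents$methyl) {
    comp <- comp_add(comp, .methyl_delta())
  }
  comp
}

#' Elemental composition of the neutral LCO molecule
#'
#' Sum of the residue compositions plus one water (the free reducing end).
#'
#' @param s an [lco_structure()].
#' @return An [elemental_composition()].
#' @examples
#' s <- parse_nomenclature("IV(C20:3, Cb, OAc)")
#' nominal_mass(composition_of(s))  # 1161
#' @export
composition_of <- function(s) {
  stopifnot(inherits(s, "lco_structure"))
  comp <- .water()
  for (k in seq_len(s$backbone_length)) {
    comp <- comp_add(comp, residue_composition(s, k))
  }
  comp
}

.ADDUCTS <- c("H", "Na")

.adduct_nominal <- function(adduct) {
  switch(adduct, H = 1L, Na = 23L,
         stop("unsupported adduct ", sQuote(adduct), call. = FALSE))
}

.adduct_mono <- function(adduct) {
  switch(adduct, H = .MONO_MASS[["H"]], Na = .MONO_MASS[["Na"]],
         stop("unsupported adduct ", sQuote(adduct), call. = FALSE))
}

.check_adduct <- function(adduct) {
  if (!(is.character(adduct) && length(adduct) == 1L &&
        adduct %in% .ADDUCTS)) {
    stop("adduct must be \"H\" or \"Na\"", call. = FALSE)
  }
  adduct
}

#' Singly charged precursor m/z of an LCO
#'
#' Computes [M+H]+ or [M+Na]+ on both mass scales. Charge is always +1; no
#' multiply charged LCO species are modeled.
#'
#' @param s an [lco_structure()].
#' @param adduct `"H"` or `"Na"`.
#' @return An object of class `ion_mz` with fields `adduct`, `mz_nominal`
#'   (integer) and `mz_mono` (Da).
#' @examples
#' precursor_mz(parse_nomenclature("IV(C20:3, Cb, OAc)"), "H")  # 1162
#' @export
precursor_mz <- function(s, adduct = c("H", "Na")) {
  adduct <- .check_adduct(match.arg(adduct))
  comp <- composition_of(s)
  structure(list(adduct = adduct,
                 mz_nominal = nominal_mass(comp) + .adduct_nominal(adduct),
                 mz_mono = monoisotopic_mass(comp) + .adduct_mono(adduct)),
            class = "ion_mz")
}

#' @export
print.ion_mz <- function(x, ...) {
  cat(sprintf("[M+%s]+  nominal %d  mono %.4f\n", x$adduct, x$mz_nominal,
              x$mz_mono))
  invisible(x)
}
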