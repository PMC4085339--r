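# The two inferences drawn from the assignment tables:
#  (1) wild type vs acetyltransferase mutant — pair every O-acetylated
#      wild-type species with its de-O-acetylated counterpart in the mutant
#      and test whether acetylation is lost;
#  (2) mild-base de-O-acetylation consistency — the -42 precursor shift,
#      conserved B1, -42 on every Bk (k >= 2), and disappearance of the
#      acetic-acid-loss companions.
# Both operate at the assignment level, not on raw peaks. Structures that
# differ only in adduct are collapsed first: the adduct is an ionization
# artifact, not chemistry.

#' A set of accepted species assignments for one sample
#'
#' @param sample_id text identifier.
#' @param nomenclature character vector of structure strings.
#' @param adduct matching character vector of `"H"`/`"Na"`.
#' @return An object of class `species_set`; duplicate (structure, adduct)
#'   pairs are dropped.
#' @export
species_set <- function(sample_id, nomenclature, adduct) {
  stopifnot(length(nomenclature) == length(adduct))
  canon <- vapply(nomenclature,
                  function(x) format_nomenclature(parse_nomenclature(x)),
                  character(1), USE.NAMES = FALSE)
  df <- unique(data.frame(nomenclature = canon, adduct = adduct,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  structure(list(sample_id = sample_id, species = df),
            class = "species_set")
}

#' @export
print.species_set <- function(x, ...) {
  cat(sprintf("species_set '%s': %d (structure, adduct) assignments\n",
              x$sample_id, nrow(x$species)))
  invisible(x)
}

.collapse_adducts <- function(set) unique(set$species$nomenclature)

.is_oac <- function(nom) {
  vapply(nom, function(x) parse_nomenclature(x)$substituents$o_acetyl,
         logical(1), USE.NAMES = FALSE)
}

#' Pair O-acetylated species in one sample with their bare counterparts
#'
#' For every O-acetylated structure in `a`, looks for the structure in `b`
#' identical except for `o_acetyl = FALSE`. Adducts are collapsed before
#' pairing. Counts of distinct acetylated structures per sample and the
#' unpaired species are reported.
#'
#' @param a,b [species_set()] objects (e.g. wild type and mutant).
#' @return An object of class `differential_report` with fields
#'   `acetylated_in_a`, `acetylated_in_b`, `oac_pairs`, `unpaired_a`,
#'   `unpaired_b` and a default `verdict` from [acetylation_verdict()].
#' @export
pair_by_acetyl <- function(a, b) {
  stopifnot(inherits(a, "species_set"), inherits(b, "species_set"))
  sa <- .collapse_adducts(a)
  sb <- .collapse_adducts(b)
  oac_a <- sa[.is_oac(sa)]
  oac_b <- sb[.is_oac(sb)]
  deac <- vapply(oac_a, function(x) {
    format_nomenclature(de_O_acetylate(parse_nomenclature(x)))
  }, character(1), USE.NAMES = FALSE)
  paired <- deac %in% sb
  pairs <- data.frame(acetylated_a = oac_a[paired],
                      deacetylated_b = deac[paired],
                      stringsAsFactors = FALSE)
  rep <- structure(list(
    sample_a = a$sample_id, sample_b = b$sample_id,
    acetylated_in_a = length(oac_a),
    acetylated_in_b = length(oac_b),
    oac_pairs = pairs,
    unpaired_a = oac_a[!paired],
    unpaired_b = setdiff(sb, c(deac, sa)),
    verdict = NA_character_), class = "differential_report")
  rep$verdict <- acetylation_verdict(rep)
  rep
}

#' Acetylation verdict from a differential report
#'
#' `ACETYLATION_LOST` when sample A contains at least `min_acetylated`
#' distinct O-acetylated structures and sample B contains none;
#' `NO_CHANGE` when both samples carry equal acetylated counts (including
#' both zero); otherwise `INCONCLUSIVE`.
#'
#' @param report a `differential_report`.
#' @param min_acetylated minimum acetylated species in A to call a loss
#'   (>= 1; default 1).
#' @return One of `"ACETYLATION_LOST"`, `"NO_CHANGE"`, `"INCONCLUSIVE"`.
#' @export
acetylation_verdict <- function(report, min_acetylated = 1L) {
  stopifnot(inherits(report, "differential_report"))
  if (min_acetylated < 1L) stop("min_acetylated must be >= 1", call. = FALSE)
  na <- report$acetylated_in_a
  nb <- report$acetylated_in_b
  if (na >= min_acetylated && nb == 0L) return("ACETYLATION_LOST")
  if (na == nb) return("NO_CHANGE")
  "INCONCLUSIVE"
}

#' @export
print.differential_report <- function(x, ...) {
  cat(sprintf("differential %s vs %s\n", x$sample_a, x$sample_b))
  cat(sprintf("  acetylated structures: %d vs %d\n", x$acetylated_in_a,
              x$acetylated_in_b))
  if (nrow(x$oac_pairs) > 0) {
    for (i in seq_len(nrow(x$oac_pairs))) {
      cat(sprintf("  %s -> %s\n", x$oac_pairs$acetylated_a[i],
                  x$oac_pairs$deacetylated_b[i]))
    }
  }
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Check model consistency of the de-O-acetylation transform
#'
#' Predicts the spectrum of an O-acetylated structure before and after
#' mild-base de-O-acetylation and verifies the expected pattern: precursor
#' shifted by exactly -42 (nominal), B1 conserved, every Bk with k >= 2
#' shifted by -42, and no acetic-acid-loss companions remaining after
#' treatment. Optional observed peak lists are checked against the
#' predictions (every predicted ion must be supported by a peak).
#'
#' @param s an O-acetylated [lco_structure()].
#' @param adduct `"H"` or `"Na"`.
#' @param before_peaks,after_peaks optional [peaklist()]s of the observed
#'   spectra before/after base treatment.
#' @param params a [match_params()] used for the observed comparison.
#' @return An object of class `base_treatment_check` with the before/after
#'   predicted ion sets, the shifts, the component flags and `consistent`.
#' @export
verify_base_treatment <- function(s, adduct = c("H", "Na"),
                                  before_peaks = NULL, after_peaks = NULL,
                                  params = match_params(nominal_mode = TRUE)) {
  adduct <- .check_adduct(match.arg(adduct))
  if (!s$substituents$o_acetyl) {
    stop("structure carries no O-acetyl group", call. = FALSE)
  }
  s2 <- de_O_acetylate(s)
  before <- predict_spectrum(s, adduct)
  after <- predict_spectrum(s2, adduct)
  bb <- before$ions[before$ions$series == "B" & !before$ions$acetic_acid_loss, ]
  ba <- after$ions[after$ions$series == "B" & !after$ions$acetic_acid_loss, ]
  shifts <- ba$mz_nominal - bb$mz_nominal[match(ba$index, bb$index)]
  precursor_shift <- after$precursor$mz_nominal - before$precursor$mz_nominal
  b1_conserved <- shifts[ba$index == 1L] == 0L
  k2 <- ba$index >= 2L
  losses_absent_after <- !any(after$ions$acetic_acid_loss)
  consistent <- precursor_shift == -42L && isTRUE(all(b1_conserved)) &&
    all(shifts[k2] == -42L) && losses_absent_after
  obs_ok <- NA
  if (!is.null(before_peaks) && !is.null(after_peaks)) {
    support <- function(pset, pl) {
      all(vapply(seq_len(nrow(pset$ions)), function(i) {
        any(.mz_matches(pl$peaks$mz, pset$ions$mz_nominal[i],
                        pset$ions$mz_mono[i], params)) ||
          (!is.null(pl$precursor_mz) &&
             .mz_matches(pl$precursor_mz, pset$ions$mz_nominal[i],
                         pset$ions$mz_mono[i], params))
      }, logical(1)))
    }
    obs_ok <- support(before, before_peaks) && support(after, after_peaks)
  }
  structure(list(structure = s, adduct = adduct,
                 before = before, after = after,
                 precursor_shift = precursor_shift,
                 b1_conserved = isTRUE(all(b1_conserved)),
                 bk_shifts = data.frame(index = ba$index, shift = shifts),
                 losses_absent_after = losses_absent_after,
                 consistent = consistent,
                 observed_consistent = obs_ok),
            class = "base_treatment_check")
}

#' @export
print.base_treatment_check <- function(x, ...) {
  cat(sprintf("de-O-acetylation check for %s [M+%s]+\n",
              format_nomenclature(x$structure), x$adduct))
  cat(sprintf("  precursor %d -> %d (shift %d)\n",
              x$before$precursor$mz_nominal, x$after$precursor$mz_nominal,
              x$precursor_shift))
  cat("  consistent:", x$consistent, "\n")
  invisible(x)
}
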