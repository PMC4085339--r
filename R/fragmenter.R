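# B-series fragment prediction. CID of these LCOs proceeds by glycosidic
# bond cleavage with charge retention on the non-reducing-terminal portion
# (B ions); a sodiated precursor yields sodiated fragments (adduct
# retention). O-acetylated ions additionally eliminate neutral acetic acid
# (C2H4O2, 60 Da nominal), giving -60 companions of the precursor and of
# every B ion that contains the O-acetylated residue (k >= 2 under the
# fixed position-2 convention).

.ion_row <- function(label, series, index, adduct, loss, nom, mono) {
  data.frame(ion_label = label, series = series, index = index,
             adduct = adduct, acetic_acid_loss = loss,
             mz_nominal = as.integer(nom), mz_mono = mono,
             stringsAsFactors = FALSE)
}

#' Predict the B-ion series of an LCO
#'
#' The Bk ion spans the k non-reducing-end residues; no B ion includes the
#' reducing-terminal residue, so the reducing-end methyl is invisible to the
#' whole series. The fragment retains the precursor's charge carrier
#' (protonated precursors give protonated B ions, sodiated give sodiated).
#'
#' @param s an [lco_structure()].
#' @param adduct `"H"` or `"Na"`.
#' @return A data.frame of fragments B1..B(n-1) with columns `ion_label`,
#'   `series`, `index`, `adduct`, `acetic_acid_loss`, `mz_nominal`,
#'   `mz_mono`, sorted by index.
#' @examples
#' b_ions(parse_nomenclature("IV(C20:3, Cb, OAc)"), "H")  # 493, 738, 941
#' @export
b_ions <- function(s, adduct = c("H", "Na")) {
  stopifnot(inherits(s, "lco_structure"))
  adduct <- .check_adduct(match.arg(adduct))
  n <- s$backbone_length
  if (n < 2L) stop("backbone too short for B ions", call. = FALSE)
  rows <- vector("list", n - 1L)
  comp <- elemental_composition()
  for (k in seq_len(n - 1L)) {
    comp <- comp_add(comp, residue_composition(s, k))
    rows[[k]] <- .ion_row(paste0("B", k), "B", k, adduct, FALSE,
                          nominal_mass(comp) + .adduct_nominal(adduct),
                          monoisotopic_mass(comp) + .adduct_mono(adduct))
  }
  do.call(rbind, rows)
}

#' Remove the O-acetyl group from a structure (mild base treatment)
#'
#' Models de-O-acetylation under mild basic conditions, which cleave the
#' ester-linked acetyl while leaving the amide-bound acyl chain in place.
#' Drops every ion containing the acetylated residue by 42 m/z (nominal).
#'
#' @param s an O-acetylated [lco_structure()].
#' @return The same structure with `o_acetyl = FALSE`.
#' @export
de_O_acetylate <- function(s) {
  stopifnot(inherits(s, "lco_structure"))
  if (!s$substituents$o_acetyl) {
    stop("structure carries no O-acetyl group", call. = FALSE)
  }
  s$substituents$o_acetyl <- FALSE
  s
}

#' Predicted ion set for one structure/adduct
#'
#' Precursor ion, B-series fragments and (for O-acetylated structures)
#' acetic-acid neutral-loss companions, deduplicated on nominal m/z with
#' merged labels so provenance is retained.
#'
#' @param s an [lco_structure()].
#' @param adduct `"H"` or `"Na"`.
#' @param neutral_losses add -60 companions for O-acetylated structures
#'   (default TRUE).
#' @return An object of class `predicted_ion_set`: a list with `structure`,
#'   `adduct`, `precursor` (an `ion_mz`) and `ions`, a data.frame of all
#'   predicted ions including the precursor row.
#' @examples
#' predict_spectrum(parse_nomenclature("IV(C20:3, Cb, OAc)"), "H")
#' @export
predict_spectrum <- function(s, adduct = c("H", "Na"),
                             neutral_losses = TRUE) {
  adduct <- .check_adduct(match.arg(adduct))
  prec <- precursor_mz(s, adduct)
  prec_row <- .ion_row(sprintf("[M+%s]+", adduct), "precursor", 0L,
                       adduct, FALSE, prec$mz_nominal, prec$mz_mono)
  ions <- rbind(prec_row, b_ions(s, adduct))
  out <- structure(list(structure = s, adduct = adduct, precursor = prec,
                        ions = ions),
                   class = "predicted_ion_set")
  if (neutral_losses) out <- acetic_acid_companions(out)
  .dedup_ions(out)
}

#' Add acetic-acid neutral-loss companions to a predicted ion set
#'
#' If the structure is O-acetylated, appends -60 (nominal; -60.0211 Da
#' monoisotopic) companions for the precursor and for every Bk with k >= 2
#' (the ions containing the O-acetylated residue 2). A set for a
#' non-acetylated structure is returned unchanged.
#'
#' @param pset a `predicted_ion_set`.
#' @return The augmented `predicted_ion_set`.
#' @export
acetic_acid_companions <- function(pset) {
  stopifnot(inherits(pset, "predicted_ion_set"))
  s <- pset$structure
  if (!s$substituents$o_acetyl) return(pset)
  ions <- pset$ions
  carriers <- ions[!ions$acetic_acid_loss &
                     (ions$series == "precursor" |
                        (ions$series == "B" & ions$index >= 2L)), ,
                   drop = FALSE]
  if (nrow(carriers) == 0) return(pset)
  loss_nom <- nominal_mass(.acetic_acid())
  loss_mono <- monoisotopic_mass(.acetic_acid())
  loss <- carriers
  loss$ion_label <- paste0(carriers$ion_label, "-60")
  loss$acetic_acid_loss <- TRUE
  loss$mz_nominal <- carriers$mz_nominal - loss_nom
  loss$mz_mono <- carriers$mz_mono - loss_mono
  pset$ions <- rbind(ions, loss)
  .dedup_ions(pset)
}

# merge rows sharing a nominal m/z, concatenating labels; sort precursor
# first then B index, losses after their parents
.dedup_ions <- function(pset) {
  ions <- pset$ions
  ord <- order(ions$series != "precursor", ions$index, ions$acetic_acid_loss)
  ions <- ions[ord, , drop = FALSE]
  if (anyDuplicated(ions$mz_nominal)) {
    keep <- !duplicated(ions$mz_nominal)
    merged <- vapply(ions$mz_nominal[keep], function(mz) {
      paste(ions$ion_label[ions$mz_nominal == mz], collapse = "/")
    }, character(1))
    ions <- ions[keep, , drop = FALSE]
    ions$ion_label <- merged
  }
  rownames(ions) <- NULL
  pset$ions <- ions
  pset
}

#' @export
print.predicted_ion_set <- function(x, ...) {
  cat(sprintf("%s  [M+%s]+\n", format_nomenclature(x$structure), x$adduct))
  print(x$ions[, c("ion_label", "mz_nominal", "mz_mono")], row.names = FALSE)
  invisible(x)
}

#' Flat ion table for one or more predicted ion sets
#'
#' @param ... `predicted_ion_set` objects (or one list of them).
#' @return A data.frame with columns nomenclature, adduct, ion_label,
#'   nominal_mz, mono_mz.
#' @export
ion_table <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "predicted_ion_set")) {
    sets <- sets[[1]]
  }
  do.call(rbind, lapply(sets, function(p) {
    data.frame(nomenclature = format_nomenclature(p$structure),
               adduct = p$adduct,
               ion_label = p$ions$ion_label,
               nominal_mz = p$ions$mz_nominal,
               mono_mz = p$ions$mz_mono,
               stringsAsFactors = FALSE)
  }))
}
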