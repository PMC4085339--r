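# Packaged reference data: the published unit-resolution assignment table
# for the LCOs of N. galegae HAMBI 1174 (wild type) and its noeT mutant
# (HAMBI 3275), and the before/after mild-base de-O-acetylation table for
# the four O-acetylated wild-type species. Reproduction functions re-predict
# every row from the structure string alone and diff against the printed
# cells. Two printed quirks are handled as data, not model behaviour: the
# 1136 row omits its B1 cell (the fixture stores only printed fragments and
# the comparison checks printed cells only), and a prose report of 987 for
# one B3 conflicts with the tabulated 897 that the 203-increment rule
# forces — the model emits 897.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "lcoms", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.split_frags <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(v) as.integer(v))
}

#' Published LCO assignments for wild type and noeT mutant
#'
#' One row per reported precursor: printed parent m/z, adduct, printed
#' fragment ions and the assigned structure string.
#'
#' @param sample `"wild_type"`, `"noeT_mutant"` or `"all"` (default).
#' @return A data.frame with columns `sample`, `parent_mz`, `adduct`,
#'   `fragments` (list column of integer vectors), `structure`.
#' @export
reference_assignments <- function(sample = c("all", "wild_type",
                                             "noeT_mutant")) {
  sample <- match.arg(sample)
  df <- .extdata("lco_reference_assignments.csv")
  if (sample != "all") df <- df[df$sample == sample, , drop = FALSE]
  df$fragments <- .split_frags(df$fragments)
  rownames(df) <- NULL
  df
}

#' Published before/after de-O-acetylation data
#'
#' @return A data.frame with the four O-acetylated wild-type species:
#'   precursor and fragment ions before and after mild base treatment,
#'   and the assigned structures.
#' @export
reference_deacetylation <- function() {
  df <- .extdata("lco_deacetylation_reference.csv")
  df$fragments_before <- .split_frags(df$fragments_before)
  df$fragments_after <- .split_frags(df$fragments_after)
  df
}

#' Species sets of the reference assignment table
#'
#' @return A list with `wild_type` and `noeT_mutant` [species_set()]s.
#' @export
reference_species_sets <- function() {
  df <- reference_assignments()
  make <- function(id) {
    sub <- df[df$sample == id, ]
    species_set(id, sub$structure, sub$adduct)
  }
  list(wild_type = make("wild_type"), noeT_mutant = make("noeT_mutant"))
}

#' Reproduce the reference assignment table from the structure strings
#'
#' For every reference row, predicts the full ion set of the assigned
#' structure/adduct in nominal mode and compares: the parent ion must equal
#' the printed value, and every printed fragment must appear among the
#' predicted nominal m/z values.
#'
#' @param sample passed to [reference_assignments()].
#' @return A data.frame with per-row columns `parent_ok`,
#'   `fragments_printed`, `fragments_matched`, `ok`.
#' @export
reproduce_assignment_table <- function(sample = "all") {
  df <- reference_assignments(sample)
  res <- lapply(seq_len(nrow(df)), function(i) {
    s <- parse_nomenclature(df$structure[i])
    pset <- predict_spectrum(s, df$adduct[i])
    frags <- df$fragments[[i]]
    matched <- sum(frags %in% pset$ions$mz_nominal)
    data.frame(parent_ok = pset$precursor$mz_nominal == df$parent_mz[i],
               fragments_printed = length(frags),
               fragments_matched = matched)
  })
  out <- cbind(df[, c("sample", "parent_mz", "adduct", "structure")],
               do.call(rbind, res))
  out$ok <- out$parent_ok & out$fragments_matched == out$fragments_printed
  out
}

#' Reproduce the de-O-acetylation table
#'
#' For each of the four rows, runs [de_O_acetylate()] and
#' [predict_spectrum()] on the assigned before-structure and compares the
#' predicted before/after precursor and fragment ions against the printed
#' cells (nominal, exact).
#'
#' @return A data.frame with per-row columns `precursor_ok`, `before_ok`,
#'   `after_ok`, `shift_ok`, `ok`.
#' @export
reproduce_deacetylation_table <- function() {
  df <- reference_deacetylation()
  res <- lapply(seq_len(nrow(df)), function(i) {
    s <- parse_nomenclature(df$structure_before[i])
    chk <- verify_base_treatment(s, df$adduct[i])
    after_structure <- format_nomenclature(chk$after$structure)
    before_ok <- all(df$fragments_before[[i]] %in% chk$before$ions$mz_nominal)
    after_ok <- all(df$fragments_after[[i]] %in% chk$after$ions$mz_nominal)
    data.frame(
      precursor_ok = chk$before$precursor$mz_nominal == df$precursor_before[i] &&
        chk$after$precursor$mz_nominal == df$precursor_after[i],
      before_ok = before_ok,
      after_ok = after_ok,
      structure_after_ok = after_structure ==
        format_nomenclature(parse_nomenclature(df$structure_after[i])),
      shift_ok = chk$consistent)
  })
  out <- cbind(df[, c("adduct", "precursor_before", "precursor_after",
                      "structure_before")],
               do.call(rbind, res))
  out$ok <- out$precursor_ok & out$before_ok & out$after_ok &
    out$structure_after_ok & out$shift_ok
  out
}
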