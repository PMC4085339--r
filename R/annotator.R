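# Peak-list annotation: match observed precursor and fragment peaks against
# enumerated candidate structures. Scoring counts matched predicted ions
# (B ions and acetic-acid-loss companions); intensity is carried for
# reporting but never scored — assignments argue from ion presence.

#' Observed peak list
#'
#' @param mz numeric vector of fragment m/z values (> 0).
#' @param intensity numeric vector of intensities (>= 0); defaults to 1.
#' @param precursor_mz the precursor ion m/z, if known.
#' @param sample_id text identifier.
#' @param metadata named list of free-form metadata.
#' @return An object of class `peaklist`; peaks are stored sorted ascending
#'   by m/z.
#' @export
peaklist <- function(mz, intensity = NULL, precursor_mz = NULL,
                     sample_id = "", metadata = list()) {
  mz <- as.numeric(mz)
  if (length(mz) > 0 && any(!is.finite(mz) | mz <= 0)) {
    stop("peak m/z values must be positive and finite", call. = FALSE)
  }
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(mz)) {
    stop("mz and intensity lengths differ", call. = FALSE)
  }
  if (length(intensity) > 0 && any(!is.finite(intensity) | intensity < 0)) {
    stop("intensities must be non-negative and finite", call. = FALSE)
  }
  ord <- order(mz)
  structure(list(peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
                 precursor_mz = if (is.null(precursor_mz)) NULL
                                else as.numeric(precursor_mz),
                 sample_id = sample_id, metadata = metadata),
            class = "peaklist")
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("peaklist '%s': %d peaks, precursor %s\n", x$sample_id,
              nrow(x$peaks),
              if (is.null(x$precursor_mz)) "unset"
              else sprintf("%.4f", x$precursor_mz)))
  invisible(x)
}

#' Matching parameters
#'
#' Two matching regimes: `nominal_mode = TRUE` compares rounded observed
#' m/z against nominal integer predictions with exact equality (used to
#' reproduce printed unit-resolution tables); otherwise observed m/z are
#' compared against monoisotopic predictions within `tolerance_da`.
#'
#' @param tolerance_da monoisotopic matching window in Da (default 0.5,
#'   suiting unit-resolution instruments).
#' @param nominal_mode logical; exact integer matching.
#' @param adducts subset of `c("H", "Na")` to consider.
#' @param min_fragment_matches minimum score for a candidate to be reported
#'   (default 0, so precursor-only annotation is possible).
#' @return An object of class `match_params`.
#' @export
match_params <- function(tolerance_da = 0.5, nominal_mode = FALSE,
                         adducts = c("H", "Na"),
                         min_fragment_matches = 0L) {
  if (!is.numeric(tolerance_da) || tolerance_da <= 0) {
    stop("tolerance_da must be positive", call. = FALSE)
  }
  adducts <- unique(match.arg(adducts, several.ok = TRUE))
  structure(list(tolerance_da = tolerance_da,
                 nominal_mode = isTRUE(nominal_mode),
                 adducts = adducts,
                 min_fragment_matches = as.integer(min_fragment_matches)),
            class = "match_params")
}

.mz_matches <- function(observed, predicted_nom, predicted_mono, params) {
  if (params$nominal_mode) {
    round(observed) == predicted_nom
  } else {
    abs(observed - predicted_mono) <= params$tolerance_da
  }
}

# precomputed precursor m/z tables per (space, adducts), so repeated
# annotation queries do not re-enumerate the space
.precursor_cache <- new.env(parent = emptyenv())

.candidate_table <- function(space, adducts) {
  key <- paste(utils::capture.output(utils::str(unclass(space))),
               paste(adducts, collapse = ","), collapse = "|")
  key <- paste(key, collapse = "|")
  hit <- .precursor_cache[[key]]
  if (!is.null(hit)) return(hit)
  structures <- enumerate_structures(space)
  tabs <- lapply(adducts, function(adduct) {
    noms <- vapply(structures, function(s) {
      nominal_mass(composition_of(s)) + .adduct_nominal(adduct)
    }, numeric(1))
    monos <- vapply(structures, function(s) {
      monoisotopic_mass(composition_of(s)) + .adduct_mono(adduct)
    }, numeric(1))
    list(adduct = rep(adduct, length(structures)), nominal = noms,
         mono = monos)
  })
  out <- list(structures = rep(structures, length(adducts)),
              adduct = unlist(lapply(tabs, `[[`, "adduct")),
              nominal = unlist(lapply(tabs, `[[`, "nominal")),
              mono = unlist(lapply(tabs, `[[`, "mono")))
  .precursor_cache[[key]] <- out
  out
}

#' Find candidate structures matching a precursor m/z
#'
#' Enumerates the search space over the allowed adducts and keeps every
#' (structure, adduct) pair whose predicted precursor matches the query
#' (nominal equality in nominal mode, else within `tolerance_da` of the
#' monoisotopic value). Order is deterministic: enumeration order within
#' adduct, H before Na. Precursor tables are cached per (space, adducts),
#' so repeated queries are cheap.
#'
#' @param mz query precursor m/z (> 0).
#' @param space a [search_space()].
#' @param params a [match_params()].
#' @return A list of candidates, each `list(structure =, adduct =)`.
#' @export
annotate_precursor <- function(mz, space, params = match_params()) {
  stopifnot(is.numeric(mz), length(mz) == 1L, mz > 0)
  tab <- .candidate_table(space, params$adducts)
  hit <- which(.mz_matches(mz, tab$nominal, tab$mono, params))
  lapply(hit, function(i) list(structure = tab$structures[[i]],
                               adduct = tab$adduct[i]))
}

#' Score one candidate against an observed peak list
#'
#' The score is the number of predicted non-precursor ions (B ions plus
#' acetic-acid-loss companions, including the precursor's -60 companion)
#' matched by at least one observed peak. Matching is greedy
#' nearest-neighbour: peaks are visited in ascending m/z and each peak
#' consumes at most one predicted ion (ties broken toward the lower
#' predicted m/z).
#'
#' @param structure an [lco_structure()].
#' @param adduct `"H"` or `"Na"`.
#' @param peaks a [peaklist()] (may be empty; score 0).
#' @param params a [match_params()].
#' @return An object of class `candidate_annotation` with the counts, the
#'   score and the matched peak map.
#' @export
score_candidate <- function(structure, adduct, peaks,
                            params = match_params()) {
  stopifnot(inherits(peaks, "peaklist"))
  pset <- predict_spectrum(structure, adduct)
  frag <- pset$ions[pset$ions$series != "precursor" |
                      pset$ions$acetic_acid_loss, , drop = FALSE]
  matched <- rep(FALSE, nrow(frag))
  map_obs <- numeric(0)
  map_lab <- character(0)
  for (omz in peaks$peaks$mz) {
    ok <- .mz_matches(omz, frag$mz_nominal, frag$mz_mono, params)
    if (!any(ok)) next
    cand <- which(ok)
    target <- if (params$nominal_mode) frag$mz_nominal else frag$mz_mono
    d <- abs(omz - target[cand])
    pick <- cand[order(d, target[cand])][1]
    matched[pick] <- TRUE
    map_obs <- c(map_obs, omz)
    map_lab <- c(map_lab, frag$ion_label[pick])
  }
  n_b <- sum(matched & !frag$acetic_acid_loss)
  n_loss <- sum(matched & frag$acetic_acid_loss)
  structure(list(structure = structure, adduct = adduct,
                 matched_fragments = n_b,
                 predicted_fragments = nrow(frag),
                 matched_losses = n_loss,
                 score = n_b + n_loss,
                 matched_peak_map = data.frame(observed_mz = map_obs,
                                               ion_label = map_lab,
                                               stringsAsFactors = FALSE)),
            class = "candidate_annotation")
}

#' Annotate a full spectrum
#'
#' Matches the precursor against the search space, scores every candidate
#' against the fragment peaks, and ranks by (score descending, fewer
#' substituents, nomenclature). Ties at the top score are reported, never
#' broken arbitrarily: isobaric assignments that the spectra cannot
#' distinguish (the situation behind duplicate table rows at one parent
#' m/z) surface as `ambiguity_flag = TRUE`.
#'
#' @param peaks a [peaklist()] with `precursor_mz` set.
#' @param space a [search_space()].
#' @param params a [match_params()].
#' @return An object of class `annotation_result`: query m/z, a ranked
#'   `candidates` data.frame (with the full `candidate_annotation` objects
#'   in `annotations`), `ambiguity_flag`, and `unmatched_peaks` (observed
#'   peaks not matched by any co-ranked top candidate, precursor included).
#' @export
annotate_spectrum <- function(peaks, space, params = match_params()) {
  stopifnot(inherits(peaks, "peaklist"))
  if (is.null(peaks$precursor_mz)) {
    stop("peak list has no precursor_mz", call. = FALSE)
  }
  cands <- annotate_precursor(peaks$precursor_mz, space, params)
  anns <- lapply(cands, function(cd) {
    score_candidate(cd$structure, cd$adduct, peaks, params)
  })
  keep <- vapply(anns, function(a) a$score >= params$min_fragment_matches,
                 logical(1))
  anns <- anns[keep]
  df <- data.frame(
    nomenclature = vapply(anns, function(a) format_nomenclature(a$structure),
                          character(1)),
    adduct = vapply(anns, function(a) a$adduct, character(1)),
    score = vapply(anns, function(a) a$score, numeric(1)),
    matched_fragments = vapply(anns, function(a) a$matched_fragments,
                               numeric(1)),
    matched_losses = vapply(anns, function(a) a$matched_losses, numeric(1)),
    predicted_fragments = vapply(anns, function(a) a$predicted_fragments,
                                 numeric(1)),
    n_substituents = vapply(anns, function(a) n_substituents(a$structure),
                            numeric(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-df$score, df$n_substituents, df$nomenclature, df$adduct)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  anns <- anns[ord]
  top <- if (nrow(df) > 0) which(df$score == df$score[1]) else integer(0)
  ambiguous <- length(top) >= 2
  unmatched <- peaks$peaks$mz
  if (length(top) > 0) {
    explained <- unique(unlist(lapply(anns[top], function(a) {
      a$matched_peak_map$observed_mz
    })))
    # peaks matching a top candidate's precursor are explained too
    for (i in top) {
      p <- precursor_mz(anns[[i]]$structure, anns[[i]]$adduct)
      hit <- .mz_matches(unmatched, p$mz_nominal, p$mz_mono, params)
      explained <- unique(c(explained, unmatched[hit]))
    }
    unmatched <- setdiff(unmatched, explained)
  }
  structure(list(precursor_mz = peaks$precursor_mz,
                 candidates = df,
                 annotations = anns,
                 ambiguity_flag = ambiguous,
                 unmatched_peaks = unmatched),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("precursor m/z %.4f: %d candidate(s)%s\n", x$precursor_mz,
              nrow(x$candidates),
              if (x$ambiguity_flag) " [ambiguous top rank]" else ""))
  if (nrow(x$candidates) > 0) print(utils::head(x$candidates, 10),
                                    row.names = FALSE)
  invisible(x)
}

#' Structures co-ranked at the top of an annotation result
#'
#' @param result an `annotation_result`.
#' @return A data.frame (nomenclature, adduct) of the candidates sharing
#'   the top score; zero rows if there were no candidates.
#' @export
top_candidates <- function(result) {
  stopifnot(inherits(result, "annotation_result"))
  df <- result$candidates
  if (nrow(df) == 0) return(df[, c("nomenclature", "adduct")])
  df[df$score == df$score[1], c("nomenclature", "adduct"), drop = FALSE]
}
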