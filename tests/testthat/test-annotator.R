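nominal <- match_params(nominal_mode = TRUE)

test_that("precursor annotation finds the isobaric assignments", {
  hits <- annotate_precursor(1162, search_space(), nominal)
  noms <- vapply(hits, function(h) {
    paste(format_nomenclature(h$structure), h$adduct)
  }, character(1))
  expect_true("IV(C20:3, Cb, OAc) H" %in% noms)
  expect_true("IV(C18:0, Cb, OAc) Na" %in% noms)

  hits <- annotate_precursor(1092, search_space(),
                             match_params(nominal_mode = TRUE,
                                          adducts = "Na"))
  noms <- vapply(hits, function(h) format_nomenclature(h$structure),
                 character(1))
  expect_true("IV(C16:0, Cb)" %in% noms)

  expect_length(annotate_precursor(100, search_space(), nominal), 0L)
})

test_that("candidate scoring counts matched predicted ions", {
  pl <- peaklist(c(493, 678, 738, 881, 941, 1102))
  ann <- score_candidate(parse_nomenclature("IV(C20:3, Cb, OAc)"), "H", pl,
                         nominal)
  expect_equal(ann$score, 6)
  expect_equal(ann$predicted_fragments, 6)
  expect_equal(ann$matched_fragments, 3)  # B1..B3
  expect_equal(ann$matched_losses, 3)     # -60 companions

  ann2 <- score_candidate(parse_nomenclature("IV(C18:1, Cb)"), "Na",
                          peaklist(c(491, 694, 897)), nominal)
  expect_equal(ann2$score, 3)
  expect_equal(ann2$predicted_fragments, 3)

  ann0 <- score_candidate(parse_nomenclature("IV(C18:1, Cb)"), "Na",
                          peaklist(numeric(0)), nominal)
  expect_equal(ann0$score, 0)
})

test_that("isobaric assignments co-rank with the ambiguity flag set", {
  r <- annotate_spectrum(peaklist(c(493, 678, 738, 881, 941, 1102),
                                  precursor_mz = 1162),
                         search_space(), nominal)
  top <- top_candidates(r)
  expect_equal(nrow(top), 2L)
  expect_true(r$ambiguity_flag)
  expect_setequal(paste(top$nomenclature, top$adduct),
                  c("IV(C20:3, Cb, OAc) H", "IV(C18:0, Cb, OAc) Na"))
})

test_that("an unambiguous mutant spectrum yields a single top assignment", {
  r <- annotate_spectrum(peaklist(c(491, 694, 897), precursor_mz = 1118),
                         search_space(),
                         match_params(nominal_mode = TRUE, adducts = "Na"))
  top <- top_candidates(r)
  expect_equal(nrow(top), 1L)
  expect_false(r$ambiguity_flag)
  expect_equal(top$nomenclature, "IV(C18:1, Cb)")
})

test_that("the 1120 isobar pair co-ranks under both adducts", {
  r <- annotate_spectrum(peaklist(c(493, 696, 899), precursor_mz = 1120),
                         search_space(), nominal)
  top <- top_candidates(r)
  expect_true(all(c("IV(C20:3, Cb)", "IV(C18:0, Cb)") %in% top$nomenclature))
  expect_setequal(top$adduct[match(c("IV(C20:3, Cb)", "IV(C18:0, Cb)"),
                                   top$nomenclature)], c("H", "Na"))
  expect_true(r$ambiguity_flag)
})

test_that("scores are monotone non-increasing as peaks are removed", {
  s <- parse_nomenclature("IV(C20:3, Cb, OAc)")
  peaks <- c(493, 678, 738, 881, 941, 1102)
  prev <- Inf
  for (n in rev(seq_along(peaks))) {
    sc <- score_candidate(s, "H", peaklist(peaks[seq_len(n)]), nominal)$score
    expect_lte(sc, prev)
    prev <- sc
  }
})

test_that("annotation is invariant under peak-list permutation", {
  set.seed(3)
  peaks <- c(493, 678, 738, 881, 941, 1102, 850.3, 612.8)
  r1 <- annotate_spectrum(peaklist(peaks, precursor_mz = 1162),
                          search_space(), nominal)
  r2 <- annotate_spectrum(peaklist(sample(peaks), precursor_mz = 1162),
                          search_space(), nominal)
  expect_identical(r1$candidates, r2$candidates)
  expect_identical(sort(r1$unmatched_peaks), sort(r2$unmatched_peaks))
})

test_that("unmatched peaks are reported and precursor is required", {
  r <- annotate_spectrum(peaklist(c(493, 678, 738, 881, 941, 1102, 444.4),
                                  precursor_mz = 1162),
                         search_space(), nominal)
  expect_equal(r$unmatched_peaks, 444.4)
  expect_error(annotate_spectrum(peaklist(c(493)), search_space(), nominal),
               "precursor")
})

test_that("min_fragment_matches filters sparse candidates", {
  r <- annotate_spectrum(peaklist(c(493, 678, 738, 881, 941, 1102),
                                  precursor_mz = 1162),
                         search_space(),
                         match_params(nominal_mode = TRUE,
                                      min_fragment_matches = 3))
  expect_true(all(r$candidates$score >= 3))
  expect_equal(nrow(r$candidates), 2L)
})

test_that("monoisotopic tolerance matching annotates jitter-free spectra", {
  s <- parse_nomenclature("IV(C20:1, Cb, OAc)")
  pset <- predict_spectrum(s, "Na")
  frag <- pset$ions[pset$ions$series == "B" | pset$ions$acetic_acid_loss, ]
  r <- annotate_spectrum(peaklist(frag$mz_mono,
                                  precursor_mz = pset$precursor$mz_mono),
                         search_space(), match_params())
  expect_true("IV(C20:1, Cb, OAc)" %in% top_candidates(r)$nomenclature)
})
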