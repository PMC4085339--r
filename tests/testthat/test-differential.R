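test_that("the reference assignment sets give ACETYLATION_LOST", {
  sets <- reference_species_sets()
  rep <- pair_by_acetyl(sets$wild_type, sets$noeT_mutant)
  # 7 O-acetylated rows in the wild-type table, 6 distinct structures
  # (IV(C20:3, Cb, OAc) is reported under both adducts)
  wt <- reference_assignments("wild_type")
  oac_rows <- grepl("OAc", wt$structure)
  expect_equal(sum(oac_rows), 7L)
  expect_equal(rep$acetylated_in_a, 6L)
  expect_equal(rep$acetylated_in_b, 0L)
  expect_equal(rep$verdict, "ACETYLATION_LOST")
  expect_equal(acetylation_verdict(rep, min_acetylated = 1), "ACETYLATION_LOST")
  # every pair differs solely in the O-acetyl flag
  for (i in seq_len(nrow(rep$oac_pairs))) {
    a <- parse_nomenclature(rep$oac_pairs$acetylated_a[i])
    b <- parse_nomenclature(rep$oac_pairs$deacetylated_b[i])
    expect_true(lco_identical(de_O_acetylate(a), b))
  }
})

test_that("pairing is symmetric up to label swap and handles degenerate sets", {
  sets <- reference_species_sets()
  ab <- pair_by_acetyl(sets$wild_type, sets$noeT_mutant)
  ba <- pair_by_acetyl(sets$noeT_mutant, sets$wild_type)
  expect_equal(ba$acetylated_in_a, ab$acetylated_in_b)
  expect_equal(ba$acetylated_in_b, ab$acetylated_in_a)

  same <- pair_by_acetyl(sets$wild_type, sets$wild_type)
  expect_equal(same$acetylated_in_a, same$acetylated_in_b)

  empty <- species_set("empty", character(0), character(0))
  r0 <- pair_by_acetyl(empty, sets$noeT_mutant)
  expect_equal(r0$acetylated_in_a, 0L)
  expect_equal(nrow(r0$oac_pairs), 0L)
})

test_that("the verdict rule distinguishes loss, no-change and inconclusive", {
  plain <- species_set("a", c("IV(C18:1, Cb)", "IV(C20:3, Cb)"),
                       c("Na", "Na"))
  expect_equal(pair_by_acetyl(plain, plain)$verdict, "NO_CHANGE")

  oac <- species_set("b", "IV(C20:3, Cb, OAc)", "H")
  both <- species_set("c", c("IV(C20:3, Cb, OAc)", "IV(C18:3, Cb, OAc)"),
                      c("H", "H"))
  expect_equal(pair_by_acetyl(oac, oac)$verdict, "NO_CHANGE")
  expect_equal(pair_by_acetyl(both, oac)$verdict, "INCONCLUSIVE")
  expect_equal(pair_by_acetyl(oac, plain)$verdict, "ACETYLATION_LOST")
  expect_error(acetylation_verdict(pair_by_acetyl(oac, plain), 0), ">= 1")
})

test_that("adducts are collapsed before pairing", {
  a <- species_set("a", rep("IV(C20:3, Cb, OAc)", 2), c("H", "Na"))
  b <- species_set("b", "IV(C20:3, Cb)", "Na")
  rep <- pair_by_acetyl(a, b)
  expect_equal(rep$acetylated_in_a, 1L)
  expect_equal(nrow(rep$oac_pairs), 1L)
  expect_equal(rep$verdict, "ACETYLATION_LOST")
})

test_that("base-treatment predictions reproduce the before/after rows", {
  chk <- verify_base_treatment(parse_nomenclature("IV(C20:3, Cb, OAc)"), "H")
  expect_equal(chk$before$precursor$mz_nominal, 1162)
  expect_equal(chk$after$precursor$mz_nominal, 1120)
  expect_setequal(chk$before$ions$mz_nominal,
                  c(1162L, 1102L, 941L, 881L, 738L, 678L, 493L))
  expect_setequal(chk$after$ions$mz_nominal, c(1120L, 493L, 696L, 899L))
  expect_true(chk$consistent)

  chk2 <- verify_base_treatment(parse_nomenclature("IV(C20:1, Cb, OAc)"),
                                "Na")
  b_before <- chk2$before$ions[chk2$before$ions$series == "B" |
                                 chk2$before$ions$acetic_acid_loss, ]
  expect_setequal(setdiff(b_before$mz_nominal, 1128L),
                  c(519L, 704L, 764L, 907L, 967L))
  expect_equal(chk2$after$precursor$mz_nominal, 1146)
  expect_true(chk2$consistent)

  expect_error(verify_base_treatment(parse_nomenclature("IV(C18:1, Cb)"),
                                     "H"), "no O-acetyl")
})

test_that("observed peak lists can corroborate the base-treatment check", {
  before <- peaklist(c(493, 678, 738, 881, 941, 1102), precursor_mz = 1162)
  after <- peaklist(c(493, 696, 899), precursor_mz = 1120)
  chk <- verify_base_treatment(parse_nomenclature("IV(C20:3, Cb, OAc)"), "H",
                               before_peaks = before, after_peaks = after)
  expect_true(chk$observed_consistent)
  # mangled after-spectrum (no -42 shifts) fails the empirical check
  bad <- verify_base_treatment(parse_nomenclature("IV(C20:3, Cb, OAc)"), "H",
                               before_peaks = before,
                               after_peaks = peaklist(c(493, 738, 941),
                                                      precursor_mz = 1162))
  expect_false(bad$observed_consistent)
})

test_that("de-O-acetylation is model-consistent for every enumerable OAc structure", {
  space <- search_space()
  for (s in enumerate_structures(space)) {
    if (!s$substituents$o_acetyl) next
    for (adduct in c("H", "Na")) {
      chk <- verify_base_treatment(s, adduct)
      expect_true(chk$consistent,
                  info = paste(format_nomenclature(s), adduct))
      expect_equal(chk$precursor_shift, -42L)
      expect_true(chk$b1_conserved)
      expect_true(all(chk$bk_shifts$shift[chk$bk_shifts$index >= 2] == -42L))
      expect_true(chk$losses_absent_after)
    }
  }
})
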