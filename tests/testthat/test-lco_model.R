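test_that("nomenclature strings parse to the expected structures", {
  s <- parse_nomenclature("IV(C20:3, Cb, OAc)")
  expect_equal(s$backbone_length, 4L)
  expect_equal(s$acyl$carbons, 20L)
  expect_equal(s$acyl$double_bonds, 3L)
  expect_equal(s$acyl$hydroxyls, 0L)
  expect_true(s$substituents$carbamoyl)
  expect_true(s$substituents$o_acetyl)
  expect_false(s$substituents$methyl)

  s <- parse_nomenclature("IV(C18:1-OH, Cb)")
  expect_equal(c(s$acyl$carbons, s$acyl$double_bonds, s$acyl$hydroxyls),
               c(18L, 1L, 1L))
  expect_true(s$substituents$carbamoyl)
  expect_false(s$substituents$o_acetyl)

  s <- parse_nomenclature("V(C18:0)")
  expect_equal(s$backbone_length, 5L)
  expect_equal(n_substituents(s), 0L)

  # arbitrary internal whitespace
  expect_equal(format_nomenclature(parse_nomenclature("IV( C20:3 ,Cb,  OAc )")),
               "IV(C20:3, Cb, OAc)")
})

test_that("parse errors name the offending token", {
  expect_error(parse_nomenclature("VII(C18:0)"), "VII")
  expect_error(parse_nomenclature("IV(Cx:1)"), "Cx:1")
  expect_error(parse_nomenclature("IV(C18:1, Sulf)"), "Sulf")
  expect_error(parse_nomenclature("IV()"), "acyl")
})

test_that("formatting is canonical and round-trips through parsing", {
  s <- lco_structure(4, acyl_chain(20, 3),
                     substituent_set(carbamoyl = TRUE, o_acetyl = TRUE))
  expect_equal(format_nomenclature(s), "IV(C20:3, Cb, OAc)")
  s <- lco_structure(4, acyl_chain(18, 0),
                     substituent_set(carbamoyl = TRUE, methyl = TRUE))
  expect_equal(format_nomenclature(s), "IV(C18:0, Cb, CH3)")
  # substituent tokens in any input order, canonical on output
  expect_equal(format_nomenclature(parse_nomenclature("IV(C18:0, CH3, Cb)")),
               "IV(C18:0, Cb, CH3)")

  set.seed(7)
  for (i in 1:100) {
    s <- random_structure()
    expect_true(lco_identical(parse_nomenclature(format_nomenclature(s)), s))
  }
})

test_that("structure invariants are enforced", {
  expect_error(acyl_chain(1), "2 carbons")
  expect_error(acyl_chain(18, 9), "double_bonds")
  expect_error(acyl_chain(18, 1, 2), "hydroxyls")
  expect_error(lco_structure(6, acyl_chain(18, 0)), "backbone_length")
  expect_error(lco_structure(2, acyl_chain(18, 0)), "backbone_length")
})

test_that("enumeration size matches the brute-force cartesian oracle", {
  sp <- search_space(backbone_lengths = 4, acyl_carbons = 18,
                     max_double_bonds = 1, max_hydroxyls = 0)
  got <- enumerate_structures(sp)
  expect_length(got, oracle_space_size(4, 18, 1, 0, TRUE, TRUE, TRUE))
  expect_length(got, 16L)

  # singleton space, no substituent axes
  sp1 <- search_space(backbone_lengths = 4, acyl_carbons = 18,
                      max_double_bonds = 0, max_hydroxyls = 0,
                      allow_carbamoyl = FALSE, allow_o_acetyl = FALSE,
                      allow_methyl = FALSE)
  expect_length(enumerate_structures(sp1), 1L)

  # a larger space, including the chemical double-bond bound on short chains
  sp2 <- search_space(backbone_lengths = c(3, 4), acyl_carbons = c(4, 18),
                      max_double_bonds = 3, max_hydroxyls = 1,
                      allow_methyl = FALSE)
  expect_length(enumerate_structures(sp2),
                oracle_space_size(c(3, 4), c(4, 18), 3, 1, TRUE, TRUE, FALSE))

  # default space
  expect_length(enumerate_structures(search_space()),
                oracle_space_size(4, c(16, 18, 20, 22), 4, 1,
                                  TRUE, TRUE, TRUE))
})

test_that("enumeration is deterministic, duplicate-free and covers the reference table", {
  sp <- search_space()
  noms <- vapply(enumerate_structures(sp), format_nomenclature, character(1))
  expect_false(anyDuplicated(noms) > 0)
  expect_identical(noms,
                   vapply(enumerate_structures(sp), format_nomenclature,
                          character(1)))
  ref <- unique(reference_assignments()$structure)
  canon <- vapply(ref, function(x) {
    format_nomenclature(parse_nomenclature(x))
  }, character(1), USE.NAMES = FALSE)
  expect_true(all(canon %in% noms))
  expect_true("IV(C22:2, Cb)" %in% noms)
})

test_that("degenerate search spaces are rejected", {
  expect_error(search_space(backbone_lengths = integer(0)), "non-empty")
  expect_error(search_space(acyl_carbons = integer(0)), "non-empty")
  expect_error(search_space(max_double_bonds = -1), "bound")
})

test_that("structure_table serializes the enumeration", {
  tab <- structure_table(enumerate_structures(search_space(
    backbone_lengths = 4, acyl_carbons = 18, max_double_bonds = 0,
    max_hydroxyls = 0)))
  expect_named(tab, c("nomenclature", "backbone", "acyl_carbons",
                      "double_bonds", "hydroxyls", "cb", "oac", "me"))
  expect_equal(nrow(tab), 8L)
  expect_true(all(tab$backbone == 4L))
})
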