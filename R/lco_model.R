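# LCO structure model: chitin backbone of beta-1,4-linked GlcNAc residues,
# one N-acyl chain replacing the N-acetyl of the non-reducing-terminal
# residue, and optional decorations. Substituent positions are fixed model
# constants: carbamoyl (Cb) on residue 1 (non-reducing terminus), O-acetyl
# (OAc) on residue 2, methyl on residue n (reducing terminus).

.ROMAN <- c("III" = 3L, "IV" = 4L, "V" = 5L)

#' N-acyl chain of an LCO
#'
#' @param carbons number of acyl carbons (>= 2).
#' @param double_bonds number of C=C unsaturations
#'   (0 <= double_bonds <= floor((carbons - 2) / 2)).
#' @param hydroxyls number of additional hydroxyl groups on the chain
#'   (0 or 1; the "-OH" suffix of e.g. "C20:1-OH").
#' @return An object of class `acyl_chain`.
#' @export
acyl_chain <- function(carbons, double_bonds = 0, hydroxyls = 0) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  hydroxyls <- as.integer(hydroxyls)
  if (is.na(carbons) || carbons < 2) {
    stop("acyl chain needs at least 2 carbons", call. = FALSE)
  }
  if (is.na(double_bonds) || double_bonds < 0 ||
      double_bonds > (carbons - 2) %/% 2) {
    stop("double_bonds must lie in [0, floor((carbons-2)/2)]", call. = FALSE)
  }
  if (is.na(hydroxyls) || !hydroxyls %in% c(0L, 1L)) {
    stop("hydroxyls must be 0 or 1", call. = FALSE)
  }
  structure(list(carbons = carbons, double_bonds = double_bonds,
                 hydroxyls = hydroxyls),
            class = "acyl_chain")
}

#' Backbone substituent flags of an LCO
#'
#' The three decorations seen on these Nod factors, each at its fixed
#' position: carbamoyl on the non-reducing-terminal residue, O-acetyl on the
#' residue adjacent to the non-reducing terminus (residue 2), methyl on the
#' reducing-terminal residue.
#'
#' @param carbamoyl,o_acetyl,methyl logical flags.
#' @return An object of class `substituent_set`.
#' @export
substituent_set <- function(carbamoyl = FALSE, o_acetyl = FALSE,
                            methyl = FALSE) {
  stopifnot(is.logical(carbamoyl), is.logical(o_acetyl), is.logical(methyl))
  structure(list(carbamoyl = isTRUE(carbamoyl), o_acetyl = isTRUE(o_acetyl),
                 methyl = isTRUE(methyl)),
            class = "substituent_set")
}

#' Lipochitin oligosaccharide structure
#'
#' @param backbone_length number of GlcNAc residues (3 to 5; the Roman
#'   numeral of the nomenclature, IV = tetramer).
#' @param acyl an [acyl_chain()].
#' @param substituents a [substituent_set()].
#' @return An object of class `lco_structure`.
#' @examples
#' lco_structure(4, acyl_chain(20, 3), substituent_set(carbamoyl = TRUE,
#'                                                     o_acetyl = TRUE))
#' @export
lco_structure <- function(backbone_length, acyl,
                          substituents = substituent_set()) {
  backbone_length <- as.integer(backbone_length)
  if (is.na(backbone_length) || backbone_length < 3L || backbone_length > 5L) {
    stop("backbone_length must be 3, 4 or 5", call. = FALSE)
  }
  if (!inherits(acyl, "acyl_chain")) stop("acyl must be an acyl_chain",
                                          call. = FALSE)
  if (!inherits(substituents, "substituent_set")) {
    stop("substituents must be a substituent_set", call. = FALSE)
  }
  structure(list(backbone_length = backbone_length, acyl = acyl,
                 substituents = substituents),
            class = "lco_structure")
}

#' @export
print.lco_structure <- function(x, ...) {
  cat(format_nomenclature(x), "\n")
  invisible(x)
}

#' @export
format.lco_structure <- function(x, ...) format_nomenclature(x)

#' Test two structures for equality
#'
#' @param a,b `lco_structure` objects.
#' @return logical.
#' @export
lco_identical <- function(a, b) {
  identical(format_nomenclature(a), format_nomenclature(b))
}

#' Parse an LCO nomenclature string
#'
#' Accepts strings of the form `"IV(C20:3, Cb, OAc)"`: a Roman numeral for
#' the backbone length, an acyl token `C<carbons>:<double bonds>` with
#' optional `-OH`, then optional substituent tokens `Cb`, `OAc`, `CH3` in
#' any order (canonical order on output). Internal whitespace is arbitrary.
#'
#' @param text a single nomenclature string.
#' @return An [lco_structure()].
#' @examples
#' parse_nomenclature("IV(C20:3, Cb, OAc)")
#' @export
parse_nomenclature <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^\\s*([IVXLC]+)\\s*\\((.*)\\)\\s*$", text))[[1]]
  if (length(m) == 0) {
    stop("cannot parse nomenclature string: ", sQuote(text), call. = FALSE)
  }
  roman <- m[2]
  if (!roman %in% names(.ROMAN)) {
    stop("unsupported Roman numeral token ", sQuote(roman),
         " (expected III, IV or V)", call. = FALSE)
  }
  tokens <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) {
    stop("missing acyl token in ", sQuote(text), call. = FALSE)
  }
  am <- regmatches(tokens[1],
                   regexec("^C([0-9]+)\\s*:\\s*([0-9]+)(-OH)?$", tokens[1]))[[1]]
  if (length(am) == 0) {
    stop("malformed acyl token ", sQuote(tokens[1]),
         " (expected e.g. C20:3 or C18:1-OH)", call. = FALSE)
  }
  acyl <- acyl_chain(as.integer(am[2]), as.integer(am[3]),
                     as.integer(nzchar(am[4])))
  subs <- substituent_set()
  for (tok in tokens[-1]) {
    if (tok == "Cb") subs$carbamoyl <- TRUE
    else if (tok == "OAc") subs$o_acetyl <- TRUE
    else if (tok == "CH3") subs$methyl <- TRUE
    else stop("unknown substituent token ", sQuote(tok), call. = FALSE)
  }
  lco_structure(.ROMAN[[roman]], acyl, subs)
}

#' Format an LCO structure as its nomenclature string
#'
#' Canonical token order: Roman numeral, acyl, `Cb`, `OAc`, `CH3`.
#' `parse_nomenclature(format_nomenclature(s))` recovers `s`.
#'
#' @param s an [lco_structure()].
#' @return A character scalar such as `"IV(C20:3, Cb, OAc)"`.
#' @export
format_nomenclature <- function(s) {
  stopifnot(inherits(s, "lco_structure"))
  roman <- names(.ROMAN)[match(s$backbone_length, .ROMAN)]
  acyl <- sprintf("C%d:%d%s", s$acyl$carbons, s$acyl$double_bonds,
                  if (s$acyl$hydroxyls > 0) "-OH" else "")
  toks <- c(acyl,
            if (s$substituents$carbamoyl) "Cb",
            if (s$substituents$o_acetyl) "OAc",
            if (s$substituents$methyl) "CH3")
  sprintf("%s(%s)", roman, paste(toks, collapse = ", "))
}

#' Number of backbone substituents on a structure
#'
#' Used as the parsimony term when ranking isobaric candidates.
#'
#' @param s an [lco_structure()].
#' @return integer in 0..3.
#' @export
n_substituents <- function(s) {
  sum(s$substituents$carbamoyl, s$substituents$o_acetyl,
      s$substituents$methyl)
}

#' Candidate search space for structure enumeration
#'
#' The default bounds cover every species reported for *Neorhizobium
#' galegae* HAMBI 1174 and its noeT mutant: tetrameric backbone, even acyl
#' chains of 16-22 carbons, up to 4 double bonds, at most one chain
#' hydroxyl, all three substituents allowed. Odd chain lengths are valid for
#' the model but excluded from the default space.
#'
#' @param backbone_lengths integer set of backbone lengths.
#' @param acyl_carbons integer set of acyl carbon counts.
#' @param max_double_bonds maximum unsaturations per chain.
#' @param max_hydroxyls maximum chain hydroxyls (0 or 1).
#' @param allow_carbamoyl,allow_o_acetyl,allow_methyl whether each
#'   substituent axis is enumerated.
#' @return An object of class `search_space`.
#' @export
search_space <- function(backbone_lengths = 4L,
                         acyl_carbons = c(16L, 18L, 20L, 22L),
                         max_double_bonds = 4L,
                         max_hydroxyls = 1L,
                         allow_carbamoyl = TRUE,
                         allow_o_acetyl = TRUE,
                         allow_methyl = TRUE) {
  backbone_lengths <- sort(unique(as.integer(backbone_lengths)))
  acyl_carbons <- sort(unique(as.integer(acyl_carbons)))
  if (length(backbone_lengths) == 0 || length(acyl_carbons) == 0) {
    stop("search space axes must be non-empty", call. = FALSE)
  }
  if (max_double_bonds < 0 || !max_hydroxyls %in% c(0L, 1L)) {
    stop("invalid double-bond or hydroxyl bound", call. = FALSE)
  }
  structure(list(backbone_lengths = backbone_lengths,
                 acyl_carbons = acyl_carbons,
                 max_double_bonds = as.integer(max_double_bonds),
                 max_hydroxyls = as.integer(max_hydroxyls),
                 allow_carbamoyl = isTRUE(allow_carbamoyl),
                 allow_o_acetyl = isTRUE(allow_o_acetyl),
                 allow_methyl = isTRUE(allow_methyl)),
            class = "search_space")
}

#' Enumerate all candidate structures in a search space
#'
#' Deterministic order: sorted by backbone length, acyl carbons, double
#' bonds, hydroxyls, then substituent flags (Cb, OAc, CH3, absent before
#' present). Double-bond counts exceeding the chemical bound
#' floor((carbons - 2) / 2) are skipped.
#'
#' @param space a [search_space()].
#' @return A list of [lco_structure()] objects, no duplicates.
#' @export
enumerate_structures <- function(space) {
  stopifnot(inherits(space, "search_space"))
  flag_vals <- function(allowed) if (allowed) c(FALSE, TRUE) else FALSE
  out <- list()
  for (n in space$backbone_lengths) {
    for (c_ in space$acyl_carbons) {
      dmax <- min(space$max_double_bonds, (c_ - 2L) %/% 2L)
      for (d in 0:dmax) {
        for (h in 0:space$max_hydroxyls) {
          for (cb in flag_vals(space$allow_carbamoyl)) {
            for (oac in flag_vals(space$allow_o_acetyl)) {
              for (me in flag_vals(space$allow_methyl)) {
                out[[length(out) + 1L]] <- lco_structure(
                  n, acyl_chain(c_, d, h),
                  substituent_set(cb, oac, me))
              }
            }
          }
        }
      }
    }
  }
  if (length(out) == 0) stop("empty search space", call. = FALSE)
  out
}

#' Serialize structures to a flat table
#'
#' @param structures list of [lco_structure()] objects.
#' @return A data.frame with columns nomenclature, backbone, acyl_carbons,
#'   double_bonds, hydroxyls, cb, oac, me.
#' @export
structure_table <- function(structures) {
  data.frame(
    nomenclature = vapply(structures, format_nomenclature, character(1)),
    backbone = vapply(structures, function(s) s$backbone_length, integer(1)),
    acyl_carbons = vapply(structures, function(s) s$acyl$carbons, integer(1)),
    double_bonds = vapply(structures, function(s) s$acyl$double_bonds,
                          integer(1)),
    hydroxyls = vapply(structures, function(s) s$acyl$hydroxyls, integer(1)),
    cb = vapply(structures, function(s) s$substituents$carbamoyl, logical(1)),
    oac = vapply(structures, function(s) s$substituents$o_acetyl, logical(1)),
    me = vapply(structures, function(s) s$substituents$methyl, logical(1)),
    stringsAsFactors = FALSE
  )
}
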