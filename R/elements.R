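# Elemental compositions and the two mass scales used throughout:
# nominal (integer, lightest-isotope integer masses) for reproducing printed
# unit-resolution m/z tables, and monoisotopic (exact lightest-isotope
# masses) for tolerance matching against observed spectra.

.ELEMENTS <- c("C", "H", "N", "O", "Na")

# integer lightest-isotope masses
.NOMINAL_MASS <- c(C = 12L, H = 1L, N = 14L, O = 16L, Na = 23L)

# monoisotopic masses, Da (electron mass neglected: < 0.001 Da, below every
# tolerance used here)
.MONO_MASS <- c(
  C  = 12.000000,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  Na = 22.98976928
)

#' Create an elemental composition
#'
#' An elemental composition is a named integer vector of atom counts over
#' C, H, N, O and Na. Compositions add and subtract element-wise;
#' subtraction that would drive any count negative is a chemistry error.
#'
#' @param C,H,N,O,Na non-negative integer atom counts.
#' @return An object of class `elemental_composition`.
#' @examples
#' glcnac <- elemental_composition(C = 8, H = 13, N = 1, O = 5)
#' nominal_mass(glcnac)  # 203
#' @export
elemental_composition <- function(C = 0, H = 0, N = 0, O = 0, Na = 0) {
  x <- c(C = C, H = H, N = N, O = O, Na = Na)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("atom counts must be non-negative integers", call. = FALSE)
  }
  structure(as.integer(x), names = .ELEMENTS, class = "elemental_composition")
}

.as_comp <- function(x) {
  structure(as.integer(x[.ELEMENTS]), names = .ELEMENTS,
            class = "elemental_composition")
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x[x > 0]
  if (length(nz) == 0) {
    cat("<empty composition>\n")
  } else {
    cat(paste0(names(nz), ifelse(nz > 1, nz, "")), "\n")
  }
  invisible(x)
}

#' Add or subtract elemental compositions
#'
#' @param a,b `elemental_composition` objects.
#' @return An `elemental_composition`. `comp_subtract()` errors if any atom
#'   count would become negative.
#' @export
comp_add <- function(a, b) {
  .as_comp(unclass(a) + unclass(b))
}

#' @rdname comp_add
#' @export
comp_subtract <- function(a, b) {
  out <- unclass(a) - unclass(b)
  if (any(out < 0)) {
    bad <- .ELEMENTS[out < 0]
    stop("invalid chemistry: negative atom count for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  .as_comp(out)
}

#' Nominal (integer) mass of a composition
#'
#' Sum of atom counts times integer lightest-isotope masses
#' (C=12, H=1, N=14, O=16, Na=23).
#'
#' @param comp an `elemental_composition`.
#' @return Integer mass in Da.
#' @export
nominal_mass <- function(comp) {
  sum(as.integer(comp) * .NOMINAL_MASS[.ELEMENTS])
}

#' Monoisotopic mass of a composition
#'
#' Sum of atom counts times exact lightest-isotope masses.
#'
#' @param comp an `elemental_composition`.
#' @return Mass in Da (double).
#' @export
monoisotopic_mass <- function(comp) {
  sum(as.integer(comp) * .MONO_MASS[.ELEMENTS])
}

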