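## Pinned monoisotopic (lightest-isotope) atomic masses in Da.
## Sources: CODATA/IUPAC values truncated at 9 decimals; C is exactly 12 by
## definition.  These are the only elements the dereplication arithmetic
## supports; extending the table extends every downstream operation.
.ELEMENT_MASSES <- c(
  H  = 1.007825032,
  C  = 12.000000000,
  N  = 14.003074005,
  O  = 15.994914620,
  S  = 31.972071174,
  P  = 30.973761998,
  Na = 22.989769282,
  Cl = 34.968852682,
  Br = 78.918337601
)

.ELECTRON_MASS <- 0.000548579909

## Isotope distributions as (nominal mass offset, relative abundance) pairs.
## Offsets are relative to the lightest isotope; abundances are IUPAC 2021
## representative values (Cl/Br as 75.78/24.22 and 50.69/49.31).
.ELEMENT_ISOTOPES <- list(
  H  = list(offset = c(0L, 1L),          abundance = c(0.999885, 0.000115)),
  C  = list(offset = c(0L, 1L),          abundance = c(0.9893, 0.0107)),
  N  = list(offset = c(0L, 1L),          abundance = c(0.99636, 0.00364)),
  O  = list(offset = c(0L, 1L, 2L),      abundance = c(0.99757, 0.00038, 0.00205)),
  S  = list(offset = c(0L, 1L, 2L, 4L),  abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P  = list(offset = 0L,                 abundance = 1),
  Na = list(offset = 0L,                 abundance = 1),
  Cl = list(offset = c(0L, 2L),          abundance = c(0.7578, 0.2422)),
  Br = list(offset = c(0L, 2L),          abundance = c(0.5069, 0.4931))
)

#' Parse a molecular formula string into element counts
#'
#' Accepts the usual condensed element-count grammar (an element symbol
#' followed by an optional positive integer, repeated), e.g. `"C18H33NO4"`.
#' Repeated symbols are summed. Only elements with pinned monoisotopic masses
#' (C, H, N, O, S, P, Na, Cl, Br) are accepted.
#'
#' @param text A single formula string.
#' @return A named integer vector of element counts with class
#'   `"element_counts"`; the canonical Hill-order string is kept in the
#'   `"formula"` attribute.
#' @examples
#' parse_formula("C18H33NO4")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("'text' must be a single non-empty formula string", call. = FALSE)
  pat <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, text)[[1]]
  tokens <- regmatches(text, gregexpr(pat, text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula: ", sQuote(text), call. = FALSE)
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Z][a-z]?", "", tokens)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  bad <- setdiff(sym, names(.ELEMENT_MASSES))
  if (length(bad))
    stop("unknown element ", sQuote(bad[1L]), " in formula ", sQuote(text),
         call. = FALSE)
  if (any(cnt < 1L))
    stop("zero element count in formula ", sQuote(text), call. = FALSE)
  counts <- tapply(cnt, sym, sum)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(counts, formula = format_formula(counts), class = "element_counts")
}

#' Canonical Hill-order formula string
#'
#' @param counts Named element counts (as from [parse_formula()]).
#' @return A single string: carbon first, hydrogen second, remaining elements
#'   alphabetical (all alphabetical when no carbon is present).
#' @export
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  nm <- names(counts)
  ord <- if ("C" %in% nm) {
    c(intersect(c("C", "H"), nm), sort(setdiff(nm, c("C", "H"))))
  } else sort(nm)
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

.as_counts <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x) && !is.null(names(x))) {
    bad <- setdiff(names(x), names(.ELEMENT_MASSES))
    if (length(bad)) stop("unknown element ", sQuote(bad[1L]), call. = FALSE)
    return(x)
  }
  stop("expected a formula string or named element counts", call. = FALSE)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of lightest-isotope atomic masses over the element counts, using the
#' package's pinned mass table (documented in the package vignette to nine
#' decimals).
#'
#' @param counts Formula string or named element counts.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("SO3")   # 79.9568
#' monoisotopic_mass("H2O")   # 18.0106
#' @export
monoisotopic_mass <- function(counts) {
  counts <- .as_counts(counts)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty formula", call. = FALSE)
  sum(.ELEMENT_MASSES[names(counts)] * as.numeric(counts))
}

## Adduct specifications: neutral atoms gained/lost plus ion charge.  The m/z
## is electron-corrected, i.e. [M+H]+ adds a proton (H minus one electron).
.ADDUCTS <- list(
  "[M+H]+"     = list(add = c(H = 1),        sub = c(),             z = +1L),
  "[M+Na]+"    = list(add = c(Na = 1),       sub = c(),             z = +1L),
  "[M+NH4]+"   = list(add = c(N = 1, H = 4), sub = c(),             z = +1L),
  "[M-H2O+H]+" = list(add = c(H = 1),        sub = c(H = 2, O = 1), z = +1L),
  "[M-H]-"     = list(add = c(),             sub = c(H = 1),        z = -1L)
)

#' Supported adduct names
#' @return Character vector of adduct specifiers usable in [adduct_mz()].
#' @export
adduct_names <- function() names(.ADDUCTS)

#' Theoretical adduct m/z for a molecular formula
#'
#' Computes (M + gained atoms - lost atoms - z * electron mass) / |z| from the
#' pinned atomic mass table, so singly protonated species add 1.007276 Da.
#'
#' @param counts Formula string or named element counts; counts summing to a
#'   zero-atom molecule are allowed (mass 0), which makes the bare-proton case
#'   easy to check.
#' @param adduct Adduct name, one of [adduct_names()].
#' @return m/z in Da.
#' @examples
#' adduct_mz("C18H33NO4", "[M+H]+")        # 328.2482
#' adduct_mz("C29H40BrClO9", "[M-H2O+H]+") # 629.1511
#' @export
adduct_mz <- function(counts, adduct = "[M+H]+") {
  spec <- .ADDUCTS[[adduct]]
  if (is.null(spec))
    stop("unsupported adduct ", sQuote(adduct), "; see adduct_names()",
         call. = FALSE)
  m <- if (is.numeric(counts) && length(counts) == 1L && is.null(names(counts))) {
    as.numeric(counts)  # a precomputed neutral mass
  } else monoisotopic_mass_or_zero(counts)
  gain <- if (length(spec$add)) sum(.ELEMENT_MASSES[names(spec$add)] * spec$add) else 0
  loss <- if (length(spec$sub)) sum(.ELEMENT_MASSES[names(spec$sub)] * spec$sub) else 0
  (m + gain - loss - spec$z * .ELECTRON_MASS) / abs(spec$z)
}

## monoisotopic_mass() that tolerates an all-zero count vector (mass 0)
monoisotopic_mass_or_zero <- function(counts) {
  counts <- .as_counts(counts)
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  sum(.ELEMENT_MASSES[names(counts)] * as.numeric(counts))
}

#' Parts-per-million mass error
#'
#' @param observed Observed m/z (Da).
#' @param calculated Theoretical m/z (Da); must be positive.
#' @return Signed ppm error `(observed - calculated) / calculated * 1e6`.
#' @examples
#' ppm_error(328.2485, 328.2483) # +0.61
#' @export
ppm_error <- function(observed, calculated) {
  if (any(!is.finite(calculated)) || any(calculated <= 0))
    stop("'calculated' must be positive", call. = FALSE)
  (observed - calculated) / calculated * 1e6
}

## Valence classes used by rdbe(): ring-and-double-bond contributions.
.RDBE_CLASS <- c(
  C = 1, H = -0.5, Cl = -0.5, Br = -0.5, N = 0.5, P = 0.5, O = 0, S = 0
)

#' Ring and double-bond equivalents (degrees of unsaturation)
#'
#' DBE = C - (H + halogens)/2 + (N + P)/2 + 1 under the usual valence
#' assumptions (tetravalent C, monovalent H/Cl/Br, trivalent N/P, divalent
#' O/S). Elements without an assigned valence class (e.g. Na) are rejected.
#'
#' @param counts Formula string or named element counts.
#' @return DBE as a real number.
#' @examples
#' rdbe("C18H33NO4")    # 3
#' rdbe("C29H40BrClO9") # 9
#' @export
rdbe <- function(counts) {
  counts <- .as_counts(counts)
  counts <- counts[counts > 0]
  bad <- setdiff(names(counts), names(.RDBE_CLASS))
  if (length(bad))
    stop("no valence class for element ", sQuote(bad[1L]), call. = FALSE)
  1 + sum(.RDBE_CLASS[names(counts)] * as.numeric(counts))
}
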