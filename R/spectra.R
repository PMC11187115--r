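#' Construct a centroided MS/MS spectrum
#'
#' @param mz Fragment m/z values (positive).
#' @param intensity Fragment intensities (non-negative, same length).
#' @param precursor_mz Precursor m/z.
#' @param charge Precursor charge (default 1).
#' @param id Spectrum identifier.
#' @return A `"spectrum"` object; peaks are stored sorted by ascending m/z.
#' @export
new_spectrum <- function(mz, intensity, precursor_mz, charge = 1L,
                         id = NA_character_) {
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' lengths differ", call. = FALSE)
  if (any(mz <= 0)) stop("m/z values must be positive", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (!is.finite(precursor_mz) || precursor_mz <= 0)
    stop("'precursor_mz' must be positive", call. = FALSE)
  o <- order(mz)
  structure(
    list(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
         precursor_mz = as.numeric(precursor_mz), charge = as.integer(charge),
         id = as.character(id)),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s> precursor m/z %.4f (%+d), %d peaks\n",
              x$id, x$precursor_mz, x$charge, length(x$mz)))
  invisible(x)
}

#' Filter an MS/MS spectrum the way classical molecular networking does
#'
#' Removes fragment ions within `precursor_exclusion` Da of the precursor m/z,
#' then keeps a peak only if it ranks among the `top_n` most intense peaks
#' within its +/- `window` Da neighborhood.
#'
#' @param s A `"spectrum"`.
#' @param precursor_exclusion Half-width of the precursor exclusion zone in Da
#'   (default 17).
#' @param window Half-width of the rank window in Da (default 50).
#' @param top_n Peaks retained per window (default 6).
#' @return The filtered `"spectrum"` (possibly with zero peaks).
#' @export
preprocess_spectrum <- function(s, precursor_exclusion = 17, window = 50,
                                top_n = 6L) {
  stopifnot(inherits(s, "spectrum"))
  keep <- abs(s$mz - s$precursor_mz) > precursor_exclusion
  mz <- s$mz[keep]; int <- s$intensity[keep]
  if (length(mz)) {
    ok <- logical(length(mz))
    for (i in seq_along(mz)) {
      nbr <- which(abs(mz - mz[i]) <= window)
      ok[i] <- sum(int[nbr] > int[i]) < top_n
    }
    mz <- mz[ok]; int <- int[ok]
  }
  out <- s
  out$mz <- mz
  out$intensity <- int
  out
}

#' Modified cosine similarity between two spectra
#'
#' Peaks may match directly (|dm/z| <= `fragment_tol`) or, when
#' `allow_precursor_shift` is on, after shifting one spectrum's peaks by the
#' precursor mass difference. Intensities are square-root weighted. Each peak
#' is used at most once; the shared intensity is maximized by an exact
#' maximum-weight bipartite assignment over the candidate pairs (the common,
#' conflict-free case short-circuits it).
#'
#' @param a,b `"spectrum"` objects (normally after [preprocess_spectrum()]).
#' @param fragment_tol Fragment match tolerance in Da (default 0.05).
#' @param allow_precursor_shift Also match peaks separated by the precursor
#'   mass difference (default TRUE).
#' @return List with `score` in \[0, 1\] and `matched` (number of matched peak
#'   pairs). Empty spectra give score 0.
#' @examples
#' a <- new_spectrum(c(100, 200), c(4, 1), 300)
#' b <- new_spectrum(c(100, 300), c(4, 1), 300)
#' modified_cosine(a, b)$score  # 0.8
#' @export
modified_cosine <- function(a, b, fragment_tol = 0.05,
                            allow_precursor_shift = TRUE) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  na <- length(a$mz); nb <- length(b$mz)
  if (na == 0L || nb == 0L) return(list(score = 0, matched = 0L))
  wa <- sqrt(a$intensity); wb <- sqrt(b$intensity)
  shift <- a$precursor_mz - b$precursor_mz
  diff <- outer(a$mz, b$mz, "-")
  cand <- abs(diff) <= fragment_tol
  if (allow_precursor_shift)
    cand <- cand | abs(diff - shift) <= fragment_tol
  idx <- which(cand, arr.ind = TRUE)
  if (!nrow(idx)) return(list(score = 0, matched = 0L))
  w <- wa[idx[, 1L]] * wb[idx[, 2L]]
  pos <- w > 0
  idx <- idx[pos, , drop = FALSE]; w <- w[pos]
  if (!nrow(idx)) return(list(score = 0, matched = 0L))
  conflict <- anyDuplicated(idx[, 1L]) || anyDuplicated(idx[, 2L])
  if (!conflict) {
    total <- sum(w); matched <- nrow(idx)
  } else {
    m <- .max_weight_assignment(idx[, 1L], idx[, 2L], w, na, nb)
    total <- m$weight; matched <- m$size
  }
  norm <- sqrt(sum(a$intensity)) * sqrt(sum(b$intensity))
  list(score = min(1, total / norm), matched = as.integer(matched))
}

## Exact maximum-weight bipartite matching over candidate peak pairs.
.max_weight_assignment <- function(i, j, w, na, nb) {
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, na), rep(TRUE, nb)),
    edges = as.vector(rbind(i, na + j)))
  m <- igraph::max_bipartite_match(g, weights = w)
  ## recover matched pair count from the matching vector
  size <- sum(!is.na(m$matching[seq_len(na)]))
  list(weight = m$matching_weight, size = size)
}

#' Annotate neutral losses among a set of ions
#'
#' Every pair of masses whose absolute difference matches a loss in the table
#' within `tolerance_da` is annotated with the loss name, the observed and
#' calculated differences, and the error.
#'
#' @param ions Numeric vector of >= 2 ion masses, a two-column matrix of ion
#'   pairs, or a `"spectrum"` (precursor paired with every fragment).
#' @param losses Named character vector of loss formulas
#'   (default `c(SO3 = "SO3", H2O = "H2O")`).
#' @param tolerance_da Absolute match tolerance in Da (default 0.01, which
#'   comfortably covers sulfate-loss attributions a few mDa off).
#' @return Data frame with one row per annotated pair (zero rows when nothing
#'   matches): `ion_a`, `ion_b`, `delta_observed`, `loss`, `delta_calcd`,
#'   `error_da`.
#' @export
annotate_neutral_losses <- function(ions,
                                    losses = c(SO3 = "SO3", H2O = "H2O"),
                                    tolerance_da = 0.01) {
  if (tolerance_da <= 0) stop("'tolerance_da' must be positive", call. = FALSE)
  if (inherits(ions, "spectrum")) {
    pairs <- cbind(ions$precursor_mz, ions$mz)
  } else if (is.matrix(ions)) {
    pairs <- ions
  } else {
    if (length(ions) < 2L) stop("need at least two ions", call. = FALSE)
    cmb <- utils::combn(sort(ions, decreasing = TRUE), 2L)
    pairs <- t(cmb)
  }
  loss_mass <- vapply(losses, monoisotopic_mass, numeric(1))
  out <- data.frame(ion_a = numeric(0), ion_b = numeric(0),
                    delta_observed = numeric(0), loss = character(0),
                    delta_calcd = numeric(0), error_da = numeric(0))
  for (r in seq_len(nrow(pairs))) {
    d <- abs(pairs[r, 1L] - pairs[r, 2L])
    hit <- which(abs(d - loss_mass) <= tolerance_da)
    for (h in hit) {
      out <- rbind(out, data.frame(
        ion_a = max(pairs[r, ]), ion_b = min(pairs[r, ]),
        delta_observed = d, loss = names(loss_mass)[h],
        delta_calcd = unname(loss_mass[h]),
        error_da = d - unname(loss_mass[h])))
    }
  }
  out
}

#' Single-point quantitation against an external standard
#'
#' Linear calibration through the origin: concentration scales with the ratio
#' of chromatographic peak areas (AUC) between sample and standard.
#'
#' @param auc_sample Peak area of the analyte in the sample.
#' @param auc_standard Peak area of the standard (> 0).
#' @param conc_standard Concentration of the standard (> 0), any unit.
#' @return Estimated concentration, in the unit of `conc_standard`.
#' @export
quantify_by_standard <- function(auc_sample, auc_standard, conc_standard) {
  if (auc_standard <= 0 || conc_standard <= 0)
    stop("standard AUC and concentration must be positive", call. = FALSE)
  conc_standard * auc_sample / auc_standard
}
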