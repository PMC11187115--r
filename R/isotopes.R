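#' Theoretical isotope pattern of a molecular formula
#'
#' Convolves the per-element isotope distributions (polynomial convolution,
#' one atom at a time) and aggregates at unit (nominal-mass) resolution, the
#' level at which isotopologue clusters are read off an MS survey scan.
#' Abundances are normalized so the base (most abundant) peak is 1 and entries
#' below `prune` relative abundance are dropped.
#'
#' @param counts Formula string or named element counts.
#' @param max_offset Largest nominal offset retained (default 10).
#' @param prune Relative-abundance floor (default 1e-4).
#' @return An object of class `"isotope_pattern"`: a data frame with columns
#'   `offset` (integer nominal mass above the monoisotopic peak) and
#'   `abundance` (base peak = 1).
#' @examples
#' isotope_pattern("CH3Cl")  # M+2/M close to 0.32
#' @export
isotope_pattern <- function(counts, max_offset = 10L, prune = 1e-4) {
  counts <- .as_counts(counts)
  counts <- counts[counts > 0]
  dist <- 1  # probability vector indexed by offset 0, 1, 2, ...
  for (el in names(counts)) {
    iso <- .ELEMENT_ISOTOPES[[el]]
    v <- numeric(max(iso$offset) + 1L)
    v[iso$offset + 1L] <- iso$abundance
    ## repeated-squaring convolution for n atoms of this element
    n <- counts[[el]]
    pw <- 1
    base <- v
    while (n > 0L) {
      if (n %% 2L == 1L) pw <- .conv_trunc(pw, base, max_offset)
      base <- .conv_trunc(base, base, max_offset)
      n <- n %/% 2L
    }
    dist <- .conv_trunc(dist, pw, max_offset)
  }
  ab <- dist / max(dist)
  keep <- which(ab >= prune)
  out <- data.frame(offset = keep - 1L, abundance = ab[keep])
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

## convolution truncated at offset `max_offset`
.conv_trunc <- function(a, b, max_offset) {
  n <- min(length(a) + length(b) - 1L, max_offset + 1L)
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1L)
    if (jmax < 1L) break
    idx <- i:(i + jmax - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Infer chlorine and bromine counts from an isotope pattern
#'
#' Fits theoretical Cl\\eqn{_n}Br\\eqn{_m} cluster shapes (0 <= n, m <=
#' `max_each`) to the even-offset envelope of an observed pattern by least
#' squares.  Both observed and candidate abundances are restricted to offsets
#' 0, 2, 4, ... and renormalized to sum to 1, which makes the comparison
#' insensitive to which isotopologue happens to be the base peak.  Ties are
#' broken toward fewer total halogens.
#'
#' @param pattern An `"isotope_pattern"` (or data frame with `offset` and
#'   `abundance` columns).
#' @param max_each Maximum count considered per halogen (default 3).
#' @return Named integer vector `c(n_Cl = ..., n_Br = ...)`; `(0, 0)` for
#'   featureless patterns.
#' @examples
#' infer_halogens(isotope_pattern("C29H40BrClO9"))  # one Cl, one Br
#' @export
infer_halogens <- function(pattern, max_each = 3L) {
  if (is.null(pattern$offset) || !nrow(pattern))
    stop("'pattern' must have at least one entry", call. = FALSE)
  offs <- seq(0L, 2L * (max_each + 1L), by = 2L)
  obs <- numeric(length(offs))
  for (i in seq_along(offs)) {
    hit <- pattern$offset == offs[i]
    if (any(hit)) obs[i] <- pattern$abundance[which(hit)[1L]]
  }
  if (sum(obs) <= 0) return(c(n_Cl = 0L, n_Br = 0L))
  obs <- obs / sum(obs)
  best <- NULL
  best_sse <- Inf
  grid <- expand.grid(n_Cl = 0:max_each, n_Br = 0:max_each)
  grid <- grid[order(grid$n_Cl + grid$n_Br, grid$n_Cl, grid$n_Br), ]
  for (r in seq_len(nrow(grid))) {
    cand_counts <- c(Cl = grid$n_Cl[r], Br = grid$n_Br[r])
    cand_counts <- cand_counts[cand_counts > 0]
    theo <- if (length(cand_counts)) {
      p <- isotope_pattern(cand_counts, max_offset = max(offs))
      vapply(offs, function(o) {
        hit <- p$offset == o
        if (any(hit)) p$abundance[which(hit)[1L]] else 0
      }, numeric(1))
    } else c(1, numeric(length(offs) - 1L))
    theo <- theo / sum(theo)
    sse <- sum((obs - theo)^2)
    if (sse < best_sse - 1e-12) {  # strict improvement; grid order breaks ties
      best_sse <- sse
      best <- c(n_Cl = grid$n_Cl[r], n_Br = grid$n_Br[r])
    }
  }
  best
}
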