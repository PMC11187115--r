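#' Signed two-sample Kolmogorov-Smirnov statistic
#'
#' The magnitude is the sup-norm distance between the two empirical
#' distribution functions. The sign is taken from `ECDF(a) - ECDF(b)` at the
#' (smallest) point of maximal absolute deviation, so the statistic is
#' positive when `b` is shifted toward larger values there, negative when it
#' is shifted toward smaller values, and exactly antisymmetric under swapping
#' the samples.
#'
#' @param sample_a,sample_b Non-empty numeric vectors (NAs rejected).
#' @return Signed statistic in \[-1, 1\].
#' @examples
#' ks_statistic(c(0, 1, 2, 3), c(2, 3, 4, 5)) # +0.5
#' @export
ks_statistic <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(sample_a) || anyNA(sample_b))
    stop("samples must not contain missing values", call. = FALSE)
  pts <- sort(unique(c(sample_a, sample_b)))
  fa <- findInterval(pts, sort(sample_a)) / length(sample_a)
  fb <- findInterval(pts, sort(sample_b)) / length(sample_b)
  d <- fa - fb
  k <- which.max(abs(d))  # first index attaining the max
  unname(sign(d[k]) * abs(d[k]))
}

## Fast signed KS of one well against a large pre-sorted pool, evaluated from
## the well side only (O(n log m)). Sign convention matches
## ks_statistic(pool, well): positive when the well is shifted toward larger
## values. `pool_sorted` must be sorted ascending.
.ks_well_vs_pool <- function(well, pool_sorted) {
  n <- length(well)
  m <- length(pool_sorted)
  x <- sort(well)
  leq <- findInterval(x, pool_sorted)                    # pool values <= x_i
  less <- findInterval(x, pool_sorted, left.open = TRUE) # pool values <  x_i
  ## deviation of F_pool - F_well evaluated at well jump points:
  ## just before x_i the well ECDF is (i-1)/n, just after it is i/n.
  d_pos <- less / m - (seq_len(n) - 1) / n  # pool above well => well larger
  d_neg <- seq_len(n) / n - leq / m         # well above pool => well smaller
  a <- max(d_pos); b <- max(d_neg)
  if (a >= b) a else -b
}

## As above but the pool is "all pooled cells minus this well's own cells":
## counts in the pool are obtained by subtracting the well's own rank counts
## from counts in the full pool (which must contain the well's values).
.ks_well_vs_pool_loo <- function(well, all_sorted) {
  n <- length(well)
  m <- length(all_sorted) - n
  x <- sort(well)
  leq <- findInterval(x, all_sorted) - seq_len(n)
  less <- findInterval(x, all_sorted, left.open = TRUE) - (seq_len(n) - 1)
  d_pos <- less / m - (seq_len(n) - 1) / n
  d_neg <- seq_len(n) / n - leq / m
  a <- max(d_pos); b <- max(d_neg)
  if (a >= b) a else -b
}
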