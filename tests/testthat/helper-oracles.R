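# Independent oracles used across the suite. These are deliberately naive
# (brute-force) implementations, kept separate from the package's code paths.

# Sup-norm ECDF distance by direct evaluation at every sample point.
ks_magnitude_oracle <- function(a, b) {
  pts <- c(a, b)
  fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(fa - fb))
}

# Exhaustive-assignment modified cosine: enumerate all ways of pairing
# candidate peaks (each peak used once), maximizing summed sqrt-intensity
# products. Branch and bound keeps ≤6-peak spectra tractable.
modified_cosine_oracle <- function(a, b, fragment_tol = 0.05,
                                   allow_precursor_shift = TRUE) {
  wa <- sqrt(a$intensity); wb <- sqrt(b$intensity)
  shift <- a$precursor_mz - b$precursor_mz
  pairs <- list()
  for (i in seq_along(a$mz)) for (j in seq_along(b$mz)) {
    d <- a$mz[i] - b$mz[j]
    if (abs(d) <= fragment_tol ||
        (allow_precursor_shift && abs(d - shift) <= fragment_tol)) {
      if (wa[i] * wb[j] > 0)
        pairs[[length(pairs) + 1L]] <- c(i, j, wa[i] * wb[j])
    }
  }
  if (!length(pairs)) return(list(score = 0, matched = 0L))
  pm <- do.call(rbind, pairs)
  ord <- order(pm[, 3], decreasing = TRUE)
  pm <- pm[ord, , drop = FALSE]
  n <- nrow(pm)
  suffix <- rev(cumsum(rev(pm[, 3])))
  best <- 0; best_cnt <- 0L
  recurse <- function(k, usedA, usedB, total, cnt) {
    if (total > best) { best <<- total; best_cnt <<- cnt }
    if (k > n) return()
    if (total + suffix[k] <= best) return()
    for (m in k:n) {
      i <- pm[m, 1]; j <- pm[m, 2]
      if (!(i %in% usedA) && !(j %in% usedB)) {
        recurse(m + 1L, c(usedA, i), c(usedB, j), total + pm[m, 3], cnt + 1L)
      }
    }
  }
  recurse(1L, integer(0), integer(0), 0, 0L)
  norm <- sqrt(sum(a$intensity)) * sqrt(sum(b$intensity))
  list(score = best / norm, matched = best_cnt)
}

# Random small spectrum pair sharing some fragments (direct and/or
# precursor-shifted coincidences arise naturally).
random_spectrum_pair <- function() {
  na <- sample(1:6, 1); nb <- sample(1:6, 1)
  shared <- sample(0:min(na, nb), 1)
  pool <- runif(shared, 60, 400)
  mza <- c(pool, runif(na - shared, 60, 400))
  mzb <- c(pool + runif(shared, -0.02, 0.02), runif(nb - shared, 60, 400))
  pa <- runif(1, 420, 800); pb <- pa - sample(c(0, runif(1, -50, 50)), 1)
  list(a = new_spectrum(mza, runif(na, 0.1, 10), pa),
       b = new_spectrum(mzb, runif(nb, 0.1, 10), pb))
}

# Closed-form isotope cluster for Cl_n: binomial over 35/37 isotopes.
cl_cluster_oracle <- function(n, p35 = 0.7578) {
  ab <- dbinom(0:n, n, 1 - p35)
  ab / max(ab)
}

# Mean silhouette width for a 2-cluster labelling of a coordinate matrix.
silhouette_oracle <- function(xy, labels) {
  d <- as.matrix(dist(xy))
  mean(vapply(seq_len(nrow(xy)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(xy)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1)))
}
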