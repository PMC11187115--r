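#' Fit a regularized DMSO reference space
#'
#' With many more features than DMSO wells the full-rank profile covariance
#' is singular, so the Mahalanobis metric is computed in a reduced space: the
#' leading `k` principal axes of the DMSO profiles, with the covariance of
#' the projected profiles shrunk toward its diagonal,
#' \eqn{\hat\Sigma = (1-\lambda) S + \lambda\,\mathrm{diag}(S)}.
#'
#' @param dmso_profiles Matrix of DMSO profiles (wells x features) or a
#'   `"phenotypic_profiles"` object (its DMSO rows are used).
#' @param k Target rank; default `min(n_dmso - 2, 20)`, held one below the
#'   hard `n_dmso - 1` cap so that leave-one-out refits
#'   ([dmso_null_distances()]) support the same rank — null and test
#'   distances then live in the same dimensionality. Always capped at
#'   `min(n_dmso - 1, n_features)`.
#' @param lambda Shrinkage weight in \[0, 1\] (default 0.1).
#' @return A `"reduced_space"`: list with `center`, `basis` (features x k,
#'   orthonormal), `cov` (k x k, symmetric positive definite), `cov_inv`,
#'   `k`, `lambda`.
#' @export
fit_reference_space <- function(dmso_profiles, k = NULL, lambda = 0.1) {
  x <- .profile_matrix(dmso_profiles, role = "dmso")
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 DMSO profiles", call. = FALSE)
  if (lambda < 0 || lambda > 1) stop("'lambda' must be in [0, 1]", call. = FALSE)
  kmax <- min(n - 1L, ncol(x))
  if (is.null(k)) k <- max(1L, min(n - 2L, 20L))
  k <- min(k, kmax)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  pos <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (pos < 1L)
    stop("DMSO profiles are rank-deficient (all identical?)", call. = FALSE)
  k <- min(k, pos)
  basis <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  s <- stats::cov(scores)
  sig <- (1 - lambda) * s + lambda * diag(diag(s), nrow = k)
  structure(list(center = pc$center, basis = basis, cov = sig,
                 cov_inv = solve(sig), k = k, lambda = lambda),
            class = "reduced_space")
}

.profile_matrix <- function(x, role = NULL) {
  if (inherits(x, "phenotypic_profiles")) {
    m <- x$profiles
    if (!is.null(role) && "role" %in% names(x$wells)) {
      sel <- x$wells$role == role
      if (any(sel)) m <- m[sel, , drop = FALSE]
    }
    return(m)
  }
  if (inherits(x, "phenotypic_profile")) return(matrix(unclass(x), nrow = 1L))
  as.matrix(x)
}

#' Mahalanobis distance of a profile from the DMSO reference
#'
#' \eqn{d = \sqrt{(z-\mu)^\top \hat\Sigma^{-1} (z-\mu)}} where `z` is the
#' profile projected into the reduced space.
#'
#' @param profile Numeric profile vector (or matrix of profiles, one per
#'   row) in the original feature space.
#' @param space A `"reduced_space"` from [fit_reference_space()].
#' @return Non-negative distance(s).
#' @export
mahalanobis_distance <- function(profile, space) {
  stopifnot(inherits(space, "reduced_space"))
  x <- if (is.matrix(profile)) profile else matrix(unclass(profile), nrow = 1L)
  if (ncol(x) != nrow(space$basis))
    stop("profile dimension (", ncol(x), ") does not match the space (",
         nrow(space$basis), ")", call. = FALSE)
  z <- sweep(x, 2L, space$center) %*% space$basis
  d2 <- rowSums((z %*% space$cov_inv) * z)
  sqrt(pmax(d2, 0))
}

#' Fit a Gaussian-kernel empirical null from DMSO-DMSO distances
#'
#' Places a Gaussian kernel on each DMSO-DMSO distance; the null CDF at `q`
#' is the mean of \eqn{\Phi((q - d_i)/h)}. The 99th percentile `q99` is
#' solved by bisection on that CDF.
#'
#' @param distances Numeric vector of >= 4 non-negative DMSO-DMSO distances,
#'   not all equal.
#' @param bandwidth `"silverman"` (default, [stats::bw.nrd0()]), `"sj"`
#'   ([stats::bw.SJ()]), or a positive number.
#' @return A `"null_model"`: list with `distances`, `h`, `q99`, `fit`
#'   (descriptor string).
#' @export
fit_null <- function(distances, bandwidth = "silverman") {
  d <- as.numeric(distances)
  if (length(d) < 4L) stop("need at least 4 null distances", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0))
    stop("null distances must be finite and non-negative", call. = FALSE)
  if (max(d) - min(d) <= 0)
    stop("all null distances are equal; increase the number of DMSO wells",
         call. = FALSE)
  h <- if (is.numeric(bandwidth)) {
    if (bandwidth <= 0) stop("'bandwidth' must be positive", call. = FALSE)
    bandwidth
  } else switch(match.arg(bandwidth, c("silverman", "sj")),
                silverman = stats::bw.nrd0(d),
                sj = stats::bw.SJ(d))
  cdf <- function(q) vapply(q, function(qi) mean(stats::pnorm((qi - d) / h)),
                            numeric(1))
  lo <- min(d) - 10 * h
  hi <- max(d) + 10 * h
  q99 <- stats::uniroot(function(q) cdf(q) - 0.99, c(lo, hi),
                        tol = 1e-10)$root
  structure(list(distances = d, h = h, q99 = q99,
                 fit = sprintf("gaussian_kde(n=%d, h=%.6g)", length(d), h)),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model> %s, q99 = %.4f\n", x$fit, x$q99))
  invisible(x)
}

#' One-sided p-value against the kernel null
#'
#' \eqn{p(d) = \frac{1}{n}\sum_i \Phi((d_i - d)/h)}: the upper tail mass of
#' the kernel mixture beyond `d`. Strictly positive, strictly decreasing in
#' `d`, no multiplicity adjustment.
#'
#' @param null A `"null_model"`.
#' @param d Non-negative distance(s).
#' @return p-value(s) in (0, 1\].
#' @export
p_value <- function(null, d) {
  stopifnot(inherits(null, "null_model"))
  if (any(d < 0)) stop("'d' must be non-negative", call. = FALSE)
  p <- vapply(d, function(di) mean(stats::pnorm((null$distances - di) / null$h)),
              numeric(1))
  pmax(p, .Machine$double.xmin)  # strictly positive even when the tail underflows
}

#' Leave-one-out DMSO null distances
#'
#' The distance of each DMSO profile from a reference space refit *without*
#' that profile. In-sample distances (profile included in its own reference
#' fit) are biased low, which would make test compounds look too extreme;
#' leave-one-out makes the null distances exchangeable with the distance of
#' a new inactive well.
#'
#' @param dmso_profiles Matrix of DMSO profiles (wells x features) or a
#'   `"phenotypic_profiles"` object.
#' @param k,lambda Passed to [fit_reference_space()].
#' @param loo Refit per held-out well (default TRUE); FALSE gives the faster
#'   in-sample distances.
#' @return Numeric vector of distances, one per DMSO profile.
#' @export
dmso_null_distances <- function(dmso_profiles, k = NULL, lambda = 0.1,
                                loo = TRUE) {
  x <- .profile_matrix(dmso_profiles, role = "dmso")
  n <- nrow(x)
  if (is.null(k)) k <- max(1L, min(n - 2L, 20L))  # same rank as the full fit
  if (!loo) {
    sp <- fit_reference_space(x, k = k, lambda = lambda)
    return(mahalanobis_distance(x, sp))
  }
  vapply(seq_len(n), function(i) {
    sp <- fit_reference_space(x[-i, , drop = FALSE], k = k, lambda = lambda)
    mahalanobis_distance(x[i, , drop = FALSE], sp)
  }, numeric(1))
}

#' Call bioactivity for one compound x cell line
#'
#' Replicate well distances are aggregated by their median; the aggregated
#' distance is scored against the kernel null. Both stated criteria are
#' reported: `bioactive_by_p` (p <= `p_cutoff`, inclusive) and
#' `bioactive_by_distance` (d >= `dist_mult` x q99, inclusive).
#'
#' @param distances Per-well Mahalanobis distances for the compound (>= 1).
#' @param null A `"null_model"`.
#' @param compound,line Identifiers carried into the result.
#' @param p_cutoff Headline p-value cutoff (default 1e-6).
#' @param dist_mult Multiplier on q99 for the distance criterion (default 2).
#' @return A one-row data frame of class `"bioactivity_call"`: `compound`,
#'   `line`, `n_wells`, `distance`, `p`, `neg_log10_p`, `bioactive_by_p`,
#'   `bioactive_by_distance`.
#' @export
call_bioactivity <- function(distances, null, compound = NA_character_,
                             line = NA_character_, p_cutoff = 1e-6,
                             dist_mult = 2) {
  if (!inherits(null, "null_model"))
    stop("'null' must be a null_model (fit_null)", call. = FALSE)
  if (!length(distances)) stop("need at least one replicate well", call. = FALSE)
  d <- stats::median(distances)
  p <- p_value(null, d)
  out <- data.frame(
    compound = compound, line = line, n_wells = length(distances),
    distance = d, p = p, neg_log10_p = -log10(p),
    bioactive_by_p = p <= p_cutoff,
    bioactive_by_distance = d >= dist_mult * null$q99,
    stringsAsFactors = FALSE)
  attr(out, "well_distances") <- as.numeric(distances)
  class(out) <- c("bioactivity_call", "data.frame")
  out
}

#' Principal-component embedding of phenotypic profiles
#'
#' Centered principal-axis projection; component variances are
#' non-increasing and projections onto distinct components are uncorrelated.
#'
#' @param profiles Matrix (wells x features) or `"phenotypic_profiles"`.
#' @param n_components Number of components (default 2).
#' @return Data frame of coordinates (`PC1`, `PC2`, ...), one row per well.
#' @export
pca_embed <- function(profiles, n_components = 2L) {
  x <- .profile_matrix(profiles)
  if (nrow(x) < 3L) stop("need at least 3 profiles", call. = FALSE)
  if (n_components > min(dim(x)))
    stop("fewer profiles/features than requested components", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k < n_components)  # degenerate input: pad constant-zero components
    coords <- cbind(coords, matrix(0, nrow(coords), n_components - k))
  out <- as.data.frame(coords)
  names(out) <- paste0("PC", seq_len(n_components))
  rownames(out) <- rownames(x)
  out
}

#' Nearest-reference-class prediction for a phenotypic profile
#'
#' Assigns the reference class whose mean profile has the highest cosine
#' similarity to the query. The confidence score is the similarity margin
#' between the best and runner-up class, clamped to \[0, 1\] (a profile
#' aligned with one class mean and orthogonal to the rest scores ~1, a tie
#' scores 0); the unique-profile flag is set when the confidence exceeds
#' `threshold`.
#'
#' @param profile Numeric profile vector.
#' @param class_means Matrix of per-class mean profiles (classes x features,
#'   rownames = class labels); >= 2 classes required.
#' @param threshold Confidence threshold for the flag (default 0.1).
#' @return List with `label`, `confidence` in \[0, 1\], `unique_profile`,
#'   and `similarities` (named vector).
#' @export
classify_reference <- function(profile, class_means, threshold = 0.1) {
  x <- as.numeric(unclass(profile))
  m <- as.matrix(class_means)
  if (nrow(m) < 2L) stop("need at least 2 reference classes", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("class", seq_len(nrow(m)))
  sims <- apply(m, 1L, function(cm) {
    den <- sqrt(sum(x^2)) * sqrt(sum(cm^2))
    if (den == 0) 0 else sum(x * cm) / den
  })
  o <- order(sims, decreasing = TRUE)
  conf <- min(max(sims[o[1L]] - sims[o[2L]], 0), 1)
  list(label = rownames(m)[o[1L]],
       confidence = unname(conf),
       unique_profile = conf > threshold,
       similarities = sims)
}

#' Run the full phenotypic screen pipeline on a feature table
#'
#' For each plate (one plate per cell line): computes leave-one-out DMSO and
#' treatment-well profiles, fits the reduced reference space, derives
#' leave-one-out DMSO null distances, fits the Gaussian-kernel null, and
#' calls bioactivity per compound.
#'
#' @param tbl Single-cell feature table (columns `plate`, `well`, `role`,
#'   `compound`, features `f_*`).
#' @param min_cells,k,lambda,bandwidth,p_cutoff,dist_mult Stage parameters;
#'   see the individual functions.
#' @param loo_null Leave-one-out refit for DMSO null distances (default
#'   TRUE).
#' @return Data frame with one row per compound x plate: the
#'   [call_bioactivity()] columns plus `q99` and `h`. The per-well
#'   distances behind every call are attached as the `"well_distances"`
#'   attribute (a long data frame: `compound`, `line`, `well`, `distance`).
#' @export
screen_bioactivity <- function(tbl, min_cells = 50L, k = NULL, lambda = 0.1,
                               bandwidth = "silverman", p_cutoff = 1e-6,
                               dist_mult = 2, loo_null = TRUE) {
  .check_feature_table(tbl)
  out <- list()
  wd <- list()
  for (pl in unique(tbl$plate)) {
    sub <- tbl[tbl$plate == pl, , drop = FALSE]
    prof <- plate_profiles(sub, min_cells = min_cells)
    is_dmso <- prof$wells$role == "dmso"
    dm <- prof$profiles[is_dmso, , drop = FALSE]
    sp <- fit_reference_space(dm, k = k, lambda = lambda)
    nulld <- dmso_null_distances(dm, k = k, lambda = lambda, loo = loo_null)
    null <- fit_null(nulld, bandwidth = bandwidth)
    trt <- prof$wells[!is_dmso, , drop = FALSE]
    for (cmp in unique(trt$compound)) {
      rows <- which(!is_dmso)[trt$compound == cmp]
      d <- mahalanobis_distance(prof$profiles[rows, , drop = FALSE], sp)
      call <- call_bioactivity(d, null, compound = cmp, line = pl,
                               p_cutoff = p_cutoff, dist_mult = dist_mult)
      call$q99 <- null$q99
      call$h <- null$h
      out[[length(out) + 1L]] <- call
      wd[[length(wd) + 1L]] <- data.frame(
        compound = cmp, line = pl, well = trt$well[trt$compound == cmp],
        distance = d, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "well_distances") <- do.call(rbind, wd)
  res
}
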