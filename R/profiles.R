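#' Feature columns of a single-cell feature table
#'
#' Feature columns are named `f_*`; everything else (`plate`, `well`, `role`,
#' `compound`, `dose`, `cell_id`, ...) is treated as metadata.
#'
#' @param tbl A single-cell feature table.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(tbl) grep("^f_", names(tbl), value = TRUE)

.check_feature_table <- function(tbl, required = c("plate", "well", "role")) {
  miss <- setdiff(required, names(tbl))
  if (length(miss))
    stop("feature table is missing required column ", sQuote(miss[1L]),
         call. = FALSE)
  if (!length(feature_columns(tbl)))
    stop("feature table has no feature columns (expected names like 'f_0001')",
         call. = FALSE)
  invisible(tbl)
}

## Drop rows with any missing feature value; returns table + count dropped.
.drop_incomplete_cells <- function(tbl, feats) {
  ok <- stats::complete.cases(tbl[feats])
  list(tbl = tbl[ok, , drop = FALSE], n_dropped = sum(!ok))
}

#' Phenotypic profile of one well against pooled control cells
#'
#' One signed Kolmogorov-Smirnov statistic per feature (see
#' [ks_statistic()]; positive entries mean the well's cells are shifted
#' toward larger values than the pool). Features with zero variance in the
#' control pool are dropped and recorded.
#'
#' @param well_cells Feature-table slice for the well's cells.
#' @param pooled_cells Feature-table slice of pooled control (DMSO) cells.
#' @param min_cells Minimum cells required in the well (default 50).
#' @return Named numeric vector of class `"phenotypic_profile"` with
#'   attributes `n_cells`, `pool` (descriptor), and `dropped_features`.
#' @export
well_profile <- function(well_cells, pooled_cells, min_cells = 50L) {
  feats <- feature_columns(pooled_cells)
  if (!length(feats)) feats <- feature_columns(well_cells)
  if (!length(feats)) stop("no feature columns found", call. = FALSE)
  if (!all(feats %in% names(well_cells)))
    stop("well and pool have different feature sets", call. = FALSE)
  wc <- .drop_incomplete_cells(well_cells, feats)$tbl
  pc <- .drop_incomplete_cells(pooled_cells, feats)$tbl
  if (nrow(wc) < min_cells)
    stop("well has ", nrow(wc), " usable cells; min_cells = ", min_cells,
         call. = FALSE)
  keep <- vapply(feats, function(f) stats::var(pc[[f]]) > 0, logical(1))
  dropped <- feats[!keep]
  feats <- feats[keep]
  prof <- vapply(feats, function(f)
    .ks_well_vs_pool(wc[[f]], sort(pc[[f]])), numeric(1))
  structure(prof, class = "phenotypic_profile",
            n_cells = nrow(wc),
            pool = sprintf("pooled_dmso(n=%d)", nrow(pc)),
            dropped_features = dropped)
}

#' Leave-one-out phenotypic profiles of a plate's DMSO wells
#'
#' Each DMSO well is profiled against the pool of all *other* DMSO wells on
#' the plate, so a well's own cells never enter its reference pool.
#'
#' @param plate_table Single-cell feature table for one plate.
#' @param min_cells Minimum usable cells per well (default 50); wells below
#'   the cutoff are excluded and listed in the `excluded_wells` attribute.
#' @return A `"phenotypic_profiles"` object: list with `profiles` (wells x
#'   features matrix of signed KS values), `wells` (metadata data frame with
#'   `well`, `n_cells`, `pool`), `features`, and `dropped_features`.
#' @export
dmso_profiles <- function(plate_table, min_cells = 50L) {
  .check_feature_table(plate_table)
  dmso <- plate_table[plate_table$role == "dmso", , drop = FALSE]
  if (length(unique(dmso$well)) < 4L)
    stop("need at least 4 DMSO wells on the plate; found ",
         length(unique(dmso$well)), call. = FALSE)
  .profiles_internal(dmso, dmso, min_cells, loo = TRUE)
}

#' Phenotypic profiles for every well on a plate
#'
#' DMSO wells are profiled leave-one-out against the other DMSO wells;
#' treatment wells are profiled against the full DMSO pool.
#'
#' @inheritParams dmso_profiles
#' @return A `"phenotypic_profiles"` object covering all retained wells; the
#'   `wells` data frame carries `role` and `compound`.
#' @export
plate_profiles <- function(plate_table, min_cells = 50L) {
  .check_feature_table(plate_table)
  dmso <- plate_table[plate_table$role == "dmso", , drop = FALSE]
  if (length(unique(dmso$well)) < 4L)
    stop("need at least 4 DMSO wells on the plate; found ",
         length(unique(dmso$well)), call. = FALSE)
  other <- plate_table[plate_table$role != "dmso", , drop = FALSE]
  pd <- .profiles_internal(dmso, dmso, min_cells, loo = TRUE)
  if (!nrow(other)) return(pd)
  po <- .profiles_internal(other, dmso, min_cells, loo = FALSE,
                           features = pd$features,
                           dropped = pd$dropped_features)
  pd$profiles <- rbind(pd$profiles, po$profiles)
  pd$wells <- rbind(pd$wells, po$wells)
  pd$excluded_wells <- c(pd$excluded_wells, po$excluded_wells)
  pd
}

## Shared worker. `loo = TRUE` means each well of `wells_tbl` is excluded from
## its own pool (wells_tbl must then equal the pool table).
.profiles_internal <- function(wells_tbl, pool_tbl, min_cells, loo,
                               features = NULL, dropped = NULL) {
  feats_all <- feature_columns(pool_tbl)
  pool <- .drop_incomplete_cells(pool_tbl, feats_all)
  wtab <- .drop_incomplete_cells(wells_tbl, feats_all)$tbl
  ptab <- pool$tbl
  if (is.null(features)) {
    keep <- vapply(feats_all, function(f) stats::var(ptab[[f]]) > 0, logical(1))
    dropped <- feats_all[!keep]
    features <- feats_all[keep]
  }
  sorted_pool <- lapply(features, function(f) sort(ptab[[f]]))
  names(sorted_pool) <- features
  row_by_well <- split(seq_len(nrow(wtab)), wtab$well)
  wells <- unique(wtab$well)
  row_by_well <- row_by_well[wells]
  counts <- lengths(row_by_well)
  ok <- counts >= min_cells
  excluded <- wells[!ok]
  wells <- wells[ok]
  row_by_well <- row_by_well[ok]
  feat_mat <- as.matrix(wtab[features])
  prof <- matrix(NA_real_, nrow = length(wells), ncol = length(features),
                 dimnames = list(wells, features))
  ## one findInterval per feature over all wells' (sorted) cells at once:
  ## per-call validation of the pool vector would otherwise dominate
  ns <- lengths(row_by_well)
  ends <- cumsum(ns)
  starts <- ends - ns + 1L
  for (fi in seq_along(features)) {
    ps <- sorted_pool[[fi]]
    m_full <- length(ps)
    q <- unlist(lapply(row_by_well, function(r)
      sort.int(feat_mat[r, fi], method = "quick")), use.names = FALSE)
    leq_all <- findInterval(q, ps)
    less_all <- findInterval(q, ps, left.open = TRUE)
    for (k in seq_along(wells)) {
      n <- ns[k]
      idx <- starts[k]:ends[k]
      i1 <- seq_len(n)
      leq <- leq_all[idx]; less <- less_all[idx]
      if (loo) {
        leq <- leq - i1
        less <- less - (i1 - 1L)
        m <- m_full - n
      } else m <- m_full
      d_pos <- max(less / m - (i1 - 1L) / n)  # pool above well
      d_neg <- max(i1 / n - leq / m)          # well above pool
      prof[k, fi] <- if (d_pos >= d_neg) d_pos else -d_neg
    }
  }
  meta <- lapply(seq_along(wells), function(k) {
    rows <- row_by_well[[k]]
    data.frame(
      well = wells[k],
      role = wtab$role[rows[1L]],
      compound = if ("compound" %in% names(wtab))
        wtab$compound[rows[1L]] else NA_character_,
      n_cells = length(rows),
      pool = if (loo) sprintf("dmso_pool_excluding(%s)", wells[k])
             else sprintf("dmso_pool(n=%d)", nrow(ptab)),
      stringsAsFactors = FALSE)
  })
  structure(list(profiles = prof,
                 wells = do.call(rbind, meta),
                 features = features,
                 dropped_features = dropped,
                 excluded_wells = as.character(excluded),
                 n_incomplete_cells = pool$n_dropped),
            class = "phenotypic_profiles")
}

#' @export
print.phenotypic_profiles <- function(x, ...) {
  cat(sprintf("<phenotypic_profiles> %d wells x %d features (%d dropped)\n",
              nrow(x$profiles), length(x$features), length(x$dropped_features)))
  invisible(x)
}
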