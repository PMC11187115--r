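## Delimited-text-first I/O: comma-separated, UTF-8, header row. MGF is the
## only non-tabular format handled.

.read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tbl))
  if (length(miss))
    stop(what, " file ", sQuote(basename(path)),
         " is missing required column ", sQuote(miss[1L]), call. = FALSE)
  tbl
}

#' Read / write single-cell feature tables
#'
#' Comma-separated with header; metadata columns `plate`, `well`, `role`
#' (plus optional `compound`, `dose`, `cell_id`) and feature columns `f_*`.
#'
#' @param path File path.
#' @return `read_feature_table()` returns the validated data frame.
#' @export
read_feature_table <- function(path) {
  tbl <- .read_csv_checked(path, c("plate", "well", "role"), "feature table")
  .check_feature_table(tbl)
  tbl
}

#' @rdname read_feature_table
#' @param tbl Table to write.
#' @export
write_feature_table <- function(tbl, path) {
  .check_feature_table(tbl)
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' Read / write fluorescence traces
#'
#' Two-column comma-separated text: `frame` (0-based) and `intensity`.
#'
#' @param path File path.
#' @param rate_hz Sampling rate to attach on read (default 30).
#' @return `read_trace()` returns a `"ca_trace"`.
#' @export
read_trace <- function(path, rate_hz = 30) {
  tbl <- .read_csv_checked(path, c("frame", "intensity"), "trace")
  new_ca_trace(tbl$intensity[order(tbl$frame)], rate_hz = rate_hz)
}

#' @rdname read_trace
#' @param trace A `"ca_trace"`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ca_trace"))
  utils::write.csv(data.frame(frame = seq_along(trace$intensity) - 1L,
                              intensity = trace$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an MGF spectrum file
#'
#' Parses `BEGIN IONS` / `END IONS` blocks with `PEPMASS`, `CHARGE`, and
#' optional `TITLE` headers followed by m/z-intensity pairs. Unsorted peak
#' lists are sorted with a warning.
#'
#' @param path File path.
#' @return List of `"spectrum"` objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN/END IONS blocks", call. = FALSE)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, character(1), 1L))
    vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
    pep <- vals[match("PEPMASS", keys)]
    if (is.na(pep))
      stop("MGF block ", k, " has no PEPMASS", call. = FALSE)
    pep <- as.numeric(strsplit(trimws(pep), "\\s+")[[1L]][1L])
    chg <- vals[match("CHARGE", keys)]
    charge <- if (is.na(chg)) 1L else {
      sgn <- if (grepl("-", chg, fixed = TRUE)) -1L else 1L
      sgn * as.integer(gsub("[^0-9]", "", chg))
    }
    title <- vals[match("TITLE", keys)]
    peaks <- block[!hdr & nzchar(trimws(block))]
    mz <- int <- numeric(0)
    if (length(peaks)) {
      fields <- strsplit(trimws(peaks), "\\s+")
      mz <- as.numeric(vapply(fields, `[`, character(1), 1L))
      int <- as.numeric(vapply(fields, `[`, character(1), 2L))
      if (anyNA(mz) || anyNA(int))
        stop("malformed peak line in MGF block ", k, call. = FALSE)
      if (is.unsorted(mz))
        warning("MGF block ", k, " has unsorted peaks; sorting", call. = FALSE)
    }
    out[[k]] <- new_spectrum(mz, int, precursor_mz = pep, charge = charge,
                             id = if (is.na(title)) sprintf("spec_%03d", k)
                                  else title)
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra List of `"spectrum"` objects.
#' @param path File path.
#' @export
write_mgf <- function(spectra, path) {
  stopifnot(all(vapply(spectra, inherits, logical(1), "spectrum")))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 sprintf("TITLE=%s", s$id),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("CHARGE=%d%s", abs(s$charge),
                         if (s$charge < 0) "-" else "+"),
                 sprintf("%.6f %.2f", s$mz, s$intensity),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Read / write microfractionation plates
#'
#' Comma-separated with columns `type`, `fraction`, `od_initial`,
#' `od_final`.
#'
#' @param path File path.
#' @return `read_fraction_plate()` returns the validated data frame.
#' @export
read_fraction_plate <- function(path) {
  .read_csv_checked(path, c("type", "fraction", "od_initial", "od_final"),
                    "fraction plate")
}

#' @rdname read_fraction_plate
#' @param plate Plate table to write.
#' @export
write_fraction_plate <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' Write / read phenotypic profiles
#'
#' One row per well: metadata columns (`well`, `role`, `compound`,
#' `n_cells`, `pool`) followed by the retained feature columns.
#'
#' @param profiles A `"phenotypic_profiles"` object.
#' @param path File path.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "phenotypic_profiles"))
  tbl <- cbind(profiles$wells, as.data.frame(profiles$profiles))
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  tbl <- .read_csv_checked(path, c("well", "n_cells", "pool"), "profiles")
  feats <- feature_columns(tbl)
  prof <- as.matrix(tbl[feats])
  rownames(prof) <- tbl$well
  structure(list(profiles = prof,
                 wells = tbl[setdiff(names(tbl), feats)],
                 features = feats, dropped_features = character(0),
                 excluded_wells = character(0)),
            class = "phenotypic_profiles")
}

#' Write bioactivity calls
#'
#' @param calls Data frame from [screen_bioactivity()] /
#'   [call_bioactivity()].
#' @param path File path.
#' @export
write_calls <- function(calls, path) {
  utils::write.csv(calls, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  .read_csv_checked(path, c("compound", "line", "distance", "p"), "calls")
}

#' Write a molecular network as edge list + component membership
#'
#' @param net A `"molecular_network"`.
#' @param edges_path,components_path Output file paths.
#' @export
write_network <- function(net, edges_path, components_path) {
  stopifnot(inherits(net, "molecular_network"))
  utils::write.csv(net$edges, edges_path, row.names = FALSE)
  utils::write.csv(net$membership, components_path, row.names = FALSE)
  invisible(edges_path)
}
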