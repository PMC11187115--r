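#' Default run configuration for the full pipeline
#'
#' Collects every stage threshold in one place. Defaults follow the standard
#' screening protocol: p-value cutoff 1e-6 with a 2 x q99 distance criterion
#' for bioactivity, cosine cutoff 0.7 with >= 4 matched fragments and a
#' family cap of 100 for networking (fragment tolerance 0.05 Da, precursor
#' tolerance 0.02 Da), a 200-600 frame analysis window for calcium traces,
#' and a 1.8 min / 0.25 min / 80-fraction collection schedule.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(
    min_cells = 50L,
    k = 20L,
    lambda = 0.1,
    bandwidth = "silverman",
    p_cutoff = 1e-6,
    dist_mult = 2,
    cosine_cutoff = 0.7,
    min_matched = 4L,
    family_cap = 100L,
    fragment_tol = 0.05,
    precursor_tol = 0.02,
    ca_window_start = 200L,
    ca_window_end = 600L,
    schedule_start_min = 1.8,
    schedule_interval_min = 0.25,
    schedule_n_fractions = 80L,
    inhibition_threshold = 80,
    confidence_threshold = 0.1,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown configuration key ", sQuote(bad[1L]), call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as flat key=value text
#'
#' Round-trips losslessly: numbers are written with full precision and read
#' back to their original types.
#'
#' @param config A `"run_config"`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- vapply(config, function(v) {
    if (is.character(v)) v else format(v, digits = 17)
  }, character(1))
  writeLines(paste0(names(config), "=", vals), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
  defaults <- run_config()
  bad <- setdiff(keys, names(defaults))
  if (length(bad))
    stop("unknown configuration key ", sQuote(bad[1L]), " in ", path,
         call. = FALSE)
  out <- defaults
  for (i in seq_along(keys)) {
    template <- defaults[[keys[i]]]
    out[[keys[i]]] <- if (is.character(template)) vals[i]
    else if (is.integer(template)) as.integer(vals[i])
    else as.numeric(vals[i])
  }
  out
}

#' Run the simulate - profile - call chain on synthetic data
#'
#' Convenience wrapper tying the synthetic screen generator to the
#' bioactivity pipeline with a single seed, mirroring how a real campaign's
#' feature table would flow through [screen_bioactivity()].
#'
#' @param config A `"screen_config"` (see [screen_config()]).
#' @param run A `"run_config"` of stage parameters.
#' @return List with `truth` (generator ground truth) and `calls`
#'   (bioactivity call table).
#' @export
run_screen_pipeline <- function(config, run = run_config()) {
  sim <- gen_screen(config)
  calls <- screen_bioactivity(
    sim$table, min_cells = run$min_cells, k = run$k, lambda = run$lambda,
    bandwidth = run$bandwidth, p_cutoff = run$p_cutoff,
    dist_mult = run$dist_mult)
  list(truth = sim$truth, calls = calls)
}
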