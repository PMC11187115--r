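#' Retention-time schedule of a microfractionation run
#'
#' Contiguous half-open retention-time intervals for timed fraction
#' collection: fraction i covers
#' `[start + (i-1) * interval, start + i * interval)` minutes.
#'
#' @param start_min Collection start in minutes (default 1.8, the system
#'   dead time).
#' @param interval_min Collection interval in minutes (default 0.25, i.e.
#'   one fraction every 15 s).
#' @param collection_span_min Total collection span in minutes (default 20).
#' @return Data frame with `fraction`, `rt_start_min`, `rt_end_min`;
#'   `floor(span / interval)` rows (zero rows for a zero span).
#' @examples
#' nrow(fraction_schedule(1.8, 0.25, 20)) # 80
#' @export
fraction_schedule <- function(start_min = 1.8, interval_min = 0.25,
                              collection_span_min = 20) {
  if (interval_min <= 0 || start_min < 0 || collection_span_min < 0)
    stop("schedule parameters must be positive", call. = FALSE)
  n <- floor(collection_span_min / interval_min + 1e-9)
  if (n < 1L)
    return(data.frame(fraction = integer(0), rt_start_min = numeric(0),
                      rt_end_min = numeric(0)))
  i <- seq_len(n)
  data.frame(fraction = i,
             rt_start_min = start_min + (i - 1) * interval_min,
             rt_end_min = start_min + i * interval_min)
}

#' Percent growth inhibition relative to solvent/media controls
#'
#' `100 * (1 - delta_od / control_delta_od)`, clamped to \[0, 100\], where
#' `delta_od` is the OD increase of the well over the incubation
#' (final - initial).
#'
#' @param od_initial,od_final OD readings before and after incubation
#'   (vectors recycled in the usual way).
#' @param control_delta_od Mean OD increase of the solvent/media control
#'   wells; must be positive (otherwise the control culture failed to grow
#'   and the plate cannot be scored).
#' @return Percent inhibition in \[0, 100\].
#' @export
growth_inhibition <- function(od_initial, od_final, control_delta_od) {
  if (!is.finite(control_delta_od) || control_delta_od <= 0)
    stop("control wells show no growth (delta OD <= 0); plate not scorable",
         call. = FALSE)
  pmin(100, pmax(0, 100 * (1 - (od_final - od_initial) / control_delta_od)))
}

#' Score a microfractionation plate into an inhibition map
#'
#' Validates the plate controls (positive control must inhibit >= 90%,
#' negative <= 10%, both scored against the solvent/media control growth),
#' then computes per-fraction percent inhibition and attaches the
#' retention-time schedule.
#'
#' @param plate A fraction plate: data frame with columns `type` (one of
#'   `fraction`, `positive`, `negative`, `solvent`), `fraction` (index, NA
#'   for controls), `od_initial`, `od_final` — as produced by
#'   [gen_fraction_plate()] or [read_fraction_plate()].
#' @param schedule Retention-time schedule (default the standard
#'   1.8 min / 15 s / 80-fraction run).
#' @param active_threshold Percent inhibition above which a fraction is
#'   flagged active (default 80).
#' @return An `"inhibition_map"`: data frame with `fraction`,
#'   `rt_start_min`, `rt_end_min`, `inhibition_pct`, `active`.
#' @export
score_fraction_plate <- function(plate, schedule = fraction_schedule(),
                                 active_threshold = 80) {
  need <- c("type", "fraction", "od_initial", "od_final")
  miss <- setdiff(need, names(plate))
  if (length(miss))
    stop("plate is missing required column ", sQuote(miss[1L]), call. = FALSE)
  ctrl_growth <- function(kind) {
    rows <- plate$type == kind
    if (!any(rows)) stop("plate has no ", kind, " control wells", call. = FALSE)
    mean(plate$od_final[rows] - plate$od_initial[rows])
  }
  solvent <- ctrl_growth("solvent")
  if (solvent <= 0)
    stop("solvent/media controls show no growth; plate not scorable",
         call. = FALSE)
  pos_inh <- growth_inhibition(0, ctrl_growth("positive"), solvent)
  neg_inh <- growth_inhibition(0, ctrl_growth("negative"), solvent)
  if (pos_inh < 90)
    stop(sprintf("positive control inhibition %.1f%% < 90%%; plate failed QC",
                 pos_inh), call. = FALSE)
  if (neg_inh > 10)
    stop(sprintf("negative control inhibition %.1f%% > 10%%; plate failed QC",
                 neg_inh), call. = FALSE)
  fr <- plate[plate$type == "fraction", , drop = FALSE]
  fr <- fr[order(fr$fraction), , drop = FALSE]
  inh <- growth_inhibition(fr$od_initial, fr$od_final, solvent)
  out <- merge(schedule, data.frame(fraction = fr$fraction,
                                    inhibition_pct = inh),
               by = "fraction", all.x = TRUE, sort = TRUE)
  out$active <- !is.na(out$inhibition_pct) &
    out$inhibition_pct >= active_threshold
  class(out) <- c("inhibition_map", "data.frame")
  out
}

#' Merge active fractions into retention-time windows
#'
#' Maximal runs of consecutive fractions at or above the threshold are
#' reported as merged half-open retention-time windows, with the peak
#' fraction and its inhibition.
#'
#' @param inhibition_map An `"inhibition_map"` (or data frame with
#'   `fraction`, `rt_start_min`, `rt_end_min`, `inhibition_pct`).
#' @param threshold Percent inhibition threshold in (0, 100\] (default 80).
#' @return Data frame (possibly empty) with `rt_start_min`, `rt_end_min`,
#'   `first_fraction`, `last_fraction`, `peak_fraction`,
#'   `max_inhibition_pct`, sorted by retention time.
#' @export
map_active_fractions <- function(inhibition_map, threshold = 80) {
  if (threshold <= 0 || threshold > 100)
    stop("'threshold' must be in (0, 100]", call. = FALSE)
  m <- inhibition_map[order(inhibition_map$fraction), , drop = FALSE]
  act <- !is.na(m$inhibition_pct) & m$inhibition_pct >= threshold
  if (!any(act))
    return(data.frame(rt_start_min = numeric(0), rt_end_min = numeric(0),
                      first_fraction = integer(0), last_fraction = integer(0),
                      peak_fraction = integer(0),
                      max_inhibition_pct = numeric(0)))
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- do.call(rbind, lapply(runs, function(k) {
    idx <- starts[k]:ends[k]
    peak <- idx[which.max(m$inhibition_pct[idx])]
    data.frame(rt_start_min = m$rt_start_min[idx[1L]],
               rt_end_min = m$rt_end_min[idx[length(idx)]],
               first_fraction = m$fraction[idx[1L]],
               last_fraction = m$fraction[idx[length(idx)]],
               peak_fraction = m$fraction[peak],
               max_inhibition_pct = max(m$inhibition_pct[idx]))
  }))
  out[order(out$rt_start_min), , drop = FALSE]
}
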