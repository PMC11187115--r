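#' Configuration for a synthetic high-content screen
#'
#' Defaults describe a single-compound screen in the style of a cell-painting
#' campaign: triplicate compound wells at one dose, 16 DMSO control wells per
#' plate (one plate per cell line), and anonymous continuous single-cell
#' features standing in for intensity/morphology/texture measurements.
#'
#' @param n_cell_lines Number of cell lines (one plate each).
#' @param n_dmso_wells DMSO wells per plate (>= 4).
#' @param n_compounds Number of test compounds.
#' @param n_compound_wells Replicate wells per compound per plate (default 3).
#' @param cells_per_well_mean Poisson mean cell count per well (> 0); counts
#'   are truncated at >= 10 so per-well ECDFs stay meaningful.
#' @param n_features Number of features (>= 2).
#' @param affected_feature_fraction Fraction of features shifted in active
#'   (compound, line) pairs; `affected_feature_fraction * n_features >= 1`
#'   required whenever `effect_size_delta != 0`.
#' @param effect_size_delta Shift applied to affected features in active
#'   wells, in within-well standard-deviation units.
#' @param active_lines Identifiers (indices) of cell lines in which the
#'   compounds are active; default none.
#' @param rho Optional equicorrelation between features (default 0,
#'   independent features with unit variance).
#' @param seed Integer seed; all randomness in [gen_screen()] flows from it.
#' @return A validated `"screen_config"` list.
#' @export
screen_config <- function(n_cell_lines = 1L, n_dmso_wells = 16L,
                          n_compounds = 1L, n_compound_wells = 3L,
                          cells_per_well_mean = 500, n_features = 100L,
                          affected_feature_fraction = 0.1,
                          effect_size_delta = 0, active_lines = integer(0),
                          rho = 0, seed = 1L) {
  cfg <- list(n_cell_lines = as.integer(n_cell_lines),
              n_dmso_wells = as.integer(n_dmso_wells),
              n_compounds = as.integer(n_compounds),
              n_compound_wells = as.integer(n_compound_wells),
              cells_per_well_mean = cells_per_well_mean,
              n_features = as.integer(n_features),
              affected_feature_fraction = affected_feature_fraction,
              effect_size_delta = effect_size_delta,
              active_lines = as.integer(active_lines),
              rho = rho, seed = as.integer(seed))
  if (cfg$n_cell_lines < 1L || cfg$n_compounds < 0L ||
      cfg$n_compound_wells < 1L)
    stop("counts must be positive", call. = FALSE)
  if (cfg$n_dmso_wells < 4L)
    stop("need n_dmso_wells >= 4", call. = FALSE)
  if (!is.finite(cfg$cells_per_well_mean) || cfg$cells_per_well_mean <= 0)
    stop("'cells_per_well_mean' must be positive", call. = FALSE)
  if (cfg$n_features < 2L) stop("need n_features >= 2", call. = FALSE)
  if (cfg$affected_feature_fraction < 0 || cfg$affected_feature_fraction > 1)
    stop("'affected_feature_fraction' must be in [0, 1]", call. = FALSE)
  if (cfg$effect_size_delta != 0 &&
      cfg$affected_feature_fraction * cfg$n_features < 1)
    stop("a nonzero effect needs at least one affected feature", call. = FALSE)
  if (cfg$rho < 0 || cfg$rho >= 1)
    stop("'rho' must be in [0, 1)", call. = FALSE)
  if (any(cfg$active_lines < 1L | cfg$active_lines > cfg$n_cell_lines))
    stop("'active_lines' must index existing cell lines", call. = FALSE)
  structure(cfg, class = "screen_config")
}

## Truncated-Poisson cell count (>= 10) by resampling.
.rpois_trunc <- function(n, lambda, lower = 10L) {
  x <- stats::rpois(n, lambda)
  while (any(bad <- x < lower)) x[bad] <- stats::rpois(sum(bad), lambda)
  x
}

#' Generate a synthetic single-cell screen with ground truth
#'
#' Per well, cell counts are Poisson (truncated at >= 10) and each cell's
#' feature vector is drawn from a line-specific Gaussian (line-specific
#' feature means, unit within-well variance, optional equicorrelation
#' `rho`). In active (compound, line) pairs the affected features are
#' shifted by `effect_size_delta` within-well standard deviations.
#'
#' @param config A `"screen_config"`.
#' @return List with `table` (single-cell feature table: `plate`, `well`,
#'   `role`, `compound`, `dose`, `cell_id`, `f_0001`...) and `truth`
#'   (ground-truth list: `active` data frame over compound x line,
#'   `affected_features`, `effect_size_delta`, `config`).
#' @export
gen_screen <- function(config) {
  if (!inherits(config, "screen_config")) config <- do.call(screen_config, config)
  set.seed(config$seed)
  F <- config$n_features
  feat_names <- sprintf("f_%04d", seq_len(F))
  n_aff <- if (config$effect_size_delta != 0)
    max(1L, round(config$affected_feature_fraction * F)) else 0L
  affected <- if (n_aff) sort(sample.int(F, n_aff)) else integer(0)
  compounds <- if (config$n_compounds)
    sprintf("cmpd_%03d", seq_len(config$n_compounds)) else character(0)
  active <- expand.grid(compound = compounds,
                        line = seq_len(config$n_cell_lines),
                        stringsAsFactors = FALSE)
  active$active <- active$line %in% config$active_lines
  mats <- list()
  meta <- list()
  for (ln in seq_len(config$n_cell_lines)) {
    plate <- sprintf("plate_%02d", ln)
    mu <- stats::rnorm(F)  # line-specific feature means
    draw_cells <- function(n, shift_features = integer(0)) {
      z <- matrix(stats::rnorm(n * F), n, F)
      if (config$rho > 0) {
        shared <- stats::rnorm(n)
        z <- sqrt(1 - config$rho) * z + sqrt(config$rho) * shared
      }
      x <- sweep(z, 2L, mu, "+")
      if (length(shift_features))
        x[, shift_features] <- x[, shift_features] + config$effect_size_delta
      x
    }
    add_well <- function(well, role, compound, dose, shift) {
      n <- .rpois_trunc(1L, config$cells_per_well_mean)
      mats[[length(mats) + 1L]] <<- draw_cells(n, shift)
      meta[[length(meta) + 1L]] <<- data.frame(
        plate = plate, well = well, role = role, compound = compound,
        dose = dose, cell_id = seq_len(n), stringsAsFactors = FALSE)
    }
    for (w in seq_len(config$n_dmso_wells)) {
      add_well(sprintf("%s_dmso_%02d", plate, w), "dmso", "DMSO", 0,
               integer(0))
    }
    for (ci in seq_along(compounds)) {
      shift <- if (ln %in% config$active_lines) affected else integer(0)
      for (w in seq_len(config$n_compound_wells)) {
        add_well(sprintf("%s_%s_r%d", plate, compounds[ci], w), "compound",
                 compounds[ci], 10, shift)
      }
    }
  }
  x <- do.call(rbind, mats)
  colnames(x) <- feat_names
  tbl <- cbind(do.call(rbind, meta), as.data.frame(x))
  rownames(tbl) <- NULL
  list(table = tbl,
       truth = list(active = active,
                    affected_features = feat_names[affected],
                    effect_size_delta = config$effect_size_delta,
                    config = config))
}

#' Generate a synthetic calcium-transient trace with ground truth
#'
#' Trace = low-order polynomial baseline drift + periodic transient kernel
#' (difference of exponentials: 50 ms rise, 400 ms decay, scaled so an
#' isolated transient peaks at `amplitude`) + Gaussian noise. At high beat
#' rates consecutive transients summate, so the ground truth records both
#' the requested `amplitude_nominal` and the realized `amplitude` (mean
#' peak-above-preceding-onset height of the clean transient component on the
#' sampling grid) — the latter is what the trace actually contains and what
#' a peak analysis can recover.
#'
#' @param frequency_hz Beat frequency (must be < `rate_hz / 4`).
#' @param amplitude Transient amplitude in a.u. (0 gives drift + noise only).
#' @param duration_s Recording length in seconds (default 20).
#' @param rate_hz Frame rate in Hz (default 30).
#' @param drift_range Peak-to-peak scale of the polynomial drift (default
#'   0.5 a.u.).
#' @param noise_sd Gaussian noise standard deviation (default 0.02 a.u.,
#'   genetically encoded indicators are high-SNR).
#' @param phase_s Time of the first transient onset (default 0.3 s).
#' @param rise_s,decay_s Kernel time constants (defaults 0.05 and 0.4 s).
#' @param seed Integer seed.
#' @return List with `trace` (a `"ca_trace"`) and `truth` (list:
#'   `onsets_s`, `frequency_hz`, `amplitude_nominal`, `amplitude`,
#'   `n_transients`).
#' @export
gen_ca_trace <- function(frequency_hz, amplitude, duration_s = 20,
                         rate_hz = 30, drift_range = 0.5, noise_sd = 0.02,
                         phase_s = 0.3, rise_s = 0.05, decay_s = 0.4,
                         seed = 1L) {
  if (frequency_hz <= 0 || duration_s <= 0 || rate_hz <= 0 || amplitude < 0)
    stop("frequency, duration, rate must be positive; amplitude >= 0",
         call. = FALSE)
  if (frequency_hz >= rate_hz / 4)
    stop("'frequency_hz' must be below rate_hz / 4 to be resolvable",
         call. = FALSE)
  set.seed(seed)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  onsets <- seq(phase_s, duration_s - 1e-9, by = 1 / frequency_hz)
  ## difference-of-exponentials kernel normalized to unit peak
  kern <- function(dt) {
    v <- exp(-dt / decay_s) - exp(-dt / rise_s)
    v[dt < 0] <- 0
    v
  }
  tp <- rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
  kmax <- kern(tp)
  clean <- numeric(n)
  for (o in onsets) clean <- clean + amplitude * kern(t - o) / kmax
  drift <- drift_range * (0.5 * sin(pi * t / duration_s) +
                            0.3 * (t / duration_s) +
                            0.2 * (t / duration_s)^2)
  y <- clean + drift + stats::rnorm(n, sd = noise_sd)
  ## realized transient heights on the sampling grid
  realized <- numeric(0)
  if (amplitude > 0) {
    for (o in onsets) {
      i0 <- min(n, max(1L, floor(o * rate_hz) + 1L))
      i1 <- min(n, i0 + ceiling((tp + 0.1) * rate_hz))
      if (i1 > i0) realized <- c(realized, max(clean[i0:i1]) - clean[i0])
    }
  }
  list(trace = new_ca_trace(y, rate_hz = rate_hz),
       truth = list(onsets_s = onsets, frequency_hz = frequency_hz,
                    amplitude_nominal = amplitude,
                    amplitude = if (length(realized)) mean(realized) else 0,
                    n_transients = length(onsets)))
}

#' Generate synthetic MS/MS spectra with ground truth
#'
#' Each compound gets a precursor consistent with its formula and adduct,
#' a set of family-shared fragment ions (compounds in the same family share
#' them, so networking links them), unique fragments, and — when the formula
#' contains an SO3 unit — a companion ion at precursor minus the calculated
#' SO3 mass. Fragment m/z values carry ppm-scale jitter.
#'
#' @param formulas Character vector of molecular formulas, one per compound.
#' @param families Integer vector assigning compounds to molecular families
#'   (default all one family).
#' @param adduct Adduct applied to every compound (default `"[M+H]+"`).
#' @param n_shared Shared fragments per family (default 6; at least 4 are
#'   needed for the default network edge criterion).
#' @param n_unique Unique fragments per compound (default 4).
#' @param mz_jitter_ppm Fragment m/z jitter in ppm (default 5).
#' @param seed Integer seed.
#' @return List with `spectra` (list of `"spectrum"`) and `truth` (data
#'   frame: `id`, `formula`, `adduct`, `family`, `precursor_mz`,
#'   `has_so3_loss`; plus `patterns`, a list of theoretical isotope
#'   patterns per compound).
#' @export
gen_spectra <- function(formulas, families = rep(1L, length(formulas)),
                        adduct = "[M+H]+", n_shared = 6L, n_unique = 4L,
                        mz_jitter_ppm = 5, seed = 1L) {
  if (!length(formulas)) stop("need at least one formula", call. = FALSE)
  if (length(families) != length(formulas))
    stop("'families' must match 'formulas' in length", call. = FALSE)
  set.seed(seed)
  counts <- lapply(formulas, parse_formula)
  prec <- vapply(counts, adduct_mz, numeric(1), adduct = adduct)
  fam_frags <- lapply(unique(families), function(f)
    sort(stats::runif(n_shared, 60, 0.6 * min(prec[families == f]))))
  names(fam_frags) <- as.character(unique(families))
  jitter <- function(mz) mz * (1 + stats::rnorm(length(mz), sd = mz_jitter_ppm * 1e-6))
  spectra <- vector("list", length(formulas))
  so3 <- logical(length(formulas))
  for (i in seq_along(formulas)) {
    shared <- fam_frags[[as.character(families[i])]]
    uniq <- stats::runif(n_unique, 60, prec[i] - 20)
    mz <- c(jitter(shared), jitter(uniq))
    int <- c(stats::rlnorm(n_shared, log(1000), 0.3),
             stats::rlnorm(n_unique, log(300), 0.5))
    cc <- counts[[i]]
    so3[i] <- !is.na(cc["S"]) && cc["S"] >= 1 &&
      !is.na(cc["O"]) && cc["O"] >= 3
    if (so3[i]) {
      mz <- c(mz, jitter(prec[i] - monoisotopic_mass("SO3")))
      int <- c(int, stats::rlnorm(1, log(800), 0.3))
    }
    spectra[[i]] <- new_spectrum(mz, int, precursor_mz = prec[i],
                                 id = sprintf("spec_%03d", i))
  }
  truth <- data.frame(id = vapply(spectra, `[[`, character(1), "id"),
                      formula = formulas, adduct = adduct,
                      family = families, precursor_mz = prec,
                      has_so3_loss = so3, stringsAsFactors = FALSE)
  list(spectra = spectra,
       truth = c(list(table = truth),
                 list(patterns = lapply(counts, isotope_pattern))))
}

#' Generate a synthetic microfractionation plate with ground truth
#'
#' 80 fractions plus positive / negative / solvent control wells; the OD
#' increase of fractions inside the active window is suppressed in
#' proportion to `strength` (1 = complete growth inhibition).
#'
#' @param active_window Integer range `c(first, last)` of active fractions
#'   within 1..`n_fractions`, or NULL for an inactive plate.
#' @param strength Inhibition strength in \[0, 1\].
#' @param n_fractions Number of fractions (default 80).
#' @param control_delta_od Mean OD increase of growing control wells
#'   (default 0.5).
#' @param od_initial Initial OD of all wells (default 0.05).
#' @param noise_sd OD reading noise (default 0.005).
#' @param seed Integer seed.
#' @return List with `plate` (data frame: `type`, `fraction`, `od_initial`,
#'   `od_final`) and `truth` (list: `active_window`, `strength`).
#' @export
gen_fraction_plate <- function(active_window = NULL, strength = 1,
                               n_fractions = 80L, control_delta_od = 0.5,
                               od_initial = 0.05, noise_sd = 0.005,
                               seed = 1L) {
  if (strength < 0 || strength > 1)
    stop("'strength' must be in [0, 1]", call. = FALSE)
  if (!is.null(active_window)) {
    if (length(active_window) != 2L || active_window[1L] > active_window[2L] ||
        active_window[1L] < 1L || active_window[2L] > n_fractions)
      stop("'active_window' must lie within [1, ", n_fractions, "]",
           call. = FALSE)
  }
  set.seed(seed)
  inhib <- numeric(n_fractions)
  if (!is.null(active_window) && strength > 0)
    inhib[active_window[1L]:active_window[2L]] <- strength
  d_od <- control_delta_od * (1 - inhib) + stats::rnorm(n_fractions, sd = noise_sd)
  d_od <- pmax(d_od, 0)
  fractions <- data.frame(type = "fraction", fraction = seq_len(n_fractions),
                          od_initial = od_initial,
                          od_final = od_initial + d_od,
                          stringsAsFactors = FALSE)
  ctrl <- data.frame(
    type = c("positive", "positive", "negative", "negative",
             "solvent", "solvent"),
    fraction = NA_integer_,
    od_initial = od_initial,
    od_final = od_initial + c(abs(stats::rnorm(2, 0.002, 0.001)),
                              control_delta_od + stats::rnorm(2, sd = noise_sd),
                              control_delta_od + stats::rnorm(2, sd = noise_sd)),
    stringsAsFactors = FALSE)
  list(plate = rbind(fractions, ctrl),
       truth = list(active_window = active_window, strength = strength))
}
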