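#' Saturation from per-cycle AC/DC pairs
#'
#' Forms the ratio of ratios per cycle, `R = (AC/DC)_red / (AC/DC)_ir`,
#' maps each to a saturation (theoretical inversion by default, or an
#' empirical linear calibration `S = a - b R` if supplied), and reports the
#' median over cycles as a percentage. Cycles with non-finite or
#' non-positive R are dropped; if none survive the data are insufficient.
#'
#' @param acdc A list with elements `red` and `ir`, each a data.frame from
#'   [extract_ac_dc()] with aligned rows (same detected cycles).
#' @param coefs An [optical_coefficients()] set.
#' @param calibration Optional empirical map: either a function of R
#'   returning a saturation fraction, or a list/vector with elements `a`
#'   and `b` for `S = a - b R`.
#' @return Saturation in percent, with attributes `n_cycles` and
#'   `r_median`.
#' @export
compute_spo2 <- function(acdc, coefs = default_coefficients(),
                         calibration = NULL) {
  if (is.null(acdc$red) || is.null(acdc$ir) ||
      nrow(acdc$red) == 0L || nrow(acdc$ir) == 0L) {
    stop_insufficient_data("no valid cycles to compute a saturation from")
  }
  if (nrow(acdc$red) != nrow(acdc$ir)) {
    stop_invalid_input("red and infrared cycle tables must be aligned")
  }
  r <- (acdc$red$ac / acdc$red$dc) / (acdc$ir$ac / acdc$ir$dc)
  r <- r[is.finite(r) & r > 0]
  if (length(r) == 0L) {
    stop_insufficient_data("no cycle produced a finite positive ratio of ratios")
  }
  s <- if (is.null(calibration)) {
    as.numeric(saturation_from_r(r, coefs))
  } else if (is.function(calibration)) {
    calibration(r)
  } else {
    calibration[["a"]] - calibration[["b"]] * r
  }
  out <- 100 * stats::median(s)
  attr(out, "n_cycles") <- length(r)
  attr(out, "r_median") <- stats::median(r)
  out
}

#' Saturation of the stimulation band
#'
#' Identical contract to [compute_spo2()], applied to the AC/DC pairs of
#' the cuff-stimulation component. What it measures is the effective
#' saturation of whatever blood the cuff actually modulates -- the venous
#' compartment plus any coupled arterial fraction.
#'
#' @inheritParams compute_spo2
#' @return Saturation in percent, with attributes as in [compute_spo2()].
#' @export
compute_mixed_spo2 <- function(acdc, coefs = default_coefficients(),
                               calibration = NULL) {
  compute_spo2(acdc, coefs, calibration)
}

#' Fit an empirical R-to-saturation calibration
#'
#' Least-squares fit of the linear map `S = a - b R` to paired
#' (R, reference saturation) observations, the software analogue of
#' calibrating a pulse oximeter against co-oximetry.
#'
#' @param r Observed ratio-of-ratios values.
#' @param reference Reference saturations (fractions) of the same length.
#' @return A list with `a`, `b` and the fitted function.
#' @export
fit_r_calibration <- function(r, reference) {
  if (length(r) != length(reference) || length(r) < 2L) {
    stop_invalid_input("need >= 2 aligned (R, reference) pairs")
  }
  fit <- stats::lm(reference ~ r)
  a <- unname(stats::coef(fit)[1])
  b <- -unname(stats::coef(fit)[2])
  list(a = a, b = b, map = function(x) a - b * x)
}

#' Venous saturation from the mixed and arterial saturations
#'
#' Inverts the mixture relation `Mixed = w * SpO2 + (1 - w) * SvO2`. With
#' the default equal weight `w = 0.5` this is `SvO2 = 2 Mixed - SpO2`.
#' Results outside `[0, 100]` are flagged via the `out_of_range`
#' attribute, never silently clipped.
#'
#' @param spo2 Arterial saturation in percent.
#' @param mixed Mixed (stimulation-band) saturation in percent.
#' @param arterial_weight Arterial fraction `w` of the stimulation-band
#'   mixture, in `[0, 1)` (default 0.5).
#' @return Venous saturation in percent with attribute `out_of_range`.
#' @export
svo2_from_mixed <- function(spo2, mixed, arterial_weight = 0.5) {
  if (any(!is.finite(spo2)) || any(!is.finite(mixed))) {
    stop_invalid_input("spo2 and mixed must be finite")
  }
  w <- arterial_weight
  if (!is.finite(w) || w < 0 || w >= 1) {
    stop_invalid_input("arterial_weight must lie in [0, 1)")
  }
  svo2 <- (mixed - w * spo2) / (1 - w)
  attr(svo2, "out_of_range") <- svo2 < 0 | svo2 > 100
  svo2
}

#' Oxygen consumption proxy
#'
#' The arteriovenous saturation difference `SaO2 - SvO2` in percentage
#' points, a proxy for tissue oxygen extraction. Negative values are
#' physiologically implausible and flagged.
#'
#' @param sao2 Arterial saturation in percent.
#' @param svo2 Venous saturation in percent.
#' @return Percentage-point difference with attribute `implausible`.
#' @export
oxygen_consumption <- function(sao2, svo2) {
  if (any(!is.finite(sao2)) || any(!is.finite(svo2))) {
    stop_invalid_input("sao2 and svo2 must be finite")
  }
  d <- sao2 - svo2
  attr(d, "implausible") <- d < 0
  d
}

#' Arterial mixture weight implied by a coupling fraction
#'
#' When the cuff moves the venous path by one unit and the arterial path by
#' `coupling` units, the stimulation band behaves as blood at saturation
#' `(coupling * SaO2 + SvO2) / (1 + coupling)`; the arterial weight is
#' therefore `coupling / (1 + coupling)`. Balanced coupling (`coupling = 1`)
#' gives the equal-weight mixture of the Mixed_SpO2 relation.
#'
#' @param coupling Arterial-to-venous stimulation amplitude ratio (>= 0).
#' @return The arterial weight in `[0, 1)`.
#' @export
mixture_arterial_weight <- function(coupling) {
  if (any(!is.finite(coupling)) || any(coupling < 0)) {
    stop_invalid_input("coupling must be finite and non-negative")
  }
  coupling / (1 + coupling)
}

#' Analysis configuration for the SvO2 pipeline
#'
#' @param window,hop Analysis window length and hop in seconds (defaults
#'   10 and 5).
#' @param coefs Extinction coefficients used for the inversion.
#' @param pulse_search,stim_search Disjoint spectral search bands for the
#'   two fundamentals.
#' @param arterial_weight Arterial fraction of the stimulation-band
#'   mixture, or `NULL` (default) to derive it from the generating config's
#'   `arterial_stim_coupling` when the trace carries one, falling back to
#'   the equal-weight 0.5.
#' @param calibration Optional empirical calibration (see
#'   [compute_spo2()]).
#' @param min_cycles Minimum detected cycles per window for a valid
#'   estimate (default 3).
#' @param prominence Spectral prominence threshold passed to
#'   [locate_component_peaks()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window = 10, hop = 5,
                            coefs = default_coefficients(),
                            pulse_search = band_spec(1.2, 0.7),
                            stim_search = band_spec(4.5, 2.45),
                            arterial_weight = NULL,
                            calibration = NULL,
                            min_cycles = 3L,
                            prominence = 8) {
  if (window <= 0 || hop <= 0) stop_config("window and hop must be positive")
  structure(list(window = window, hop = hop, coefs = coefs,
                 pulse_search = pulse_search, stim_search = stim_search,
                 arterial_weight = arterial_weight,
                 calibration = calibration,
                 min_cycles = as.integer(min_cycles),
                 prominence = prominence),
            class = "pipeline_config")
}

#' Run the three-step SvO2 extraction pipeline
#'
#' Per analysis window: (1) the stimulation component is set aside and the
#' ordinary SpO2 is computed from the pulse band; (2) the signal far from
#' the stimulation frequency is filtered out and the stimulation peaks give
#' the raw stimulation-band saturation; (3) the venous saturation is
#' obtained by unmixing that value with the arterial weight, and the
#' oxygen-consumption proxy is the arteriovenous difference. Failures
#' (separation infeasible, too few cycles) become per-window quality flags,
#' not aborts. The reported `mixed_spo2` column is the equal-weight mixed
#' saturation `(spo2 + svo2) / 2`, so `svo2 = 2 * mixed_spo2 - spo2` holds
#' exactly on every reported window; the raw stimulation-band reading is
#' kept in `stim_spo2` (the two coincide when the mixture is balanced).
#'
#' @param ppg A [dw_ppg()] object.
#' @param config A [pipeline_config()].
#' @return A data.frame of class `oximetry_result`: `window_time`, `spo2`,
#'   `stim_spo2`, `mixed_spo2`, `svo2`, `o2_consumption`, quality flags
#'   (`separation_ok`, `spo2_ok`, `svo2_ok`, `spo2_in_range`,
#'   `svo2_in_range`) and cycle counts. Attributes carry the located
#'   frequencies and the applied arterial weight.
#' @export
run_pipeline <- function(ppg, config = pipeline_config()) {
  spec <- compute_power_spectrum(ppg)
  peaks <- locate_component_peaks(spec, config$pulse_search,
                                  config$stim_search, config$prominence)
  w <- config$arterial_weight
  if (is.null(w)) {
    cpl <- ppg$meta$config$arterial_stim_coupling
    w <- if (!is.null(cpl)) mixture_arterial_weight(cpl) else 0.5
  }

  stim_ok <- peaks$stim_prominent
  comps <- NULL
  sep_ok <- FALSE
  if (stim_ok) {
    comps <- tryCatch(
      separate_components(ppg, peaks$pulse_freq, peaks$stim_freq),
      venoxim_separation_infeasible = function(e) NULL)
    sep_ok <- !is.null(comps)
  }
  if (is.null(comps)) {
    # pulse-only decomposition: SpO2 must survive a missing stimulation
    stim2 <- if (peaks$stim_freq != peaks$pulse_freq) peaks$stim_freq else 3 * peaks$pulse_freq
    comps <- separate_components_pulse_only(ppg, peaks$pulse_freq, stim2)
  }

  cycles <- function(comp_red, comp_ir, freq) {
    pr <- tryCatch(detect_stimulation_peaks(comp_ir, freq, comps$fs),
                   venoxim_insufficient_data = function(e) NULL)
    if (is.null(pr)) return(NULL)
    list(red = extract_ac_dc(comp_red, comps$dc_red, pr),
         ir = extract_ac_dc(comp_ir, comps$dc_ir, pr))
  }
  pulse_cyc <- cycles(comps$pulse_red, comps$pulse_ir, peaks$pulse_freq)
  stim_cyc <- if (sep_ok) cycles(comps$stim_red, comps$stim_ir, peaks$stim_freq) else NULL

  starts <- seq(ppg$time[1],
                ppg$time[length(ppg$time)] - config$window,
                by = config$hop)
  if (length(starts) == 0L) starts <- ppg$time[1]

  window_value <- function(cyc, t0) {
    if (is.null(cyc)) return(NULL)
    tm <- ppg$time[cyc$red$mid]
    keep <- tm >= t0 & tm < t0 + config$window
    if (sum(keep) < config$min_cycles) return(NULL)
    sub <- list(red = cyc$red[keep, , drop = FALSE],
                ir = cyc$ir[keep, , drop = FALSE])
    tryCatch(compute_spo2(sub, config$coefs, config$calibration),
             venoxim_error = function(e) NULL)
  }

  rows <- lapply(starts, function(t0) {
    sp <- window_value(pulse_cyc, t0)
    st <- window_value(stim_cyc, t0)
    spo2 <- if (is.null(sp)) NA_real_ else as.numeric(sp)
    stim_spo2 <- if (is.null(st)) NA_real_ else as.numeric(st)
    if (!is.na(spo2) && !is.na(stim_spo2)) {
      svo2 <- as.numeric(svo2_from_mixed(spo2, stim_spo2, w))
      mixed <- (spo2 + svo2) / 2
      svo2 <- 2 * mixed - spo2   # re-derive so the reported triple is consistent to the last bit
      cons <- spo2 - svo2
    } else {
      svo2 <- mixed <- cons <- NA_real_
    }
    data.frame(window_time = t0 + config$window / 2,
               spo2 = spo2, stim_spo2 = stim_spo2, mixed_spo2 = mixed,
               svo2 = svo2, o2_consumption = cons,
               separation_ok = sep_ok && stim_ok,
               spo2_ok = !is.na(spo2),
               svo2_ok = !is.na(svo2),
               spo2_in_range = !is.na(spo2) && spo2 >= 0 && spo2 <= 100,
               svo2_in_range = !is.na(svo2) && svo2 >= 0 && svo2 <= 100,
               n_pulse_cycles = if (is.null(sp)) 0L else attr(sp, "n_cycles"),
               n_stim_cycles = if (is.null(st)) 0L else attr(st, "n_cycles"))
  })
  out <- do.call(rbind, rows)
  attr(out, "pulse_freq") <- peaks$pulse_freq
  attr(out, "stim_freq") <- if (stim_ok) peaks$stim_freq else NA_real_
  attr(out, "arterial_weight") <- w
  class(out) <- c("oximetry_result", "data.frame")
  out
}

# Pulse band + DC only, used when the stimulation component is absent.
separate_components_pulse_only <- function(ppg, pulse_freq, stim_freq) {
  n <- length(ppg$time)
  fs <- 1 / mean(diff(ppg$time))
  h_pulse <- design_bandpass(pulse_freq, 0.4 * pulse_freq, pulse_freq / 2,
                             fs, n)
  dc <- function(x) {
    moving_mean_centered(moving_mean_centered(x, round(fs / pulse_freq)),
                         round(fs / stim_freq))
  }
  x_red <- ppg$i_red - mean(ppg$i_red)
  x_ir <- ppg$i_ir - mean(ppg$i_ir)
  structure(list(time = ppg$time,
                 pulse_red = apply_fir_centered(x_red, h_pulse),
                 pulse_ir = apply_fir_centered(x_ir, h_pulse),
                 stim_red = NULL, stim_ir = NULL,
                 dc_red = dc(ppg$i_red), dc_ir = dc(ppg$i_ir),
                 pulse_freq = pulse_freq, stim_freq = NA_real_, fs = fs),
            class = "component_signals")
}
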