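#' Simulation configuration for the three-compartment finger model
#'
#' Describes a finger illuminated in transmission whose optical path is the
#' sum of a static tissue absorbance, a cardiac-pulsatile arterial
#' compartment, and a venous compartment that an air cuff compresses
#' periodically at a frequency distinct from the pulse rate. Arterial and
#' venous saturations are independently programmable, and a fraction of the
#' cuff stimulation leaks into the arterial path
#' (`arterial_stim_coupling`), so the stimulation band is a mixture of the
#' two saturations.
#'
#' Path units are centimetres (to pair with [default_coefficients()]);
#' absorbances are dimensionless; rates are Hz.
#'
#' @param sampling_rate Sampling rate in Hz (default 100). Must exceed twice
#'   the larger of `pulse_rate` and `stim_rate`.
#' @param duration Trace duration in seconds (default 60).
#' @param pulse_rate Cardiac pulse rate in Hz (default 1.2, i.e. 72 bpm).
#' @param stim_rate Cuff inflation/deflation rate in Hz (default 4); must
#'   differ from the pulse rate.
#' @param sao2,svo2 Arterial and venous saturations as fractions in
#'   `[0, 1]`; scalars or per-sample vectors (defaults 0.98 and 0.75).
#' @param static_absorbance_red,static_absorbance_ir Baseline tissue
#'   absorbance per channel (defaults 0.5 and 0.4).
#' @param incident Incident intensity `I0` per channel (default 1).
#' @param arterial_path_mean,arterial_path_amp Mean and peak-to-trough
#'   excursion of the arterial path (cm; defaults 0.2 and 0.02).
#' @param venous_path_mean,venous_stim_amp Mean venous path and the
#'   peak-to-trough excursion the cuff imposes on it (cm; defaults 0.3 and
#'   0.02).
#' @param arterial_stim_coupling Fraction of the cuff excursion that also
#'   modulates the arterial path (default 0.1).
#' @param noise_sd Additive white Gaussian noise, as a fraction of each
#'   channel's mean intensity (default 0.002). A `seed` is required
#'   whenever this is positive.
#' @param seed Integer seed for reproducible noise (default `NULL`).
#' @param clip_negative If `TRUE` (default), intensities driven non-positive
#'   by noise are clipped to a small positive floor with a warning;
#'   otherwise this is an error.
#' @return A validated `ppg_sim_config` list.
#' @export
ppg_config <- function(sampling_rate = 100, duration = 60,
                       pulse_rate = 1.2, stim_rate = 4,
                       sao2 = 0.98, svo2 = 0.75,
                       static_absorbance_red = 0.5,
                       static_absorbance_ir = 0.4,
                       incident = 1,
                       arterial_path_mean = 0.2, arterial_path_amp = 0.02,
                       venous_path_mean = 0.3, venous_stim_amp = 0.02,
                       arterial_stim_coupling = 0.1,
                       noise_sd = 0.002, seed = NULL,
                       clip_negative = TRUE) {
  cfg <- list(sampling_rate = sampling_rate, duration = duration,
              pulse_rate = pulse_rate, stim_rate = stim_rate,
              sao2 = sao2, svo2 = svo2,
              static_absorbance_red = static_absorbance_red,
              static_absorbance_ir = static_absorbance_ir,
              incident = incident,
              arterial_path_mean = arterial_path_mean,
              arterial_path_amp = arterial_path_amp,
              venous_path_mean = venous_path_mean,
              venous_stim_amp = venous_stim_amp,
              arterial_stim_coupling = arterial_stim_coupling,
              noise_sd = noise_sd, seed = seed,
              clip_negative = clip_negative)
  validate_ppg_config(cfg)
  structure(cfg, class = "ppg_sim_config")
}

validate_ppg_config <- function(cfg) {
  if (cfg$sampling_rate <= 2 * max(cfg$pulse_rate, cfg$stim_rate)) {
    stop_config("sampling_rate must exceed twice the highest component frequency (Nyquist)")
  }
  if (cfg$stim_rate == cfg$pulse_rate) {
    stop_config("stim_rate must differ from pulse_rate")
  }
  if (cfg$duration <= 0) stop_config("duration must be positive")
  lens <- c(cfg$arterial_path_mean, cfg$arterial_path_amp,
            cfg$venous_path_mean, cfg$venous_stim_amp,
            cfg$arterial_stim_coupling)
  if (any(lens < 0)) stop_config("path lengths, amplitudes and coupling must be non-negative")
  total_art_amp <- cfg$arterial_path_amp +
    cfg$arterial_stim_coupling * cfg$venous_stim_amp
  if (total_art_amp >= 2 * cfg$arterial_path_mean && total_art_amp > 0) {
    stop_config("arterial excursion must stay below the mean arterial path")
  }
  if (cfg$venous_stim_amp >= 2 * cfg$venous_path_mean && cfg$venous_stim_amp > 0) {
    stop_config("venous excursion must stay below the mean venous path")
  }
  if (any(cfg$sao2 < 0 | cfg$sao2 > 1) || any(cfg$svo2 < 0 | cfg$svo2 > 1)) {
    stop_config("saturations must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0) stop_config("noise_sd must be non-negative")
  if (cfg$noise_sd > 0 && is.null(cfg$seed)) {
    stop_config("a seed is required for any stochastic simulation (noise_sd > 0)")
  }
  invisible(cfg)
}

#' Dual-wavelength PPG container
#'
#' @param time Strictly increasing, uniform time grid (seconds).
#' @param i_red,i_ir Strictly positive transmitted-intensity traces at
#'   660 nm and 940 nm, same length as `time`.
#' @param meta Optional metadata list (typically the generating config).
#' @return An object of class `dw_ppg`.
#' @export
dw_ppg <- function(time, i_red, i_ir, meta = list()) {
  if (length(time) != length(i_red) || length(time) != length(i_ir)) {
    stop_invalid_input("time, i_red and i_ir must have equal lengths")
  }
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop_invalid_input("time must be strictly increasing")
  }
  if (any(i_red <= 0) || any(i_ir <= 0)) {
    stop_invalid_input("intensities must be strictly positive")
  }
  structure(list(time = time, i_red = i_red, i_ir = i_ir, meta = meta),
            class = "dw_ppg")
}

#' @export
print.dw_ppg <- function(x, ...) {
  fs <- if (length(x$time) > 1) 1 / mean(diff(x$time)) else NA_real_
  cat(sprintf("Dual-wavelength PPG: %d samples, %.3g s at %.4g Hz\n",
              length(x$time), diff(range(x$time)), fs))
  invisible(x)
}

# Per-sample optical paths of the two pulsatile compartments.
compartment_paths <- function(cfg, t) {
  stim <- stim_waveform(t, cfg$stim_rate)
  list(
    arterial = cfg$arterial_path_mean +
      cfg$arterial_path_amp * pulse_waveform(t, cfg$pulse_rate) +
      cfg$arterial_stim_coupling * cfg$venous_stim_amp * stim,
    venous = cfg$venous_path_mean + cfg$venous_stim_amp * stim
  )
}

#' Simulate a dual-wavelength PPG trace
#'
#' Evaluates the three-compartment forward model per wavelength:
#' \deqn{I(\lambda, t) = I_0 \exp\{-[A_{static}(\lambda) +
#'   \mu(s_a,\lambda)\, l_a(t) + \mu(s_v,\lambda)\, l_v(t)]\} + noise}
#' where \eqn{\mu(s,\lambda) = s\,\epsilon_{HbO2} + (1-s)\,\epsilon_{Hb}},
#' the arterial path \eqn{l_a(t)} carries the cardiac beat plus the coupled
#' fraction of the cuff stimulation, and the venous path \eqn{l_v(t)}
#' follows the smoothed-rectangular cuff waveform. Identical seeds give
#' bit-identical traces.
#'
#' @param config A [ppg_config()] object.
#' @param coefs Extinction coefficients (default [default_coefficients()]).
#' @return A [dw_ppg()] object whose `meta` holds the generating config and
#'   coefficient set.
#' @export
simulate_ppg <- function(config, coefs = default_coefficients()) {
  validate_ppg_config(config)
  n <- round(config$sampling_rate * config$duration)
  if (n < 2) stop_config("duration too short for the sampling rate")
  t <- (seq_len(n) - 1L) / config$sampling_rate
  paths <- compartment_paths(config, t)

  channel <- function(wavelength, static_a) {
    mu_a <- effective_mu(config$sao2, coefs, wavelength)
    mu_v <- effective_mu(config$svo2, coefs, wavelength)
    a <- static_a + mu_a * paths$arterial + mu_v * paths$venous
    i <- config$incident * exp(-a)
    if (config$noise_sd > 0) {
      i <- i + stats::rnorm(n, sd = config$noise_sd * mean(i))
    }
    if (any(i <= 0)) {
      if (config$clip_negative) {
        warning("noise drove intensities non-positive; clipping to a positive floor")
        i <- pmax(i, .Machine$double.eps)
      } else {
        stop_invalid_input("noise drove intensities non-positive")
      }
    }
    i
  }

  gen <- function() {
    i_red <- channel("red", config$static_absorbance_red)
    i_ir  <- channel("ir", config$static_absorbance_ir)
    list(red = i_red, ir = i_ir)
  }
  ch <- if (config$noise_sd > 0) with_seed(config$seed, gen()) else gen()

  dw_ppg(t, ch$red, ch$ir,
         meta = list(config = config, coefs = coefs))
}

#' Simulate a stepped hypoxia protocol
#'
#' Steps the arterial saturation through `levels` (piecewise constant,
#' `dwell` seconds each) while the venous saturation tracks it at the
#' constant arteriovenous difference implied by the config
#' (`config$sao2 - config$svo2`), floored at zero. Returns the trace plus
#' the per-sample ground-truth trajectories for recovery testing.
#'
#' @param levels Arterial saturation levels (fractions in `[0, 1]`),
#'   ordered as they should be visited.
#' @param dwell Dwell time per level in seconds.
#' @param config A [ppg_config()] template; its `duration` is replaced by
#'   `length(levels) * dwell`.
#' @param coefs Extinction coefficients.
#' @return A list with `ppg` (a [dw_ppg()]) and `truth`
#'   (data.frame `time`, `sao2`, `svo2`, `level`).
#' @export
hypoxia_protocol <- function(levels, dwell, config = ppg_config(),
                             coefs = default_coefficients()) {
  if (length(levels) == 0L) stop_config("at least one saturation level is required")
  if (any(levels < 0 | levels > 1)) stop_config("levels must lie in [0, 1]")
  if (dwell <= 0) stop_config("dwell must be positive")
  av_diff <- config$sao2[1] - config$svo2[1]
  n_per <- round(config$sampling_rate * dwell)
  level_idx <- rep(seq_along(levels), each = n_per)
  sao2_t <- levels[level_idx]
  svo2_t <- pmax(0, sao2_t - av_diff)
  cfg <- config
  cfg$duration <- length(levels) * dwell
  cfg$sao2 <- sao2_t
  cfg$svo2 <- svo2_t
  class(cfg) <- class(config)
  ppg <- simulate_ppg(cfg, coefs)
  truth <- data.frame(time = ppg$time, sao2 = sao2_t, svo2 = svo2_t,
                      level = level_idx)
  list(ppg = ppg, truth = truth)
}

#' Build the co-oximetry sampling schedule
#'
#' Orders the blood-draw protocol: a set of target saturation levels,
#' a number of samples per level, repeated a number of times, visiting the
#' levels in order within each repeat. Six levels with two samples each,
#' repeated twice, gives the 24-point protocol.
#'
#' @param levels Either an integer count of levels or a numeric vector of
#'   level saturation values (fractions). A bare count lays the levels out
#'   evenly from 1.00 down to 0.70.
#' @param samples_per_level Samples collected at each level (>= 1).
#' @param repeats Number of passes through all levels (>= 1).
#' @return A `sampling_schedule` list with `levels`, `samples_per_level`,
#'   `repeats` and an ordered `points` data.frame
#'   (`rep`, `level`, `replicate`, `saturation`).
#' @export
build_sampling_schedule <- function(levels, samples_per_level, repeats) {
  if (length(levels) == 1L && levels == round(levels)) {
    n_levels <- as.integer(levels)
    if (n_levels < 1L) stop_config("level count must be >= 1")
    level_values <- if (n_levels == 1L) 1.0 else seq(1.0, 0.70, length.out = n_levels)
  } else {
    if (any(levels < 0 | levels > 1)) stop_config("level values must lie in [0, 1]")
    level_values <- as.numeric(levels)
    n_levels <- length(level_values)
  }
  if (samples_per_level < 1 || repeats < 1) {
    stop_config("samples_per_level and repeats must be >= 1")
  }
  samples_per_level <- as.integer(samples_per_level)
  repeats <- as.integer(repeats)
  points <- expand.grid(replicate = seq_len(samples_per_level),
                        level = seq_len(n_levels),
                        rep = seq_len(repeats))
  points <- points[order(points$rep, points$level, points$replicate), ,
                   drop = FALSE]
  points$saturation <- level_values[points$level]
  rownames(points) <- NULL
  structure(list(levels = level_values,
                 samples_per_level = samples_per_level,
                 repeats = repeats,
                 points = points[, c("rep", "level", "replicate", "saturation")]),
            class = "sampling_schedule")
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat(sprintf("Sampling schedule: %d levels x %d samples x %d repeats = %d points\n",
              length(x$levels), x$samples_per_level, x$repeats,
              nrow(x$points)))
  invisible(x)
}
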