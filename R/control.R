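#' Stimulation state of the cuff controller
#'
#' @param frequency Commanded cuff inflation/deflation frequency in Hz.
#' @param amplitude Cuff-pressure surrogate, in the same units as
#'   `pressure_threshold`.
#' @param enabled Whether the stimulation is active.
#' @param pressure_threshold NIBP-derived ceiling the amplitude may never
#'   exceed.
#' @param max_freq Highest allowed stimulation frequency in Hz.
#' @return A `stimulation_state` object.
#' @export
stimulation_state <- function(frequency = 4, amplitude = 20, enabled = TRUE,
                              pressure_threshold = 40, max_freq = 10) {
  if (frequency <= 0 || frequency > max_freq) {
    stop_config("frequency must lie in (0, max_freq]")
  }
  if (amplitude < 0 || amplitude > pressure_threshold) {
    stop_config("amplitude must lie in [0, pressure_threshold]")
  }
  structure(list(frequency = frequency, amplitude = amplitude,
                 enabled = enabled,
                 pressure_threshold = pressure_threshold,
                 max_freq = max_freq, saturated = FALSE),
            class = "stimulation_state")
}

#' Controller policy
#'
#' Rule parameters of the feedback loop. The paper-level loop is
#' qualitative; these numbers are the package's defaults.
#'
#' @param min_separation Required distance (Hz) between the stimulation
#'   frequency and the nearest pulse harmonic (default 0.5).
#' @param target_snr Stimulation-band SNR target in dB (default 15).
#' @param freq_step Frequency step in Hz when moving away from harmonics
#'   (default 0.2).
#' @param amp_step_frac Amplitude step as a fraction of the pressure
#'   threshold (default 0.1).
#' @param hysteresis_sep,hysteresis_snr Margins above the targets inside
#'   which the controller leaves the state untouched.
#' @param harmonics Pulse harmonics considered for avoidance (default 1:3).
#' @param min_freq Lower frequency bound used when wrapping (default 0.5).
#' @param stim_half_width Half-width (Hz) of the stimulation measurement
#'   band (default 0.3).
#' @param amp_gain Venous path excursion (cm) per pressure-surrogate unit
#'   in the simulated plant (default 5e-4): linear below threshold.
#' @return A `control_policy` list.
#' @export
control_policy <- function(min_separation = 0.5, target_snr = 15,
                           freq_step = 0.2, amp_step_frac = 0.1,
                           hysteresis_sep = 0.1, hysteresis_snr = 2,
                           harmonics = 1:3, min_freq = 0.5,
                           stim_half_width = 0.3, amp_gain = 5e-4) {
  structure(list(min_separation = min_separation, target_snr = target_snr,
                 freq_step = freq_step, amp_step_frac = amp_step_frac,
                 hysteresis_sep = hysteresis_sep,
                 hysteresis_snr = hysteresis_snr,
                 harmonics = harmonics, min_freq = min_freq,
                 stim_half_width = stim_half_width, amp_gain = amp_gain),
            class = "control_policy")
}

harmonic_separation <- function(freq, pulse_freq, harmonics) {
  if (!is.finite(pulse_freq)) return(Inf)
  min(abs(freq - harmonics * pulse_freq))
}

#' Feedback metrics from a decomposed PPG
#'
#' Measures what the loop feeds back on: the pulse frequency (spectral peak
#' in the pulse search band), band-power SNRs of both components over the
#' out-of-band noise floor (median power outside both bands), and the
#' distance between the commanded stimulation frequency and the nearest
#' pulse harmonic. A stimulation band with no prominent peak (or a
#' disabled stimulation) reports `stim_snr = -Inf`, which is a valid
#' signal to the controller, not an error.
#'
#' @param components A `component_signals` object or `NULL` (metrics are
#'   spectral; components are accepted for interface symmetry).
#' @param spectrum A [compute_power_spectrum()] result.
#' @param state The current [stimulation_state()].
#' @param policy A [control_policy()].
#' @param pulse_search Search band for the pulse peak.
#' @return A `feedback_metrics` list: `pulse_freq`, `stim_snr`,
#'   `pulse_snr` (dB), `separation` (Hz).
#' @export
compute_feedback_metrics <- function(components, spectrum, state,
                                     policy = control_policy(),
                                     pulse_search = band_spec(1.2, 0.7)) {
  total <- spectrum$power_red + spectrum$power_ir
  f <- spectrum$frequency
  in_band <- function(lo, hi) f >= lo & f <= hi & f > 0
  pulse_idx <- which(in_band(pulse_search$lower, pulse_search$upper))
  if (length(pulse_idx) == 0L) {
    stop_venoxim("pulse search band contains no bins", "venoxim_band_error")
  }
  pulse_peak_i <- pulse_idx[which.max(total[pulse_idx])]
  pulse_freq <- f[pulse_peak_i]
  stim_lo <- state$frequency - policy$stim_half_width
  stim_hi <- state$frequency + policy$stim_half_width
  stim_idx <- which(in_band(stim_lo, stim_hi))
  out_idx <- which(f > 0 &
                     !in_band(pulse_search$lower, pulse_search$upper) &
                     !in_band(stim_lo, stim_hi))
  floor_p <- if (length(out_idx)) stats::median(total[out_idx]) else .Machine$double.xmin
  floor_p <- max(floor_p, .Machine$double.xmin)
  snr <- function(idx) {
    if (length(idx) == 0L) return(-Inf)
    10 * log10(max(total[idx]) / floor_p)
  }
  # screen out artefacts that mimic a stimulation peak: spectral-leakage
  # skirts (argmax on the band edge), anything weaker than the floor, and
  # residues orders of magnitude below the pulse line (a real cuff
  # stimulation is commensurate with the pulse)
  stim_present <- FALSE
  if (state$enabled && length(stim_idx) >= 3L) {
    at <- which.max(total[stim_idx])
    stim_present <- at > 1L && at < length(stim_idx) &&
      total[stim_idx][at] >= 4 * floor_p &&
      total[stim_idx][at] >= 1e-4 * total[pulse_peak_i]
  }
  stim_snr <- if (stim_present) snr(stim_idx) else -Inf
  structure(list(pulse_freq = pulse_freq,
                 stim_snr = stim_snr,
                 pulse_snr = snr(pulse_idx),
                 separation = harmonic_separation(state$frequency, pulse_freq,
                                                  policy$harmonics)),
            class = "feedback_metrics")
}

#' One feedback-rule update of the stimulation state
#'
#' Deterministic rules: if the harmonic separation is below
#' `min_separation`, the frequency moves upward in `freq_step` increments
#' (wrapping to `min_freq` below `max_freq`) until it clears every
#' considered pulse harmonic by at least `min_separation`. If the
#' stimulation SNR is below `target_snr`, the amplitude increases by one
#' step of `amp_step_frac * pressure_threshold`, capped at the threshold;
#' reaching the cap with SNR still unmet sets the `saturated` warning
#' flag. When both targets are met (hysteresis means no rule ever reverses
#' a previous move) the state is returned unchanged.
#'
#' @param state Current [stimulation_state()].
#' @param metrics [compute_feedback_metrics()] output.
#' @param policy A [control_policy()].
#' @return The updated `stimulation_state`.
#' @export
adjust_stimulation <- function(state, metrics, policy = control_policy()) {
  new <- state
  if (is.finite(metrics$separation) &&
      metrics$separation < policy$min_separation) {
    f <- state$frequency
    pf <- metrics$pulse_freq
    for (i in seq_len(1000L)) {
      f <- f + policy$freq_step
      if (f > state$max_freq) f <- policy$min_freq
      if (harmonic_separation(f, pf, policy$harmonics) >=
          policy$min_separation) break
    }
    new$frequency <- f
  }
  if (metrics$stim_snr < policy$target_snr) {
    step <- policy$amp_step_frac * state$pressure_threshold
    proposed <- min(state$amplitude + step, state$pressure_threshold)
    new$saturated <- proposed >= state$pressure_threshold &&
      metrics$stim_snr < policy$target_snr
    new$amplitude <- proposed
  } else {
    new$saturated <- FALSE
  }
  new
}

#' Closed-loop simulation of the stimulation feedback system
#'
#' Alternates simulate -> decompose (spectrum) -> feedback metrics ->
#' rule update, driving the simulated finger with the controller's current
#' frequency and cuff amplitude (linear pressure-to-path plant,
#' `venous_stim_amp = amp_gain * amplitude`). If the commanded frequency
#' collides exactly with the pulse rate the simulator cannot separate the
#' components, so the loop runs that step as a stimulation-off probe and
#' reports `stim_snr = -Inf` and zero separation, which the policy then
#' corrects. Seeded and fully reproducible.
#'
#' @param subject A [ppg_config()] describing the simulated subject; its
#'   `stim_rate` and `venous_stim_amp` are overridden by the controller
#'   each step.
#' @param policy A [control_policy()].
#' @param n_steps Number of loop iterations (>= 1).
#' @param seed Integer seed; step `k` uses `seed + k`.
#' @param init Initial [stimulation_state()].
#' @param step_duration Trace length simulated per step in seconds
#'   (default 20).
#' @return A data.frame trace with one row per step: commanded state,
#'   measured metrics, and satisfaction flags.
#' @export
closed_loop_run <- function(subject, policy = control_policy(),
                            n_steps = 5, seed = 1,
                            init = stimulation_state(),
                            step_duration = 20) {
  if (n_steps < 1) stop_config("n_steps must be >= 1")
  state <- init
  rows <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    cfg <- subject
    cfg$duration <- step_duration
    cfg$seed <- if (!is.null(seed)) seed + k else subject$seed
    cfg$venous_stim_amp <- policy$amp_gain * state$amplitude
    cfg$stim_rate <- state$frequency
    collided <- identical(cfg$stim_rate, cfg$pulse_rate)
    if (collided || !state$enabled || cfg$venous_stim_amp == 0) {
      # probe step: no stimulation content, just measure the pulse
      cfg$venous_stim_amp <- 0
      cfg$stim_rate <- if (collided) 2 * cfg$pulse_rate + 0.1 else cfg$stim_rate
    }
    class(cfg) <- class(subject)
    ppg <- simulate_ppg(cfg)
    spec <- compute_power_spectrum(ppg)
    metrics <- compute_feedback_metrics(NULL, spec, state, policy)
    sep_ok <- is.finite(metrics$separation) &&
      metrics$separation >= policy$min_separation
    snr_ok <- metrics$stim_snr >= policy$target_snr
    rows[[k]] <- data.frame(step = k,
                            frequency = state$frequency,
                            amplitude = state$amplitude,
                            pulse_freq = metrics$pulse_freq,
                            stim_snr = metrics$stim_snr,
                            pulse_snr = metrics$pulse_snr,
                            separation = metrics$separation,
                            sep_ok = sep_ok, snr_ok = snr_ok,
                            saturated = state$saturated)
    state <- adjust_stimulation(state, metrics, policy)
  }
  do.call(rbind, rows)
}
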