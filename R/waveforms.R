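# Periodic path-length waveform templates, unit peak-to-trough amplitude,
# zero mean in closed form so generated traces are duration-independent.

#' Arterial pulse waveform template
#'
#' Asymmetric beat shape: a raised-cosine systolic upstroke occupying
#' `systolic_fraction` of the cycle followed by a slower quarter-cosine
#' diastolic decay. Unit peak-to-trough excursion, zero mean (closed form).
#'
#' @param t Time vector (seconds).
#' @param rate Beat rate in Hz.
#' @param systolic_fraction Fraction of the cycle spent on the upstroke
#'   (default 0.3).
#' @return Zero-mean waveform values, peak-to-trough 1.
#' @export
pulse_waveform <- function(t, rate, systolic_fraction = 0.3) {
  sf <- systolic_fraction
  if (sf <= 0 || sf >= 1) stop_config("systolic_fraction must lie in (0, 1)")
  phase <- (t * rate) %% 1
  w <- ifelse(phase < sf,
              0.5 * (1 - cos(pi * phase / sf)),
              cos(0.5 * pi * (phase - sf) / (1 - sf)))
  # analytic cycle mean: sf/2 from the upstroke, (2/pi)(1-sf) from the decay
  w - (0.5 * sf + (2 / pi) * (1 - sf))
}

#' Cuff stimulation waveform template
#'
#' Smoothed rectangular inflation/deflation profile: raised-cosine rise over
#' `rise_fraction` of the cycle, plateau, raised-cosine fall, then off. This
#' emulates periodic cuff inflation with finite pneumatic rise time; its
#' harmonic content is deliberate and handled downstream by band filtering.
#'
#' @param t Time vector (seconds).
#' @param rate Inflation/deflation rate in Hz.
#' @param duty Fraction of the cycle the cuff is (at least partly) inflated
#'   (default 0.5).
#' @param rise_fraction Rise/fall time as a fraction of the cycle
#'   (default 0.15).
#' @return Zero-mean waveform values, peak-to-trough 1.
#' @export
stim_waveform <- function(t, rate, duty = 0.5, rise_fraction = 0.15) {
  r <- rise_fraction
  if (duty <= 0 || duty >= 1) stop_config("duty must lie in (0, 1)")
  if (r <= 0 || r > min(duty, 1 - duty)) {
    stop_config("rise_fraction must be positive and fit inside the duty cycle")
  }
  phase <- (t * rate) %% 1
  w <- numeric(length(phase))
  up <- phase < r
  w[up] <- 0.5 * (1 - cos(pi * phase[up] / r))
  w[phase >= r & phase < duty] <- 1
  down <- phase >= duty & phase < duty + r
  w[down] <- 0.5 * (1 + cos(pi * (phase[down] - duty) / r))
  # cycle mean is exactly `duty` (rise and fall halves complement each other)
  w - duty
}
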