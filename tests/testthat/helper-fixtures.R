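# Shared fixtures: short, noiseless configs and synthetic two-tone traces.

quick_config <- function(duration = 20, noise_sd = 0, ...) {
  ppg_config(duration = duration, noise_sd = noise_sd, ...)
}

# Two sinusoids on a positive baseline, same trace in both channels.
two_tone_ppg <- function(f1 = 1.2, f2 = 4, a1 = 0.01, a2 = 0.02,
                         fs = 100, duration = 30, baseline = 1) {
  t <- (seq_len(fs * duration) - 1) / fs
  x <- baseline + a1 * sin(2 * pi * f1 * t) + a2 * sin(2 * pi * f2 * t)
  dw_ppg(t, x, x)
}

# Raw periodogram argmax, independent of compute_power_spectrum.
fft_peak_freq <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- 2:floor(n / 2)
  (half[which.max(p[half])] - 1) * fs / n
}

rms <- function(x) sqrt(mean(x^2, na.rm = TRUE))
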