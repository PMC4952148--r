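# Linear-phase FIR band separation. Kernels are windowed-sinc (Hamming)
# designs from signal::fir1, applied as a centered symmetric convolution so
# group delay is exactly compensated; the half-kernel at each edge is NA
# and excluded from downstream cycle statistics.

design_bandpass <- function(center, half_width, transition, fs, n_samples) {
  lo <- center - half_width
  hi <- center + half_width
  if (lo <= 0 || hi >= fs / 2) {
    stop_venoxim("band-pass edges must lie strictly inside (0, Nyquist)",
                 "venoxim_band_error")
  }
  order <- ceiling(3.3 * fs / transition)       # Hamming transition heuristic
  max_order <- 2L * (n_samples %/% 3L)
  order <- min(order, max_order)
  if (order %% 2 == 1) order <- order + 1       # type-I (odd tap count)
  if (order < 6) stop_insufficient_data("signal too short to design the band filter")
  signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
}

# Centered convolution: zero phase for symmetric kernels, NA edges.
apply_fir_centered <- function(x, h) {
  as.numeric(stats::filter(x, h, method = "convolution", sides = 2))
}

moving_mean_centered <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
}

#' Separate a PPG into pulse, stimulation and DC components
#'
#' Band-pass filters each intensity channel around the pulse frequency and
#' around the stimulation frequency with linear-phase FIR kernels
#' (windowed-sinc, Hamming), applied as centered convolutions so the
#' components stay time-aligned with the input. The DC baseline is a
#' cascade of two centered moving means with widths of one pulse period and
#' one stimulation period, which nulls both fundamentals and all their
#' harmonics. Stimulation harmonics outside the stimulation band are
#' deliberately discarded; the waveform-shape factor they carry cancels in
#' the red/infrared ratio.
#'
#' @param ppg A [dw_ppg()] object.
#' @param pulse_freq,stim_freq Component fundamentals in Hz.
#' @param pulse_half_width,stim_half_width Pass-band half-widths in Hz
#'   (default 0.4 x the respective fundamental).
#' @param transition FIR transition width in Hz (default
#'   `min(pulse_freq, stim_freq) / 2`); sets the kernel order.
#' @return A `component_signals` list: `time`, `pulse_red`, `pulse_ir`,
#'   `stim_red`, `stim_ir`, `dc_red`, `dc_ir` (all on the input time base,
#'   NA inside the filter edges) plus `pulse_freq`, `stim_freq`, `fs`.
#' @export
separate_components <- function(ppg, pulse_freq, stim_freq,
                                pulse_half_width = 0.4 * pulse_freq,
                                stim_half_width = 0.4 * stim_freq,
                                transition = min(pulse_freq, stim_freq) / 2) {
  pulse_band <- band_spec(pulse_freq, pulse_half_width)
  stim_band <- band_spec(stim_freq, stim_half_width)
  if (bands_overlap(pulse_band, stim_band)) {
    stop_venoxim("pulse and stimulation bands overlap: move the stimulation frequency",
                 "venoxim_separation_infeasible")
  }
  n <- length(ppg$time)
  fs <- 1 / mean(diff(ppg$time))
  h_pulse <- design_bandpass(pulse_freq, pulse_half_width, transition, fs, n)
  h_stim <- design_bandpass(stim_freq, stim_half_width, transition, fs, n)
  dc <- function(x) {
    moving_mean_centered(moving_mean_centered(x, round(fs / pulse_freq)),
                         round(fs / stim_freq))
  }
  # band-pass the mean-removed signal: the kernel's residual DC gain would
  # otherwise couple the large intensity baseline into the small components
  x_red <- ppg$i_red - mean(ppg$i_red)
  x_ir <- ppg$i_ir - mean(ppg$i_ir)
  structure(list(time = ppg$time,
                 pulse_red = apply_fir_centered(x_red, h_pulse),
                 pulse_ir = apply_fir_centered(x_ir, h_pulse),
                 stim_red = apply_fir_centered(x_red, h_stim),
                 stim_ir = apply_fir_centered(x_ir, h_stim),
                 dc_red = dc(ppg$i_red),
                 dc_ir = dc(ppg$i_ir),
                 pulse_freq = pulse_freq, stim_freq = stim_freq, fs = fs),
            class = "component_signals")
}

# Strict local extrema with a greedy minimum-distance constraint:
# candidates are ranked by |value| relative to the search sign, kept
# largest-first, earliest sample wins ties.
local_extrema <- function(x, min_dist, maxima = TRUE) {
  v <- if (maxima) x else -x
  n <- length(v)
  if (n < 3) return(integer(0))
  ok <- !is.na(v)
  i <- 2:(n - 1)
  # >= on the left, > on the right: the earliest sample of a plateau wins
  cand <- i[ok[i] & ok[i - 1] & ok[i + 1] &
              v[i] >= v[i - 1] & v[i] > v[i + 1]]
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[order(-v[cand], cand)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Detect per-cycle peak/trough pairs in a periodic component
#'
#' Finds one peak-trough pair per stimulation (or pulse) cycle, enforcing a
#' minimum peak spacing of `0.6 / freq` seconds so ripple cannot split a
#' cycle. Each peak is paired with the deepest trough before the next peak.
#' Although named for the stimulation component, the routine applies
#' unchanged to the pulse component.
#'
#' @param component Band-limited trace (NA edge samples allowed).
#' @param stim_freq Component fundamental in Hz.
#' @param fs Sampling rate in Hz.
#' @return A data.frame with columns `peak` and `trough` (sample indices,
#'   ordered in time).
#' @export
detect_stimulation_peaks <- function(component, stim_freq, fs) {
  if (stim_freq <= 0 || fs <= 0) stop_invalid_input("stim_freq and fs must be positive")
  min_dist <- max(2L, round(0.6 * fs / stim_freq))
  peaks <- local_extrema(component, min_dist, maxima = TRUE)
  troughs <- local_extrema(component, min_dist, maxima = FALSE)
  if (length(peaks) < 2L || length(troughs) < 1L) {
    stop_insufficient_data("fewer than two component cycles in the window")
  }
  pair_trough <- function(i) {
    upper <- if (i < length(peaks)) peaks[i + 1L] else length(component) + 1L
    cand <- troughs[troughs > peaks[i] & troughs < upper]
    if (length(cand) == 0L) return(NA_integer_)
    cand[which.min(component[cand])]
  }
  tr <- vapply(seq_along(peaks), pair_trough, integer(1))
  keep <- !is.na(tr)
  if (sum(keep) < 1L) {
    stop_insufficient_data("no complete peak-trough cycles found")
  }
  data.frame(peak = peaks[keep], trough = tr[keep])
}

#' Per-cycle AC and DC values
#'
#' AC is the peak-to-trough intensity difference of the band-limited
#' component within each detected cycle; DC is the slowly-varying baseline
#' evaluated at the cycle midpoint. The DC must be strictly positive.
#'
#' @param component Band-limited trace.
#' @param dc Baseline trace on the same time base.
#' @param peaks Peak/trough index pairs from [detect_stimulation_peaks()].
#' @return A data.frame: `peak`, `trough`, `mid` (sample indices), `ac`,
#'   `dc`.
#' @export
extract_ac_dc <- function(component, dc, peaks) {
  if (nrow(peaks) == 0L) stop_insufficient_data("no cycles supplied")
  mid <- (peaks$peak + peaks$trough) %/% 2L
  ac <- component[peaks$peak] - component[peaks$trough]
  dcv <- dc[mid]
  if (any(is.na(dcv)) || any(dcv <= 0)) {
    stop_venoxim("non-positive or undefined DC baseline at a cycle midpoint",
                 "venoxim_invalid_signal")
  }
  data.frame(peak = peaks$peak, trough = peaks$trough, mid = mid,
             ac = ac, dc = dcv)
}
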