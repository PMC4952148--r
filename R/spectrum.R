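#' Frequency band specification
#'
#' A band centred on `center` Hz with half-width `half_width` Hz, i.e. the
#' interval `[center - half_width, center + half_width]`.
#'
#' @param center Band centre in Hz (> 0).
#' @param half_width Half-width in Hz, in `(0, center)` so the band stays
#'   strictly positive.
#' @return A `band_spec` object.
#' @export
band_spec <- function(center, half_width) {
  if (!is.finite(center) || center <= 0) stop_config("band center must be positive")
  if (!is.finite(half_width) || half_width <= 0 || half_width >= center) {
    stop_config("half_width must satisfy 0 < half_width < center")
  }
  structure(list(center = center, half_width = half_width,
                 lower = center - half_width, upper = center + half_width),
            class = "band_spec")
}

bands_overlap <- function(a, b) a$lower <= b$upper && b$lower <= a$upper

#' Power spectrum of a dual-wavelength PPG
#'
#' Mean-and-trend-removed, Hann-tapered one-sided periodogram of each
#' channel. The scaling is a spectral density (power per Hz) normalised so
#' that `sum(power) * df` equals the mean square of the detrended, tapered
#' signal divided by the taper's mean square power -- i.e. Parseval's
#' identity holds exactly in this convention.
#'
#' @param ppg A [dw_ppg()] object with >= 2 samples on a uniform time base.
#' @return A `ppg_spectrum` list: `frequency` (0 to Nyquist), `power_red`,
#'   `power_ir`, `df` (bin width), `fs`.
#' @export
compute_power_spectrum <- function(ppg) {
  n <- length(ppg$time)
  if (n < 2) stop_insufficient_data("need at least 2 samples for a spectrum")
  dt <- diff(ppg$time)
  if (max(abs(dt - mean(dt))) > 1e-9 * mean(dt)) {
    stop_venoxim("non-uniform time base: resample before spectral analysis",
                 "venoxim_resample_required")
  }
  fs <- 1 / mean(dt)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / n))  # Hann taper
  wss <- sum(w^2)
  one_sided <- function(x) {
    x <- stats::residuals(stats::lm.fit(cbind(1, seq_len(n)), x))  # detrend
    X <- stats::fft(x * w)
    p2 <- Mod(X)^2 / (fs * wss)
    half <- seq_len(floor(n / 2) + 1L)
    p <- p2[half]
    inner <- 2:(length(half) - if (n %% 2 == 0) 1L else 0L)
    p[inner] <- 2 * p[inner]
    p
  }
  half <- seq_len(floor(n / 2) + 1L)
  structure(list(frequency = (half - 1L) * fs / n,
                 power_red = one_sided(ppg$i_red),
                 power_ir = one_sided(ppg$i_ir),
                 df = fs / n, fs = fs),
            class = "ppg_spectrum")
}

#' Locate the pulse and stimulation spectral peaks
#'
#' Finds the argmax of the (summed two-channel) power inside each search
#' band. Ties and plateaus resolve to the lowest frequency. A peak is
#' flagged "prominent" when it exceeds `prominence` times the median
#' in-band power; a non-prominent stimulation peak signals that the
#' stimulation component is absent or buried.
#'
#' @param spectrum A [compute_power_spectrum()] result.
#' @param pulse_search,stim_search Disjoint [band_spec()] search bands.
#' @param prominence Peak-to-in-band-median power ratio required to call a
#'   peak prominent (default 8).
#' @param floor_mult Additionally, a prominent peak must exceed this
#'   multiple of the out-of-band noise floor, the median power above both
#'   search bands (default 50).
#' @return A list: `pulse_freq`, `stim_freq`, `pulse_prominent`,
#'   `stim_prominent`, `separated` (both peaks prominent).
#' @details A stimulation "peak" can be mimicked by three artefacts, each
#'   screened out before the peak is called prominent: a spectral-leakage
#'   skirt from the pulse line (its argmax sits on the band edge, so edge
#'   maxima are rejected), broadband noise (rejected by the out-of-band
#'   floor test), and pulse harmonics falling inside the stimulation search
#'   band (maxima within three bins of a multiple of the located pulse
#'   frequency are rejected).
#' @export
locate_component_peaks <- function(spectrum, pulse_search, stim_search,
                                   prominence = 8, floor_mult = 50) {
  if (bands_overlap(pulse_search, stim_search)) {
    stop_venoxim("pulse and stimulation search bands must be disjoint",
                 "venoxim_band_error")
  }
  total <- spectrum$power_red + spectrum$power_ir
  f <- spectrum$frequency
  out_idx <- which(f > max(pulse_search$upper, stim_search$upper))
  noise_floor <- if (length(out_idx)) stats::median(total[out_idx]) else 0
  pick <- function(band, harmonics_of = NULL) {
    idx <- which(f >= band$lower & f <= band$upper & f > 0)
    if (length(idx) == 0L) {
      stop_venoxim("search band contains no spectral bins", "venoxim_band_error")
    }
    p <- total[idx]
    at <- which.max(p)                  # which.max: first (lowest-f) wins ties
    peak <- idx[at]
    med <- stats::median(p)
    prom <- max(p) > 0 &&
      (med <= 0 || max(p) >= prominence * med) &&
      max(p) >= floor_mult * noise_floor &&
      at > 1L && at < length(idx)       # leakage skirts peak at a band edge
    if (prom && !is.null(harmonics_of)) {
      k <- round(f[peak] / harmonics_of)
      if (k >= 1 && abs(f[peak] - k * harmonics_of) <= 3 * spectrum$df) {
        prom <- FALSE                   # sitting on a pulse harmonic
      }
    }
    list(freq = f[peak], prominent = prom, peak_power = max(p), floor = med)
  }
  pu <- pick(pulse_search)
  st <- pick(stim_search, harmonics_of = pu$freq)
  list(pulse_freq = pu$freq, stim_freq = st$freq,
       pulse_prominent = pu$prominent, stim_prominent = st$prominent,
       separated = pu$prominent && st$prominent)
}
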