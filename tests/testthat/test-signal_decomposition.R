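test_that("power spectrum peaks at a pure tone and conserves energy", {
  fs <- 100
  t <- (0:2999) / fs
  x <- 1 + 0.05 * sin(2 * pi * 1.7 * t)
  ppg <- dw_ppg(t, x, x)
  spec <- compute_power_spectrum(ppg)
  expect_equal(spec$frequency[which.max(spec$power_red)], 1.7,
               tolerance = spec$df + 1e-9)
  # Parseval in the package's convention: sum(psd)*df = sum((xd*w)^2)/sum(w^2)
  n <- length(t)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  xd <- residuals(lm(x ~ seq_len(n)))
  expect_equal(sum(spec$power_red) * spec$df,
               sum((xd * w)^2) / sum(w^2), tolerance = 1e-8)
})

test_that("a constant trace has no power after detrending", {
  t <- (0:499) / 100
  ppg <- dw_ppg(t, rep(2, 500), rep(3, 500))
  spec <- compute_power_spectrum(ppg)
  expect_lt(max(spec$power_red), 1e-20)
})

test_that("non-uniform time bases are rejected", {
  t <- c(0, 0.01, 0.021, 0.03, 0.04, 0.05)
  expect_error(compute_power_spectrum(dw_ppg(t, rep(1, 6), rep(1, 6))),
               class = "venoxim_resample_required")
})

test_that("component peaks are located within one bin, with prominence flags", {
  ppg <- two_tone_ppg()
  spec <- compute_power_spectrum(ppg)
  pk <- locate_component_peaks(spec, band_spec(1.2, 0.7), band_spec(4.5, 2.45))
  expect_equal(pk$pulse_freq, 1.2, tolerance = spec$df + 1e-9)
  expect_equal(pk$stim_freq, 4.0, tolerance = spec$df + 1e-9)
  expect_true(pk$separated)
  # stimulation absent: the stimulation peak must not be called prominent
  ppg0 <- two_tone_ppg(a2 = 0)
  pk0 <- locate_component_peaks(compute_power_spectrum(ppg0),
                                band_spec(1.2, 0.7), band_spec(4.5, 2.45))
  expect_false(pk0$stim_prominent)
  expect_true(pk0$pulse_prominent)
  expect_error(locate_component_peaks(spec, band_spec(1.2, 0.7),
                                      band_spec(1.5, 0.5)),
               class = "venoxim_band_error")
})

test_that("flat in-band power ties break to the lowest frequency", {
  fake <- structure(list(frequency = seq(0, 10, by = 0.1),
                         power_red = rep(1, 101), power_ir = rep(1, 101),
                         df = 0.1, fs = 20), class = "ppg_spectrum")
  pk <- locate_component_peaks(fake, band_spec(1.2, 0.5), band_spec(4, 1),
                               prominence = 0)
  expect_equal(pk$pulse_freq, 0.7)
  expect_equal(pk$stim_freq, 3.0)
})

test_that("two well-separated tones are recovered with small error and leakage", {
  f1 <- 1.2; f2 <- 4; a1 <- 0.01; a2 <- 0.02; fs <- 100
  ppg <- two_tone_ppg(f1, f2, a1, a2, fs = fs)
  comps <- separate_components(ppg, f1, f2)
  keep <- !is.na(comps$pulse_red) & !is.na(comps$stim_red)
  true1 <- a1 * sin(2 * pi * f1 * ppg$time)
  true2 <- a2 * sin(2 * pi * f2 * ppg$time)
  expect_lt(rms(comps$pulse_red[keep] - true1[keep]) / rms(true1[keep]), 0.01)
  expect_lt(rms(comps$stim_red[keep] - true2[keep]) / rms(true2[keep]), 0.01)
  # cross-band leakage: filter a single tone with the other band's filter
  only1 <- two_tone_ppg(f1, f2, a1, 0, fs = fs)
  c1 <- separate_components(only1, f1, f2)
  expect_lt(rms(c1$stim_red) / rms(true1[keep]), 0.01)
  only2 <- two_tone_ppg(f1, f2, 0, a2, fs = fs)
  c2 <- separate_components(only2, f1, f2)
  expect_lt(rms(c2$pulse_red) / rms(true2[keep]), 0.01)
  # DC baseline is recovered
  expect_equal(median(comps$dc_red, na.rm = TRUE), 1, tolerance = 1e-3)
})

test_that("separation is linear and deterministic, and rejects overlapping bands", {
  ppg <- two_tone_ppg()
  comps <- separate_components(ppg, 1.2, 4)
  scaled <- dw_ppg(ppg$time, 3 * ppg$i_red, 3 * ppg$i_ir)
  comps3 <- separate_components(scaled, 1.2, 4)
  expect_equal(comps3$pulse_red, 3 * comps$pulse_red, tolerance = 1e-12)
  expect_equal(comps3$stim_ir, 3 * comps$stim_ir, tolerance = 1e-12)
  # bit-identical across repeated runs on the same seeded noisy input
  cfg <- ppg_config(duration = 20, seed = 5)
  p1 <- simulate_ppg(cfg); p2 <- simulate_ppg(cfg)
  expect_identical(separate_components(p1, 1.2, 4)$stim_red,
                   separate_components(p2, 1.2, 4)$stim_red)
  expect_error(separate_components(ppg, 2, 3),
               class = "venoxim_separation_infeasible")
})

test_that("an absent stimulation leaves only noise in the stimulation band", {
  cfg <- ppg_config(duration = 20, venous_stim_amp = 0,
                    arterial_stim_coupling = 0, noise_sd = 0.001, seed = 2)
  ppg <- simulate_ppg(cfg)
  comps <- separate_components(ppg, 1.2, 4)
  noise_floor <- cfg$noise_sd * mean(ppg$i_red)
  expect_lt(rms(comps$stim_red), noise_floor)
})

test_that("stimulation peak detection yields one pair per cycle", {
  fs <- 100; f <- 2.5; n_cycles <- 10
  t <- (seq_len(fs * n_cycles / f) - 1) / fs
  x <- sin(2 * pi * f * t)
  pairs <- detect_stimulation_peaks(x, f, fs)
  expect_equal(nrow(pairs), n_cycles)
  expect_true(all(diff(pairs$peak) > 0))
  expect_true(all(pairs$trough > pairs$peak))
  expect_error(detect_stimulation_peaks(rep(1, 500), f, fs),
               class = "venoxim_insufficient_data")
})

test_that("modulated-amplitude peaks track the exhaustive extremum scan", {
  fs <- 100; f <- 2
  t <- (0:1999) / fs
  x <- (1 + 0.5 * sin(2 * pi * 0.1 * t)) * sin(2 * pi * f * t)
  pairs <- detect_stimulation_peaks(x, f, fs)
  # oracle: every strict local maximum over a half-period neighbourhood
  half <- round(fs / (2 * f))
  oracle <- which(vapply(seq_along(x), function(i) {
    lo <- max(1, i - half); hi <- min(length(x), i + half)
    x[i] == max(x[lo:hi]) && x[i] > min(x[lo:hi])
  }, logical(1)))
  expect_true(all(vapply(pairs$peak, function(p) min(abs(oracle - p)) <= 1,
                         logical(1))))
})

test_that("AC/DC extraction is analytic on a sinusoid and null on silence", {
  fs <- 100; f <- 2.5; a <- 0.03; b <- 1.7
  t <- (0:999) / fs
  comp <- a * sin(2 * pi * f * t)
  dc <- rep(b, length(t))
  pairs <- detect_stimulation_peaks(comp, f, fs)
  acdc <- extract_ac_dc(comp, dc, pairs)
  expect_equal(unique(round(acdc$ac, 10)), 2 * a)
  expect_equal(unique(acdc$dc), b)
  # zero-amplitude component: AC is zero on every supplied cycle
  zero <- extract_ac_dc(rep(0, length(t)), dc, pairs)
  expect_true(all(zero$ac == 0))
  expect_error(extract_ac_dc(comp, rep(-1, length(t)), pairs),
               class = "venoxim_invalid_signal")
})

test_that("filtered AC/DC matches the forward model's relative modulation", {
  cfg <- quick_config(duration = 40)
  ppg <- simulate_ppg(cfg)
  comps <- separate_components(ppg, 1.2, 4)
  pr <- detect_stimulation_peaks(comps$stim_ir, 4, 100)
  red <- extract_ac_dc(comps$stim_red, comps$dc_red, pr)
  ir <- extract_ac_dc(comps$stim_ir, comps$dc_ir, pr)
  r_measured <- median((red$ac / red$dc) / (ir$ac / ir$dc))
  # forward model: the stimulation band mixes venous and coupled arterial paths
  co <- default_coefficients()
  mu <- function(s, wl) venoxim:::effective_mu(s, co, wl)
  c_ <- cfg$arterial_stim_coupling
  r_true <- (c_ * mu(cfg$sao2, "red") + mu(cfg$svo2, "red")) /
            (c_ * mu(cfg$sao2, "ir") + mu(cfg$svo2, "ir"))
  expect_equal(r_measured, r_true, tolerance = 0.02)
})

test_that("zero-phase filtering keeps component peaks aligned with the input", {
  fs <- 100; f <- 4
  ppg <- two_tone_ppg(1.2, f, 0.01, 0.02, fs = fs)
  comps <- separate_components(ppg, 1.2, f)
  pairs <- detect_stimulation_peaks(comps$stim_red, f, fs)
  true_peaks <- detect_stimulation_peaks(
    0.02 * sin(2 * pi * f * ppg$time), f, fs)
  # compare peaks in the overlapping (non-edge) region
  for (p in pairs$peak) {
    expect_lte(min(abs(true_peaks$peak - p)), 1)
  }
})
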