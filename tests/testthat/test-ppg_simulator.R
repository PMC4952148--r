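co <- default_coefficients()

test_that("static limit produces constant traces at the DC transmission", {
  cfg <- quick_config(arterial_path_amp = 0, venous_stim_amp = 0,
                      arterial_stim_coupling = 0)
  ppg <- simulate_ppg(cfg)
  mu_a <- function(wl) cfg$sao2 * co[[paste0("eps_hbo2_", wl)]] +
    (1 - cfg$sao2) * co[[paste0("eps_hb_", wl)]]
  mu_v <- function(wl) cfg$svo2 * co[[paste0("eps_hbo2_", wl)]] +
    (1 - cfg$svo2) * co[[paste0("eps_hb_", wl)]]
  exp_red <- exp(-(cfg$static_absorbance_red +
                     mu_a("red") * cfg$arterial_path_mean +
                     mu_v("red") * cfg$venous_path_mean))
  expect_equal(ppg$i_red, rep(exp_red, length(ppg$time)), tolerance = 1e-12)
  expect_equal(diff(range(ppg$i_ir)), 0)
})

test_that("spectral peaks land at the programmed frequencies (FFT oracle)", {
  fs <- 100
  cfg <- quick_config(venous_stim_amp = 0, arterial_stim_coupling = 0)
  ppg <- simulate_ppg(cfg)
  expect_equal(fft_peak_freq(ppg$i_red, fs), 1.2, tolerance = fs / length(ppg$time))
  cfg2 <- quick_config()
  ppg2 <- simulate_ppg(cfg2)
  # two separated peaks: pulse below 2 Hz, stimulation near 4 Hz
  x <- ppg2$i_ir - mean(ppg2$i_ir)
  p <- Mod(stats::fft(x))^2
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  low <- f > 0.5 & f < 2
  high <- f >= 2.5 & f < 6
  expect_equal(f[low][which.max(p[low])], 1.2, tolerance = fs / n + 1e-9)
  expect_equal(f[high][which.max(p[high])], 4.0, tolerance = fs / n + 1e-9)
})

test_that("identical seeds give bit-identical traces", {
  cfg <- ppg_config(duration = 10, noise_sd = 0.005, seed = 123)
  a <- simulate_ppg(cfg)
  b <- simulate_ppg(cfg)
  expect_identical(a$i_red, b$i_red)
  expect_identical(a$i_ir, b$i_ir)
  c2 <- simulate_ppg(ppg_config(duration = 10, noise_sd = 0.005, seed = 124))
  expect_false(identical(a$i_red, c2$i_red))
})

test_that("noiseless absorbance decomposes into the three compartments", {
  cfg <- quick_config()
  ppg <- simulate_ppg(cfg)
  paths <- venoxim:::compartment_paths(cfg, ppg$time)
  mu <- function(s, wl) venoxim:::effective_mu(s, co, wl)
  a_red <- cfg$static_absorbance_red +
    mu(cfg$sao2, "red") * paths$arterial + mu(cfg$svo2, "red") * paths$venous
  expect_lt(max(abs(-log(ppg$i_red / cfg$incident) - a_red)), 1e-10)
})

test_that("equal venous and arterial saturation equalises the two band ratios", {
  cfg <- quick_config(svo2 = 0.98, duration = 40)
  ppg <- simulate_ppg(cfg)
  comps <- separate_components(ppg, 1.2, 4)
  r_band <- function(comp_red, comp_ir, freq) {
    pr <- detect_stimulation_peaks(comp_ir, freq, 100)
    red <- extract_ac_dc(comp_red, comps$dc_red, pr)
    ir <- extract_ac_dc(comp_ir, comps$dc_ir, pr)
    median((red$ac / red$dc) / (ir$ac / ir$dc))
  }
  r_pulse <- r_band(comps$pulse_red, comps$pulse_ir, 1.2)
  r_stim <- r_band(comps$stim_red, comps$stim_ir, 4)
  expect_equal(r_stim, r_pulse, tolerance = 0.02)
})

test_that("hypoxia protocol steps the saturations and aligns ground truth", {
  levels <- seq(1.0, 0.70, length.out = 6)
  hp <- hypoxia_protocol(levels, dwell = 5, quick_config())
  expect_equal(nrow(hp$truth), length(hp$ppg$time))
  expect_equal(sort(unique(hp$truth$sao2), decreasing = TRUE), levels)
  # venous tracks at the config's arteriovenous difference
  expect_equal(unique(hp$truth$sao2 - hp$truth$svo2), 0.23, tolerance = 1e-12)
  # a single level reproduces the constant-saturation simulation
  cfg <- quick_config(duration = 5)
  one <- hypoxia_protocol(cfg$sao2, dwell = 5, cfg)
  plain <- simulate_ppg(cfg)
  expect_equal(one$ppg$i_red, plain$i_red, tolerance = 1e-12)
  expect_error(hypoxia_protocol(numeric(0), 5, cfg), class = "venoxim_config_error")
})

test_that("sampling schedule counts multiply out", {
  sched <- build_sampling_schedule(6, 2, 2)
  expect_equal(nrow(sched$points), 24)
  expect_equal(nrow(build_sampling_schedule(1, 1, 1)$points), 1)
  expect_equal(nrow(build_sampling_schedule(3, 2, 1)$points), 6)
  # explicit level values are honoured and ordered within each repeat
  s2 <- build_sampling_schedule(c(1.0, 0.9, 0.8), 2, 2)
  expect_equal(nrow(s2$points), 12)
  expect_equal(s2$points$saturation[1:6], rep(c(1.0, 0.9, 0.8), each = 2))
  expect_error(build_sampling_schedule(0, 1, 1), class = "venoxim_config_error")
  expect_error(build_sampling_schedule(3, 0, 1), class = "venoxim_config_error")
})

test_that("configuration invariants are enforced", {
  expect_error(ppg_config(sampling_rate = 7, stim_rate = 4),
               class = "venoxim_config_error")  # Nyquist
  expect_error(ppg_config(stim_rate = 1.2, pulse_rate = 1.2),
               class = "venoxim_config_error")
  expect_error(ppg_config(noise_sd = 0.01, seed = NULL),
               class = "venoxim_config_error")  # stochastic run needs a seed
  expect_error(ppg_config(arterial_path_mean = 0.005, arterial_path_amp = 0.02,
                          noise_sd = 0),
               class = "venoxim_config_error")  # excursion exceeds mean
})
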