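co <- default_coefficients()

# Build aligned AC/DC tables straight from the forward model at saturation s:
# intensities at two path values, AC as their difference, DC as their mean.
forward_acdc <- function(s, n_cycles = 5, l1 = 0.30, l2 = 0.32) {
  mk <- function(wl) {
    i1 <- transmitted_intensity(1, s, co, wl, l1)
    i2 <- transmitted_intensity(1, s, co, wl, l2)
    data.frame(peak = seq_len(n_cycles), trough = seq_len(n_cycles),
               mid = seq_len(n_cycles),
               ac = rep(i1 - i2, n_cycles), dc = rep((i1 + i2) / 2, n_cycles))
  }
  list(red = mk("red"), ir = mk("ir"))
}

test_that("SpO2 from forward-model cycles recovers the programmed saturation", {
  sp <- compute_spo2(forward_acdc(0.98), co)
  expect_equal(as.numeric(sp), 98, tolerance = 0.5)
  expect_equal(attr(sp, "n_cycles"), 5)
  # R = 1 maps to the saturation the inversion assigns to R = 1
  acdc <- list(red = data.frame(ac = 0.01, dc = 1, mid = 1, peak = 1, trough = 1),
               ir = data.frame(ac = 0.01, dc = 1, mid = 1, peak = 1, trough = 1))
  expect_equal(as.numeric(compute_spo2(acdc, co)),
               100 * as.numeric(saturation_from_r(1, co)))
  expect_error(compute_spo2(list(red = data.frame(), ir = data.frame()), co),
               class = "venoxim_insufficient_data")
})

test_that("an empirical calibration map is honoured", {
  s_grid <- seq(0.7, 1, by = 0.02)
  r_grid <- r_from_saturation(s_grid, co)
  cal <- fit_r_calibration(r_grid, s_grid)
  # the linear fit is only approximate over a wide range, but must be used
  sp <- compute_spo2(forward_acdc(0.9), co, calibration = cal$map)
  expect_equal(as.numeric(sp), 90, tolerance = 2)
  sp2 <- compute_spo2(forward_acdc(0.9), co, calibration = list(a = cal$a, b = cal$b))
  expect_equal(as.numeric(sp2), as.numeric(sp), tolerance = 1e-9)
})

test_that("mixed saturation equals SpO2 when venous equals arterial blood", {
  cfg <- quick_config(svo2 = 0.98, duration = 40)
  res <- run_pipeline(simulate_ppg(cfg))
  ok <- stats::complete.cases(res[, c("spo2", "stim_spo2")])
  expect_true(any(ok))
  expect_equal(res$stim_spo2[ok], res$spo2[ok], tolerance = 0.01)
})

test_that("venous unmixing follows the mixture algebra and flags excursions", {
  expect_equal(as.numeric(svo2_from_mixed(98, 86.5)), 75)
  expect_equal(as.numeric(svo2_from_mixed(90, 90)), 90)
  s <- svo2_from_mixed(90, 96)
  expect_equal(as.numeric(s), 102)
  expect_true(attr(s, "out_of_range"))
  # non-default arterial weight
  expect_equal(as.numeric(svo2_from_mixed(98, 77.0909090909, 0.1 / 1.1)), 75,
               tolerance = 1e-9)
  expect_error(svo2_from_mixed(Inf, 80), class = "venoxim_invalid_input")
})

test_that("oxygen consumption is the arteriovenous difference", {
  expect_equal(as.numeric(oxygen_consumption(98, 75)), 23)
  expect_equal(as.numeric(oxygen_consumption(80, 80)), 0)
  d <- oxygen_consumption(70, 75)
  expect_equal(as.numeric(d), -5)
  expect_true(attr(d, "implausible"))
})

test_that("noiseless end-to-end run recovers both saturations", {
  cfg <- ppg_config(noise_sd = 0)  # 60 s, SaO2 98 %, SvO2 75 %, coupling 0.1
  res <- run_pipeline(simulate_ppg(cfg))
  expect_true(all(res$spo2_ok))
  expect_lt(max(abs(res$spo2 - 98)), 1)
  expect_lt(max(abs(res$svo2 - 75)), 2)
})

test_that("noisy end-to-end run stays within the relaxed tolerances", {
  cfg <- ppg_config(seed = 17)  # default noise
  res <- run_pipeline(simulate_ppg(cfg))
  expect_lt(abs(median(res$spo2, na.rm = TRUE) - 98), 2)
  expect_lt(abs(median(res$svo2, na.rm = TRUE) - 75), 4)
})

test_that("the Mixed_SpO2 identity holds bit-exactly on every reported window", {
  res <- run_pipeline(simulate_ppg(ppg_config(seed = 9)))
  ok <- stats::complete.cases(res[, c("spo2", "mixed_spo2", "svo2")])
  expect_true(any(ok))
  expect_identical(res$svo2[ok], 2 * res$mixed_spo2[ok] - res$spo2[ok])
})

test_that("disabling stimulation degrades gracefully: SpO2 survives, SvO2 is flagged", {
  cfg <- ppg_config(duration = 30, venous_stim_amp = 0,
                    arterial_stim_coupling = 0, seed = 4)
  res <- run_pipeline(simulate_ppg(cfg))
  expect_true(all(!res$separation_ok))
  expect_true(all(is.na(res$svo2)))
  expect_true(all(res$spo2_ok))
  expect_lt(abs(median(res$spo2) - 98), 2)
})

test_that("the pipeline is deterministic on identical input", {
  ppg <- simulate_ppg(ppg_config(duration = 30, seed = 21))
  expect_identical(run_pipeline(ppg), run_pipeline(ppg))
})

test_that("a hypoxia ramp yields monotone, rank-correlated venous estimates", {
  levels <- seq(1.00, 0.70, length.out = 6)
  hp <- hypoxia_protocol(levels, dwell = 30, ppg_config(seed = 11))
  res <- run_pipeline(hp$ppg)
  lvl <- findInterval(res$window_time, seq(0, by = 30, length.out = 7),
                      rightmost.closed = TRUE)
  full <- (res$window_time - 5) >= (lvl - 1) * 30 &
          (res$window_time + 5) <= lvl * 30
  per_level <- tapply(res$svo2[full], lvl[full], median, na.rm = TRUE)
  expect_equal(length(per_level), 6)
  expect_true(all(diff(per_level) < 1))  # non-increasing within 1 pp slack
  truth <- pmax(0, levels - 0.23) * 100
  expect_gte(cor(as.numeric(per_level), truth[as.numeric(names(per_level))],
                 method = "spearman"), 0.95)
})
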