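test_that("waveform has a DC plateau, AC peaks at quarter periods, and dense sampling", {
  p <- stimulation_protocol(dc_field_T = 0.3, dc_duration_s = 5e-3,
                            ac_duration_s = 30e-3)
  wf <- build_waveform(p, ac_amplitude_T = 6.5e-3)
  dc <- wf$t_s < wf$t_dc_off
  expect_true(all(wf$H_T[dc] == 0.3))
  ac <- !dc
  expect_equal(max(wf$H_T[ac]), 6.5e-3, tolerance = 1e-6)
  t_pk <- wf$t_s[ac][which.max(wf$H_T[ac])]
  expect_equal(t_pk, wf$t_dc_off + 1 / 400, tolerance = 1 / (200 * 100))
  # grid density: at least 200 samples per 10 ms period
  expect_gte(1 / (100 * median(diff(wf$t_s))), 200)
  # zero amplitude: identically zero after switch-off
  wf0 <- build_waveform(p, ac_amplitude_T = 0)
  expect_true(all(wf0$H_T[wf0$t_s >= wf0$t_dc_off] == 0))
  expect_error(build_waveform(stimulation_protocol(dc_duration_s = 1e-3,
                                                   ac_duration_s = 1e-3)
                              , ac_amplitude_T = -1), NA)
})

test_that("q_ionic is exactly linear with zero intercept and rejects bad gains", {
  b <- bond_model_params()
  expect_equal(q_ionic(0, b), 0)
  expect_equal(q_ionic(2 * 1.7, b), 2 * q_ionic(1.7, b))
  x <- c(0.3, 1.1, 2.92)
  expect_equal(q_ionic(x, b), b$k_q_C_per_V * x * 1e-3)
  expect_error(bond_model_params(k_q_C_per_V = -1), "positive")
  # documented capacitor-like parameterization
  expect_equal(b$k_q_C_per_V,
               8.8541878128e-12 * 10 * pi * (70e-9)^2 / 0.3e-9)
})

test_that("time-dependent run: constant M in the DC phase, retained remanence, oscillation at the drive frequency", {
  rs <- bv_release_default()
  r <- rs[["6.5"]]
  wf <- attr(r, "waveform")
  dc <- r$t_s > 1e-3 & r$t_s < wf$t_dc_off
  expect_lt(stats::sd(r$M_A_per_m[dc]) / mean(r$M_A_per_m[dc]), 1e-9)
  M_dc <- mean(r$M_A_per_m[dc])
  i_off <- which(r$t_s >= wf$t_dc_off)[1]
  M_rem <- r$M_A_per_m[i_off]
  expect_gt(M_rem, 0)
  expect_gt(M_rem / M_dc, 0.8)            # hysteretic retention
  expect_lt(M_rem / M_dc, 1)
  # dV oscillates at the input frequency (spectral peak at 100 Hz)
  ac <- r$t_s >= wf$t_dc_off
  x <- r$dV_mV[ac] - mean(r$dV_mV[ac])
  dt <- stats::median(diff(r$t_s))
  sp <- Mod(stats::fft(x))^2
  freqs <- (seq_along(x) - 1) / (length(x) * dt)
  half <- 2:floor(length(x) / 2)
  f_peak <- freqs[half][which.max(sp[half])]
  expect_equal(f_peak, 100, tolerance = 0.05)
  expect_true(all(r$dV_mV >= 0))
})

test_that("Q_ionic and dV extrema coincide in time and peak dV grows with amplitude", {
  rs <- bv_release_default()
  r <- rs[["6.5"]]
  expect_equal(which.max(r$Q_ionic_C), which.max(r$dV_mV))
  expect_equal(which.min(r$Q_ionic_C), which.min(r$dV_mV))
  pt <- peak_table(rs)
  expect_equal(pt$H_AC_mT, c(1, 2, 2.5, 3, 4.5, 5, 6.5))
  expect_true(all(diff(pt$dV_mV) > 0))
  expect_true(all(diff(pt$M_A_per_m) > 0))
  expect_gt(pt$dV_mV[7], pt$dV_mV[1])
  expect_length(attr(pt, "missing_amplitudes_mT"), 0)
})

test_that("CM and BV time series differ negligibly in dV", {
  cfg_cm <- scenario_config(environment = environment_material("CM"),
                            mesh_resolution = "coarse")
  cfg_bv <- scenario_config(mesh_resolution = "coarse")
  wf <- build_waveform(cfg_bv$stimulation, 6.5e-3)
  r_cm <- suppressMessages(time_dependent_run(cfg_cm, wf))
  r_bv <- suppressMessages(time_dependent_run(cfg_bv, wf))
  rel <- abs(r_cm$dV_mV - r_bv$dV_mV) / max(r_bv$dV_mV)
  expect_lt(max(rel), 0.02)
})

test_that("halving the time step changes the peak dV by < 0.5%", {
  cfg <- scenario_config()
  dv_sat <- 6.42                      # fixed transfer constant: isolates the ODE
  p1 <- stimulation_protocol()
  wf1 <- build_waveform(p1, 6.5e-3)
  r1 <- time_dependent_run(cfg, wf1, dv_sat_mV = dv_sat)
  # double the sampling density
  f <- p1$ac_frequency_Hz
  t2 <- seq(0, wf1$t_end, by = 1 / (400 * f))
  wf2 <- wf1
  wf2$t_s <- t2
  wf2$H_T <- ifelse(t2 < wf1$t_dc_off, p1$dc_field_T,
                    6.5e-3 * sin(2 * pi * f * (t2 - wf1$t_dc_off)))
  r2 <- time_dependent_run(cfg, wf2, dv_sat_mV = dv_sat)
  ac1 <- r1$t_s >= wf1$t_dc_off
  ac2 <- r2$t_s >= wf1$t_dc_off
  expect_equal(max(r1$dV_mV[ac1]), max(r2$dV_mV[ac2]), tolerance = 0.005)
})
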