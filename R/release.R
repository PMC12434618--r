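# Step-3 time-dependent study: DC magnetization/electroporation phase, AC
# sinusoidal phase under Jiles-Atherton hysteresis, the quasi-static surface
# potential map dV(t), and the ionic charge-displacement proxy Q_ionic(t).
#
# At 100 Hz the electromechanical response of a 140 nm particle is
# quasi-static, so dV(t) is obtained from the stationary coupled operator:
# the potential difference per unit saturation eigenstrain is computed once
# and scaled by (M(t)/Ms)^2 (the magnetostrictive eigenstrain is quadratic
# in the magnetization).  The hysteretic state is advanced as a lumped
# (volume-averaged) J-A model with the sphere demagnetizing factor.

#' Ionic-bond charge-displacement model parameters
#'
#' The drug-release proxy is linear in the surface potential difference:
#' `Q_ionic = k_q * dV`.  The default gain uses the capacitor-like
#' parameterization `k_q = eps0 * eps_r_shell * pi * r_MENP^2 / d0` with an
#' equilibrium bond length `d0` of 0.3 nm — a documented hypothesis that
#' maps the published mV-scale potential range onto the published 1e-17 C
#' charge scale; it is a calibratable gain, not a derived constant.
#'
#' @param eps_r_shell shell relative permittivity.
#' @param r_MENP_m particle outer radius (m).
#' @param d0_m equilibrium bond length (m).
#' @param k_q_C_per_V optional explicit gain; overrides the parameterization.
#' @return object of class `bond_model_params` with the gain `k_q_C_per_V`.
#' @export
bond_model_params <- function(eps_r_shell = 10, r_MENP_m = 70e-9, d0_m = 0.3e-9,
                              k_q_C_per_V = NULL) {
  if (is.null(k_q_C_per_V)) {
    k_q_C_per_V <- EPS0 * eps_r_shell * pi * r_MENP_m^2 / d0_m
  }
  if (k_q_C_per_V <= 0) stop("bond model: k_q must be positive", call. = FALSE)
  structure(list(eps_r_shell = eps_r_shell, r_MENP_m = r_MENP_m, d0_m = d0_m,
                 k_q_C_per_V = k_q_C_per_V), class = "bond_model_params")
}

#' Ionic charge displacement from a surface potential difference
#'
#' @param dV_mV potential difference (mV), vectorized.
#' @param params a [bond_model_params()].
#' @return charge displacement (C); zero at zero potential, strictly linear.
#' @export
q_ionic <- function(dV_mV, params = bond_model_params()) {
  params$k_q_C_per_V * dV_mV * 1e-3
}

#' Two-phase DC + AC stimulation waveform
#'
#' Constant `H_DC` for the electroporation phase, then
#' `H_AC * sin(2*pi*f*(t - t_dc_off))` for the drug-release phase; the time
#' grid resolves at least 200 points per AC period.
#'
#' @param protocol a [stimulation_protocol()].
#' @param ac_amplitude_T AC amplitude (T); defaults to the protocol's first.
#' @return object of class `stimulus_waveform`: `t_s`, `H_T`, `t_dc_off`,
#'   `t_end`, and the protocol metadata.
#' @export
build_waveform <- function(protocol = stimulation_protocol(),
                           ac_amplitude_T = protocol$ac_amplitudes_T[1]) {
  if (protocol$dc_duration_s <= 0 || protocol$ac_duration_s <= 0) {
    stop("waveform: durations must be positive", call. = FALSE)
  }
  f <- protocol$ac_frequency_Hz
  dt <- 1 / (200 * f)
  t_dc_off <- protocol$dc_duration_s
  t_end <- t_dc_off + protocol$ac_duration_s
  t <- seq(0, t_end, by = dt)
  if (abs(t[length(t)] - t_end) > dt / 2) t <- c(t, t_end)
  H <- ifelse(t < t_dc_off,
              protocol$dc_field_T,
              ac_amplitude_T * sin(2 * pi * f * (t - t_dc_off)))
  structure(list(t_s = t, H_T = H, t_dc_off = t_dc_off, t_end = t_end,
                 H_DC_T = protocol$dc_field_T, H_AC_T = ac_amplitude_T,
                 f_Hz = f), class = "stimulus_waveform")
}

# Potential difference per unit (M/Ms)^2, from one stationary coupled solve
# with the core uniformly magnetized to Ms.  This is the quasi-static
# transfer constant reused by every time step.
dv_saturation_mV <- function(config, mesh = NULL, operator = NULL) {
  if (is.null(mesh)) mesh <- build_mesh(config$geometry, config$mesh_resolution)
  if (is.null(operator)) operator <- build_coupled_operator(mesh, config)
  ne <- length(operator$pre$area)
  Mz <- ifelse(operator$pre$region == "core", config$core$Ms_A_per_m, 0)
  eig <- magnetostrictive_strain(Mz, config$core)
  sol <- solve_coupled_with_operator(operator, eig)
  delta_v(sol)
}

#' Time-dependent magnetoelectric run
#'
#' Integrates the lumped Jiles-Atherton state along the waveform and maps
#' the magnetization to the surface potential difference through the
#' stationary operator (quasi-static assumption), then appends the ionic
#' charge displacement.
#'
#' @param config a [scenario_config()].
#' @param waveform a [build_waveform()] waveform.
#' @param dv_sat_mV optional precomputed saturation potential difference
#'   (mV); computed from the config's mesh otherwise.
#' @param bond a [bond_model_params()].
#' @return data.frame of class `time_series_result`: `t_s`, `H_T`,
#'   `M_A_per_m`, `dV_mV`, `Q_ionic_C`, with the waveform metadata and
#'   `dv_sat_mV` as attributes.
#' @export
time_dependent_run <- function(config, waveform, dv_sat_mV = NULL,
                               bond = bond_model_params()) {
  if (is.null(dv_sat_mV)) dv_sat_mV <- dv_saturation_mV(config)
  st <- ja_state(config$ja, demag_factor = 1 / 3)
  nt <- length(waveform$t_s)
  M <- numeric(nt)
  H_Am <- waveform$H_T / MU0
  for (i in seq_len(nt)) {
    st <- ja_update(st, H_Am[i])
    M[i] <- st$M
  }
  dV <- dv_sat_mV * (M / config$ja$Ms_A_per_m)^2
  out <- data.frame(
    t_s = waveform$t_s, H_T = waveform$H_T, M_A_per_m = M, dV_mV = dV,
    Q_ionic_C = q_ionic(dV, bond)
  )
  attr(out, "waveform") <- waveform[c("t_dc_off", "t_end", "H_DC_T", "H_AC_T", "f_Hz")]
  attr(out, "dv_sat_mV") <- dv_sat_mV
  attr(out, "environment") <- config$environment$name
  class(out) <- c("time_series_result", class(out))
  out
}

#' Peak-instant summary table across AC amplitudes
#'
#' Extracts magnetization, potential difference and the magnetoelectric
#' coefficient at the first AC peak (`t_dc_off + 1/(4f)`) of each run.  The
#' coefficient is reported under two conventions: `alpha_ME_ac` divides by
#' the AC amplitude alone, `alpha_ME_eff` divides by the effective field
#' `mu0*(H + (alpha - N)*M)` seen by the hysteretic state at the peak; the
#' published convention for this table is not stated, so both are given.
#'
#' @param results list of [time_dependent_run()] results, one per amplitude.
#' @param phi_cm particle diameter (cm).
#' @param ja [ja_parameters()] used for the effective-field convention.
#' @return data.frame with one row per amplitude, sorted by amplitude.
#' @export
peak_table <- function(results, phi_cm = 1.4e-5, ja = ja_parameters()) {
  rows <- lapply(results, function(res) {
    wf <- attr(res, "waveform")
    if (is.null(wf)) stop("peak_table: result lacks waveform metadata", call. = FALSE)
    t_peak <- wf$t_dc_off + 1 / (4 * wf$f_Hz)
    i <- which.min(abs(res$t_s - t_peak))
    H_eff_T <- MU0 * (res$H_T[i] / MU0 + (ja$alpha - 1 / 3) * res$M_A_per_m[i])
    data.frame(
      H_AC_mT = wf$H_AC_T * 1e3,
      M_A_per_m = res$M_A_per_m[i],
      dV_mV = res$dV_mV[i],
      Q_ionic_C = res$Q_ionic_C[i],
      alpha_ME_ac = alpha_me(res$dV_mV[i], convert_field_units(wf$H_AC_T, "T", "Oe"), phi_cm),
      alpha_ME_eff = alpha_me(res$dV_mV[i], convert_field_units(H_eff_T, "T", "Oe"), phi_cm)
    )
  })
  out <- do.call(rbind, rows)
  ref_amps <- c(1, 2, 2.5, 3, 4.5, 5, 6.5)
  missing_amp <- ref_amps[!vapply(ref_amps, function(a) {
    any(abs(out$H_AC_mT - a) < 1e-9)
  }, logical(1))]
  attr(out, "missing_amplitudes_mT") <- missing_amp
  out[order(out$H_AC_mT), , drop = FALSE]
}

#' Run the AC drug-release study over a list of amplitudes
#'
#' @param config a [scenario_config()].
#' @param amplitudes_T AC amplitudes (T); defaults to the protocol list.
#' @param mesh,operator optional pre-built mesh/operator.
#' @param bond a [bond_model_params()].
#' @return list of [time_dependent_run()] results keyed by amplitude (mT).
#' @export
release_study <- function(config, amplitudes_T = config$stimulation$ac_amplitudes_T,
                          mesh = NULL, operator = NULL,
                          bond = bond_model_params(eps_r_shell = config$shell$eps_r,
                                                   r_MENP_m = config$geometry$outer_radius_m)) {
  dv_sat <- dv_saturation_mV(config, mesh, operator)
  out <- lapply(amplitudes_T, function(amp) {
    wf <- build_waveform(config$stimulation, ac_amplitude_T = amp)
    time_dependent_run(config, wf, dv_sat_mV = dv_sat, bond = bond)
  })
  names(out) <- sprintf("%g", amplitudes_T * 1e3)
  out
}
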