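# Material, stimulation and scenario parameterization.
#
# All numeric fields carry explicit unit suffixes in their names and in the
# serialized JSON schema (schema_version 1).  Defaults reproduce the study
# scenario: CoFe2O4 core / BaTiO3 shell particle (core radius 45 nm, shell
# 25 nm) in either culture medium ("CM", liquid) or blood-vessel wall ("BV",
# solid) surroundings.

#' Magnetostrictive core material (CoFe2O4)
#'
#' @param Ms_A_per_m saturation magnetization (A/m).
#' @param chi0 initial magnetic susceptibility (dimensionless).
#' @param lambda_s saturation magnetostriction (dimensionless strain; the
#'   default -200e-6 is a contraction along the field axis).
#' @param rho_kg_per_m3 density (kg/m^3).
#' @param E_Pa isotropic Young's modulus (Pa).
#' @param nu Poisson's ratio.
#' @param eps_r relative permittivity used in the electrostatic solve.
#' @return object of class `core_material`.
#' @export
core_material <- function(Ms_A_per_m = 3.69e5,
                          chi0 = 3,
                          lambda_s = -200e-6,
                          rho_kg_per_m3 = 5.3e3,
                          E_Pa = 150e9,
                          nu = 0.3,
                          eps_r = 1) {
  m <- structure(list(
    Ms_A_per_m = Ms_A_per_m, chi0 = chi0, lambda_s = lambda_s,
    rho_kg_per_m3 = rho_kg_per_m3, E_Pa = E_Pa, nu = nu, eps_r = eps_r
  ), class = "core_material")
  validate_core_material(m)
}

validate_core_material <- function(m) {
  if (!(m$Ms_A_per_m > 0)) stop("core: Ms must be positive", call. = FALSE)
  if (!(m$chi0 > 0)) stop("core: chi0 must be positive", call. = FALSE)
  if (!(m$nu > -1 && m$nu < 0.5)) stop("core: poisson_ratio out of range (-1, 0.5)", call. = FALSE)
  if (!(m$rho_kg_per_m3 > 0)) stop("core: density must be positive", call. = FALSE)
  if (!(m$E_Pa > 0)) stop("core: youngs_modulus must be positive", call. = FALSE)
  if (!(m$eps_r >= 1)) stop("core: eps_r must be >= 1", call. = FALSE)
  m
}

#' Piezoelectric shell material (BaTiO3)
#'
#' The stress-charge piezoelectric coupling is the tetragonal 4mm set
#' (e31, e33, e15 families), poled along +z.  The published parameter table
#' does not include the coupling matrix; the default is a literature BaTiO3
#' stress-charge set scaled by a single calibration factor fixed once against
#' the 2 T baseline surface-potential difference (see the methods vignette).
#' The printed shell conductivity is stored but deliberately not used by the
#' dielectric electrostatic formulation.
#'
#' @param rho_kg_per_m3 density (kg/m^3).
#' @param eps_r relative permittivity.
#' @param E_Pa Young's modulus (Pa).
#' @param nu Poisson's ratio.
#' @param e31_C_per_m2,e33_C_per_m2,e15_C_per_m2 stress-charge coefficients
#'   (C/m^2) before scaling.
#' @param piezo_scale dimensionless calibration factor multiplying the whole
#'   e-matrix.  The default was calibrated once so that the default blood-vessel
#'   scenario at 2 T yields a 6.07 mV pole-to-pole potential difference.
#' @param sigma_S_per_m electrical conductivity (S/m); stored, unused in the
#'   potential solve (a warning is emitted when nonzero at solve time).
#' @return object of class `shell_material`.
#' @export
shell_material <- function(rho_kg_per_m3 = 5.2e3,
                           eps_r = 10,
                           E_Pa = 230e9,
                           nu = 0.48,
                           e31_C_per_m2 = -4.35,
                           e33_C_per_m2 = 17.5,
                           e15_C_per_m2 = 11.4,
                           piezo_scale = PIEZO_SCALE_DEFAULT,
                           sigma_S_per_m = 5.2e6) {
  m <- structure(list(
    rho_kg_per_m3 = rho_kg_per_m3, eps_r = eps_r, E_Pa = E_Pa, nu = nu,
    e31_C_per_m2 = e31_C_per_m2, e33_C_per_m2 = e33_C_per_m2,
    e15_C_per_m2 = e15_C_per_m2, piezo_scale = piezo_scale,
    sigma_S_per_m = sigma_S_per_m
  ), class = "shell_material")
  validate_shell_material(m)
}

validate_shell_material <- function(m) {
  if (!(m$eps_r >= 1)) stop("shell: eps_r must be >= 1", call. = FALSE)
  if (!(m$E_Pa > 0)) stop("shell: youngs_modulus must be positive", call. = FALSE)
  if (!(m$nu > -1 && m$nu < 0.5)) stop("shell: poisson_ratio out of range (-1, 0.5)", call. = FALSE)
  if (!(m$piezo_scale >= 0)) stop("shell: piezo_scale must be >= 0", call. = FALSE)
  m
}

#' Surrounding environment material
#'
#' Two named environments are used in the study: culture medium (`"CM"`,
#' a liquid: no static mechanical domain) and blood-vessel wall (`"BV"`,
#' a soft solid).  Both are purely resistive with relative permittivity 1;
#' conductivity is stored for completeness but the DC potential solve is a
#' dielectric Poisson problem (free-charge screening is out of scope).
#'
#' @param name `"CM"` or `"BV"`.
#' @param sigma_S_per_m conductivity (S/m).
#' @param eps_r relative permittivity.
#' @param mu_r relative permeability.
#' @param is_solid does the environment carry static elastic stress?
#' @param E_Pa,nu elastic constants (solid environments only).
#' @param rho_kg_per_m3 density (kg/m^3).
#' @return object of class `environment_material`.
#' @export
environment_material <- function(name = c("BV", "CM"),
                                 sigma_S_per_m = NULL,
                                 eps_r = 1, mu_r = 1,
                                 is_solid = NULL,
                                 E_Pa = NULL, nu = NULL,
                                 rho_kg_per_m3 = NULL) {
  name <- match.arg(name)
  if (is.null(sigma_S_per_m)) sigma_S_per_m <- if (name == "CM") 1.5 else 0.232
  if (is.null(is_solid)) is_solid <- (name == "BV")
  if (is_solid) {
    if (is.null(E_Pa)) E_Pa <- 1e6
    if (is.null(nu)) nu <- 0.49
  }
  if (is.null(rho_kg_per_m3)) rho_kg_per_m3 <- if (name == "CM") 1007 else 1102
  m <- structure(list(
    name = name, sigma_S_per_m = sigma_S_per_m, eps_r = eps_r, mu_r = mu_r,
    is_solid = is_solid, E_Pa = E_Pa, nu = nu, rho_kg_per_m3 = rho_kg_per_m3
  ), class = "environment_material")
  validate_environment_material(m)
}

validate_environment_material <- function(m) {
  if (!(m$sigma_S_per_m >= 0)) stop("environment: conductivity must be >= 0", call. = FALSE)
  if (!(m$eps_r >= 1)) stop("environment: eps_r must be >= 1", call. = FALSE)
  if (isTRUE(m$is_solid)) {
    if (is.null(m$E_Pa) || is.null(m$nu)) {
      stop("environment: solid environment requires youngs_modulus and poisson_ratio", call. = FALSE)
    }
    if (!(m$nu > -1 && m$nu < 0.5)) stop("environment: poisson_ratio out of range (-1, 0.5)", call. = FALSE)
  }
  m
}

#' Jiles-Atherton hysteresis parameters
#'
#' @param Ms_A_per_m saturation magnetization (A/m).
#' @param k_A_per_m pinning loss (A/m).
#' @param a_A_per_m domain wall density parameter (A/m).
#' @param alpha inter-domain coupling (dimensionless).
#' @param c_rev magnetic reversibility, in \[0, 1\].
#' @return object of class `ja_parameters`.
#' @export
ja_parameters <- function(Ms_A_per_m = 3.69e5,
                          k_A_per_m = 2e5,
                          a_A_per_m = 1.5e5,
                          alpha = 1.5,
                          c_rev = 0.3) {
  p <- structure(list(
    Ms_A_per_m = Ms_A_per_m, k_A_per_m = k_A_per_m, a_A_per_m = a_A_per_m,
    alpha = alpha, c_rev = c_rev
  ), class = "ja_parameters")
  validate_ja_parameters(p)
}

validate_ja_parameters <- function(p) {
  if (!(p$c_rev >= 0 && p$c_rev <= 1)) stop("ja: c_rev out of range [0, 1]", call. = FALSE)
  if (!(p$k_A_per_m > 0)) stop("ja: k must be positive", call. = FALSE)
  if (!(p$a_A_per_m > 0)) stop("ja: a must be positive", call. = FALSE)
  if (!(p$Ms_A_per_m > 0)) stop("ja: Ms must be positive", call. = FALSE)
  p
}

#' Magnetic stimulation protocol
#'
#' Describes the DC sweep grid and the two-phase (DC then AC) time-dependent
#' protocol.  The default sweep grid is 15 linearly spaced values in each of
#' the three sub-intervals 2-50 mT, 100-800 mT and 1-4 T (45 points total;
#' 0 T is excluded since the magnetoelectric coefficient is undefined there).
#'
#' @param dc_field_T DC amplitude (T) for the time-dependent electroporation
#'   phase.
#' @param dc_duration_s duration of the DC phase (s).
#' @param ac_amplitudes_T AC sinusoid amplitudes (T) to sweep.
#' @param ac_frequency_Hz AC frequency (Hz).
#' @param ac_duration_s duration of the AC phase (s).
#' @param sweep_grid_T ordered DC sweep grid (T).
#' @return object of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(dc_field_T = 0.3,
                                 dc_duration_s = 5e-3,
                                 ac_amplitudes_T = c(1, 2, 2.5, 3, 4.5, 5, 6.5) * 1e-3,
                                 ac_frequency_Hz = 100,
                                 ac_duration_s = 30e-3,
                                 sweep_grid_T = default_sweep_grid()) {
  p <- structure(list(
    dc_field_T = dc_field_T, dc_duration_s = dc_duration_s,
    ac_amplitudes_T = ac_amplitudes_T, ac_frequency_Hz = ac_frequency_Hz,
    ac_duration_s = ac_duration_s, sweep_grid_T = sweep_grid_T
  ), class = "stimulation_protocol")
  validate_stimulation_protocol(p)
}

validate_stimulation_protocol <- function(p) {
  if (!(p$ac_frequency_Hz > 0)) stop("stimulation: frequency must be positive", call. = FALSE)
  if (!(p$dc_duration_s > 0 && p$ac_duration_s > 0)) {
    stop("stimulation: durations must be positive", call. = FALSE)
  }
  if (any(p$ac_amplitudes_T < 0) || p$dc_field_T < 0) {
    stop("stimulation: amplitudes must be >= 0", call. = FALSE)
  }
  if (is.unsorted(p$sweep_grid_T, strictly = TRUE)) {
    stop("stimulation: sweep grid must be strictly increasing", call. = FALSE)
  }
  p
}

#' Default DC sweep grid (T): 15 values per sub-interval
#' @export
default_sweep_grid <- function() {
  c(seq(2e-3, 50e-3, length.out = 15),
    seq(100e-3, 800e-3, length.out = 15),
    seq(1, 4, length.out = 15))
}

#' Full scenario configuration
#'
#' Bundles materials, geometry, environment, hysteresis parameters and the
#' stimulation protocol.  Defaults reproduce the study's blood-vessel-wall
#' scenario.
#'
#' @param core [core_material()].
#' @param shell [shell_material()].
#' @param environment [environment_material()].
#' @param geometry [core_shell_geometry()].
#' @param ja [ja_parameters()].
#' @param stimulation [stimulation_protocol()].
#' @param mesh_resolution `"coarse"`, `"default"` or `"fine"`.
#' @param random_seed integer seed for sampling-based post-processing.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(core = core_material(),
                            shell = shell_material(),
                            environment = environment_material("BV"),
                            geometry = core_shell_geometry(),
                            ja = ja_parameters(),
                            stimulation = stimulation_protocol(),
                            mesh_resolution = c("default", "coarse", "fine"),
                            random_seed = 1L) {
  mesh_resolution <- match.arg(mesh_resolution)
  structure(list(
    schema_version = 1L,
    core = core, shell = shell, environment = environment,
    geometry = geometry, ja = ja, stimulation = stimulation,
    mesh_resolution = mesh_resolution, random_seed = as.integer(random_seed)
  ), class = "scenario_config")
}

config_classes <- c(
  core = "core_material", shell = "shell_material",
  environment = "environment_material", geometry = "core_shell_geometry",
  ja = "ja_parameters", stimulation = "stimulation_protocol"
)

#' Save a scenario configuration to JSON
#'
#' All quantities are written in SI with unit-suffixed field names; the file
#' round-trips losslessly through [load_scenario_config()].
#'
#' @param config a [scenario_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  x <- strip(config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Load (and validate) a scenario configuration from JSON
#'
#' Unspecified fields take the study defaults; unknown keys raise an error
#' naming the offending key, and invariant violations raise an error naming
#' the constraint.
#'
#' @param path JSON file path.
#' @return a validated [scenario_config()].
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_top <- c("schema_version", names(config_classes), "mesh_resolution", "random_seed")
  bad <- setdiff(names(raw), known_top)
  if (length(bad)) stop("unknown config key: '", bad[[1]], "'", call. = FALSE)

  args <- list()
  for (section in names(config_classes)) {
    ctor <- switch(section,
      core = core_material, shell = shell_material,
      environment = environment_material, geometry = core_shell_geometry,
      ja = ja_parameters, stimulation = stimulation_protocol
    )
    if (!is.null(raw[[section]])) {
      # JSON whole numbers parse as integers; physical fields are doubles
      fields <- rapply(raw[[section]],
                       function(v) if (is.integer(v)) as.double(v) else v,
                       how = "replace")
      ok <- names(formals(ctor))
      bad <- setdiff(names(fields), ok)
      if (length(bad)) {
        stop("unknown config key: '", section, ".", bad[[1]], "'", call. = FALSE)
      }
      args[[section]] <- do.call(ctor, fields)
    }
  }
  if (!is.null(raw$mesh_resolution)) args$mesh_resolution <- raw$mesh_resolution
  if (!is.null(raw$random_seed)) args$random_seed <- raw$random_seed
  do.call(scenario_config, args)
}
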