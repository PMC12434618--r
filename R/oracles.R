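# Analytic verification oracles and study-scenario fixtures.
#
# Every reference value here is a closed-form expression evaluated without
# touching the FEM machinery, so the solvers can be checked against
# independent ground truth: the linear magnetizable sphere (uniform interior
# field, demagnetizing factor 1/3), the dielectric sphere in a uniform
# imposed field, and the uniform-eigenstrain spherical inclusion (uniform
# interior stress).

#' Linear magnetizable sphere oracle
#'
#' A sphere of susceptibility chi in applied flux density `H_ext_T` has the
#' uniform interior magnetization `M = chi * (H_ext/mu0) / (1 + chi/3)`.
#'
#' @param chi susceptibility (> 0).
#' @param H_ext_T applied field (T).
#' @return `oracle_case` with `reference` (A/m) and a 2% default tolerance.
#' @export
make_linear_sphere_case <- function(chi, H_ext_T) {
  stopifnot(chi >= 0)
  structure(list(
    name = "linear_magnetizable_sphere",
    chi = chi, H_ext_T = H_ext_T,
    reference = chi * (H_ext_T / MU0) / (1 + chi / 3),
    formula = "M = chi*(H/mu0)/(1 + chi/3)",
    tolerance = 0.02
  ), class = "oracle_case")
}

#' Dielectric sphere in a uniform imposed field oracle
#'
#' Interior field magnitude `3*eps_out*E0/(eps_in + 2*eps_out)`.
#'
#' @param eps_in,eps_out relative permittivities (>= 1).
#' @param E0 imposed far-field magnitude (V/m).
#' @return `oracle_case` with `reference` (V/m) and a 1% default tolerance.
#' @export
make_dielectric_sphere_case <- function(eps_in, eps_out, E0) {
  stopifnot(eps_in >= 1, eps_out >= 1)
  structure(list(
    name = "dielectric_sphere",
    eps_in = eps_in, eps_out = eps_out, E0 = E0,
    reference = 3 * eps_out * E0 / (eps_in + 2 * eps_out),
    formula = "E_int = 3*eps_out*E0/(eps_in + 2*eps_out)",
    tolerance = 0.01
  ), class = "oracle_case")
}

#' Uniform-eigenstrain spherical inclusion oracle
#'
#' For homogeneous elastic constants, a uniform eigenstrain confined to the
#' spherical core produces a uniform interior stress field (Eshelby
#' property); the oracle asserts interior uniformity (coefficient of
#' variation below tolerance) and exact linearity in the eigenstrain
#' amplitude, both checkable without a closed-form stress value.
#'
#' @param lambda_s_eff eigenstrain amplitude (axial component).
#' @return `oracle_case` with `uniformity_tolerance` (CV) of 3%.
#' @export
make_eigenstrain_inclusion_case <- function(lambda_s_eff) {
  structure(list(
    name = "uniform_eigenstrain_inclusion",
    lambda_s_eff = lambda_s_eff,
    property = "interior stress uniform; stress linear in eigenstrain",
    uniformity_tolerance = 0.03
  ), class = "oracle_case")
}

#' FEM electrostatics solve for the dielectric-sphere verification mode
#'
#' Scalar dielectric Poisson solve with `V = -E0 * z` imposed on the outer
#' box boundary; the particle (core + shell) carries `eps_in`, the
#' surroundings `eps_out`.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param eps_in,eps_out relative permittivities.
#' @param E0 imposed field magnitude (V/m) along z.
#' @return list with nodal `V` and element `Er`, `Ez`, `Emag`, plus the
#'   volume-averaged interior field magnitude `E_interior`.
#' @export
solve_dielectric_sphere <- function(mesh, eps_in, eps_out, E0) {
  pre <- fem_precompute(mesh)
  coef <- ifelse(pre$region == "surroundings", eps_out, eps_in) * EPS0
  K <- assemble_scalar_laplace(pre, coef)
  nn <- pre$n_nodes
  fixed <- mesh$box_nodes
  free <- setdiff(seq_len(nn), fixed)
  V <- numeric(nn)
  V[fixed] <- -E0 * mesh$nodes[fixed, 2]
  rhs <- -as.numeric(K[free, fixed, drop = FALSE] %*% V[fixed])
  V[free] <- as.numeric(Matrix::solve(K[free, free, drop = FALSE], rhs))
  Vt <- matrix(V[pre$tri], ncol = 3)
  Er <- -rowSums(pre$b * Vt)
  Ez <- -rowSums(pre$c * Vt)
  inside <- pre$region != "surroundings"
  w <- pre$w[inside] / sum(pre$w[inside])
  list(V = V, Er = Er, Ez = Ez, Emag = sqrt(Er^2 + Ez^2),
       E_interior = sum(w * sqrt(Er[inside]^2 + Ez[inside]^2)))
}

#' Study scenario fixtures
#'
#' The two full default scenarios (culture medium and blood-vessel wall)
#' plus coarse-mesh smoke-test variants with fixed seeds.
#'
#' @return named list of four [scenario_config()] objects:
#'   `CM`, `BV`, `CM_smoke`, `BV_smoke`.
#' @export
generate_study_scenarios <- function() {
  list(
    CM = scenario_config(environment = environment_material("CM")),
    BV = scenario_config(environment = environment_material("BV")),
    CM_smoke = scenario_config(environment = environment_material("CM"),
                               mesh_resolution = "coarse", random_seed = 42L),
    BV_smoke = scenario_config(environment = environment_material("BV"),
                               mesh_resolution = "coarse", random_seed = 42L)
  )
}
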