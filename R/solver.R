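# Stationary coupled solve: magnetostrictive eigenstrain -> elasticity with
# piezoelectric coupling in the shell -> electrostatics everywhere.
#
# The chain is linear downstream of the magnetization, so for parameter
# sweeps the assembled coupled operator is factorized once and re-used for
# every right-hand side (see dc_sweep()).

# Default piezoelectric calibration factor.  The shell's stress-charge
# coupling matrix is not part of the published parameter set (it comes from
# a commercial material library); the package ships a literature tetragonal
# BaTiO3 set (e31 = -4.35, e33 = 17.5, e15 = 11.4 C/m^2) multiplied by this
# single scale factor, fixed once so that the default blood-vessel scenario
# at 2 T yields a pole-to-pole surface potential difference of 6.07 mV on
# the default mesh.  See the methods vignette for the calibration rationale.
PIEZO_SCALE_DEFAULT <- 0.01296839

#' Magnetostrictive eigenstrain from a magnetization field
#'
#' Isotropic quadratic deviatoric magnetostriction: for M along z,
#' `eps_zz = lambda_s (M/Ms)^2`, `eps_rr = eps_tt = -lambda_s/2 (M/Ms)^2`,
#' traceless by construction and zero outside the core.
#'
#' @param Mz_element element magnetization along z (A/m), zero outside core.
#' @param core a [core_material()].
#' @return list of element-wise eigenstrain components `er`, `et`, `ez`,
#'   `grz` (engineering shear, identically zero for z-aligned M).
#' @export
magnetostrictive_strain <- function(Mz_element, core = core_material()) {
  s <- core$lambda_s * (Mz_element / core$Ms_A_per_m)^2
  list(er = -s / 2, et = -s / 2, ez = s, grz = numeric(length(s)))
}

lame_parameters <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

# Element-wise material arrays for the coupled solve.  `override` supports
# the verification oracles (homogeneous elasticity, custom permittivities).
coupled_material_arrays <- function(pre, config, override = NULL) {
  m <- length(pre$area)
  reg <- pre$region
  lam <- mu <- eps <- e15 <- e31 <- e33 <- numeric(m)

  lc <- lame_parameters(config$core$E_Pa, config$core$nu)
  ls <- lame_parameters(config$shell$E_Pa, config$shell$nu)
  lam[reg == "core"] <- lc$lambda;  mu[reg == "core"] <- lc$mu
  lam[reg == "shell"] <- ls$lambda; mu[reg == "shell"] <- ls$mu
  env <- config$environment
  mech_all <- isTRUE(env$is_solid)
  if (mech_all) {
    le <- lame_parameters(env$E_Pa, env$nu)
    lam[reg == "surroundings"] <- le$lambda; mu[reg == "surroundings"] <- le$mu
  }
  eps[reg == "core"] <- EPS0 * config$core$eps_r
  eps[reg == "shell"] <- EPS0 * config$shell$eps_r
  eps[reg == "surroundings"] <- EPS0 * env$eps_r
  sc <- config$shell$piezo_scale
  e15[reg == "shell"] <- sc * config$shell$e15_C_per_m2
  e31[reg == "shell"] <- sc * config$shell$e31_C_per_m2
  e33[reg == "shell"] <- sc * config$shell$e33_C_per_m2

  if (!is.null(override)) for (nm in names(override)) {
    val <- override[[nm]]
    switch(nm,
      lambda = {lam <- val}, mu = {mu <- val}, eps = {eps <- val},
      e15 = {e15 <- val}, e31 = {e31 <- val}, e33 = {e33 <- val},
      mech_all = {mech_all <- val},
      stop("unknown override: ", nm, call. = FALSE)
    )
  }
  list(lambda = lam, mu = mu, eps = eps, e15 = e15, e31 = e31, e33 = e33,
       mech_all = mech_all)
}

# Build the coupled operator for a config + mesh; returns the factorized
# system and the index bookkeeping needed to solve for arbitrary eigenstrain
# loads.
build_coupled_operator <- function(mesh, config, override = NULL) {
  if (config$shell$sigma_S_per_m > 0 && is.null(override)) {
    # stored conductivities are not used by the dielectric potential solve
    message("note: shell conductivity ", config$shell$sigma_S_per_m,
            " S/m is stored but ignored by the electrostatic formulation")
  }
  pre <- fem_precompute(mesh)
  mat <- coupled_material_arrays(pre, config, override)
  nn <- pre$n_nodes

  mech_elems <- if (mat$mech_all) rep(TRUE, length(pre$area)) else pre$region != "surroundings"
  # zero out elastic stiffness on mechanically inactive elements
  lam <- ifelse(mech_elems, mat$lambda, 0)
  mu <- ifelse(mech_elems, mat$mu, 0)
  A <- assemble_coupled(pre, lam, mu, mat$eps, mat$e15, mat$e31, mat$e33)

  mech_nodes <- sort(unique(as.integer(pre$tri[mech_elems, ])))
  inactive_nodes <- setdiff(seq_len(nn), mech_nodes)
  fixed <- c(2L * nn + mesh$box_nodes)                       # V = 0 on box
  fixed <- c(fixed, 2L * intersect(mesh$axis_nodes, mech_nodes) - 1L)  # u_r = 0 on axis
  if (mat$mech_all) {
    fixed <- c(fixed, 2L * mesh$box_nodes - 1L, 2L * mesh$box_nodes)   # clamped box
  } else {
    # liquid surroundings: traction-free particle; pin rigid z-translation
    # at the particle centre node (origin)
    centre <- which.min(rowSums(mesh$nodes^2))
    fixed <- c(fixed, 2L * centre)
  }
  fixed <- c(fixed, 2L * inactive_nodes - 1L, 2L * inactive_nodes)
  fixed <- sort(unique(fixed))

  free <- setdiff(seq_len(3L * nn), fixed)
  Af <- A[free, free, drop = FALSE]
  dg <- abs(Matrix::diag(Af)); dg[dg == 0] <- 1
  s <- 1 / sqrt(dg)
  D <- Matrix::Diagonal(x = s)
  fac <- Matrix::lu(Matrix::drop0(D %*% Af %*% D))
  list(pre = pre, mat = mat, mesh = mesh, config = config,
       mech_elems = mech_elems, mech_nodes = mech_nodes,
       free = free, scale = s, fac = fac, nn = nn,
       lam = lam, mu = mu)
}

solve_coupled_with_operator <- function(op, eig) {
  f <- coupled_eigenstrain_rhs(op$pre, op$lam, op$mu, eig$er, eig$et, eig$ez, eig$grz)
  x <- numeric(3L * op$nn)
  y <- as.numeric(Matrix::solve(op$fac, op$scale * f[op$free]))
  x[op$free] <- op$scale * y
  ur <- x[2 * seq_len(op$nn) - 1]; uz <- x[2 * seq_len(op$nn)]
  V <- x[2L * op$nn + seq_len(op$nn)]
  ur[!seq_len(op$nn) %in% op$mech_nodes] <- NA_real_
  uz[!seq_len(op$nn) %in% op$mech_nodes] <- NA_real_

  pre <- op$pre
  urt <- matrix(ifelse(is.na(ur[pre$tri]), 0, ur[pre$tri]), ncol = 3)
  uzt <- matrix(ifelse(is.na(uz[pre$tri]), 0, uz[pre$tri]), ncol = 3)
  Vt <- matrix(V[pre$tri], ncol = 3)
  S_rr <- rowSums(pre$b * urt)
  S_tt <- rowSums(urt) / (3 * pre$rc)
  S_zz <- rowSums(pre$c * uzt)
  S_rz <- rowSums(pre$c * urt) + rowSums(pre$b * uzt)
  Er <- -rowSums(pre$b * Vt)
  Ez <- -rowSums(pre$c * Vt)
  lam <- op$lam; mu <- op$mu
  tr_el <- S_rr + S_tt + S_zz
  tr_eig <- eig$er + eig$et + eig$ez
  # stress T = C (S - eps*) - e^T E
  T_rr <- lam * (tr_el - tr_eig) + 2 * mu * (S_rr - eig$er) + op$mat$e31 * (-Ez)
  T_tt <- lam * (tr_el - tr_eig) + 2 * mu * (S_tt - eig$et) + op$mat$e31 * (-Ez)
  T_zz <- lam * (tr_el - tr_eig) + 2 * mu * (S_zz - eig$ez) + op$mat$e33 * (-Ez)
  T_rz <- mu * (S_rz - eig$grz) + op$mat$e15 * (-Er)
  structure(list(
    ur = ur, uz = uz, V = V,
    strain = cbind(rr = S_rr, tt = S_tt, zz = S_zz, rz = S_rz),
    stress = cbind(rr = T_rr, tt = T_tt, zz = T_zz, rz = T_rz),
    Er = Er, Ez = Ez, Emag = sqrt(Er^2 + Ez^2),
    mesh = op$mesh, region = pre$region
  ), class = "field_solution")
}

#' Coupled elasticity / piezoelectricity / electrostatics solve
#'
#' Solves the monolithic linear system for displacement and potential under
#' a prescribed eigenstrain load.  Mechanical domain: particle only with a
#' traction-free outer shell surface for the liquid culture-medium
#' environment; all regions with a clamped outer box for the solid
#' blood-vessel environment.  V is grounded on the outer box boundary;
#' u_r = 0 on the symmetry axis.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param eigenstrain element-wise eigenstrain from
#'   [magnetostrictive_strain()].
#' @param config a [scenario_config()].
#' @return a `field_solution`: nodal `ur`, `uz` (m; NA outside the mechanical
#'   domain), nodal `V` (volt), element `strain`, `stress` (Pa), element
#'   electric field `Er`, `Ez`, `Emag` (V/m).
#' @export
solve_coupled_mech_electro <- function(mesh, eigenstrain, config) {
  op <- build_coupled_operator(mesh, config)
  solve_coupled_with_operator(op, eigenstrain)
}

#' Full stationary magnetoelectric solve
#'
#' Chains [solve_magnetostatics()], [magnetostrictive_strain()] and
#' [solve_coupled_mech_electro()]; deterministic for a fixed config and mesh.
#'
#' @param config a [scenario_config()].
#' @param H_ext_T applied field (T) along z.
#' @param mesh optional pre-built mesh (rebuilt from the config otherwise).
#' @param operator optional pre-built coupled operator (for sweeps).
#' @return a `field_solution` with the `magnetostatic_solution` attached as
#'   `$magnetostatics`.
#' @export
stationary_solve <- function(config, H_ext_T, mesh = NULL, operator = NULL) {
  if (is.null(mesh)) {
    mesh <- build_mesh(config$geometry, config$mesh_resolution)
  }
  curve <- anhysteretic_curve(config$core$Ms_A_per_m, config$core$chi0)
  ms <- solve_magnetostatics(mesh, curve, H_ext_T)
  eig <- magnetostrictive_strain(ms$Mz, config$core)
  if (is.null(operator)) operator <- build_coupled_operator(mesh, config)
  sol <- solve_coupled_with_operator(operator, eig)
  sol$magnetostatics <- ms
  sol
}
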