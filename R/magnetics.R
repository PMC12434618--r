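# Magnetization constitutive models and the magnetostatic field solve.
#
# Stationary studies use an anhysteretic Langevin curve reparameterized so
# that the small-field slope is exactly the initial susceptibility chi0 and
# the large-field limit is Ms.  The time-dependent study uses the classic
# scalar Jiles-Atherton model on a lumped (volume-averaged) state with the
# analytic sphere demagnetizing factor N = 1/3; the stationary solver
# demonstrates separately that the spherical core is magnetized uniformly,
# which justifies the lumping.
#
# All applied fields are along +z (the magnetic easy axis); magnetization is
# reduced to its z component throughout.

langevin <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- x[small] / 3 - x[small]^3 / 45
  out[!small] <- 1 / tanh(x[!small]) - 1 / x[!small]
  out
}

#' Anhysteretic magnetization curve
#'
#' @param Ms_A_per_m saturation magnetization (A/m).
#' @param chi0 initial susceptibility; the curve's slope at H = 0.
#' @param form functional form; only `"langevin"` is calibrated against the
#'   study's printed potential-difference pair, `"tanh"` is provided for
#'   comparison.
#' @return object of class `anhysteretic_curve` (callable via
#'   [anhysteretic_magnetization()]).
#' @export
anhysteretic_curve <- function(Ms_A_per_m = 3.69e5, chi0 = 3,
                               form = c("langevin", "tanh")) {
  form <- match.arg(form)
  structure(list(Ms_A_per_m = Ms_A_per_m, chi0 = chi0, form = form),
            class = "anhysteretic_curve")
}

#' Evaluate the anhysteretic magnetization M(H_int)
#'
#' `M = Ms * L(3 chi0 H / Ms)` (Langevin `L`), an odd function with
#' `dM/dH(0) = chi0` and `M -> Ms` as `H -> Inf`.  `H_int` is the internal
#' field in A/m along z.
#'
#' @param H_int_A_per_m internal magnetic field (A/m), vectorized.
#' @param curve an [anhysteretic_curve()].
#' @return magnetization (A/m).
#' @export
anhysteretic_magnetization <- function(H_int_A_per_m, curve = anhysteretic_curve()) {
  Ms <- curve$Ms_A_per_m
  x <- 3 * curve$chi0 * H_int_A_per_m / Ms
  if (curve$form == "langevin") Ms * langevin(x) else Ms * tanh(x / 3)
}

#' Self-consistent magnetostatic solve on the axisymmetric mesh
#'
#' Reduced-scalar-potential formulation: with uniform applied field H_ext
#' along z and core magnetization M(r) z, the perturbation potential solves
#' `div(grad phi) = div(M z 1_core)` with phi = 0 on the outer box; the
#' element field is `H = H_ext z - grad phi` and the core constitutive law
#' `M = M_an(H_z)` is converged by damped Picard iteration.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param curve an [anhysteretic_curve()] (or a linear-susceptibility
#'   surrogate via `linear = chi` below).
#' @param H_ext_T applied flux density (T) along +z.
#' @param linear optional susceptibility; when non-NULL, replaces the curve by
#'   `M = linear * H` (used by verification oracles).
#' @param tol Picard tolerance on max |dM|/Ms.
#' @param max_iter iteration cap; non-convergence raises an error carrying the
#'   residual history.
#' @return object of class `magnetostatic_solution`: nodal potential `phi`,
#'   element fields `Hr`, `Hz` (A/m), element core magnetization `Mz` (A/m,
#'   0 outside the core), the volume-averaged core magnetization
#'   `M_core_mean`, its coefficient of variation `M_core_cv`, and iteration
#'   diagnostics.
#' @export
solve_magnetostatics <- function(mesh, curve = anhysteretic_curve(), H_ext_T,
                                 linear = NULL, tol = 1e-10, max_iter = 400L) {
  pre <- fem_precompute(mesh)
  H0 <- H_ext_T / MU0
  K <- assemble_scalar_laplace(pre, coef = rep(1, length(pre$area)))
  fixed <- mesh$box_nodes
  free <- setdiff(seq_len(pre$n_nodes), fixed)
  Kf <- K[free, free, drop = FALSE]
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Kf), LDL = FALSE, perm = TRUE)

  core <- pre$region == "core"
  Ms <- if (is.null(linear)) curve$Ms_A_per_m else 1
  constitutive <- function(Hz) {
    if (is.null(linear)) anhysteretic_magnetization(Hz, curve) else linear * Hz
  }
  scale_ref <- if (is.null(linear)) Ms else max(abs(H0), 1)

  Mz <- numeric(length(pre$area))
  Mz[core] <- constitutive(rep(H0, sum(core)))   # uniform-field initial guess
  resid <- numeric(0)
  # Picard stability: short-wavelength M modes see an effective demagnetizing
  # factor up to 1, so the iteration matrix eigenvalues reach -chi; damping
  # must satisfy d < 2/(1 + chi) for the stiffest mode.
  chi_max <- if (is.null(linear)) curve$chi0 else abs(linear)
  damp <- 1.5 / (1 + max(chi_max, 1))
  phi <- numeric(pre$n_nodes)
  for (it in seq_len(max_iter)) {
    f <- scalar_vector_source_rhs(pre, Sr = numeric(length(Mz)), Sz = Mz)
    phi_f <- as.numeric(Matrix::solve(fac, f[free]))
    phi <- numeric(pre$n_nodes); phi[free] <- phi_f
    # element field H = H0 z - grad phi
    gp_r <- rowSums(pre$b * matrix(phi[pre$tri], ncol = 3))
    gp_z <- rowSums(pre$c * matrix(phi[pre$tri], ncol = 3))
    Hz_e <- H0 - gp_z
    M_new <- Mz
    M_new[core] <- constitutive(Hz_e[core])
    r <- max(abs(M_new - Mz)) / scale_ref
    resid <- c(resid, r)
    Mz <- Mz + damp * (M_new - Mz)
    if (r < tol) break
  }
  if (resid[length(resid)] >= tol) {
    stop("magnetostatic Picard iteration did not converge; residual history: ",
         paste(signif(utils::tail(resid, 5), 3), collapse = ", "), call. = FALSE)
  }
  vol <- pre$w
  wcore <- vol[core] / sum(vol[core])
  Mmean <- sum(wcore * Mz[core])
  Mcv <- sqrt(sum(wcore * (Mz[core] - Mmean)^2)) / abs(Mmean)
  structure(list(
    phi = phi, Hr = -gp_r, Hz = Hz_e, Mz = Mz,
    M_core_mean = Mmean, M_core_cv = Mcv,
    H_ext_T = H_ext_T, iterations = it, residuals = resid
  ), class = "magnetostatic_solution")
}

# ---- Jiles-Atherton hysteresis -------------------------------------------

#' Initialize a Jiles-Atherton state
#'
#' @param params [ja_parameters()].
#' @param demag_factor demagnetizing factor N in \[0, 1\] (1/3 for a sphere);
#'   the effective field is `He = H_app - N*M + alpha*M`.
#' @param M,M_irr,H initial values (A/m); default demagnetized.
#' @return object of class `ja_state`.
#' @export
ja_state <- function(params = ja_parameters(), demag_factor = 1 / 3,
                     M = 0, M_irr = 0, H = 0) {
  stopifnot(demag_factor >= 0, demag_factor <= 1)
  structure(list(params = params, N = demag_factor,
                 M = M, M_irr = M_irr, H = H, delta = 1L),
            class = "ja_state")
}

#' Advance a Jiles-Atherton state to a new applied field
#'
#' Explicit sub-stepped Euler on the field increment: the irreversible
#' component follows `dM_irr/dH = (M_an - M_irr) / (k*delta - a_eff*(M_an -
#' M_irr))` with `a_eff = alpha - N`, `delta = sign(dH)`, and the standard
#' guard that suppresses unphysical negative susceptibility; the total is
#' `M = c*M_an(He) + (1-c)*M_irr`.  A step is subdivided until no substep
#' changes M by more than 2% of Ms.
#'
#' @param state a [ja_state()].
#' @param H_new_A_per_m new applied field (A/m).
#' @return the advanced `ja_state`.
#' @export
ja_update <- function(state, H_new_A_per_m) {
  p <- state$params
  a_eff <- p$alpha - state$N
  dH_tot <- H_new_A_per_m - state$H
  if (dH_tot == 0) return(state)
  man <- function(He) p$Ms_A_per_m * langevin(He / p$a_A_per_m)

  # total M is implicit through He = H + a_eff*M; relax to the consistent
  # (stable) solution at each substep, continuing from the previous M
  relax_M <- function(H, M0, Mi) {
    M <- M0
    for (j in 1:200) {
      Mt <- p$c_rev * man(H + a_eff * M) + (1 - p$c_rev) * Mi
      M_new <- 0.5 * M + 0.5 * Mt
      if (abs(M_new - M) < 1e-10 * p$Ms_A_per_m) return(M_new)
      M <- M_new
    }
    M
  }

  n_sub <- max(1L, ceiling(abs(dH_tot) / p$a_A_per_m))
  # below this field resolution any residual |dM| spike is a genuine
  # constitutive jump (mean-field fold), not integration error: accept it
  n_cap <- max(n_sub, ceiling(abs(dH_tot) / (1e-3 * p$a_A_per_m)))
  repeat {
    M <- state$M; Mi <- state$M_irr; H <- state$H
    dH <- dH_tot / n_sub
    delta <- sign(dH)
    ok <- TRUE
    for (s in seq_len(n_sub)) {
      He <- H + a_eff * M
      Man <- man(He)
      den <- p$k_A_per_m * delta - a_eff * (Man - Mi)
      # regularize the pinning-avalanche singularity: cap the differential
      # susceptibility by clamping |den| >= 0.01 k (sign delta)
      if (abs(den) < 0.01 * p$k_A_per_m) den <- 0.01 * p$k_A_per_m * delta
      chi <- (Man - Mi) / den
      # dissipation guard: the irreversible component only moves toward the
      # anhysteretic state ((M_an - M_irr) and dH of the same sign)
      if (!is.finite(chi) || (Man - Mi) * delta < 0 || chi < 0) chi <- 0
      Mi2 <- Mi + chi * dH
      H2 <- H + dH
      M2 <- relax_M(H2, M, Mi2)
      if (abs(M2 - M) > 0.02 * p$Ms_A_per_m && n_sub < n_cap) { ok <- FALSE; break }
      M <- M2; Mi <- Mi2; H <- H2
    }
    if (ok) break
    n_sub <- min(n_sub * 2L, n_cap)
  }
  M <- max(min(M, p$Ms_A_per_m), -p$Ms_A_per_m)
  structure(list(params = p, N = state$N, M = M, M_irr = Mi, H = H,
                 delta = as.integer(sign(dH_tot))),
            class = "ja_state")
}

#' Quasi-static major hysteresis loop
#'
#' Drives a demagnetized state to +H_max, then through a full
#' +H_max -> -H_max -> +H_max cycle and returns the closed loop branches.
#'
#' @param params [ja_parameters()].
#' @param H_max_T loop amplitude (T).
#' @param n_steps field steps per branch (>= 100).
#' @param demag_factor demagnetizing factor (default sphere).
#' @return data.frame with columns `H_T`, `H_A_per_m`, `M_A_per_m`, `branch`
#'   (`initial`, `descending`, `ascending`).
#' @export
hysteresis_loop <- function(params = ja_parameters(), H_max_T = 4,
                            n_steps = 200L, demag_factor = 1 / 3) {
  if (n_steps < 100) stop("hysteresis_loop: n_steps must be >= 100", call. = FALSE)
  Hm <- H_max_T / MU0
  st <- ja_state(params, demag_factor)
  path <- list(
    initial    = seq(0, Hm, length.out = n_steps + 1)[-1],
    descending = seq(Hm, -Hm, length.out = 2 * n_steps + 1)[-1],
    ascending  = seq(-Hm, Hm, length.out = 2 * n_steps + 1)[-1]
  )
  out <- list()
  for (br in names(path)) {
    H <- path[[br]]
    M <- numeric(length(H))
    for (i in seq_along(H)) {
      st <- ja_update(st, H[i])
      M[i] <- st$M
    }
    out[[br]] <- data.frame(H_T = H * MU0, H_A_per_m = H, M_A_per_m = M,
                            branch = br, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
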