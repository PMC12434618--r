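# Step-2 analysis: DC sweep curves (M, dV, alpha_ME), semi-corona E-field
# statistics, nano-electroporation regime classification and operating-field
# selection.

#' Pole-to-pole surface potential difference (mV)
#'
#' `max(V) - min(V)` over the shell outer-surface nodes.
#'
#' @param solution a `field_solution` (or any list with nodal `V` and a
#'   `mesh` carrying `surface_nodes`).
#' @return potential difference in mV.
#' @export
delta_v <- function(solution) {
  idx <- solution$mesh$surface_nodes
  if (!length(idx)) stop("delta_v: empty shell outer-surface node set", call. = FALSE)
  v <- solution$V[idx]
  (max(v) - min(v)) * 1e3
}

#' Magnetoelectric coefficient (mV / (Oe cm))
#'
#' `alpha_ME = dV / (H * phi)` with dV in mV, H in Oe and the particle
#' diameter phi in cm.
#'
#' @param dV_mV surface potential difference (mV).
#' @param H_Oe applied field (Oe), must be positive.
#' @param phi_cm particle diameter (cm); the full core+shell diameter
#'   (140 nm = 1.4e-5 cm by default).
#' @return alpha_ME in mV Oe^-1 cm^-1.
#' @export
alpha_me <- function(dV_mV, H_Oe, phi_cm = 1.4e-5) {
  if (any(H_Oe <= 0)) stop("alpha_me: H must be positive", call. = FALSE)
  if (any(phi_cm <= 0)) stop("alpha_me: diameter must be positive", call. = FALSE)
  dV_mV / (H_Oe * phi_cm)
}

#' Stationary DC field sweep
#'
#' Runs the full stationary magnetoelectric solve at each grid field and
#' records the volume-averaged core magnetization, the surface potential
#' difference and the magnetoelectric coefficient.  The mesh, the
#' magnetostatic operator and the coupled operator are each built once and
#' re-used across the grid.
#'
#' @param config a [scenario_config()].
#' @param grid_T optional sweep grid (T); defaults to the protocol grid.
#' @param mesh optional pre-built mesh.
#' @return data.frame of class `sweep_result` with columns `H_T`, `H_mT`,
#'   `H_Oe`, `M_A_per_m`, `dV_mV`, `alpha_ME`, `environment`.
#' @export
dc_sweep <- function(config, grid_T = NULL, mesh = NULL) {
  if (is.null(grid_T)) grid_T <- config$stimulation$sweep_grid_T
  if (is.null(mesh)) mesh <- build_mesh(config$geometry, config$mesh_resolution)
  op <- build_coupled_operator(mesh, config)
  curve <- anhysteretic_curve(config$core$Ms_A_per_m, config$core$chi0)
  phi_cm <- config$geometry$particle_diameter_m * 1e2

  rows <- lapply(grid_T, function(H) {
    ms <- solve_magnetostatics(mesh, curve, H)
    eig <- magnetostrictive_strain(ms$Mz, config$core)
    sol <- solve_coupled_with_operator(op, eig)
    dv <- delta_v(sol)
    data.frame(
      H_T = H, H_mT = H * 1e3, H_Oe = convert_field_units(H, "T", "Oe"),
      M_A_per_m = ms$M_core_mean, dV_mV = dv,
      alpha_ME = alpha_me(dv, convert_field_units(H, "T", "Oe"), phi_cm),
      environment = config$environment$name, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Weighted percentile (linear interpolation on the cumulative weights)
#'
#' @param x numeric values.
#' @param w non-negative weights.
#' @param probs probabilities in \[0, 1\].
#' @return percentile values.
#' @export
weighted_percentile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  # midpoint convention: P(x_k) = (cw_k - w_k/2) / sum(w)
  p <- (cw - w / 2) / cw[length(cw)]
  stats::approx(p, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Electric-field statistics over a semi-corona region
#'
#' Interpolates |E| (element-constant) at the corona sample points and
#' returns the weighted median and the 1st/99th percentiles.
#'
#' @param solution a `field_solution`.
#' @param region a [corona_region()].
#' @return object of class `corona_stats`: `distance_nm`, `median`, `p1`,
#'   `p99` (V/m), `n_samples`, `weighting`.
#' @export
corona_statistics <- function(solution, region) {
  E <- field_at_points(solution, region$points)
  if (anyNA(E)) stop("corona_statistics: region extends outside the mesh", call. = FALSE)
  q <- weighted_percentile(E, region$weights, c(0.01, 0.5, 0.99))
  structure(list(
    distance_nm = region$distance_nm, median = q[2], p1 = q[1], p99 = q[3],
    max = max(E), n_samples = length(E), weighting = region$weighting
  ), class = "corona_stats")
}

# Locate sample points in the mesh and return the element |E| there.
# Candidates are restricted by centroid radius for speed; assignment is by
# barycentric point-in-triangle test with a nearest-centroid fallback for
# points that graze element edges.
field_at_points <- function(solution, pts) {
  mesh <- solution$mesh
  cen <- element_centroids(mesh)
  rad_c <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  rad_p <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  lo <- min(rad_p) * 0.8; hi <- max(rad_p) * 1.25
  cand <- which(rad_c > lo & rad_c < hi)
  tri <- mesh$tri[cand, , drop = FALSE]
  n <- mesh$nodes
  x1 <- n[tri[, 1], 1]; y1 <- n[tri[, 1], 2]
  x2 <- n[tri[, 2], 1]; y2 <- n[tri[, 2], 2]
  x3 <- n[tri[, 3], 1]; y3 <- n[tri[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)

  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    px <- pts[i, 1]; py <- pts[i, 2]
    l1 <- ((x2 - px) * (y3 - py) - (x3 - px) * (y2 - py)) / det
    l2 <- ((x3 - px) * (y1 - py) - (x1 - px) * (y3 - py)) / det
    l3 <- 1 - l1 - l2
    inside <- which(l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9)
    e <- if (length(inside)) {
      inside[1]
    } else {
      which.min((cen[cand, 1] - px)^2 + (cen[cand, 2] - py)^2)
    }
    out[i] <- solution$Emag[cand[e]]
  }
  out
}

#' Classify the nano-electroporation regime from corona statistics
#'
#' Thresholds: reversible nano-electroporation window 2e4 to 5e4 V/m.
#' `irreversible` if p99 exceeds the upper threshold, `sub_threshold` if p99
#' is below the lower one, `reversible` if the whole p1-p99 band lies inside
#' the window, otherwise `mixed`.
#'
#' @param stats a `corona_stats`.
#' @param E_rev_low,E_rev_high window bounds (V/m).
#' @return object of class `regime_label` with fields `label` and the
#'   thresholds used.
#' @export
classify_regime <- function(stats, E_rev_low = 2e4, E_rev_high = 5e4) {
  label <- if (stats$p99 > E_rev_high) {
    "irreversible"
  } else if (stats$p99 < E_rev_low) {
    "sub_threshold"
  } else if (stats$p1 >= E_rev_low && stats$p99 <= E_rev_high) {
    "reversible"
  } else {
    "mixed"
  }
  structure(list(label = label, E_rev_low = E_rev_low, E_rev_high = E_rev_high,
                 p1 = stats$p1, p99 = stats$p99),
            class = "regime_label")
}

#' Select the three operating fields from a DC sweep
#'
#' `H2` is the alpha_ME maximizer.  `H3` is the plateau-onset field: scanning
#' consecutive grid pairs above `H2`, the first upper point whose potential
#' increment falls below `dV_increment_threshold_mV` (the rule is only
#' meaningful on the plateau approach; applied from the origin it would
#' trigger on the vanishing low-field increments).  `H1` is the largest grid
#' point below `H2` whose local alpha_ME slope is still within
#' `linear_slope_tol` of the initial slope (the low-field linear regime).
#'
#' @param sweep a [dc_sweep()] result, sorted by H.
#' @param dV_increment_threshold_mV plateau increment cutoff (mV).
#' @param linear_slope_tol relative slope tolerance for the H1 rule.
#' @return list with `H1_T`, `H2_T`, `H3_T` (NA with a `"not reached"`
#'   status when the plateau rule never triggers) and per-field diagnostics.
#' @export
select_operating_fields <- function(sweep, dV_increment_threshold_mV = 0.15,
                                    linear_slope_tol = 0.2) {
  if (nrow(sweep) < 3) stop("select_operating_fields: need >= 3 sweep points", call. = FALSE)
  if (is.unsorted(sweep$H_T, strictly = TRUE)) {
    stop("select_operating_fields: sweep grid must be strictly increasing", call. = FALSE)
  }
  i2 <- which.max(sweep$alpha_ME)
  H2 <- sweep$H_T[i2]

  inc <- diff(sweep$dV_mV)
  H3 <- NA_real_; h3_status <- "not reached"
  if (i2 < nrow(sweep)) {
    for (i in i2:(nrow(sweep) - 1)) {
      if (inc[i] < dV_increment_threshold_mV) {
        H3 <- sweep$H_T[i + 1]; h3_status <- "reached"; break
      }
    }
  }

  slope <- sweep$alpha_ME / sweep$H_T          # alpha grows ~linearly from 0
  s0 <- slope[1]
  lin <- which(abs(slope - s0) / s0 <= linear_slope_tol & sweep$H_T < H2)
  H1 <- if (length(lin)) sweep$H_T[max(lin)] else sweep$H_T[1]

  list(H1_T = H1, H2_T = H2, H3_T = H3, h3_status = h3_status,
       alpha_max = sweep$alpha_ME[i2],
       dV_increment_threshold_mV = dV_increment_threshold_mV)
}
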