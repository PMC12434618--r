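# Axisymmetric geometry and mesh generation.
#
# The computational domain is the r >= 0 half of a square box of side
# 2*box_half_side in the (r, z) plane, with the particle centred at the
# origin.  The mesh is a structured polar grid: rings of nodes at radii
# graded from the particle centre out to the box boundary, uniformly spaced
# in the polar angle theta in [0, pi] measured from the +z axis.  The
# outermost rings are stretched onto the square boundary so the grid is
# boundary-fitted.  The grid is symmetric under z -> -z (triangle diagonals
# are mirrored across the equator), which the field solvers exploit only
# implicitly: it makes the discrete potential exactly antisymmetric.

#' Core-shell particle geometry
#'
#' @param core_radius_m radius of the magnetostrictive core (m).
#' @param shell_thickness_m uniform piezoelectric shell thickness (m).
#' @param box_half_side_m half side length of the surrounding box (m).
#' @param outer_radius_m optional; must equal core radius + shell thickness.
#' @return object of class `core_shell_geometry` with derived fields
#'   `outer_radius_m` and `particle_diameter_m`.
#' @export
core_shell_geometry <- function(core_radius_m = 45e-9,
                                shell_thickness_m = 25e-9,
                                box_half_side_m = 1000e-9,
                                outer_radius_m = NULL,
                                particle_diameter_m = NULL) {
  r_out <- core_radius_m + shell_thickness_m
  if (!is.null(outer_radius_m) &&
      abs(outer_radius_m - r_out) > 1e-12 * max(r_out, 1e-12)) {
    stop("geometry: outer_radius must equal core_radius + shell_thickness",
         call. = FALSE)
  }
  if (!is.null(particle_diameter_m) &&
      abs(particle_diameter_m - 2 * r_out) > 1e-12 * max(r_out, 1e-12)) {
    stop("geometry: particle_diameter must equal 2 * (core_radius + shell_thickness)",
         call. = FALSE)
  }
  g <- structure(list(
    core_radius_m = core_radius_m,
    shell_thickness_m = shell_thickness_m,
    box_half_side_m = box_half_side_m,
    outer_radius_m = r_out,
    particle_diameter_m = 2 * r_out
  ), class = "core_shell_geometry")
  validate_geometry(g)
}

validate_geometry <- function(g) {
  if (!(g$core_radius_m > 0)) stop("geometry: core_radius must be positive", call. = FALSE)
  if (!(g$shell_thickness_m > 0)) stop("geometry: shell_thickness must be positive", call. = FALSE)
  if (!(g$box_half_side_m > 5 * g$outer_radius_m)) {
    stop("geometry: box_half_side must exceed 5 * outer_radius", call. = FALSE)
  }
  g
}

mesh_resolution_params <- function(resolution = c("default", "coarse", "fine")) {
  resolution <- match.arg(resolution)
  switch(resolution,
    coarse  = list(n_core = 9,  n_shell = 6,  n_theta = 48,  h0_m = 4e-9,   grow = 1.35, h_max_m = 160e-9),
    default = list(n_core = 15, n_shell = 13, n_theta = 72,  h0_m = 2e-9,   grow = 1.25, h_max_m = 110e-9),
    fine    = list(n_core = 30, n_shell = 25, n_theta = 120, h0_m = 1e-9,   grow = 1.18, h_max_m = 80e-9)
  )
}

#' Build the axisymmetric core-shell-box triangular mesh
#'
#' @param geometry a [core_shell_geometry()].
#' @param resolution `"coarse"`, `"default"` or `"fine"`; controls the number
#'   of radial layers through core and shell (shell element size about 5, 2
#'   and 1 nm respectively), the angular resolution, and the geometric grading
#'   of the surrounding layers.
#' @return object of class `axisym_mesh` with fields:
#'   `nodes` (n x 2 matrix, columns r and z, metres), `tri` (m x 3 integer
#'   connectivity, positively oriented), `region` (factor per element:
#'   core/shell/surroundings), node index vectors `axis_nodes`,
#'   `box_nodes`, `interface_nodes`, `surface_nodes`, and `geometry`.
#' @export
build_mesh <- function(geometry, resolution = "default") {
  stopifnot(inherits(geometry, "core_shell_geometry"))
  validate_geometry(geometry)
  p <- mesh_resolution_params(resolution)

  rc <- geometry$core_radius_m
  ro <- geometry$outer_radius_m
  b  <- geometry$box_half_side_m

  # radial ladder: core | shell | graded surroundings (normalized 0..1)
  radii_core  <- rc * seq_len(p$n_core) / p$n_core
  radii_shell <- rc + (ro - rc) * seq_len(p$n_shell) / p$n_shell
  steps <- p$h0_m * p$grow^(0:200)
  steps <- pmin(steps, p$h_max_m)
  cum <- cumsum(steps)
  span_min <- b - ro                      # shortest distance surface -> box
  n_keep <- which(cum >= span_min)[1]
  cum <- cum[seq_len(n_keep)]
  s_out <- cum / cum[n_keep]              # normalized fractions, last = 1
  n_out <- length(s_out)

  n_ring <- p$n_core + p$n_shell + n_out  # rings beyond the centre node
  theta <- seq(0, pi, length.out = p$n_theta + 1)
  st <- sin(theta); ct <- cos(theta)
  # distance from origin to the square boundary along each direction
  r_box_theta <- b / pmax(abs(ct), st)

  # node coordinates: centre node first, then ring-major
  nodes_r <- c(0, rep(NA_real_, n_ring * (p$n_theta + 1)))
  nodes_z <- c(0, rep(NA_real_, n_ring * (p$n_theta + 1)))
  ring_radius <- function(i, jt) {   # jt: theta index vector
    if (i <= p$n_core) return(rep(radii_core[i], length(jt)))
    if (i <= p$n_core + p$n_shell) return(rep(radii_shell[i - p$n_core], length(jt)))
    s <- s_out[i - p$n_core - p$n_shell]
    ro + s * (r_box_theta[jt] - ro)
  }
  idx <- function(i, j) 1L + (i - 1L) * (p$n_theta + 1L) + j   # j in 1..n_theta+1
  jt <- seq_len(p$n_theta + 1)
  for (i in seq_len(n_ring)) {
    R <- ring_radius(i, jt)
    nodes_r[idx(i, jt)] <- R * st
    nodes_z[idx(i, jt)] <- R * ct
  }
  nodes_r[abs(nodes_r) < 1e-18] <- 0     # snap axis nodes exactly

  # triangles: centre fan + quad strips with equator-mirrored diagonals
  tris <- vector("list", n_ring)
  tris[[1]] <- cbind(rep(1L, p$n_theta), idx(1L, 1:p$n_theta), idx(1L, 2:(p$n_theta + 1)))
  half <- p$n_theta / 2
  for (i in 2:n_ring) {
    a <- idx(i - 1L, 1:p$n_theta);       bnd <- idx(i - 1L, 2:(p$n_theta + 1))
    cme <- idx(i, 1:p$n_theta);          d <- idx(i, 2:(p$n_theta + 1))
    upper <- seq_len(p$n_theta) <= half  # z > 0 half: mirror diagonals below
    tri_a <- matrix(NA_integer_, p$n_theta, 3)
    tri_b <- matrix(NA_integer_, p$n_theta, 3)
    tri_a[upper, ] <- cbind(a[upper], cme[upper], d[upper])
    tri_b[upper, ] <- cbind(a[upper], d[upper], bnd[upper])
    tri_a[!upper, ] <- cbind(a[!upper], cme[!upper], bnd[!upper])
    tri_b[!upper, ] <- cbind(bnd[!upper], cme[!upper], d[!upper])
    tris[[i]] <- rbind(tri_a, tri_b)
  }
  tri <- do.call(rbind, tris)

  nodes <- cbind(r = nodes_r, z = nodes_z)
  # ensure positive orientation (counter-clockwise in (r, z))
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  det2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  flip <- det2 < 0
  tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]

  cen_r <- (x1 + x2 + x3) / 3
  radius_cen <- sqrt(cen_r^2 + ((y1 + y2 + y3) / 3)^2)
  region <- factor(
    ifelse(radius_cen < rc, "core", ifelse(radius_cen < ro, "shell", "surroundings")),
    levels = c("core", "shell", "surroundings")
  )

  node_radius <- sqrt(nodes_r^2 + nodes_z^2)
  tol <- 1e-6 * rc
  mesh <- structure(list(
    nodes = nodes, tri = tri, region = region,
    axis_nodes = which(nodes_r <= tol),
    box_nodes = which(pmax(nodes_r, abs(nodes_z)) >= b - 1e-6 * b),
    interface_nodes = which(abs(node_radius - rc) <= tol),
    surface_nodes = which(abs(node_radius - ro) <= tol),
    geometry = geometry, resolution = resolution,
    n_theta = p$n_theta
  ), class = "axisym_mesh")
  validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  if (any(mesh$nodes[, 1] < 0)) stop("mesh: negative r coordinate", call. = FALSE)
  a <- element_areas(mesh)
  if (any(a <= 0)) stop("mesh: inverted or degenerate element", call. = FALSE)
  if (any(table(mesh$region) == 0)) stop("mesh: empty region", call. = FALSE)
  invisible(mesh)
}

element_areas <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tri
  x1 <- n[t[, 1], 1]; y1 <- n[t[, 1], 2]
  x2 <- n[t[, 2], 1]; y2 <- n[t[, 2], 2]
  x3 <- n[t[, 3], 1]; y3 <- n[t[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

element_centroids <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tri
  cbind(r = (n[t[, 1], 1] + n[t[, 2], 1] + n[t[, 3], 1]) / 3,
        z = (n[t[, 1], 2] + n[t[, 2], 2] + n[t[, 3], 2]) / 3)
}

# revolved element volumes 2*pi*r_c*A (m^3)
element_volumes <- function(mesh) {
  2 * pi * element_centroids(mesh)[, "r"] * element_areas(mesh)
}

#' Semi-corona sampling region around the particle
#'
#' Builds a Monte-Carlo sample of the annular region between the shell outer
#' surface (70 nm) and an outer radius of 75, 80 or 90 nm, corresponding to
#' distances of 5, 10 or 20 nm from the particle surface.  Sampling is
#' uniform with respect to the revolved (3D spherical-shell) volume measure
#' by default, or the half-plane area measure; per-sample weights are equal
#' and sum to the corresponding region measure.
#'
#' @param mesh an [build_mesh()] mesh (defines the surface radius).
#' @param distance_nm one of 5, 10, 20.
#' @param n_samples number of sample points (>= 1000).
#' @param seed integer seed; same seed gives the identical sample set.
#' @param weighting `"volume"` (revolved measure, default) or `"area"`
#'   (half-plane measure).
#' @return object of class `corona_region` with `points` (n x 2, r/z in m),
#'   `weights` (summing to the region measure), radii and the weighting mode.
#' @export
corona_region <- function(mesh, distance_nm, n_samples = 4000L, seed = 1L,
                          weighting = c("volume", "area")) {
  weighting <- match.arg(weighting)
  if (!distance_nm %in% c(5, 10, 20)) {
    stop("corona distance must be one of 5, 10, 20 nm", call. = FALSE)
  }
  if (n_samples < 1000) stop("corona: n_samples must be >= 1000", call. = FALSE)
  r_in <- mesh$geometry$outer_radius_m
  r_out <- r_in + distance_nm * 1e-9
  rng <- local({
    set.seed(as.integer(seed))
    list(u = stats::runif(n_samples), v = stats::runif(n_samples))
  })
  if (weighting == "volume") {
    R <- (r_in^3 + rng$u * (r_out^3 - r_in^3))^(1 / 3)
    costh <- 2 * rng$v - 1
    th <- acos(costh)
    measure <- 4 * pi / 3 * (r_out^3 - r_in^3)
  } else {
    R <- sqrt(r_in^2 + rng$u * (r_out^2 - r_in^2))
    th <- pi * rng$v
    measure <- pi / 2 * (r_out^2 - r_in^2)
  }
  structure(list(
    points = cbind(r = R * sin(th), z = R * cos(th)),
    weights = rep(measure / n_samples, n_samples),
    inner_radius_m = r_in, outer_radius_m = r_out,
    distance_nm = distance_nm, weighting = weighting, seed = as.integer(seed)
  ), class = "corona_region")
}

#' Export a mesh to legacy-ASCII VTK (triangular, with optional cell data)
#'
#' @param mesh an `axisym_mesh`.
#' @param path output `.vtk` file.
#' @param point_data named list of per-node numeric vectors.
#' @param cell_data named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "axisymmetric half-plane mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(sprintf("%.12e %.12e 0.0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L, mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.12e", point_data[[nm]]), con)
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.12e", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}
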