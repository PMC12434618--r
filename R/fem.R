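# Axisymmetric P1 finite-element assembly.
#
# Linear triangles for every unknown (displacement components u_r, u_z and
# electric potential V); element-constant strain, stress and fields.  The
# axisymmetric measure 2*pi*r dA is integrated with one-point (centroid)
# quadrature, the standard choice for P1 axisymmetric elements: the hoop
# strain u_r/r is evaluated at the centroid radius, which is strictly
# positive for all elements including those touching the axis.
#
# Strain ordering: (S_rr, S_tt, S_zz, S_rz) with engineering shear
# S_rz = du_r/dz + du_z/dr.  Piezoelectric stress-charge form with poling
# along +z: D_r = e15*S_rz, D_z = e31*(S_rr + S_tt) + e33*S_zz.

fem_precompute <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tri
  x1 <- n[t[, 1], 1]; y1 <- n[t[, 1], 2]
  x2 <- n[t[, 2], 1]; y2 <- n[t[, 2], 2]
  x3 <- n[t[, 3], 1]; y3 <- n[t[, 3], 2]
  A <- 0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  # P1 shape gradients: dN_i/dr = b_i, dN_i/dz = c_i
  b1 <- (y2 - y3) / (2 * A); b2 <- (y3 - y1) / (2 * A); b3 <- (y1 - y2) / (2 * A)
  c1 <- (x3 - x2) / (2 * A); c2 <- (x1 - x3) / (2 * A); c3 <- (x2 - x1) / (2 * A)
  rc <- (x1 + x2 + x3) / 3
  list(
    tri = t, area = A, rc = rc, zc = (y1 + y2 + y3) / 3,
    b = cbind(b1, b2, b3), c = cbind(c1, c2, c3),
    w = 2 * pi * rc * A,            # revolved volume weight
    region = mesh$region, n_nodes = nrow(n)
  )
}

# Scalar Laplace-type operator: K_ij = sum_e w_e coef_e (b_i b_j + c_i c_j).
assemble_scalar_laplace <- function(pre, coef) {
  m <- length(pre$area)
  ii <- jj <- vv <- vector("list", 9)
  k <- 1
  for (a in 1:3) for (bb in 1:3) {
    ii[[k]] <- pre$tri[, a]
    jj[[k]] <- pre$tri[, bb]
    vv[[k]] <- pre$w * coef * (pre$b[, a] * pre$b[, bb] + pre$c[, a] * pre$c[, bb])
    k <- k + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(pre$n_nodes, pre$n_nodes))
}

# RHS for the scalar problem from an element-wise vector source (Sr, Sz):
# f_i = sum_e w_e (Sr b_i + Sz c_i)   (weak divergence of the source field)
scalar_vector_source_rhs <- function(pre, Sr, Sz) {
  f <- numeric(pre$n_nodes)
  for (a in 1:3) {
    contrib <- pre$w * (Sr * pre$b[, a] + Sz * pre$c[, a])
    f <- f + tabulate_sum(pre$tri[, a], contrib, pre$n_nodes)
  }
  f
}

tabulate_sum <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)          # rows keyed by unique sorted index
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# local dof tables for the 6 mechanical dofs (u_r1..3, u_z1..3):
# B-matrix rows per dof as element-wise vectors
mech_B_rows <- function(pre) {
  inv3r <- 1 / (3 * pre$rc)
  B1 <- B2 <- B3 <- B4 <- vector("list", 6)
  for (i in 1:3) {        # u_r dofs
    B1[[i]] <- pre$b[, i]
    B2[[i]] <- rep(0, length(pre$rc)) + inv3r
    B3[[i]] <- rep(0, length(pre$rc))
    B4[[i]] <- pre$c[, i]
  }
  for (i in 1:3) {        # u_z dofs
    B1[[3 + i]] <- rep(0, length(pre$rc))
    B2[[3 + i]] <- rep(0, length(pre$rc))
    B3[[3 + i]] <- pre$c[, i]
    B4[[3 + i]] <- pre$b[, i]
  }
  list(B1 = B1, B2 = B2, B3 = B3, B4 = B4)
}

# Assemble the monolithic coupled (u, V) system.
#
# lambda_e, mu_e: element Lame parameters (0 on mechanically inactive elements)
# eps_e: element permittivity (absolute, F/m)
# e15_e, e31_e, e33_e: element piezo coefficients (0 outside the shell)
# Numbering: u_r(node i) -> 2i-1, u_z(node i) -> 2i, V(node i) -> 2*nn + i.
assemble_coupled <- function(pre, lambda_e, mu_e, eps_e, e15_e, e31_e, e33_e) {
  nn <- pre$n_nodes
  Br <- mech_B_rows(pre)
  d <- vector("list", 6)                       # divergence row per dof
  for (a in 1:6) d[[a]] <- Br$B1[[a]] + Br$B2[[a]] + Br$B3[[a]]
  gdof <- function(a) {                        # global dof for local mech dof a
    node <- pre$tri[, ((a - 1) %% 3) + 1]
    if (a <= 3) 2L * node - 1L else 2L * node
  }

  ii <- jj <- vv <- list(); k <- 1
  push <- function(i, j, x) {
    ii[[k]] <<- i; jj[[k]] <<- j; vv[[k]] <<- x; k <<- k + 1
  }
  # K_uu
  for (a in 1:6) for (bb in 1:6) {
    val <- pre$w * (lambda_e * d[[a]] * d[[bb]] +
                    2 * mu_e * (Br$B1[[a]] * Br$B1[[bb]] +
                                Br$B2[[a]] * Br$B2[[bb]] +
                                Br$B3[[a]] * Br$B3[[bb]]) +
                    mu_e * Br$B4[[a]] * Br$B4[[bb]])
    push(gdof(a), gdof(bb), val)
  }
  # K_uv and its transpose
  for (a in 1:6) for (j in 1:3) {
    val <- pre$w * (e15_e * Br$B4[[a]] * pre$b[, j] +
                    (e31_e * (Br$B1[[a]] + Br$B2[[a]]) + e33_e * Br$B3[[a]]) * pre$c[, j])
    vj <- 2L * nn + pre$tri[, j]
    push(gdof(a), vj, val)
    push(vj, gdof(a), val)
  }
  # -K_vv
  for (i in 1:3) for (j in 1:3) {
    val <- -pre$w * eps_e * (pre$b[, i] * pre$b[, j] + pre$c[, i] * pre$c[, j])
    push(2L * nn + pre$tri[, i], 2L * nn + pre$tri[, j], val)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(3L * nn, 3L * nn))
}

# RHS from an eigenstrain load (element-wise 4-vector er, et, ez, grz):
# f_a = sum_e w_e B_a : (C eps*)
coupled_eigenstrain_rhs <- function(pre, lambda_e, mu_e, er, et, ez, grz) {
  nn <- pre$n_nodes
  Br <- mech_B_rows(pre)
  tr <- er + et + ez
  f <- numeric(3L * nn)
  for (a in 1:6) {
    val <- pre$w * (lambda_e * tr * (Br$B1[[a]] + Br$B2[[a]] + Br$B3[[a]]) +
                    2 * mu_e * (Br$B1[[a]] * er + Br$B2[[a]] * et + Br$B3[[a]] * ez) +
                    mu_e * Br$B4[[a]] * grz)
    node <- pre$tri[, ((a - 1) %% 3) + 1]
    dof <- if (a <= 3) 2L * node - 1L else 2L * node
    f <- f + tabulate_sum(dof, val, 3L * nn)
  }
  f
}

# Solve A x = b with Dirichlet dofs fixed to zero, using symmetric diagonal
# equilibration (the mechanical and electric blocks differ by ~20 orders of
# magnitude in natural SI scaling).
solve_constrained <- function(A, b, fixed) {
  n <- nrow(A)
  free <- setdiff(seq_len(n), fixed)
  Af <- A[free, free, drop = FALSE]
  bf <- b[free]
  dg <- abs(Matrix::diag(Af))
  dg[dg == 0] <- 1
  s <- 1 / sqrt(dg)
  D <- Matrix::Diagonal(x = s)
  As <- D %*% Af %*% D
  ys <- Matrix::solve(As, s * bf)
  x <- numeric(n)
  x[free] <- s * as.numeric(ys)
  x
}
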