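test_that("anhysteretic curve has slope chi0 at zero, saturates at Ms, and is odd", {
  cv <- anhysteretic_curve()
  h <- 1e-3
  slope <- (anhysteretic_magnetization(h, cv) - anhysteretic_magnetization(-h, cv)) / (2 * h)
  expect_equal(slope, 3, tolerance = 1e-6)
  expect_equal(anhysteretic_magnetization(1e12, cv), 3.69e5, tolerance = 1e-6)
  H <- c(1e3, 1e4, 1e5, 1e6)
  expect_equal(anhysteretic_magnetization(-H, cv), -anhysteretic_magnetization(H, cv))
  expect_equal(anhysteretic_magnetization(0, cv), 0)
})

test_that("magnetostatic solve matches the linear-sphere closed form and a fixed-point oracle", {
  # independent brute-force oracle: lumped fixed point M = chi*(H0 - M/3)
  chi <- 3; H0 <- 0.04 / (4e-7 * pi)
  M_fp <- 0
  for (i in 1:500) M_fp <- 0.5 * M_fp + 0.5 * chi * (H0 - M_fp / 3)
  oc <- make_linear_sphere_case(chi, 0.04)
  expect_equal(M_fp, oc$reference, tolerance = 1e-10)

  sol <- fx("ms_linear_40mT", function() {
    solve_magnetostatics(default_mesh(), H_ext_T = 0.04, linear = 3)
  })
  expect_equal(sol$M_core_mean, oc$reference, tolerance = 0.02)
  expect_lt(sol$M_core_cv, 0.05)   # near-uniform interior magnetization
})

test_that("without a particle the field is the uniform background", {
  sol <- solve_magnetostatics(coarse_mesh(), H_ext_T = 0.1, linear = 0)
  H0 <- 0.1 / (4e-7 * pi)
  expect_equal(max(abs(sol$phi)), 0)
  expect_equal(range(sol$Hz), c(H0, H0))
})

test_that("strong-field solve saturates the core and M(H) is monotone toward Ms", {
  s2 <- bv_solution_default(2)$magnetostatics
  expect_gt(s2$M_core_mean / 3.69e5, 0.97)
  expect_lt(s2$M_core_cv, 0.05)
  # plateau behaviour on the coarse mesh across rising fields
  Ms <- sapply(c(0.65, 1, 2, 4), function(H) {
    solve_magnetostatics(coarse_mesh(), anhysteretic_curve(), H)$M_core_mean
  })
  expect_true(all(diff(Ms) > 0))
  expect_gt(Ms[4] / 3.69e5, 0.98)
})

test_that("fully reversible J-A limit collapses onto the anhysteretic curve", {
  p <- ja_parameters(c_rev = 1)
  st <- ja_state(p, demag_factor = 0)
  H <- seq(0, 1e6, length.out = 200)
  M <- numeric(length(H))
  for (i in seq_along(H)) { st <- ja_update(st, H[i]); M[i] <- st$M }
  # c = 1: M = Man(He) with He = H + alpha*M (self-consistent anhysteretic)
  for (i in c(50, 120, 200)) {
    Man <- p$Ms_A_per_m * (1 / tanh((H[i] + p$alpha * M[i]) / p$a_A_per_m) -
                             p$a_A_per_m / (H[i] + p$alpha * M[i]))
    expect_equal(M[i], Man, tolerance = 1e-3)
  }
})

test_that("major loop closes, dissipates, and respects the Ms bound", {
  loop <- fx("ja_loop", function() hysteresis_loop(ja_parameters(), 4, 200))
  expect_true(all(abs(loop$M_A_per_m) <= 3.69e5 * (1 + 1e-9)))
  desc <- loop[loop$branch == "descending", ]
  asc <- loop[loop$branch == "ascending", ]
  # closure at +Hmax
  expect_equal(asc$M_A_per_m[nrow(asc)], desc$M_A_per_m[1],
               tolerance = 0.005 * 3.69e5 / abs(desc$M_A_per_m[1]))
  # saturation at the tips
  expect_gt(abs(desc$M_A_per_m[1]) / 3.69e5, 0.95)
  # hysteresis: positive enclosed area and positive remanence
  i0 <- which.min(abs(desc$H_A_per_m))
  expect_gt(desc$M_A_per_m[i0], 0)
  area <- -sum(diff(desc$H_A_per_m) * (desc$M_A_per_m[-1] + desc$M_A_per_m[-nrow(desc)]) / 2) -
    sum(diff(asc$H_A_per_m) * (asc$M_A_per_m[-1] + asc$M_A_per_m[-nrow(asc)]) / 2)
  expect_gt(area, 0)
  # antisymmetry of the closed loop under (H, M) -> (-H, -M)
  M_desc_at <- stats::approx(desc$H_A_per_m, desc$M_A_per_m, xout = -asc$H_A_per_m)$y
  expect_lt(max(abs(M_desc_at + asc$M_A_per_m), na.rm = TRUE) / 3.69e5, 0.01)
})

test_that("weak-pinning reversible limit collapses the loop onto the anhysteretic curve", {
  p <- ja_parameters(k_A_per_m = 1, c_rev = 1)
  loop <- hysteresis_loop(p, 2, 100, demag_factor = 0)
  desc <- loop[loop$branch == "descending", ]
  He <- desc$H_A_per_m + p$alpha * desc$M_A_per_m
  Man <- p$Ms_A_per_m * ifelse(abs(He) < 1,
                               He / (3 * p$a_A_per_m),
                               1 / tanh(He / p$a_A_per_m) - p$a_A_per_m / He)
  expect_lt(max(abs(desc$M_A_per_m - Man)) / p$Ms_A_per_m, 1e-3)
})

test_that("J-A magnetization stays bounded on random field paths", {
  set.seed(20)
  for (rep in 1:5) {
    st <- ja_state(ja_parameters())
    H <- cumsum(stats::rnorm(150, sd = 2e5))
    for (h in H) {
      st <- ja_update(st, h)
      expect_lte(abs(st$M), 3.69e5)
    }
  }
})
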