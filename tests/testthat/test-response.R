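test_that("delta_v is the pole-to-pole extreme difference in mV", {
  fake <- list(V = c(3.00e-3, -3.07e-3, 0),
               mesh = list(surface_nodes = 1:3))
  expect_equal(delta_v(fake), 6.07)
  fake$V <- rep(1e-3, 3)
  expect_equal(delta_v(fake), 0)
  fake$mesh$surface_nodes <- integer(0)
  expect_error(delta_v(fake), "empty")
})

test_that("alpha_ME definition is consistent with the published example numbers", {
  # dV = 6.22 mV at 4 T (= 40000 Oe) with phi = 140 nm = 1.4e-5 cm
  a <- alpha_me(6.22, 40000, 1.4e-5)
  expect_equal(a, 6.22 / (40000 * 1.4e-5), tolerance = 1e-12)
  expect_equal(a, 11.107, tolerance = 1e-3)
  expect_equal(alpha_me(0, 100), 0)
  expect_error(alpha_me(1, 0), "positive")
})

test_that("weighted percentiles agree with a brute-force oracle", {
  brute <- function(x, w, p) {
    o <- order(x); x <- x[o]; w <- w[o]
    cw <- (cumsum(w) - w / 2) / sum(w)
    stats::approx(cw, x, xout = p, rule = 2, ties = "ordered")$y
  }
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    x <- stats::rnorm(n)
    w <- stats::runif(n, 0.1, 2)
    p <- sort(stats::runif(4))
    expect_equal(weighted_percentile(x, w, p), brute(x, w, p))
  }
  # equal weights, median of odd-length sample = middle order statistic
  x <- c(5, 1, 9, 3, 7)
  expect_equal(weighted_percentile(x, rep(1, 5), 0.5), 5)
})

test_that("uniform field over a corona gives degenerate statistics", {
  m <- coarse_mesh()
  sol <- list(Emag = rep(1234, nrow(m$tri)), mesh = m)
  cr <- corona_region(m, 5, 1000, 1)
  st <- corona_statistics(sol, cr)
  expect_equal(st$median, 1234)
  expect_equal(st$p1, 1234)
  expect_equal(st$p99, 1234)
})

test_that("regime classification follows the percentile thresholds", {
  mk <- function(p1, p99) structure(list(p1 = p1, median = (p1 + p99) / 2, p99 = p99),
                                    class = "corona_stats")
  expect_equal(classify_regime(mk(3.14e4, 4.67e4))$label, "reversible")
  expect_equal(classify_regime(mk(4.85e4, 7.21e4))$label, "irreversible")
  expect_equal(classify_regime(mk(1.21e4, 1.80e4))$label, "sub_threshold")
  expect_equal(classify_regime(mk(1.5e4, 4.0e4))$label, "mixed")
  expect_equal(classify_regime(mk(5.1e4, 5.2e4))$label, "irreversible")
})

test_that("operating-field selection applies the increment rule above the efficiency peak", {
  H <- seq(0.1, 1.5, by = 0.05)
  # synthetic curve: quadratic onset then saturation, so the efficiency
  # dV/H rises, peaks and falls like the physical one
  dV <- 6 * (1 - exp(-(H / 0.5)^2))
  alpha <- dV / (H * 1e4 * 1.4e-5)
  sw <- data.frame(H_T = H, dV_mV = dV, alpha_ME = alpha)
  sel <- select_operating_fields(sw, dV_increment_threshold_mV = 0.15)
  expect_equal(sel$H2_T, H[which.max(alpha)])
  inc <- diff(dV)
  i2 <- which.max(alpha)
  first <- which(inc[i2:(length(H) - 1)] < 0.15)[1] + i2
  expect_equal(sel$H3_T, H[first])
  expect_lt(sel$H1_T, sel$H2_T)

  # strictly linear dV with increments above threshold: plateau never reached
  sw_lin <- data.frame(H_T = H, dV_mV = 10 * H,
                       alpha_ME = 10 / (1e4 * 1.4e-5) + 0 * H)
  sel_lin <- select_operating_fields(sw_lin, dV_increment_threshold_mV = 0.15)
  expect_true(is.na(sel_lin$H3_T))
  expect_equal(sel_lin$h3_status, "not reached")

  expect_error(select_operating_fields(sw[3:1, ]), "increasing")
  expect_error(select_operating_fields(sw[1:2, ]), ">= 3")
})

test_that("alpha_ME recomputed from stored dV and H reproduces the stored column", {
  sw <- bv_sweep_default()
  expect_equal(sw$alpha_ME, sw$dV_mV / (sw$H_Oe * 1.4e-5), tolerance = 1e-12)
  expect_true(all(sw$dV_mV >= 0))
  expect_true(!is.unsorted(sw$dV_mV))       # dV non-decreasing in H
})
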