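test_that("mesh satisfies its structural invariants", {
  m <- coarse_mesh()
  expect_true(all(m$nodes[, 1] >= 0))
  expect_true(all(menpsim:::element_areas(m) > 0))
  expect_setequal(levels(m$region), c("core", "shell", "surroundings"))
  expect_true(all(table(m$region) > 0))
  expect_gt(length(m$axis_nodes), 0)
  expect_gt(length(m$box_nodes), 0)
  # interface and surface rings are closed curves from axis to axis
  for (set in list(m$interface_nodes, m$surface_nodes)) {
    expect_equal(sum(abs(m$nodes[set, 1]) < 1e-15), 2)  # two polar nodes
    expect_equal(length(set), m$n_theta + 1)
  }
})

test_that("region areas match the analytic half-disc values and are conserved under refinement", {
  rc <- 45e-9; ro <- 70e-9
  ref_core <- pi * rc^2 / 2
  ref_shell <- pi * (ro^2 - rc^2) / 2
  areas <- list()
  for (res in c("coarse", "default")) {
    m <- if (res == "coarse") coarse_mesh() else default_mesh()
    a <- menpsim:::element_areas(m)
    areas[[res]] <- c(core = sum(a[m$region == "core"]),
                      shell = sum(a[m$region == "shell"]))
    expect_equal(areas[[res]][["core"]], ref_core, tolerance = 2e-3)
    expect_equal(areas[[res]][["shell"]], ref_shell, tolerance = 2e-3)
  }
  # refinement changes region areas by < 0.1%
  expect_equal(areas$default[["core"]], areas$coarse[["core"]], tolerance = 1e-3)
  m1 <- coarse_mesh(); m2 <- default_mesh()
  expect_gt(nrow(m2$tri), nrow(m1$tri))
})

test_that("shell is resolved by at least 5 element layers at default resolution", {
  m <- default_mesh()
  cen <- menpsim:::element_centroids(m)
  rad <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  shell_r <- rad[m$region == "shell"]
  # distinct radial bands along the equator direction
  eq <- which(m$region == "shell" & abs(cen[, 2]) < 5e-9)
  expect_gte(length(unique(round(rad[eq] * 1e10))) / 2, 5)
})

test_that("degenerate geometry is rejected before meshing", {
  expect_error(core_shell_geometry(shell_thickness_m = 0))
  g <- core_shell_geometry()
  g$shell_thickness_m <- 0; g$outer_radius_m <- g$core_radius_m
  expect_error(build_mesh(g), "shell_thickness")
})

test_that("corona samples stay inside their annulus and weights sum to the region measure", {
  m <- coarse_mesh()
  for (d in c(5, 10, 20)) {
    for (wm in c("volume", "area")) {
      cr <- corona_region(m, d, n_samples = 2000, seed = 3, weighting = wm)
      rad <- sqrt(cr$points[, 1]^2 + cr$points[, 2]^2)
      expect_true(all(rad >= 70e-9 - 1e-15))
      expect_true(all(rad <= (70 + d) * 1e-9 + 1e-15))
      expect_true(all(cr$points[, 1] >= 0))
      ref <- if (wm == "volume") {
        4 * pi / 3 * (((70 + d) * 1e-9)^3 - (70e-9)^3)
      } else {
        pi / 2 * (((70 + d) * 1e-9)^2 - (70e-9)^2)
      }
      expect_equal(sum(cr$weights), ref, tolerance = 0.005)
    }
  }
})

test_that("corona sampling is deterministic in the seed and rejects bad distances", {
  m <- coarse_mesh()
  a <- corona_region(m, 5, 1000, seed = 11)
  b <- corona_region(m, 5, 1000, seed = 11)
  c <- corona_region(m, 5, 1000, seed = 12)
  expect_identical(a$points, b$points)
  expect_false(identical(a$points, c$points))
  expect_error(corona_region(m, 7, 1000, 1), "5, 10, 20")
  expect_error(corona_region(m, 5, 100, 1), "1000")
})

test_that("corona samples are uniform in the revolved volume measure", {
  m <- coarse_mesh()
  cr <- corona_region(m, 20, n_samples = 20000, seed = 5, weighting = "volume")
  rad <- sqrt(cr$points[, 1]^2 + cr$points[, 2]^2)
  # cube of radius should be uniform between r_in^3 and r_out^3
  u <- (rad^3 - (70e-9)^3) / ((90e-9)^3 - (70e-9)^3)
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})
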