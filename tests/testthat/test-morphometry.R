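test_that("internal volume modes bracket the hemisphere analytically", {
  hemi <- hemisphere_mesh(r = 1)
  v_cap <- internal_volume(hemi, "capped")
  v_fan <- internal_volume(hemi, "origin_fan")
  expect_equal(v_cap, 2 * pi / 3, tolerance = 0.005)
  expect_equal(v_fan, pi / 2, tolerance = 0.005)
  # the gap is exactly the cone from the surface centroid (z = r/2) to the
  # boundary circle: pi/6 per unit r^3
  expect_equal(v_cap - v_fan, pi / 6, tolerance = 0.01)
})

test_that("closed surfaces give the same volume in either mode", {
  sph <- make_icosphere(3, radius = 2)
  sph$role <- "interior_surface"
  expect_warning(v1 <- internal_volume(sph, "capped"), "closed")
  expect_warning(v2 <- internal_volume(sph, "origin_fan"), "closed")
  expect_equal(v1, v2)
  expect_equal(v1, 4 * pi * 8 / 3, tolerance = 0.01)
})

test_that("nested hemi-ellipsoid valve recovers the analytic pSV", {
  # proportional inner axes: discretization cancels exactly in the ratio
  v <- make_valve(shell_params(c(2, 1, 1), inner_axes = c(1.6, 0.8, 0.8)))
  met <- compute_metrics(v$shell, v$interior)
  expect_equal(met$pSV, 0.488, tolerance = 1e-9)
  expect_equal(met$TSV, 2 * met$valve_shell_volume)
  expect_equal(met$TIV, 2 * met$valve_internal_volume)
  expect_equal(met$SL, 4, tolerance = 1e-9)
  expect_equal(met$width / met$height, met$XS)
  expect_equal(met$logSL, log10(met$SL))
})

test_that("volumes converge monotonically with refinement; pSV is exact", {
  axes <- c(2, 1, 1)
  t <- 0.3
  shell_true <- (2 * pi / 3) * (prod(axes) - prod(axes - t))
  int_true <- (2 * pi / 3) * prod(axes - t)
  shell_err <- int_err <- psv_err <- numeric(4)
  for (k in seq_along(s_levels <- c(4L, 8L, 16L, 32L))) {
    v <- make_valve(shell_params(axes, thickness = t,
                                 subdiv = s_levels[k]))
    shell_err[k] <- abs(abs(signed_volume(v$shell)) - shell_true)
    int_err[k] <- abs(internal_volume(v$interior) - int_true)
    met <- compute_metrics(v$shell, v$interior)
    psv_err[k] <- abs(met$pSV - v$params$analytic_pSV)
  }
  expect_true(all(diff(shell_err) < 0))   # O(h^2) inscribed-mesh deficit
  expect_true(all(diff(int_err) < 0))
  # the UV grids of outer and inner surfaces are affine images of one
  # grid, so the discretization factor cancels exactly in the pSV ratio
  expect_true(all(psv_err < 1e-12))
  v_def <- make_valve(shell_params(axes, thickness = t))
  met_def <- compute_metrics(v_def$shell, v_def$interior)
  expect_lt(abs(met_def$pSV - v_def$params$analytic_pSV) /
              v_def$params$analytic_pSV, 0.005)
})

test_that("pSV and XS are scale- and mirror-invariant; SL scales linearly", {
  v <- make_valve(shell_params(c(2, 1.2, 0.8), thickness = 0.25, subdiv = 8))
  met <- compute_metrics(v$shell, v$interior)
  for (s in c(0.25, 3, 17)) {
    ms <- compute_metrics(scale_mesh(v$shell, s), scale_mesh(v$interior, s))
    expect_lt(abs(ms$pSV - met$pSV) / met$pSV, 1e-9)
    expect_lt(abs(ms$XS - met$XS) / met$XS, 1e-9)
    expect_equal(ms$SL, s * met$SL, tolerance = 1e-9)
  }
  mm <- compute_metrics(v$shell, v$interior, mirror = TRUE)
  expect_lt(abs(mm$pSV - met$pSV) / met$pSV, 1e-9)
  expect_lt(abs(mm$XS - met$XS) / met$XS, 1e-9)
  expect_equal(mm$SL, met$SL)
})

test_that("a valve as wide as tall has XS = 1", {
  # extent y = 2b, extent z = c, width = 2c; width = height needs c = b
  v <- make_valve(shell_params(c(2, 1, 1), thickness = 0.2, subdiv = 8))
  met <- compute_metrics(v$shell, v$interior)
  expect_equal(met$XS, 1, tolerance = 1e-9)
})

test_that("vanishing internal volume drives pSV to 1", {
  v <- make_valve(shell_params(c(2, 1, 1),
                               inner_axes = c(2, 1, 1) * 1e-4, subdiv = 8))
  met <- compute_metrics(v$shell, v$interior)
  expect_gt(met$pSV, 0.999)
})

test_that("log base is configurable", {
  v <- make_valve(shell_params(c(2, 1, 1), thickness = 0.2, subdiv = 6))
  m10 <- compute_metrics(v$shell, v$interior, log_base = 10)
  me <- compute_metrics(v$shell, v$interior, log_base = exp(1))
  expect_equal(m10$logSL, log10(m10$SL))
  expect_equal(me$logSL, log(me$SL))
})

test_that("non-closed shell solids are refused with a validity report", {
  v <- make_valve(shell_params(c(2, 1, 1), thickness = 0.2, subdiv = 6))
  broken <- v$shell
  broken$faces <- broken$faces[-1, , drop = FALSE]
  expect_error(compute_metrics(broken, v$interior), "not closed\\+manifold")
})

test_that("multi-loop interiors raise the ambiguous-opening error", {
  hemi <- hemisphere_mesh(r = 1, m = 8L)
  two <- hemi
  shifted <- hemi$vertices
  shifted[, 1] <- shifted[, 1] + 10
  two$vertices <- rbind(hemi$vertices, shifted)
  two$faces <- rbind(hemi$faces, hemi$faces + nrow(hemi$vertices))
  expect_error(internal_volume(two), "ambiguous opening")
})
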