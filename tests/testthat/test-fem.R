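# 3D engine verification: Poiseuille limits, conservation, no-slip,
# Windkessel coupling, mesh-independence procedure, and consistency with the
# reduced-order engine on stenosed tubes.

test_that("a straight tube reproduces the Poiseuille solution within 5%", {
  fx <- poiseuille_field()
  sol <- fx$sol
  expect_true(sol$converged)
  psv <- extract_psv(sol, "ica", "field_max_in_branch")$psv
  expect_rel(psv, 50, 0.05)
  dp <- pressure_drop(sol, list(branch = "ica", s = 1), list(branch = "ica", s = 11))
  Q <- sol$inlet_flow * 1e-6 / 60
  dp_an <- 8 * 0.004 * 0.010 * Q / (pi * 0.002^4) / 133.322
  expect_rel(dp, dp_an, 0.05)
  # profile shape: centerline sample close to the parabolic conversion
  psv_flow <- extract_psv(sol, "ica", "parabolic_from_flow")$psv
  expect_rel(psv, psv_flow, 0.05)
})

test_that("3D solves conserve mass and satisfy no-slip exactly", {
  fx <- poiseuille_field()
  sol <- fx$sol
  expect_lt(abs(sol$inlet_flow - sum(sol$outlets$q)) / sol$inlet_flow, 0.005)
  wall_faces <- sol$boundary_faces[sol$boundary_tag == 4L, , drop = FALSE]
  wall_nodes <- unique(as.vector(wall_faces))
  expect_lt(max(abs(sol$velocity[wall_nodes, ])), 1e-10)
})

test_that("pressure planes are antisymmetric under swapping", {
  sol <- poiseuille_field()$sol
  a <- list(branch = "ica", s = 2); b <- list(branch = "ica", s = 10)
  expect_equal(pressure_drop(sol, a, b), -pressure_drop(sol, b, a))
  expect_error(pressure_drop(sol, a, list(branch = "ica", s = 99)),
               "outside the solution domain")
})

test_that("a Windkessel outlet settles on its resistive operating point", {
  tube <- build_tube(2, 10, resolution = 1.1)
  mesh <- suppressWarnings(generate_mesh(tube, mesh_params(0.2, 1.1)))
  R_out <- 2e9
  sol <- solve_fem3d(mesh, fluid_properties(), inlet_profile(40, 2),
                     outlets = list(ica = windkessel_params(R_out)),
                     time_cfg = fem_time_config(max_steps = 3000))
  q_si <- sum(sol$outlets$q) * 1e-6 / 60
  expect_rel(sol$outlets$p[1], q_si * R_out / 133.322, 0.02)
})

test_that("the stopping rule fires on the prescribed relative change", {
  expect_equal(independence_stop_index(c(100, 105, 106), tol = 0.1), 2L)
  expect_equal(independence_stop_index(c(100, 140, 150), tol = 0.1), 3L)
  expect_identical(independence_stop_index(c(100, 150, 225), tol = 0.1),
                   NA_integer_)
  expect_error(independence_stop_index(c(100, 101), tol = 0), "positive")
})

test_that("grid refinement reaches mesh independence on a tube", {
  tube <- build_tube(2, 10, resolution = 1.4)
  res <- mesh_independence(
    tube,
    solve_cfg = list(inlet = inlet_profile(50, 2),
                     outlets = list(ica = list(P = 0)),
                     max_edge0 = 1.4, min_edge = 0.1),
    refinement_factor = 0.72, tol = 0.1, max_levels = 4)
  expect_gte(res$level, 2)
  expect_rel(res$psv[res$level], 50, 0.08)
  rel <- abs(diff(res$psv)) / res$psv[-length(res$psv)]
  expect_lt(rel[res$level - 1], 0.1)
})

test_that("both engines agree on a stenosed tube in the loss-dominated regime", {
  tube <- apply_stenosis(build_tube(2.5, 24, 1.1),
                         stenosis_spec("ica", 50, center_s = 12, length = 6))
  mesh <- suppressWarnings(generate_mesh(tube, mesh_params(0.25, 1.1)))
  sol <- solve_fem3d(mesh, fluid_properties(), inlet_profile(60, 2.5),
                     outlets = list(ica = list(P = 0)),
                     time_cfg = fem_time_config(steady = FALSE, t_end = 0.095))
  Q <- sol$inlet_flow
  dp_fem <- pressure_drop(sol, list(branch = "ica", s = 4),
                          list(branch = "ica", s = 20))
  el <- stenosis_element(2.5, 50, length = 6)
  dp_red <- stenosis_dp(Q, el) +
    poiseuille_resistance(10, 2.5) * (1e-6 / 60) / 133.322 * Q
  expect_rel(dp_fem, dp_red, 0.30)
  # jet acceleration: the throat maximum exceeds the inlet peak
  expect_gt(extract_psv(sol, "ica", "field_max_in_branch")$psv, 60)
})

test_that("both engines rank idealized stenoses identically by pressure drop", {
  dp_fem <- dp_red <- numeric(0)
  for (deg in c(30, 45, 60)) {
    tube <- apply_stenosis(build_tube(2.5, 20, 1.2),
                           stenosis_spec("ica", deg, center_s = 10, length = 6))
    mesh <- suppressWarnings(generate_mesh(tube, mesh_params(0.3, 1.2)))
    sol <- solve_fem3d(mesh, fluid_properties(), inlet_profile(20, 2.5),
                       outlets = list(ica = list(P = 0)),
                       time_cfg = fem_time_config(steady = FALSE, t_end = 0.08))
    dp_fem <- c(dp_fem, pressure_drop(sol, list(branch = "ica", s = 3),
                                      list(branch = "ica", s = 17)))
    Q <- sol$inlet_flow
    dp_red <- c(dp_red, stenosis_dp(Q, stenosis_element(2.5, deg, length = 6)))
  }
  expect_equal(order(dp_fem), order(dp_red))
  expect_true(all(diff(dp_fem) > 0))
})
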