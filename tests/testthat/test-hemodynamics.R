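# Boundary-condition model: inlet profile and flow integral, Windkessel
# dynamics against the analytic solution, resistance partition identities,
# and outlet calibration.

test_that("the parabolic inlet profile hits its landmark values", {
  prof <- inlet_profile(80, 3)
  expect_equal(inlet_velocity(0, 0, prof), 80)
  expect_equal(inlet_velocity(3, 0, prof), 0)
  expect_equal(inlet_velocity(1.5, 0, prof), 0.75 * 80)
  expect_error(inlet_velocity(3.1, 0, prof), "outside")
  # nonnegative inside, maximum at the centerline
  th <- seq(0, 2 * pi, length.out = 33)
  v <- inlet_velocity(2.9 * cos(th), 2.9 * sin(th), prof)
  expect_true(all(v >= 0) && all(v <= 80))
})

test_that("inlet flow equals the disk integral of the profile", {
  prof <- inlet_profile(100, 3)
  expect_rel(inlet_flow_rate(prof), 848.23, 1e-3)
  # independent oracle: midpoint quadrature over the inlet disk
  nr <- 400; nt <- 256
  r_mid <- (seq_len(nr) - 0.5) / nr * 0.3        # cm
  th <- (seq_len(nt) - 0.5) / nt * 2 * pi
  vr <- 100 * (1 - (r_mid / 0.3)^2)
  q_quad <- sum(outer(vr * r_mid, rep(1, nt))) * (0.3 / nr) * (2 * pi / nt) * 60
  expect_rel(inlet_flow_rate(prof), q_quad, 1e-4)
  expect_equal(inlet_flow_rate(inlet_profile(1e-9, 3)) > 0, TRUE)
  expect_rel(inlet_flow_rate(inlet_profile(100, 6)),
             4 * inlet_flow_rate(prof), 1e-12)
})

test_that("pulsatile waveforms modulate the profile and must be normalized", {
  wf <- data.frame(t = c(0, 0.25, 0.5, 1), w = c(0.4, 1, 0.5, 0.4))
  prof <- inlet_profile(100, 3, waveform = "pulsatile", samples = wf, period = 1)
  expect_equal(inlet_velocity(0, 0, prof, t = 0.25), 100)
  expect_equal(inlet_velocity(0, 0, prof, t = 1.25), 100)  # periodic
  expect_error(inlet_profile(100, 3, waveform = "pulsatile",
                             samples = data.frame(t = 0:1, w = c(0.2, 0.5))),
               "normalized")
})

test_that("the outlet resistance split satisfies both defining identities", {
  sp <- split_outlet_resistances(1, 2, 2)
  expect_equal(sp$R_ica, 2); expect_equal(sp$R_eca, 2)
  sp2 <- split_outlet_resistances(1e9, 2 * 1.3, 1.3)
  expect_rel(sp2$R_ica, sp2$R_eca / 4, 1e-12)
  set.seed(5)
  for (i in 1:200) {
    rt <- stats::runif(1, 1e7, 1e10)
    ri <- stats::runif(1, 0.5, 4); re <- stats::runif(1, 0.5, 4)
    s <- split_outlet_resistances(rt, ri, re)
    expect_rel(s$R_ica / s$R_eca, (re / ri)^2, 1e-12)
    expect_rel(1 / (1 / s$R_ica + 1 / s$R_eca), rt, 1e-12)
  }
  expect_error(split_outlet_resistances(-1, 1, 1), "positive")
})

test_that("the Windkessel integrator reproduces its analytic limits", {
  # resistive limit
  st <- windkessel_step(windkessel_state(), windkessel_params(1e8, 0),
                        Q = 5e-6, dt = 0.01)
  expect_equal(st$P, 500)
  # free decay: P(RC)/P0 = 1/e
  par <- windkessel_params(1e8, 1e-8)   # RC = 1 s
  st <- windkessel_state(P = 1000)
  dt <- 1e-4
  for (i in seq_len(1e4)) st <- windkessel_step(st, par, 0, dt)
  expect_rel(st$P, 1000 * exp(-1), 1e-3)
  # approach to steady state: within 0.1% after 10 RC
  st <- windkessel_state(P = 0)
  for (i in seq_len(2e4)) st <- windkessel_step(st, par, 5e-6, 5e-4)
  expect_rel(st$P, 5e-6 * 1e8, 1e-3)
  expect_error(windkessel_step(st, par, 5e-6, dt = -1), "positive")
})

test_that("backward Euler converges first order to the exact trajectory", {
  par <- windkessel_params(2e8, 5e-9)   # RC = 1 s
  Q <- 4e-6; P0 <- 200
  exact <- windkessel_exact_constant_flow(par, Q, P0, 1)
  err_at <- function(dt) {
    st <- windkessel_state(P = P0)
    for (i in seq_len(round(1 / dt))) st <- windkessel_step(st, par, Q, dt)
    abs(st$P - exact)
  }
  e1 <- err_at(2e-3); e2 <- err_at(1e-3)
  expect_rel(e1 / e2, 2, 0.1)           # halving dt halves the error
  expect_equal(windkessel_exact_constant_flow(par, Q, P0, 0), P0)
  expect_rel(windkessel_exact_constant_flow(par, Q, P0, 100), Q * par$R, 1e-6)
  expect_error(windkessel_exact_constant_flow(windkessel_params(1e8, 0),
                                              Q, P0, 1), "resistive")
})

test_that("outlet calibration converts pressure/flow targets to R and C", {
  cal <- calibrate_outlet_parameters(90, 600, 1.3)
  expect_rel(cal$R_total, 90 * 133.322 / 1e-5, 1e-6)
  expect_rel(calibrate_outlet_parameters(180, 600, 1.3)$R_total,
             2 * cal$R_total, 1e-12)
  expect_rel(cal$C_total, 1.3 / cal$R_total, 1e-12)
  expect_error(calibrate_outlet_parameters(90, 0, 1.3), "positive")
})
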