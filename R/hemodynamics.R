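# Boundary-condition model: Poiseuille-type inlet, two-element Windkessel
# outlets, and the area-based partition of the total peripheral resistance
# between the internal and external carotid outlets.

#' Blood properties
#'
#' Incompressible Newtonian blood model. Defaults are the standard large-vessel
#' values: density 1060 kg/m^3, dynamic viscosity 0.004 Pa.s.
#'
#' @param density Density rho (kg/m^3).
#' @param viscosity Dynamic viscosity mu (Pa.s).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1060, viscosity = 0.004) {
  abort_if(!is_number(density) || density <= 0, "`density` must be a positive number")
  abort_if(!is_number(viscosity) || viscosity <= 0, "`viscosity` must be a positive number")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Inlet velocity profile of the common carotid artery
#'
#' Describes the Dirichlet inflow applied at the CCA inlet: a Poiseuille-type
#' (parabolic) spatial profile whose centerline value is the CCA peak systolic
#' velocity, optionally modulated in time by a normalized waveform.
#'
#' @param v_peak Centerline peak systolic velocity (cm/s).
#' @param r_cca CCA lumen radius (mm).
#' @param waveform Either `"steady_peak"` (quasi-steady solve at the systolic
#'   peak, the default) or `"pulsatile"`.
#' @param samples For `"pulsatile"`: a data frame with columns `t` (s) and `w`
#'   (dimensionless), the normalized waveform over one period. Its maximum must
#'   be 1 so that `v_peak` retains its meaning.
#' @param period Waveform period (s), used for `"pulsatile"`.
#' @return An object of class `inlet_profile`.
#' @export
inlet_profile <- function(v_peak, r_cca,
                          waveform = c("steady_peak", "pulsatile"),
                          samples = NULL, period = 1) {
  waveform <- match.arg(waveform)
  abort_if(!is_number(v_peak) || v_peak <= 0, "`v_peak` must be a positive number (cm/s)")
  abort_if(!is_number(r_cca) || r_cca <= 0, "`r_cca` must be a positive number (mm)")
  if (waveform == "pulsatile") {
    abort_if(is.null(samples), "pulsatile profiles need `samples` (columns t, w)")
    samples <- as.data.frame(samples)
    abort_if(!all(c("t", "w") %in% names(samples)), "`samples` must have columns t and w")
    abort_if(abs(max(samples$w) - 1) > 1e-8, "waveform must be normalized so max(w) == 1")
    abort_if(!is_number(period) || period <= 0, "`period` must be positive")
  }
  structure(list(v_peak = v_peak, r_cca = r_cca, waveform = waveform,
                 samples = samples, period = period),
            class = "inlet_profile")
}

waveform_value <- function(profile, t) {
  if (profile$waveform == "steady_peak") return(rep(1, length(t)))
  tt <- t %% profile$period
  stats::approx(profile$samples$t, profile$samples$w, xout = tt, rule = 2)$y
}

#' Axial inlet velocity at a point
#'
#' Evaluates the parabolic inlet profile
#' `v = v_peak * w(t) * (1 - (x^2 + y^2) / r_cca^2)` at in-plane coordinates
#' `(x, y)` (mm) relative to the inlet center. `w(t)` is 1 for the
#' `steady_peak` waveform.
#'
#' @param x,y In-plane coordinates (mm), vectorized.
#' @param profile An [inlet_profile()].
#' @param t Time (s).
#' @return Axial velocity (cm/s).
#' @export
inlet_velocity <- function(x, y, profile, t = 0) {
  stopifnot(inherits(profile, "inlet_profile"))
  rsq <- x^2 + y^2
  abort_if(any(rsq > profile$r_cca^2 * (1 + 1e-12)),
           "point outside the inlet lumen (x^2 + y^2 > r_cca^2)")
  profile$v_peak * waveform_value(profile, t) * (1 - rsq / profile$r_cca^2)
}

#' Volumetric inlet flow rate
#'
#' Integral of the parabolic profile over the inlet disk: the mean velocity of
#' a Poiseuille profile is half its peak, so
#' `Q = (pi / 2) * r_cca^2 * v_peak * w(t)`.
#'
#' @inheritParams inlet_velocity
#' @return Flow rate (ml/min).
#' @export
inlet_flow_rate <- function(profile, t = 0) {
  stopifnot(inherits(profile, "inlet_profile"))
  r_cm <- profile$r_cca / 10
  q_cm3s <- (pi / 2) * r_cm^2 * profile$v_peak * waveform_value(profile, t)
  q_cm3s * 60  # cm^3/s -> ml/min
}

#' Two-element Windkessel parameters
#'
#' Peripheral resistance and capacitance of the downstream vascular bed,
#' related to outlet pressure and flow by `Q = P/R + C dP/dt`.
#'
#' @param R Resistance (Pa.s/m^3), positive.
#' @param C Capacitance (m^3/Pa), non-negative; `C = 0` is the purely
#'   resistive limit `P = Q R`.
#' @return An object of class `windkessel_params`.
#' @export
windkessel_params <- function(R, C = 0) {
  abort_if(!is_number(R) || R <= 0, "`R` must be a positive number")
  abort_if(!is_number(C) || C < 0, "`C` must be non-negative")
  structure(list(R = R, C = C), class = "windkessel_params")
}

#' Windkessel state
#'
#' Outlet pressure and time carried between coupling steps.
#'
#' @param P Pressure (Pa), relative to the venous reference (0 Pa).
#' @param t Time (s).
#' @return An object of class `windkessel_state`.
#' @export
windkessel_state <- function(P = 0, t = 0) {
  abort_if(!is_number(P), "`P` must be a finite number")
  abort_if(!is_number(t), "`t` must be a finite number")
  structure(list(P = P, t = t), class = "windkessel_state")
}

#' Advance a Windkessel outlet by one time step
#'
#' One backward-Euler step of `C dP/dt = Q - P/R` at imposed flow `Q`. For
#' `C = 0` the resistive limit `P = Q R` is returned immediately.
#'
#' @param state A [windkessel_state()].
#' @param params A [windkessel_params()].
#' @param Q Outlet flow during the step (m^3/s).
#' @param dt Time-step size (s), positive.
#' @return The updated [windkessel_state()].
#' @export
windkessel_step <- function(state, params, Q, dt) {
  stopifnot(inherits(state, "windkessel_state"), inherits(params, "windkessel_params"))
  abort_if(!is_number(dt) || dt <= 0, "`dt` must be positive")
  abort_if(!is_number(Q), "`Q` must be a finite number")
  P_new <- if (params$C == 0) {
    Q * params$R
  } else {
    (state$P + dt * Q / params$C) / (1 + dt / (params$R * params$C))
  }
  windkessel_state(P = P_new, t = state$t + dt)
}

#' Exact Windkessel pressure under constant flow
#'
#' Closed-form solution of `C dP/dt = Q - P/R` for constant `Q`:
#' `P(t) = Q R + (P0 - Q R) exp(-t / (R C))`. Serves as the analytic
#' reference for the backward-Euler integrator.
#'
#' @param params A [windkessel_params()] with `C > 0`.
#' @param Q Constant flow (m^3/s).
#' @param P0 Initial pressure (Pa).
#' @param t Time (s), vectorized.
#' @return Pressure (Pa).
#' @export
windkessel_exact_constant_flow <- function(params, Q, P0, t) {
  stopifnot(inherits(params, "windkessel_params"))
  abort_if(params$C == 0, "C = 0 has no exponential solution; use the resistive limit Q * R")
  Q * params$R + (P0 - Q * params$R) * exp(-t / (params$R * params$C))
}

#' Split the total peripheral resistance between ICA and ECA outlets
#'
#' Outlet resistances are inversely proportional to the outlet cross-sectional
#' areas, `R_ICA / R_ECA = (r_ECA / r_ICA)^2`, while their parallel combination
#' reproduces the total peripheral resistance.
#'
#' @param R_parallel_total Total (parallel) peripheral resistance (Pa.s/m^3).
#' @param r_ica,r_eca Outlet lumen radii (mm).
#' @return A list with `R_ica`, `R_eca` (Pa.s/m^3) and the radii.
#' @export
split_outlet_resistances <- function(R_parallel_total, r_ica, r_eca) {
  abort_if(!is_number(R_parallel_total) || R_parallel_total <= 0,
           "`R_parallel_total` must be positive")
  abort_if(!is_number(r_ica) || r_ica <= 0, "`r_ica` must be positive")
  abort_if(!is_number(r_eca) || r_eca <= 0, "`r_eca` must be positive")
  k <- (r_eca / r_ica)^2          # R_ica / R_eca
  R_ica <- R_parallel_total * (1 + k)
  R_eca <- R_ica / k
  structure(list(R_ica = R_ica, R_eca = R_eca, r_ica = r_ica, r_eca = r_eca),
            class = "outlet_resistance_split")
}

#' Calibrate outlet Windkessel parameters
#'
#' The model publishes the resistance split rule but not absolute R and C
#' values, so the total peripheral resistance is calibrated from a target mean
#' arterial pressure and a baseline flow, `R_total = P_mean / Q_baseline`, and
#' the total capacitance from a diastolic decay time constant,
#' `C_total = tau / R_total`.
#'
#' @param target_mean_pressure Mean arterial pressure target (mmHg).
#' @param baseline_flow Baseline total carotid flow (ml/min).
#' @param rc_time_constant Windkessel decay time constant tau = R C (s).
#' @return A list with `R_total` (Pa.s/m^3) and `C_total` (m^3/Pa).
#' @export
calibrate_outlet_parameters <- function(target_mean_pressure = 90,
                                        baseline_flow = 600,
                                        rc_time_constant = 1.3) {
  abort_if(!is_number(target_mean_pressure) || target_mean_pressure <= 0,
           "`target_mean_pressure` must be positive (mmHg)")
  abort_if(!is_number(baseline_flow) || baseline_flow <= 0,
           "`baseline_flow` must be positive (ml/min); zero flow cannot be calibrated")
  abort_if(!is_number(rc_time_constant) || rc_time_constant <= 0,
           "`rc_time_constant` must be positive (s)")
  R_total <- mmhg_to_pa(target_mean_pressure) / mlmin_to_m3s(baseline_flow)
  list(R_total = R_total, C_total = rc_time_constant / R_total)
}
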