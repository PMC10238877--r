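# Reduced-order vessel network: the carotid bifurcation as a CCA conduit
# feeding ICA and ECA chains of conduit and stenosis elements, closed by
# Windkessel outlets. Conduits carry Poiseuille resistance; stenoses carry a
# quadratic pressure-drop law dP = a Q + b Q^2 whose linear coefficient is
# the viscous (Poiseuille) resistance of the throat and whose quadratic
# coefficient is a Borda-Carnot expansion loss.

#' Stenosis pressure-drop element
#'
#' Coefficients of the quadratic trans-stenotic pressure-drop law
#' `dP = a Q + b Q^2` (mmHg vs ml/min): `a` is the Poiseuille resistance of
#' the stenotic throat, `b = K_t rho/2 (1/A_s - 1/A_0)^2` an expansion
#' (Borda-Carnot) loss with discharge factor `K_t`.
#'
#' @param r_distal Normal (distal) lumen radius of the branch (mm).
#' @param degree_nascet Percent diameter reduction in `[0, 100)`.
#' @param length Stenosis length (mm).
#' @param K_t Expansion-loss factor (default 1.52).
#' @param fluid A [fluid_properties()].
#' @return An object of class `stenosis_element` with fields `a`
#'   (mmHg/(ml/min)) and `b` (mmHg/(ml/min)^2).
#' @export
stenosis_element <- function(r_distal, degree_nascet, length = 10, K_t = 1.52,
                             fluid = fluid_properties()) {
  abort_if(!is_number(r_distal) || r_distal <= 0, "`r_distal` must be positive")
  abort_if(!is_number(degree_nascet) || degree_nascet < 0 || degree_nascet >= 100,
           "`degree_nascet` must lie in [0, 100)")
  abort_if(!is_number(K_t) || K_t <= 0, "`K_t` must be positive")
  r_s <- r_distal * (1 - degree_nascet / 100)
  A0 <- pi * mm_to_m(r_distal)^2
  As <- pi * mm_to_m(r_s)^2
  a_si <- 8 * fluid$viscosity * mm_to_m(length) / (pi * mm_to_m(r_s)^4)
  b_si <- K_t * fluid$density / 2 * (1 / As - 1 / A0)^2
  structure(list(
    a = a_si * M3S_PER_MLMIN / PA_PER_MMHG,
    b = b_si * M3S_PER_MLMIN^2 / PA_PER_MMHG,
    r_distal = r_distal, degree_nascet = degree_nascet, length = length,
    K_t = K_t
  ), class = "stenosis_element")
}

#' Quadratic stenosis pressure drop
#'
#' Evaluates `dP = a Q + b Q^2` for a stenosis element. Retrograde flow
#' (negative Q) is out of scope and rejected.
#'
#' @param Q Flow rate (ml/min), vectorized, non-negative.
#' @param element A [stenosis_element()] or any list with fields `a`, `b`.
#' @return Pressure drop (mmHg).
#' @export
stenosis_dp <- function(Q, element) {
  abort_if(any(!is.finite(Q)) || any(Q < 0), "`Q` must be non-negative (retrograde flow is out of scope)")
  abort_if(is.null(element$a) || is.null(element$b) || element$a < 0 || element$b < 0,
           "element must carry non-negative coefficients a and b")
  element$a * Q + element$b * Q^2
}

conduit_coeff <- function(length_mm, radius_mm, fluid) {
  poiseuille_resistance(length_mm, radius_mm, fluid$viscosity) *
    M3S_PER_MLMIN / PA_PER_MMHG
}

#' Reduced-order network model of a carotid bifurcation
#'
#' Assembles the segment table of the lumped network. Segments are applied in
#' series along each branch; the CCA feeds the ICA/ECA junction; each outlet
#' closes on a two-element Windkessel.
#'
#' @param segments A data frame with columns `branch` (cca/ica/eca), `kind`
#'   (conduit/stenosis), `length_mm`, `radius_mm`, `a`, `b` (mmHg-ml/min
#'   units; conduits carry their Poiseuille `a` and `b = 0`).
#' @param outlets List with elements `ica` and `eca`, each a
#'   [windkessel_params()].
#' @param fluid A [fluid_properties()].
#' @return An object of class `network_model`.
#' @export
network_model <- function(segments, outlets, fluid = fluid_properties()) {
  segments <- tibble::as_tibble(segments)
  need <- c("branch", "kind", "a", "b")
  abort_if(!all(need %in% names(segments)),
           paste0("`segments` needs columns ", paste(need, collapse = ", ")))
  abort_if(!all(segments$branch %in% c("cca", "ica", "eca")),
           "segment branches must be cca/ica/eca")
  abort_if(!all(c("ica", "eca") %in% names(outlets)),
           "`outlets` must have 'ica' and 'eca' entries")
  abort_if(any(segments$a < 0) || any(segments$b < 0),
           "segment coefficients must be non-negative")
  for (o in outlets[c("ica", "eca")]) stopifnot(inherits(o, "windkessel_params"))
  structure(list(segments = segments, outlets = outlets, fluid = fluid),
            class = "network_model")
}

#' Build the reduced-order network of a parametric twin
#'
#' Translates a twin surface into the lumped network: one Poiseuille conduit
#' per branch plus one quadratic element per stenosis, with the total
#' peripheral resistance calibrated by [calibrate_outlet_parameters()] and
#' split between the outlets by [split_outlet_resistances()].
#'
#' @param surface A bifurcation [carotid_surface].
#' @param outlets Either a list with `ica`/`eca` [windkessel_params()], or
#'   `NULL` to calibrate from `target_mean_pressure`/`baseline_flow`.
#' @param target_mean_pressure,baseline_flow,rc_time_constant Calibration
#'   inputs (mmHg, ml/min, s) used when `outlets` is `NULL`.
#' @param K_t Expansion-loss factor for stenosis elements.
#' @param fluid A [fluid_properties()].
#' @return A [network_model()].
#' @export
twin_network <- function(surface, outlets = NULL,
                         target_mean_pressure = 90, baseline_flow = 600,
                         rc_time_constant = 1.3, K_t = 1.52,
                         fluid = fluid_properties()) {
  stopifnot(inherits(surface, "carotid_surface"))
  abort_if(surface$geom$kind != "bifurcation",
           "reduced-order networks require a bifurcation twin")
  sp <- surface$geom$spec
  segs <- list()
  add_seg <- function(branch, kind, length_mm, radius_mm, a, b) {
    segs[[length(segs) + 1L]] <<- tibble::tibble(
      branch = branch, kind = kind, length_mm = length_mm,
      radius_mm = radius_mm, a = a, b = b)
  }
  for (br in c("cca", "ica", "eca")) {
    r_b <- switch(br, cca = sp$r_cca, ica = sp$r_ica, eca = sp$r_eca)
    len_b <- switch(br, cca = sp$len_cca, ica = sp$len_ica, eca = sp$len_eca)
    add_seg(br, "conduit", len_b, r_b, conduit_coeff(len_b, r_b, fluid), 0)
    for (st in surface$geom$stenoses) {
      if (st$branch == br && st$degree_nascet > 0) {
        el <- stenosis_element(r_b, st$degree_nascet, st$length, K_t, fluid)
        add_seg(br, "stenosis", st$length, r_b * (1 - st$degree_nascet / 100),
                el$a, el$b)
      }
    }
  }
  if (is.null(outlets)) {
    cal <- calibrate_outlet_parameters(target_mean_pressure, baseline_flow,
                                       rc_time_constant)
    spl <- split_outlet_resistances(cal$R_total, sp$r_ica, sp$r_eca)
    # capacitances split to preserve the common RC time constant per outlet
    outlets <- list(
      ica = windkessel_params(spl$R_ica, rc_time_constant / spl$R_ica),
      eca = windkessel_params(spl$R_eca, rc_time_constant / spl$R_eca))
  }
  network_model(dplyr::bind_rows(segs), outlets, fluid)
}

branch_dp <- function(network, branch, Q) {
  seg <- network$segments[network$segments$branch == branch, ]
  sum(seg$a) * Q + sum(seg$b) * Q^2
}

#' Solve the reduced-order network
#'
#' At every time step the inlet flow (integral of the Poiseuille inlet
#' profile) is partitioned between ICA and ECA by bisection on the flow split
#' so that both paths meet at a single junction pressure; each outlet
#' pressure follows its Windkessel by backward Euler. With the default
#' `duration = NULL` a quasi-steady solve at the systolic peak is performed
#' (outlet pressure `Q R`, capacitances inactive).
#'
#' @param network A [network_model()].
#' @param inlet An [inlet_profile()].
#' @param duration Simulated time span (s), or `NULL` for a steady solve.
#' @param dt Time-step size (s).
#' @return An object of class `flow_solution`: tibble `series` with per-step
#'   flows (ml/min) and pressures (mmHg), per-segment drops in `segments`,
#'   and a convergence flag.
#' @export
solve_reduced_order <- function(network, inlet, duration = NULL, dt = 0.005) {
  stopifnot(inherits(network, "network_model"), inherits(inlet, "inlet_profile"))
  abort_if(!is.null(duration) && (!is_number(duration) || duration <= 0),
           "`duration` must be positive or NULL for a steady solve")
  abort_if(!is_number(dt) || dt <= 0, "`dt` must be positive")

  wk_pressure_steady <- function(params, q_mlmin) {
    pa_to_mmhg(mlmin_to_m3s(q_mlmin) * params$R)
  }
  steady <- is.null(duration)
  times <- if (steady) 0 else seq(0, duration, by = dt)[-1]

  split_at <- function(Q_in, p_fun_ica, p_fun_eca) {
    f <- function(q) {
      (p_fun_ica(q) + branch_dp(network, "ica", q)) -
        (p_fun_eca(Q_in - q) + branch_dp(network, "eca", Q_in - q))
    }
    if (Q_in <= 0) return(0)
    if (f(0) >= 0) return(0)
    if (f(Q_in) <= 0) return(Q_in)
    stats::uniroot(f, c(0, Q_in), tol = max(1e-12, 1e-12 * Q_in),
                   maxiter = 200)$root
  }

  st_ica <- windkessel_state(); st_eca <- windkessel_state()
  rows <- vector("list", length(if (steady) 1 else times))
  prev <- NULL; converged <- steady
  for (k in seq_along(if (steady) 1 else times)) {
    t_k <- if (steady) 0 else times[k]
    Q_in <- inlet_flow_rate(inlet, t_k)
    if (steady) {
      p_ica <- function(q) wk_pressure_steady(network$outlets$ica, q)
      p_eca <- function(q) wk_pressure_steady(network$outlets$eca, q)
    } else {
      p_ica <- function(q) pa_to_mmhg(
        windkessel_step(st_ica, network$outlets$ica, mlmin_to_m3s(q), dt)$P)
      p_eca <- function(q) pa_to_mmhg(
        windkessel_step(st_eca, network$outlets$eca, mlmin_to_m3s(q), dt)$P)
    }
    q_ica <- split_at(Q_in, p_ica, p_eca)
    q_eca <- Q_in - q_ica
    p_out_ica <- p_ica(q_ica); p_out_eca <- p_eca(q_eca)
    if (!steady) {
      st_ica <- windkessel_step(st_ica, network$outlets$ica, mlmin_to_m3s(q_ica), dt)
      st_eca <- windkessel_step(st_eca, network$outlets$eca, mlmin_to_m3s(q_eca), dt)
    }
    p_junction <- p_out_ica + branch_dp(network, "ica", q_ica)
    p_inlet <- p_junction + branch_dp(network, "cca", Q_in)
    rows[[k]] <- tibble::tibble(
      t = t_k, q_cca = Q_in, q_ica = q_ica, q_eca = q_eca,
      p_inlet = p_inlet, p_junction = p_junction,
      p_out_ica = p_out_ica, p_out_eca = p_out_eca)
    if (!steady && !is.null(prev)) {
      converged <- abs(p_out_ica - prev) < 1e-6 * max(1, abs(p_out_ica))
    }
    prev <- p_out_ica
  }
  series <- dplyr::bind_rows(rows)
  peak <- series[which.max(series$q_ica), ]
  seg <- network$segments
  seg$q <- ifelse(seg$branch == "cca", peak$q_cca,
                  ifelse(seg$branch == "ica", peak$q_ica, peak$q_eca))
  seg$dp <- seg$a * seg$q + seg$b * seg$q^2
  structure(list(series = series, segments = seg, converged = converged,
                 network = network, inlet = inlet, engine = "reduced"),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat("flow_solution (reduced-order):", nrow(x$series), "time point(s)\n")
  cat(sprintf("  Q: cca %.1f, ica %.1f, eca %.1f ml/min\n",
              last$q_cca, last$q_ica, last$q_eca))
  cat(sprintf("  P: inlet %.1f, junction %.1f, outlets %.1f / %.1f mmHg\n",
              last$p_inlet, last$p_junction, last$p_out_ica, last$p_out_eca))
  invisible(x)
}
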