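# Readout extraction: ICA peak systolic velocity from a virtual probe,
# trans-stenotic pressure drop, hyperemia sweeps with quadratic dP(Q) fits,
# and an FFR-like distal/proximal pressure ratio.

#' Extract a peak-systolic-velocity probe reading
#'
#' @param solution A `flow_solution` (reduced-order) or `field_solution` (3D).
#' @param branch Branch to probe (`"ica"` by default).
#' @param basis Probe basis. `"field_max_in_branch"` (3D only) takes the
#'   maximum velocity magnitude over branch-interior nodes at the stored
#'   systolic peak — the virtual-probe convention, since in a computed field
#'   the peak can be searched for exactly. `"parabolic_from_flow"` (the only
#'   valid basis for reduced-order solutions) converts peak branch flow to a
#'   centerline velocity via the parabolic-profile rule `psv = 2 Q / A`.
#'   `"centerline_point"` (3D) samples the velocity at the node nearest the
#'   branch centerline, mid-branch.
#' @return A one-row tibble (class `probe_reading`) with `branch`, `psv`
#'   (cm/s) and `basis`.
#' @export
extract_psv <- function(solution, branch = "ica",
                        basis = c("field_max_in_branch", "parabolic_from_flow",
                                  "centerline_point")) {
  UseMethod("extract_psv")
}

probe_reading <- function(branch, psv, basis) {
  out <- tibble::tibble(branch = branch, psv = psv, basis = basis)
  class(out) <- c("probe_reading", class(out))
  out
}

#' @export
extract_psv.flow_solution <- function(solution, branch = "ica",
                                      basis = c("parabolic_from_flow",
                                                "field_max_in_branch",
                                                "centerline_point")) {
  basis <- match.arg(basis)
  abort_if(basis != "parabolic_from_flow",
           "reduced-order solutions only support basis = 'parabolic_from_flow'")
  qcol <- switch(branch, cca = "q_cca", ica = "q_ica", eca = "q_eca",
                 rlang::abort("unknown branch"))
  q_peak <- max(solution$series[[qcol]])            # ml/min
  seg <- solution$network$segments
  r_mm <- seg$radius_mm[seg$branch == branch & seg$kind == "conduit"][1]
  abort_if(is.na(r_mm), "network carries no conduit for this branch")
  area_cm2 <- pi * (r_mm / 10)^2
  probe_reading(branch, 2 * (q_peak / 60) / area_cm2, basis)
}

#' @export
extract_psv.field_solution <- function(solution, branch = "ica",
                                       basis = c("field_max_in_branch",
                                                 "parabolic_from_flow",
                                                 "centerline_point")) {
  basis <- match.arg(basis)
  meta <- solution$mesh$node_meta
  sel <- meta$branch == branch
  abort_if(!any(sel), "solution does not cover this branch")
  umag <- sqrt(rowSums(solution$velocity^2))  # cm/s
  if (basis == "field_max_in_branch") {
    return(probe_reading(branch, max(umag[sel]), basis))
  }
  if (basis == "centerline_point") {
    s_mid <- stats::median(meta$s[sel])
    near <- which(sel)[abs(meta$s[sel] - s_mid) < 1e-9 |
                         rank(abs(meta$s[sel] - s_mid)) <= 1]
    layer <- which(sel & abs(meta$s - meta$s[near[1]]) < 1e-9)
    V <- solution$mesh$vertices[layer, , drop = FALSE]
    ctr <- colMeans(V)
    i <- layer[which.min(rowSums(sweep(V, 2, ctr)^2))]
    return(probe_reading(branch, umag[i], basis))
  }
  # parabolic_from_flow: outlet flux -> mean velocity -> 2x
  q <- outlet_flux(solution, branch)                 # m^3/s
  r_mm <- branch_reference_radius(solution$mesh, branch)
  area_m2 <- pi * mm_to_m(r_mm)^2
  probe_reading(branch, ms_to_cms(2 * q / area_m2), basis)
}

branch_reference_radius <- function(mesh, branch) {
  g <- mesh$geom
  if (g$kind == "tube") return(g$spec$radius)
  switch(branch, cca = g$spec$r_cca, ica = g$spec$r_ica, eca = g$spec$r_eca)
}

#' Trans-stenotic pressure drop
#'
#' Difference of section-averaged pressure between a proximal and a distal
#' plane. For 3D solutions planes are `list(branch =, s =)` section
#' locations (mm of arclength); for reduced-order solutions the drop is the
#' quadratic stenosis-element law evaluated at the systolic-peak branch flow.
#'
#' @param solution A `flow_solution` or `field_solution`.
#' @param plane_proximal,plane_distal For 3D solutions: section locators
#'   `list(branch, s)`. Ignored for reduced-order solutions.
#' @param branch For reduced-order solutions: the branch whose stenosis
#'   elements are summed.
#' @return Pressure drop (mmHg); positive when pressure falls downstream.
#' @export
pressure_drop <- function(solution, plane_proximal = NULL, plane_distal = NULL,
                          branch = "ica") {
  UseMethod("pressure_drop")
}

#' @export
pressure_drop.flow_solution <- function(solution, plane_proximal = NULL,
                                        plane_distal = NULL, branch = "ica") {
  seg <- solution$segments
  sel <- seg$branch == branch & seg$kind == "stenosis"
  abort_if(!any(sel), "branch has no stenosis element; nothing to bracket")
  sum(seg$dp[sel])
}

plane_pressure <- function(solution, plane) {
  abort_if(!is.list(plane) || is.null(plane$branch) || is.null(plane$s),
           "planes are lists with fields `branch` and `s`")
  meta <- solution$mesh$node_meta
  sel <- meta$branch == plane$branch
  abort_if(!any(sel), "plane outside the solution domain (unknown branch)")
  svals <- meta$s[sel]
  abort_if(plane$s < min(svals) - 1e-9 || plane$s > max(svals) + 1e-9,
           "plane outside the solution domain (arclength out of range)")
  s_near <- svals[which.min(abs(svals - plane$s))]
  idx <- which(sel & abs(meta$s - s_near) < 1e-9)
  mean(solution$pressure[idx])
}

#' @export
pressure_drop.field_solution <- function(solution, plane_proximal = NULL,
                                         plane_distal = NULL, branch = "ica") {
  abort_if(is.null(plane_proximal) || is.null(plane_distal),
           "field solutions need explicit proximal and distal planes")
  plane_pressure(solution, plane_proximal) - plane_pressure(solution, plane_distal)
}

#' Fit the quadratic pressure-drop/flow law
#'
#' Least squares of `dP = a Q + b Q^2` through the origin. Negative
#' coefficients are clipped to zero with a constrained refit, since both loss
#' terms are physically non-negative. The goodness of fit `R^2` is the
#' uncentered coefficient of determination (the model has no intercept).
#'
#' @param points A data frame with columns `q` (ml/min) and `dp` (mmHg), or
#'   a two-column matrix.
#' @return A list with `a`, `b`, `r2` and the fitted values.
#' @export
fit_dp_q <- function(points) {
  pts <- as.data.frame(points)
  if (!all(c("q", "dp") %in% names(pts))) names(pts)[1:2] <- c("q", "dp")
  abort_if(nrow(pts) < 2, "need at least two (Q, dP) points")
  abort_if(any(pts$q <= 0), "flows must be positive")
  abort_if(stats::sd(pts$q) == 0, "rank deficiency: all flows equal")
  X <- cbind(q = pts$q, q2 = pts$q^2)
  beta <- stats::lm.fit(X, pts$dp)$coefficients
  if (any(beta < 0)) {
    # constrained refit with the offending coefficient clipped at zero
    if (beta[1] < 0) {
      beta <- c(0, stats::lm.fit(X[, 2, drop = FALSE], pts$dp)$coefficients)
    } else {
      beta <- c(stats::lm.fit(X[, 1, drop = FALSE], pts$dp)$coefficients, 0)
    }
    beta <- pmax(beta, 0)
  }
  fitted <- as.vector(X %*% beta)
  r2 <- 1 - sum((pts$dp - fitted)^2) / sum(pts$dp^2)
  list(a = unname(beta[1]), b = unname(beta[2]), r2 = r2, fitted = fitted)
}

#' Hyperemia sweep of a twin
#'
#' Re-solves the twin at increasing CCA peak systolic velocities (hyperemia
#' is mimicked by raising inflow), recording ICA flow and trans-stenotic
#' pressure drop at each level, and fits the stenosis-specific quadratic
#' `dP = a Q + b Q^2` through the points.
#'
#' @param twin A [network_model()] (reduced-order engine).
#' @param v_peak_values At least three increasing CCA PSV values (cm/s).
#' @param r_cca CCA radius for the inlet profile (mm); defaults to the CCA
#'   conduit radius of the network.
#' @param branch Branch carrying the stenosis of interest.
#' @return An object of class `dp_flow_curve`: tibble `points`
#'   (`v_peak`, `q_ica`, `dp`), the fit (`a`, `b`, `r2`), and per-level
#'   FFR-like ratios.
#' @export
hyperemia_sweep <- function(twin, v_peak_values, r_cca = NULL, branch = "ica") {
  stopifnot(inherits(twin, "network_model"))
  abort_if(length(v_peak_values) < 3 || any(diff(v_peak_values) <= 0),
           "need at least three strictly increasing v_peak values")
  if (is.null(r_cca)) {
    seg <- twin$segments
    r_cca <- seg$radius_mm[seg$branch == "cca" & seg$kind == "conduit"][1]
  }
  rows <- vector("list", length(v_peak_values))
  for (i in seq_along(v_peak_values)) {
    sol <- solve_reduced_order(twin, inlet_profile(v_peak_values[i], r_cca))
    abort_if(!isTRUE(sol$converged),
             paste0("solve did not converge at v_peak = ", v_peak_values[i], " cm/s"))
    peak <- sol$series[which.max(sol$series$q_ica), ]
    dp <- pressure_drop(sol, branch = branch)
    rows[[i]] <- tibble::tibble(
      v_peak = v_peak_values[i],
      q_ica = peak$q_ica, dp = dp,
      p_proximal = peak$p_junction,
      ffr_like = ffr_like(peak$p_junction, dp))
  }
  points <- dplyr::bind_rows(rows)
  fit <- fit_dp_q(data.frame(q = points$q_ica, dp = points$dp))
  structure(list(points = points, a = fit$a, b = fit$b, r2 = fit$r2,
                 branch = branch),
            class = "dp_flow_curve")
}

#' FFR-like trans-stenotic pressure ratio
#'
#' Ratio of distal to proximal mean pressure across a stenosis under a
#' hyperemic solve, `(P_prox - dP) / P_prox = 1 - dP / P_prox` — the
#' CT-derived FFR convention adapted to the carotid circulation. Pressures
#' are relative to the venous reference (0 mmHg).
#'
#' @param p_proximal Proximal mean pressure (mmHg), positive, or a
#'   `flow_solution` (the junction pressure is then used as proximal).
#' @param dp Trans-stenotic pressure drop (mmHg); taken from the solution's
#'   stenosis elements when a solution is supplied.
#' @param branch Branch of interest for solution input.
#' @return Ratio in (0, 1]; 1 when `dP = 0`.
#' @export
ffr_like <- function(p_proximal, dp = NULL, branch = "ica") {
  if (inherits(p_proximal, "flow_solution")) {
    sol <- p_proximal
    peak <- sol$series[which.max(sol$series$q_ica), ]
    if (is.null(dp)) dp <- pressure_drop(sol, branch = branch)
    p_proximal <- peak$p_junction
  }
  abort_if(!is_number(p_proximal) || p_proximal <= 0,
           "`p_proximal` must be positive relative to the reference pressure")
  abort_if(!is_number(dp) || dp < 0, "`dp` must be a non-negative number")
  ratio <- 1 - dp / p_proximal
  abort_if(ratio <= 0, "nonphysical: distal pressure at or below the venous reference")
  ratio
}

#' @export
print.dp_flow_curve <- function(x, ...) {
  cat("dp_flow_curve:", nrow(x$points), "flow levels on branch", x$branch, "\n")
  cat(sprintf("  dP = %.3g Q + %.3g Q^2  (R^2 = %.4f)\n", x$a, x$b, x$r2))
  invisible(x)
}

#' @export
tidy.dp_flow_curve <- function(x, ...) x$points

#' @export
glance.dp_flow_curve <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r2 = x$r2, n_levels = nrow(x$points),
                 branch = x$branch)
}

#' @export
autoplot.dp_flow_curve <- function(object, ...) {
  pts <- object$points
  qq <- seq(0, max(pts$q_ica) * 1.05, length.out = 100)
  curve_df <- data.frame(q = qq, dp = object$a * qq + object$b * qq^2)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$q_ica, y = .data$dp)) +
    ggplot2::geom_line(data = curve_df, ggplot2::aes(x = .data$q, y = .data$dp),
                       linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "ICA blood flow (ml/min)",
                  y = expression(Delta * P ~ "(mmHg)"),
                  title = "Trans-stenotic pressure drop vs flow") +
    ggplot2::theme_minimal()
}
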