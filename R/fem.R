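# 3D incompressible Navier-Stokes on tetrahedral twins: P1/P1 finite
# elements with an incremental pressure-correction (projection) scheme.
# Viscosity is implicit, convection explicit (lagged), so both the velocity
# and the pressure operators are constant and factorized once per mesh.
# Outlets carry either a fixed pressure or a two-element Windkessel updated
# from the computed outlet flux (staggered coupling); walls are rigid no-slip;
# the inlet is a Dirichlet Poiseuille profile.

fem_orient_tets <- function(V, Tm) {
  vol <- tet_volumes(V, Tm)
  neg <- vol < 0
  if (any(neg)) Tm[neg, ] <- Tm[neg, c(1, 2, 4, 3), drop = FALSE]
  Tm
}

fem_geometry <- function(Vm, Tm) {
  a <- Vm[Tm[, 1], , drop = FALSE]
  e1 <- Vm[Tm[, 2], , drop = FALSE] - a
  e2 <- Vm[Tm[, 3], , drop = FALSE] - a
  e3 <- Vm[Tm[, 4], , drop = FALSE] - a
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
    e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
    e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  abort_if(any(det <= 0), "mesh contains inverted or degenerate elements")
  vol <- det / 6
  inv <- function(r, c) {
    # cofactor-based inverse of M = rbind(e1, e2, e3), column-major
    E <- list(e1, e2, e3)
    i2 <- c(2, 3, 1)[r]; i3 <- c(3, 1, 2)[r]
    j2 <- c(2, 3, 1)[c]; j3 <- c(3, 1, 2)[c]
    (E[[j2]][, i2] * E[[j3]][, i3] - E[[j2]][, i3] * E[[j3]][, i2]) / det
  }
  # grad lambda_{k+1} = column k of M^{-1}; grad lambda_1 = -sum
  G <- array(0, dim = c(nrow(Tm), 4L, 3L))
  for (k in 1:3) for (r in 1:3) G[, k + 1L, r] <- inv(r, k)
  G[, 1L, ] <- -(G[, 2L, ] + G[, 3L, ] + G[, 4L, ])
  list(vol = vol, G = G)
}

fem_matrices <- function(n, Tm, geo) {
  vol <- geo$vol; G <- geo$G
  ii <- jj <- integer(0)
  kv <- gx <- gy <- gz <- numeric(0)
  for (a in 1:4) for (b in 1:4) {
    ii <- c(ii, Tm[, a]); jj <- c(jj, Tm[, b])
    kv <- c(kv, vol * (G[, a, 1] * G[, b, 1] + G[, a, 2] * G[, b, 2] +
                         G[, a, 3] * G[, b, 3]))
    gx <- c(gx, vol / 4 * G[, b, 1])
    gy <- c(gy, vol / 4 * G[, b, 2])
    gz <- c(gz, vol / 4 * G[, b, 3])
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kv, dims = c(n, n))
  Gx <- Matrix::sparseMatrix(i = ii, j = jj, x = gx, dims = c(n, n))
  Gy <- Matrix::sparseMatrix(i = ii, j = jj, x = gy, dims = c(n, n))
  Gz <- Matrix::sparseMatrix(i = ii, j = jj, x = gz, dims = c(n, n))
  ML <- as.vector(Matrix::sparseMatrix(i = as.vector(Tm), j = rep(1L, 4 * nrow(Tm)),
                                       x = rep(vol / 4, 4), dims = c(n, 1)))
  scatter <- Matrix::sparseMatrix(i = as.vector(Tm), j = rep(seq_len(nrow(Tm)), 4),
                                  x = rep(vol / 4, 4), dims = c(n, nrow(Tm)))
  list(K = K, Gx = Gx, Gy = Gy, Gz = Gz, ML = ML, scatter = scatter)
}

# explicit convection vector rho * (u . grad) u, lumped per element
fem_convection <- function(u, Tm, geo, mats) {
  ub <- (u[Tm[, 1], ] + u[Tm[, 2], ] + u[Tm[, 3], ] + u[Tm[, 4], ]) / 4
  out <- matrix(0, nrow(u), 3)
  for (cc in 1:3) {
    gr1 <- gr2 <- gr3 <- 0
    for (a in 1:4) {
      gr1 <- gr1 + geo$G[, a, 1] * u[Tm[, a], cc]
      gr2 <- gr2 + geo$G[, a, 2] * u[Tm[, a], cc]
      gr3 <- gr3 + geo$G[, a, 3] * u[Tm[, a], cc]
    }
    conv <- ub[, 1] * gr1 + ub[, 2] * gr2 + ub[, 3] * gr3
    out[, cc] <- as.vector(mats$scatter %*% conv)
  }
  out
}

face_normals_areas <- function(Vm, faces) {
  a <- Vm[faces[, 1], , drop = FALSE]
  b <- Vm[faces[, 2], , drop = FALSE] - a
  c_ <- Vm[faces[, 3], , drop = FALSE] - a
  nrm <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
               b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
               b[, 1] * c_[, 2] - b[, 2] * c_[, 1]) / 2
  area <- sqrt(rowSums(nrm * nrm))
  list(normal = nrm, area = area)  # normal has magnitude = area (outward)
}

boundary_flux <- function(u, faces, fn) {
  # integral of u . n over the faces; P1 exact: mean of nodal u dotted with
  # the area-weighted outward normal
  um <- (u[faces[, 1], , drop = FALSE] + u[faces[, 2], , drop = FALSE] +
           u[faces[, 3], , drop = FALSE]) / 3
  sum(rowSums(um * fn$normal))
}

#' Time-stepping configuration for the 3D engine
#'
#' @param dt Time-step size (s); `NULL` picks a convective (CFL) limit from
#'   the mesh spacing and the expected jet velocity.
#' @param max_steps Step budget.
#' @param steady If `TRUE` (default) the solve marches in pseudo-time until
#'   the velocity field changes by less than `steady_tol` between steps.
#' @param t_end Simulated time span (s) for unsteady runs.
#' @param steady_tol Relative per-step change declaring a steady state.
#' @param init Initial velocity field: `"auto"` (developed profile on tubes,
#'   rest elsewhere), `"profile"` or `"zero"`.
#' @return A list of class `fem_time_config`.
#' @export
fem_time_config <- function(dt = NULL, max_steps = 8000, steady = TRUE,
                            t_end = NULL, steady_tol = 1e-4,
                            init = c("auto", "profile", "zero")) {
  init <- match.arg(init)
  abort_if(!is.null(dt) && (!is_number(dt) || dt <= 0), "`dt` must be positive")
  abort_if(!steady && is.null(t_end), "unsteady runs need `t_end`")
  structure(list(dt = dt, max_steps = max_steps, steady = steady,
                 t_end = t_end, steady_tol = steady_tol, init = init),
            class = "fem_time_config")
}

outlet_spec_pressure <- function(o) {
  if (inherits(o, "windkessel_params")) return(NULL)
  abort_if(!is.list(o) || is.null(o$P), "outlets are windkessel_params or list(P = mmHg)")
  mmhg_to_pa(o$P)
}

#' Solve 3D incompressible flow on a meshed twin
#'
#' Weak-form incompressible Navier-Stokes with a Dirichlet Poiseuille inlet,
#' rigid no-slip walls and pressure/Windkessel outlets, advanced by an
#' incremental pressure-correction scheme until steady (default) or until
#' `t_end`.
#'
#' @param mesh A [generate_mesh()] result.
#' @param fluid A [fluid_properties()].
#' @param inlet An [inlet_profile()]; its `r_cca` should match the inlet
#'   radius of the mesh.
#' @param outlets Named list over the mesh's outlets (`ica`, and `eca` for
#'   bifurcations): each a [windkessel_params()] or `list(P = <mmHg>)`.
#' @param time_cfg A [fem_time_config()].
#' @return An object of class `field_solution`: nodal `velocity` (cm/s),
#'   `pressure` (mmHg), outlet summary, solver diagnostics.
#' @export
solve_fem3d <- function(mesh, fluid = fluid_properties(), inlet,
                        outlets = list(ica = list(P = 0), eca = list(P = 0)),
                        time_cfg = fem_time_config()) {
  stopifnot(inherits(mesh, "carotid_mesh"), inherits(inlet, "inlet_profile"),
            inherits(time_cfg, "fem_time_config"))
  rho <- fluid$density; mu <- fluid$viscosity
  Vm <- mesh$vertices * 1e-3
  Tm <- fem_orient_tets(Vm, mesh$tets)
  n <- nrow(Vm)
  geo <- fem_geometry(Vm, Tm)
  mats <- fem_matrices(n, Tm, geo)
  bf <- tet_boundary_faces(Tm)
  tag <- tag_boundary_faces(bf, face_cap_from_mesh(mesh, bf))

  out_tags <- c(outlet_ica = 2L, outlet_eca = 3L)
  out_tags <- out_tags[out_tags %in% tag]
  abort_if(length(out_tags) == 0, "mesh has no outlet faces")
  names(out_tags) <- sub("outlet_", "", names(out_tags))
  abort_if(!all(names(out_tags) %in% names(outlets)),
           paste0("`outlets` must name: ", paste(names(out_tags), collapse = ", ")))

  wall_nodes <- unique(as.vector(bf[tag == 4L, , drop = FALSE]))
  inlet_faces <- bf[tag == 1L, , drop = FALSE]
  inlet_nodes <- setdiff(unique(as.vector(inlet_faces)), wall_nodes)
  outlet_nodes <- lapply(out_tags, function(tg)
    unique(as.vector(bf[tag == tg, , drop = FALSE])))

  # inlet profile values (flow along +z; the inlet opening is z-normal)
  ctr <- colMeans(Vm[unique(as.vector(inlet_faces)), , drop = FALSE])
  rr2 <- (Vm[inlet_nodes, 1] - ctr[1])^2 + (Vm[inlet_nodes, 2] - ctr[2])^2
  R_in <- mm_to_m(inlet$r_cca)
  vin <- cms_to_ms(inlet$v_peak) * pmax(0, 1 - rr2 / R_in^2)

  dir_nodes <- c(wall_nodes, inlet_nodes)
  dir_vals <- matrix(0, length(dir_nodes), 3)
  dir_vals[length(wall_nodes) + seq_along(inlet_nodes), 3] <- vin
  free_v <- setdiff(seq_len(n), dir_nodes)
  all_out_nodes <- unique(unlist(outlet_nodes))
  free_p <- setdiff(seq_len(n), all_out_nodes)

  # time step: implicit viscosity, explicit convection -> convective limit
  h_min <- mm_to_m(mesh$edge_stats[["min"]])
  deg_max <- max(c(0, vapply(mesh$geom$stenoses, `[[`, numeric(1), "degree_nascet")))
  u_est <- cms_to_ms(inlet$v_peak) * max(1.3, 1.15 / (1 - deg_max / 100)^2)
  dt <- if (is.null(time_cfg$dt)) 0.45 * h_min / u_est else time_cfg$dt

  A1 <- Matrix::Diagonal(n, rho / dt * mats$ML) + mu * mats$K
  A1_ff <- A1[free_v, free_v]
  A1_fd <- A1[free_v, dir_nodes, drop = FALSE]
  chol_v <- Matrix::Cholesky(Matrix::forceSymmetric(A1_ff), LDL = FALSE)
  Kp_ff <- mesh_pressure_operator(mats$K, free_p)
  chol_p <- Matrix::Cholesky(Matrix::forceSymmetric(Kp_ff), LDL = FALSE)
  K_fd <- mats$K[free_p, all_out_nodes, drop = FALSE]

  fn <- face_normals_areas(Vm, bf)
  out_faces <- lapply(out_tags, function(tg) which(tag == tg))
  inlet_face_idx <- which(tag == 1L)

  # initial state
  u <- matrix(0, n, 3)
  init <- time_cfg$init
  if (init == "auto") init <- if (mesh$geom$kind == "tube") "profile" else "zero"
  if (init == "profile") {
    # flow-conserving developed profile: centerline scaled by the local area
    # ratio, so the start-up transient is short even through a stenosis
    rr2a <- (Vm[, 1] - ctr[1])^2 + (Vm[, 2] - ctr[2])^2
    r_loc <- R_in * branch_scale(mesh$geom$stenoses, "ica", mesh$node_meta$s)
    u[, 3] <- cms_to_ms(inlet$v_peak) * (R_in / r_loc)^2 *
      pmax(0, 1 - rr2a / r_loc^2)
    u[wall_nodes, ] <- 0
  }
  u[dir_nodes, ] <- dir_vals
  p <- rep(0, n)
  wk_state <- lapply(out_tags, function(...) windkessel_state())
  P_out <- vapply(outlets[names(out_tags)], function(o) {
    po <- outlet_spec_pressure(o); if (is.null(po)) 0 else po
  }, numeric(1))

  n_steps <- if (time_cfg$steady) time_cfg$max_steps else
    min(time_cfg$max_steps, ceiling(time_cfg$t_end / dt))
  hist <- numeric(0)
  converged <- FALSE
  # fixed-duration runs report the time-mean over the second half of the
  # march: transitional jets reach a statistically steady state whose
  # instantaneous fields oscillate
  avg_from <- if (time_cfg$steady) Inf else floor(n_steps / 2)
  u_acc <- 0; p_acc <- 0; acc_n <- 0L
  u_cap <- 40 * max(u_est, 1e-6)
  ML_f <- mats$ML

  for (step in seq_len(n_steps)) {
    w_t <- waveform_value(inlet, (step - 1) * dt)
    dir_vals_t <- dir_vals
    dir_vals_t[, 3] <- dir_vals[, 3] * w_t
    conv <- fem_convection(u, Tm, geo, mats)
    gp <- cbind(as.vector(mats$Gx %*% p), as.vector(mats$Gy %*% p),
                as.vector(mats$Gz %*% p))
    u_star <- matrix(0, n, 3)
    u_star[dir_nodes, ] <- dir_vals_t
    for (cc in 1:3) {
      rhs <- rho / dt * ML_f * u[, cc] - rho * conv[, cc] - gp[, cc]
      b <- rhs[free_v] - as.vector(A1_fd %*% dir_vals_t[, cc])
      u_star[free_v, cc] <- as.vector(Matrix::solve(chol_v, b))
    }
    # pressure increment: Kp phi = -(rho/dt) div u*, phi = P_out - p at outlets
    div_u <- as.vector(mats$Gx %*% u_star[, 1] + mats$Gy %*% u_star[, 2] +
                         mats$Gz %*% u_star[, 3])
    phi <- rep(0, n)
    phi[all_out_nodes] <- unlist(lapply(seq_along(out_tags), function(k) {
      rep(P_out[k], length(outlet_nodes[[k]]))
    })) - p[all_out_nodes]
    b_p <- -(rho / dt) * div_u[free_p] - as.vector(K_fd %*% phi[all_out_nodes])
    phi[free_p] <- as.vector(Matrix::solve(chol_p, b_p))
    p_new <- p + phi
    grad_phi <- cbind(as.vector(mats$Gx %*% phi), as.vector(mats$Gy %*% phi),
                      as.vector(mats$Gz %*% phi))
    u_new <- u_star - (dt / rho) * grad_phi / ML_f
    u_new[dir_nodes, ] <- dir_vals_t

    # outlet coupling (staggered): flux -> Windkessel -> next-step pressure
    for (k in seq_along(out_tags)) {
      o <- outlets[[names(out_tags)[k]]]
      if (inherits(o, "windkessel_params")) {
        q_k <- boundary_flux(u_new, bf[out_faces[[k]], , drop = FALSE],
                             list(normal = fn$normal[out_faces[[k]], , drop = FALSE]))
        if (time_cfg$steady) {
          P_out[k] <- 0.5 * P_out[k] + 0.5 * q_k * o$R  # resistive limit
        } else {
          wk_state[[k]] <- windkessel_step(wk_state[[k]], o, q_k, dt)
          P_out[k] <- wk_state[[k]]$P
        }
      }
    }

    # per-step change normalized to a 1 ms reference step, so the steady
    # criterion is a rate and does not weaken with small CFL-limited steps
    delta <- max(abs(u_new - u)) / max(max(abs(u_new)), 1e-12) * (1e-3 / dt)
    hist <- c(hist, delta)
    umax <- max(abs(u_new))
    if (!is.finite(umax) || umax > u_cap) {
      rlang::abort(paste0(
        "3D solve diverged at step ", step, " (|u|max = ", signif(umax, 3),
        " m/s); residual history tail: ",
        paste(signif(utils::tail(hist, 5), 3), collapse = ", ")))
    }
    u <- u_new; p <- p_new
    if (step > avg_from) {
      u_acc <- u_acc + u; p_acc <- p_acc + p; acc_n <- acc_n + 1L
    }
    if (time_cfg$steady && step > 5 && delta < time_cfg$steady_tol) {
      converged <- TRUE
      break
    }
  }
  if (!time_cfg$steady) {
    converged <- TRUE
    if (acc_n > 0L) {
      u <- u_acc / acc_n
      p <- p_acc / acc_n
    }
  }

  q_in <- -boundary_flux(u, bf[inlet_face_idx, , drop = FALSE],
                         list(normal = fn$normal[inlet_face_idx, , drop = FALSE]))
  out_summary <- dplyr::bind_rows(lapply(seq_along(out_tags), function(k) {
    q_k <- boundary_flux(u, bf[out_faces[[k]], , drop = FALSE],
                         list(normal = fn$normal[out_faces[[k]], , drop = FALSE]))
    tibble::tibble(outlet = names(out_tags)[k], q = m3s_to_mlmin(q_k),
                   p = pa_to_mmhg(P_out[k]))
  }))
  div_norm <- sqrt(sum((as.vector(mats$Gx %*% u[, 1] + mats$Gy %*% u[, 2] +
                                    mats$Gz %*% u[, 3]))^2))
  structure(list(
    mesh = mesh, velocity = ms_to_cms(u), pressure = pa_to_mmhg(p),
    t = dt * length(hist), dt = dt,
    boundary_faces = bf, boundary_tag = tag,
    inlet_flow = m3s_to_mlmin(q_in), outlets = out_summary,
    diagnostics = list(steps = length(hist), rel_change = utils::tail(hist, 1),
                       history = hist, div_norm = div_norm,
                       converged = converged),
    converged = converged, engine = "fem3d"
  ), class = "field_solution")
}

face_cap_from_mesh <- function(mesh, bf) {
  # recover per-node cap ids from the mesh's own tagged boundary
  cap <- integer(nrow(mesh$vertices))
  for (tg in 1:3) {
    fs <- mesh$boundary_faces[mesh$boundary_tag == tg, , drop = FALSE]
    cap[unique(as.vector(fs))] <- tg
  }
  # wall nodes shared with caps keep the cap id only if every incident
  # boundary face is capped; the tagging helper needs all-three-same anyway
  cap
}

mesh_pressure_operator <- function(K, free_p) K[free_p, free_p]

# outlet volume flux (m^3/s) of a stored field solution
outlet_flux <- function(solution, branch) {
  tg <- c(ica = 2L, eca = 3L)[[branch]]
  sel <- solution$boundary_tag == tg
  abort_if(!any(sel), "solution has no such outlet")
  Vm <- solution$mesh$vertices * 1e-3
  fn <- face_normals_areas(Vm, solution$boundary_faces[sel, , drop = FALSE])
  boundary_flux(cms_to_ms(solution$velocity),
                solution$boundary_faces[sel, , drop = FALSE], fn)
}

#' @export
print.field_solution <- function(x, ...) {
  cat("field_solution (3D FEM):", nrow(x$velocity), "nodes,",
      x$diagnostics$steps, "steps, dt =", signif(x$dt, 3), "s\n")
  cat(sprintf("  inflow %.1f ml/min; outlets: %s\n", x$inlet_flow,
              paste(sprintf("%s %.1f ml/min @ %.1f mmHg", x$outlets$outlet,
                            x$outlets$q, x$outlets$p), collapse = ", ")))
  cat(sprintf("  converged: %s (last rel change %.2e)\n", x$converged,
              x$diagnostics$rel_change))
  invisible(x)
}

#' Apply the mesh-independence stopping rule to a PSV sequence
#'
#' Returns the 1-based index of the first grid whose ICA peak systolic
#' velocity differs from the immediately preceding grid's by less than `tol`
#' relative to the preceding value, or `NA` if the rule never fires.
#'
#' @param psv Numeric vector of PSV readings over successive refinements.
#' @param tol Relative tolerance (default 0.1, i.e. the <10% rule).
#' @return Integer index (>= 2), or `NA_integer_`.
#' @export
independence_stop_index <- function(psv, tol = 0.1) {
  abort_if(!is.numeric(psv) || length(psv) < 2, "need at least two PSV values")
  abort_if(!is_number(tol) || tol <= 0, "`tol` must be strictly positive")
  rel <- abs(diff(psv)) / abs(psv[-length(psv)])
  hit <- which(rel < tol)
  if (length(hit) == 0) NA_integer_ else hit[1] + 1L
}

#' Mesh-independence study
#'
#' Re-meshes the geometry at successively refined maximum edge lengths
#' (factor `refinement_factor` per level), solves each grid with the 3D
#' engine, and stops at the first grid whose ICA PSV changed by less than
#' `tol` relative to the previous grid.
#'
#' @param geometry A [carotid_surface].
#' @param solve_cfg List with entries `fluid`, `inlet`, `outlets`,
#'   `time_cfg` (optional), `max_edge0` (coarsest grid), `min_edge`.
#' @param refinement_factor Multiplier (< 1) applied to the maximum edge
#'   length between levels.
#' @param tol Relative PSV tolerance (default 0.1).
#' @param max_levels Refinement budget.
#' @param branch Branch probed for PSV.
#' @return List with the selected `mesh`, its `solution`, the `psv` sequence
#'   (cm/s) and the stopping `level`.
#' @export
mesh_independence <- function(geometry, solve_cfg, refinement_factor = 0.7,
                              tol = 0.1, max_levels = 5, branch = "ica") {
  stopifnot(inherits(geometry, "carotid_surface"))
  abort_if(!is_number(refinement_factor) || refinement_factor <= 0 ||
             refinement_factor >= 1, "`refinement_factor` must lie in (0, 1)")
  abort_if(!is_number(tol) || tol <= 0, "`tol` must be strictly positive")
  psv <- numeric(0)
  meshes <- list(); sols <- list()
  max_edge <- solve_cfg$max_edge0
  for (lev in seq_len(max_levels)) {
    params <- mesh_params(min_edge = solve_cfg$min_edge %||% 0.08,
                          max_edge = max_edge)
    mesh <- suppressWarnings(generate_mesh(geometry, params))
    sol <- solve_fem3d(mesh, solve_cfg$fluid %||% fluid_properties(),
                       solve_cfg$inlet, solve_cfg$outlets,
                       solve_cfg$time_cfg %||% fem_time_config())
    meshes[[lev]] <- mesh; sols[[lev]] <- sol
    psv <- c(psv, extract_psv(sol, branch, "field_max_in_branch")$psv)
    idx <- if (lev >= 2) independence_stop_index(psv, tol) else NA_integer_
    if (!is.na(idx)) {
      return(list(mesh = meshes[[idx]], solution = sols[[idx]], psv = psv,
                  level = idx))
    }
    max_edge <- max_edge * refinement_factor
  }
  rlang::abort(paste0("mesh independence not reached after ", max_levels,
                      " levels; PSV sequence: ",
                      paste(signif(psv, 4), collapse = ", ")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
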