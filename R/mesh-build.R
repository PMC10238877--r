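# Structured tetrahedral meshing of parametric carotid lumens.
#
# Cross-sections are triangulated with a concentric-ring disk template
# (ring j carries 8j nodes, so the vertical diameter is a mesh polyline on
# every ring); layers are swept along each vessel's centerline and consecutive
# layers are joined into prisms, each split into three tetrahedra with a
# globally consistent (minimum-vertex-index) diagonal rule. At the
# bifurcation the disk splits along its vertical diameter: each half-disk is
# extruded along its branch axis while morphing into a circular section, the
# shared diameter nodes forming the flow-divider apex. In-plane spacing and
# axial steps scale with the local lumen diameter, which makes the grids
# diameter-adaptive: elements shrink where the lumen narrows.

disk_template <- function(m) {
  stopifnot(m >= 1)
  xy <- matrix(0, nrow = 1, ncol = 2)
  ring <- 0L
  ids_by_ring <- list(`0` = 1L)
  for (j in seq_len(m)) {
    nj <- 8L * j
    th <- pi / 2 + 2 * pi * (seq_len(nj) - 1) / nj
    rho <- j / m
    xy <- rbind(xy, cbind(rho * cos(th), rho * sin(th)))
    ring <- c(ring, rep.int(j, nj))
    ids_by_ring[[as.character(j)]] <- which(ring == j)
  }
  # snap septum nodes to exactly x = 0
  xy[abs(xy[, 1]) < 1e-12, 1] <- 0
  tri <- list()
  r1 <- ids_by_ring[["1"]]
  for (k in seq_along(r1)) {
    k2 <- if (k == length(r1)) 1L else k + 1L
    tri[[length(tri) + 1L]] <- c(1L, r1[k], r1[k2])
  }
  ang_of <- function(ids) {
    a <- atan2(xy[ids, 2], xy[ids, 1])
    (a - pi / 2) %% (2 * pi)  # relative angle, 0 at the +y septum node
  }
  for (j in seq_len(m - 1)) {
    A <- ids_by_ring[[as.character(j)]]
    B <- ids_by_ring[[as.character(j + 1)]]
    tri <- c(tri, ring_zip(A, ang_of(A), B, ang_of(B)))
  }
  tri <- do.call(rbind, tri)
  tx <- matrix(xy[tri, 1], ncol = 3)
  if (any(apply(tx, 1, min) < -1e-9 & apply(tx, 1, max) > 1e-9)) {
    rlang::abort("internal error: disk template triangle straddles the splitting diameter")
  }
  side <- ifelse(apply(tx, 1, min) > -1e-9, "right", "left")
  list(xy = xy, tri = tri, ring = ring, m = m,
       outer = ids_by_ring[[as.character(m)]], side = side)
}

# Stitch two concentric closed node rings (both ordered by increasing relative
# angle, both containing nodes at relative angles 0 and pi) into a triangle
# strip. Ties advance the inner ring first so that the two diameter-aligned
# radial edges are always part of the triangulation.
ring_zip <- function(a_ids, a_ang, b_ids, b_ang) {
  nA <- length(a_ids); nB <- length(b_ids)
  oa <- order(a_ang); ob <- order(b_ang)
  a_ids <- a_ids[oa]; a_ang <- a_ang[oa]
  b_ids <- b_ids[ob]; b_ang <- b_ang[ob]
  a_next <- c(a_ang[-1], 2 * pi)
  b_next <- c(b_ang[-1], 2 * pi)
  tris <- vector("list", nA + nB)
  i <- 1L; j <- 1L; k <- 0L
  cur_a <- function() a_ids[if (i <= nA) i else 1L]
  cur_b <- function() b_ids[if (j <= nB) j else 1L]
  while (i <= nA || j <= nB) {
    adv_a <- if (i > nA) FALSE else if (j > nB) TRUE else a_next[i] <= b_next[j]
    k <- k + 1L
    if (adv_a) {
      i2 <- if (i == nA) 1L else i + 1L
      tris[[k]] <- c(cur_a(), cur_b(), a_ids[i2])
      i <- i + 1L
    } else {
      j2 <- if (j == nB) 1L else j + 1L
      tris[[k]] <- c(cur_a(), cur_b(), b_ids[j2])
      j <- j + 1L
    }
  }
  tris[seq_len(k)]
}

# Split prisms (rows: b1 b2 b3 t1 t2 t3) into three tetrahedra each, with the
# diagonal of every quadrilateral face chosen through its smallest global
# vertex index. The rule is acyclic, so every prism admits a 3-tet split.
prisms_to_tets <- function(P) {
  stopifnot(is.matrix(P), ncol(P) == 6)
  p <- max.col(-P, ties.method = "first")  # position of the minimum
  flip <- p >= 4L
  if (any(flip)) {
    P[flip, ] <- P[flip, c(4L, 6L, 5L, 1L, 3L, 2L), drop = FALSE]
    p[flip] <- c(1L, 3L, 2L)[p[flip] - 3L]
  }
  rot1 <- p == 2L
  rot2 <- p == 3L
  if (any(rot1)) P[rot1, ] <- P[rot1, c(2L, 3L, 1L, 5L, 6L, 4L), drop = FALSE]
  if (any(rot2)) P[rot2, ] <- P[rot2, c(3L, 1L, 2L, 6L, 4L, 5L), drop = FALSE]
  # now the global minimum is b1; quad (b2,b3,t3,t2) picks its own diagonal
  q <- cbind(P[, 2], P[, 3], P[, 6], P[, 5])
  qmin <- max.col(-q, ties.method = "first")
  case1 <- qmin == 1L | qmin == 3L  # diagonal b2-t3
  n <- nrow(P)
  tets <- matrix(0L, nrow = 3 * n, ncol = 4)
  i1 <- seq_len(n)
  tets[i1, ] <- cbind(P[, 1], P[, 2], P[, 3], ifelse(case1, P[, 6], P[, 5]))
  tets[n + i1, ] <- cbind(P[, 1],
                          ifelse(case1, P[, 2], P[, 3]),
                          P[, 6], P[, 5])
  tets[2 * n + i1, ] <- cbind(P[, 1], P[, 4], P[, 5], P[, 6])
  tets
}

tet_volumes <- function(V, Tm) {
  a <- V[Tm[, 1], , drop = FALSE]
  b <- V[Tm[, 2], , drop = FALSE] - a
  c_ <- V[Tm[, 3], , drop = FALSE] - a
  d <- V[Tm[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
     b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

tet_boundary_faces <- function(Tm) {
  Fc <- rbind(Tm[, c(2, 3, 4)], Tm[, c(1, 4, 3)], Tm[, c(1, 2, 4)], Tm[, c(1, 3, 2)])
  a <- pmin(Fc[, 1], Fc[, 2], Fc[, 3])
  c_ <- pmax(Fc[, 1], Fc[, 2], Fc[, 3])
  b <- Fc[, 1] + Fc[, 2] + Fc[, 3] - a - c_
  o <- order(a, b, c_)
  aa <- a[o]; bb <- b[o]; cc <- c_[o]
  same_prev <- c(FALSE, aa[-1] == aa[-length(aa)] & bb[-1] == bb[-length(bb)] &
                   cc[-1] == cc[-length(cc)])
  same_next <- c(same_prev[-1], FALSE)
  solo <- !(same_prev | same_next)
  Fc[o[solo], , drop = FALSE]
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# combined stenosis diameter factor on one branch
branch_scale <- function(stenoses, branch, s) {
  k <- rep(1, length(s))
  for (st in stenoses) if (st$branch == branch) k <- k * stenosis_scale(st, s)
  k
}

# adaptive arclength grid: step proportional to the local diameter factor,
# floored so steps never fall below `floor_step`
walk_grid <- function(s0, s1, base_step, scale_fun, mandatory = numeric(0),
                      floor_step = 0) {
  local_step <- function(s) max(base_step * max(0.05, scale_fun(s)), floor_step)
  s <- s0
  out <- s0
  guard <- 0L
  while (s < s1 - 1e-9) {
    s <- min(s + local_step(s), s1)
    out <- c(out, s)
    guard <- guard + 1L
    if (guard > 2e5) rlang::abort("layer walk failed to terminate")
  }
  n <- length(out)
  if (n >= 3 && (out[n] - out[n - 1]) < 0.6 * local_step(out[n])) {
    out <- out[-(n - 1)]  # merge a short final interval into its neighbour
  }
  mandatory <- mandatory[mandatory > s0 + 1e-9 & mandatory < s1 - 1e-9]
  for (q in mandatory) {
    # snap the nearest walk point if close, otherwise insert: never leaves
    # sliver layers nor enlarged gaps
    interior <- out > s0 + 1e-9 & out < s1 - 1e-9
    d <- abs(out - q)
    i <- which.min(d + ifelse(interior, 0, Inf))
    if (length(i) && d[i] <= 0.55 * local_step(q)) out[i] <- q else out <- c(out, q)
  }
  sort(unique(out))
}

# Morph of the unit right half-disk onto the circle of radius rho tangent to
# the vertical diameter at the origin. The septum (x = 0) maps onto the left
# semicircle and the wall arc onto the right semicircle, both arc-length
# uniformly; interior rows map linearly onto the connecting chords, which
# keeps the map injective and its stretch bounded near the septum corners.
half_to_circle <- function(u, rho) {
  x <- u[, 1]; y <- pmin(pmax(u[, 2], -1), 1)
  w <- sqrt(pmax(0, 1 - y^2))
  lam <- ifelse(w > 1e-12, pmin(x / w, 1), 0)
  beta <- pi / 2 + (1 - y) * pi / 2
  Sx <- rho * (1 + cos(beta)); Sy <- rho * sin(beta)
  Wx <- rho * (1 + w);         Wy <- rho * y
  cbind((1 - lam) * Sx + lam * Wx, (1 - lam) * Sy + lam * Wy)
}

# --- lattice construction -------------------------------------------------

# geom: list(kind = "bifurcation"|"tube", spec, stenoses, ext)
build_lattice <- function(geom, max_edge, min_edge = 0.08) {
  he <- 0.47 * max_edge
  # template ring count: as fine as the max-edge bound asks, but never so fine
  # that throat-scaled in-plane edges drop below the min-edge floor
  ring_count <- function(r_ref, minscale) {
    m_fine <- as.integer(ceiling(r_ref / he))
    m_cap <- max(2L, as.integer(floor(0.74 * r_ref * minscale / min_edge)))
    max(2L, min(m_fine, m_cap))
  }
  if (geom$kind == "tube") {
    r <- geom$spec$radius
    s0 <- -geom$ext$inlet
    s1 <- geom$spec$length + geom$ext$outlet
    sgrid <- seq(s0, s1, length.out = 400)
    m <- ring_count(r, min(branch_scale(geom$stenoses, "ica", sgrid)))
    tpl <- disk_template(m)
    grid <- walk_grid(s0, s1, he, function(s) branch_scale(geom$stenoses, "ica", s),
                      mandatory = stenosis_points(geom$stenoses, "ica"),
                      floor_step = min_edge)
    kap <- branch_scale(geom$stenoses, "ica", grid)
    nl <- length(grid); nt <- nrow(tpl$xy)
    coords <- vector("list", nl)
    for (i in seq_len(nl)) {
      coords[[i]] <- cbind(r * kap[i] * tpl$xy[, 1], r * kap[i] * tpl$xy[, 2], grid[i])
    }
    V <- do.call(rbind, coords)
    LID <- matrix(seq_len(nl * nt), nrow = nl, ncol = nt, byrow = TRUE)
    tets <- block_tets(LID, tpl$tri)
    node_branch <- rep("ica", nrow(V))
    node_s <- rep(grid, each = nt)
    cap <- integer(nrow(V))
    cap[LID[1, ]] <- 1L   # inlet
    cap[LID[nl, ]] <- 2L  # single outlet reuses the ICA slot
    return(list(V = V, tets = tets, cap = cap, branch = node_branch, s = node_s,
                template_m = m))
  }

  sp <- geom$spec
  minscale <- {
    sc <- min(branch_scale(geom$stenoses, "cca", seq(0, sp$len_cca, length.out = 200)))
    for (br in c("ica", "eca")) {
      r_b <- if (br == "ica") sp$r_ica else sp$r_eca
      len_b <- if (br == "ica") sp$len_ica else sp$len_eca
      sc <- min(sc, (r_b / sp$r_cca) *
                  min(branch_scale(geom$stenoses, br, seq(0, len_b, length.out = 200))))
    }
    sc
  }
  m <- ring_count(sp$r_cca, minscale)
  tpl <- disk_template(m)
  nt <- nrow(tpl$xy)
  Tmorph <- 1.2 * sp$r_cca
  check_stenoses(geom, Tmorph)

  nodes <- list(); branch <- list(); svals <- list(); cap_marks <- list()
  n_nodes <- 0L
  push_layer <- function(coords, br, s, capv = 0L) {
    nodes[[length(nodes) + 1L]] <<- coords
    branch[[length(branch) + 1L]] <<- rep(br, nrow(coords))
    svals[[length(svals) + 1L]] <<- rep(s, nrow(coords))
    cap_marks[[length(cap_marks) + 1L]] <<- rep(as.integer(capv), nrow(coords))
    ids <- n_nodes + seq_len(nrow(coords))
    n_nodes <<- n_nodes + nrow(coords)
    ids
  }

  # CCA: arclength s measured from the apex (z = -s); inlet at the far end
  s_cca <- rev(walk_grid(0, sp$len_cca + geom$ext$inlet, he,
                         function(s) branch_scale(geom$stenoses, "cca", s),
                         mandatory = stenosis_points(geom$stenoses, "cca"),
                         floor_step = min_edge))
  kap <- branch_scale(geom$stenoses, "cca", s_cca)
  LID_cca <- matrix(0L, nrow = length(s_cca), ncol = nt)
  for (i in seq_along(s_cca)) {
    co <- cbind(sp$r_cca * kap[i] * tpl$xy[, 1], sp$r_cca * kap[i] * tpl$xy[, 2],
                -s_cca[i])
    LID_cca[i, ] <- push_layer(co, "cca", s_cca[i], capv = if (i == 1) 1L else 0L)
  }
  apex_ids <- LID_cca[nrow(LID_cca), ]
  tets <- list(block_tets(LID_cca, tpl$tri))

  build_branch <- function(br) {
    side_name <- if (br == "ica") "right" else "left"
    sub <- if (br == "ica") which(tpl$xy[, 1] > -1e-9) else which(tpl$xy[, 1] < 1e-9)
    idx_map <- integer(nt); idx_map[sub] <- seq_along(sub)
    tri_sub_rows <- tpl$tri[tpl$side == side_name, , drop = FALSE]
    tri_sub <- matrix(idx_map[tri_sub_rows], ncol = 3)
    u <- cbind(abs(tpl$xy[sub, 1]), tpl$xy[sub, 2])  # right-half convention
    r_b <- if (br == "ica") sp$r_ica else sp$r_eca
    len_b <- if (br == "ica") sp$len_ica else sp$len_eca
    ang <- (if (br == "ica") sp$angle_ica else sp$angle_eca) * pi / 180
    ext_b <- if (br == "ica") geom$ext$ica else geom$ext$eca
    rho <- r_b / sp$r_cca
    sgn <- if (br == "ica") 1 else -1

    Tbend <- 2.2 * sp$r_cca  # the axis turn is spread beyond the section morph
    theta_prime <- function(s) {
      u <- pmin(pmax(s / Tbend, 0), 1)
      ang * 6 * u * (1 - u) / Tbend
    }
    grid <- walk_grid(0, len_b + ext_b, he, function(s) {
      # finer steps while the section morphs; enlarge steps through the bend
      # so layer spacing at the section center stays nominal despite the
      # inner-curve compression
      morph_ref <- if (s < Tmorph) 0.85 else 1
      relief <- 1 / (1 - min(0.7, r_b * theta_prime(s)))
      morph_ref * relief * (r_b / sp$r_cca) * branch_scale(geom$stenoses, br, s)
    }, mandatory = c(Tmorph, stenosis_points(geom$stenoses, br)),
       floor_step = 1.45 * min_edge)  # bend compression shortens inner edges
    theta <- ang * smoothstep(grid / Tbend)
    g <- smoothstep(grid / Tmorph)
    kapb <- branch_scale(geom$stenoses, br, grid)
    # centerline by trapezoidal integration of the unit tangent
    ds <- diff(grid)
    cx <- cumsum(c(0, ds * (sin(theta[-1]) + sin(theta[-length(theta)])) / 2))
    cz <- cumsum(c(0, ds * (cos(theta[-1]) + cos(theta[-length(theta)])) / 2))
    target <- half_to_circle(u, rho)
    nl <- length(grid)
    LID <- matrix(0L, nrow = nl, ncol = length(sub))
    LID[1, ] <- apex_ids[sub]
    for (i in 2:nl) {
      q <- (1 - g[i]) * u + g[i] * target
      # stenosis scaling about the branch circle center (rho, 0)
      q <- cbind(rho + (q[, 1] - rho) * kapb[i], q[, 2] * kapb[i])
      X <- sp$r_cca * q[, 1]; Y <- sp$r_cca * q[, 2]
      ct <- cos(theta[i]); st <- sin(theta[i])
      co <- cbind(sgn * (cx[i] + X * ct), Y, cz[i] - X * st)
      LID[i, ] <- push_layer(co, br, grid[i],
                             capv = if (i == nl) (if (br == "ica") 2L else 3L) else 0L)
    }
    block_tets(LID, tri_sub)
  }

  tets[[2]] <- build_branch("ica")
  tets[[3]] <- build_branch("eca")
  V <- do.call(rbind, nodes)
  allt <- do.call(rbind, tets)
  br_vec <- unlist(branch, use.names = FALSE)
  # branch sections must stay above the apex plane (no dip into the CCA lumen)
  dip <- br_vec != "cca" & V[, 3] < -1e-6
  if (any(dip)) {
    rlang::abort("degenerate spec: branch sections intersect the CCA lumen (reduce branch angles or radii)")
  }
  list(V = V, tets = allt, cap = unlist(cap_marks, use.names = FALSE),
       branch = br_vec, s = unlist(svals, use.names = FALSE),
       template_m = m, t_morph = Tmorph)
}

stenosis_points <- function(stenoses, branch) {
  unlist(lapply(stenoses, function(st) {
    if (st$branch != branch || st$degree_nascet == 0) return(numeric(0))
    c(st$center_s - st$length / 2, st$center_s, st$center_s + st$length / 2)
  }))
}

check_stenoses <- function(geom, Tmorph) {
  sp <- geom$spec
  for (st in geom$stenoses) {
    lo <- st$center_s - st$length / 2
    hi <- st$center_s + st$length / 2
    if (st$branch == "cca") {
      abort_if(lo < 0.5 || hi > sp$len_cca,
               "CCA stenosis must lie within the CCA segment, clear of the apex")
    } else {
      len_b <- if (st$branch == "ica") sp$len_ica else sp$len_eca
      abort_if(lo < Tmorph,
               paste0("stenosis on the ", st$branch, " must start distal to the ",
                      "bifurcation transition (>= ", signif(Tmorph, 3), " mm)"))
      abort_if(hi > len_b, "stenotic segment extends beyond the branch")
    }
  }
  invisible(NULL)
}

block_tets <- function(LID, tri) {
  nl <- nrow(LID)
  if (nl < 2) rlang::abort("block needs at least two layers")
  L0 <- LID[-nl, , drop = FALSE]
  L1 <- LID[-1, , drop = FALSE]
  P <- cbind(as.vector(L0[, tri[, 1]]), as.vector(L0[, tri[, 2]]),
             as.vector(L0[, tri[, 3]]), as.vector(L1[, tri[, 1]]),
             as.vector(L1[, tri[, 2]]), as.vector(L1[, tri[, 3]]))
  prisms_to_tets(P)
}

#' Meshing parameters
#'
#' Edge-length bounds of the diameter-adaptive tetrahedral grids. The defaults
#' are the model's stated grid constraints (0.08 mm minimum and 0.5 mm maximum
#' edge length), which on a full twin produce grids in the million-element
#' range; desk-scale examples pass a coarser `max_edge`.
#'
#' @param min_edge Minimum admissible edge length (mm).
#' @param max_edge Maximum admissible edge length (mm).
#' @return An object of class `mesh_params`.
#' @export
mesh_params <- function(min_edge = 0.08, max_edge = 0.5) {
  abort_if(!is_number(min_edge) || min_edge <= 0, "`min_edge` must be positive")
  abort_if(!is_number(max_edge) || max_edge <= min_edge,
           "`max_edge` must exceed `min_edge`")
  structure(list(min_edge = min_edge, max_edge = max_edge), class = "mesh_params")
}

#' Generate a tetrahedral mesh of a carotid lumen
#'
#' Meshes a parametric lumen surface with the structured diameter-adaptive
#' sweeping scheme. Boundary faces are tagged `inlet` (1), `outlet_ica` (2),
#' `outlet_eca` (3) and `wall` (4); straight tubes use the `outlet_ica` slot
#' for their single outlet.
#'
#' @param surface A [build_bifurcation()] or [build_tube()] surface.
#' @param params A [mesh_params()].
#' @return An object of class `carotid_mesh` with fields `vertices` (mm),
#'   `tets`, `boundary_faces`, `boundary_tag`, `edge_stats`, `node_meta`.
#' @export
generate_mesh <- function(surface, params = mesh_params()) {
  stopifnot(inherits(surface, "carotid_surface"), inherits(params, "mesh_params"))
  lat <- build_lattice(surface$geom, max_edge = params$max_edge,
                       min_edge = params$min_edge)
  vol <- tet_volumes(lat$V, lat$tets)
  if (any(abs(vol) < 1e-12)) {
    rlang::abort("meshing failure: degenerate (zero-volume) elements; the spec is geometrically invalid at this resolution")
  }
  bf <- tet_boundary_faces(lat$tets)
  tag <- tag_boundary_faces(bf, lat$cap)
  es <- edge_stats_of(lat$V, lat$tets)
  if (es[["max"]] > params$max_edge * 1.05 || es[["min"]] < params$min_edge * 0.95) {
    rlang::warn(sprintf(
      "mesh edge lengths [%.3g, %.3g] mm fall outside the requested bounds [%.3g, %.3g] mm",
      es[["min"]], es[["max"]], params$min_edge, params$max_edge))
  }
  structure(list(
    vertices = lat$V, tets = lat$tets, boundary_faces = bf, boundary_tag = tag,
    tag_names = c(inlet = 1L, outlet_ica = 2L, outlet_eca = 3L, wall = 4L),
    edge_stats = es,
    node_meta = tibble::tibble(branch = lat$branch, s = lat$s),
    geom = surface$geom, params = params,
    coordinate_convention = "CCA axis = +z, bifurcation apex at origin, ICA toward +x"
  ), class = "carotid_mesh")
}

tag_boundary_faces <- function(bf, cap) {
  c1 <- cap[bf[, 1]]; c2 <- cap[bf[, 2]]; c3 <- cap[bf[, 3]]
  tag <- rep.int(4L, nrow(bf))
  same <- c1 > 0L & c1 == c2 & c2 == c3
  tag[same] <- c1[same]
  tag
}

edge_stats_of <- function(V, Tm) {
  pairs <- rbind(Tm[, c(1, 2)], Tm[, c(1, 3)], Tm[, c(1, 4)],
                 Tm[, c(2, 3)], Tm[, c(2, 4)], Tm[, c(3, 4)])
  d <- V[pairs[, 1], , drop = FALSE] - V[pairs[, 2], , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  c(min = min(len), max = max(len))
}

#' Edge-length statistics of a mesh
#'
#' @param mesh A [generate_mesh()] result.
#' @return Named numeric vector with `min` and `max` edge lengths (mm).
#' @export
mesh_edge_stats <- function(mesh) {
  stopifnot(inherits(mesh, "carotid_mesh"))
  mesh$edge_stats
}

#' Check that a mesh's boundary is watertight
#'
#' Every face of the tetrahedral lattice must be shared by at most two
#' elements, and the set of single-sided (boundary) faces must form a closed
#' surface: each boundary edge is used by exactly two boundary faces.
#'
#' @param mesh A [generate_mesh()] result.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
mesh_is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "carotid_mesh"))
  closed_surface_check(mesh$boundary_faces)
}

closed_surface_check <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  key <- paste(a, b)
  cnt <- table(key)
  if (any(cnt != 2)) {
    rlang::abort("surface is not watertight: boundary edges with face count != 2")
  }
  invisible(TRUE)
}

#' @export
print.carotid_mesh <- function(x, ...) {
  cat("carotid_mesh:", nrow(x$vertices), "vertices,", nrow(x$tets), "tetrahedra\n")
  cat(sprintf("  edge lengths: %.3g - %.3g mm\n", x$edge_stats[["min"]],
              x$edge_stats[["max"]]))
  cat("  boundary faces:", nrow(x$boundary_faces), "(",
      paste(names(x$tag_names), tabulate(x$boundary_tag, 4L), collapse = ", "), ")\n")
  cat(" ", x$coordinate_convention, "\n")
  invisible(x)
}
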