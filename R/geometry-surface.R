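# Lumen surfaces: parametric twins triangulated by the sweeping mesher.
# A carotid_surface keeps both the parametric description (spec, stenoses,
# flow extensions) and a triangulated boundary at the requested resolution,
# so downstream stages can re-mesh at any resolution from the parameters.

rebuild_surface <- function(geom, resolution) {
  lat <- build_lattice(geom, max_edge = resolution)
  bf <- tet_boundary_faces(lat$tets)
  tag <- tag_boundary_faces(bf, lat$cap)
  used <- sort(unique(as.vector(bf)))
  remap <- integer(nrow(lat$V)); remap[used] <- seq_along(used)
  structure(list(
    geom = geom, resolution = resolution,
    vertices = lat$V[used, , drop = FALSE],
    faces = matrix(remap[bf], ncol = 3),
    face_tag = tag,
    vertex_meta = tibble::tibble(branch = lat$branch[used], s = lat$s[used],
                                 cap = lat$cap[used]),
    template_m = lat$template_m,
    t_morph = if (geom$kind == "bifurcation") lat$t_morph else 0
  ), class = "carotid_surface")
}

#' Build a parametric carotid bifurcation lumen surface
#'
#' Constructs a closed triangulated lumen surface with three circular
#' openings (CCA inlet, ICA and ECA outlets) from a [bifurcation_spec()].
#' This is the synthetic stand-in for a segmented patient geometry.
#'
#' @param spec A [bifurcation_spec()].
#' @param resolution Target maximum edge length of the surface triangulation
#'   (mm).
#' @return An object of class `carotid_surface`.
#' @export
build_bifurcation <- function(spec, resolution = 1.2) {
  stopifnot(inherits(spec, "bifurcation_spec"))
  abort_if(!is_number(resolution) || resolution <= 0, "`resolution` must be positive")
  geom <- list(kind = "bifurcation", spec = spec, stenoses = list(),
               ext = list(inlet = 0, ica = 0, eca = 0), extended = FALSE)
  rebuild_surface(geom, resolution)
}

#' Build a straight tube lumen surface
#'
#' A single straight vessel along +z, used for analytic verification
#' (Poiseuille flow) and for idealized single-stenosis studies. Its one
#' outlet occupies the `outlet_ica` tag slot.
#'
#' @param radius Lumen radius (mm).
#' @param length Tube length (mm).
#' @param resolution Target maximum edge length (mm).
#' @return An object of class `carotid_surface`.
#' @export
build_tube <- function(radius, length, resolution = 1.2) {
  abort_if(!is_number(radius) || radius <= 0, "`radius` must be positive")
  abort_if(!is_number(length) || length <= 0, "`length` must be positive")
  geom <- list(kind = "tube", spec = list(radius = radius, length = length),
               stenoses = list(), ext = list(inlet = 0, outlet = 0),
               extended = FALSE)
  rebuild_surface(geom, resolution)
}

#' Narrow a lumen surface with a graded stenosis
#'
#' Applies an axisymmetric diameter reduction to one branch so that the
#' minimal lumen diameter in the stenotic segment equals
#' `(1 - degree/100)` times the branch's normal distal diameter. The lumen is
#' unchanged outside the stenotic segment. Degree 100 (occlusion) is
#' rejected at [stenosis_spec()] construction.
#'
#' @param surface A [carotid_surface].
#' @param sten A [stenosis_spec()]. On tube surfaces only the main branch
#'   (`"ica"`) is valid.
#' @return The narrowed `carotid_surface`.
#' @export
apply_stenosis <- function(surface, sten) {
  stopifnot(inherits(surface, "carotid_surface"), inherits(sten, "stenosis_spec"))
  geom <- surface$geom
  if (geom$kind == "tube") {
    abort_if(sten$branch != "ica", "tube surfaces carry stenoses on the main branch ('ica')")
    abort_if(sten$center_s - sten$length / 2 < 0 ||
               sten$center_s + sten$length / 2 > geom$spec$length,
             "stenotic segment must lie fully within the tube")
  }
  geom$stenoses <- c(geom$stenoses, list(sten))
  if (geom$kind == "bifurcation") {
    check_stenoses(geom, 1.2 * geom$spec$r_cca)  # fail early, before meshing
  }
  rebuild_surface(geom, surface$resolution)
}

#' Append flow extensions to all openings
#'
#' Adds straight cylindrical extensions at the inlet and outlet(s) so the
#' flow can develop before reaching the region of interest. The default
#' length is three CCA diameters, the accepted validity threshold for the
#' extension approach. A second application is rejected.
#'
#' @param surface A [carotid_surface].
#' @param length Extension length (mm); defaults to `3 * 2 * r_cca` (three
#'   CCA diameters; for tubes, three tube diameters). Shorter values are
#'   rejected.
#' @return The extended `carotid_surface`.
#' @export
add_flow_extensions <- function(surface, length = NULL) {
  stopifnot(inherits(surface, "carotid_surface"))
  geom <- surface$geom
  abort_if(isTRUE(geom$extended), "surface already has flow extensions")
  d_ref <- if (geom$kind == "tube") 2 * geom$spec$radius else 2 * geom$spec$r_cca
  if (is.null(length)) length <- 3 * d_ref
  abort_if(!is_number(length) || length < 3 * d_ref,
           sprintf("extension length must be at least three reference diameters (%g mm)", 3 * d_ref))
  if (geom$kind == "tube") {
    geom$ext <- list(inlet = length, outlet = length)
  } else {
    geom$ext <- list(inlet = length, ica = length, eca = length)
  }
  geom$extended <- TRUE
  rebuild_surface(geom, surface$resolution)
}

triangle_areas <- function(V, Fc) {
  a <- V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 2], , drop = FALSE] - a
  c_ <- V[Fc[, 3], , drop = FALSE] - a
  n <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
             b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
             b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sqrt(rowSums(n * n)) / 2
}

#' Area of a surface opening
#'
#' @param surface A [carotid_surface].
#' @param opening `"inlet"`, `"outlet_ica"` or `"outlet_eca"`.
#' @return Opening area (mm^2).
#' @export
opening_area <- function(surface, opening = c("inlet", "outlet_ica", "outlet_eca")) {
  stopifnot(inherits(surface, "carotid_surface"))
  opening <- match.arg(opening)
  tag <- c(inlet = 1L, outlet_ica = 2L, outlet_eca = 3L)[[opening]]
  sel <- surface$face_tag == tag
  abort_if(!any(sel), paste0("surface has no opening tagged ", opening))
  sum(triangle_areas(surface$vertices, surface$faces[sel, , drop = FALSE]))
}

#' Minimal lumen diameter along a branch
#'
#' Measured from the triangulated surface: for each swept section the lumen
#' diameter is the largest chord between wall vertices; the
#' minimum over sections in `s_range` gives the minimal diameter. For
#' bifurcation branches the default range excludes the bifurcation transition
#' zone, where sections are not circular.
#'
#' @param surface A [carotid_surface].
#' @param branch `"cca"`, `"ica"` or `"eca"` (tubes: `"ica"`).
#' @param s_range Arclength window (mm) to search, `c(lo, hi)`.
#' @return Minimal lumen diameter (mm).
#' @export
min_lumen_diameter <- function(surface, branch = "ica", s_range = NULL) {
  stopifnot(inherits(surface, "carotid_surface"))
  vm <- surface$vertex_meta
  if (is.null(s_range)) {
    if (surface$geom$kind == "tube") {
      s_range <- c(0, surface$geom$spec$length)
    } else {
      len_b <- switch(branch, cca = surface$geom$spec$len_cca,
                      ica = surface$geom$spec$len_ica,
                      eca = surface$geom$spec$len_eca)
      s_range <- if (branch == "cca") c(0, len_b) else c(surface$t_morph, len_b)
    }
  }
  sel <- vm$branch == branch & vm$s >= s_range[1] - 1e-9 & vm$s <= s_range[2] + 1e-9
  abort_if(!any(sel), "no surface vertices in the requested branch/arclength window")
  V <- surface$vertices[sel, , drop = FALSE]
  svals <- round(vm$s[sel], 9)
  d_layer <- vapply(split(seq_len(nrow(V)), svals), function(ii) {
    P <- V[ii, , drop = FALSE]
    max(stats::dist(P))  # max chord: the diameter for (near-)circular sections
  }, numeric(1))
  min(d_layer)
}

#' @export
print.carotid_surface <- function(x, ...) {
  cat("carotid_surface (", x$geom$kind, "): ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " triangles\n", sep = "")
  if (length(x$geom$stenoses)) {
    for (st in x$geom$stenoses) {
      cat(sprintf("  stenosis: %s, %.0f%% NASCET, center %.1f mm, length %.1f mm (%s)\n",
                  st$branch, st$degree_nascet, st$center_s, st$length, st$profile))
    }
  }
  if (isTRUE(x$geom$extended)) cat("  flow extensions:", x$geom$ext$inlet, "mm\n")
  invisible(x)
}
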