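# Mesh and surface export: VTU (VTK XML unstructured grid) and Gmsh MSH 4.1
# ASCII for volumetric grids, STL for lumen surfaces. The MSH reader parses
# the subset this package writes (one node block, tagged surface and volume
# element blocks).

#' Write a mesh (and optional nodal fields) to a VTU file
#'
#' @param mesh A [generate_mesh()] result.
#' @param path Output file path (`.vtu`).
#' @param point_data Optional named list of per-node vectors (scalars) or
#'   3-column matrices (vectors) to attach, e.g. velocity and pressure.
#' @return `path`, invisibly.
#' @export
write_mesh_vtu <- function(mesh, path, point_data = list()) {
  stopifnot(inherits(mesh, "carotid_mesh"))
  V <- mesh$vertices; Tm <- mesh$tets
  n <- nrow(V); m <- nrow(Tm)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(V[, 1], V[, 2], V[, 3]), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(Tm[, 1] - 1L, Tm[, 2] - 1L, Tm[, 3] - 1L, Tm[, 4] - 1L), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(m) * 4L), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("10", m), con)
  w('        </DataArray>')
  w('      </Cells>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      x <- point_data[[nm]]
      if (is.matrix(x) && ncol(x) == 3) {
        w('        <DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm)
        writeLines(paste(x[, 1], x[, 2], x[, 3]), con)
      } else {
        w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
        writeLines(as.character(x), con)
      }
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Write a mesh to Gmsh MSH 4.1 ASCII
#'
#' Nodes are written in one block; boundary triangles are grouped into 2D
#' entities named by their tag (1 inlet, 2 outlet_ica, 3 outlet_eca,
#' 4 wall); tetrahedra form one 3D entity.
#'
#' @param mesh A [generate_mesh()] result.
#' @param path Output file path (`.msh`).
#' @return `path`, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  stopifnot(inherits(mesh, "carotid_mesh"))
  V <- mesh$vertices; Tm <- mesh$tets
  bf <- mesh$boundary_faces; tag <- mesh$boundary_tag
  n <- nrow(V)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  tags_present <- sort(unique(tag))
  w("$Entities")
  w("0 0 %d 1", length(tags_present))
  for (tg in tags_present) w("%d 0 0 0 0 0 0 1 %d 0", tg, tg)
  w("1 0 0 0 0 0 0 1 1 0")
  w("$EndEntities")
  w("$Nodes")
  w("1 %d 1 %d", n, n)
  w("3 1 0 %d", n)
  writeLines(as.character(seq_len(n)), con)
  writeLines(paste(V[, 1], V[, 2], V[, 3]), con)
  w("$EndNodes")
  w("$Elements")
  n_blocks <- length(tags_present) + 1L
  n_elem <- nrow(bf) + nrow(Tm)
  w("%d %d 1 %d", n_blocks, n_elem, n_elem)
  eid <- 0L
  for (tg in tags_present) {
    sel <- which(tag == tg)
    w("2 %d 2 %d", tg, length(sel))
    writeLines(paste(eid + seq_along(sel), bf[sel, 1], bf[sel, 2], bf[sel, 3]), con)
    eid <- eid + length(sel)
  }
  w("3 1 4 %d", nrow(Tm))
  writeLines(paste(eid + seq_len(nrow(Tm)), Tm[, 1], Tm[, 2], Tm[, 3], Tm[, 4]), con)
  w("$EndElements")
  invisible(path)
}

#' Read a mesh written by [write_mesh_msh()]
#'
#' Parses the MSH 4.1 ASCII subset this package emits and rebuilds the
#' tagged `carotid_mesh` (without parametric metadata).
#'
#' @param path Path to a `.msh` file.
#' @return A `carotid_mesh` with vertices, tetrahedra and tagged boundary.
#' @export
read_mesh_msh <- function(path) {
  ln <- readLines(path)
  sec <- function(name) {
    i0 <- which(ln == paste0("$", name)); i1 <- which(ln == paste0("$End", name))
    abort_if(length(i0) != 1 || length(i1) != 1, paste0("malformed MSH: ", name))
    ln[(i0 + 1):(i1 - 1)]
  }
  nd <- sec("Nodes")
  hdr <- as.integer(strsplit(nd[1], " ")[[1]])
  n <- hdr[2]
  coords <- do.call(rbind, lapply(nd[(2 + n + 1):(2 + 2 * n)], function(s)
    as.numeric(strsplit(s, " ")[[1]])))
  el <- sec("Elements")
  i <- 2L
  faces <- list(); ftag <- list(); tets <- list()
  while (i <= length(el)) {
    bh <- as.integer(strsplit(el[i], " ")[[1]])  # dim, entity, type, count
    rows <- el[i + seq_len(bh[4])]
    vals <- do.call(rbind, lapply(rows, function(s) as.integer(strsplit(s, " ")[[1]])))
    if (bh[3] == 2L) {
      faces[[length(faces) + 1L]] <- vals[, 2:4, drop = FALSE]
      ftag[[length(ftag) + 1L]] <- rep.int(bh[2], nrow(vals))
    } else if (bh[3] == 4L) {
      tets[[length(tets) + 1L]] <- vals[, 2:5, drop = FALSE]
    }
    i <- i + 1L + bh[4]
  }
  V <- coords
  Tm <- do.call(rbind, tets)
  bf <- do.call(rbind, faces)
  structure(list(
    vertices = V, tets = Tm, boundary_faces = bf,
    boundary_tag = unlist(ftag),
    tag_names = c(inlet = 1L, outlet_ica = 2L, outlet_eca = 3L, wall = 4L),
    edge_stats = edge_stats_of(V, Tm),
    node_meta = tibble::tibble(branch = NA_character_, s = NA_real_,
                               .rows = nrow(V)),
    geom = list(kind = "imported", stenoses = list()),
    coordinate_convention = "as imported"
  ), class = "carotid_mesh")
}

#' Write a lumen surface to ASCII STL
#'
#' @param surface A [carotid_surface].
#' @param path Output file path (`.stl`).
#' @param solid_name Name recorded in the STL header.
#' @return `path`, invisibly.
#' @export
write_surface_stl <- function(surface, path, solid_name = "carotid_lumen") {
  stopifnot(inherits(surface, "carotid_surface"))
  V <- surface$vertices; Fc <- surface$faces
  a <- V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 2], , drop = FALSE] - a
  c_ <- V[Fc[, 3], , drop = FALSE] - a
  nrm <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
               b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
               b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  nn <- sqrt(rowSums(nrm^2)); nn[nn == 0] <- 1
  nrm <- nrm / nn
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", solid_name), con)
  v1 <- V[Fc[, 1], , drop = FALSE]
  v2 <- V[Fc[, 2], , drop = FALSE]
  v3 <- V[Fc[, 3], , drop = FALSE]
  block <- paste0(
    "  facet normal ", nrm[, 1], " ", nrm[, 2], " ", nrm[, 3], "\n",
    "    outer loop\n",
    "      vertex ", v1[, 1], " ", v1[, 2], " ", v1[, 3], "\n",
    "      vertex ", v2[, 1], " ", v2[, 2], " ", v2[, 3], "\n",
    "      vertex ", v3[, 1], " ", v3[, 2], " ", v3[, 3], "\n",
    "    endloop\n",
    "  endfacet")
  writeLines(block, con)
  writeLines(paste("endsolid", solid_name), con)
  invisible(path)
}
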