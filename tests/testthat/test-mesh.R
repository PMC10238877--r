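# Tetrahedral meshing: element validity, watertightness, boundary tags,
# diameter-adaptive edge sizing, refinement behaviour, and file round-trips.

test_that("tube meshes carry positive volumes and fully tagged boundaries", {
  mesh <- suppressWarnings(generate_mesh(build_tube(3, 20, 1.5),
                                         mesh_params(0.2, 1.5)))
  vol <- carotidtwin:::tet_volumes(mesh$vertices, mesh$tets)
  expect_gt(min(abs(vol)), 0)
  expect_rel(sum(abs(vol)), pi * 9 * 20, 0.03)   # polygonal lumen area deficit
  expect_true(all(mesh$boundary_tag %in% 1:4))
  expect_true(all(c(1L, 2L, 4L) %in% mesh$boundary_tag))
  expect_silent(mesh_is_watertight(mesh))
})

test_that("bifurcation meshes are watertight with all four tags", {
  mesh <- suppressWarnings(generate_mesh(stenosed_bifurcation(),
                                         mesh_params(0.15, 1.4)))
  expect_silent(mesh_is_watertight(mesh))
  expect_setequal(unique(mesh$boundary_tag), 1:4)
  vol <- carotidtwin:::tet_volumes(mesh$vertices, mesh$tets)
  expect_gt(min(abs(vol)), 0)
})

test_that("a full twin at the default edge bounds meets them", {
  # mildly stenosed twin with realistic radii; shortened segments keep the
  # element count desk-scale while exercising the full construction
  sp <- bifurcation_spec(r_cca = 3.2, r_ica = 2.2, r_eca = 2.0,
                         len_cca = 14, len_ica = 16, len_eca = 14)
  tw <- apply_stenosis(build_bifurcation(sp, 1.4),
                       stenosis_spec("ica", 30, center_s = 10, length = 6))
  mesh <- generate_mesh(tw, mesh_params())   # defaults: 0.08 / 0.5 mm
  es <- mesh_edge_stats(mesh)
  expect_gte(es[["min"]], 0.08)
  expect_lte(es[["max"]], 0.5)
  expect_gt(nrow(mesh$tets), 1e5)
})

test_that("halving the maximum edge length increases the element count", {
  tube <- build_tube(2.5, 15, 1.6)
  m1 <- suppressWarnings(generate_mesh(tube, mesh_params(0.2, 1.6)))
  m2 <- suppressWarnings(generate_mesh(tube, mesh_params(0.1, 0.8)))
  expect_gt(nrow(m2$tets), nrow(m1$tets))
})

test_that("grids are diameter-adaptive: finer where the lumen narrows", {
  tube <- apply_stenosis(build_tube(2.5, 24, 1.2),
                         stenosis_spec("ica", 50, center_s = 12, length = 8))
  mesh <- suppressWarnings(generate_mesh(tube, mesh_params(0.1, 1.2)))
  s <- mesh$node_meta$s
  throat <- which(abs(s - 12) < 2)
  away <- which(s < 6 | s > 20)
  # mean axial layer spacing near the throat vs away from it
  sp_throat <- mean(diff(sort(unique(round(s[throat], 6)))))
  sp_away <- mean(diff(sort(unique(round(s[away], 6)))))
  expect_lt(sp_throat, 0.7 * sp_away)
})

test_that("mirror-image specs give identical element counts", {
  sp_a <- bifurcation_spec(r_ica = 2.4, r_eca = 2.0, len_cca = 14,
                           len_ica = 16, len_eca = 14)
  sp_b <- bifurcation_spec(r_ica = 2.0, r_eca = 2.4, len_cca = 14,
                           len_ica = 16, len_eca = 14)
  m_a <- suppressWarnings(generate_mesh(build_bifurcation(sp_a, 1.5),
                                        mesh_params(0.15, 1.5)))
  m_b <- suppressWarnings(generate_mesh(build_bifurcation(sp_b, 1.5),
                                        mesh_params(0.15, 1.5)))
  expect_lt(abs(nrow(m_a$tets) - nrow(m_b$tets)) / nrow(m_a$tets), 0.05)
})

test_that("consistent-diagonal prism splitting conserves volume", {
  set.seed(11)
  for (rep in 1:50) {
    base <- matrix(stats::runif(6, -1, 1), 3, 2)
    h <- stats::runif(1, 0.5, 2)
    off <- stats::runif(2, -0.3, 0.3)
    bot <- cbind(base, 0)
    top <- cbind(base + matrix(off, 3, 2, byrow = TRUE), h)
    V <- rbind(bot, top)
    area <- abs((base[2, 1] - base[1, 1]) * (base[3, 2] - base[1, 2]) -
                  (base[3, 1] - base[1, 1]) * (base[2, 2] - base[1, 2])) / 2
    ids <- sample(6)   # arbitrary global numbering drives the diagonal rule
    Vg <- matrix(0, 6, 3)
    Vg[ids, ] <- V     # global vertex table: corner j carries id ids[j]
    tets <- carotidtwin:::prisms_to_tets(matrix(ids, nrow = 1))
    vols <- abs(carotidtwin:::tet_volumes(Vg, tets))
    expect_equal(sum(vols), area * h, tolerance = 1e-10)
  }
})

test_that("meshes round-trip through MSH and export to VTU/STL", {
  mesh <- suppressWarnings(generate_mesh(build_tube(2, 10, 1.5),
                                         mesh_params(0.25, 1.5)))
  tmp <- withr::local_tempdir()
  msh <- file.path(tmp, "tube.msh")
  write_mesh_msh(mesh, msh)
  back <- read_mesh_msh(msh)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-12)
  expect_equal(back$tets, mesh$tets)
  expect_equal(sort(table(back$boundary_tag)), sort(table(mesh$boundary_tag)))
  vtu <- file.path(tmp, "tube.vtu")
  write_mesh_vtu(mesh, vtu, point_data = list(p = seq_len(nrow(mesh$vertices))))
  expect_true(any(grepl("UnstructuredGrid", readLines(vtu, n = 5))))
  stl <- file.path(tmp, "tube.stl")
  write_surface_stl(build_tube(2, 10, 1.5), stl)
  stl_lines <- readLines(stl)
  expect_true(grepl("^solid", stl_lines[1]))
  expect_true(grepl("^endsolid", stl_lines[length(stl_lines)]))
})
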