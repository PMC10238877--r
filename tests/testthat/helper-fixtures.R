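# Shared fixtures, built once per test session. Geometries are desk-scale
# (short segments, coarse grids) so the whole suite stays fast; resolutions
# are chosen for numerical verification, not clinical fidelity.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

short_spec <- function(...) {
  bifurcation_spec(len_cca = 20, len_ica = 25, len_eca = 20, ...)
}

coarse_bifurcation <- function() {
  fixture("coarse_bifurcation", function() build_bifurcation(short_spec(), 1.4))
}

stenosed_bifurcation <- function() {
  fixture("stenosed_bifurcation", function() {
    apply_stenosis(coarse_bifurcation(),
                   stenosis_spec("ica", 47, center_s = 12, length = 8))
  })
}

poiseuille_field <- function() {
  fixture("poiseuille_field", function() {
    tube <- build_tube(2, 12, resolution = 1.0)
    mesh <- suppressWarnings(generate_mesh(tube, mesh_params(0.1, 1.0)))
    sol <- solve_fem3d(mesh, fluid_properties(), inlet_profile(50, 2),
                       outlets = list(ica = list(P = 0)))
    list(tube = tube, mesh = mesh, sol = sol)
  })
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
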