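# Parametric lumen construction: specs, NASCET grading, stenosis narrowing,
# flow extensions, symmetry and watertightness.

test_that("specification invariants are enforced", {
  expect_error(bifurcation_spec(r_cca = -1), "positive")
  expect_error(bifurcation_spec(r_ica = 4, r_cca = 3.5), "r_ica")
  expect_error(bifurcation_spec(angle_ica = 95), "angles")
  expect_error(stenosis_spec("ica", 100, center_s = 10), "occlusion")
  expect_error(stenosis_spec("ica", -5, center_s = 10), "degree_nascet")
  expect_silent(stenosis_spec("ica", 0, center_s = 10))
})

test_that("NASCET degree follows its defining ratio and rejects bad input", {
  expect_equal(nascet_degree(5, 5), 0)
  expect_equal(nascet_degree(0, 5), 100)
  expect_equal(nascet_degree(2.65, 5.0), 47)
  expect_error(nascet_degree(6, 5), "exceeds")
  expect_error(nascet_degree(1, -2), "positive")
})

test_that("NASCET bands are left-closed with exact 10/50/70 boundaries", {
  expect_equal(as.character(classify_nascet(c(0, 9.999, 10, 47, 49.999, 50,
                                              51, 69.999, 70, 99))),
               c("free", "free", "mild", "mild", "mild", "moderate",
                 "moderate", "moderate", "severe", "severe"))
  expect_error(classify_nascet(100), "\\[0, 100\\)")
  expect_error(classify_nascet(-1), "\\[0, 100\\)")
})

test_that("bifurcation surfaces are watertight with circular openings", {
  bs <- coarse_bifurcation()
  expect_silent(carotidtwin:::closed_surface_check(bs$faces))
  expect_rel(opening_area(bs, "inlet"), pi * 3.5^2, 0.01)
  expect_rel(opening_area(bs, "outlet_ica"), pi * 2.5^2, 0.01)
  expect_rel(opening_area(bs, "outlet_eca"), pi * 2.0^2, 0.01)
})

test_that("symmetric specs produce mirror-symmetric surfaces", {
  sp <- bifurcation_spec(r_ica = 2.2, r_eca = 2.2, len_cca = 15,
                         len_ica = 18, len_eca = 18,
                         angle_ica = 30, angle_eca = 30)
  bs <- build_bifurcation(sp, 1.4)
  vi <- bs$vertices[bs$vertex_meta$branch == "ica", ]
  ve <- bs$vertices[bs$vertex_meta$branch == "eca", ]
  expect_equal(nrow(vi), nrow(ve))
  expect_lt(max(abs(sort(vi[, 1]) - sort(-ve[, 1]))), 1e-9)
  expect_lt(max(abs(sort(vi[, 3]) - sort(ve[, 3]))), 1e-9)
})

test_that("stenosis narrows the lumen to the prescribed NASCET diameter", {
  bs <- stenosed_bifurcation()  # 47% on the ICA, distal diameter 5 mm
  d_min <- min_lumen_diameter(bs, "ica")
  expect_rel(d_min, (1 - 0.47) * 5, 0.02)
  # a deeper stenosis narrows strictly further
  bs51 <- apply_stenosis(coarse_bifurcation(),
                         stenosis_spec("ica", 51, center_s = 12, length = 8))
  expect_lt(min_lumen_diameter(bs51, "ica"), d_min)
})

test_that("zero-degree stenosis leaves the surface vertexwise unchanged", {
  bs0 <- apply_stenosis(coarse_bifurcation(),
                        stenosis_spec("ica", 0, center_s = 12, length = 8))
  expect_identical(bs0$vertices, coarse_bifurcation()$vertices)
})

test_that("grading round-trips through the built geometry across degrees", {
  for (deg in c(10, 30, 50, 70, 90)) {
    tube <- apply_stenosis(build_tube(2.5, 30, resolution = 1.3),
                           stenosis_spec("ica", deg, center_s = 15, length = 10))
    rec <- nascet_degree(min_lumen_diameter(tube, "ica"), 5.0)
    expect_lt(abs(rec - deg), 2)
  }
})

test_that("flow extensions lengthen every opening by three CCA diameters", {
  bs <- coarse_bifurcation()
  ext <- add_flow_extensions(bs)
  expect_true(ext$geom$extended)
  expect_gte(ext$geom$ext$inlet, 3 * 2 * 3.5)
  # opening stays circular with the branch radius
  expect_rel(opening_area(ext, "outlet_ica"), pi * 2.5^2, 0.01)
  # the extended CCA spans the extra length
  expect_gt(diff(range(ext$vertices[, 3])) ,
            diff(range(bs$vertices[, 3])) + 20)
  expect_error(add_flow_extensions(ext), "already")
  expect_error(add_flow_extensions(bs, length = 5), "at least three")
})

test_that("stenoses outside the branch or inside the transition are rejected", {
  bs <- coarse_bifurcation()
  expect_error(apply_stenosis(bs, stenosis_spec("ica", 30, center_s = 2,
                                                length = 4)),
               "transition")
  expect_error(apply_stenosis(bs, stenosis_spec("ica", 30, center_s = 24,
                                                length = 6)),
               "beyond the branch")
  tube <- build_tube(2, 20, resolution = 1.3)
  expect_error(apply_stenosis(tube, stenosis_spec("ica", 30, center_s = 19,
                                                  length = 6)),
               "fully within")
})

test_that("geometrically impossible specs are rejected with a message", {
  sp <- bifurcation_spec(r_cca = 3.5, r_ica = 3.4, r_eca = 3.3,
                         len_cca = 12, len_ica = 15, len_eca = 15,
                         angle_ica = 80, angle_eca = 80)
  expect_error(build_bifurcation(sp, 1.4), "degenerate|inverted|intersect")
})
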