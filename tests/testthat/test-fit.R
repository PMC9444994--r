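# Template personalization: pose initialization, mesh fitting, accuracy,
# contraction fields.

test_that("fit configuration guards", {
  expect_error(fit_config(tolerance = 0), "positive")
  expect_error(fit_config(max_iterations = 0), "at least 1")
  expect_error(fit_config(lambda = -1), "non-negative")
})

test_that("pose initialization is near-identity on the template's own slices", {
  tpl <- fx_template()
  # top slice half a gap below the basal rim so the longitudinal convention
  # is exact; the apex is localized by the quadratic area extrapolation
  zs <- seq(-58, 22, by = 8)
  ct <- slice_mesh_contours(tpl, zs, slice_gap = 8)
  pose <- initialize_pose(tpl, ct)
  expect_equal(pose$rot, diag(3))
  expect_equal(pose$s_xy, 1, tolerance = 0.03)
  expect_equal(pose$s_z, 1, tolerance = 0.03)
  expect_lt(max(abs(pose$translation[1:2])), 0.5)
  expect_lt(abs(pose$translation[3]), 2.5)
  expect_error(initialize_pose(tpl, slice_mesh_contours(tpl, c(-40, 0))),
               "at least 3")
})

test_that("apply_pose composes scale, rotation and translation", {
  tpl <- fx_template()
  pose <- list(rot = diag(3), s_xy = 2, s_z = 0.5, translation = c(1, 2, 3))
  out <- apply_pose(tpl, pose)
  expect_equal(out$nodes[, 1], 2 * tpl$nodes[, 1] + 1, ignore_attr = TRUE)
  expect_equal(out$nodes[, 3], 0.5 * tpl$nodes[, 3] + 3, ignore_attr = TRUE)
})

test_that("point-triangle distances match analytic cases", {
  v1 <- matrix(c(0, 0, 0), 1)
  v2 <- matrix(c(1, 0, 0), 1)
  v3 <- matrix(c(0, 1, 0), 1)
  ptd <- lvshape:::point_triangle_dist
  expect_equal(ptd(c(0.2, 0.2, 1), v1, v2, v3), 1)          # interior face
  expect_equal(ptd(c(2, 0, 0), v1, v2, v3), 1)              # vertex region
  expect_equal(ptd(c(0.5, -1, 0), v1, v2, v3), 1)           # edge region
  expect_equal(ptd(c(1, 1, 0), v1, v2, v3), sqrt(0.5))      # hypotenuse
  expect_equal(ptd(c(0.1, 0.1, 0), v1, v2, v3), 0)          # on the face
})

test_that("fitting the template's own contours is near-exact", {
  tpl <- fx_template()
  # dense-slice limit: the basal half-gap convention is exact and the apex
  # quadratic localization sees near-apical areas, isolating the
  # projection/smoothing machinery itself
  zs <- seq(-61, 25, by = 2)
  ct <- slice_mesh_contours(tpl, zs, slice_gap = 2)
  fit <- fit_mesh(tpl, ct)
  err <- sqrt(rowSums((fit$nodes - tpl$nodes)^2))
  expect_lt(mean(err), 0.5)
  acc <- fit_accuracy(fit, ct)
  expect_lt(acc$median, 0.3)
  info <- attr(fit, "fit_info")
  expect_true(info$converged)
  expect_true(info$thickness_ok)
})

test_that("non-convergence inside the iteration cap is reported", {
  fixture <- fx_deformed_fixture()
  expect_warning(
    fit_mesh(fixture$template, fixture$contours,
             fit_config(max_iterations = 1, tolerance = 1e-6)),
    "did not converge")
})

test_that("clean-stack fit reaches sub-pixel median accuracy", {
  co <- fx_cohort_raster()
  tpl <- fx_template()
  stack <- co$subjects[[1]]$stack
  ct <- extract_contours(stack, 1)
  fit <- fit_mesh(tpl, ct)
  acc <- fit_accuracy(fit, ct)
  expect_lte(acc$median, 1)
  expect_length(acc$iqr, 2L)
  expect_true(all(acc$distances >= 0))
})

test_that("fitted volumes track the generator ground truth", {
  co <- fx_cohort_raster()
  tpl <- fx_template()
  rel_err <- function(a, b) abs(a - b) / b
  for (i in 1:3) {
    s <- co$subjects[[i]]
    ph <- detect_phases(s$stack)
    ed_fit <- fit_mesh(tpl, extract_contours(s$stack, ph$ed_frame))
    es_fit <- fit_mesh(tpl, extract_contours(s$stack, ph$es_frame))
    v <- mesh_volumes(ed_fit, es_fit)
    expect_lt(rel_err(v$edv, co$table$edv[i]), 0.10)
    expect_lt(rel_err(v$esv, co$table$esv[i]), 0.10)
  }
})

test_that("contraction field removes bulk translation and checks topology", {
  co <- fx_cohort_small()
  s <- co$subjects[[1]]
  cf <- contraction_field(s$ed_mesh, s$es_mesh)
  expect_s3_class(cf, "contraction_field")
  expect_equal(unname(colMeans(cf$displacements)), c(0, 0, 0),
               tolerance = 1e-12)
  shifted <- s$es_mesh
  shifted$nodes <- sweep(shifted$nodes, 2, c(3, -2, 5), `+`)
  cf2 <- contraction_field(s$ed_mesh, shifted)
  expect_equal(cf2$displacements, cf$displacements, tolerance = 1e-12)
  expect_error(contraction_field(s$ed_mesh, build_template(25, 13)),
               "topology")
  expect_output(print(cf), "Contraction field")
})
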