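# Mesh geometry: volumes, LVEF, wall thickness, AHA-17, alignment.

# Closed-form cavity volume of a truncated ellipsoid with a flat basal cap:
# V = pi a^2 * integral_{-c}^{zb} (1 - z^2/c^2) dz.
truncated_ellipsoid_volume_ml <- function(a, c_ax, z_base) {
  f <- function(z) z - z^3 / (3 * c_ax^2)
  pi * a^2 * (f(z_base) - f(-c_ax)) / 1000
}

test_that("cavity volume matches the closed form on both surfaces", {
  tpl <- fx_template()
  g <- tpl$geometry
  v_endo <- truncated_ellipsoid_volume_ml(g$a_endo, g$c_endo, g$z_base)
  v_epi <- truncated_ellipsoid_volume_ml(g$a_endo + g$wall,
                                         g$c_endo + g$apex_thickness, g$z_base)
  expect_lt(abs(mesh_cavity_volume(tpl) - v_endo) / v_endo, 0.01)
  expect_lt(abs(mesh_cavity_volume(tpl, "epi") - v_epi) / v_epi, 0.01)
  expect_lt(abs(mesh_myocardial_volume(tpl) - (v_epi - v_endo)) /
              (v_epi - v_endo), 0.02)
})

test_that("volume integration converges with resolution", {
  g <- lv_geometry_params()
  v_true <- truncated_ellipsoid_volume_ml(g$a_endo, g$c_endo, g$z_base)
  err <- vapply(c(24, 48, 96), function(nc) {
    abs(mesh_cavity_volume(build_template(nc, nc %/% 2 + 1, g)) - v_true)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("volume scales with the cube of a uniform scale factor", {
  tpl <- fx_template()
  v0 <- mesh_cavity_volume(tpl)
  for (s in c(0.7, 1.3)) {
    scaled <- tpl
    scaled$nodes <- tpl$nodes * s
    expect_equal(mesh_cavity_volume(scaled), s^3 * v0, tolerance = 1e-12)
  }
})

test_that("non-star-shaped rings trigger a volume warning", {
  tpl <- fx_template()
  bad <- tpl
  sel <- which(bad$param$layer == "endo" & bad$param$v == 12)
  # collapse one ring to a figure-eight shaped curve
  t8 <- 2 * pi * seq_along(sel) / length(sel)
  bad$nodes[sel, 1] <- 20 * sin(2 * t8)
  bad$nodes[sel, 2] <- 10 * sin(t8)
  expect_warning(mesh_cavity_volume(bad), "star-shaped")
})

test_that("lvef arithmetic and guards", {
  expect_equal(lvef(100, 45), 55)
  expect_equal(lvef(c(100, 200), c(50, 50)), c(50, 75))
  expect_lt(lvef(80, 90), 0)
  expect_error(lvef(0, 10), "positive")
})

test_that("mesh_volumes is consistent with its parts", {
  co <- fx_cohort_small()
  s <- co$subjects[[1]]
  v <- mesh_volumes(s$ed_mesh, s$es_mesh)
  expect_equal(v$edv, mesh_cavity_volume(s$ed_mesh))
  expect_equal(v$lvef, lvef(v$edv, v$esv))
  expect_equal(v$myocardial_mass_volume, mesh_myocardial_volume(s$ed_mesh))
  other <- build_template(25, 13)
  expect_error(mesh_volumes(s$ed_mesh, other), "topology")
})

test_that("wall thickness map is positive with the exact apex thickness", {
  tpl <- fx_template()
  th <- wall_thickness(tpl)
  expect_equal(dim(th), c(tpl$n_circ, tpl$n_long))
  expect_true(all(th > 0))
  expect_equal(unname(th[, 1]), rep(tpl$geometry$apex_thickness, tpl$n_circ),
               tolerance = 1e-12)
})

test_that("AHA-17 map follows the standard layout", {
  tpl <- fx_template()
  map <- aha17_map(tpl)
  expect_setequal(sort(unique(as.integer(map))), 1:17)
  # anterior meridian: segment 1 at base, 7 mid, 13 apical, 17 at the cap
  expect_equal(map[1, tpl$n_long], 1L)
  expect_equal(map[1, 1], 17L)
  ant_col <- map[1, ]
  expect_true(all(ant_col %in% c(1L, 7L, 13L, 17L)))
  # zone ordering from apex cap to base along any meridian
  zone_of <- function(s) ifelse(s == 17, 0L,
                                ifelse(s >= 13, 1L, ifelse(s >= 7, 2L, 3L)))
  expect_true(all(diff(zone_of(map[5, ])) >= 0))
  unoriented <- tpl
  unoriented$anterior_u <- NULL
  expect_error(aha17_map(unoriented), "anterior_u")
})

test_that("segment aggregation averages per segment", {
  tpl <- fx_template()
  map <- aha17_map(tpl)
  vals <- segment_aggregate(map, map)  # mean of the label itself = the label
  expect_equal(unname(vals), as.numeric(1:17))
  expect_named(vals, paste0("segment_", 1:17))
  expect_error(segment_aggregate(map, 1:5), "differ")
})

test_that("canonical alignment undoes a known rigid transform", {
  tpl <- fx_template()
  th <- 0.7
  axis_rot <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  twist <- rbind(c(cos(0.4), -sin(0.4), 0), c(sin(0.4), cos(0.4), 0), c(0, 0, 1))
  rot <- axis_rot %*% twist
  moved <- tpl
  moved$nodes <- sweep(tpl$nodes %*% t(rot), 2, c(12, -5, 30), `+`)
  aligned <- canonical_align(moved, orientation = list(
    long_axis = as.numeric(rot %*% c(0, 0, 1)),
    anterior = as.numeric(rot %*% c(1, 0, 0))))
  centered <- sweep(tpl$nodes, 2, colMeans(tpl$nodes))
  expect_lt(max(abs(aligned$nodes - centered)), 1e-8)
  expect_error(canonical_align(moved, list(long_axis = c(0, 0, 0),
                                           anterior = c(1, 0, 0))),
               "degenerate")
  expect_error(canonical_align(moved, list(long_axis = c(0, 0, 1),
                                           anterior = c(0, 0, 2))),
               "degenerate|parallel")
})
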