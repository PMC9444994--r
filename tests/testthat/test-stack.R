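# Stack-level mask operations: cavity filling, phase detection, Dice,
# contour extraction, exclusion filter.

# Hand-built ring mask: annulus between r_in and r_out on an n x n grid.
ring_mask <- function(n = 24, r_in = 4, r_out = 8) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  (d <= r_out & d > r_in) * 1L
}

disk_pixels <- function(n = 24, r = 4) {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  sum(d <= r)
}

test_that("cavity filling recovers the enclosed disk exactly", {
  ring <- ring_mask()
  fc <- lvshape:::fill_cavity(ring)
  expect_false(fc$flagged)
  expect_equal(sum(fc$cavity), disk_pixels())
  expect_false(any(fc$cavity & ring == 1))
})

test_that("broken rings are filled best-effort and flagged", {
  ring <- ring_mask()
  ring[12:13, ] <- ring[12:13, ] * 0L  # cut the annulus open
  fc <- lvshape:::fill_cavity(ring)
  expect_true(fc$flagged || !any(fc$cavity))
  vox <- array(ring, c(24, 24, 1, 2))
  stack <- cine_stack(vox, c(1, 1), c(0, 0), 0, 8)
  expect_warning(blood_pool_area(stack, 1, 1), "broken|no closed")
})

test_that("blood-pool area converts pixels with the pixel area", {
  vox <- array(ring_mask(), c(24, 24, 1, 2))
  stack <- cine_stack(vox, c(1.5, 1.5), c(0, 0), 0, 8)
  expect_equal(blood_pool_area(stack, 1, 1), disk_pixels() * 1.5^2)
  expect_error(blood_pool_area(stack, 2, 1), "out of range")
  expect_error(blood_pool_area(stack, 1, 3), "out of range")
})

test_that("phase detection finds extremal areas with earliest-tie rule", {
  # 5 frames with inner radii 6,5,3,3,5: ED at frame 1, ES tie at 3 and 4
  radii <- c(6, 5, 3, 3, 5)
  vox <- array(0L, c(24, 24, 1, 5))
  for (f in 1:5) vox[, , 1, f] <- ring_mask(r_in = radii[f], r_out = 9)
  stack <- cine_stack(vox, c(1, 1), c(0, 0), 0, 8)
  ph <- detect_phases(stack)
  expect_equal(ph$ed_frame, 1L)
  expect_equal(ph$es_frame, 3L)
  expect_equal(ph$mid_slice, 1L)
})

test_that("degenerate stacks are rejected by phase detection", {
  vox <- array(0L, c(24, 24, 1, 3))
  stack <- cine_stack(vox, c(1, 1), c(0, 0), 0, 8)
  expect_error(detect_phases(stack), "no ring-bearing slice")
  vox2 <- array(ring_mask(), c(24, 24, 1, 3))
  stack2 <- cine_stack(vox2, c(1, 1), c(0, 0), 0, 8)
  expect_error(detect_phases(stack2), "indistinct")
  expect_error(detect_phases(cine_stack(array(0L, c(4, 4, 1, 1)),
                                        c(1, 1), c(0, 0), 0, 8)),
               "two frames")
})

test_that("phase detection recovers the generator phases on mask stacks", {
  co <- fx_cohort_raster()
  for (s in co$subjects) {
    ph <- detect_phases(s$stack)
    expect_equal(ph$ed_frame, 1L)
    expect_equal(ph$es_frame, co$config$es_frame)
  }
})

test_that("dice matches hand-computed overlaps", {
  a <- matrix(0, 4, 4)
  b <- a
  a[1:2, 1:2] <- 1  # 4 pixels
  b[2, 1:2] <- 1    # 2 pixels, both inside a
  expect_equal(dice(a, b), 2 * 2 / (4 + 2))
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, matrix(0, 4, 4)), 0)
  expect_equal(dice(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
  expect_error(dice(a, matrix(0, 3, 3)), "differ")
})

test_that("extracted contours are CCW, positioned, and omissions recorded", {
  co <- fx_cohort_raster()
  stack <- co$subjects[[1]]$stack
  ct <- extract_contours(stack, 1)
  expect_s3_class(ct, "lv_contours")
  expect_gt(length(ct$slices), 3)
  shoelace2 <- function(p) {
    sum(p[, 1] * c(p[-1, 2], p[1, 2]) - c(p[-1, 1], p[1, 1]) * p[, 2]) / 2
  }
  for (s in ct$slices) {
    expect_gt(shoelace2(s$endo), 0)
    expect_gt(shoelace2(s$epi), 0)
    expect_equal(s$z, stack$slice_positions[s$slice])
    expect_gt(shoelace2(s$epi), shoelace2(s$endo))
  }
  all_slices <- seq_len(dim(stack$voxels)[3])
  expect_setequal(c(vapply(ct$slices, `[[`, numeric(1), "slice"),
                    ct$omitted), all_slices)
  expect_error(extract_contours(stack, 99), "out of range")
})

test_that("contours rasterize back onto the source mask (Dice round trip)", {
  co <- fx_cohort_raster()
  stack <- co$subjects[[1]]$stack
  ct <- extract_contours(stack, 1)
  xs <- lvshape:::stack_axis(stack, 1)
  ys <- lvshape:::stack_axis(stack, 2)
  d <- vapply(ct$slices, function(s) {
    m <- lvshape:::rasterize_ring(matrix(FALSE, length(xs), length(ys)),
                                  xs, ys, outer = s$epi, inner = s$endo)
    dice(m, stack$voxels[, , s$slice, 1])
  }, numeric(1))
  expect_gt(median(d), 0.95)
  expect_true(all(d > 0.85))
})

test_that("exact mesh slicing returns analytic contours", {
  tpl <- fx_template()
  ct <- slice_mesh_contours(tpl, c(-40, 0, 20), slice_gap = 8)
  expect_equal(length(ct$slices), 3L)
  r <- sqrt(ct$slices[[2]]$endo[, 1]^2 + ct$slices[[2]]$endo[, 2]^2)
  expect_equal(mean(r), tpl$geometry$a_endo, tolerance = 0.01)
  ct2 <- slice_mesh_contours(tpl, c(-100, 0), slice_gap = 8)
  expect_equal(ct2$omitted, 1L)
})

test_that("exclusion filter removes non-positive LVEF with a logged reason", {
  df <- data.frame(id = 1:4, lvef = c(55, -3, 0, 40))
  ex <- exclusion_filter(df)
  expect_equal(ex$kept, c(1L, 4L))
  expect_equal(ex$excluded, c(2L, 3L))
  expect_match(ex$log$reason, "non-positive", all = TRUE)
  empty <- exclusion_filter(df[0, ])
  expect_length(empty$kept, 0)
  expect_equal(nrow(empty$log), 0L)
})
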