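test_that("an empty scene renders to a constant patch", {
  eye <- eye_model("human")
  pose <- data.frame(index = 1L, x = 0, y = 1.8, z = 0, heading_deg = 0)
  p <- render_patch(build_empty_scene(0.4), pose, NULL, vf_coord(0, 0), eye,
                    512, 120, 32)
  expect_equal(dim(p$pixels), c(32, 32, 3))
  expect_true(all(abs(p$pixels - 0.4) < 1e-12))
})

test_that("off-axis patches agree with crops of a full-frame render", {
  eye <- eye_model("human")
  # smooth scene so values vary continuously with ray direction
  sc <- build_forest_scene(3, trunk_density = 0, clutter_density = 0)
  pose <- data.frame(index = 1L, x = 0.3, y = 1.8, z = -0.2, heading_deg = 40)
  view <- c(heading_deg = 40, elevation_deg = -10)
  res <- 96
  pitch <- 2 * (2 * eye$radius_mm) * tan(pi / 3) / res
  frame <- render_patch(sc, pose, view, vf_coord(0, 0), eye, res, 120, res,
                        supersample = 1)
  # place the patch center on an exact frame pixel column offset
  k <- 12
  co <- vf_coord(atan(k * pitch / (2 * eye$radius_mm)) * 180 / pi, 0)
  n <- 24
  patch <- render_patch(sc, pose, view, co, eye, res, 120, n, supersample = 1)
  ctr <- (res + 1) / 2
  cols <- (k - n / 2 + ctr + 0.5):(k + n / 2 + ctr - 0.5)
  rows <- (ctr - n / 2 + 0.5):(ctr + n / 2 - 0.5)
  expect_equal(patch$pixels, frame$pixels[rows, cols, , drop = FALSE],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("patches exceeding the frame can be rejected on request", {
  eye <- eye_model("human")
  sc <- build_empty_scene()
  pose <- data.frame(index = 1L, x = 0, y = 1.8, z = 0, heading_deg = 0)
  expect_error(render_patch(sc, pose, NULL, vf_coord(58, 45), eye, 512, 120,
                            200, enforce_frame_bounds = TRUE),
               "exceeds the 120-deg frame")
  # default behavior extends the frustum instead
  expect_silent(render_patch(sc, pose, NULL, vf_coord(55, 45), eye, 512, 120,
                             16))
})

test_that("luminance conversion follows the XYZ Y channel", {
  white <- array(1, dim = c(4, 4, 3))
  expect_true(all(to_luminance(white) == 1))
  gray <- array(0.37, dim = c(4, 4, 3))
  expect_equal(to_luminance(gray), matrix(0.37, 4, 4), tolerance = 1e-12)
  red <- array(0, dim = c(4, 4, 3)); red[, , 1] <- 1
  green <- array(0, dim = c(4, 4, 3)); green[, , 2] <- 1
  expect_gt(to_luminance(green)[1, 1], to_luminance(red)[1, 1])
  bad <- array(1.4, dim = c(2, 2, 3))
  expect_warning(y <- to_luminance(bad), "clamped")
  expect_true(all(y == 1))
})

test_that("mean normalization is exact, idempotent and scale invariant", {
  set.seed(4)
  m <- matrix(rexp(64 * 64) + 0.1, 64)
  n1 <- normalize_mean(m)
  expect_equal(mean(n1), 1, tolerance = 1e-12)
  expect_equal(normalize_mean(n1), n1, tolerance = 1e-12)
  expect_equal(normalize_mean(10 * m), n1, tolerance = 1e-12)
  expect_equal(normalize_mean(matrix(5, 8, 8)), matrix(1, 8, 8))
  expect_error(normalize_mean(matrix(0, 8, 8)), "not positive")
})

test_that("a vertical trunk produces vertically oriented edges", {
  eye <- eye_model("human")
  sc <- build_forest_scene(3, trunk_density = 0, clutter_density = 0)
  sc$trunks <- cbind(cx = 3, cz = 0, radius = 0.25, height = 8)
  # untextured trunk, no ground/horizon: the occluding boundaries of the
  # cylinder carry the orientation signal
  sc$trunk_tex$noise_amp <- 0
  sc$trunk_tex$band_v_amp <- 0
  sc$trunk_tex$band_h_amp <- 0
  sc$ground <- NULL
  sc$background_tex <- NULL
  pose <- data.frame(index = 1L, x = 0, y = 1.8, z = 0, heading_deg = 0)
  p <- to_luminance(render_patch(sc, pose, NULL, vf_coord(0, 0), eye,
                                 512, 120, 64))
  edges <- edge_orientations(normalize_mean(p))
  expect_gt(nrow(edges), 20)
  expect_lt(median(ori_diff(edges$orientation_deg, 90)), 5)
})

test_that("ensemble capture enumerates poses x grid and is deterministic", {
  eye <- eye_model("human")
  tr <- generate_trajectory(1, 2, eye)
  plan <- ensemble_plan(tr, visual_field_grid())
  expect_equal(nrow(plan), 34)
  expect_equal(anyDuplicated(plan[, c("pose_index", "phi_deg", "chi_deg")]), 0L)

  sc <- build_random_edge_scene(6, 60)
  grid <- visual_field_grid(c(0, 30), c(0, 180))
  s1 <- capture_ensemble(sc, tr, gaze_spec("straight"), eye, grid,
                         scene_resolution_px = 256, patch_px = 24)
  s2 <- capture_ensemble(sc, tr, gaze_spec("straight"), eye, grid,
                         scene_resolution_px = 256, patch_px = 24)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$patches, s2$patches)
  expect_equal(nrow(s1$manifest), 2 * 3)
  expect_true(all(vapply(s1$patches, function(p) is.matrix(p$pixels), TRUE)))

  # tangent twins double the store and carry the projection label
  s3 <- capture_ensemble(sc, tr, gaze_spec("straight"), eye, grid,
                         scene_resolution_px = 256, patch_px = 24,
                         tangent = TRUE)
  expect_equal(nrow(s3$manifest), 12)
  expect_equal(sum(s3$manifest$projection == "tangent"), 6)
})

test_that("central crops require parity alignment", {
  m <- matrix(1:64, 8)
  expect_equal(crop_center(m, 4), m[3:6, 3:6])
  expect_error(crop_center(m, 5), "parity")
})
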