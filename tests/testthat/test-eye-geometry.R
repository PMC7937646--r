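test_that("eye models carry the thin-lens relation and species presets", {
  h <- eye_model("human")
  expect_equal(h$focal_length_mm, 16.67)
  expect_equal(h$radius_mm, h$focal_length_mm / 2)
  expect_equal(h$eye_height_m, 1.8)
  c_ <- eye_model("cat")
  expect_equal(c_$focal_length_mm, 12.5)
  expect_equal(c_$eye_height_m, 0.25)
  expect_equal(eye_model("human", focal_length_mm = 2)$radius_mm, 1)
})

test_that("visual-field coordinates canonicalize the center", {
  expect_equal(vf_coord(0, 135)$chi_deg, 0)
  expect_equal(vf_coord(30, 370)$chi_deg, 10)
  expect_error(vf_coord(90, 0), "eccentricity")
  expect_error(vf_coord(-1, 0), "eccentricity")
})

test_that("plane points follow the projective-plane mapping", {
  h <- eye_model("human")
  expect_equal(plane_point(vf_coord(0, 0), h), c(0, 0, -16.67))
  expect_equal(plane_point(vf_coord(45, 0), eye_model("human", focal_length_mm = 2)),
               c(2, 0, -2))
  # high-precision evaluation at phi = 30, chi = 90
  p <- plane_point(vf_coord(30, 90), h)
  expect_equal(p[1], 0, tolerance = 1e-12)
  expect_equal(p[2], 16.67 * tan(pi / 6), tolerance = 1e-10)
  expect_equal(p[2], 9.6249, tolerance = 1e-4)
  expect_equal(p[3], -16.67)
})

test_that("sphere points lie on the retinal sphere and share the plane ray", {
  h <- eye_model("human")
  expect_equal(sphere_point(vf_coord(0, 0), h), plane_point(vf_coord(0, 0), h))
  s <- sphere_point(vf_coord(45, 90), eye_model("human", focal_length_mm = 2))
  expect_equal(s, c(0, 1, -1), tolerance = 1e-12)
  p30 <- sphere_point(vf_coord(30, 0), h)
  expect_equal(p30[1], 7.2185, tolerance = 1e-4)
  expect_equal(p30[3], -12.5025, tolerance = 1e-3)

  # sphere membership and along-ray correspondence over a coordinate grid
  ctr <- c(0, 0, -h$radius_mm)
  set.seed(1)
  for (i in 1:250) {
    co <- vf_coord(runif(1, 0, 89), runif(1, 0, 360))
    s <- sphere_point(co, h)
    expect_lt(abs(sqrt(sum((s - ctr)^2)) - h$radius_mm), 1e-9 * h$radius_mm)
    p <- plane_point(co, h)
    # same ray through the origin: cross product ~ 0
    cr <- c(s[2] * p[3] - s[3] * p[2], s[3] * p[1] - s[1] * p[3],
            s[1] * p[2] - s[2] * p[1])
    expect_lt(max(abs(cr)), 1e-9 * h$radius_mm^2)
  }
})

test_that("tangent planes are orthonormal and correctly tilted", {
  h <- eye_model("human")
  tp0 <- tangent_plane_at(vf_coord(0, 0), h)
  expect_equal(tp0$normal, c(0, 0, -1), tolerance = 1e-12)
  expect_equal(tp0$tangent_point_mm[3], -2 * h$radius_mm)

  for (co in list(vf_coord(30, 0), vf_coord(50, 123), vf_coord(10, 300))) {
    tp <- tangent_plane_at(co, h)
    expect_lt(abs(sum(tp$normal * tp$basis[, 1])), 1e-12)
    expect_lt(abs(sum(tp$normal * tp$basis[, 2])), 1e-12)
    expect_lt(abs(sum(tp$basis[, 1] * tp$basis[, 2])), 1e-12)
    expect_equal(sum(tp$basis[, 1]^2), 1, tolerance = 1e-12)
    expect_equal(sum(tp$basis[, 2]^2), 1, tolerance = 1e-12)
    expect_lt(abs(sqrt(sum((tp$tangent_point_mm - tp$center_mm)^2)) - h$radius_mm),
              1e-9 * h$radius_mm)
  }
  # central angle of the tangent point is twice the eccentricity
  tp30 <- tangent_plane_at(vf_coord(30, 0), h)
  ang <- acos(sum(tp30$normal * c(0, 0, -1))) * 180 / pi
  expect_equal(ang, 60, tolerance = 1e-9)
})

test_that("the homography is identity at the center and maps center to center", {
  h <- eye_model("human")
  H0 <- homography_for(vf_coord(0, 0), h, 0.01)$matrix
  expect_equal(H0, diag(3), tolerance = 1e-9, ignore_attr = TRUE)

  for (co in list(vf_coord(30, 0), vf_coord(50, 315), vf_coord(20, 77))) {
    hh <- homography_for(co, h, 0.02)
    expect_equal(hh$matrix[3, 3], 1)
    ctr <- apply_homography(hh, c(0, 0))
    expect_lt(max(abs(ctr)), 1e-6)
    # scale invariance after homogeneous normalization
    q1 <- apply_homography(hh$matrix, c(5, -3))
    q2 <- apply_homography(3.7 * hh$matrix, c(5, -3))
    expect_equal(q1, q2, tolerance = 1e-12)
  }
})

test_that("warping preserves constants and inverts cleanly", {
  h <- eye_model("human")
  co <- vf_coord(30, 30)
  pitch <- 2 * (2 * h$radius_mm) * tan(pi / 3) / 512
  hom <- homography_for(co, h, pitch)

  cst <- matrix(2.5, 120, 120)
  w <- warp_to_tangent(cst, hom, 64)
  expect_true(all(w$pixels[w$valid] == 2.5))
  expect_identical(w$projection, "tangent")

  # identity homography, matched sizes: bit-identical central crop
  idm <- structure(list(matrix = diag(3)), class = "homography")
  src <- matrix(rnorm(80 * 80), 80)
  out <- warp_to_tangent(src, idm, 40, supersample = 1)
  expect_identical(out$pixels, crop_center(src, 40))

  # round trip of a smooth gradient: RMS error below 1% of range
  g <- outer(seq(0, 1, length = 160), seq(1, 2, length = 160),
             function(a, b) a + sin(3 * a) + b)
  fw <- warp_to_tangent(g, hom, 120, supersample = 1)
  hinv <- structure(list(matrix = solve(hom$matrix)), class = "homography")
  bk <- warp_to_tangent(fw$pixels, hinv, 80, supersample = 1)
  ref <- crop_center(g, 80)
  ok <- is.finite(bk$pixels)
  rms <- sqrt(mean((bk$pixels[ok] - ref[ok])^2))
  expect_lt(rms / diff(range(ref)), 0.01)

  # oversized requests fail loudly, naming the largest valid size
  expect_error(warp_to_tangent(matrix(0, 40, 40), hom, 64, require_full = TRUE),
               "maximum fully valid output size")
})

test_that("tangent approximation error is monotone, symmetric, and vanishing", {
  h <- eye_model("human")
  # monotone in eccentricity
  errs <- vapply(c(10, 20, 30, 40, 50), function(phi)
    tangent_approx_error(vf_coord(phi, 0), h, 64, 5954, 120), 1)
  expect_true(all(diff(errs) > 0))
  # monotone in patch size
  e1 <- tangent_approx_error(vf_coord(30, 0), h, 32, 5954, 120)
  e2 <- tangent_approx_error(vf_coord(30, 0), h, 96, 5954, 120)
  expect_gt(e2, e1)
  # single-pixel patch: tangency
  expect_lt(tangent_approx_error(vf_coord(30, 0), h, 1, 5954, 120), 1e-12)
  # rotational symmetry in chi
  ref <- tangent_approx_error(vf_coord(30, 0), h, 64, 5954, 120)
  for (chi in c(45, 133, 270)) {
    expect_lt(abs(tangent_approx_error(vf_coord(30, chi), h, 64, 5954, 120) - ref),
              1e-9)
  }
  # perpendicular pairing is also available and no larger than along-ray
  perp <- tangent_approx_error(vf_coord(30, 0), h, 128, 5954, 120,
                               method = "perpendicular")
  expect_lt(perp, tangent_approx_error(vf_coord(30, 0), h, 128, 5954, 120))
})
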