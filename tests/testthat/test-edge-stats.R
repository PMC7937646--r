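test_that("derivative pair responds to ramps and ignores constants", {
  n <- 32
  ramp <- matrix(rep(seq_len(n), each = n), n) # I = x (varies along columns)
  g <- gradient_pair(ramp)
  inner <- g$valid
  expect_true(all(g$gx[inner] > 0.9))
  expect_lt(max(abs(g$gy[inner])), 1e-10)
  g0 <- gradient_pair(matrix(5, n, n))
  expect_lt(max(abs(g0$gx)), 1e-12)
  expect_lt(max(abs(g0$gy)), 1e-12)
  expect_error(gradient_pair(matrix(0, 8, 8)), "at least 16")
})

test_that("gradient energy is invariant to pattern rotation within 2 percent", {
  n <- 64
  off <- (seq_len(n) - 1) - (n - 1) / 2
  xg <- matrix(off, n, n, byrow = TRUE)
  yg <- matrix(rev(off), n, n)
  f0 <- 0.08
  # average over a centered disk (whole periods, no corner bias)
  disk <- sqrt(xg^2 + yg^2) <= 25
  energy <- function(psi) {
    img <- sin(2 * pi * f0 * (xg * cos(psi) + yg * sin(psi)))
    g <- gradient_pair(img)
    mean((g$gx^2 + g$gy^2)[g$valid & disk])
  }
  e0 <- energy(0)
  e30 <- energy(pi / 6)
  expect_lt(abs(e30 - e0) / e0, 0.02)
})

test_that("orientation tensor finds edges and stays positive semidefinite", {
  n <- 40
  step <- matrix(0, n, n); step[, (n / 2 + 1):n] <- 1 # vertical step edge
  tn <- orientation_tensor(gradient_pair(step))
  expect_true(all(tn$l1 >= tn$l2 - 1e-12))
  expect_true(all(tn$l2 >= -1e-12))
  on_edge <- tn$valid & tn$energy > 0.5 * max(tn$energy)
  expect_gt(sum(on_edge), 10)
  expect_lt(max(ori_diff(tn$orientation_deg[on_edge], 90)), 1)
  expect_gt(min(tn$orientedness[on_edge]), 0.95)

  # isotropic noise: orientedness low
  set.seed(8)
  tn2 <- orientation_tensor(gradient_pair(matrix(rnorm(n * n), n)))
  expect_lt(median(tn2$orientedness[tn2$valid]), 0.5)
  expect_lt(quantile(tn2$orientedness[tn2$valid], 0.9), 0.8)
})

test_that("edge selection applies the energy percentile and orientedness rules", {
  set.seed(9)
  img <- matrix(rnorm(64 * 64), 64)
  tn <- orientation_tensor(gradient_pair(img))
  # energy criterion alone keeps ~32 percent of valid pixels
  e_only <- select_edges(tn, orientedness_min = -1)
  expect_equal(nrow(e_only) / sum(tn$valid), 0.32, tolerance = 0.02)
  # with the orientedness rule, white noise passes far fewer pixels
  both <- select_edges(tn)
  expect_lt(nrow(both) / sum(tn$valid), 0.1)

  # a full-frame grating passes with its own orientation
  off <- (seq_len(64) - 1) - 63 / 2
  xg <- matrix(off, 64, 64, byrow = TRUE); yg <- matrix(rev(off), 64, 64)
  psi <- 40 * pi / 180
  img2 <- sin(2 * pi * 0.1 * (xg * cos(psi + pi / 2) + yg * sin(psi + pi / 2)))
  sel <- edge_orientations(img2)
  expect_gt(nrow(sel), 100)
  expect_lt(stats::median(ori_diff(sel$orientation_deg, 40)), 2)
})

test_that("orientation histograms are normalized, wrapped and asymptotically flat", {
  h1 <- orientation_histogram(rep(45.2, 100), n_bins = 36)
  expect_equal(sum(h1$density * 5), 1)
  expect_equal(h1$density[10], 1 / 5) # all mass in the 45-50 bin
  set.seed(10)
  a <- runif(1e5, 0, 180)
  h2 <- orientation_histogram(a)
  expect_lt(max(h2$density) / min(h2$density), 1.2)
  expect_identical(orientation_histogram(c(10, 40), 12)$counts,
                   orientation_histogram(c(190, 220), 12)$counts)
  expect_error(orientation_histogram(numeric(0)), "no orientations")
})

test_that("von Mises fits recover concentration and mode", {
  f1 <- fit_von_mises(rep(30, 100))
  expect_equal(f1$mu_deg, 30, tolerance = 1e-6)
  expect_equal(f1$kappa2, 500) # capped for degenerate input
  set.seed(11)
  draws <- rvonmises(1e4, 120, 4) / 2 # doubled-space sample, halved to orientations
  f2 <- fit_von_mises(draws)
  expect_lt(abs(f2$mu2_deg - 120), 2)
  expect_equal(f2$kappa2, 4, tolerance = 0.1)
  # the reported orientation-space parameters are the halved estimates
  expect_equal(f2$mu_deg, f2$mu2_deg / 2)
  expect_equal(f2$kappa, f2$kappa2 / 2)
  f3 <- fit_von_mises(runif(5000, 0, 180))
  expect_lt(f3$kappa2, 0.05)
  expect_error(fit_von_mises(1:5), "at least 10")
})

test_that("the two-component mixture EM recovers a cardinal pair", {
  set.seed(12)
  ang <- c(rvonmises(5000, 0, 5), rvonmises(5000, 180, 5)) / 2
  mix <- fit_von_mises_mixture(ang)
  expect_false(mix$degenerate)
  mus <- mix$components$mu_deg
  expect_lt(min(ori_diff(mus, 0)), 3)
  expect_lt(min(ori_diff(mus, 90)), 3)
  expect_equal(mix$components$kappa2, c(5, 5), tolerance = 0.1)
  expect_equal(mix$components$weight, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sum(mix$components$weight), 1, tolerance = 1e-9)

  # permutation of the input leaves the fit unchanged
  mix2 <- fit_von_mises_mixture(ang[sample.int(length(ang))])
  expect_equal(mix$components, mix2$components, tolerance = 1e-6)
})

test_that("single-mode data degrade the mixture to one component", {
  set.seed(13)
  ang <- 45 + 0.01 * rnorm(300) # essentially a point mass at 45 degrees
  expect_warning(mix <- fit_von_mises_mixture(ang), "collapsed")
  expect_true(mix$degenerate)
  expect_equal(nrow(mix$components), 1)
  expect_equal(mix$components$weight, 1)
})

test_that("circular correlation honors identity, rotation and independence", {
  set.seed(14)
  a <- runif(50, 0, 360)
  expect_equal(circular_correlation(a, a, n_perm = 499)$rho, 1, tolerance = 1e-9)
  expect_equal(circular_correlation(a, a + 40, n_perm = 499)$rho, 1,
               tolerance = 1e-9)
  expect_true(circular_correlation(rep(10, 20), a[1:20])$undefined)

  ok <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    r <- circular_correlation(runif(1000, 0, 360), runif(1000, 0, 360),
                              n_perm = 499, seed = s)
    if (abs(r$rho) < 0.1 && r$p_value > 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 9)
})

test_that("the Watson-Williams test detects mean shifts at the right rate", {
  a <- c(10, 20, 30, 15, 25, 18, 22, 12, 28, 19)
  ww0 <- watson_williams(list(a, a))
  expect_lt(ww0$F, 1e-9)
  expect_gt(ww0$p_value, 0.99)

  # power: two groups 30 degrees apart (full-circle data)
  hits <- 0L
  for (s in 1:10) {
    set.seed(200 + s)
    g1 <- rvonmises(200, 0, 5); g2 <- rvonmises(200, 30, 5)
    if (watson_williams(list(g1, g2), orientation = FALSE)$p_value < 0.01)
      hits <- hits + 1L
  }
  expect_gte(hits, 9)

  # type-I error calibration near the nominal 5 percent
  set.seed(15)
  rej <- 0L
  for (i in 1:2000) {
    g1 <- rvonmises(100, 50, 5); g2 <- rvonmises(100, 50, 5)
    if (watson_williams(list(g1, g2), orientation = FALSE)$p_value < 0.05)
      rej <- rej + 1L
  }
  expect_gte(rej / 2000, 0.03)
  expect_lte(rej / 2000, 0.07)
  expect_error(watson_williams(list(a)), "groups")
})

test_that("the Kuiper test is rotation invariant with calibrated power", {
  set.seed(16)
  a <- rvonmises(100, 40, 3)
  k0 <- kuiper_two_sample(a, a, orientation = FALSE)
  expect_gt(k0$p_value, 0.9)
  k1 <- kuiper_two_sample(a, a + 0.001, orientation = FALSE)
  expect_gt(k1$p_value, 0.9)

  b <- rvonmises(120, 200, 2)
  v1 <- kuiper_two_sample(a, b, orientation = FALSE)$V
  v2 <- kuiper_two_sample((a + 77) %% 360, (b + 77) %% 360,
                          orientation = FALSE)$V
  expect_equal(v1, v2, tolerance = 1e-12)

  hits <- 0L
  for (s in 1:10) {
    set.seed(300 + s)
    g1 <- rvonmises(200, 0, 4) / 2; g2 <- rvonmises(200, 180, 4) / 2
    if (kuiper_two_sample(g1, g2)$p_value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("rendered oriented bars are read out within 3 degrees end to end", {
  eye <- eye_model("human")
  pose <- data.frame(index = 1L, x = 0, y = 1.8, z = 0, heading_deg = 0)
  sc <- build_random_edge_scene(1, 0)
  for (psi in c(0, 30, 45, 90, 135)) {
    # one thick bar through the view center at image orientation psi
    # (CCW from the image x axis, i.e. the camera right vector)
    cam <- retinastats:::camera_frame(0, 0)
    dir3 <- cos(psi * pi / 180) * cam$right + sin(psi * pi / 180) * cam$up
    ctr <- c(0, 1.8, 0) + 4 * cam$forward
    sc$clutter <- matrix(c(ctr - 3 * dir3, ctr + 3 * dir3, 0.05, 0.1),
                         nrow = 1)
    p <- normalize_mean(to_luminance(
      render_patch(sc, pose, NULL, vf_coord(0, 0), eye, 512, 120, 64)))
    edges <- edge_orientations(p)
    expect_gt(nrow(edges), 30)
    vm <- fit_von_mises(edges$orientation_deg)
    expect_lt(ori_diff(vm$mu_deg, psi), 3)
    h <- orientation_histogram(edges)
    expect_lt(ori_diff(h$mid_deg[which.max(h$counts)], psi), 5)
  }
})
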