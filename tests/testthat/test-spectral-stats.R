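test_that("the radial Hamming window has the classic profile and symmetry", {
  w <- radial_hamming_window(64)
  expect_equal(max(w), w[33, 33], tolerance = 1e-12)
  expect_gt(w[33, 33], 0.998) # even size: nearest pixel center is 0.7 px off
  w65 <- radial_hamming_window(65)
  expect_equal(w65[33, 33], 1) # odd size: center pixel sits at the peak
  # value at the window radius equals the Hamming endpoint
  expect_equal(0.54 + 0.46 * cos(pi), 0.08)
  off <- (seq_len(64) - 1) - 63 / 2
  rho <- sqrt(outer(off^2, off^2, "+"))
  edge <- abs(rho - 32) < 0.2 & rho <= 32
  expect_true(all(abs(w[edge] - (0.54 + 0.46 * cos(pi * rho[edge] / 32))) < 1e-12))
  expect_equal(w, t(w))
  expect_equal(w, w[, 64:1])
  expect_error(radial_hamming_window(4))
})

test_that("mean power spectra behave on constants, gratings and white noise", {
  # constant images carry zero contrast
  ps0 <- mean_power_spectrum(list(matrix(3, 64, 64), matrix(7, 64, 64)))
  expect_true(all(ps0$power < 1e-20))

  # horizontal grating: stripes horizontal, energy on the vertical axis
  off <- (seq_len(64) - 1) - 63 / 2
  yv <- matrix(rev(off), 64, 64)   # +y up in row 1..n layout
  f0 <- 8 / 64
  grating <- 1 + 0.5 * cos(2 * pi * f0 * yv)
  ps <- mean_power_spectrum(list(grating))
  uv <- expand.grid(u = ps$freq, v = ps$freq)[, c("u", "v")]
  # top two off-DC peaks
  ord <- order(ps$power, decreasing = TRUE)
  # power matrix rows index v; reconstruct coordinates of the peaks
  idx <- arrayInd(ord[1:2], dim(ps$power))
  pk_u <- ps$freq[idx[, 2]]; pk_v <- ps$freq[idx[, 1]]
  expect_equal(abs(pk_v), c(f0, f0), tolerance = 1e-9)
  expect_equal(pk_u, c(0, 0), tolerance = 1e-9)

  # Hermitian symmetry of the averaged power
  set.seed(1)
  psn <- mean_power_spectrum(list(matrix(1 + 0.1 * rnorm(4096), 64)))
  p <- psn$power[2:64, 2:64]
  expect_equal(p, p[63:1, 63:1], tolerance = 1e-9)

  # Parseval: total power equals windowed-contrast energy
  set.seed(2)
  img <- matrix(1 + 0.2 * rnorm(4096), 64)
  w <- radial_hamming_window(64)
  mu <- sum(img * w) / sum(w)
  contrast <- ((img - mu) / mu) * w
  ps1 <- mean_power_spectrum(list(img), w)
  expect_equal(sum(ps1$power), sum(contrast^2), tolerance = 1e-9)

  # white noise: flat radial profile in the mid band
  set.seed(3)
  pats <- replicate(200, matrix(1 + 0.2 * rnorm(4096), 64), simplify = FALSE)
  ra <- radial_average(mean_power_spectrum(pats))
  sel <- ra$freq >= 0.1 & ra$freq <= 0.35
  expect_lt(max(ra$power[sel]) / min(ra$power[sel]), 1.2)
  expect_lt(abs(ra$alpha), 0.1)

  expect_error(mean_power_spectrum(list(matrix(1, 32, 32)),
                                   radial_hamming_window(64)),
               "window")
})

test_that("radial slopes recover constructed power laws", {
  set.seed(5)
  for (alpha in c(2, 3)) {
    fields <- replicate(20, matrix(2 + 0.2 * powerlaw_field(64, alpha), 64),
                        simplify = FALSE)
    ra <- radial_average(mean_power_spectrum(fields))
    expect_equal(ra$alpha, alpha, tolerance = 0.1 / alpha)
  }
})

test_that("the elliptical power-law fit recovers known parameters", {
  set.seed(1)
  ps <- synthesize_spectrum(64, A = 0.1, b = 0.5, beta = 1.0, theta_deg = 30,
                            noise_sd = 0.01)
  f <- fit_elliptical_powerlaw(ps)
  expect_equal(f$A, 0.1, tolerance = 0.05)
  expect_equal(f$b, 0.5, tolerance = 0.05)
  expect_equal(f$beta, 1.0, tolerance = 0.05)
  expect_lt(ori_diff(f$theta_deg, 30), 2)
  expect_false(f$isotropic)

  # recovery across a parameter grid with ensemble-averaging noise
  set.seed(42)
  for (i in 1:20) {
    A <- runif(1, 0.02, 0.5); b <- runif(1, 0.2, 0.9)
    beta <- runif(1, 0.7, 1.8); th <- runif(1, 5, 175)
    ps <- synthesize_spectrum(64, A, b, beta, th)
    ps$power <- ps$power * rgamma(length(ps$power), 100, 100)
    f <- fit_elliptical_powerlaw(ps)
    expect_lt(abs(f$A - A) / A, 0.1)
    expect_lt(abs(f$b - b) / b, 0.1)
    expect_lt(abs(f$beta - beta) / beta, 0.1)
    expect_lt(ori_diff(f$theta_deg, th), 5)
  }
})

test_that("isotropic spectra raise the isotropy flag instead of a direction", {
  ps <- synthesize_spectrum(64, A = 0.1, b = 1, beta = 1, theta_deg = 0)
  f <- fit_elliptical_powerlaw(ps)
  expect_true(f$isotropic)
  expect_equal(f$beta, 1, tolerance = 0.02)
  # the isotropic model's radial decay is the 1/f^2 law
  expect_equal(radial_average(ps)$alpha, 2, tolerance = 1e-3)
})

test_that("rotating the input by 90 degrees rotates the fitted orientation", {
  # oriented random field: spectral synthesis from the elliptical model
  set.seed(2)
  n <- 64
  f <- sort(ifelse(0:(n - 1) < n / 2, 0:(n - 1), 0:(n - 1) - n) / n)
  u <- matrix(f, n, n, byrow = TRUE) * n; v <- matrix(f, n, n) * n
  amp <- sqrt(elliptical_powerlaw(u, v, 0.1, 0.4, 1.2, 20))
  amp[u == 0 & v == 0] <- 0
  sh <- function(m) { s <- n / 2; m[c((s + 1):n, 1:s), c((s + 1):n, 1:s)] }
  imgs <- replicate(40, {
    z <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
    field <- Re(fft(z * sh(amp), inverse = TRUE)) / (n * n)
    field <- field[n:1, ] # synthesis rows follow +y; patches store row 1 = top
    1 + 0.3 * field / sd(field)
  }, simplify = FALSE)
  imgs90 <- lapply(imgs, function(m) t(m)[, nrow(m):1]) # exact 90-deg rotation

  f1 <- fit_elliptical_powerlaw(mean_power_spectrum(imgs))
  f2 <- fit_elliptical_powerlaw(mean_power_spectrum(imgs90))
  expect_lt(ori_diff(f1$theta_deg, 20), 5)
  expect_lt(ori_diff(f2$theta_deg, f1$theta_deg + 90), 2)
  expect_equal(f2$b, f1$b, tolerance = 0.05)
  expect_equal(f2$beta, f1$beta, tolerance = 0.05)
})
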