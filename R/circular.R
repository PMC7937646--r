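# Circular statistics for orientation data: von Mises fits (single and
# two-component mixtures via EM), circular-circular correlation with
# permutation inference, the Watson-Williams test and the two-sample
# Kuiper test.
#
# Orientations live on the half-circle [0, 180); they are doubled to the
# full circle before fitting, and fitted parameters are divided by 2 for
# reporting in orientation space (both the mode and the concentration, the
# reporting convention adopted here for comparability across analyses).

KAPPA_MAX <- 500

# inverse of A1(kappa) = I1(kappa)/I0(kappa) (Fisher 1993 approximation,
# refined by Newton steps on the Bessel ratio)
A1inv <- function(R) {
  if (R >= 1) return(KAPPA_MAX)
  if (R <= 0) return(0)
  k <- if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
       else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
       else 1 / (R^3 - 4 * R^2 + 3 * R)
  k <- min(max(k, 1e-8), KAPPA_MAX)
  for (i in 1:4) {
    A1 <- besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
    dA1 <- 1 - A1^2 - A1 / k
    if (!is.finite(A1) || !is.finite(dA1) || dA1 <= 0) break
    k <- k - (A1 - R) / dA1
    if (!is.finite(k) || k <= 0) { k <- 1e-8; break }
    if (k > KAPPA_MAX) { k <- KAPPA_MAX; break }
  }
  min(max(k, 0), KAPPA_MAX)
}

# log von Mises density on the full circle, stable for large kappa
log_dvm <- function(x, mu, kappa) {
  kappa * (cos(x - mu) - 1) - log(2 * pi) -
    log(besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler on the full circle.
#'
#' @param n Number of draws.
#' @param mu_deg Mode (degrees).
#' @param kappa Concentration (>= 0); 0 gives the circular uniform.
#' @return Angles in degrees in `[0, 360)`.
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  rad2deg(out) %% 360
}

#' Maximum-likelihood von Mises fit to orientation data
#'
#' Orientations in `[0, 180)` are doubled onto the full circle, the von
#' Mises mode and concentration are estimated by maximum likelihood, and
#' both parameters are divided by 2 for reporting in orientation space.
#' The doubled-space estimates are retained as `mu2_deg` and `kappa2`.
#'
#' @param angles_deg Orientations in degrees (at least 10).
#' @return Object of class `von_mises_fit`: `mu_deg` in `[0, 180)`,
#'   `kappa` (halved), `mu2_deg`, `kappa2`, `R_bar` (mean resultant
#'   length in doubled space), `n`, `undefined` (TRUE when the resultant
#'   length is ~0 and the mode is meaningless).
#' @export
fit_von_mises <- function(angles_deg) {
  angles_deg <- angles_deg[is.finite(angles_deg)]
  if (length(angles_deg) < 10)
    stop("need at least 10 angles for a von Mises fit", call. = FALSE)
  x <- deg2rad(2 * (angles_deg %% 180))
  C <- mean(cos(x)); S <- mean(sin(x))
  R <- sqrt(C^2 + S^2)
  undefined <- R < 1e-8
  mu2 <- if (undefined) NA_real_ else rad2deg(atan2(S, C)) %% 360
  kappa2 <- if (undefined) 0 else A1inv(R)
  structure(list(mu_deg = if (undefined) NA_real_ else mu2 / 2,
                 kappa = kappa2 / 2, mu2_deg = mu2, kappa2 = kappa2,
                 R_bar = R, n = length(angles_deg), undefined = undefined),
            class = "von_mises_fit")
}

#' @export
print.von_mises_fit <- function(x, ...) {
  if (x$undefined)
    cat("<von_mises_fit> undefined mode (resultant length ~ 0), kappa = 0\n")
  else
    cat(sprintf("<von_mises_fit> mu = %.2f deg, kappa = %.3f (doubled space: mu = %.2f, kappa = %.3f), n = %d\n",
                x$mu_deg, x$kappa, x$mu2_deg, x$kappa2, x$n))
  invisible(x)
}

#' Two-component von Mises mixture via expectation maximization
#'
#' Fits a mixture of two von Mises components to doubled orientations.
#' Component modes are initialized at the two strongest, well-separated
#' histogram modes; EM iterates until the log-likelihood gain falls below
#' `tol` or `max_iter` iterations. Components are reported sorted by mode.
#' If a component collapses (weight below 1e-3) or the two modes coincide
#' (within 1 degree of orientation, as happens for single-mode data), the
#' fit degrades to a single von Mises with a warning.
#'
#' @param angles_deg Orientations in degrees (at least 50).
#' @param max_iter,tol EM stopping rule.
#' @return Object of class `von_mises_mixture`: `components` (data.frame
#'   with `mu_deg`, `kappa`, `mu2_deg`, `kappa2`, `weight`, sorted by
#'   `mu_deg`), `log_lik`, `n_iter`, `n`, `degenerate`.
#' @export
fit_von_mises_mixture <- function(angles_deg, max_iter = 500, tol = 1e-6) {
  angles_deg <- angles_deg[is.finite(angles_deg)]
  if (length(angles_deg) < 50)
    stop("need at least 50 angles for a mixture fit", call. = FALSE)
  x <- deg2rad(2 * (angles_deg %% 180))
  n <- length(x)

  # init from the two largest histogram modes at least 45 deg apart (doubled)
  h <- orientation_histogram(angles_deg, n_bins = 36)
  ord <- order(h$counts, decreasing = TRUE)
  m1 <- h$mid_deg[ord[1]]
  m2 <- NA_real_
  for (j in ord[-1]) {
    d <- abs(h$mid_deg[j] - m1); d <- min(d, 180 - d)
    if (d >= 22.5) { m2 <- h$mid_deg[j]; break }
  }
  if (is.na(m2)) m2 <- (m1 + 90) %% 180
  mu <- deg2rad(2 * c(m1, m2)); kappa <- c(2, 2); w <- c(0.5, 0.5)

  ll_old <- -Inf; it <- 0L
  repeat {
    it <- it + 1L
    lg <- cbind(log(w[1]) + log_dvm(x, mu[1], kappa[1]),
                log(w[2]) + log_dvm(x, mu[2], kappa[2]))
    mx <- pmax(lg[, 1], lg[, 2])
    lse <- mx + log(exp(lg[, 1] - mx) + exp(lg[, 2] - mx))
    ll <- sum(lse)
    g1 <- exp(lg[, 1] - lse)
    g <- cbind(g1, 1 - g1)
    for (j in 1:2) {
      sw <- sum(g[, j])
      C <- sum(g[, j] * cos(x)) / sw
      S <- sum(g[, j] * sin(x)) / sw
      mu[j] <- atan2(S, C)
      kappa[j] <- A1inv(min(sqrt(C^2 + S^2), 1 - 1e-12))
      w[j] <- sw / n
    }
    if (it >= max_iter || (is.finite(ll_old) && ll - ll_old < tol)) break
    ll_old <- ll
  }

  sep2 <- abs(atan2(sin(mu[1] - mu[2]), cos(mu[1] - mu[2])))
  degenerate <- any(w < 1e-3) || sep2 < deg2rad(2) # < 1 deg in orientation
  if (degenerate) {
    warning("mixture component collapsed; refitting a single von Mises")
    single <- fit_von_mises(angles_deg)
    comp <- data.frame(mu_deg = single$mu_deg, kappa = single$kappa,
                       mu2_deg = single$mu2_deg, kappa2 = single$kappa2,
                       weight = 1)
    return(structure(list(components = comp, log_lik = NA_real_,
                          n_iter = it, n = n, degenerate = TRUE),
                     class = "von_mises_mixture"))
  }
  mu2 <- rad2deg(mu) %% 360
  comp <- data.frame(mu_deg = mu2 / 2, kappa = kappa / 2,
                     mu2_deg = mu2, kappa2 = kappa, weight = w)
  comp <- comp[order(comp$mu_deg), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(components = comp, log_lik = ll, n_iter = it, n = n,
                 degenerate = FALSE),
            class = "von_mises_mixture")
}

#' @export
print.von_mises_mixture <- function(x, ...) {
  cat(sprintf("<von_mises_mixture> %d component(s), n = %d, %d EM iterations\n",
              nrow(x$components), x$n, x$n_iter))
  print(round(x$components, 3))
  invisible(x)
}

#' Circular-circular correlation with permutation inference
#'
#' Circular correlation coefficient for paired angles. When both marginals
#' have a well-defined mean direction the classical mean-direction form
#' `sum sin(a - abar) sin(b - bbar) / sqrt(sum sin^2 sum sin^2)` is used;
#' when either marginal is near-uniform (mean resultant length below 0.05,
#' as the polar angle of a visual-field ring is by design) the mean
#' direction is arbitrary and the uniform-marginal-corrected form
#' `(|sum exp(i(a - b))| - |sum exp(i(a + b))|) / (2 sqrt(sum sin^2 sum sin^2))`
#' is used instead. A seeded permutation p-value accompanies the
#' coefficient. Orientation-valued inputs (half-circle) are doubled before
#' computing.
#'
#' @param a_deg,b_deg Paired angles (degrees), length >= 3.
#' @param orientation_a,orientation_b Whether each input is
#'   orientation-valued (period 180) and must be doubled.
#' @param n_perm Number of permutations for the p-value.
#' @param seed Seed for the permutation draw.
#' @return List of class `circular_correlation`: `rho`, `p_value`
#'   (two-sided), `n`, `undefined` (constant input).
#' @export
circular_correlation <- function(a_deg, b_deg, orientation_a = FALSE,
                                 orientation_b = FALSE, n_perm = 9999,
                                 seed = 1L) {
  stopifnot(length(a_deg) == length(b_deg), length(a_deg) >= 3)
  a <- deg2rad(if (orientation_a) 2 * (a_deg %% 180) else a_deg %% 360)
  b <- deg2rad(if (orientation_b) 2 * (b_deg %% 180) else b_deg %% 360)
  abar <- atan2(mean(sin(a)), mean(cos(a)))
  bbar <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - abar); sb <- sin(b - bbar)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den < 1e-12)
    return(structure(list(rho = NA_real_, p_value = NA_real_,
                          n = length(a), undefined = TRUE),
                     class = "circular_correlation"))
  Ra <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  Rb <- sqrt(mean(sin(b))^2 + mean(cos(b))^2)
  rho_of <- if (min(Ra, Rb) < 0.05) {
    function(bb) (Mod(sum(exp(1i * (a - bb)))) -
                    Mod(sum(exp(1i * (a + bb))))) / (2 * den)
  } else {
    function(bb) {
      bbar_p <- atan2(mean(sin(bb)), mean(cos(bb)))
      sum(sa * sin(bb - bbar_p)) / den
    }
  }
  rho <- rho_of(b)
  p <- with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (abs(rho_of(b[sample.int(length(b))])) >= abs(rho) - 1e-15)
        hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
  structure(list(rho = rho, p_value = p, n = length(a), undefined = FALSE),
            class = "circular_correlation")
}

#' @export
print.circular_correlation <- function(x, ...) {
  if (x$undefined) cat("<circular_correlation> undefined (constant input)\n")
  else cat(sprintf("<circular_correlation> rho_c = %.3f, permutation p = %.4g, n = %d\n",
                   x$rho, x$p_value, x$n))
  invisible(x)
}

#' Watson-Williams test for equal circular means
#'
#' Classical high-concentration F test comparing the mean directions of
#' two or more groups of angles, with the standard concentration
#' correction `(1 + 3/(8 kappa))`. Orientation-valued data are doubled
#' first. The test assumes von Mises samples with common, sufficiently
#' large concentration; when the pooled mean resultant length falls below
#' 0.45 the result carries a low-concentration warning flag.
#'
#' @param groups List of angle vectors (degrees), each of length >= 10.
#' @param orientation Whether inputs are orientation-valued (period 180).
#' @return List of class `watson_williams`: `F`, `p_value`, `df1`, `df2`,
#'   `kappa`, `low_concentration`.
#' @export
watson_williams <- function(groups, orientation = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 10))
    stop("each group needs at least 10 angles", call. = FALSE)
  xs <- lapply(groups, function(a)
    deg2rad(if (orientation) 2 * (a %% 180) else a %% 360))
  k <- length(xs)
  ns <- vapply(xs, length, 1L); N <- sum(ns)
  Ri <- vapply(xs, function(x) sqrt(sum(cos(x))^2 + sum(sin(x))^2), 1)
  Call <- sum(vapply(xs, function(x) sum(cos(x)), 1))
  Sall <- sum(vapply(xs, function(x) sum(sin(x)), 1))
  R <- sqrt(Call^2 + Sall^2)
  rw <- sum(Ri) / N
  kap <- A1inv(rw)
  Fstat <- (1 + 3 / (8 * kap)) * ((N - k) * (sum(Ri) - R)) / ((k - 1) * (N - sum(Ri)))
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  structure(list(F = Fstat, p_value = p, df1 = k - 1, df2 = N - k,
                 kappa = kap, low_concentration = rw < 0.45),
            class = "watson_williams")
}

#' @export
print.watson_williams <- function(x, ...) {
  cat(sprintf("<watson_williams> F(%d, %d) = %.3f, p = %.4g%s\n",
              x$df1, x$df2, x$F, x$p_value,
              if (x$low_concentration) " [low concentration: F test approximate]" else ""))
  invisible(x)
}

#' Two-sample Kuiper test on the circle
#'
#' Rotation-invariant nonparametric comparison of two circular samples:
#' `V = D+ + D-`, the sum of the maximal deviations of the two empirical
#' distribution functions above and below each other, with the standard
#' asymptotic tail series for the p-value.
#'
#' @param a_deg,b_deg Angle samples (degrees), each of length >= 10.
#' @param orientation Whether inputs are orientation-valued (period 180)
#'   and should be doubled onto the full circle first.
#' @return List of class `kuiper_test`: `V`, `p_value`, `n_a`, `n_b`.
#' @export
kuiper_two_sample <- function(a_deg, b_deg, orientation = TRUE) {
  stopifnot(length(a_deg) >= 10, length(b_deg) >= 10)
  a <- (if (orientation) 2 * (a_deg %% 180) else a_deg %% 360) / 360
  b <- (if (orientation) 2 * (b_deg %% 180) else b_deg %% 360) / 360
  na <- length(a); nb <- length(b)
  xs <- sort(unique(c(a, b)))
  Fa <- vapply(xs, function(t) sum(a <= t), 1) / na
  Fb <- vapply(xs, function(t) sum(b <= t), 1) / nb
  V <- max(c(0, Fa - Fb)) + max(c(0, Fb - Fa))
  ne <- na * nb / (na + nb)
  lam <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
  # the asymptotic series is valid only away from 0; below it p -> 1
  p <- if (lam < 0.4) 1 else {
    kk <- 1:100
    min(max(2 * sum((4 * kk^2 * lam^2 - 1) * exp(-2 * kk^2 * lam^2)), 0), 1)
  }
  structure(list(V = V, p_value = p, n_a = na, n_b = nb),
            class = "kuiper_test")
}

#' @export
print.kuiper_test <- function(x, ...) {
  cat(sprintf("<kuiper_test> V = %.4f, p = %.4g (n = %d, %d)\n",
              x$V, x$p_value, x$n_a, x$n_b))
  invisible(x)
}
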