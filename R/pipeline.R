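# Orchestration: visual-field grids, run configuration, dataset
# generation, per-position statistics and cross-condition comparisons.

#' Visual-field sampling grid
#'
#' Cartesian product of eccentricities and polar angles, with all
#' eccentricity-0 entries collapsed to the single central coordinate.
#' The default grid mirrors the study layout: eccentricities 0, 30 and 50
#' degrees crossed with 8 polar angles, 17 positions in all.
#'
#' @param eccentricities_deg Eccentricities (degrees).
#' @param polar_angles_deg Polar angles (degrees).
#' @return data.frame of class `vf_grid` with columns `phi_deg`,
#'   `chi_deg`, ordered by eccentricity then polar angle.
#' @examples
#' nrow(visual_field_grid()) # 17
#' @export
visual_field_grid <- function(eccentricities_deg = c(0, 30, 50),
                              polar_angles_deg = seq(0, 315, by = 45)) {
  stopifnot(length(eccentricities_deg) >= 1, length(polar_angles_deg) >= 1,
            all(eccentricities_deg >= 0 & eccentricities_deg < 90))
  if (anyDuplicated(eccentricities_deg) || anyDuplicated(polar_angles_deg)) {
    warning("duplicate grid inputs deduplicated")
    eccentricities_deg <- unique(eccentricities_deg)
    polar_angles_deg <- unique(polar_angles_deg)
  }
  g <- expand.grid(chi_deg = polar_angles_deg %% 360,
                   phi_deg = eccentricities_deg)[, 2:1]
  g$chi_deg[g$phi_deg == 0] <- 0
  g <- unique(g)
  g <- g[order(g$phi_deg, g$chi_deg), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("vf_grid", "data.frame")
  g
}

#' Run configuration
#'
#' Bundles every knob of a generation + analysis run. Defaults are the
#' full-scale study conditions: 120-degree field of view sampled at
#' 5,954 px, 512-px capture patches, 128-px analysis patches, the
#' 17-position grid and 663 poses. Scaled-down test profiles override
#' `scene_resolution_px`, `capture_patch_px`, `analysis_patch_px` and
#' `n_poses`.
#'
#' @param species,strategy Avatar species and gaze strategy.
#' @param n_poses Number of trajectory poses.
#' @param seeds Named list of integer seeds (`scene`, `trajectory`,
#'   `gaze`, `stats`).
#' @param scene_resolution_px,fov_deg Imaging frame parameters.
#' @param capture_patch_px,analysis_patch_px Capture and analysis patch
#'   sizes (analysis patches are central crops of captures).
#' @param grid [visual_field_grid()] data.frame.
#' @param projections Character subset of `c("planar", "tangent")`.
#' @param scene_params Named list passed to [build_forest_scene()] or
#'   [build_random_edge_scene()].
#' @param scene_kind `"forest"` or `"random_edge"`.
#' @param supersample Rays per pixel side when rendering.
#' @return List of class `run_config`.
#' @export
run_config <- function(species = "human", strategy = "straight",
                       n_poses = 663,
                       seeds = list(scene = 1L, trajectory = 2L,
                                    gaze = 3L, stats = 4L),
                       scene_resolution_px = 5954, fov_deg = 120,
                       capture_patch_px = 512, analysis_patch_px = 128,
                       grid = visual_field_grid(),
                       projections = c("planar", "tangent"),
                       scene_params = list(), scene_kind = "forest",
                       supersample = 2) {
  stopifnot(species %in% c("human", "cat"),
            strategy %in% c("straight", "down", "random"),
            n_poses >= 1, all(projections %in% c("planar", "tangent")),
            scene_kind %in% c("forest", "random_edge"),
            analysis_patch_px <= capture_patch_px,
            all(c("scene", "trajectory", "gaze", "stats") %in% names(seeds)))
  structure(list(species = species, strategy = strategy, n_poses = n_poses,
                 seeds = seeds, scene_resolution_px = scene_resolution_px,
                 fov_deg = fov_deg, capture_patch_px = capture_patch_px,
                 analysis_patch_px = analysis_patch_px, grid = grid,
                 projections = projections, scene_params = scene_params,
                 scene_kind = scene_kind, supersample = supersample),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' `config_to_list()` flattens a `run_config` into plain lists and data
#' frames that survive JSON round-trips; `config_from_list()` rebuilds the
#' configuration, validating it on the way.
#'
#' @param config A `run_config`.
#' @return A plain list / a `run_config`.
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$grid <- as.data.frame(out$grid)
  out
}

#' @rdname config_to_list
#' @param x Plain list from `config_to_list()`.
#' @export
config_from_list <- function(x) {
  x <- as.list(x)
  grid <- as.data.frame(x$grid)
  class(grid) <- c("vf_grid", "data.frame")
  do.call(run_config, c(x[setdiff(names(x), "grid")], list(grid = grid)))
}

#' Generate a patch ensemble from a run configuration
#'
#' Builds the scene, the avatar trajectory and the gaze directions from
#' the configured seeds, then captures the full (pose x grid) ensemble of
#' luminance patches, including tangent-projection twins when configured.
#'
#' @param config A [run_config()].
#' @param scene Optional prebuilt `scene_primitives` (otherwise built from
#'   `config$scene_kind` and `config$seeds$scene`).
#' @return A `patch_store` with an extra `config` field.
#' @export
run_generate <- function(config, scene = NULL) {
  stopifnot(inherits(config, "run_config"))
  eye <- eye_model(config$species)
  if (is.null(scene)) {
    builder <- switch(config$scene_kind,
                      forest = build_forest_scene,
                      random_edge = build_random_edge_scene)
    scene <- do.call(builder, c(list(seed = config$seeds$scene),
                                config$scene_params))
  }
  extent <- if (!is.null(scene$extent_m) && scene$extent_m > 0)
    scene$extent_m else 40
  traj <- generate_trajectory(config$seeds$trajectory, config$n_poses, eye,
                              extent_m = extent)
  gaze <- gaze_spec(config$strategy, seed = config$seeds$gaze)
  store <- capture_ensemble(scene, traj, gaze, eye, config$grid,
                            scene_resolution_px = config$scene_resolution_px,
                            fov_deg = config$fov_deg,
                            patch_px = config$capture_patch_px,
                            tangent = "tangent" %in% config$projections,
                            supersample = config$supersample)
  store$config <- config
  store
}

#' Per-position image statistics of a patch ensemble
#'
#' For every (eccentricity, polar angle, projection) cell of the store:
#' crops patches to the analysis size, normalizes each by its mean
#' luminance, computes the windowed mean power spectrum, its elliptical
#' power-law fit and radially averaged slope, extracts edge orientations,
#' and fits single and two-component von Mises models to the aggregated
#' orientations.
#'
#' @param store A `patch_store` from [run_generate()] or
#'   [capture_ensemble()].
#' @param analysis_patch_px Analysis patch size (central crop); defaults
#'   to the store config's value or the patch size itself.
#' @param n_bins Orientation histogram bins.
#' @return data.frame of class `vf_stats`, one row per cell, with the
#'   spectral parameters (`A`, `b`, `beta`, `theta_deg`, `isotropic`,
#'   `alpha`) and edge statistics (`n_edges`, `mu_deg`, `kappa`,
#'   `kappa2`, mixture parameters `mu1`, `mu2`, `w1`). Aggregated edge
#'   orientations are kept in `attr(, "edges")`; spectra in
#'   `attr(, "spectra")`.
#' @export
run_stats <- function(store, analysis_patch_px = NULL, n_bins = 36) {
  stopifnot(inherits(store, "patch_store"))
  man <- store$manifest
  if (is.null(analysis_patch_px))
    analysis_patch_px <- if (!is.null(store$config))
      store$config$analysis_patch_px else store$patches[[1]]$patch_px
  window <- radial_hamming_window(analysis_patch_px)
  cells <- unique(man[, c("phi_deg", "chi_deg", "projection")])
  cells <- cells[order(cells$projection, cells$phi_deg, cells$chi_deg), ]
  rows <- vector("list", nrow(cells))
  edges_by_cell <- vector("list", nrow(cells))
  spectra <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ids <- man$patch_id[man$phi_deg == cells$phi_deg[i] &
                        man$chi_deg == cells$chi_deg[i] &
                        man$projection == cells$projection[i]]
    patches <- lapply(store$patches[ids], function(p)
      normalize_mean(crop_center(p, analysis_patch_px)))
    ps <- mean_power_spectrum(patches, window)
    efit <- fit_elliptical_powerlaw(ps)
    ra <- radial_average(ps)
    ang <- unlist(lapply(patches, function(p) edge_orientations(p)$orientation_deg))
    has_edges <- length(ang) >= 10
    vm <- if (has_edges) fit_von_mises(ang) else NULL
    mix <- if (length(ang) >= 50) fit_von_mises_mixture(ang) else NULL
    rows[[i]] <- data.frame(
      phi_deg = cells$phi_deg[i], chi_deg = cells$chi_deg[i],
      projection = cells$projection[i], n_patches = length(ids),
      A = efit$A, b = efit$b, beta = efit$beta, theta_deg = efit$theta_deg,
      isotropic = efit$isotropic, alpha = ra$alpha,
      n_edges = length(ang),
      mu_deg = if (has_edges) vm$mu_deg else NA_real_,
      kappa = if (has_edges) vm$kappa else NA_real_,
      kappa2 = if (has_edges) vm$kappa2 else NA_real_,
      mu1 = if (!is.null(mix)) mix$components$mu_deg[1] else NA_real_,
      mu2 = if (!is.null(mix) && nrow(mix$components) > 1)
        mix$components$mu_deg[2] else NA_real_,
      w1 = if (!is.null(mix)) mix$components$weight[1] else NA_real_)
    edges_by_cell[[i]] <- ang
    spectra[[i]] <- ps
  }
  out <- do.call(rbind, rows)
  key <- paste(cells$projection, cells$phi_deg, cells$chi_deg)
  names(edges_by_cell) <- key
  names(spectra) <- key
  attr(out, "edges") <- edges_by_cell
  attr(out, "spectra") <- spectra
  class(out) <- c("vf_stats", "data.frame")
  out
}

#' Radial-bias summary of a statistics table
#'
#' Circular correlations, within one projection and eccentricity ring,
#' between the fitted spectral orientation `theta` (and the von Mises mode
#' `mu`) and the polar angle `chi` of the visual-field position. A
#' positive, significant correlation is the signature of the radial
#' orientation bias.
#'
#' @param stats A `vf_stats` table.
#' @param phi_deg Eccentricity ring to summarize.
#' @param projection Projection to summarize.
#' @param seed Seed for permutation p-values.
#' @return data.frame with rows for `theta_vs_chi` and `mu_vs_chi`.
#' @export
radial_bias_summary <- function(stats, phi_deg = 30, projection = "planar",
                                seed = 1L) {
  s <- stats[stats$phi_deg == phi_deg & stats$projection == projection, ]
  if (nrow(s) < 3) stop("need at least 3 positions on the ring", call. = FALSE)
  # the radial direction at chi and chi + 180 is the same orientation, so
  # both variables live in orientation space and are doubled together
  ct <- circular_correlation(s$theta_deg, s$chi_deg, orientation_a = TRUE,
                             orientation_b = TRUE, seed = seed)
  cm <- circular_correlation(s$mu_deg, s$chi_deg, orientation_a = TRUE,
                             orientation_b = TRUE, seed = seed)
  data.frame(measure = c("theta_vs_chi", "mu_vs_chi"),
             rho_c = c(ct$rho, cm$rho),
             p_value = c(ct$p_value, cm$p_value),
             n = nrow(s), phi_deg = phi_deg, projection = projection)
}

#' Compare orientation distributions across gaze strategies
#'
#' At every visual-field position shared by the reports: a Watson-Williams
#' test across all strategies plus pairwise two-sample Kuiper tests on the
#' aggregated edge orientations. Positions where every pairwise Kuiper
#' test is significant at `alpha` are flagged.
#'
#' @param reports Named list of `vf_stats` tables (names = strategy
#'   labels), all computed on the same grid.
#' @param projection Projection to compare.
#' @param alpha Significance level for flagging.
#' @param max_n Per-cell subsample cap for the tests (seeded), keeping
#'   Kuiper statistics comparable across cells.
#' @param seed Subsampling seed.
#' @return data.frame: one row per position with `ww_F`, `ww_p`, pairwise
#'   `kuiper_p_*` columns and `all_pairs_significant`.
#' @export
compare_strategies <- function(reports, projection = "planar", alpha = 0.01,
                               max_n = 5000, seed = 1L) {
  stopifnot(is.list(reports), length(reports) >= 2, !is.null(names(reports)))
  grids <- lapply(reports, function(r)
    unique(r[r$projection == projection, c("phi_deg", "chi_deg")]))
  g0 <- grids[[1]]
  for (g in grids[-1])
    if (!identical(dim(g0), dim(g)) || !all(g0 == g))
      stop("reports were computed on different grids", call. = FALSE)
  labs <- names(reports)
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  rows <- vector("list", nrow(g0))
  for (i in seq_len(nrow(g0))) {
    key <- paste(projection, g0$phi_deg[i], g0$chi_deg[i])
    angs <- lapply(reports, function(r) {
      a <- attr(r, "edges")[[key]]
      if (length(a) > max_n)
        a <- with_seed(seed, a[sample.int(length(a), max_n)])
      a
    })
    ww <- watson_williams(angs, orientation = TRUE)
    kp <- vapply(pairs, function(pr)
      kuiper_two_sample(angs[[pr[1]]], angs[[pr[2]]])$p_value, 1)
    row <- data.frame(phi_deg = g0$phi_deg[i], chi_deg = g0$chi_deg[i],
                      ww_F = ww$F, ww_p = ww$p_value)
    for (j in seq_along(pairs))
      row[[paste0("kuiper_p_", pairs[[j]][1], "_vs_", pairs[[j]][2])]] <- kp[j]
    row$all_pairs_significant <- all(kp < alpha)
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Compare spectral parameters between planar and tangent projections
#'
#' Pairs each visual-field position's planar and tangent elliptical-fit
#' parameters and quantifies the upper-versus-lower visual field
#' asymmetry of `A` and `beta` under each projection: positions at
#' mirrored polar angles (`chi`, `360 - chi`) are differenced, and a sign
#' test asks whether the magnitude of that vertical asymmetry shrinks
#' after projecting onto the spherical retina.
#'
#' @param stats A `vf_stats` table holding both projections.
#' @return List: `paired` (per-position parameter deltas
#'   tangent - planar), `asymmetry` (per mirrored pair and parameter, the
#'   absolute upper-lower difference under each projection), and
#'   `sign_test` (data.frame per parameter: number of pairs with reduced
#'   asymmetry, binomial p).
#' @export
compare_projections <- function(stats) {
  pl <- stats[stats$projection == "planar", ]
  tg <- stats[stats$projection == "tangent", ]
  if (nrow(pl) == 0 || nrow(tg) == 0)
    stop("store must contain both projections", call. = FALSE)
  m <- merge(pl, tg, by = c("phi_deg", "chi_deg"),
             suffixes = c("_planar", "_tangent"))
  paired <- data.frame(phi_deg = m$phi_deg, chi_deg = m$chi_deg,
                       dA = m$A_tangent - m$A_planar,
                       dbeta = m$beta_tangent - m$beta_planar,
                       db = m$b_tangent - m$b_planar,
                       dtheta = ((m$theta_deg_tangent - m$theta_deg_planar + 90) %% 180) - 90)
  # vertical mirror pairs: chi in (0, 180) vs 360 - chi, per eccentricity
  up <- m[sin(deg2rad(m$chi_deg)) > 1e-9, ]
  asym <- NULL
  for (i in seq_len(nrow(up))) {
    mirror <- m[m$phi_deg == up$phi_deg[i] &
                m$chi_deg == (360 - up$chi_deg[i]) %% 360, ]
    if (nrow(mirror) != 1) next
    asym <- rbind(asym, data.frame(
      phi_deg = up$phi_deg[i], chi_up = up$chi_deg[i],
      chi_down = mirror$chi_deg,
      A_planar = abs(up$A_planar[i] - mirror$A_planar),
      A_tangent = abs(up$A_tangent[i] - mirror$A_tangent),
      beta_planar = abs(up$beta_planar[i] - mirror$beta_planar),
      beta_tangent = abs(up$beta_tangent[i] - mirror$beta_tangent)))
  }
  sign_test <- NULL
  if (!is.null(asym) && nrow(asym) > 0) {
    for (par in c("A", "beta")) {
      d <- asym[[paste0(par, "_tangent")]] - asym[[paste0(par, "_planar")]]
      d <- d[d != 0]
      n_red <- sum(d < 0)
      p <- if (length(d) > 0)
        stats::binom.test(n_red, length(d), alternative = "greater")$p.value
      else NA_real_
      sign_test <- rbind(sign_test,
                         data.frame(parameter = par, n_pairs = length(d),
                                    n_reduced = n_red, p_value = p))
    }
  }
  list(paired = paired, asymmetry = asym, sign_test = sign_test)
}
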