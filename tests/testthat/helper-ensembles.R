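# Shared rendered ensembles for the heavier statistical checks.
# Built lazily and cached for the session so several tests can reuse them.

.ensemble_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .ensemble_cache)) {
    assign(name, builder(), envir = .ensemble_cache)
  }
  get(name, envir = .ensemble_cache)
}

# random-edge control ensemble: phi in {30, 50} x 8 polar angles,
# random-gaze avatar walking through a segment cloud
edge_field_stats <- function() {
  cached("edge_field_stats", function() {
    eye <- eye_model("human")
    sc <- build_random_edge_scene(11, n_segments = 800)
    tr <- generate_trajectory(12, 72, eye, extent_m = 16)
    grid <- visual_field_grid(c(30, 50), seq(0, 315, by = 45))
    store <- capture_ensemble(sc, tr, gaze_spec("random", seed = 13), eye,
                              grid, scene_resolution_px = 512, patch_px = 64)
    suppressWarnings(run_stats(store, analysis_patch_px = 64))
  })
}

# forest ensemble with planar + tangent twins on mirrored polar angles
# at three outer eccentricity rings (finer frame resolution keeps the
# angular extent of tangent patches close to the full-scale geometry)
forest_projection_stats <- function() {
  cached("forest_projection_stats", function() {
    eye <- eye_model("human")
    sc <- build_forest_scene(21)
    tr <- generate_trajectory(22, 40, eye)
    grid <- visual_field_grid(c(30, 40, 50), c(45, 90, 135, 225, 270, 315))
    store <- capture_ensemble(sc, tr, gaze_spec("straight"), eye, grid,
                              scene_resolution_px = 2048, patch_px = 64,
                              tangent = TRUE)
    suppressWarnings(run_stats(store, analysis_patch_px = 64))
  })
}

# central-field forest edge orientations, straight gaze
forest_center_angles <- function() {
  cached("forest_center_angles", function() {
    eye <- eye_model("human")
    sc <- build_forest_scene(21)
    tr <- generate_trajectory(22, 48, eye)
    store <- capture_ensemble(sc, tr, gaze_spec("straight"), eye,
                              visual_field_grid(0, 0),
                              scene_resolution_px = 512, patch_px = 64)
    st <- run_stats(store, analysis_patch_px = 64)
    attr(st, "edges")[["planar 0 0"]]
  })
}

# straight vs down edge orientations at the lower-right position (30, 315)
strategy_stats <- function() {
  cached("strategy_stats", function() {
    eye <- eye_model("human")
    sc <- build_forest_scene(21)
    tr <- generate_trajectory(22, 40, eye)
    grid <- visual_field_grid(30, 315)
    lapply(list(straight = gaze_spec("straight"), down = gaze_spec("down")),
           function(g) {
             store <- capture_ensemble(sc, tr, g, eye, grid,
                                       scene_resolution_px = 512,
                                       patch_px = 64)
             run_stats(store, analysis_patch_px = 64)
           })
  })
}

# normalized cross-correlation over jointly finite pixels
ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok] - mean(a[ok]); b <- b[ok] - mean(b[ok])
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# smallest absolute angular difference for orientation data (period 180)
ori_diff <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}
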