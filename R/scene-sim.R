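# Procedural 3D scenes, avatar trajectories and gaze strategies.
#
# The forest generator emulates a naturalistic wooded environment with the
# ingredients that drive its orientation statistics: vertical elongated
# trunks, a textured ground plane with track-like striping toward a
# vanishing point plus perpendicular grass strokes, and sparse near-ground
# clutter. The random-edge generator builds a control scene of randomly
# oriented 3D line segments, used to show that the radial orientation bias
# arises from perspective projection alone.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

new_scene <- function(kind, ground, trunks, trunk_tex, clutter, background,
                      background_grad, light, seed, extent_m,
                      background_tex = NULL) {
  structure(list(kind = kind, ground = ground, trunks = trunks,
                 trunk_tex = trunk_tex, clutter = clutter,
                 background = background, background_grad = background_grad,
                 background_tex = background_tex, light = light, seed = seed,
                 extent_m = extent_m),
            class = "scene_primitives")
}

#' @export
print.scene_primitives <- function(x, ...) {
  cat(sprintf("<scene_primitives> %s (seed %d): %d trunks, %d clutter segments, ground %s\n",
              x$kind, x$seed,
              if (is.null(x$trunks)) 0L else nrow(x$trunks),
              if (is.null(x$clutter)) 0L else nrow(x$clutter),
              if (is.null(x$ground)) "absent" else "present"))
  invisible(x)
}

#' Procedural forest scene
#'
#' Builds a forest-like scene: vertical cylindrical trunks scattered by a
#' Poisson process, a noise-textured ground plane (band-limited power-law
#' noise plus oriented track striping and perpendicular grass strokes),
#' sparse fallen branches near the ground, and a canopy-textured
#' background dome. Albedo textures are Fourier-synthesized periodic
#' tiles with a configurable spectral slope, calibrated so that rendered
#' central-field patches have approximately `1/f^2` power spectra, as
#' natural images do.
#'
#' @param seed Integer seed; the scene is fully deterministic given it.
#' @param extent_m Side length (m) of the square region populated with
#'   primitives, centered on the origin.
#' @param trunk_density Expected trunks per square meter.
#' @param trunk_radius_range,trunk_height_range Uniform ranges (m).
#' @param clutter_density Expected fallen-branch segments per square meter.
#' @param stripe_dir_deg Direction of the ground track striping (degrees in
#'   the ground plane).
#' @param texture_slope Spectral power-law exponent of the synthesized
#'   bark/ground noise textures (power ~ 1/f^slope).
#' @param tile_px Resolution of the periodic noise tiles.
#' @return A `scene_primitives` object.
#' @examples
#' sc <- build_forest_scene(seed = 1)
#' nrow(sc$trunks)
#' @export
build_forest_scene <- function(seed, extent_m = 40, trunk_density = 0.15,
                               trunk_radius_range = c(0.12, 0.4),
                               trunk_height_range = c(5, 14),
                               clutter_density = 0.01,
                               stripe_dir_deg = 0,
                               texture_slope = 1.6, tile_px = 256) {
  stopifnot(extent_m > 0, trunk_density >= 0, clutter_density >= 0)
  with_seed(seed, {
    area <- extent_m^2
    n_trunk <- stats::rpois(1, trunk_density * area)
    trunks <- if (n_trunk > 0) {
      cbind(cx = stats::runif(n_trunk, -extent_m / 2, extent_m / 2),
            cz = stats::runif(n_trunk, -extent_m / 2, extent_m / 2),
            radius = stats::runif(n_trunk, trunk_radius_range[1], trunk_radius_range[2]),
            height = stats::runif(n_trunk, trunk_height_range[1], trunk_height_range[2]))
    } else NULL
    n_cl <- stats::rpois(1, clutter_density * area)
    clutter <- if (n_cl > 0) {
      p1 <- cbind(stats::runif(n_cl, -extent_m / 2, extent_m / 2),
                  stats::runif(n_cl, 0.05, 0.5),
                  stats::runif(n_cl, -extent_m / 2, extent_m / 2))
      # mostly horizontal branch directions
      az <- stats::runif(n_cl, 0, 2 * pi)
      elv <- stats::rnorm(n_cl, 0, 0.25)
      len <- stats::runif(n_cl, 0.5, 2)
      d <- cbind(cos(elv) * cos(az), sin(elv), cos(elv) * sin(az))
      cbind(p1, p1 + d * len, stats::runif(n_cl, 0.02, 0.05),
            stats::runif(n_cl, 0.15, 0.45))
    } else NULL
    ground <- list(base = c(0.45, 0.42, 0.32),
                   noise_amp = 0.5, noise_scale = 2.5, octaves = 5L,
                   seed = (seed %% 100000) + 11,
                   stripe_amp = 0.10, stripe_period = 0.8,
                   stripe_dir_deg = stripe_dir_deg,
                   cross_amp = 0.10, cross_period = 0.5,
                   tile = powerlaw_field(tile_px, texture_slope),
                   tile_period = 2)
    trunk_tex <- list(base = c(0.50, 0.40, 0.30),
                      noise_amp = 0.5, noise_scale = 8, octaves = 4L,
                      band_v_amp = 0.10, band_v_period = 0.12,
                      band_h_amp = 0.05, band_h_period = 0.5,
                      seed = (seed %% 100000) + 23,
                      tile = powerlaw_field(tile_px, texture_slope),
                      tile_period = 0.8)
    new_scene("forest", ground, trunks, trunk_tex, clutter,
              background = c(0.42, 0.44, 0.41), background_grad = 0.05,
              light = list(dir = c(0.35, 1, 0.25), ambient = 0.6, diffuse = 0.4),
              seed = seed, extent_m = extent_m,
              background_tex = list(tile = powerlaw_field(tile_px, texture_slope),
                                    amp = 0.55, period_rad = 0.6))
  })
}

#' Random-edge control scene
#'
#' A cloud of 3D line segments with independent uniformly random
#' orientations and positions, suspended in a slab around the viewing
#' region, against a uniform mid-gray background with no ground plane.
#' Any orientation anisotropy measured in projections of this scene must
#' come from the projection geometry, not the scene.
#'
#' @param seed Integer seed.
#' @param n_segments Number of segments.
#' @param extent_m Half-size (m) of the cube containing segment centers.
#' @param center_height_m Vertical center of the slab (m); segments surround
#'   the camera at typical eye heights.
#' @return A `scene_primitives` object.
#' @export
build_random_edge_scene <- function(seed, n_segments = 800, extent_m = 10,
                                    center_height_m = 1.0) {
  stopifnot(n_segments >= 0)
  with_seed(seed, {
    clutter <- if (n_segments > 0) {
      ctr <- cbind(stats::runif(n_segments, -extent_m, extent_m),
                   center_height_m + stats::runif(n_segments, -extent_m, extent_m),
                   stats::runif(n_segments, -extent_m, extent_m))
      # isotropic directions: normalized standard normal triples
      d <- matrix(stats::rnorm(3 * n_segments), ncol = 3)
      d <- d / sqrt(rowSums(d^2))
      hl <- stats::runif(n_segments, 0.3, 1.2)
      dark <- stats::runif(n_segments) < 0.5
      alb <- ifelse(dark, stats::runif(n_segments, 0.05, 0.35),
                    stats::runif(n_segments, 0.65, 0.95))
      cbind(ctr - d * hl, ctr + d * hl,
            stats::runif(n_segments, 0.05, 0.12), alb)
    } else NULL
    new_scene("random_edge", ground = NULL, trunks = NULL, trunk_tex = NULL,
              clutter = clutter,
              background = c(0.5, 0.5, 0.5), background_grad = 0,
              light = list(dir = c(0.3, 1, 0.2), ambient = 0.7, diffuse = 0.3),
              seed = seed, extent_m = extent_m)
  })
}

#' Uniform background scene
#'
#' Degenerate scene with nothing but a constant background; useful for
#' renderer sanity checks.
#' @param value Background gray level in `[0, 1]`.
#' @return A `scene_primitives` object.
#' @export
build_empty_scene <- function(value = 0.5) {
  new_scene("empty", ground = NULL, trunks = NULL, trunk_tex = NULL,
            clutter = NULL, background = rep(value, 3), background_grad = 0,
            light = list(dir = c(0, 1, 0), ambient = 1, diffuse = 0),
            seed = 0L, extent_m = 0)
}

# list passed to the C++ ray caster
as_raycast_scene <- function(scene) {
  list(ground = scene$ground, trunks = scene$trunks,
       trunk_tex = scene$trunk_tex, clutter = scene$clutter,
       background = scene$background, background_grad = scene$background_grad,
       background_tex = scene$background_tex, light = scene$light)
}

#' Correlated random-walk avatar trajectory
#'
#' Simulates a walking avatar: poses sampled every `dt_s` seconds, heading
#' evolving as a correlated random walk (Gaussian increments), positions
#' advancing `speed_mps * dt_s` per step at fixed eye height. The walk is
#' kept inside a circular arena by steering back toward the center when the
#' boundary is approached, so a scene of matching extent always covers it.
#'
#' @param seed Integer seed.
#' @param n_poses Number of poses (the full-scale study records 663).
#' @param eye An [eye_model()]; sets the eye height.
#' @param speed_mps Walking speed (m/s); default 1.4, a typical human
#'   walking pace.
#' @param dt_s Sampling interval (s) between recorded poses.
#' @param sigma_heading_deg Standard deviation of per-step heading
#'   increments (degrees).
#' @param extent_m Diameter (m) of the arena the walk is confined to.
#' @return A data.frame of class `trajectory` with columns
#'   `index`, `x`, `y`, `z`, `heading_deg`.
#' @examples
#' tr <- generate_trajectory(1, 10, eye_model("human"))
#' nrow(tr)
#' @export
generate_trajectory <- function(seed, n_poses, eye, speed_mps = 1.4,
                                dt_s = 2, sigma_heading_deg = 15,
                                extent_m = 40) {
  stopifnot(n_poses >= 1, inherits(eye, "eye_model"), speed_mps >= 0)
  r_max <- 0.45 * extent_m
  with_seed(seed, {
    x <- z <- numeric(n_poses)
    heading <- numeric(n_poses)
    heading[1] <- stats::runif(1, 0, 360)
    step <- speed_mps * dt_s
    for (i in seq_len(n_poses)[-1]) {
      h_new <- heading[i - 1] + stats::rnorm(1, 0, sigma_heading_deg)
      xn <- x[i - 1] + step * cos(deg2rad(h_new))
      zn <- z[i - 1] + step * sin(deg2rad(h_new))
      if (sqrt(xn^2 + zn^2) > r_max) {
        # steer toward the arena center, with some wobble
        h_new <- rad2deg(atan2(-z[i - 1], -x[i - 1])) + stats::rnorm(1, 0, sigma_heading_deg)
        xn <- x[i - 1] + step * cos(deg2rad(h_new))
        zn <- z[i - 1] + step * sin(deg2rad(h_new))
      }
      heading[i] <- h_new %% 360
      x[i] <- xn; z[i] <- zn
    }
    out <- data.frame(index = seq_len(n_poses), x = x, y = eye$eye_height_m,
                      z = z, heading_deg = heading)
    class(out) <- c("trajectory", "data.frame")
    out
  })
}

#' Gaze strategy specification
#'
#' Three active-gaze strategies of a walking avatar: `straight` looks in
#' the heading direction at zero elevation; `down` looks 30 degrees below
#' the horizontal heading direction; `random` adds independent Gaussian
#' offsets with a standard deviation of 1 radian (57.30 degrees) to both
#' heading and elevation.
#'
#' @param strategy One of `"straight"`, `"down"`, `"random"`.
#' @param elevation_offset_deg Elevation of the `down` strategy (degrees,
#'   negative = below horizontal).
#' @param random_sd_rad Standard deviation (radians) of the `random`
#'   strategy's offsets.
#' @param seed Seed used when drawing random gaze offsets for a trajectory.
#' @return An object of class `gaze_spec`.
#' @export
gaze_spec <- function(strategy = c("straight", "down", "random"),
                      elevation_offset_deg = -30, random_sd_rad = 1,
                      seed = 1L) {
  strategy <- match.arg(strategy)
  structure(list(strategy = strategy,
                 elevation_offset_deg = elevation_offset_deg,
                 random_sd_rad = random_sd_rad, seed = as.integer(seed)),
            class = "gaze_spec")
}

#' Gaze direction for one pose
#'
#' Maps a pose's heading to a view direction under a gaze strategy. The
#' `random` strategy draws from the current R random number generator
#' state; use [gaze_directions()] for a seeded, reproducible set of draws
#' along a whole trajectory.
#'
#' @param pose A single-row `trajectory` data.frame (or list with
#'   `heading_deg`).
#' @param gaze A [gaze_spec()].
#' @return Named numeric vector `c(heading_deg, elevation_deg)`.
#' @export
apply_gaze <- function(pose, gaze) {
  stopifnot(inherits(gaze, "gaze_spec"))
  h <- pose$heading_deg
  stopifnot(is.numeric(h), length(h) == 1L)
  switch(gaze$strategy,
    straight = c(heading_deg = h, elevation_deg = 0),
    down = c(heading_deg = h, elevation_deg = gaze$elevation_offset_deg),
    random = {
      off <- stats::rnorm(2, 0, gaze$random_sd_rad)
      c(heading_deg = h + rad2deg(off[1]), elevation_deg = rad2deg(off[2]))
    },
    stop("unknown gaze strategy: ", gaze$strategy, call. = FALSE))
}

#' Seeded gaze directions along a trajectory
#'
#' @param trajectory A [generate_trajectory()] result.
#' @param gaze A [gaze_spec()]; its `seed` makes random-strategy draws
#'   reproducible.
#' @return data.frame with columns `index`, `heading_deg`, `elevation_deg`.
#' @export
gaze_directions <- function(trajectory, gaze) {
  stopifnot(inherits(gaze, "gaze_spec"))
  n <- nrow(trajectory)
  if (gaze$strategy == "random") {
    with_seed(gaze$seed, {
      dh <- rad2deg(stats::rnorm(n, 0, gaze$random_sd_rad))
      de <- rad2deg(stats::rnorm(n, 0, gaze$random_sd_rad))
      data.frame(index = trajectory$index,
                 heading_deg = trajectory$heading_deg + dh,
                 elevation_deg = de)
    })
  } else {
    el <- if (gaze$strategy == "down") gaze$elevation_offset_deg else 0
    data.frame(index = trajectory$index,
               heading_deg = trajectory$heading_deg,
               elevation_deg = el)
  }
}
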