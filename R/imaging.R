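# Off-axis pinhole rendering of image patches across the visual field,
# grayscale conversion and luminance normalization.

#' Image patch container
#'
#' A square luminance (or RGB) raster captured at one visual-field position
#' from one pose, with its projection type and provenance.
#'
#' @param pixels Numeric matrix (grayscale) or n x n x 3 array (RGB).
#' @param pixel_pitch_mm Physical pixel size on the imaging plane (mm).
#' @param projection `"planar"` (projective plane `z = -2r`) or `"tangent"`
#'   (local tangent plane to the retinal sphere).
#' @param coord [vf_coord()] of the patch center.
#' @param pose_index,strategy,species Provenance labels.
#' @param valid Logical matrix of valid pixels (`NULL` = all valid).
#' @return An object of class `image_patch`.
#' @export
image_patch <- function(pixels, pixel_pitch_mm = NA_real_,
                        projection = c("planar", "tangent"),
                        coord = NULL, pose_index = NA_integer_,
                        strategy = NA_character_, species = NA_character_,
                        valid = NULL) {
  projection <- match.arg(projection)
  n <- if (is.matrix(pixels)) nrow(pixels) else dim(pixels)[1]
  structure(list(pixels = pixels, patch_px = n,
                 pixel_pitch_mm = pixel_pitch_mm, projection = projection,
                 coord = coord, pose_index = pose_index, strategy = strategy,
                 species = species, valid = valid),
            class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  cat(sprintf("<image_patch> %d px, %s projection%s%s\n", x$patch_px, x$projection,
              if (!is.null(x$coord)) sprintf(", phi = %g chi = %g deg",
                                             x$coord$phi_deg, x$coord$chi_deg) else "",
              if (is.matrix(x$pixels)) " [gray]" else " [rgb]"))
  invisible(x)
}

patch_values <- function(patch) {
  px <- patch$pixels
  if (!is.null(patch$valid)) px[!patch$valid] <- NA
  px
}

camera_frame <- function(heading_deg, elevation_deg) {
  h <- deg2rad(heading_deg); e <- deg2rad(elevation_deg)
  fwd <- c(cos(e) * cos(h), sin(e), cos(e) * sin(h))
  up <- c(0, 1, 0)
  right <- c(fwd[2] * up[3] - fwd[3] * up[2],
             fwd[3] * up[1] - fwd[1] * up[3],
             fwd[1] * up[2] - fwd[2] * up[1])
  rn <- sqrt(sum(right^2))
  if (rn < 1e-9) { # looking straight up/down: pick right from heading
    right <- c(-sin(h), 0, cos(h)); rn <- 1
  }
  right <- right / rn
  upc <- c(right[2] * fwd[3] - right[3] * fwd[2],
           right[3] * fwd[1] - right[1] * fwd[3],
           right[1] * fwd[2] - right[2] * fwd[1])
  list(forward = fwd, right = right, up = upc)
}

#' Render an image patch through an off-axis pinhole frustum
#'
#' Ray-casts a procedural scene through a pinhole at the pose position. For
#' the planar projection, the patch lies on the projective plane `z = -2r`
#' of the eye, centered at [plane_point()] of the requested visual-field
#' coordinate — an off-axis (asymmetric-frustum) projection with bounds
#' `[x - s/2, x + s/2] x [y - s/2, y + s/2]`, `s = patch_px * pitch`. For
#' the tangent projection, the patch lies on the tangent plane to the
#' retinal sphere at that coordinate (rendered directly; the production
#' path instead warps planar captures, see [warp_to_tangent()]).
#'
#' The pixel pitch is `2 * (2r) * tan(fov/2) / scene_resolution_px` — the
#' pitch of a notional full frame covering `fov_deg` at the stated
#' resolution; patches at all eccentricities share it.
#'
#' @param scene A `scene_primitives` object.
#' @param pose Single-row `trajectory` data.frame (position + heading).
#' @param view Named vector `c(heading_deg, elevation_deg)` from
#'   [apply_gaze()], or `NULL` to look along the pose heading.
#' @param coord [vf_coord()] of the patch center.
#' @param eye [eye_model()].
#' @param scene_resolution_px Notional full-frame resolution (pixels).
#' @param fov_deg Full-frame field of view (degrees).
#' @param patch_px Patch side length (pixels).
#' @param projection `"planar"` or `"tangent"`.
#' @param supersample Rays per pixel side (anti-aliasing); 2 casts 4 rays
#'   per pixel and averages.
#' @param enforce_frame_bounds Error if the patch extends beyond the
#'   full-frame bounds instead of extending the frustum.
#' @return An RGB [image_patch].
#' @export
render_patch <- function(scene, pose, view = NULL, coord, eye,
                         scene_resolution_px, fov_deg = 120, patch_px,
                         projection = c("planar", "tangent"),
                         supersample = 2, enforce_frame_bounds = FALSE) {
  projection <- match.arg(projection)
  stopifnot(inherits(scene, "scene_primitives"), inherits(coord, "vf_coord"),
            inherits(eye, "eye_model"), patch_px >= 1, supersample >= 1)
  if (is.null(view)) view <- c(heading_deg = pose$heading_deg, elevation_deg = 0)
  pitch <- frame_pixel_pitch(eye, scene_resolution_px, fov_deg)

  if (projection == "planar") {
    p0 <- plane_point(coord, eye)
    ex <- c(1, 0, 0); ey <- c(0, 1, 0)
    if (enforce_frame_bounds) {
      half_frame <- scene_resolution_px * pitch / 2
      s <- patch_px * pitch
      if (max(abs(p0[1]), abs(p0[2])) + s / 2 > half_frame)
        stop(sprintf("patch at phi = %g deg exceeds the %g-deg frame bounds",
                     coord$phi_deg, fov_deg), call. = FALSE)
    }
  } else {
    tp <- tangent_plane_at(coord, eye)
    p0 <- tp$tangent_point_mm
    ex <- tp$basis[, 1]; ey <- tp$basis[, 2]
  }

  ss <- as.integer(supersample)
  n_hi <- patch_px * ss
  uu <- px_grid(n_hi) / ss
  vv <- rev(uu) # rows top to bottom
  g <- expand.grid(u = uu, v = vv)
  X <- cbind(p0[1] + pitch * (g$u * ex[1] + g$v * ey[1]),
             p0[2] + pitch * (g$u * ex[2] + g$v * ey[2]),
             p0[3] + pitch * (g$u * ex[3] + g$v * ey[3]))
  cam <- camera_frame(view[["heading_deg"]], view[["elevation_deg"]])
  # camera frame: x = right, y = up, looking along -z (z_cam = -forward)
  dirs <- cbind(X[, 1] * cam$right[1] + X[, 2] * cam$up[1] - X[, 3] * cam$forward[1],
                X[, 1] * cam$right[2] + X[, 2] * cam$up[2] - X[, 3] * cam$forward[2],
                X[, 1] * cam$right[3] + X[, 2] * cam$up[3] - X[, 3] * cam$forward[3])
  origin <- c(pose$x, pose$y, pose$z)
  rgb <- raycast_rays(dirs, origin, as_raycast_scene(scene))

  px <- array(NA_real_, dim = c(patch_px, patch_px, 3))
  for (ch in 1:3) {
    hi <- matrix(rgb[, ch], nrow = n_hi, ncol = n_hi, byrow = TRUE)
    px[, , ch] <- downsample_mean(hi, ss)
  }
  image_patch(px, pixel_pitch_mm = pitch, projection = projection,
              coord = coord, pose_index = pose$index)
}

downsample_mean <- function(m, ss) {
  if (ss == 1L) return(m)
  n <- nrow(m) / ss
  # average ss x ss blocks
  m2 <- matrix(colMeans(matrix(m, nrow = ss)), nrow = n) # rows pooled
  t(matrix(colMeans(matrix(t(m2), nrow = ss)), nrow = n))
}

#' Convert a rendered RGB patch to luminance
#'
#' Transforms linear RGB to CIE XYZ (sRGB primaries, D65 white) and keeps
#' the Y (luminance) channel; white `(1, 1, 1)` maps to `Y = 1`.
#'
#' @param patch RGB [image_patch] (or n x n x 3 array).
#' @return Grayscale [image_patch].
#' @export
to_luminance <- function(patch) {
  is_patch <- inherits(patch, "image_patch")
  px <- if (is_patch) patch$pixels else patch
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 3)
  if (any(px < 0 | px > 1, na.rm = TRUE)) {
    warning("RGB values outside [0, 1] clamped")
    px[px < 0] <- 0; px[px > 1] <- 1
  }
  y <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
  if (is_patch)
    image_patch(y, pixel_pitch_mm = patch$pixel_pitch_mm,
                projection = patch$projection, coord = patch$coord,
                pose_index = patch$pose_index, strategy = patch$strategy,
                species = patch$species, valid = patch$valid)
  else y
}

#' Divide a patch by its mean luminance
#'
#' After normalization the mean over valid pixels is exactly 1, making
#' patches comparable regardless of overall illumination; the operation is
#' idempotent and scale-invariant.
#'
#' @param patch Grayscale [image_patch] (or numeric matrix).
#' @return Normalized [image_patch] (or matrix).
#' @export
normalize_mean <- function(patch) {
  is_patch <- inherits(patch, "image_patch")
  px <- if (is_patch) patch$pixels else patch
  stopifnot(is.matrix(px))
  vals <- if (is_patch && !is.null(patch$valid)) px[patch$valid] else px
  m <- mean(vals, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("patch mean luminance is not positive; uninformative patch", call. = FALSE)
  out <- px / m
  if (is_patch) { patch$pixels <- out; patch } else out
}

#' Central crop of a patch
#'
#' Integer-aligned central crop; `out_px` must have the same parity as the
#' patch so that pixel centers coincide.
#'
#' @param patch [image_patch] or matrix.
#' @param out_px Output side length (pixels).
#' @return Cropped patch of the same type.
#' @export
crop_center <- function(patch, out_px) {
  is_patch <- inherits(patch, "image_patch")
  px <- if (is_patch) patch$pixels else patch
  n <- if (is.matrix(px)) nrow(px) else dim(px)[1]
  stopifnot(out_px <= n)
  if ((n - out_px) %% 2 != 0)
    stop("crop size must have the same parity as the source for center alignment",
         call. = FALSE)
  off <- (n - out_px) / 2
  idx <- (off + 1):(off + out_px)
  out <- if (is.matrix(px)) px[idx, idx] else px[idx, idx, , drop = FALSE]
  if (is_patch) {
    patch$pixels <- out
    patch$patch_px <- out_px
    if (!is.null(patch$valid)) patch$valid <- patch$valid[idx, idx]
    patch
  } else out
}

#' Enumerate the patches of an ensemble capture
#'
#' The capture plan is the Cartesian product of poses and visual-field grid
#' positions; each row identifies one planar patch to render.
#'
#' @param poses `trajectory` data.frame.
#' @param grid [visual_field_grid()] data.frame.
#' @return data.frame with columns `pose_index`, `phi_deg`, `chi_deg`.
#' @examples
#' tr <- generate_trajectory(1, 2, eye_model("human"))
#' nrow(ensemble_plan(tr, visual_field_grid())) # 2 x 17 = 34
#' @export
ensemble_plan <- function(poses, grid) {
  stopifnot(nrow(grid) >= 1)
  out <- merge(data.frame(pose_index = poses$index), grid, by = NULL)
  out <- out[order(out$pose_index, out$phi_deg, out$chi_deg), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# source capture size (px) needed so the warped tangent patch of out_px is
# fully covered; same parity as out_px so central crops stay pixel-aligned
tangent_source_px <- function(coord, eye, pitch, out_px, margin = 1.1) {
  if (coord$phi_deg == 0) return(out_px)
  h <- homography_for(coord, eye, pitch)
  half <- (out_px - 1) / 2 + 0.5
  corners <- rbind(c(-half, -half), c(-half, half), c(half, -half), c(half, half),
                   c(0, half), c(0, -half), c(half, 0), c(-half, 0))
  q <- apply_homography(h, corners, inverse = TRUE)
  need <- 2 * max(abs(q)) * margin + 2
  n <- as.integer(ceiling(need))
  if ((n - out_px) %% 2 != 0) n <- n + 1L
  n
}

#' Capture an ensemble of image patches
#'
#' Renders one planar luminance patch per (pose x grid position) and,
#' optionally, its tangent-plane twin obtained by warping a larger planar
#' capture through the local homography. Patches are converted to
#' luminance; mean normalization is left to the statistics stage.
#'
#' @param scene `scene_primitives`.
#' @param poses `trajectory` data.frame.
#' @param gaze [gaze_spec()].
#' @param eye [eye_model()].
#' @param grid [visual_field_grid()] data.frame.
#' @param scene_resolution_px,fov_deg,patch_px Imaging parameters (see
#'   [render_patch()]).
#' @param tangent Also produce tangent-projection twins.
#' @param supersample Rays per pixel side.
#' @return A `patch_store`: list with `patches` (list of [image_patch]) and
#'   `manifest` (data.frame: `patch_id`, `pose_index`, `strategy`,
#'   `species`, `phi_deg`, `chi_deg`, `projection`, `pixel_pitch_mm`).
#' @export
capture_ensemble <- function(scene, poses, gaze, eye, grid,
                             scene_resolution_px, fov_deg = 120, patch_px,
                             tangent = FALSE, supersample = 2) {
  stopifnot(nrow(grid) >= 1)
  views <- gaze_directions(poses, gaze)
  plan <- ensemble_plan(poses, grid)
  pitch <- frame_pixel_pitch(eye, scene_resolution_px, fov_deg)

  # per-coordinate warp machinery
  coords <- unique(grid[, c("phi_deg", "chi_deg")])
  warp_info <- lapply(seq_len(nrow(coords)), function(i) {
    co <- vf_coord(coords$phi_deg[i], coords$chi_deg[i])
    src <- if (tangent) tangent_source_px(co, eye, pitch, patch_px) else patch_px
    list(coord = co,
         h = if (tangent && co$phi_deg > 0) homography_for(co, eye, pitch) else NULL,
         src_px = src)
  })
  names(warp_info) <- paste(coords$phi_deg, coords$chi_deg)

  patches <- vector("list", nrow(plan) * (1L + as.integer(tangent)))
  man <- vector("list", length(patches))
  k <- 0L
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    wi <- warp_info[[paste(row$phi_deg, row$chi_deg)]]
    pose <- poses[poses$index == row$pose_index, ]
    view <- c(heading_deg = views$heading_deg[views$index == row$pose_index],
              elevation_deg = views$elevation_deg[views$index == row$pose_index])
    cap <- render_patch(scene, pose, view, wi$coord, eye,
                        scene_resolution_px, fov_deg, wi$src_px,
                        projection = "planar", supersample = supersample)
    cap <- to_luminance(cap)
    cap$strategy <- gaze$strategy
    cap$species <- eye$species
    planar <- crop_center(cap, patch_px)
    k <- k + 1L
    patches[[k]] <- planar
    man[[k]] <- data.frame(patch_id = k, pose_index = row$pose_index,
                           strategy = gaze$strategy, species = eye$species,
                           phi_deg = row$phi_deg, chi_deg = row$chi_deg,
                           projection = "planar", pixel_pitch_mm = pitch)
    if (tangent) {
      tw <- if (is.null(wi$h)) {
        p <- planar; p$projection <- "tangent"; p
      } else warp_to_tangent(cap, wi$h, patch_px, supersample = supersample)
      k <- k + 1L
      patches[[k]] <- tw
      man[[k]] <- data.frame(patch_id = k, pose_index = row$pose_index,
                             strategy = gaze$strategy, species = eye$species,
                             phi_deg = row$phi_deg, chi_deg = row$chi_deg,
                             projection = "tangent", pixel_pitch_mm = pitch)
    }
  }
  structure(list(patches = patches[seq_len(k)],
                 manifest = do.call(rbind, man[seq_len(k)])),
            class = "patch_store")
}

#' @export
print.patch_store <- function(x, ...) {
  cat(sprintf("<patch_store> %d patches (%d planar, %d tangent)\n",
              nrow(x$manifest), sum(x$manifest$projection == "planar"),
              sum(x$manifest$projection == "tangent")))
  invisible(x)
}
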