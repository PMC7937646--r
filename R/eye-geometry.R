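#' Thin-lens equivalent eye model
#'
#' Constructs an idealized eye focused at infinity: the retina is modeled as
#' a sphere of radius `r` centered at `c = (0, 0, -r)` in camera coordinates,
#' and the focal length is `f = 2r`. The world is projected either onto the
#' projective plane `z = -2r` at the back of the eyeball (planar imaging, as
#' in an ordinary camera) or onto the sphere itself.
#'
#' Species presets follow classical schematic-eye parameters: the reduced
#' human eye has `f = 16.67` mm with an eye height of 1.8 m, and the cat eye
#' has `f = 12.5` mm with an eye height of 0.25 m.
#'
#' @param species `"human"` or `"cat"`; selects default focal length and eye
#'   height.
#' @param focal_length_mm Optional override of the focal length (mm).
#' @param eye_height_m Optional override of the avatar's eye height (m).
#' @return An object of class `eye_model` with fields `species`,
#'   `focal_length_mm`, `radius_mm` (`= f/2`), `eye_height_m`.
#' @examples
#' eye_model("human")
#' eye_model("cat")$radius_mm
#' @export
eye_model <- function(species = c("human", "cat"),
                      focal_length_mm = NULL, eye_height_m = NULL) {
  species <- match.arg(species)
  defaults <- switch(species,
    human = list(f = 16.67, h = 1.8),
    cat   = list(f = 12.5,  h = 0.25))
  f <- if (is.null(focal_length_mm)) defaults$f else focal_length_mm
  h <- if (is.null(eye_height_m)) defaults$h else eye_height_m
  stopifnot(is.numeric(f), length(f) == 1L, f > 0,
            is.numeric(h), length(h) == 1L, h > 0)
  structure(list(species = species, focal_length_mm = f,
                 radius_mm = f / 2, eye_height_m = h),
            class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf("<eye_model> %s: f = %.4g mm (retina radius %.4g mm), eye height %.3g m\n",
              x$species, x$focal_length_mm, x$radius_mm, x$eye_height_m))
  invisible(x)
}

#' Visual-field coordinate
#'
#' A location in the visual field specified by eccentricity `phi` (angular
#' distance from the center of gaze) and polar angle `chi` (angle around the
#' center of gaze, counter-clockwise from the positive x axis with +y up).
#' At `phi = 0` all polar angles denote the same point; the canonical form
#' stores `chi = 0` there.
#'
#' @param eccentricity_deg Eccentricity in degrees, `0 <= phi < 90`.
#' @param polar_angle_deg Polar angle in degrees, reduced modulo 360.
#' @return An object of class `vf_coord` with fields `phi_deg`, `chi_deg`.
#' @examples
#' vf_coord(30, 90)
#' vf_coord(0, 135) # canonicalized to chi = 0
#' @export
vf_coord <- function(eccentricity_deg, polar_angle_deg = 0) {
  stopifnot(is.numeric(eccentricity_deg), length(eccentricity_deg) == 1L,
            is.numeric(polar_angle_deg), length(polar_angle_deg) == 1L)
  if (eccentricity_deg < 0 || eccentricity_deg >= 90)
    stop("eccentricity must lie in [0, 90) degrees", call. = FALSE)
  chi <- polar_angle_deg %% 360
  if (eccentricity_deg == 0) chi <- 0
  structure(list(phi_deg = eccentricity_deg, chi_deg = chi), class = "vf_coord")
}

#' @export
print.vf_coord <- function(x, ...) {
  cat(sprintf("<vf_coord> phi = %g deg, chi = %g deg\n", x$phi_deg, x$chi_deg))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Point on the projective plane for a visual-field coordinate
#'
#' Maps (phi, chi) to Cartesian coordinates on the imaging plane `z = -2r`
#' at the back of the model eye:
#' `(2r tan(phi) cos(chi), 2r tan(phi) sin(chi), -2r)`.
#'
#' @param coord A [vf_coord()].
#' @param eye An [eye_model()].
#' @return Numeric 3-vector (mm).
#' @examples
#' plane_point(vf_coord(45, 0), eye_model("human", focal_length_mm = 2))
#' @export
plane_point <- function(coord, eye) {
  stopifnot(inherits(coord, "vf_coord"), inherits(eye, "eye_model"))
  r <- eye$radius_mm
  phi <- deg2rad(coord$phi_deg); chi <- deg2rad(coord$chi_deg)
  c(2 * r * tan(phi) * cos(chi), 2 * r * tan(phi) * sin(chi), -2 * r)
}

#' Point on the spherical retina for a visual-field coordinate
#'
#' Maps (phi, chi) to the point where the ray through the corresponding
#' plane point pierces the retinal sphere of radius `r` centered at
#' `(0, 0, -r)`:
#' `(2r sin(phi) cos(phi) cos(chi), 2r sin(phi) cos(phi) sin(chi), -2r cos^2(phi))`.
#'
#' @inheritParams plane_point
#' @return Numeric 3-vector (mm), lying on the retinal sphere.
#' @examples
#' p <- sphere_point(vf_coord(30, 0), eye_model("human"))
#' sqrt(sum((p - c(0, 0, -eye_model("human")$radius_mm))^2)) # = r
#' @export
sphere_point <- function(coord, eye) {
  stopifnot(inherits(coord, "vf_coord"), inherits(eye, "eye_model"))
  r <- eye$radius_mm
  phi <- deg2rad(coord$phi_deg); chi <- deg2rad(coord$chi_deg)
  c(2 * r * sin(phi) * cos(phi) * cos(chi),
    2 * r * sin(phi) * cos(phi) * sin(chi),
    -2 * r * cos(phi)^2)
}

#' Tangent plane to the spherical retina at a visual-field coordinate
#'
#' The plane tangent to the retinal sphere at `sphere_point(coord)`. Its
#' in-plane basis is chosen so that the first axis points along the local
#' radial direction (increasing eccentricity) and the second completes a
#' right-handed frame with the inward normal; this makes orientations
#' measured on the tangent patch rotationally interpretable across polar
#' angles.
#'
#' @inheritParams plane_point
#' @return An object of class `tangent_plane` with fields `tangent_point_mm`
#'   (3-vector on the sphere), `normal` (outward unit normal `(p - c)/r`),
#'   and `basis` (3 x 2 matrix of orthonormal in-plane axes).
#' @export
tangent_plane_at <- function(coord, eye) {
  stopifnot(inherits(coord, "vf_coord"), inherits(eye, "eye_model"))
  r <- eye$radius_mm
  phi <- deg2rad(coord$phi_deg); chi <- deg2rad(coord$chi_deg)
  pT <- sphere_point(coord, eye)
  ctr <- c(0, 0, -r)
  nrm <- (pT - ctr) / r
  # d(sphere_point)/dphi, normalized: local radial (increasing-phi) direction
  e1 <- c(cos(2 * phi) * cos(chi), cos(2 * phi) * sin(chi), sin(2 * phi))
  e1 <- e1 / sqrt(sum(e1^2))
  n_in <- -nrm
  e2 <- c(n_in[2] * e1[3] - n_in[3] * e1[2],
          n_in[3] * e1[1] - n_in[1] * e1[3],
          n_in[1] * e1[2] - n_in[2] * e1[1])
  structure(list(tangent_point_mm = pT, normal = nrm,
                 basis = cbind(radial = e1, tangential = e2),
                 center_mm = ctr, radius_mm = r, coord = coord),
            class = "tangent_plane")
}

#' @export
print.tangent_plane <- function(x, ...) {
  cat(sprintf("<tangent_plane> at phi = %g, chi = %g deg; tangent point (%.4g, %.4g, %.4g) mm\n",
              x$coord$phi_deg, x$coord$chi_deg,
              x$tangent_point_mm[1], x$tangent_point_mm[2], x$tangent_point_mm[3]))
  invisible(x)
}

#' Homography between the projective plane and the local tangent plane
#'
#' Both the projective plane `z = -2r` and the tangent plane at
#' `(phi, chi)` are images of the same scene taken from the same center of
#' projection (the origin), so their pixel coordinates are related by a
#' 3 x 3 homography `H`, defined up to scale. With `B` embedding planar-patch
#' pixel coordinates into 3D and `A` embedding tangent-patch pixel
#' coordinates, corresponding points lie on the same ray through the origin
#' and `H` is proportional to `A^{-1} B`. `H` is normalized so that
#' `H[3, 3] = 1`.
#'
#' Pixel coordinates are centered: `(0, 0)` is the patch center, the first
#' axis increases rightward (planar patch: world +x at `chi = 0`; tangent
#' patch: local radial direction), the second increases upward. Both patches
#' share the same metric pixel pitch.
#'
#' @inheritParams plane_point
#' @param pixel_pitch_mm Physical size of one pixel on either plane (mm).
#' @return An object of class `homography`: fields `matrix` (3 x 3, `H[3,3] = 1`),
#'   `pixel_pitch_mm`, `coord`.
#' @export
homography_for <- function(coord, eye, pixel_pitch_mm) {
  stopifnot(inherits(coord, "vf_coord"), inherits(eye, "eye_model"),
            is.numeric(pixel_pitch_mm), pixel_pitch_mm > 0)
  p0 <- plane_point(coord, eye)
  tp <- tangent_plane_at(coord, eye)
  # planar-patch axes are frame-aligned (off-axis frustum renders with world
  # x right / y up); the tangent frame is radial-aligned, so H includes the
  # in-plane rotation between the two conventions
  B <- cbind(pixel_pitch_mm * c(1, 0, 0), pixel_pitch_mm * c(0, 1, 0), p0)
  A <- cbind(pixel_pitch_mm * tp$basis[, 1], pixel_pitch_mm * tp$basis[, 2],
             tp$tangent_point_mm)
  H <- solve(A, B)
  dimnames(H) <- NULL
  if (abs(H[3, 3]) < 1e-12)
    stop("degenerate homography (H[3,3] ~ 0)", call. = FALSE)
  H <- H / H[3, 3]
  structure(list(matrix = H, pixel_pitch_mm = pixel_pitch_mm, coord = coord,
                 eye = eye), class = "homography")
}

#' @export
print.homography <- function(x, ...) {
  cat(sprintf("<homography> plane -> tangent at phi = %g, chi = %g deg\n",
              x$coord$phi_deg, x$coord$chi_deg))
  print(round(x$matrix, 6))
  invisible(x)
}

#' Apply a homography to centered pixel coordinates
#'
#' @param h A [homography()] (or plain 3 x 3 matrix).
#' @param uv Matrix with two columns (or length-2 vector) of centered pixel
#'   coordinates.
#' @param inverse Map tangent-patch to planar-patch coordinates instead.
#' @return Matrix of mapped centered pixel coordinates.
#' @export
apply_homography <- function(h, uv, inverse = FALSE) {
  H <- if (inherits(h, "homography")) h$matrix else h
  if (inverse) H <- solve(H)
  uv <- rbind(matrix(uv, ncol = 2))
  q <- cbind(uv, 1) %*% t(H)
  q[, 1:2, drop = FALSE] / q[, 3]
}

#' Warp a planar image patch onto the tangent plane
#'
#' Resamples a planar-projection patch into the tangent-plane frame through
#' the homography, with bilinear interpolation. Output pixels whose preimage
#' falls outside the source patch are marked invalid (`NA` in the raster,
#' `FALSE` in the `valid` mask).
#'
#' @param patch An [image_patch] with `projection = "planar"`, or a plain
#'   numeric matrix (grayscale).
#' @param h The [homography_for()] the patch's visual-field position.
#' @param out_px Output patch side length in pixels.
#' @param require_full Error if any output pixel would be invalid, reporting
#'   the largest fully valid output size.
#' @param supersample Taps per output pixel side; tangent pixels cover
#'   several source pixels away from the patch center, so averaging
#'   `supersample^2` bilinear taps reduces resampling aliasing.
#' @return An [image_patch] with `projection = "tangent"`.
#' @export
warp_to_tangent <- function(patch, h, out_px, require_full = FALSE,
                            supersample = 2) {
  is_patch <- inherits(patch, "image_patch")
  px <- if (is_patch) patch$pixels else patch
  stopifnot(is.matrix(px))
  if (is_patch && !identical(patch$projection, "planar"))
    stop("warp_to_tangent expects a planar-projection patch", call. = FALSE)
  n_src <- nrow(px)
  Hinv <- solve(if (inherits(h, "homography")) h$matrix else h)

  ss <- as.integer(supersample)
  n_hi <- out_px * ss
  uv_out <- px_grid(n_hi) / ss
  g <- expand.grid(u = uv_out, v = uv_out)
  q <- cbind(g$u, g$v, 1) %*% t(Hinv)
  us <- q[, 1] / q[, 3]
  vs <- q[, 2] / q[, 3]
  # centered coords -> source matrix row/col (row 1 = top, v decreasing)
  ctr <- (n_src + 1) / 2
  cs <- us + ctr
  rs <- ctr - vs
  ok <- cs >= 1 & cs <= n_src & rs >= 1 & rs <= n_src & q[, 3] > 0

  if (require_full && !all(ok)) {
    lo <- 1L; hi <- out_px
    while (lo < hi) { # largest fully valid output size
      mid <- (lo + hi + 1L) %/% 2L
      uvm <- px_grid(mid); gm <- expand.grid(u = uvm, v = uvm)
      qm <- cbind(gm$u, gm$v, 1) %*% t(Hinv)
      um <- qm[, 1] / qm[, 3] + ctr; vm <- ctr - qm[, 2] / qm[, 3]
      if (all(um >= 1 & um <= n_src & vm >= 1 & vm <= n_src & qm[, 3] > 0))
        lo <- mid else hi <- mid - 1L
    }
    stop(sprintf("requested %d px exceeds the valid preimage; maximum fully valid output size is %d px",
                 out_px, lo), call. = FALSE)
  }

  out <- rep(NA_real_, n_hi * n_hi)
  if (any(ok)) {
    c0 <- floor(cs[ok]); r0 <- floor(rs[ok])
    fc <- cs[ok] - c0;   fr <- rs[ok] - r0
    c0 <- pmin.int(pmax.int(c0, 1L), n_src); r0 <- pmin.int(pmax.int(r0, 1L), n_src)
    c1 <- pmin.int(c0 + 1L, n_src);          r1 <- pmin.int(r0 + 1L, n_src)
    idx <- function(rr, cc) px[cbind(rr, cc)]
    val <- (1 - fr) * ((1 - fc) * idx(r0, c0) + fc * idx(r0, c1)) +
           fr       * ((1 - fc) * idx(r1, c0) + fc * idx(r1, c1))
    out[ok] <- val
  }
  # assemble the supersampled raster (row 1 = top), then block-average
  mat_hi <- matrix(NA_real_, n_hi, n_hi)
  ctr_h <- (n_hi + 1) / 2
  rows <- round(ctr_h - g$v * ss); cols <- round(g$u * ss + ctr_h)
  mat_hi[cbind(rows, cols)] <- out
  ok_hi <- matrix(FALSE, n_hi, n_hi)
  ok_hi[cbind(rows, cols)] <- ok
  if (ss > 1L) {
    mat <- downsample_mean(mat_hi, ss)
    vmask <- downsample_mean(ok_hi + 0, ss) == 1
    mat[!vmask] <- NA_real_
  } else {
    mat <- mat_hi
    vmask <- ok_hi
  }

  meta <- if (is_patch) patch else list()
  image_patch(mat,
              pixel_pitch_mm = if (is_patch) patch$pixel_pitch_mm else NA_real_,
              projection = "tangent",
              coord = if (is_patch) patch$coord else NULL,
              pose_index = if (is_patch) patch$pose_index else NA_integer_,
              strategy = if (is_patch) patch$strategy else NA_character_,
              species = if (is_patch) patch$species else NA_character_,
              valid = vmask)
}

#' Maximum 3D approximation error of the tangent plane
#'
#' For every pixel of a `patch_px` x `patch_px` patch laid out on the
#' tangent plane at `(phi, chi)` (pixel pitch set by rendering a `fov_deg`
#' field of view onto `scene_resolution_px` pixels on the projective plane),
#' the ray from the center of projection through the tangent-plane point is
#' intersected with the retinal sphere, and the Euclidean distance between
#' the paired sphere and plane points is computed. The maximum over the
#' patch quantifies how far the local planar approximation departs from the
#' spherical retina.
#'
#' @inheritParams plane_point
#' @param patch_px Patch side length in pixels on the tangent plane.
#' @param scene_resolution_px Full-frame resolution defining the pixel pitch.
#' @param fov_deg Full field of view of the frame (degrees).
#' @param method `"along_ray"` pairs points along rays through the camera
#'   center (the imaging correspondence); `"perpendicular"` measures the
#'   nearest-sphere-point distance instead.
#' @return Maximum distance (mm).
#' @examples
#' tangent_approx_error(vf_coord(30, 0), eye_model("human"), 128, 5954, 120)
#' @export
tangent_approx_error <- function(coord, eye, patch_px, scene_resolution_px,
                                 fov_deg = 120,
                                 method = c("along_ray", "perpendicular")) {
  method <- match.arg(method)
  stopifnot(inherits(coord, "vf_coord"), inherits(eye, "eye_model"),
            patch_px >= 1, scene_resolution_px > 0, fov_deg > 0, fov_deg < 180)
  r <- eye$radius_mm
  pitch <- frame_pixel_pitch(eye, scene_resolution_px, fov_deg)
  tp <- tangent_plane_at(coord, eye)
  off <- px_grid(patch_px)
  g <- expand.grid(u = off, v = off)
  X <- cbind(tp$tangent_point_mm[1] + pitch * (g$u * tp$basis[1, 1] + g$v * tp$basis[1, 2]),
             tp$tangent_point_mm[2] + pitch * (g$u * tp$basis[2, 1] + g$v * tp$basis[2, 2]),
             tp$tangent_point_mm[3] + pitch * (g$u * tp$basis[3, 1] + g$v * tp$basis[3, 2]))
  ctr <- c(0, 0, -r)
  if (method == "along_ray") {
    # |c| = r, so the sphere intersection along ray t*X solves t = 2 X.c / |X|^2
    tt <- 2 * (X %*% ctr) / rowSums(X^2)
    if (any(tt <= 0))
      stop("ray misses the retinal sphere; eccentricity too large for this patch",
           call. = FALSE)
    S <- X * as.numeric(tt)
    max(sqrt(rowSums((S - X)^2)))
  } else {
    d <- sqrt(rowSums((X - matrix(ctr, nrow(X), 3, byrow = TRUE))^2))
    max(abs(d - r))
  }
}

# centered pixel offsets for an n-pixel patch (pixel centers, patch center 0)
px_grid <- function(n) (seq_len(n) - 1) - (n - 1) / 2

# mm per pixel on the projective plane z = -2r for a full frame of
# resolution_px pixels spanning fov_deg
frame_pixel_pitch <- function(eye, resolution_px, fov_deg = 120) {
  2 * (2 * eye$radius_mm) * tan(deg2rad(fov_deg / 2)) / resolution_px
}
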