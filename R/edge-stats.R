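# Orientation-tensor edge detection and orientation histograms.
#
# Gradients come from a matched 5-tap prefilter/derivative pair designed
# for rotation invariance; the local structure (orientation) tensor is the
# smoothed outer product of the gradient, and its eigenstructure yields
# per-pixel energy (sum of eigenvalues), orientedness (normalized
# eigenvalue difference) and dominant edge orientation.

# 5-tap matched pair (interpolator + first derivative), rotation-invariant
# gradient design
.fs_p <- c(0.037659, 0.249153, 0.426375, 0.249153, 0.037659)
.fs_d <- c(-0.109604, -0.276691, 0.0, 0.276691, 0.109604)

# centered 1D convolution along rows (axis = 1: kernel runs down columns)
# or columns (axis = 2); edge-replicated borders (masked invalid upstream)
filter_axis <- function(m, k, axis) {
  stopifnot(length(k) %% 2 == 1)
  half <- (length(k) - 1) / 2
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  for (o in -half:half) {
    if (axis == 1) {
      idx <- pmin.int(pmax.int(seq_len(n1) + o, 1L), n1)
      out <- out + k[o + half + 1] * m[idx, , drop = FALSE]
    } else {
      idx <- pmin.int(pmax.int(seq_len(n2) + o, 1L), n2)
      out <- out + k[o + half + 1] * m[, idx, drop = FALSE]
    }
  }
  out
}

#' Rotation-invariant image gradients
#'
#' Applies the matched 5-tap prefilter/derivative pair separably: the
#' derivative kernel along one axis and the interpolating prefilter along
#' the other. Gradients are returned in visual-field coordinates (x
#' rightward, y upward); since matrix rows increase downward, the vertical
#' derivative is sign-flipped. A 2-pixel border is invalid.
#'
#' @param image Numeric matrix (grayscale patch) at least 16 px square, or
#'   an [image_patch].
#' @return List with `gx`, `gy` (matrices) and `valid` (logical matrix,
#'   `FALSE` on the 2-px border).
#' @export
gradient_pair <- function(image) {
  px <- if (inherits(image, "image_patch")) image$pixels else image
  stopifnot(is.matrix(px))
  if (nrow(px) < 16 || ncol(px) < 16)
    stop("image must be at least 16 px square", call. = FALSE)
  if (anyNA(px)) px[is.na(px)] <- mean(px, na.rm = TRUE)
  gx <- filter_axis(filter_axis(px, .fs_d, 2), .fs_p, 1)
  gy_row <- filter_axis(filter_axis(px, .fs_d, 1), .fs_p, 2)
  valid <- matrix(FALSE, nrow(px), ncol(px))
  valid[3:(nrow(px) - 2), 3:(ncol(px) - 2)] <- TRUE
  if (inherits(image, "image_patch") && !is.null(image$valid))
    valid <- valid & image$valid
  list(gx = gx, gy = -gy_row, valid = valid)
}

gauss_kernel_1d <- function(sigma = 1.2, half = 2L) {
  x <- -half:half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Local orientation tensor and its eigenstructure
#'
#' The tensor is the Gaussian-weighted local average of the gradient outer
#' product `[gx^2, gx gy; gx gy, gy^2]`. Its eigenvalues `l1 >= l2 >= 0`
#' give the local energy `l1 + l2` and orientedness
#' `(l1 - l2)/(l1 + l2)`; the dominant *edge* orientation (perpendicular
#' to the dominant gradient direction) is reported in degrees in
#' `[0, 180)`.
#'
#' @param gx,gy Gradient matrices from [gradient_pair()] (or a list with
#'   those fields as the first argument).
#' @param sigma Gaussian smoothing width (pixels) of the 5 x 5 local
#'   average.
#' @param valid Optional validity mask; shrunk by the smoothing support.
#' @return List of class `orientation_tensor`: `energy`, `orientedness`,
#'   `orientation_deg`, `l1`, `l2`, `valid`.
#' @export
orientation_tensor <- function(gx, gy = NULL, sigma = 1.2, valid = NULL) {
  if (is.list(gx) && is.null(gy)) {
    valid <- gx$valid; gy <- gx$gy; gx <- gx$gx
  }
  stopifnot(is.matrix(gx), is.matrix(gy), all(dim(gx) == dim(gy)))
  k <- gauss_kernel_1d(sigma)
  sm <- function(m) filter_axis(filter_axis(m, k, 1), k, 2)
  j11 <- sm(gx * gx); j22 <- sm(gy * gy); j12 <- sm(gx * gy)
  energy <- j11 + j22
  dif <- sqrt((j11 - j22)^2 + 4 * j12^2)
  orientedness <- ifelse(energy > 0, dif / energy, 0)
  # dominant gradient direction; edge orientation is perpendicular
  grad_dir <- 0.5 * atan2(2 * j12, j11 - j22)
  orientation <- (rad2deg(grad_dir) + 90) %% 180
  if (is.null(valid)) valid <- matrix(TRUE, nrow(gx), ncol(gx))
  # shrink mask by smoothing half-width
  half <- (length(k) - 1) / 2
  v2 <- matrix(FALSE, nrow(gx), ncol(gx))
  r <- (1 + half):(nrow(gx) - half); c <- (1 + half):(ncol(gx) - half)
  v2[r, c] <- valid[r, c]
  structure(list(energy = energy, orientedness = orientedness,
                 orientation_deg = orientation,
                 l1 = (energy + dif) / 2, l2 = (energy - dif) / 2,
                 valid = v2),
            class = "orientation_tensor")
}

#' Select edge pixels from an orientation tensor field
#'
#' Keeps pixels whose energy strictly exceeds the image's energy quantile
#' (default 68th percentile over valid pixels) and whose orientedness
#' strictly exceeds a threshold (default 0.8).
#'
#' @param tensor An `orientation_tensor`.
#' @param energy_quantile Per-image energy percentile (fraction).
#' @param orientedness_min Orientedness threshold.
#' @return data.frame of class `edge_pixel_set` with columns
#'   `orientation_deg`, `energy`, `orientedness`. May have zero rows.
#' @export
select_edges <- function(tensor, energy_quantile = 0.68, orientedness_min = 0.8) {
  stopifnot(inherits(tensor, "orientation_tensor"))
  v <- tensor$valid
  if (!any(v)) return(empty_edge_set())
  thr <- stats::quantile(tensor$energy[v], energy_quantile, names = FALSE)
  keep <- v & tensor$energy > thr & tensor$orientedness > orientedness_min
  out <- data.frame(orientation_deg = tensor$orientation_deg[keep],
                    energy = tensor$energy[keep],
                    orientedness = tensor$orientedness[keep])
  class(out) <- c("edge_pixel_set", "data.frame")
  out
}

empty_edge_set <- function() {
  out <- data.frame(orientation_deg = numeric(0), energy = numeric(0),
                    orientedness = numeric(0))
  class(out) <- c("edge_pixel_set", "data.frame")
  out
}

#' Edge orientations of a patch
#'
#' Convenience wrapper: gradients, orientation tensor, edge selection.
#'
#' @param patch Grayscale [image_patch] or matrix.
#' @param ... Passed to [select_edges()].
#' @return `edge_pixel_set` data.frame.
#' @export
edge_orientations <- function(patch, ...) {
  select_edges(orientation_tensor(gradient_pair(patch)), ...)
}

#' Circular orientation histogram
#'
#' Bins orientations (wrapped at 180 degrees) into equal-width bins and
#' normalizes to a density integrating to 1 over `[0, 180)`.
#'
#' @param angles_deg Orientations in degrees (an `edge_pixel_set` is also
#'   accepted).
#' @param n_bins Number of bins (>= 8); default 36 bins of 5 degrees.
#' @return List of class `orientation_histogram`: `mid_deg`, `density`,
#'   `counts`, `breaks_deg`, `n`.
#' @export
orientation_histogram <- function(angles_deg, n_bins = 36) {
  if (inherits(angles_deg, "edge_pixel_set")) angles_deg <- angles_deg$orientation_deg
  stopifnot(n_bins >= 8)
  if (length(angles_deg) == 0) stop("no orientations to histogram", call. = FALSE)
  a <- angles_deg %% 180
  width <- 180 / n_bins
  idx <- floor(a / width) %% n_bins
  counts <- tabulate(idx + 1L, nbins = n_bins)
  structure(list(mid_deg = (seq_len(n_bins) - 0.5) * width,
                 density = counts / (sum(counts) * width),
                 counts = counts,
                 breaks_deg = seq(0, 180, by = width),
                 n = length(a)),
            class = "orientation_histogram")
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf("<orientation_histogram> %d angles in %d bins of %g deg\n",
              x$n, length(x$counts), diff(x$breaks_deg[1:2])))
  invisible(x)
}
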