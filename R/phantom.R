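# Lateral-view phantom rendering: four soft-edged quadrilateral "vertebral
# bodies" (C4-C7) on a flat background, each rigidly rotated per frame
# according to a ground-truth recording. Not a photorealistic fluoroscopy
# simulation -- just enough structure for rigid template tracking to have a
# well-defined optimum, with controllable edge blur and pixel noise.

#' Specify a phantom image stack
#'
#' @param size Image side in pixels (square frames, >= 128). The acquisition
#'   protocol this emulates uses 1024 x 1024 frames; tests typically use a
#'   smaller size for speed.
#' @param centers Optional 4 x 2 matrix of body centres (x, y pixels, y down,
#'   1-based), cranial (C4) to caudal (C7). Default: a mildly curved
#'   vertical column.
#' @param body_scale Body half-width as a fraction of `size`.
#' @param contrast Intensity of a body above background, in `[0, 1]`.
#' @param blur_sigma Edge softness in pixels (>= 0); the body edge follows a
#'   logistic profile of this scale, approximating Gaussian-blurred edges.
#' @param noise_sd Additive i.i.d. Gaussian pixel noise, intensity units.
#' @param background Background intensity.
#' @param seed Integer seed for the pixel noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 1024L,
                         centers = NULL,
                         body_scale = 0.075,
                         contrast = 0.6,
                         blur_sigma = 1.5,
                         noise_sd = 0.02,
                         background = 0.15,
                         seed = 1L) {
  check_number(size, "size", min = 128)
  check_number(blur_sigma, "blur_sigma", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(contrast, "contrast", min = 0, max = 1)
  size <- as.integer(size)
  if (is.null(centers)) {
    centers <- cbind(
      x = size * c(0.53, 0.505, 0.49, 0.50),
      y = size * c(0.28, 0.44, 0.60, 0.76)
    )
  }
  stopifnot(is.matrix(centers), nrow(centers) == 4, ncol(centers) == 2)
  spec <- structure(
    list(size = size, centers = centers, body_scale = body_scale,
         contrast = contrast, blur_sigma = blur_sigma, noise_sd = noise_sd,
         background = background, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  polys <- phantom_polygons(spec)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      if (polygons_overlap(polys[[i]], polys[[j]])) {
        abort("phantom bodies overlap in the neutral pose; adjust centers or body_scale.")
      }
    }
  }
  spec
}

# neutral-pose body polygon (slightly trapezoidal so rotation is observable)
phantom_polygons <- function(spec) {
  w <- spec$body_scale * spec$size
  h <- 0.6 * w
  base <- rbind(
    c(-w, -0.90 * h),
    c(0.95 * w, -h),
    c(w, 0.95 * h),
    c(-0.90 * w, h)
  )
  lapply(1:4, function(i) sweep(base, 2, spec$centers[i, ], "+"))
}

# separating-axis test for convex polygons
polygons_overlap <- function(p1, p2) {
  axes <- rbind(poly_edge_normals(p1), poly_edge_normals(p2))
  for (k in seq_len(nrow(axes))) {
    a <- axes[k, ]
    r1 <- range(p1 %*% a)
    r2 <- range(p2 %*% a)
    if (r1[2] < r2[1] || r2[2] < r1[1]) return(FALSE)
  }
  TRUE
}

poly_edge_normals <- function(p) {
  nv <- nrow(p)
  e <- p[c(2:nv, 1), ] - p
  cbind(-e[, 2], e[, 1]) / pmax(sqrt(rowSums(e^2)), 1e-12)
}

poly_centroid <- function(p) colMeans(p)

# signed distance of points to a convex polygon (< 0 inside)
signed_dist_convex <- function(px, py, poly) {
  cen <- poly_centroid(poly)
  nv <- nrow(poly)
  d <- rep(-Inf, length(px))
  for (k in seq_len(nv)) {
    v1 <- poly[k, ]
    v2 <- poly[if (k == nv) 1L else k + 1L, ]
    e <- v2 - v1
    nrm <- c(-e[2], e[1]) / max(sqrt(sum(e^2)), 1e-12)
    if (sum((cen - v1) * nrm) > 0) nrm <- -nrm  # outward
    d <- pmax(d, (px - v1[1]) * nrm[1] + (py - v1[2]) * nrm[2])
  }
  d
}

# 2D rotation in image coordinates (x right, y down); theta in degrees.
rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

transform_points <- function(pts, theta_deg, tx, ty, center) {
  sweep(sweep(pts, 2, center) %*% t(rot2(theta_deg)), 2,
        center + c(tx, ty), "+")
}

#' Per-frame ground-truth vertebral poses of a recording
#'
#' Converts the segmental angles of a ground-truth recording into absolute
#' per-vertebra rotations: C7 is held fixed and each vertebra above it
#' accumulates its segments, so `theta(C4) - theta(C7)` equals the block
#' rotation and each segmental angle equals the difference of adjacent
#' vertebral angles. Translations are zero (each body rotates about its own
#' centre).
#'
#' @param rec A `gt_recording`.
#' @return Tibble `(frame, vertebra, theta_deg, tx_px, ty_px)`.
#' @export
recording_poses <- function(rec) {
  stopifnot(inherits(rec, "gt_recording"))
  wide <- pivot_wider(rec$angles, names_from = "segment",
                      values_from = "angle_deg")
  th_c7 <- 0 * wide$`C6-C7`
  th_c6 <- wide$`C6-C7`
  th_c5 <- wide$`C6-C7` + wide$`C5-C6`
  th_c4 <- wide$`C6-C7` + wide$`C5-C6` + wide$`C4-C5`
  tibble(
    frame = rep(wide$frame, times = 4),
    vertebra = rep(cervseq_vertebrae(), each = nrow(wide)),
    theta_deg = c(th_c4, th_c5, th_c6, th_c7),
    tx_px = 0, ty_px = 0
  )
}

#' Render a ground-truth recording as a phantom image stack
#'
#' One square grayscale frame per recording frame; each vertebral body is
#' rotated about its own centre by the ground-truth pose. The true poses and
#' the neutral (frame 0) body contours are returned alongside the frames so
#' trackers can be benchmarked against them.
#'
#' @param rec A `gt_recording` from [generate_profile()].
#' @param phantom A [phantom_spec()].
#' @return An object of class `phantom_stack`: list with `frames` (list of
#'   `size x size` matrices, values in intensity units), `poses` (the
#'   ground-truth pose tibble), `contours` (named list of neutral-pose
#'   polygons), and the `phantom` spec.
#' @export
#' @examples
#' rec <- generate_profile(young_consistent_spec(n_frames = 12))
#' stack <- render_frames(rec, phantom_spec(size = 160, seed = 2))
#' length(stack$frames)
render_frames <- function(rec, phantom) {
  stopifnot(inherits(rec, "gt_recording"), inherits(phantom, "phantom_spec"))
  poses <- recording_poses(rec)
  polys <- phantom_polygons(phantom)
  names(polys) <- cervseq_vertebrae()
  n_frames <- max(poses$frame) + 1L
  size <- phantom$size
  sg <- max(phantom$blur_sigma, 0.25)
  frames <- vector("list", n_frames)
  pose_w <- pivot_wider(poses[, c("frame", "vertebra", "theta_deg")],
                        names_from = "vertebra", values_from = "theta_deg")
  for (f in seq_len(n_frames)) {
    img <- matrix(phantom$background, size, size)
    for (v in seq_along(polys)) {
      theta <- pose_w[[cervseq_vertebrae()[v]]][f]
      poly <- transform_points(polys[[v]], theta, 0, 0,
                               poly_centroid(polys[[v]]))
      if (any(poly < 1) || any(poly > size)) {
        abort(sprintf(
          "vertebra %s leaves the field of view at frame %d",
          cervseq_vertebrae()[v], f - 1L
        ), class = "cervseq_out_of_view")
      }
      margin <- ceiling(5 * sg)
      xr <- max(1L, floor(min(poly[, 1])) - margin):
        min(size, ceiling(max(poly[, 1])) + margin)
      yr <- max(1L, floor(min(poly[, 2])) - margin):
        min(size, ceiling(max(poly[, 2])) + margin)
      gx <- rep(xr, each = length(yr))
      gy <- rep(yr, times = length(xr))
      d <- signed_dist_convex(gx, gy, poly)
      img[cbind(gy, gx)] <- img[cbind(gy, gx)] +
        phantom$contrast * stats::plogis(-d / sg)
    }
    if (phantom$noise_sd > 0) {
      set.seed(derive_seed(phantom$seed, f))
      img <- img + matrix(rnorm(size * size, 0, phantom$noise_sd), size, size)
    }
    frames[[f]] <- img
  }
  structure(
    list(frames = frames, poses = poses, contours = polys, phantom = phantom,
         fps = rec$fps, label = rec$label),
    class = "phantom_stack"
  )
}

#' @export
print.phantom_stack <- function(x, ...) {
  cat(sprintf("<phantom_stack> %d frames of %d x %d px (%s)\n",
              length(x$frames), x$phantom$size, x$phantom$size, x$label))
  invisible(x)
}
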