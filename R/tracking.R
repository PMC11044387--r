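# Rigid 2D template tracking of annotated vertebrae across an image
# sequence. Each vertebra is a rigid body: its pose per frame is an in-plane
# rotation about the annotated contour centroid plus a translation, found by
# maximising the normalized cross-correlation (NCC) of the pixels under the
# (transformed) contour against the reference frame. Contrast changes
# between frames do not affect NCC, which is why it is the standard score
# for fluoroscopy template tracking.

#' Define a vertebral contour template
#'
#' A closed polygon annotated on the reference (first) frame, identifying
#' one vertebra. The tracked pose of every later frame is expressed relative
#' to this annotation.
#'
#' @param vertebra Label, one of `"C4" ... "C7"` (other labels are allowed
#'   but the kinematics stage expects C4-C7).
#' @param vertices Numeric matrix (>= 3 rows, 2 columns: x, y pixels,
#'   1-based, y down) of polygon vertices in order. Must be simple
#'   (non-self-intersecting).
#' @return An object of class `contour_template` with fields `vertebra`,
#'   `vertices` and `center` (the centroid).
#' @export
contour_template <- function(vertebra, vertices) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3 ||
      any(!is.finite(vertices))) {
    abort("`vertices` must be a finite numeric matrix with >= 3 rows and 2 columns.")
  }
  if (polygon_self_intersects(vertices)) {
    abort("contour polygon is self-intersecting.")
  }
  structure(
    list(vertebra = as.character(vertebra), vertices = vertices,
         center = colMeans(vertices)),
    class = "contour_template"
  )
}

# brute-force proper-crossing check between non-adjacent edges
polygon_self_intersects <- function(p) {
  nv <- nrow(p)
  seg <- function(k) rbind(p[k, ], p[if (k == nv) 1L else k + 1L, ])
  cross_z <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  crosses <- function(s1, s2) {
    d1 <- cross_z(s2[1, ], s2[2, ], s1[1, ])
    d2 <- cross_z(s2[1, ], s2[2, ], s1[2, ])
    d3 <- cross_z(s1[1, ], s1[2, ], s2[1, ])
    d4 <- cross_z(s1[1, ], s1[2, ], s2[2, ])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (nv < 4) return(FALSE)
  for (i in seq_len(nv - 2)) {
    for (j in (i + 2):nv) {
      if (i == 1 && j == nv) next  # adjacent through the closing edge
      if (crosses(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

#' Templates from a rendered phantom stack
#'
#' Convenience constructor that annotates the neutral-pose (frame 0) body
#' contours of a rendered phantom, mimicking the manual annotation step of a
#' real analysis.
#'
#' @param stack A `phantom_stack` from [render_frames()].
#' @return Named list of [contour_template()] objects (C4-C7).
#' @export
templates_from_stack <- function(stack) {
  stopifnot(inherits(stack, "phantom_stack"))
  lapply(setNames(nm = names(stack$contours)), function(v) {
    contour_template(v, stack$contours[[v]])
  })
}

#' Tracking configuration
#'
#' @param grid_theta Half-width of the coarse rotation search around the
#'   previous pose, degrees.
#' @param grid_theta_step Coarse rotation step, degrees.
#' @param grid_trans Half-width of the coarse translation search, pixels.
#' @param grid_trans_step Coarse translation step, pixels.
#' @param dilate_px Outward dilation of the contour when sampling template
#'   pixels, so that body edges (which carry the rotation signal) are
#'   included.
#' @param score_floor NCC below which a frame is marked lost.
#' @param min_valid_fraction Minimum fraction of template pixels that must
#'   land inside the image for a candidate pose to be scored.
#' @param presmooth_sigma Gaussian pre-smoothing (pixels) applied to every
#'   frame (reference included) before matching; suppresses pixel noise so
#'   the similarity landscape stays smooth enough for sub-degree
#'   refinement. `0` disables.
#' @param reltol Relative convergence tolerance of the simplex refinement.
#' @return A list of class `track_config`.
#' @export
track_config <- function(grid_theta = 2, grid_theta_step = 0.5,
                         grid_trans = 8, grid_trans_step = 4,
                         dilate_px = 3, score_floor = 0.4,
                         min_valid_fraction = 0.8, presmooth_sigma = 1.5,
                         reltol = 1e-9) {
  structure(
    list(grid_theta = grid_theta, grid_theta_step = grid_theta_step,
         grid_trans = grid_trans, grid_trans_step = grid_trans_step,
         dilate_px = dilate_px, score_floor = score_floor,
         min_valid_fraction = min_valid_fraction,
         presmooth_sigma = presmooth_sigma, reltol = reltol),
    class = "track_config"
  )
}

# separable Gaussian blur with replicated edges (banded convolution
# matrices, so it stays fast for fluoroscopy-sized frames)
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  band <- function(n) {
    m <- matrix(0, n, n)
    for (j in seq(-r, r)) {
      idx <- seq_len(n)
      src <- pmin(pmax(idx + j, 1L), n)  # replicate edges
      m[cbind(idx, src)] <- m[cbind(idx, src)] + k[j + r + 1]
    }
    m
  }
  br <- band(nrow(img))
  bc <- band(ncol(img))
  br %*% img %*% t(bc)
}

# bilinear interpolation; x = column, y = row, 1-based. Returns NA outside.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  valid <- x >= 1 & x <= nc & y >= 1 & y <= nr
  out <- rep(NA_real_, length(x))
  if (!any(valid)) return(out)
  xv <- pmin(x[valid], nc - 1e-9)
  yv <- pmin(y[valid], nr - 1e-9)
  x0 <- floor(xv); y0 <- floor(yv)
  fx <- xv - x0; fy <- yv - y0
  x1 <- pmin(x0 + 1, nc); y1 <- pmin(y0 + 1, nr)
  v00 <- img[cbind(y0, x0)]
  v10 <- img[cbind(y0, x1)]
  v01 <- img[cbind(y1, x0)]
  v11 <- img[cbind(y1, x1)]
  out[valid] <- (1 - fy) * ((1 - fx) * v00 + fx * v10) +
    fy * ((1 - fx) * v01 + fx * v11)
  out
}

# integer pixels inside the dilated template polygon
template_pixels <- function(template, dilate_px) {
  poly <- template$vertices
  cen <- template$center
  radii <- sqrt(rowSums(sweep(poly, 2, cen)^2))
  dil <- sweep(sweep(poly, 2, cen) * (1 + dilate_px / pmax(radii, 1e-9)),
               2, cen, "+")
  xr <- floor(min(dil[, 1])):ceiling(max(dil[, 1]))
  yr <- floor(min(dil[, 2])):ceiling(max(dil[, 2]))
  gx <- rep(xr, each = length(yr))
  gy <- rep(yr, times = length(xr))
  inside <- signed_dist_convex(gx, gy, dil) <= 0
  cbind(x = gx[inside], y = gy[inside])
}

ncc_score <- function(tvals, svals, min_valid_fraction) {
  ok <- !is.na(svals)
  if (mean(ok) < min_valid_fraction) return(-Inf)
  tv <- tvals[ok]; sv <- svals[ok]
  if (sd(tv) < 1e-12 || sd(sv) < 1e-12) return(NA_real_)
  cor(tv, sv)
}

#' Track vertebral poses through an image sequence
#'
#' Estimates, for every frame and every template, the planar rigid pose
#' (rotation about the template centroid plus translation) that maximises
#' the normalized cross-correlation between the reference-frame template
#' pixels and the target frame. The search is a coarse grid around the
#' previous frame's pose followed by Nelder-Mead refinement; the pose of
#' frame 0 is the identity by definition. Frames whose best score falls
#' below `config$score_floor` (or cannot be scored at all) are marked
#' `lost` and reported via a warning -- they are never silently
#' interpolated.
#'
#' @param frames List of numeric matrices (one per frame, equal size), or a
#'   `phantom_stack`.
#' @param templates List of [contour_template()] objects annotated on
#'   frame 0.
#' @param config A [track_config()].
#' @return Tibble `(frame, vertebra, theta_deg, tx_px, ty_px, score, lost)`
#'   with `frame` 0-based. Lost frames are listed in the
#'   `"lost_frames"` attribute.
#' @export
#' @examples
#' rec <- generate_profile(young_consistent_spec(n_frames = 12))
#' stack <- render_frames(rec, phantom_spec(size = 160))
#' poses <- track_sequence(stack, templates_from_stack(stack))
track_sequence <- function(frames, templates, config = track_config()) {
  if (inherits(frames, "phantom_stack")) frames <- frames$frames
  if (!is.list(frames) || length(frames) < 2) {
    abort("`frames` must be a list of at least 2 image matrices.")
  }
  stopifnot(inherits(config, "track_config"))
  n_frames <- length(frames)
  if (config$presmooth_sigma > 0) {
    frames <- lapply(frames, gaussian_blur, sigma = config$presmooth_sigma)
  }
  ref <- frames[[1]]
  out <- vector("list", length(templates))
  for (ti in seq_along(templates)) {
    tmpl <- templates[[ti]]
    stopifnot(inherits(tmpl, "contour_template"))
    pix <- template_pixels(tmpl, config$dilate_px)
    tvals <- bilinear_sample(ref, pix[, "x"], pix[, "y"])
    cen <- tmpl$center
    score_pose <- function(par, img) {
      q <- transform_points(pix, par[1], par[2], par[3], cen)
      ncc_score(tvals, bilinear_sample(img, q[, 1], q[, 2]),
                config$min_valid_fraction)
    }
    theta <- numeric(n_frames); tx <- numeric(n_frames); ty <- numeric(n_frames)
    score <- numeric(n_frames); lost <- logical(n_frames)
    score[1] <- 1; lost[1] <- FALSE
    degenerate <- is.na(sd(tvals, na.rm = TRUE)) ||
      sd(tvals, na.rm = TRUE) < 1e-12
    for (f in 2:n_frames) {
      if (degenerate) {
        score[f] <- NA_real_; lost[f] <- TRUE
        theta[f] <- theta[f - 1]; tx[f] <- tx[f - 1]; ty[f] <- ty[f - 1]
        next
      }
      img <- frames[[f]]
      prev <- c(theta[f - 1], tx[f - 1], ty[f - 1])
      gth <- prev[1] + seq(-config$grid_theta, config$grid_theta,
                           by = config$grid_theta_step)
      gtr <- seq(-config$grid_trans, config$grid_trans,
                 by = config$grid_trans_step)
      grid <- expand.grid(th = gth, dx = prev[2] + gtr, dy = prev[3] + gtr)
      sc <- vapply(seq_len(nrow(grid)), function(k) {
        s <- score_pose(c(grid$th[k], grid$dx[k], grid$dy[k]), img)
        if (is.na(s)) -Inf else s
      }, numeric(1))
      best <- as.numeric(grid[which.max(sc), ])
      if (all(!is.finite(sc))) {
        score[f] <- NA_real_; lost[f] <- TRUE
        theta[f] <- prev[1]; tx[f] <- prev[2]; ty[f] <- prev[3]
        next
      }
      opt <- optim(
        best,
        function(p) {
          s <- score_pose(p, img)
          if (is.finite(s)) -s else 1e6
        },
        method = "Nelder-Mead",
        control = list(reltol = config$reltol, maxit = 400,
                       parscale = c(0.5, 1, 1))
      )
      theta[f] <- opt$par[1]; tx[f] <- opt$par[2]; ty[f] <- opt$par[3]
      score[f] <- -opt$value
      lost[f] <- !is.finite(score[f]) || score[f] < config$score_floor
    }
    out[[ti]] <- tibble(
      frame = seq_len(n_frames) - 1L,
      vertebra = tmpl$vertebra,
      theta_deg = theta, tx_px = tx, ty_px = ty,
      score = score, lost = lost
    )
  }
  poses <- bind_rows(out)
  lost_tbl <- poses[poses$lost, c("frame", "vertebra")]
  if (nrow(lost_tbl) > 0) {
    warn(sprintf(
      "tracking lost %d frame/vertebra pose(s): %s",
      nrow(lost_tbl),
      paste(utils::head(paste0(lost_tbl$vertebra, "@", lost_tbl$frame), 10),
            collapse = ", ")
    ))
  }
  attr(poses, "lost_frames") <- lost_tbl
  attr(poses, "config") <- config
  poses
}

#' Manually correct a tracked pose
#'
#' Replaces the pose of one vertebra in one frame, mirroring the manual
#' check-and-adjust step of the analysis workflow. The correction is
#' appended to the `"corrections"` attribute so it remains auditable;
#' downstream kinematics recompute from the corrected values.
#'
#' @param poses Pose tibble as returned by [track_sequence()].
#' @param frame 0-based frame index (must exist in `poses`).
#' @param vertebra Vertebra label (must exist in `poses`).
#' @param theta_deg,tx_px,ty_px The corrected pose.
#' @return The corrected pose tibble.
#' @export
manual_correction <- function(poses, frame, vertebra, theta_deg,
                              tx_px = 0, ty_px = 0) {
  idx <- which(poses$frame == frame & poses$vertebra == vertebra)
  if (length(idx) != 1) {
    abort(sprintf("no tracked pose for vertebra %s at frame %s.",
                  vertebra, format(frame)))
  }
  log <- attr(poses, "corrections") %||%
    tibble(frame = integer(), vertebra = character(),
           old_theta_deg = numeric(), new_theta_deg = numeric())
  log <- bind_rows(log, tibble(
    frame = as.integer(frame), vertebra = vertebra,
    old_theta_deg = poses$theta_deg[idx], new_theta_deg = theta_deg
  ))
  poses$theta_deg[idx] <- theta_deg
  poses$tx_px[idx] <- tx_px
  poses$ty_px[idx] <- ty_px
  if ("lost" %in% names(poses)) poses$lost[idx] <- FALSE
  attr(poses, "corrections") <- log
  poses
}
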