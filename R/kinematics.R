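# From vertebral poses to segmental kinematics. The relative angle of a
# motion segment is theta(upper vertebra) - theta(lower vertebra); the block
# rotation of C4-C7 is the sum of the three segmental angles, which equals
# theta(C4) - theta(C7) identically. The SSC (sequence of segmental
# contributions) curve re-expresses each segment's rotation as a function of
# cumulative block rotation instead of time.

#' Segmental angle series from vertebral poses
#'
#' For each motion segment (C4-C5, C5-C6, C6-C7), computes the per-frame
#' relative angle `theta(upper) - theta(lower)`, referenced to zero at the
#' first frame.
#'
#' @param poses Tibble with columns `frame`, `vertebra`, `theta_deg`
#'   containing all four vertebrae C4-C7 on every frame (as produced by
#'   [track_sequence()] or [recording_poses()]).
#' @return Tibble `(frame, segment, angle_deg)`, one row per segment per
#'   frame.
#' @export
#' @examples
#' rec <- generate_profile(young_consistent_spec(n_frames = 12))
#' ang <- segmental_angles(recording_poses(rec))
segmental_angles <- function(poses) {
  need <- c("frame", "vertebra", "theta_deg")
  if (!all(need %in% names(poses))) {
    abort("`poses` must have columns frame, vertebra, theta_deg.")
  }
  frames <- sort(unique(poses$frame))
  for (v in cervseq_vertebrae()) {
    fv <- poses$frame[poses$vertebra == v]
    missing <- setdiff(frames, fv)
    if (length(fv) == 0 || length(missing) > 0) {
      abort(sprintf(
        "poses incomplete: vertebra %s missing%s.", v,
        if (length(missing) > 0)
          paste0(" at frame(s) ", paste(head(missing, 5), collapse = ", "))
        else ""
      ))
    }
  }
  wide <- pivot_wider(poses[, need], names_from = "vertebra",
                      values_from = "theta_deg")
  wide <- arrange(wide, .data$frame)
  segs <- list(
    "C4-C5" = wide$C4 - wide$C5,
    "C5-C6" = wide$C5 - wide$C6,
    "C6-C7" = wide$C6 - wide$C7
  )
  bind_rows(lapply(names(segs), function(s) {
    tibble(frame = wide$frame, segment = s,
           angle_deg = segs[[s]] - segs[[s]][1])
  }))
}

#' Cumulative C4-C7 block rotation
#'
#' The per-frame sum of the three segmental angles. Because the segmental
#' angles telescope, this equals `theta(C4) - theta(C7)` exactly.
#'
#' @param angles Segment angle tibble from [segmental_angles()] (or a
#'   `gt_recording`'s `$angles`).
#' @return Tibble `(frame, block_deg)`.
#' @export
cumulative_block <- function(angles) {
  wide <- angles_wide(angles)
  tibble(frame = wide$frame,
         block_deg = wide$`C4-C5` + wide$`C5-C6` + wide$`C6-C7`)
}

angles_wide <- function(angles) {
  if (inherits(angles, "gt_recording")) angles <- angles$angles
  need <- c("frame", "segment", "angle_deg")
  if (!all(need %in% names(angles))) {
    abort("`angles` must have columns frame, segment, angle_deg.")
  }
  if (!setequal(unique(angles$segment), cervseq_segments())) {
    abort("`angles` must contain exactly the segments C4-C5, C5-C6, C6-C7.")
  }
  counts <- table(angles$segment)
  if (length(unique(counts)) != 1) {
    abort("segment series have mismatched lengths.")
  }
  arrange(pivot_wider(angles[, need], names_from = "segment",
                      values_from = "angle_deg"), .data$frame)
}

#' SSC configuration
#'
#' @param sg_window Savitzky-Golay window length (odd, frames) applied to
#'   each segmental angle series before differencing; `1` disables
#'   smoothing.
#' @param sg_order Polynomial order of the filter.
#' @param grid_step Width of the cumulative-rotation grid cells, degrees.
#' @param min_rotation Net block rotation (degrees) below which the
#'   recording is flagged `insufficient motion` instead of yielding a curve.
#' @return List of class `ssc_config`.
#' @export
ssc_config <- function(sg_window = 5, sg_order = 2, grid_step = 0.1,
                       min_rotation = 3) {
  if (sg_window %% 2 != 1 || sg_window < 1) {
    abort("`sg_window` must be an odd positive integer.")
  }
  if (sg_window > 1 && sg_order >= sg_window) {
    abort("`sg_order` must be smaller than `sg_window`.")
  }
  check_number(grid_step, "grid_step", min = 1e-6)
  check_number(min_rotation, "min_rotation", min = 0)
  structure(list(sg_window = sg_window, sg_order = sg_order,
                 grid_step = grid_step, min_rotation = min_rotation),
            class = "ssc_config")
}

#' Build the sequence-of-segmental-contributions curve
#'
#' Re-expresses each segment's (optionally smoothed) rotation as a function
#' of cumulative C4-C7 block rotation on a uniform grid. Frames where the
#' block transiently rotates backwards are folded onto the running maximum
#' of cumulative rotation for grid placement, while their (possibly
#' negative) segmental contributions are kept, so the integral of each
#' segment's curve over cumulative rotation equals that segment's net
#' (smoothed) rotation exactly.
#'
#' Two y representations are returned per grid cell: `rate` (degrees of
#' segmental rotation per degree of block rotation; the three rates sum to
#' 1 where the block moves forward) and `contribution_per_frame` (degrees
#' per frame, the quantity conventionally plotted and to which the peak
#' significance threshold applies).
#'
#' @param angles Segment angle tibble (or a `gt_recording`).
#' @param fps Frame rate; used only for metadata.
#' @param config An [ssc_config()].
#' @return Object of class `ssc_curve`: a tibble
#'   `(x, segment, rate, contribution_per_frame)` with attributes
#'   `net_rotation` (named, smoothed net rotation per segment),
#'   `total_rotation` (block), `grid_step`, `cell_width`,
#'   `insufficient_motion`, `config`. When the net block rotation is below
#'   `config$min_rotation` the tibble is empty and
#'   `insufficient_motion = TRUE`.
#' @export
#' @examples
#' rec <- generate_profile(young_consistent_spec())
#' curve <- build_ssc(rec)
build_ssc <- function(angles, fps = 10, config = ssc_config()) {
  if (inherits(angles, "gt_recording")) {
    fps <- angles$fps
    angles <- angles$angles
  }
  stopifnot(inherits(config, "ssc_config"))
  wide <- angles_wide(angles)
  n <- nrow(wide)
  segs <- cervseq_segments()
  sm <- sapply(segs, function(s) smooth_series(wide[[s]], config))
  sm <- sweep(sm, 2, sm[1, ])  # re-zero at first frame
  block <- rowSums(sm)
  net_block <- block[n] - block[1]
  empty_curve <- function() {
    structure(
      tibble(x = numeric(), segment = character(), rate = numeric(),
             contribution_per_frame = numeric()),
      net_rotation = setNames(sm[n, ] - sm[1, ], segs),
      total_rotation = net_block,
      grid_step = config$grid_step, cell_width = numeric(),
      insufficient_motion = TRUE, fps = fps, config = config,
      class = c("ssc_curve", "tbl_df", "tbl", "data.frame")
    )
  }
  if (net_block < config$min_rotation) return(empty_curve())
  xm <- cummax(block - block[1])
  xmax <- xm[n]
  step <- config$grid_step
  n_cells <- max(1L, ceiling(xmax / step - 1e-9))
  edges <- c(seq(0, by = step, length.out = n_cells), xmax)
  widths <- diff(edges)
  acc <- matrix(0, nrow = n_cells, ncol = 3)
  tfrm <- numeric(n_cells)
  for (t in 2:n) {
    a <- xm[t - 1]; b <- xm[t]
    da <- sm[t, ] - sm[t - 1, ]
    if (b - a < 1e-12) {
      k <- min(n_cells, max(1L, findInterval(a, edges, rightmost.closed = TRUE)))
      acc[k, ] <- acc[k, ] + da
      tfrm[k] <- tfrm[k] + 1
    } else {
      k0 <- max(1L, findInterval(a, edges, rightmost.closed = TRUE))
      k1 <- min(n_cells, findInterval(b, edges, rightmost.closed = TRUE))
      for (k in k0:k1) {
        lo <- max(a, edges[k]); hi <- min(b, edges[k + 1])
        wfrac <- max(hi - lo, 0) / (b - a)
        acc[k, ] <- acc[k, ] + da * wfrac
        tfrm[k] <- tfrm[k] + wfrac
      }
    }
  }
  mid <- (edges[-length(edges)] + edges[-1]) / 2
  rate <- sweep(acc, 1, widths, "/")
  perfr <- sweep(acc, 1, pmax(tfrm, 1e-12), "/")
  curve <- tibble(
    x = rep(mid, times = 3),
    segment = rep(segs, each = n_cells),
    rate = c(rate[, 1], rate[, 2], rate[, 3]),
    contribution_per_frame = c(perfr[, 1], perfr[, 2], perfr[, 3])
  )
  structure(
    curve,
    net_rotation = setNames(colSums(acc), segs),
    total_rotation = xmax,
    grid_step = step, cell_width = widths,
    insufficient_motion = FALSE, fps = fps, config = config,
    class = c("ssc_curve", "tbl_df", "tbl", "data.frame")
  )
}

smooth_series <- function(y, config) {
  if (config$sg_window <= 1 || length(y) < config$sg_window) return(y)
  as.numeric(signal::sgolayfilt(y, p = config$sg_order,
                                n = config$sg_window))
}

#' @export
print.ssc_curve <- function(x, ...) {
  if (attr(x, "insufficient_motion")) {
    cat(sprintf(
      "<ssc_curve> insufficient motion (net block rotation %.2f deg)\n",
      attr(x, "total_rotation")))
  } else {
    nr <- attr(x, "net_rotation")
    cat(sprintf(
      "<ssc_curve> block %.2f deg over grid of %.2g deg; net per segment: %s\n",
      attr(x, "total_rotation"), attr(x, "grid_step"),
      paste(sprintf("%s %.2f", names(nr), nr), collapse = ", ")))
  }
  NextMethod()
}

#' Range-of-motion summary
#'
#' Computes the segmental ranges of motion (sROM) and the total C4-C7 range
#' (tROM) from angle series. The `"extremal"` method takes the max-minus-min
#' excursion along the whole path, recognising that maximal segmental
#' rotation often does not occur at the movement endpoints; the
#' `"endpoint"` method takes `|last - first|` for comparability with static
#' flexion-extension radiograph studies. Extremal values are never smaller
#' than endpoint values.
#'
#' @param angles Segment angle tibble (or `gt_recording`).
#' @param method `"extremal"` (default) or `"endpoint"`.
#' @param timepoint Optional label (e.g. `"T1"`) carried into the output.
#' @return Tibble `(measure, rom_deg, method, timepoint)` with one row per
#'   segment plus a `tROM (C4-C7)` row.
#' @export
#' @examples
#' rec <- generate_profile(young_consistent_spec())
#' rom_summary(rec)
rom_summary <- function(angles, method = c("extremal", "endpoint"),
                        timepoint = NA_character_) {
  method <- match.arg(method)
  wide <- angles_wide(angles)
  one <- function(y) {
    if (method == "extremal") max(y) - min(y) else abs(y[length(y)] - y[1])
  }
  segs <- cervseq_segments()
  block <- wide$`C4-C5` + wide$`C5-C6` + wide$`C6-C7`
  tibble(
    measure = c(segs, "tROM (C4-C7)"),
    rom_deg = unname(c(vapply(segs, function(s) one(wide[[s]]), numeric(1)),
                       one(block))),
    method = method,
    timepoint = timepoint
  )
}
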