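# Synthetic ground-truth kinematics for the C4-C7 block.
#
# A recording is parameterised in the cumulative-rotation coordinate of the
# block: each segment's contribution rate along cumulative C4-C7 extension is
# a broad baseline plus a Gaussian bump centred where that segment peaks.
# The three rates are balanced (Sinkhorn iteration) so that they form an
# exact partition of unity at every frame step while each segment's
# integrated contribution equals its prescribed total. Consequences, by
# construction: the block advances uniformly over frames, block angle equals
# the sum of the segmental angles exactly, and each segment's recorded range
# equals its prescribed total.

#' Specify a synthetic segmental motion profile
#'
#' Defines the ground truth for one synthetic extension recording of the
#' C4--C7 block: how much each motion segment rotates in total, where along
#' cumulative block rotation its contribution peaks, and how wide the peak
#' is. An optional late C4-C5 bump reproduces the small trailing C4-C5
#' contribution commonly seen at the end of extension.
#'
#' @param segment_totals Numeric length 3, degrees of extension contributed
#'   by C4-C5, C5-C6 and C6-C7; their sum is the total range of motion
#'   (tROM) of the block.
#' @param peak_centers Numeric length 3, cumulative-rotation coordinate
#'   (degrees, in `[0, trom]`) of each segment's main contribution peak.
#' @param peak_widths Numeric length 3, Gaussian widths (degrees) of the
#'   peaks. Must be positive.
#' @param trailing_c45_fraction Height of a late C4-C5 bump relative to the
#'   main C4-C5 bump, in `[0, 1)`. `0` disables it.
#' @param trailing_c45_center Cumulative-rotation position of the trailing
#'   bump; defaults to 93% of `trom`.
#' @param noise_sd Standard deviation (degrees) of i.i.d. Gaussian noise
#'   added to every per-frame segmental increment.
#' @param n_frames Number of frames (>= 10); default 52 at 10 frames/s,
#'   i.e. the extension half of a ~10 s flexion-extension movement.
#' @param fps Frame rate, frames per second.
#' @param trom Total block rotation in degrees; defaults to
#'   `sum(segment_totals)` and must match it within 1e-9.
#' @param baseline Relative weight of the broad baseline contribution each
#'   segment makes outside its peak (unitless, >= 0).
#' @param seed Integer seed controlling the noise.
#' @param label Free-text label stored with recordings made from this spec.
#'
#' @return An object of class `motion_profile_spec`.
#' @seealso [generate_profile()], [young_consistent_spec()],
#'   [elderly_inconsistent_spec()]
#' @export
#' @examples
#' spec <- motion_profile_spec(c(10, 8, 7), c(14, 17.5, 21), rep(1.6, 3))
#' rec <- generate_profile(spec)
motion_profile_spec <- function(segment_totals,
                                peak_centers,
                                peak_widths,
                                trailing_c45_fraction = 0,
                                trailing_c45_center = NULL,
                                noise_sd = 0,
                                n_frames = 52L,
                                fps = 10,
                                trom = sum(segment_totals),
                                baseline = 0.15,
                                seed = 1L,
                                label = "custom") {
  check_number(segment_totals, "segment_totals", min = 0, len = 3L)
  check_number(peak_centers, "peak_centers", len = 3L)
  check_number(peak_widths, "peak_widths", len = 3L)
  if (any(peak_widths <= 0)) abort("`peak_widths` must be positive.")
  check_number(trailing_c45_fraction, "trailing_c45_fraction", min = 0)
  if (trailing_c45_fraction >= 1) {
    abort("`trailing_c45_fraction` must be in [0, 1).")
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(n_frames, "n_frames", min = 10)
  check_number(fps, "fps", min = 1e-6)
  check_number(trom, "trom", min = 0)
  check_number(baseline, "baseline", min = 0)
  if (abs(sum(segment_totals) - trom) > 1e-9) {
    abort("`segment_totals` must sum to `trom` within 1e-9.")
  }
  if (is.null(trailing_c45_center)) trailing_c45_center <- 0.93 * trom
  structure(
    list(
      segment_totals = as.numeric(segment_totals),
      peak_centers = as.numeric(peak_centers),
      peak_widths = as.numeric(peak_widths),
      trailing_c45_fraction = trailing_c45_fraction,
      trailing_c45_center = trailing_c45_center,
      noise_sd = noise_sd,
      n_frames = as.integer(n_frames),
      fps = fps,
      trom = trom,
      baseline = baseline,
      seed = as.integer(seed),
      label = label
    ),
    class = "motion_profile_spec"
  )
}

#' @export
print.motion_profile_spec <- function(x, ...) {
  cat("<motion_profile_spec>", x$label, "\n")
  cat(sprintf("  tROM %.1f deg over %d frames (%.0f fps), noise sd %.2f deg\n",
              x$trom, x$n_frames, x$fps, x$noise_sd))
  for (i in 1:3) {
    cat(sprintf("  %s: %.1f deg, peak at %.1f deg (width %.1f)\n",
                cervseq_segments()[i], x$segment_totals[i],
                x$peak_centers[i], x$peak_widths[i]))
  }
  invisible(x)
}

#' Preset profile with the normal cranial-to-caudal extension sequence
#'
#' Segment totals of (14, 11, 10) degrees (tROM 35 degrees) with contribution
#' peaks ordered C4-C5 < C5-C6 < C6-C7 in the second half of extension and a
#' small (30% of main) trailing C4-C5 bump. The scale sits roughly one
#' reported decade-of-aging slope (about 0.11 degrees per segment per year)
#' above the elderly cohort averages, i.e. a plausible young adult.
#'
#' @param seed Integer seed.
#' @param noise_sd Per-frame increment noise, degrees.
#' @param n_frames Number of frames.
#' @return A [motion_profile_spec()].
#' @export
young_consistent_spec <- function(seed = 1L, noise_sd = 0, n_frames = 52L) {
  trom <- 35
  motion_profile_spec(
    segment_totals = c(14, 11, 10),
    peak_centers = c(0.55, 0.70, 0.85) * trom,
    peak_widths = rep(1.8, 3),
    trailing_c45_fraction = 0.3,
    noise_sd = noise_sd,
    n_frames = n_frames,
    seed = seed,
    label = "young_consistent"
  )
}

#' Preset profile emulating inconsistent elderly motion
#'
#' Reduced segment totals (9.3, 7.1, 5.9 degrees, the elderly cohort T2
#' averages) with contribution peaks in a permuted, non-cranial-to-caudal
#' order and per-frame jitter, so the normal sequence is absent.
#'
#' @param seed Integer seed (also selects the peak-order permutation).
#' @param noise_sd Per-frame increment noise, degrees.
#' @param n_frames Number of frames.
#' @param peak_order Optional integer permutation of `1:3` giving the order
#'   (along cumulative rotation) in which the segments peak; any permutation
#'   other than `c(1, 2, 3)` breaks the normal sequence. Drawn at random
#'   from the non-identity permutations when `NULL`.
#' @return A [motion_profile_spec()].
#' @export
elderly_inconsistent_spec <- function(seed = 1L, noise_sd = 0.15,
                                      n_frames = 52L, peak_order = NULL) {
  if (is.null(peak_order)) {
    perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    peak_order <- perms[[1L + (derive_seed(seed, 17L) %% 5L)]]
  }
  if (!identical(sort(as.integer(peak_order)), 1:3)) {
    abort("`peak_order` must be a permutation of 1:3.")
  }
  trom <- 22.3
  slots <- c(0.55, 0.70, 0.85) * trom
  centers <- numeric(3)
  centers[as.integer(peak_order)] <- slots
  motion_profile_spec(
    segment_totals = c(9.3, 7.1, 5.9),
    peak_centers = centers,
    peak_widths = rep(1.8, 3),
    trailing_c45_fraction = 0,
    noise_sd = noise_sd,
    n_frames = n_frames,
    seed = seed,
    label = "elderly_inconsistent"
  )
}

# Balance bump weights into per-step contribution fractions: columns (frame
# steps) sum to 1 exactly, rows (segments) integrate to their totals.
balance_fractions <- function(weights, totals, dx, max_iter = 1000L,
                              tol = 1e-13) {
  m <- weights + 1e-10
  row_target <- totals / dx
  if (any(row_target <= 0)) {
    # a segment with zero total contributes nothing; handle separately
    zero <- row_target <= 0
    m[zero, ] <- 0
    if (all(zero)) return(m)
    sub <- balance_fractions(weights[!zero, , drop = FALSE],
                             totals[!zero], dx, max_iter, tol)
    m[!zero, ] <- sub
    return(m)
  }
  for (i in seq_len(max_iter)) {
    m <- sweep(m, 2, colSums(m), "/")
    rs <- rowSums(m)
    m <- m * (row_target / rs)
    if (max(abs(colSums(m) - 1)) < tol) break
  }
  sweep(m, 2, colSums(m), "/")
}

#' Generate a ground-truth recording from a motion profile
#'
#' Realises the profile as per-frame segmental angles on a uniform
#' cumulative-rotation grid. The noiseless contribution curve of each
#' segment attains its maximum at the requested peak centre (within one
#' frame-grid step for peaks separated by at least about three widths), each
#' segment's angles rise monotonically to its prescribed total, and the
#' block angle equals the sum of the three segmental angles at every frame,
#' exactly, with or without noise.
#'
#' @param spec A [motion_profile_spec()].
#' @return An object of class `gt_recording`: a list with
#'   * `angles` -- tibble `(frame, segment, angle_deg)`, frame 0-based,
#'     angles zeroed at frame 0;
#'   * `block` -- tibble `(frame, block_deg)`, cumulative C4-C7 rotation;
#'   * `fps`, `label`, `spec`.
#' @export
#' @examples
#' rec <- generate_profile(young_consistent_spec())
#' head(rec$angles)
generate_profile <- function(spec) {
  stopifnot(inherits(spec, "motion_profile_spec"))
  n_steps <- spec$n_frames - 1L
  dx <- spec$trom / n_steps
  if (dx > 0) {
    gaps <- abs(diff(sort(spec$peak_centers)))
    if (any(gaps < dx)) {
      abort(paste0(
        "peak_centers overlap: separated by less than the frame grid ",
        sprintf("resolution (%.3f deg); move them apart.", dx)
      ), class = "cervseq_overlapping_peaks")
    }
  }
  if (spec$trom <= 0) {
    # degenerate zero-motion recording: all increments are zero
    inc <- matrix(0, nrow = 3, ncol = n_steps)
    return(assemble_recording(inc, spec))
  }
  xm <- (seq_len(n_steps) - 0.5) * dx
  w <- matrix(0, nrow = 3, ncol = n_steps)
  for (i in 1:3) {
    w[i, ] <- spec$baseline * spec$segment_totals[i] / max(spec$trom, 1e-12) +
      exp(-(xm - spec$peak_centers[i])^2 / (2 * spec$peak_widths[i]^2))
  }
  if (spec$trailing_c45_fraction > 0) {
    tw <- 0.8 * spec$peak_widths[1]
    w[1, ] <- w[1, ] + spec$trailing_c45_fraction *
      exp(-(xm - spec$trailing_c45_center)^2 / (2 * tw^2))
  }
  frac <- balance_fractions(w, spec$segment_totals, dx)
  inc <- frac * dx
  assemble_recording(inc, spec)
}

assemble_recording <- function(inc, spec) {
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    inc <- inc + matrix(rnorm(length(inc), 0, spec$noise_sd), nrow = 3)
  }
  ang <- cbind(0, t(apply(inc, 1, cumsum)))  # 3 x n_frames, zero at frame 0
  frames <- seq_len(spec$n_frames) - 1L
  angles <- tibble(
    frame = rep(frames, times = 3),
    segment = rep(cervseq_segments(), each = spec$n_frames),
    angle_deg = c(ang[1, ], ang[2, ], ang[3, ])
  )
  # elementwise so block equals the segment sum bit-exactly
  block <- tibble(frame = frames,
                  block_deg = ang[1, ] + ang[2, ] + ang[3, ])
  structure(
    list(angles = angles, block = block, fps = spec$fps,
         label = spec$label, spec = spec),
    class = "gt_recording"
  )
}

#' @export
print.gt_recording <- function(x, ...) {
  cat("<gt_recording>", x$label, "\n")
  cat(sprintf("  %d frames at %.0f fps, block rotation %.2f deg\n",
              max(x$angles$frame) + 1L, x$fps, max(x$block$block_deg)))
  invisible(x)
}

#' Generate a synthetic cohort of recordings
#'
#' Produces `n` ground-truth recordings, a fraction `mix` of which follow
#' the normal young-consistent extension sequence and the remainder the
#' inconsistent elderly pattern. Per-individual parameters (totals, peak
#' positions) are jittered reproducibly from `seed`; peak-order labels are
#' recorded so downstream classification can be scored against truth.
#'
#' @param n Number of individuals (> 0).
#' @param mix Fraction in `[0, 1]` of young-consistent recordings; the count
#'   is `round(mix * n)`.
#' @param seed Integer seed.
#' @param noise_sd Per-frame increment noise passed to every recording.
#' @param n_frames Frames per recording.
#' @return A tibble with one row per individual: `id`, `label`,
#'   and a list-column `recording` of `gt_recording` objects.
#' @export
#' @examples
#' cohort <- generate_cohort(4, mix = 0.5, seed = 7)
#' cohort$label
generate_cohort <- function(n, mix, seed = 1L, noise_sd = 0, n_frames = 52L) {
  check_number(n, "n", min = 1)
  check_number(mix, "mix", min = 0, max = 1)
  n <- as.integer(n)
  n_young <- as.integer(round(mix * n))
  set.seed(derive_seed(seed, 1L))
  labels <- sample(c(rep("young_consistent", n_young),
                     rep("elderly_inconsistent", n - n_young)))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    s_i <- derive_seed(seed, i + 100L)
    set.seed(s_i)
    if (labels[i] == "young_consistent") {
      base <- young_consistent_spec(seed = s_i, noise_sd = noise_sd,
                                    n_frames = n_frames)
      totals <- base$segment_totals * runif(3, 0.9, 1.1)
      trom <- sum(totals)
      spec <- motion_profile_spec(
        segment_totals = totals,
        peak_centers = c(0.55, 0.70, 0.85) * trom + runif(3, -0.4, 0.4),
        peak_widths = base$peak_widths,
        trailing_c45_fraction = base$trailing_c45_fraction,
        noise_sd = noise_sd, n_frames = n_frames, seed = s_i,
        label = "young_consistent"
      )
    } else {
      spec <- elderly_inconsistent_spec(seed = s_i, noise_sd = noise_sd,
                                        n_frames = n_frames)
    }
    recs[[i]] <- generate_profile(spec)
  }
  tibble(
    id = sprintf("S%02d", seq_len(n)),
    label = labels,
    recording = recs
  )
}
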