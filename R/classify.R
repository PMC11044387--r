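# Classification of the normal extension sequence. The pattern sought is an
# ordering claim about the terminal phase of extension: the C4-C5
# contribution peaks first, then C5-C6, then C6-C7. Peaks smaller than the
# significance threshold (default 0.3 degrees per frame) are ignored, and a
# late C4-C5 peak much smaller than the primary one is considered normal.

#' Classifier configuration
#'
#' @param significance_threshold Peak prominence (degrees per frame of
#'   segmental rotation) below which a peak is deemed insignificant.
#'   Default 0.3.
#' @param terminal_phase_fraction Fraction of cumulative block rotation, at
#'   the end of the movement, within which the ordered peaks must occur.
#'   Default 0.5 (the second half of extension).
#' @param trailing_c45_max_ratio A late C4-C5 peak whose prominence reaches
#'   this fraction of the selected C4-C5 peak's prominence disqualifies the
#'   sequence; smaller trailing peaks are considered normal. Default 0.5.
#' @param tie_tolerance Two selected peaks closer than this (degrees of
#'   cumulative rotation) are treated as a tie and the ordering is deemed
#'   undecidable. Default 0.5.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(significance_threshold = 0.3,
                              terminal_phase_fraction = 0.5,
                              trailing_c45_max_ratio = 0.5,
                              tie_tolerance = 0.5) {
  check_number(significance_threshold, "significance_threshold", min = 1e-12)
  check_number(terminal_phase_fraction, "terminal_phase_fraction",
               min = 1e-12, max = 1)
  check_number(trailing_c45_max_ratio, "trailing_c45_max_ratio",
               min = 1e-12)
  if (trailing_c45_max_ratio >= 1) {
    abort("`trailing_c45_max_ratio` must be in (0, 1).")
  }
  check_number(tie_tolerance, "tie_tolerance", min = 0)
  structure(
    list(significance_threshold = significance_threshold,
         terminal_phase_fraction = terminal_phase_fraction,
         trailing_c45_max_ratio = trailing_c45_max_ratio,
         tie_tolerance = tie_tolerance),
    class = "classifier_config"
  )
}

# local maxima of y with topographic prominence; plateaus collapse to their
# midpoint. Returns tibble(index, x, height, prominence).
find_peaks_prominence <- function(x, y) {
  n <- length(y)
  if (n < 3) {
    return(tibble(index = integer(), x = numeric(), height = numeric(),
                  prominence = numeric()))
  }
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  peak_idx <- integer(0)
  for (j in seq_len(k)) {
    left_lower <- j == 1 || r$values[j - 1] < r$values[j]
    right_lower <- j == k || r$values[j + 1] < r$values[j]
    if (j > 1 && j < k && left_lower && right_lower) {
      peak_idx <- c(peak_idx, as.integer(floor((starts[j] + ends[j]) / 2)))
    }
  }
  if (length(peak_idx) == 0) {
    return(tibble(index = integer(), x = numeric(), height = numeric(),
                  prominence = numeric()))
  }
  prom <- vapply(peak_idx, function(p) {
    h <- y[p]
    left_min <- h
    i <- p
    while (i > 1) {
      i <- i - 1
      if (y[i] > h) break
      left_min <- min(left_min, y[i])
    }
    right_min <- h
    i <- p
    while (i < n) {
      i <- i + 1
      if (y[i] > h) break
      right_min <- min(right_min, y[i])
    }
    h - max(left_min, right_min)
  }, numeric(1))
  tibble(index = peak_idx, x = x[peak_idx], height = y[peak_idx],
         prominence = prom)
}

#' Detect contribution peaks on an SSC curve
#'
#' Finds the local maxima of each segment's contribution-per-frame curve and
#' scores each by its topographic prominence (height above the highest
#' saddle connecting it to taller terrain), which avoids counting shoulders
#' on a monotone rise. A peak is significant when its prominence reaches the
#' configured threshold; sub-threshold maxima are returned but flagged
#' insignificant.
#'
#' @param curve An `ssc_curve` from [build_ssc()].
#' @param config A [classifier_config()].
#' @return Tibble `(segment, x, height, prominence, significant)`.
#' @export
detect_peaks <- function(curve, config = classifier_config()) {
  stopifnot(inherits(curve, "ssc_curve"), inherits(config, "classifier_config"))
  if (attr(curve, "insufficient_motion") || nrow(curve) == 0) {
    return(tibble(segment = character(), x = numeric(), height = numeric(),
                  prominence = numeric(), significant = logical()))
  }
  out <- lapply(cervseq_segments(), function(s) {
    d <- curve[curve$segment == s, ]
    d <- d[order(d$x), ]
    pk <- find_peaks_prominence(d$x, d$contribution_per_frame)
    pk <- pk[pk$prominence > 1e-9, , drop = FALSE]  # drop fp micro-maxima
    if (nrow(pk) == 0) return(NULL)
    tibble(segment = s, x = pk$x, height = pk$height,
           prominence = pk$prominence,
           significant = pk$prominence >= config$significance_threshold)
  })
  bind_rows(out)
}

#' Classify the presence of the normal extension sequence
#'
#' Restricts attention to the terminal phase of the movement (the last
#' `terminal_phase_fraction` of cumulative block rotation), selects each
#' segment's most prominent peak there, and declares the normal sequence
#' present (`"+"`) when all three selected peaks are significant, their
#' positions are strictly ordered C4-C5 < C5-C6 < C6-C7, no two are within
#' `tie_tolerance` of each other, and any later C4-C5 peak is markedly
#' smaller (its prominence below `trailing_c45_max_ratio` times the selected
#' peak's prominence; prominence rather than raw height, because late in
#' extension every segment's baseline contribution is elevated). Any
#' other configuration yields `"-"` with machine-readable reason codes.
#'
#' @param x An `ssc_curve`, or a peak tibble from [detect_peaks()] (in which
#'   case `total_rotation` must be supplied).
#' @param config A [classifier_config()].
#' @param total_rotation Total cumulative block rotation (degrees); taken
#'   from the curve when `x` is an `ssc_curve`.
#' @param insufficient_motion Logical; propagated from the kinematics stage
#'   when `x` is a peak tibble.
#' @return Object of class `sequence_classification`: list with `presence`
#'   (`"+"` or `"-"`), `selected` (tibble of the selected per-segment
#'   peaks), `peaks` (all detected peaks), `reasons` (character), `config`.
#' @export
#' @examples
#' rec <- generate_profile(young_consistent_spec())
#' classify_sequence(build_ssc(rec))
classify_sequence <- function(x, config = classifier_config(),
                              total_rotation = NULL,
                              insufficient_motion = FALSE) {
  stopifnot(inherits(config, "classifier_config"))
  if (inherits(x, "ssc_curve")) {
    insufficient_motion <- attr(x, "insufficient_motion")
    total_rotation <- attr(x, "total_rotation")
    peaks <- detect_peaks(x, config)
  } else {
    peaks <- x
    if (is.null(total_rotation) && !insufficient_motion) {
      abort("`total_rotation` is required when classifying a peak tibble.")
    }
  }
  reasons <- character(0)
  empty_sel <- tibble(segment = character(), x = numeric(),
                      height = numeric(), prominence = numeric(),
                      significant = logical())
  selected <- empty_sel
  if (insufficient_motion) {
    reasons <- "insufficient-motion"
  } else {
    phase_start <- (1 - config$terminal_phase_fraction) * total_rotation
    inphase <- peaks[peaks$x >= phase_start, , drop = FALSE]
    sel <- lapply(cervseq_segments(), function(s) {
      p <- inphase[inphase$segment == s, , drop = FALSE]
      if (nrow(p) == 0) return(NULL)
      p[which.max(p$prominence), , drop = FALSE]
    })
    names(sel) <- cervseq_segments()
    for (s in cervseq_segments()) {
      if (is.null(sel[[s]]) || !sel[[s]]$significant) {
        reasons <- c(reasons, paste0("no-significant-peak:", s))
      }
    }
    selected <- bind_rows(sel)
    if (length(reasons) == 0) {
      xs <- setNames(selected$x, selected$segment)
      if (!(xs["C4-C5"] < xs["C5-C6"] && xs["C5-C6"] < xs["C6-C7"])) {
        reasons <- c(reasons, "order-violation")
      }
      if (min(dist(xs)) < config$tie_tolerance) {
        reasons <- c(reasons, "tie")
      }
      later_c45 <- peaks[peaks$segment == "C4-C5" &
                           peaks$x > xs["C4-C5"], , drop = FALSE]
      if (nrow(later_c45) > 0 &&
          max(later_c45$prominence) >=
            config$trailing_c45_max_ratio * sel[["C4-C5"]]$prominence) {
        reasons <- c(reasons, "trailing-c45-too-large")
      }
    }
  }
  structure(
    list(presence = if (length(reasons) == 0) "+" else "-",
         selected = selected, peaks = peaks,
         reasons = reasons, config = config,
         total_rotation = total_rotation %||% NA_real_),
    class = "sequence_classification"
  )
}

#' @export
print.sequence_classification <- function(x, ...) {
  cat("<sequence_classification>", x$presence, "\n")
  if (length(x$reasons) > 0) {
    cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  }
  if (nrow(x$selected) > 0) {
    cat("  selected peaks:\n")
    for (i in seq_len(nrow(x$selected))) {
      cat(sprintf("    %s at %.2f deg (height %.2f deg/frame)\n",
                  x$selected$segment[i], x$selected$x[i],
                  x$selected$height[i]))
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname classify_sequence
#' @param ... Unused.
#' @export
tidy.sequence_classification <- function(x, ...) {
  x$peaks
}

#' @rdname classify_sequence
#' @export
glance.sequence_classification <- function(x, ...) {
  tibble(
    presence = x$presence,
    n_peaks = nrow(x$peaks),
    n_significant = sum(x$peaks$significant %||% logical(0)),
    reasons = paste(x$reasons, collapse = ";"),
    total_rotation = x$total_rotation
  )
}

#' Prevalence of the normal sequence in a cohort
#'
#' @param classifications A character vector of `"+"`/`"-"` outcomes, or a
#'   list of `sequence_classification` objects.
#' @return Percentage (0-100) of `"+"` classifications.
#' @export
#' @examples
#' cohort_prevalence(c("+", "-", "-", "-"))
cohort_prevalence <- function(classifications) {
  if (is.list(classifications) && !is.data.frame(classifications)) {
    classifications <- vapply(classifications, function(c) {
      if (inherits(c, "sequence_classification")) c$presence else as.character(c)
    }, character(1))
  }
  cls <- as.character(classifications)
  cls <- trimws(cls)
  if (length(cls) == 0) abort("no classifications supplied.")
  if (!all(cls %in% c("+", "-"))) {
    abort("classifications must be '+' or '-'.")
  }
  100 * mean(cls == "+")
}
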