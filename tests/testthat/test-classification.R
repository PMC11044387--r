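ordered_curve <- function(h = c(1.5, 1.2, 1.0), centers = c(12.62, 16.33, 20.18),
                          trailing = 0, xmax = 24) {
  x <- seq(0.05, xmax, by = 0.1)
  y45 <- bump(x, centers[1], h[1]) + trailing * bump(x, 0.9 * xmax, h[1])
  make_test_curve(x, list(
    "C4-C5" = y45,
    "C5-C6" = bump(x, centers[2], h[2]),
    "C6-C7" = bump(x, centers[3], h[3])
  ), total_rotation = xmax)
}

test_that("peak detection: flat curves, boundary significance, bump recovery", {
  x <- seq(0.05, 20, by = 0.1)
  flat <- make_test_curve(x, list("C4-C5" = 0 * x, "C5-C6" = 0 * x,
                                  "C6-C7" = 0 * x))
  expect_identical(nrow(detect_peaks(flat)), 0L)
  # a 0.29-degree bump is detected but insignificant (0.3 threshold)
  small <- make_test_curve(x, list("C4-C5" = bump(x, 10, 0.29),
                                   "C5-C6" = 0 * x, "C6-C7" = 0 * x))
  pk <- detect_peaks(small)
  expect_identical(nrow(pk), 1L)
  expect_false(pk$significant)
  expect_equal(pk$height, 0.29, tolerance = 5e-3)
  # just past the threshold it becomes significant
  ok <- make_test_curve(x, list("C4-C5" = bump(x, 10, 0.31),
                                "C5-C6" = 0 * x, "C6-C7" = 0 * x))
  expect_true(detect_peaks(ok)$significant)
  # three bumps are found at their centers, all significant
  pk3 <- detect_peaks(ordered_curve())
  sig <- pk3[pk3$significant, ]
  expect_identical(nrow(sig), 3L)
  expect_equal(sig$x, c(12.62, 16.33, 20.18), tolerance = 0.1)
  expect_equal(sort(sig$height, decreasing = TRUE), c(1.5, 1.2, 1.0),
               tolerance = 1e-3)
})

test_that("prominence ignores shoulders on a monotone rise", {
  x <- seq(0.05, 20, by = 0.1)
  # a ramp with a small plateau shoulder: no significant interior peak
  ramp <- pmin(x / 10, 1) + 0.02 * bump(x, 5, 1)
  shoulder <- make_test_curve(x, list("C4-C5" = ramp, "C5-C6" = 0 * x,
                                      "C6-C7" = 0 * x))
  pk <- detect_peaks(shoulder)
  expect_true(all(pk$prominence < 0.3))
})

test_that("classification encodes the ordering claim with reason codes", {
  expect_identical(classify_sequence(ordered_curve())$presence, "+")
  swapped <- ordered_curve(centers = c(12.62, 20.18, 16.33))
  cls <- classify_sequence(swapped)
  expect_identical(cls$presence, "-")
  expect_true("order-violation" %in% cls$reasons)
  # trailing C4-C5 peak at 0.4 x main prominence is normal
  cls_ok <- classify_sequence(ordered_curve(trailing = 0.4))
  expect_identical(cls_ok$presence, "+")
  # at 0.6 x main it disqualifies
  cls_big <- classify_sequence(ordered_curve(trailing = 0.6))
  expect_identical(cls_big$presence, "-")
  expect_true("trailing-c45-too-large" %in% cls_big$reasons)
  # near-coincident peaks are a tie, not a guessed order
  tied <- ordered_curve(centers = c(16.33, 16.63, 20.18))
  cls_tie <- classify_sequence(tied)
  expect_identical(cls_tie$presence, "-")
  expect_true("tie" %in% cls_tie$reasons)
  # a missing significant peak is named
  weak <- ordered_curve(h = c(1.5, 0.2, 1.0))
  cls_weak <- classify_sequence(weak)
  expect_identical(cls_weak$presence, "-")
  expect_true("no-significant-peak:C5-C6" %in% cls_weak$reasons)
  # insufficient motion propagates
  x <- seq(0.05, 2, by = 0.1)
  low <- make_test_curve(x, list("C4-C5" = 0 * x, "C5-C6" = 0 * x,
                                 "C6-C7" = 0 * x), insufficient = TRUE)
  cls_low <- classify_sequence(low)
  expect_identical(cls_low$presence, "-")
  expect_identical(cls_low$reasons, "insufficient-motion")
})

test_that("peaks outside the terminal phase do not qualify", {
  # ordered peaks, but C4-C5 peaks in the first half of the movement
  early <- ordered_curve(centers = c(5.12, 16.33, 20.18))
  cls <- classify_sequence(early)
  expect_identical(cls$presence, "-")
  expect_true("no-significant-peak:C4-C5" %in% cls$reasons)
  # widening the terminal phase to the whole movement admits it
  cls_all <- classify_sequence(
    early, classifier_config(terminal_phase_fraction = 1))
  expect_identical(cls_all$presence, "+")
})

test_that("generator-built recordings classify as constructed", {
  expect_identical(
    classify_sequence(build_ssc(generate_profile(young_consistent_spec())))$presence,
    "+")
  for (seed in 1:5) {
    cls <- classify_sequence(build_ssc(generate_profile(
      elderly_inconsistent_spec(seed = seed, noise_sd = 0))))
    expect_identical(cls$presence, "-")
  }
  # explicitly swapped peak order in the young profile
  spec <- young_consistent_spec()
  swapped <- motion_profile_spec(
    spec$segment_totals, spec$peak_centers[c(1, 3, 2)], spec$peak_widths,
    trailing_c45_fraction = spec$trailing_c45_fraction)
  cls_sw <- classify_sequence(build_ssc(generate_profile(swapped)))
  expect_identical(cls_sw$presence, "-")
  expect_true("order-violation" %in% cls_sw$reasons)
})

test_that("raising the significance threshold never turns '-' into '+'", {
  curves <- list(
    ordered_curve(),
    ordered_curve(h = c(0.6, 0.5, 0.4)),
    ordered_curve(centers = c(12.62, 20.18, 16.33)),
    ordered_curve(trailing = 0.55),
    build_ssc(generate_profile(young_consistent_spec(seed = 2,
                                                     noise_sd = 0.1)))
  )
  for (curve in curves) {
    presences <- vapply(seq(0.05, 1.2, by = 0.05), function(th) {
      classify_sequence(curve,
                        classifier_config(significance_threshold = th))$presence
    }, character(1))
    plus <- presences == "+"
    # once lost, the pattern never reappears at a stricter threshold
    expect_true(all(diff(as.integer(plus)) <= 0))
  }
})

test_that("classification is deterministic for a fixed curve and config", {
  curve <- build_ssc(generate_profile(young_consistent_spec(seed = 3,
                                                            noise_sd = 0.1)))
  g1 <- generics::glance(classify_sequence(curve))
  g2 <- generics::glance(classify_sequence(curve))
  expect_identical(g1, g2)
})

test_that("classification '+' rate is 100% noiseless and non-increasing in noise", {
  rate_at <- function(noise_sd, n = 200) {
    pres <- vapply(seq_len(n), function(i) {
      rec <- generate_profile(young_consistent_spec(seed = 5000L + i,
                                                    noise_sd = noise_sd))
      classify_sequence(build_ssc(rec))$presence
    }, character(1))
    cohort_prevalence(pres)
  }
  rates <- vapply(c(0, 0.05, 0.1, 0.2), rate_at, numeric(1))
  expect_equal(rates[1], 100)
  # allow 3 points of sampling wiggle between adjacent noise levels
  expect_true(all(diff(rates) <= 3))
})

test_that("prevalence arithmetic and input validation", {
  t1 <- load_cohort_table("baseline")
  expect_equal(cohort_prevalence(t1$seq_t1), 10)
  expect_equal(cohort_prevalence(t1$seq_t2), 0)
  expect_equal(cohort_prevalence(rep("+", 4)), 100)
  expect_error(cohort_prevalence(character(0)), "no classifications")
  expect_error(cohort_prevalence(c("+", "?")), "must be")
  cls <- classify_sequence(ordered_curve())
  expect_equal(cohort_prevalence(list(cls, "-")), 50)
})

test_that("tidy and glance expose peaks and outcome", {
  cls <- classify_sequence(ordered_curve())
  td <- generics::tidy(cls)
  expect_true(all(c("segment", "x", "height", "prominence", "significant")
                  %in% names(td)))
  gl <- generics::glance(cls)
  expect_identical(gl$presence, "+")
  expect_identical(nrow(gl), 1L)
})
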