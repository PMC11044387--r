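test_that("segmental angles are adjacent-vertebra differences, zeroed at frame 0", {
  poses <- make_poses(theta_c4 = c(0, 2), theta_c5 = c(0, 0.5))
  ang <- segmental_angles(poses)
  a <- function(seg, f) ang$angle_deg[ang$segment == seg & ang$frame == f]
  expect_equal(a("C4-C5", 1), 1.5)
  expect_equal(a("C5-C6", 1), 0.5)
  expect_equal(a("C6-C7", 1), 0)
  # equal rotations of both vertebrae cancel
  same <- make_poses(theta_c4 = c(0, 3, 7), theta_c5 = c(0, 3, 7))
  ang2 <- segmental_angles(same)
  expect_true(all(ang2$angle_deg[ang2$segment == "C4-C5"] == 0))
  # poses that do not start at zero are re-referenced to the first frame
  shifted <- make_poses(theta_c4 = c(4, 6), theta_c5 = c(1, 1.5))
  ang3 <- segmental_angles(shifted)
  expect_equal(ang3$angle_deg[ang3$segment == "C4-C5" & ang3$frame == 1], 1.5)
})

test_that("missing vertebrae or frames are reported by name", {
  poses <- make_poses(theta_c4 = c(0, 1))
  expect_error(segmental_angles(poses[poses$vertebra != "C6", ]), "C6")
  holey <- poses[!(poses$vertebra == "C5" & poses$frame == 1), ]
  expect_error(segmental_angles(holey), "C5")
})

test_that("cumulative block rotation is the segment sum and telescopes", {
  ang <- dplyr::bind_rows(
    tibble::tibble(frame = 0:1, segment = "C4-C5", angle_deg = c(0, 1)),
    tibble::tibble(frame = 0:1, segment = "C5-C6", angle_deg = c(0, 2)),
    tibble::tibble(frame = 0:1, segment = "C6-C7", angle_deg = c(0, 3))
  )
  blk <- cumulative_block(ang)
  expect_equal(blk$block_deg, c(0, 6))
  zero <- dplyr::mutate(ang, angle_deg = 0)
  expect_equal(cumulative_block(zero)$block_deg, c(0, 0))
  # telescoping: block equals theta(C4) - theta(C7) from arbitrary poses
  set.seed(21)
  poses <- make_poses(theta_c4 = cumsum(rnorm(12, 0.4, 0.3)),
                      theta_c5 = cumsum(rnorm(12, 0.3, 0.3)),
                      theta_c6 = cumsum(rnorm(12, 0.2, 0.3)),
                      theta_c7 = cumsum(rnorm(12, 0.0, 0.2)))
  ang2 <- segmental_angles(poses)
  blk2 <- cumulative_block(ang2)
  wide <- tidyr::pivot_wider(poses[, c("frame", "vertebra", "theta_deg")],
                             names_from = vertebra, values_from = theta_deg)
  ref <- (wide$C4 - wide$C7) - (wide$C4[1] - wide$C7[1])
  expect_equal(blk2$block_deg, ref, tolerance = 1e-9)
  expect_error(cumulative_block(ang[ang$segment != "C6-C7", ]), "segments")
})

test_that("rom methods agree on monotone paths and differ on excursions", {
  mono <- dplyr::bind_rows(lapply(cervseq_segments(), function(s) {
    tibble::tibble(frame = 0:4, segment = s,
                   angle_deg = if (s == "C4-C5") c(0, 2.5, 5, 7.5, 10) else 0)
  }))
  expect_equal(rom_summary(mono, "extremal")$rom_deg[1], 10)
  expect_equal(rom_summary(mono, "endpoint")$rom_deg[1], 10)
  excur <- dplyr::bind_rows(lapply(cervseq_segments(), function(s) {
    tibble::tibble(frame = 0:2, segment = s,
                   angle_deg = if (s == "C5-C6") c(0, 12, 8) else 0)
  }))
  expect_equal(rom_summary(excur, "extremal")$rom_deg[2], 12)
  expect_equal(rom_summary(excur, "endpoint")$rom_deg[2], 8)
  # extremal is never smaller than endpoint, on random paths
  set.seed(7)
  for (i in 1:10) {
    totals <- runif(3, 2, 12)
    rec <- generate_profile(motion_profile_spec(
      totals, c(0.3, 0.55, 0.8) * sum(totals), rep(2, 3),
      noise_sd = 0.4, seed = i))
    ex <- rom_summary(rec, "extremal")$rom_deg
    ep <- rom_summary(rec, "endpoint")$rom_deg
    expect_true(all(ex >= ep - 1e-12))
  }
})

test_that("ssc resampling conserves each segment's rotation", {
  # unsmoothed, noiseless: conservation against the prescribed totals
  rec <- generate_profile(young_consistent_spec())
  curve <- build_ssc(rec, config = ssc_config(sg_window = 1))
  widths <- attr(curve, "cell_width")
  for (i in seq_along(cervseq_segments())) {
    s <- cervseq_segments()[i]
    integral <- sum(curve$rate[curve$segment == s] * widths)
    expect_equal(integral, rec$spec$segment_totals[i], tolerance = 1e-6)
  }
  # with smoothing and noise the machinery still conserves the smoothed
  # series it was given (and stays within 0.1 deg of the raw rotation)
  spec <- young_consistent_spec(seed = 8, noise_sd = 0.1)
  recn <- generate_profile(spec)
  curven <- build_ssc(recn)
  nets <- attr(curven, "net_rotation")
  for (s in cervseq_segments()) {
    integral <- sum(curven$rate[curven$segment == s] *
                      attr(curven, "cell_width"))
    expect_equal(integral, unname(nets[s]), tolerance = 1e-9)
  }
  wide <- tidyr::pivot_wider(recn$angles, names_from = segment,
                             values_from = angle_deg)
  raw_net <- vapply(cervseq_segments(),
                    function(s) wide[[s]][nrow(wide)] - wide[[s]][1],
                    numeric(1))
  expect_lt(max(abs(nets - raw_net)), 0.1)
})

test_that("constant-rate profiles give flat curves at total/trom", {
  spec <- motion_profile_spec(c(10, 8, 7), c(5, 12.5, 20), rep(1e6, 3))
  rec <- generate_profile(spec)
  curve <- build_ssc(rec, config = ssc_config(sg_window = 1))
  for (i in seq_along(cervseq_segments())) {
    r <- curve$rate[curve$segment == cervseq_segments()[i]]
    expect_lt(max(abs(r - spec$segment_totals[i] / spec$trom)), 1e-6)
  }
})

test_that("ssc maxima sit near the generator's peak centers", {
  spec <- young_consistent_spec()
  curve <- build_ssc(generate_profile(spec))
  pk <- detect_peaks(curve)
  sig <- pk[pk$significant, ]
  expect_identical(nrow(sig), 3L)
  for (i in seq_along(cervseq_segments())) {
    got <- sig$x[sig$segment == cervseq_segments()[i]]
    expect_lt(abs(got - spec$peak_centers[i]), 0.8)
  }
})

test_that("negative-motion excursions are folded without losing rotation", {
  rec <- generate_profile(young_consistent_spec())
  ang <- rec$angles
  # inject a zero-sum backward excursion into C5-C6 mid-movement
  sel <- ang$segment == "C5-C6"
  y <- ang$angle_deg[sel]
  dip <- c(rep(0, 20), -1.2, -1.8, -1.2, rep(0, length(y) - 23))
  ang$angle_deg[sel] <- y + dip
  curve <- build_ssc(ang, config = ssc_config(sg_window = 1))
  expect_true(all(diff(sort(unique(curve$x))) > 0))
  widths <- attr(curve, "cell_width")
  int_c56 <- sum(curve$rate[curve$segment == "C5-C6"] * widths)
  expect_equal(int_c56, y[length(y)] - y[1], tolerance = 1e-9)
  # negative contributions survive folding
  expect_true(any(curve$rate[curve$segment == "C5-C6"] < 0))
})

test_that("insufficient block rotation raises the flag instead of a curve", {
  spec <- motion_profile_spec(c(1, 0.9, 0.6), c(0.8, 1.7, 2.6), rep(0.4, 3))
  curve <- build_ssc(generate_profile(spec))
  expect_true(attr(curve, "insufficient_motion"))
  expect_identical(nrow(curve), 0L)
  # a low-motion recording just above the floor still yields a curve
  spec2 <- motion_profile_spec(c(1.4, 1.2, 1.0), c(0.9, 1.9, 2.9),
                               rep(0.4, 3))
  curve2 <- build_ssc(generate_profile(spec2))
  expect_false(attr(curve2, "insufficient_motion"))
  # the configurable floor moves the boundary
  curve3 <- build_ssc(generate_profile(spec2),
                      config = ssc_config(min_rotation = 5))
  expect_true(attr(curve3, "insufficient_motion"))
})

test_that("packaged rom tables are internally consistent per individual", {
  for (name in c("rom", "external")) {
    tab <- load_cohort_table(name)
    for (tp in c("t1", "t2")) {
      sums <- tab[[paste0("srom_c45_", tp)]] +
        tab[[paste0("srom_c56_", tp)]] + tab[[paste0("srom_c67_", tp)]]
      expect_lt(max(abs(sums - tab[[paste0("trom_", tp)]])), 0.3 + 1e-9)
    }
  }
})
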