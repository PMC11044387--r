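# Shared fixtures and independent oracles, built in code at test time.

# Hand-built ssc_curve: y is the contribution-per-frame series per segment
# on a common x grid; rate is derived so that integrals stay meaningful.
make_test_curve <- function(x, y_by_segment, block_speed = 0.5,
                            total_rotation = max(x),
                            insufficient = FALSE) {
  stopifnot(setequal(names(y_by_segment), cervseq_segments()))
  step <- if (length(x) > 1) diff(x)[1] else 0.1
  curve <- dplyr::bind_rows(lapply(cervseq_segments(), function(s) {
    tibble::tibble(x = x, segment = s,
                   rate = y_by_segment[[s]] / block_speed,
                   contribution_per_frame = y_by_segment[[s]])
  }))
  structure(
    curve,
    net_rotation = stats::setNames(
      vapply(y_by_segment, function(y) sum(y / block_speed) * step,
             numeric(1))[cervseq_segments()],
      cervseq_segments()),
    total_rotation = total_rotation,
    grid_step = step, cell_width = rep(step, length(x)),
    insufficient_motion = insufficient, fps = 10,
    config = ssc_config(),
    class = c("ssc_curve", "tbl_df", "tbl", "data.frame")
  )
}

# Gaussian bump helper for curve construction
bump <- function(x, center, height, width = 1) {
  height * exp(-(x - center)^2 / (2 * width^2))
}

# pose tibble for all four vertebrae from per-vertebra theta series
make_poses <- function(theta_c4, theta_c5 = 0 * theta_c4,
                       theta_c6 = 0 * theta_c4, theta_c7 = 0 * theta_c4) {
  n <- length(theta_c4)
  tibble::tibble(
    frame = rep(seq_len(n) - 1L, times = 4),
    vertebra = rep(c("C4", "C5", "C6", "C7"), each = n),
    theta_deg = c(theta_c4, theta_c5, theta_c6, theta_c7),
    tx_px = 0, ty_px = 0
  )
}

# independent ICC oracle: mean squares from stats::aov
icc_aov_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = c(m), row = factor(rep(seq_len(n), k)),
                   col = factor(rep(seq_len(k), each = n)))
  a <- stats::anova(stats::aov(y ~ row + col, data = df))
  msr <- a["row", "Mean Sq"]
  msc <- a["col", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}

# independent permutation enumeration (recursive) for the Spearman p-value
spearman_p_enum_oracle <- function(x, y) {
  perm_rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  rho <- stats::cor(x, y, method = "spearman")
  rhos <- vapply(perm_rec(y), function(yp) {
    stats::cor(x, yp, method = "spearman")
  }, numeric(1))
  mean(abs(rhos) >= abs(rho) - 1e-12)
}

# printed column means of the packaged tables, verified against the source
# tables; the T1 C6-C7 average is omitted (inconsistent with its column)
printed_rom_means <- c(
  trom_t1 = 25.8, srom_c45_t1 = 11.1, srom_c56_t1 = 7.9,
  trom_t2 = 22.3, srom_c45_t2 = 9.3, srom_c56_t2 = 7.1, srom_c67_t2 = 5.9
)
printed_external_means <- c(
  trom_t1 = 10.0, srom_c45_t1 = 4.6, srom_c56_t1 = 2.6, srom_c67_t1 = 2.8,
  trom_t2 = 11.8, srom_c45_t2 = 4.8, srom_c56_t2 = 4.3, srom_c67_t2 = 2.6
)
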