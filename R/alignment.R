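# Sagittal alignment from endplate landmarks, and the study eligibility
# screen (age window, Neck Disability Index, Kellgren degeneration grade).

#' Cobb angle between two endplate lines
#'
#' Signed angle between the lines through two landmark pairs, wrapped to
#' `(-90, 90]` degrees (lines are undirected, so angles are defined modulo
#' 180). With landmarks digitised on a lateral radiograph (x to the
#' anterior, y down) and each endplate given anterior point first, lordotic
#' curvature is positive and kyphotic curvature negative. The angle is
#' invariant under rigid transforms and uniform scaling of all landmarks,
#' and swapping the two lines negates it.
#'
#' For the C2-C7 lordosis use the inferior endplate of C2 and the inferior
#' endplate of C7; for a single segment use the superior vertebra's upper
#' endplate and the lower vertebra's lower endplate.
#'
#' @param line1,line2 Two-point lines: 2 x 2 numeric matrices (rows = points,
#'   columns = x, y) or data frames with columns `x`, `y`. The two points of
#'   a line must be distinct.
#' @return Signed angle in degrees, magnitude in `[0, 90]`.
#' @export
#' @examples
#' cobb_angle(rbind(c(0, 0), c(1, 0)), rbind(c(0, 0), c(1, 1)))
cobb_angle <- function(line1, line2) {
  l1 <- as_line(line1, "line1")
  l2 <- as_line(line2, "line2")
  a1 <- atan2(l1[2], l1[1])
  a2 <- atan2(l2[2], l2[1])
  d <- (a2 - a1) * 180 / pi
  d <- ((d + 90) %% 180) - 90
  if (d == -90) d <- 90
  unname(d)
}

as_line <- function(l, name) {
  if (is.data.frame(l)) l <- as.matrix(l[, c("x", "y")])
  if (!is.matrix(l) || !identical(dim(l), c(2L, 2L)) || any(!is.finite(l))) {
    abort(sprintf("`%s` must be a finite 2 x 2 matrix (two points).", name))
  }
  d <- l[2, ] - l[1, ]
  if (sqrt(sum(d^2)) < 1e-12) {
    abort(sprintf("`%s` is degenerate: its two points coincide.", name))
  }
  d
}

#' Cobb angles from a landmark table
#'
#' Computes the C2-C7 lordosis (inferior endplate of C2 vs inferior endplate
#' of C7) and the per-segment alignment for C4-C5, C5-C6 and C6-C7 (upper
#' endplate of the upper vertebra vs lower endplate of the lower vertebra)
#' from a tidy landmark table.
#'
#' @param landmarks Tibble with columns `vertebra` (`"C2"`, `"C4"` ...),
#'   `endplate` (`"superior"`/`"inferior"`), `role`
#'   (`"anterior"`/`"posterior"`), `x_px`, `y_px`.
#' @return Tibble `(measure, angle_deg)`.
#' @export
alignment_from_landmarks <- function(landmarks) {
  need <- c("vertebra", "endplate", "role", "x_px", "y_px")
  if (!all(need %in% names(landmarks))) {
    abort("`landmarks` must have columns vertebra, endplate, role, x_px, y_px.")
  }
  line_of <- function(vertebra, endplate) {
    d <- landmarks[landmarks$vertebra == vertebra &
                     landmarks$endplate == endplate, ]
    if (nrow(d) != 2) {
      abort(sprintf("need exactly 2 landmarks for %s %s endplate.",
                    vertebra, endplate))
    }
    d <- d[order(d$role), ]  # anterior first
    cbind(x = d$x_px, y = d$y_px)
  }
  seg_pairs <- list(`C4-C5` = c("C4", "C5"), `C5-C6` = c("C5", "C6"),
                    `C6-C7` = c("C6", "C7"))
  vals <- c(
    `C2-C7` = cobb_angle(line_of("C2", "inferior"), line_of("C7", "inferior")),
    vapply(seg_pairs, function(p) {
      cobb_angle(line_of(p[1], "superior"), line_of(p[2], "inferior"))
    }, numeric(1))
  )
  tibble(measure = names(vals), angle_deg = unname(vals))
}

#' Eligibility screen for the asymptomatic elderly cohort
#'
#' Applies the inclusion criteria: age between 55 and 70 years, Neck
#' Disability Index of at most 4 points, and no analysed segment with a
#' Kellgren degeneration grade of 4 (i.e. maximum grade 3).
#'
#' @param records Tibble with columns `age`, `ndi_points`, and Kellgren
#'   grades `ks_c45`, `ks_c56`, `ks_c67` (ordinal 0-4). An optional `id`
#'   column is carried through.
#' @return Tibble with `included` (logical) and `reasons` (comma-separated
#'   string, empty when included) per row.
#' @export
#' @examples
#' eligibility(tibble::tibble(age = 61, ndi_points = 2,
#'                            ks_c45 = 1, ks_c56 = 1, ks_c67 = 2))
eligibility <- function(records) {
  need <- c("age", "ndi_points", "ks_c45", "ks_c56", "ks_c67")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    abort(paste0("`records` is missing field(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(is.na(records[need]))) {
    abort("`records` contains missing values in required fields.")
  }
  ks <- pmax(records$ks_c45, records$ks_c56, records$ks_c67)
  if (any(records$ks_c45 < 0 | records$ks_c45 > 4 |
          records$ks_c56 < 0 | records$ks_c56 > 4 |
          records$ks_c67 < 0 | records$ks_c67 > 4)) {
    abort("Kellgren grades must be between 0 and 4.")
  }
  reasons <- mapply(function(age, ndi, ksmax) {
    r <- character(0)
    if (age < 55 || age > 70) r <- c(r, "age")
    if (ndi > 4) r <- c(r, "NDI")
    if (ksmax > 3) r <- c(r, "KS")
    paste(r, collapse = ",")
  }, records$age, records$ndi_points, ks)
  out <- tibble(included = reasons == "", reasons = unname(reasons))
  if ("id" %in% names(records)) out <- tibble(id = records$id, out)
  out
}
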