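# File formats: UTF-8 comma-separated CSV with mandatory header, '.' decimal,
# angles always in degrees (stated in the column names); JSON for structured
# results. Values are stored at full precision -- rounding happens only when
# a report is rendered.

#' Load a packaged cohort table
#'
#' The package ships plain-text transcriptions of the study cohort tables:
#' `"baseline"` (demographics, NDI, Kellgren grades and sequence
#' classifications of the 10 elderly individuals), `"rom"` (their segmental
#' and total ranges of motion at both sessions) and `"external"` (the three
#' external-validation individuals, whose recordings cover only the second
#' half of extension). See `inst/extdata/README` for the column dictionary.
#'
#' @param name One of `"baseline"`, `"rom"`, `"external"`.
#' @return A tibble.
#' @export
#' @examples
#' load_cohort_table("baseline")
load_cohort_table <- function(name = c("baseline", "rom", "external")) {
  name <- match.arg(name)
  file <- c(baseline = "table1_baseline.csv", rom = "table2_rom.csv",
            external = "table4_external.csv")[[name]]
  path <- system.file("extdata", file, package = "cervseq", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write and read pose tables
#'
#' Poses as CSV `(frame, vertebra, theta_deg, tx_px, ty_px)`; extra columns
#' (score, lost) are preserved.
#'
#' @param poses Pose tibble.
#' @param path File path.
#' @return `read_poses()` returns the tibble; `write_poses()` returns `path`
#'   invisibly.
#' @export
write_poses <- function(poses, path) {
  readr::write_csv(poses, path)
  invisible(path)
}

#' @rdname write_poses
#' @export
read_poses <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write and read segmental angle series
#'
#' CSV `(frame, segment, angle_deg)`.
#'
#' @param angles Angle tibble.
#' @param path File path.
#' @export
write_angles <- function(angles, path) {
  readr::write_csv(angles[, c("frame", "segment", "angle_deg")], path)
  invisible(path)
}

#' @rdname write_angles
#' @export
read_angles <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write and read SSC curves
#'
#' The curve itself is CSV `(x, segment, rate, contribution_per_frame)`; its
#' metadata (net rotations, total rotation, grid, insufficient-motion flag)
#' goes to a JSON sidecar `<path>.json`, so a round trip reconstructs the
#' `ssc_curve` object.
#'
#' @param curve An `ssc_curve`.
#' @param path CSV file path.
#' @export
write_ssc_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ssc_curve"))
  readr::write_csv(as_tibble(curve), path)
  meta <- list(
    net_rotation = as.list(attr(curve, "net_rotation")),
    total_rotation = attr(curve, "total_rotation"),
    grid_step = attr(curve, "grid_step"),
    cell_width = attr(curve, "cell_width"),
    insufficient_motion = attr(curve, "insufficient_motion"),
    fps = attr(curve, "fps"),
    config = unclass(attr(curve, "config"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ssc_curve
#' @export
read_ssc_curve <- function(path) {
  curve <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    curve,
    net_rotation = unlist(meta$net_rotation),
    total_rotation = meta$total_rotation,
    grid_step = meta$grid_step,
    cell_width = meta$cell_width,
    insufficient_motion = meta$insufficient_motion,
    fps = meta$fps,
    config = do.call(ssc_config, as.list(meta$config)),
    class = c("ssc_curve", class(curve))
  )
}

#' Write and read a sequence classification
#'
#' JSON containing the presence, selected and detected peaks, reason codes
#' and an echo of the classifier configuration.
#'
#' @param classification A `sequence_classification`.
#' @param path JSON file path.
#' @export
write_classification <- function(classification, path) {
  stopifnot(inherits(classification, "sequence_classification"))
  out <- list(
    presence = classification$presence,
    reasons = as.list(classification$reasons),
    selected = classification$selected,
    peaks = classification$peaks,
    total_rotation = classification$total_rotation,
    config = unclass(classification$config)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_classification
#' @export
read_classification <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(presence = raw$presence,
         selected = as_tibble(raw$selected),
         peaks = as_tibble(raw$peaks),
         reasons = as.character(unlist(raw$reasons)),
         config = do.call(classifier_config, as.list(raw$config)),
         total_rotation = raw$total_rotation),
    class = "sequence_classification"
  )
}

#' Write rendered phantom frames as PNG files
#'
#' One 8-bit grayscale PNG per frame (`frame_000.png`, ...) plus the
#' ground-truth poses as CSV alongside. Requires the `png` package.
#'
#' @param stack A `phantom_stack`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_frames_png <- function(stack, dir) {
  stopifnot(inherits(stack, "phantom_stack"))
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("writing PNG frames requires the 'png' package.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(stack$frames)) {
    img <- pmin(pmax(stack$frames[[f]], 0), 1)
    png::writePNG(img, file.path(dir, sprintf("frame_%03d.png", f - 1L)))
  }
  write_poses(stack$poses, file.path(dir, "true_poses.csv"))
  invisible(dir)
}

#' Read an image stack from PNG or TIFF files
#'
#' @param paths Character vector of image files in frame order, or a
#'   directory containing only the frame images (sorted by name).
#' @return List of numeric matrices. Colour images are averaged to
#'   grayscale.
#' @export
read_frames <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.(png|tif|tiff)$",
                             full.names = TRUE, ignore.case = TRUE))
  }
  if (length(paths) == 0) abort("no frame images found.")
  lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    img <- if (ext == "png") {
      if (!requireNamespace("png", quietly = TRUE)) {
        abort("reading PNG frames requires the 'png' package.")
      }
      png::readPNG(p)
    } else if (ext %in% c("tif", "tiff")) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        abort("reading TIFF frames requires the 'tiff' package.")
      }
      tiff::readTIFF(p)
    } else {
      abort(sprintf("unsupported frame format: %s", p))
    }
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
    img
  })
}

#' Read contour annotations from JSON
#'
#' Expected format: an object mapping vertebra labels to vertex lists,
#' `{"C4": [[x, y], ...], ...}`.
#'
#' @param path JSON file.
#' @return Named list of [contour_template()] objects.
#' @export
read_templates_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw))) {
    abort(sprintf("malformed template file %s: expected a named object.", path))
  }
  lapply(setNames(nm = names(raw)), function(v) {
    verts <- raw[[v]]
    if (!is.matrix(verts)) {
      verts <- do.call(rbind, lapply(verts, function(p) as.numeric(unlist(p))))
    }
    contour_template(v, verts)
  })
}

#' Summarise a cohort table the way the printed tables do
#'
#' Applies [summarize_column()] to every numeric column and
#' [cohort_prevalence()] to every `+/-` sequence column of a cohort table
#' (e.g. from [load_cohort_table()]).
#'
#' @param table Cohort tibble.
#' @param digits Decimal places for printed means (single value or named by
#'   column).
#' @return List with `columns` (tibble: column, mean, min, max, n,
#'   formatted) and `prevalence_pct` (named numeric, possibly empty).
#' @export
#' @examples
#' summarize_cohort_table(load_cohort_table("rom"))
summarize_cohort_table <- function(table, digits = 1) {
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "id")
  digit_of <- function(col) {
    if (length(digits) == 1 && is.null(names(digits))) return(digits)
    if (col %in% names(digits)) return(digits[[col]])
    1
  }
  columns <- bind_rows(lapply(num_cols, function(col) {
    tibble(column = col,
           summarize_column(table[[col]], digits = digit_of(col)))
  }))
  seq_cols <- names(table)[vapply(table, function(v) {
    is.character(v) && all(trimws(v) %in% c("+", "-"))
  }, logical(1))]
  prevalence <- vapply(seq_cols, function(col) {
    cohort_prevalence(table[[col]])
  }, numeric(1))
  list(columns = columns, prevalence_pct = prevalence)
}

#' Render a cohort report as Markdown and CSV
#'
#' Writes the per-individual table, its average row and any sequence
#' prevalences as a Markdown document and a CSV twin, with a provenance
#' footer (package version, date, configuration echo).
#'
#' @param table Cohort tibble.
#' @param path Output stem; writes `<path>.md` and `<path>.csv`.
#' @param digits Decimal places for printed means.
#' @param config Optional named list echoed in the footer.
#' @return The summary (from [summarize_cohort_table()]), invisibly.
#' @export
report_cohort <- function(table, path, digits = 1, config = list()) {
  s <- summarize_cohort_table(table, digits = digits)
  md <- c(
    "# Cohort report", "",
    knit_markdown_table(table), "",
    "## Column averages", "",
    knit_markdown_table(s$columns[, c("column", "formatted", "n")]), ""
  )
  if (length(s$prevalence_pct) > 0) {
    md <- c(md, "## Normal-sequence prevalence", "",
            sprintf("- %s: %.0f%%", names(s$prevalence_pct),
                    s$prevalence_pct), "")
  }
  cfg <- if (length(config) > 0) {
    paste(names(config), vapply(config, function(x)
      paste(format(x), collapse = " "), character(1)),
      sep = "=", collapse = ", ")
  } else "defaults"
  md <- c(md, "---",
          sprintf("cervseq %s | %s | config: %s",
                  as.character(utils::packageVersion("cervseq")),
                  format(Sys.Date()), cfg))
  writeLines(md, paste0(path, ".md"))
  readr::write_csv(s$columns, paste0(path, ".csv"))
  invisible(s)
}

knit_markdown_table <- function(df) {
  df <- as.data.frame(df)
  cells <- vapply(df, function(col) format(col, trim = TRUE),
                  character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
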