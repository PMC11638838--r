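#' Field plot layout and trait-derivation constants
#'
#' Describes the plot geometry and the constants used to convert field weight
#' to grain yield. Defaults reproduce a standard tropical testcross trial:
#' two-row plots of 5 m, 0.75 m between rows, 0.25 m between hills, one plant
#' per hill, a shelling percentage of 80 and yield standardised to 12.5%
#' grain moisture.
#'
#' @param row_spacing Distance between rows, metres.
#' @param hill_spacing Distance between hills within a row, metres.
#' @param rows_per_plot Number of rows per plot.
#' @param plot_length Plot length, metres.
#' @param plants_per_hill Plants left per hill after thinning.
#' @param shelling_fraction Grain mass as a fraction of dehusked ear mass,
#'   in (0, 1].
#' @param standard_moisture Moisture content (%) that yields are adjusted to.
#' @return An object of class `trial_layout`.
#' @examples
#' layout <- trial_layout()
#' plant_density(layout) # 53333 plants/ha
#' @export
trial_layout <- function(row_spacing = 0.75, hill_spacing = 0.25,
                         rows_per_plot = 2L, plot_length = 5,
                         plants_per_hill = 1L, shelling_fraction = 0.80,
                         standard_moisture = 12.5) {
  assert_number(row_spacing, "row_spacing", lower = 0, strict = TRUE)
  assert_number(hill_spacing, "hill_spacing", lower = 0, strict = TRUE)
  assert_number(plot_length, "plot_length", lower = 0, strict = TRUE)
  rows_per_plot <- assert_count(rows_per_plot, "rows_per_plot")
  plants_per_hill <- assert_count(plants_per_hill, "plants_per_hill")
  assert_number(shelling_fraction, "shelling_fraction", lower = 0, upper = 1,
                strict = FALSE)
  if (shelling_fraction <= 0) abort("`shelling_fraction` must be > 0.")
  assert_number(standard_moisture, "standard_moisture", lower = 0, upper = 100,
                strict = TRUE)
  structure(
    list(
      row_spacing = row_spacing, hill_spacing = hill_spacing,
      rows_per_plot = rows_per_plot, plot_length = plot_length,
      plants_per_hill = plants_per_hill,
      shelling_fraction = shelling_fraction,
      standard_moisture = standard_moisture
    ),
    class = "trial_layout"
  )
}

#' @export
print.trial_layout <- function(x, ...) {
  cat("<trial_layout>\n")
  cat(sprintf("  plot: %d row(s) x %g m, %g m between rows, %g m between hills\n",
              x$rows_per_plot, x$plot_length, x$row_spacing, x$hill_spacing))
  cat(sprintf("  area: %g m^2; density: %d plants/ha\n",
              plot_area(x), plant_density(x)))
  cat(sprintf("  shelling fraction: %g; standard moisture: %g%%\n",
              x$shelling_fraction, x$standard_moisture))
  invisible(x)
}

#' Read a plot layout from a flat YAML key-value file
#'
#' Unspecified keys fall back to the [trial_layout()] defaults.
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [trial_layout()].
#' @return A `trial_layout`.
#' @export
read_layout_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(trial_layout))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    warn(paste0("Ignoring unknown layout keys: ", paste(extra, collapse = ", ")))
  }
  do.call(trial_layout, vals[intersect(names(vals), known)])
}

plot_area <- function(layout) {
  layout$rows_per_plot * layout$plot_length * layout$row_spacing
}

#' Grain yield from field weight and grain moisture
#'
#' Converts the dehusked ear weight of a plot (kg) to grain yield in t/ha:
#' `GY = FW * shelling * (100 - MOI) / (100 - standard_moisture) * 10 / area`,
#' with the plot area in square metres taken from the layout.
#'
#' @param field_weight Dehusked ear weight per plot, kg. Vectorised.
#' @param moisture Grain moisture at harvest, percent, in (0, 100). Vectorised.
#' @param layout A [trial_layout()].
#' @return Grain yield in t/ha; `NA` where either input is missing.
#' @examples
#' derive_grain_yield(7.5, 12.5) # 8 t/ha with the default layout
#' @export
derive_grain_yield <- function(field_weight, moisture, layout = trial_layout()) {
  stopifnot(inherits(layout, "trial_layout"))
  area <- plot_area(layout)
  if (area <= 0) abort("Plot area must be positive; check the layout.")
  bad_fw <- !is.na(field_weight) & field_weight < 0
  if (any(bad_fw)) abort("`field_weight` must be >= 0.")
  bad_moi <- !is.na(moisture) & (moisture < 0 | moisture >= 100)
  if (any(bad_moi)) abort("`moisture` must lie in [0, 100).")
  field_weight * layout$shelling_fraction *
    (100 - moisture) / (100 - layout$standard_moisture) * 10 / area
}

#' Anthesis-silking interval
#'
#' ASI = SD - AD (days): positive when silking lags pollen shed, as it
#' typically does under drought stress. Missing when either input is missing.
#'
#' @param ad Days to 50% anthesis.
#' @param sd Days to 50% silking.
#' @return ASI in days (may be negative).
#' @export
derive_asi <- function(ad, sd) {
  sd - ad
}

#' Plant density implied by a layout
#'
#' @param layout A [trial_layout()].
#' @return Plants per hectare, rounded to the nearest integer.
#' @export
plant_density <- function(layout = trial_layout()) {
  stopifnot(inherits(layout, "trial_layout"))
  round(layout$plants_per_hill * 10000 / (layout$row_spacing * layout$hill_spacing))
}

.plot_id_cols <- c("environment", "regime", "replicate", "block",
                   "entry_id", "entry_kind", "line_id", "tester_id")
.plot_trait_cols <- c("field_weight", "moisture", "AD", "SD", "PH", "EH",
                      "GY", "ASI")

#' Validate a plot-level trait table
#'
#' Checks the structural invariants of a plot table: identifier columns are
#' present, `entry_kind` is `"testcross"` or `"check"`, testcross rows carry
#' both `line_id` and `tester_id` while check rows carry neither, `moisture`
#' lies in (0, 100), and a present `GY` is consistent with `field_weight`
#' under [derive_grain_yield()]. Physically implausible trait values
#' (negative yields or heights, `EH > PH`) raise warnings rather than errors,
#' so that model-generated data with Gaussian noise are not rejected.
#'
#' @param data A data frame of plot records.
#' @param layout A [trial_layout()] used for the yield-consistency check.
#' @return The validated data, invisibly as a tibble.
#' @export
validate_plot_table <- function(data, layout = trial_layout()) {
  data <- as_tibble(data)
  need <- c("environment", "replicate", "block", "entry_id", "entry_kind")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Plot table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_kind <- which(!data$entry_kind %in% c("testcross", "check"))
  if (length(bad_kind)) {
    abort(paste0("Invalid entry_kind in row(s): ",
                 paste(head(bad_kind, 10), collapse = ", ")))
  }
  if (!"line_id" %in% names(data)) data$line_id <- NA_character_
  if (!"tester_id" %in% names(data)) data$tester_id <- NA_character_
  tc <- data$entry_kind == "testcross"
  bad_tc <- which(tc & (is.na(data$line_id) | is.na(data$tester_id)))
  if (length(bad_tc)) {
    abort(paste0("Design error: testcross row(s) lacking line_id or tester_id: ",
                 paste(head(bad_tc, 10), collapse = ", ")))
  }
  bad_chk <- which(!tc & (!is.na(data$line_id) | !is.na(data$tester_id)))
  if (length(bad_chk)) {
    abort(paste0("Design error: check row(s) carrying line_id or tester_id: ",
                 paste(head(bad_chk, 10), collapse = ", ")))
  }
  if ("moisture" %in% names(data)) {
    bad <- which(!is.na(data$moisture) &
                   (data$moisture <= 0 | data$moisture >= 100))
    if (length(bad)) {
      abort(paste0("Moisture outside (0, 100) in row(s): ",
                   paste(head(bad, 10), collapse = ", ")))
    }
  }
  for (col in c("GY", "PH", "EH", "AD", "SD", "field_weight")) {
    if (col %in% names(data)) {
      bad <- which(!is.na(data[[col]]) & data[[col]] < 0)
      if (length(bad)) {
        warn(sprintf("%d row(s) have negative %s (e.g. row %d).",
                     length(bad), col, bad[1]))
      }
    }
  }
  if (all(c("PH", "EH") %in% names(data))) {
    bad <- which(!is.na(data$PH) & !is.na(data$EH) & data$EH > data$PH)
    if (length(bad)) {
      warn(sprintf("%d row(s) have EH > PH (e.g. row %d).", length(bad), bad[1]))
    }
  }
  if (all(c("GY", "field_weight", "moisture") %in% names(data))) {
    both <- !is.na(data$GY) & !is.na(data$field_weight) & !is.na(data$moisture)
    if (any(both)) {
      implied <- derive_grain_yield(data$field_weight[both],
                                    data$moisture[both], layout)
      bad <- which(abs(implied - data$GY[both]) > 1e-6)
      if (length(bad)) {
        abort(paste0("GY inconsistent with field_weight/moisture in row(s): ",
                     paste(head(which(both)[bad], 10), collapse = ", ")))
      }
    }
  }
  invisible(data)
}

#' Fill derived trait columns of a plot table
#'
#' Adds `GY` (from `field_weight` and `moisture`) and `ASI` (from `AD` and
#' `SD`) where the derived column is absent. Columns already present are
#' passed through untouched, and missing raw values yield missing derived
#' values — nothing is imputed.
#'
#' @inheritParams validate_plot_table
#' @return The data with derived columns appended, as a tibble.
#' @export
derive_traits <- function(data, layout = trial_layout()) {
  data <- as_tibble(data)
  if (!"GY" %in% names(data) &&
      all(c("field_weight", "moisture") %in% names(data))) {
    data$GY <- derive_grain_yield(data$field_weight, data$moisture, layout)
  }
  if (!"ASI" %in% names(data) && all(c("AD", "SD") %in% names(data))) {
    data$ASI <- derive_asi(data$AD, data$SD)
  }
  data
}

#' Read a plot-level trait table from CSV
#'
#' Comma-separated, UTF-8; `"NA"` and the empty string are read as missing.
#' One row is one plot. Unknown columns are preserved. The table is
#' validated with [validate_plot_table()] and derived traits are filled with
#' [derive_traits()].
#'
#' @param path Path to the CSV file.
#' @param layout A [trial_layout()].
#' @return A validated tibble of plot records.
#' @export
read_plot_table <- function(path, layout = trial_layout()) {
  data <- readr::read_csv(path, na = c("NA", ""), show_col_types = FALSE,
                          progress = FALSE)
  for (col in intersect(c("environment", "regime", "block", "entry_id",
                          "entry_kind", "line_id", "tester_id"), names(data))) {
    data[[col]] <- as.character(data[[col]])
  }
  for (col in intersect(.plot_trait_cols, names(data))) {
    if (!is.numeric(data[[col]])) data[[col]] <- as.numeric(data[[col]])
  }
  validate_plot_table(data, layout)
  derive_traits(data, layout)
}

#' Write a plot table to CSV
#'
#' Inverse of [read_plot_table()]: missing values are written as `"NA"` so a
#' round trip reproduces the table.
#'
#' @param data A plot table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(data, path) {
  readr::write_csv(data, path, na = "NA", progress = FALSE)
  invisible(path)
}
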