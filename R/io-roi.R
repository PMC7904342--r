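ROI_NAMES <- c("projection", "association", "subcortical")
ROI_DOMINANT_AXIS <- c(projection = "z", association = "y", subcortical = "x")

#' Construct ROI specifications
#'
#' One row per spherical ROI: a name, a centre in world mm, a diameter
#' (default 5 mm) and the fibre axis expected to dominate there —
#' projection fibres run along z, association fibres along y and
#' subcortical fibres along x at the level of the lateral ventricle body.
#'
#' @param name Character, each one of `projection`, `association`,
#'   `subcortical`.
#' @param center_mm Numeric matrix (n x 3) or length-3 vector of ROI
#'   centres, world mm.
#' @param diameter_mm Sphere diameter(s), mm; default 5.
#' @return A tibble of class `alps_roi_spec` with columns `name`, `cx`,
#'   `cy`, `cz`, `diameter_mm`, `expected_dominant_axis`.
#' @export
roi_spec <- function(name, center_mm, diameter_mm = 5) {
  name <- as.character(name)
  bad <- setdiff(name, ROI_NAMES)
  if (length(bad)) {
    abort(sprintf("Unknown ROI name(s): %s (allowed: %s).",
                  paste(bad, collapse = ", "),
                  paste(ROI_NAMES, collapse = ", ")),
          class = "alps_validation_error")
  }
  if (is.null(dim(center_mm))) center_mm <- matrix(center_mm, nrow = 1)
  center_mm <- as.matrix(center_mm)
  if (ncol(center_mm) != 3 || nrow(center_mm) != length(name) ||
      any(!is.finite(center_mm))) {
    abort("`center_mm` must be a finite n x 3 matrix matching `name`.",
          class = "alps_validation_error")
  }
  diameter_mm <- rep_len(as.numeric(diameter_mm), length(name))
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0)) {
    abort("`diameter_mm` must be positive.", class = "alps_validation_error")
  }
  out <- tibble(
    name = name,
    cx = center_mm[, 1], cy = center_mm[, 2], cz = center_mm[, 3],
    diameter_mm = diameter_mm,
    expected_dominant_axis = unname(ROI_DOMINANT_AXIS[name]))
  class(out) <- c("alps_roi_spec", class(out))
  out
}

#' Read ROI specifications from a YAML or JSON config
#'
#' The config is a list of entries with keys `name`, `center_mm` and
#' optionally `diameter_mm` (default 5 mm).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `alps_roi_spec` tibble.
#' @export
read_roi_specs <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path),
                                class = "alps_io_error")
  entries <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!length(entries)) abort("ROI config is empty.", class = "alps_format_error")
  rows <- purrr::map(entries, function(e) {
    if (is.null(e$name)) abort("ROI entry missing `name`.",
                               class = "alps_format_error")
    if (is.null(e$center_mm) || length(e$center_mm) != 3) {
      abort(sprintf("ROI `%s` missing a 3-component `center_mm`.",
                    e$name), class = "alps_format_error")
    }
    roi_spec(e$name, as.numeric(e$center_mm),
             diameter_mm = e$diameter_mm %||% 5)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("alps_roi_spec", setdiff(class(out), "alps_roi_spec"))
  out
}

#' Write ROI specifications as YAML
#'
#' @param rois An `alps_roi_spec` tibble.
#' @param path Output `.yaml` path.
#' @return Invisibly, `path`.
#' @export
write_roi_specs <- function(rois, path) {
  entries <- purrr::pmap(rois, function(name, cx, cy, cz, diameter_mm, ...) {
    list(name = name, center_mm = c(cx, cy, cz), diameter_mm = diameter_mm)
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
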