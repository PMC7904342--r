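#' Voxels inside a spherical ROI
#'
#' Selects every voxel whose CENTRE lies within `diameter_mm / 2` of the
#' sphere centre, boundary inclusive (a centre exactly on the radius is
#' selected). Reproducible alternative to manual ROI placement on the
#' colour-FA map.
#'
#' @param dims Integer length-3 grid dimensions.
#' @param voxel_size Length-3 voxel spacing, mm.
#' @param center_mm Length-3 sphere centre, world mm.
#' @param diameter_mm Sphere diameter, mm.
#' @param origin Length-3 world origin; default grid centre.
#' @param name ROI name used in error messages.
#' @return Integer matrix (n x 3) of 1-based voxel indices.
#' @export
sphere_voxels <- function(dims, voxel_size, center_mm, diameter_mm,
                          origin = NULL, name = "ROI") {
  dims <- as.integer(dims)
  if (is.null(origin)) origin <- default_origin(dims, voxel_size)
  r <- diameter_mm / 2
  lo <- origin - voxel_size / 2
  hi <- origin + (dims - 1) * voxel_size + voxel_size / 2
  if (any(center_mm < lo) || any(center_mm > hi)) {
    abort(sprintf("%s centre (%.1f, %.1f, %.1f) mm lies outside the grid.",
                  name, center_mm[1], center_mm[2], center_mm[3]),
          class = "alps_validation_error")
  }
  wx <- axis_world(dims[1], voxel_size[1], origin[1])
  wy <- axis_world(dims[2], voxel_size[2], origin[2])
  wz <- axis_world(dims[3], voxel_size[3], origin[3])
  # candidate index window, then exact centre-distance test
  ix <- which(abs(wx - center_mm[1]) <= r + 1e-9)
  iy <- which(abs(wy - center_mm[2]) <= r + 1e-9)
  iz <- which(abs(wz - center_mm[3]) <= r + 1e-9)
  grid <- expand.grid(i = ix, j = iy, k = iz)
  d2 <- (wx[grid$i] - center_mm[1])^2 + (wy[grid$j] - center_mm[2])^2 +
    (wz[grid$k] - center_mm[3])^2
  keep <- d2 <= r^2 + 1e-9
  if (!any(keep)) {
    abort(sprintf("%s selects no voxels (diameter %.2f mm on spacing %s mm).",
                  name, diameter_mm,
                  paste(voxel_size, collapse = " x ")),
          class = "alps_validation_error")
  }
  as.matrix(grid[keep, , drop = FALSE])
}

roi_mean_tensor <- function(tf, roi_row) {
  vox <- sphere_voxels(dim(tf$mask), tf$voxel_size,
                       c(roi_row$cx, roi_row$cy, roi_row$cz),
                       roi_row$diameter_mm, origin = tf$origin,
                       name = roi_row$name)
  inside <- tf$mask[vox]
  if (!any(inside)) {
    abort(sprintf("ROI `%s` lies entirely outside the fitted mask.",
                  roi_row$name), class = "alps_validation_error")
  }
  vox <- vox[inside, , drop = FALSE]
  lin <- vox[, 1] + dim(tf$mask)[1] * (vox[, 2] - 1) +
    prod(dim(tf$mask)[1:2]) * (vox[, 3] - 1)
  comp_means <- vapply(TENSOR_COMPONENTS,
                       function(cn) mean(tf$tensor[, , , cn][lin]),
                       numeric(1))
  list(voxels = vox, lin = lin, mean_tensor = comp_means)
}

#' Fibre-dominance check for an ROI
#'
#' TRUE iff the principal eigenvector of the ROI-mean tensor has its
#' largest absolute component on the ROI's expected axis. An exact tie
#' (e.g. an isotropic ROI) fails the check with a warning — conservative
#' QC before the ALPS ratio is trusted.
#'
#' @param tensor_field An `alps_tensor_field`.
#' @param roi One-row `alps_roi_spec`.
#' @return Logical flag.
#' @export
dominance_check <- function(tensor_field, roi) {
  rm <- roi_mean_tensor(tensor_field, as.list(roi))
  eg <- eigen(tensor_to_matrix(rm$mean_tensor), symmetric = TRUE)
  lam <- eg$values
  scale <- max(abs(lam), .Machine$double.eps)
  if ((lam[1] - lam[2]) <= 1e-9 * scale) {
    # degenerate principal direction (e.g. isotropic CSF): no dominance
    warn(sprintf(
      "ROI `%s`: principal-eigenvalue tie; dominance flagged FALSE.",
      roi$name))
    return(FALSE)
  }
  e1 <- abs(eg$vectors[, 1])
  axis_idx <- match(roi$expected_dominant_axis, c("x", "y", "z"))
  others <- max(e1[-axis_idx])
  if (abs(e1[axis_idx] - others) < 1e-12) {
    warn(sprintf(
      "ROI `%s`: principal-direction tie; dominance flagged FALSE.",
      roi$name))
    return(FALSE)
  }
  e1[axis_idx] > others
}

#' ROI axis diffusivities for the ALPS ratio
#'
#' Means of Dxx over the projection and association ROIs, Dyy over the
#' projection ROI and Dzz over the association ROI — the four inputs of
#' the ALPS index — plus per-ROI voxel counts and fibre-dominance flags.
#' Measurements are taken in the left hemisphere by convention; an ROI
#' centred at positive x (right side) triggers a warning.
#'
#' @param tensor_field An `alps_tensor_field`.
#' @param roi_specs An `alps_roi_spec` containing at least `projection`
#'   and `association` rows.
#' @return One-row tibble of class `alps_roi_diffusivities`: `dxx_proj`,
#'   `dxx_assoc`, `dyy_proj`, `dzz_assoc` (mm^2/s), `n_vox_proj`,
#'   `n_vox_assoc`, `dominance_proj`, `dominance_assoc`, `dominance_ok`.
#' @export
roi_axis_means <- function(tensor_field, roi_specs) {
  stopifnot(inherits(tensor_field, "alps_tensor_field"))
  need <- c("projection", "association")
  if (!all(need %in% roi_specs$name)) {
    abort("Need both `projection` and `association` ROIs for the ALPS index.",
          class = "alps_validation_error")
  }
  if (any(roi_specs$cx > 0)) {
    warn("ROI centred in the right hemisphere (x > 0); the ALPS convention measures the left hemisphere only.")
  }
  get_roi <- function(nm) roi_specs[roi_specs$name == nm, ][1, ]
  proj <- roi_mean_tensor(tensor_field, as.list(get_roi("projection")))
  asso <- roi_mean_tensor(tensor_field, as.list(get_roi("association")))
  dom_p <- dominance_check(tensor_field, get_roi("projection"))
  dom_a <- dominance_check(tensor_field, get_roi("association"))
  out <- tibble(
    dxx_proj = mean(tensor_field$maps$dxx[proj$lin]),
    dxx_assoc = mean(tensor_field$maps$dxx[asso$lin]),
    dyy_proj = mean(tensor_field$maps$dyy[proj$lin]),
    dzz_assoc = mean(tensor_field$maps$dzz[asso$lin]),
    n_vox_proj = nrow(proj$voxels),
    n_vox_assoc = nrow(asso$voxels),
    dominance_proj = dom_p,
    dominance_assoc = dom_a,
    dominance_ok = dom_p && dom_a)
  class(out) <- c("alps_roi_diffusivities", class(out))
  out
}

#' The ALPS index
#'
#' Ratio of the mean x-axis diffusivity in the projection- and
#' association-fibre areas (both perpendicular to their dominant fibres
#' and parallel to the perivascular space) to the mean of the
#' fibre-perpendicular references Dyy (projection) and Dzz (association):
#'
#' \deqn{ALPS = \mathrm{mean}(Dxx_{proj}, Dxx_{assoc}) /
#'   \mathrm{mean}(Dyy_{proj}, Dzz_{assoc})}
#'
#' Arithmetic means on both sides. A value near 1 indicates no measurable
#' perivascular diffusion component; larger values indicate more.
#'
#' @param rd An `alps_roi_diffusivities` row, or a data frame with columns
#'   `dxx_proj`, `dxx_assoc`, `dyy_proj`, `dzz_assoc`.
#' @return Numeric vector of ALPS indices (dimensionless).
#' @examples
#' alps_index(data.frame(dxx_proj = 1.2e-3, dxx_assoc = 1.0e-3,
#'                       dyy_proj = 0.8e-3, dzz_assoc = 0.6e-3))
#' @export
alps_index <- function(rd) {
  need <- c("dxx_proj", "dxx_assoc", "dyy_proj", "dzz_assoc")
  if (!all(need %in% names(rd))) {
    abort(sprintf("`rd` must provide %s.", paste(need, collapse = ", ")),
          class = "alps_validation_error")
  }
  vals <- lapply(need, function(nm) rd[[nm]])
  if (any(!is.finite(unlist(vals)))) {
    abort("ALPS inputs must be finite.", class = "alps_validation_error")
  }
  num <- (vals[[1]] + vals[[2]]) / 2
  den <- (vals[[3]] + vals[[4]]) / 2
  if (any(den <= 0)) {
    abort("Non-positive denominator diffusivity; ALPS index undefined (QC failure).",
          class = "alps_qc_error")
  }
  num / den
}

#' End-to-end per-subject ALPS computation
#'
#' Chains tensor fitting, ROI sampling and the ALPS ratio for one DWI
#' dataset: `fit_tensor_volume()` then `roi_axis_means()` then
#' `alps_index()`, with the fibre-dominance QC flag attached.
#'
#' @param dataset An `alps_dwi`.
#' @param roi_specs An `alps_roi_spec` with projection and association
#'   rows.
#' @param mask Optional logical 3D mask.
#' @param subject Subject identifier carried into the output.
#' @return One-row tibble of class `alps_subject`: `subject`, `alps`, the
#'   four diffusivities, voxel counts and `qc_pass`.
#' @export
compute_subject_alps <- function(dataset, roi_specs, mask = NULL,
                                 subject = "subject") {
  tf <- fit_tensor_volume(dataset, mask)
  rd <- roi_axis_means(tf, roi_specs)
  out <- dplyr::bind_cols(tibble(subject = as.character(subject),
                                 alps = alps_index(rd)), rd)
  out$qc_pass <- out$dominance_ok
  class(out) <- c("alps_subject", setdiff(class(out), "alps_roi_diffusivities"))
  out
}
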