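#' Construct a DWI dataset
#'
#' Bundles a 4D signal array with its gradient table and voxel geometry.
#' The anatomical frame is fixed: +x right-left, +y posterior-anterior,
#' +z inferior-superior; images are assumed already in this orientation.
#' World coordinate of (0-based) voxel (i, j, k) is
#' `voxel_size * (i, j, k) + origin`; the default origin centres the grid
#' on (0, 0, 0) so phantom ROIs can be placed symmetrically.
#'
#' @param signal 4D non-negative array (x, y, z, volume), scanner units.
#' @param gtab `alps_gradient_table` with one entry per volume.
#' @param voxel_size Length-3 positive numeric, mm.
#' @param origin Length-3 numeric, mm; default the grid's geometric centre.
#' @return An object of class `alps_dwi`.
#' @export
dwi_dataset <- function(signal, gtab, voxel_size = c(2, 2, 2.5),
                        origin = NULL) {
  stopifnot(inherits(gtab, "alps_gradient_table"))
  signal <- as.array(signal)
  if (length(dim(signal)) != 4) {
    abort("`signal` must be a 4D array (x, y, z, volume).",
          class = "alps_validation_error")
  }
  if (dim(signal)[4] != length(gtab)) {
    abort(sprintf(
      "Volume count mismatch: image has %d volumes, gradient table %d.",
      dim(signal)[4], length(gtab)), class = "alps_format_error")
  }
  if (any(signal < 0, na.rm = TRUE)) {
    abort("DWI signal must be non-negative.", class = "alps_validation_error")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    abort("`voxel_size` must be 3 strictly positive numbers (mm).",
          class = "alps_validation_error")
  }
  dims <- dim(signal)[1:3]
  if (is.null(origin)) origin <- default_origin(dims, voxel_size)
  structure(list(signal = signal, gtab = gtab, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "alps_dwi")
}

#' @export
print.alps_dwi <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<alps_dwi> %d x %d x %d grid, %d volumes, voxels %g x %g x %g mm\n",
              d[1], d[2], d[3], d[4],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Read a DWI dataset from NIfTI + FSL gradient files
#'
#' @param nifti_path 4D NIfTI image.
#' @param bval_path,bvec_path FSL-dialect whitespace-separated gradient
#'   files (bvec as 3 rows x N columns; an N x 3 file is transposed with a
#'   warning).
#' @return An `alps_dwi`; voxel size is taken from the image header and
#'   gradient directions are normalised on load.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  for (p in c(nifti_path, bval_path, bvec_path)) {
    if (!file.exists(p)) abort(sprintf("File not found: %s", p),
                               class = "alps_io_error")
  }
  img <- RNifti::readNifti(nifti_path)
  arr <- structure(as.vector(as.array(img)), dim = dim(img))  # plain array
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
  gtab <- gradient_table(read_bval(bval_path), read_bvec(bvec_path))
  vox <- RNifti::pixdim(img)[1:3]
  ds <- dwi_dataset(arr, gtab, voxel_size = vox)
  check_fit_ready(gtab)
  ds
}

#' Write a DWI dataset as NIfTI + FSL gradient files
#'
#' Stored as float64 so the read/write round trip is lossless.
#'
#' @param dataset An `alps_dwi`.
#' @param nifti_path,bval_path,bvec_path Output paths.
#' @return Invisibly, the dataset.
#' @export
write_dwi <- function(dataset, nifti_path, bval_path, bvec_path) {
  stopifnot(inherits(dataset, "alps_dwi"))
  img <- RNifti::asNifti(dataset$signal,
                         reference = list(pixdim = c(-1, dataset$voxel_size,
                                                     1, 1, 1, 1)),
                         datatype = "double")
  RNifti::writeNifti(img, nifti_path)
  write_bval(dataset$gtab$bvals, bval_path)
  write_bvec(dataset$gtab$bvecs, bvec_path)
  invisible(dataset)
}

#' Write scalar or RGB maps of a tensor field as NIfTI
#'
#' @param tf An `alps_tensor_field`.
#' @param dir Output directory (created if needed).
#' @param maps Character vector among `fa`, `md`, `dxx`, `dyy`, `dzz`,
#'   `color_fa`.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_tensor_maps <- function(tf, dir,
                              maps = c("fa", "md", "dxx", "dyy", "dzz",
                                       "color_fa")) {
  stopifnot(inherits(tf, "alps_tensor_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maps <- match.arg(maps, several.ok = TRUE)
  out <- character(0)
  for (m in maps) {
    arr <- if (m == "color_fa") tf$color_fa else tf$maps[[m]]
    path <- file.path(dir, paste0(m, ".nii.gz"))
    img <- RNifti::asNifti(arr,
                           reference = list(pixdim = c(-1, tf$voxel_size,
                                                       1, 1, 1, 1)),
                           datatype = "double")
    RNifti::writeNifti(img, path)
    out[m] <- path
  }
  invisible(out)
}
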