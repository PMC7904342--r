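diag_tensor <- function(dxx, dyy, dzz) {
  c(dxx = dxx, dyy = dyy, dzz = dzz, dxy = 0, dxz = 0, dyz = 0)
}

PHANTOM_COMPARTMENTS <- c("projection", "association", "subcortical", "csf",
                          "background")

#' Specify a DWI phantom
#'
#' A block phantom on the clinical ALPS grid: a z-dominant projection-fibre
#' block, a y-dominant association block, an x-dominant subcortical block
#' and an isotropic high-diffusivity CSF block, all in the left (negative x)
#' half of the grid over an isotropic background. `perivascular_boost`
#' (delta) adds a known increment to Dxx in the projection and association
#' blocks — the quantity the ALPS ratio senses — so ground truth stays
#' analytic: ALPS = (Dxx_perp + delta) / Dxx_perp.
#'
#' @param dims Grid size in voxels; default `c(20, 20, 20)`.
#' @param voxel_size Voxel spacing, mm; default `c(2, 2, 2.5)`.
#' @param tensors Named list of base compartment tensors (length-6
#'   component vectors, mm^2/s) for `projection`, `association`,
#'   `subcortical`, `csf`, `background`.
#' @param perivascular_boost Additive Dxx increment (mm^2/s) in the
#'   projection and association blocks; >= 0.
#' @param s0 Non-diffusion-weighted signal level.
#' @param noise_sigma Rician noise sigma on the complex channels, signal
#'   units; 0 for noiseless.
#' @param nex Number of excitations averaged (default 3).
#' @param roi_diameter ROI sphere diameter emitted with the phantom, mm.
#' @param seed Integer seed used by [simulate_dwi()] when noise is drawn.
#' @return A list of class `alps_phantom_spec`.
#' @export
phantom_spec <- function(dims = c(20, 20, 20),
                         voxel_size = c(2, 2, 2.5),
                         tensors = list(
                           projection = diag_tensor(0.4e-3, 0.4e-3, 1.4e-3),
                           association = diag_tensor(0.4e-3, 1.4e-3, 0.4e-3),
                           subcortical = diag_tensor(1.4e-3, 0.4e-3, 0.4e-3),
                           csf = diag_tensor(3.0e-3, 3.0e-3, 3.0e-3),
                           background = diag_tensor(0.8e-3, 0.8e-3, 0.8e-3)),
                         perivascular_boost = 0,
                         s0 = 1000,
                         noise_sigma = 0,
                         nex = 3,
                         roi_diameter = 5,
                         seed = 1L) {
  stopifnot(length(dims) == 3, all(dims >= 1),
            length(voxel_size) == 3, all(voxel_size > 0))
  if (!all(PHANTOM_COMPARTMENTS %in% names(tensors))) {
    abort(sprintf("`tensors` must name all of: %s.",
                  paste(PHANTOM_COMPARTMENTS, collapse = ", ")),
          class = "alps_validation_error")
  }
  if (perivascular_boost < 0) {
    abort("`perivascular_boost` must be >= 0.", class = "alps_validation_error")
  }
  if (noise_sigma < 0) {
    abort("`noise_sigma` must be >= 0.", class = "alps_validation_error")
  }
  tensors <- lapply(tensors, as_tensor_vector)
  structure(list(dims = as.integer(dims), voxel_size = as.numeric(voxel_size),
                 tensors = tensors,
                 perivascular_boost = perivascular_boost,
                 s0 = s0, noise_sigma = noise_sigma, nex = as.integer(nex),
                 roi_diameter = roi_diameter, seed = as.integer(seed)),
            class = "alps_phantom_spec")
}

#' All-isotropic phantom specification
#'
#' Every compartment gets the same isotropic tensor, so the ALPS ratio of
#' the phantom is exactly 1 — the no-perivascular-component baseline.
#'
#' @param d Isotropic diffusivity, mm^2/s.
#' @param ... Passed to [phantom_spec()].
#' @export
isotropic_phantom_spec <- function(d = 0.7e-3, ...) {
  iso <- diag_tensor(d, d, d)
  phantom_spec(tensors = list(projection = iso, association = iso,
                              subcortical = iso, csf = iso,
                              background = iso), ...)
}

# Block layout: compartments live in the left half (x indices 1..floor(nx/2),
# i.e. negative world x); projection/subcortical stack in the lower-y half,
# association/csf in the upper-y half, split along z.
phantom_blocks <- function(spec) {
  dims <- spec$dims
  hx <- dims[1] %/% 2
  hy <- dims[2] %/% 2
  hz <- dims[3] %/% 2
  wx <- min(6L, hx); wy <- min(6L, hy); wz <- min(6L, hz)
  need <- ceiling(spec$roi_diameter / spec$voxel_size)
  if (wx < need[1] || wy < need[2] || wz < need[3]) {
    abort(sprintf(
      "Grid %s too small: a %g mm ROI sphere needs blocks of at least %s voxels.",
      paste(dims, collapse = "x"), spec$roi_diameter,
      paste(need, collapse = "x")), class = "alps_validation_error")
  }
  rng <- function(half_start, half_len, w) {
    off <- (half_len - w) %/% 2
    half_start + off + seq_len(w) - 1L
  }
  xs <- rng(1L, hx, wx)
  y_lo <- rng(1L, hy, wy);  y_hi <- rng(hy + 1L, dims[2] - hy, wy)
  z_lo <- rng(1L, hz, wz);  z_hi <- rng(hz + 1L, dims[3] - hz, wz)
  list(projection = list(x = xs, y = y_lo, z = z_lo),
       association = list(x = xs, y = y_hi, z = z_lo),
       subcortical = list(x = xs, y = y_lo, z = z_hi),
       csf = list(x = xs, y = y_hi, z = z_hi))
}

ground_truth_field <- function(labels, tensors, voxel_size, origin, s0) {
  dims <- dim(labels)
  tensor <- array(NA_real_, c(dims, 6),
                  dimnames = list(NULL, NULL, NULL, TENSOR_COMPONENTS))
  for (comp in names(tensors)) {
    idx <- which(labels == comp)
    for (k in seq_along(TENSOR_COMPONENTS)) {
      tensor[, , , k][idx] <- tensors[[comp]][k]
    }
  }
  D <- matrix(tensor, ncol = 6)
  colnames(D) <- TENSOR_COMPONENTS
  scal <- tensor_scalars(D)
  maps <- list(fa = array(scal$fa, dims),
               md = array(scal$md, dims),
               dxx = array(D[, "dxx"], dims),
               dyy = array(D[, "dyy"], dims),
               dzz = array(D[, "dzz"], dims))
  color_fa <- array(scal$color, c(dims, 3),
                    dimnames = list(NULL, NULL, NULL, c("r", "g", "b")))
  structure(list(tensor = tensor,
                 s0 = array(s0, dims),
                 mask = array(TRUE, dims),
                 maps = maps, color_fa = color_fa,
                 voxel_size = voxel_size, origin = origin,
                 n_clamped = 0L), class = "alps_tensor_field")
}

#' Build a phantom with analytic tensor ground truth
#'
#' Lays out the four tissue compartments, applies the perivascular Dxx
#' boost, and emits the matching ROI configuration: one sphere centred in
#' each of the projection, association and subcortical blocks (all in the
#' left half of the grid).
#'
#' @param spec An `alps_phantom_spec`.
#' @return List of class `alps_phantom`: `ground_truth`
#'   (`alps_tensor_field`), `labels` (character 3D array), `rois`
#'   (`alps_roi_spec`), `tensors` (boosted compartment tensors),
#'   `analytic_alps` and the `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "alps_phantom_spec"))
  blocks <- phantom_blocks(spec)
  tensors <- spec$tensors
  for (comp in c("projection", "association")) {
    tensors[[comp]]["dxx"] <- tensors[[comp]]["dxx"] + spec$perivascular_boost
  }
  for (comp in names(tensors)) {
    ev <- eigen(tensor_to_matrix(tensors[[comp]]), symmetric = TRUE,
                only.values = TRUE)$values
    if (any(ev <= 0)) {
      abort(sprintf("Compartment `%s` tensor is not positive definite.",
                    comp), class = "alps_validation_error")
    }
  }
  labels <- array("background", spec$dims)
  for (comp in names(blocks)) {
    b <- blocks[[comp]]
    labels[b$x, b$y, b$z] <- comp
  }
  origin <- default_origin(spec$dims, spec$voxel_size)
  gt <- ground_truth_field(labels, tensors, spec$voxel_size, origin, spec$s0)

  centre_of <- function(b) {
    c(mean(axis_world(spec$dims[1], spec$voxel_size[1], origin[1])[b$x]),
      mean(axis_world(spec$dims[2], spec$voxel_size[2], origin[2])[b$y]),
      mean(axis_world(spec$dims[3], spec$voxel_size[3], origin[3])[b$z]))
  }
  rois <- roi_spec(c("projection", "association", "subcortical"),
                   rbind(centre_of(blocks$projection),
                         centre_of(blocks$association),
                         centre_of(blocks$subcortical)),
                   diameter_mm = spec$roi_diameter)
  analytic <- (tensors$projection["dxx"] + tensors$association["dxx"]) /
    (tensors$projection["dyy"] + tensors$association["dzz"])
  structure(list(ground_truth = gt, labels = labels, rois = rois,
                 tensors = tensors, analytic_alps = unname(analytic),
                 spec = spec), class = "alps_phantom")
}

#' @export
print.alps_phantom <- function(x, ...) {
  cat(sprintf(
    "<alps_phantom> %s grid, boost %g mm^2/s, analytic ALPS %.4f\n",
    paste(x$spec$dims, collapse = "x"), x$spec$perivascular_boost,
    x$analytic_alps))
  invisible(x)
}

#' Forward-simulate a DWI acquisition
#'
#' Per voxel and volume, `S = s0 * exp(-b g' D g)`. Rician noise (the
#' magnitude-MR convention: sigma on each complex channel) is drawn
#' independently for each of `nex` excitations and the excitations are
#' averaged, emulating repeated acquisitions. Noiseless when
#' `noise_sigma = 0`.
#'
#' @param ground_truth An `alps_phantom` or an `alps_tensor_field` with
#'   full tensor coverage.
#' @param gtab Gradient table; default the 14-volume b = 1000 scheme.
#' @param s0,noise_sigma,nex,seed Override the phantom spec values.
#' @return An `alps_dwi`, reproducible for a fixed seed.
#' @export
simulate_dwi <- function(ground_truth, gtab = default_gradient_table(),
                         s0 = NULL, noise_sigma = NULL, nex = NULL,
                         seed = NULL) {
  if (inherits(ground_truth, "alps_phantom")) {
    spec <- ground_truth$spec
    s0 <- s0 %||% spec$s0
    noise_sigma <- noise_sigma %||% spec$noise_sigma
    nex <- nex %||% spec$nex
    seed <- seed %||% derive_seed(spec$seed, "dwi")
    tf <- ground_truth$ground_truth
  } else if (inherits(ground_truth, "alps_tensor_field")) {
    tf <- ground_truth
    s0 <- s0 %||% 1000
    noise_sigma <- noise_sigma %||% 0
    nex <- nex %||% 3L
  } else {
    abort("`ground_truth` must be an alps_phantom or alps_tensor_field.")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.",
                             class = "alps_validation_error")
  dims <- dim(tf$mask)
  D <- matrix(tf$tensor, ncol = 6)
  if (any(!is.finite(D))) {
    abort("Ground-truth field has unfitted voxels; full coverage required.",
          class = "alps_validation_error")
  }
  Xd <- design_matrix(gtab)[, -1, drop = FALSE]   # diffusion coefficients
  logS <- log(s0) + D %*% t(Xd)
  S <- exp(logS)                                  # n_voxel x n_volume
  if (noise_sigma > 0) {
    S <- with_seed(seed, {
      acc <- matrix(0, nrow(S), ncol(S))
      for (e in seq_len(nex)) {
        re <- S + matrix(rnorm(length(S), 0, noise_sigma), nrow(S))
        im <- matrix(rnorm(length(S), 0, noise_sigma), nrow(S))
        acc <- acc + sqrt(re^2 + im^2)
      }
      acc / nex
    })
  }
  dwi_dataset(array(S, c(dims, length(gtab))), gtab,
              voxel_size = tf$voxel_size, origin = tf$origin)
}
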