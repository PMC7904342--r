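tensor_to_matrix <- function(d) {
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3, 3)
}

#' Fit a diffusion tensor in one voxel
#'
#' Ordinary least squares on the log signal under
#' ln S = ln S0 - b g' D g. Signals at or below zero are clamped to
#' 1e-6 * max(signal) before the log; the clamp count is reported via a
#' message by the volume fitter.
#'
#' @param signals Numeric vector, one signal per volume.
#' @param gtab `alps_gradient_table` (needs a b0 volume and >= 6
#'   non-collinear diffusion directions).
#' @return Named list with the six tensor elements (mm^2/s, anatomical
#'   frame) and `s0 = exp(intercept)`.
#' @examples
#' gt <- default_gradient_table()
#' d <- c(dxx = 7e-4, dyy = 7e-4, dzz = 7e-4, dxy = 0, dxz = 0, dyz = 0)
#' s <- as.vector(exp(design_matrix(gt) %*% c(log(1000), d)))
#' fit_tensor_voxel(s, gt)$dxx
#' @export
fit_tensor_voxel <- function(signals, gtab) {
  check_fit_ready(gtab)
  if (length(signals) != length(gtab)) {
    abort("Signal/volume count mismatch.", class = "alps_format_error")
  }
  floor_val <- 1e-6 * max(signals)
  y <- log(pmax(signals, floor_val))
  X <- design_matrix(gtab)
  theta <- qr.solve(X, y)
  out <- as.list(theta[TENSOR_COMPONENTS])
  out$s0 <- exp(unname(theta["log_s0"]))
  out
}

#' Fit diffusion tensors over a volume
#'
#' Vectorised OLS of the log-linear tensor model across all masked voxels,
#' with the derived maps the ALPS method reads: FA, MD and the axis
#' diffusivities Dxx/Dyy/Dzz (tensor diagonal in the anatomical frame, not
#' eigenvalues), plus a colour-FA volume FA * |e1|.
#'
#' @param dataset An `alps_dwi`.
#' @param mask Logical 3D array on the dataset grid, or `NULL` for all
#'   voxels.
#' @return An `alps_tensor_field`: tensor component array
#'   `(x, y, z, 6)`, `s0`, scalar maps, `color_fa`, the mask and the grid
#'   geometry.
#' @export
fit_tensor_volume <- function(dataset, mask = NULL) {
  stopifnot(inherits(dataset, "alps_dwi"))
  check_fit_ready(dataset$gtab)
  dims <- dim(dataset$signal)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!identical(dim(mask), dims)) {
    abort("Mask grid does not match the dataset grid.",
          class = "alps_validation_error")
  }
  idx <- which(mask)
  if (!length(idx)) abort("Empty mask.", class = "alps_validation_error")

  nvol <- dim(dataset$signal)[4]
  sig <- matrix(dataset$signal, ncol = nvol)[idx, , drop = FALSE]
  floor_val <- 1e-6 * max(sig)
  n_clamped <- sum(sig < floor_val)
  if (n_clamped > 0) {
    inform(sprintf("Clamped %d non-positive/low signal value(s) before log.",
                   n_clamped))
  }
  y <- log(pmax(sig, floor_val))
  X <- design_matrix(dataset$gtab)
  theta <- t(qr.solve(X, t(y)))          # n_voxel x 7

  comp <- function(name, vals) {
    a <- array(NA_real_, dims)
    a[idx] <- vals
    a
  }
  tensor <- array(NA_real_, c(dims, 6),
                  dimnames = list(NULL, NULL, NULL, TENSOR_COMPONENTS))
  for (k in seq_along(TENSOR_COMPONENTS)) {
    tensor[, , , k][idx] <- theta[, TENSOR_COMPONENTS[k]]
  }
  scal <- tensor_scalars(theta[, TENSOR_COMPONENTS, drop = FALSE])
  maps <- list(
    fa = comp("fa", scal$fa),
    md = comp("md", scal$md),
    dxx = comp("dxx", theta[, "dxx"]),
    dyy = comp("dyy", theta[, "dyy"]),
    dzz = comp("dzz", theta[, "dzz"]))
  color_fa <- array(NA_real_, c(dims, 3),
                    dimnames = list(NULL, NULL, NULL, c("r", "g", "b")))
  for (k in 1:3) color_fa[, , , k][idx] <- scal$color[, k]

  structure(list(
    tensor = tensor,
    s0 = comp("s0", exp(theta[, "log_s0"])),
    mask = mask,
    maps = maps,
    color_fa = color_fa,
    voxel_size = dataset$voxel_size,
    origin = dataset$origin,
    n_clamped = n_clamped), class = "alps_tensor_field")
}

# Vectorised FA / MD / colour-FA over an n x 6 tensor-component matrix.
tensor_scalars <- function(D) {
  n <- nrow(D)
  md <- (D[, "dxx"] + D[, "dyy"] + D[, "dzz"]) / 3
  fa <- numeric(n)
  color <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    M <- tensor_to_matrix(D[i, ])
    eg <- eigen(M, symmetric = TRUE)
    lam <- pmax(eg$values, 0)            # clip negatives for FA only
    fa[i] <- fa_from_eigenvalues(lam)
    color[i, ] <- fa[i] * abs(eg$vectors[, 1])
  }
  list(fa = fa, md = md, color = color)
}

fa_from_eigenvalues <- function(lam) {
  ss <- sum(lam^2)
  if (ss == 0) return(0)
  min(1, max(0, sqrt(3 / 2 * sum((lam - mean(lam))^2) / ss)))
}

as_tensor_vector <- function(tensor) {
  if (is.list(tensor)) tensor <- unlist(tensor[TENSOR_COMPONENTS])
  if (is.matrix(tensor) && all(dim(tensor) == c(3, 3))) {
    tensor <- c(tensor[1, 1], tensor[2, 2], tensor[3, 3],
                tensor[1, 2], tensor[1, 3], tensor[2, 3])
  }
  stopifnot(length(tensor) == 6, all(is.finite(tensor)))
  setNames(as.numeric(tensor), TENSOR_COMPONENTS)
}

#' Tensor-derived scalars
#'
#' `fa()` is the normalised eigenvalue dispersion clamped to `[0, 1]`
#' (negative eigenvalues are clipped to 0 first; an all-zero tensor has
#' FA 0). `md()` is trace/3. `axis_diffusivities()` returns the tensor
#' DIAGONAL in the anatomical frame — the quantities Eq.-style ALPS ratios
#' consume — which, unlike FA, are not rotation invariant.
#'
#' @param tensor A length-6 vector/list `(dxx, dyy, dzz, dxy, dxz, dyz)`
#'   or a symmetric 3 x 3 matrix, mm^2/s.
#' @return `fa()`: scalar in `[0, 1]`; `md()`: mm^2/s;
#'   `axis_diffusivities()`: named numeric `(dxx, dyy, dzz)`.
#' @export
fa <- function(tensor) {
  d <- as_tensor_vector(tensor)
  lam <- pmax(eigen(tensor_to_matrix(d), symmetric = TRUE,
                    only.values = TRUE)$values, 0)
  fa_from_eigenvalues(lam)
}

#' @rdname fa
#' @export
md <- function(tensor) {
  d <- as_tensor_vector(tensor)
  unname((d["dxx"] + d["dyy"] + d["dzz"]) / 3)
}

#' @rdname fa
#' @export
axis_diffusivities <- function(tensor) {
  as_tensor_vector(tensor)[c("dxx", "dyy", "dzz")]
}

#' Colour-FA triple of a tensor
#'
#' `(R, G, B) = FA * (|e1_x|, |e1_y|, |e1_z|)` with `e1` the principal
#' eigenvector: red marks x-dominant (subcortical), green y-dominant
#' (association) and blue z-dominant (projection) fibre orientation.
#'
#' @inheritParams fa
#' @return Named numeric `(r, g, b)`, each in `[0, 1]`.
#' @export
color_fa <- function(tensor) {
  d <- as_tensor_vector(tensor)
  eg <- eigen(tensor_to_matrix(d), symmetric = TRUE)
  f <- fa_from_eigenvalues(pmax(eg$values, 0))
  setNames(f * abs(eg$vectors[, 1]), c("r", "g", "b"))
}

#' @export
print.alps_tensor_field <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<alps_tensor_field> %d x %d x %d grid, %d voxels fitted (%d clamped)\n",
    d[1], d[2], d[3], sum(x$mask), x$n_clamped))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.alps_tensor_field <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  lin <- which(x$mask)
  tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    x_mm = axis_world(dim(x$mask)[1], x$voxel_size[1], x$origin[1])[idx[, 1]],
    y_mm = axis_world(dim(x$mask)[2], x$voxel_size[2], x$origin[2])[idx[, 2]],
    z_mm = axis_world(dim(x$mask)[3], x$voxel_size[3], x$origin[3])[idx[, 3]],
    dxx = x$tensor[, , , "dxx"][lin],
    dyy = x$tensor[, , , "dyy"][lin],
    dzz = x$tensor[, , , "dzz"][lin],
    dxy = x$tensor[, , , "dxy"][lin],
    dxz = x$tensor[, , , "dxz"][lin],
    dyz = x$tensor[, , , "dyz"][lin],
    fa = x$maps$fa[lin],
    md = x$maps$md[lin])
}
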