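#' Diffusion-encoding gradient tables
#'
#' A gradient table pairs one b-value (s/mm^2) with one unit gradient
#' direction per DWI volume. Directions for b > 0 volumes are normalised to
#' unit length at construction; b = 0 volumes carry the zero vector.
#'
#' @param bvals Numeric vector of b-values, one per volume (s/mm^2).
#' @param bvecs Numeric matrix of gradient directions, either n x 3 or the
#'   FSL 3 x n layout (auto-detected by shape; a 3-column layout with a
#'   non-3 row count is taken as n x 3).
#' @return An object of class `alps_gradient_table`: a list with `bvals`
#'   (length n) and `bvecs` (n x 3, rows unit-norm where bval > 0).
#' @examples
#' gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(2, 0, 0)))
#' gt$bvecs[2, ]  # normalised to (1, 0, 0)
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) == 3 && ncol(bvecs) != 3) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3) {
    abort("`bvecs` must have 3 components per direction.", class = "alps_format_error")
  }
  if (length(bvals) != nrow(bvecs)) {
    abort(sprintf(
      "Volume count mismatch: %d b-values but %d gradient directions.",
      length(bvals), nrow(bvecs)), class = "alps_format_error")
  }
  if (any(!is.finite(bvals)) || any(bvals < 0)) {
    abort("b-values must be finite and non-negative.", class = "alps_validation_error")
  }
  nrm <- sqrt(rowSums(bvecs^2))
  b0 <- bvals == 0
  if (any(!b0 & nrm == 0)) {
    abort("Zero gradient direction on a diffusion-weighted volume.",
          class = "alps_validation_error")
  }
  bvecs[!b0, ] <- bvecs[!b0, , drop = FALSE] / nrm[!b0]
  bvecs[b0, ] <- 0
  structure(list(bvals = bvals, bvecs = unname(bvecs)),
            class = "alps_gradient_table")
}

#' @export
length.alps_gradient_table <- function(x) length(x$bvals)

#' @export
print.alps_gradient_table <- function(x, ...) {
  cat(sprintf("<alps_gradient_table> %d volumes (%d b0, b up to %g s/mm^2)\n",
              length(x), sum(x$bvals == 0), max(x$bvals)))
  invisible(x)
}

# 13 unit directions from a fixed electrostatic-repulsion optimisation
# (antipodally symmetric energy), frozen so the default acquisition scheme
# is reproducible. Max |cos| between distinct lines is 0.805.
ALPS_DIRECTIONS_13 <- rbind(
  c(0.0571724900, 0.2749024073, 0.9597707918),
  c(-0.2736926709, -0.2644147363, 0.9247578976),
  c(0.5423375046, -0.2673876183, 0.7964759210),
  c(-0.6045464330, 0.4448912930, 0.6607536210),
  c(0.6412935113, 0.4140166655, 0.6460130286),
  c(-0.0168142271, 0.8227462562, 0.5681600828),
  c(0.2439618972, -0.7933107808, 0.5577997830),
  c(-0.4945622673, -0.6976113321, 0.5184077480),
  c(-0.9029332388, -0.0810629755, 0.4220667723),
  c(0.9530265802, -0.2043311263, 0.2235824863),
  c(0.8122534844, 0.5793107789, 0.0681417525),
  c(-0.6278722433, 0.7774593638, 0.0365155259),
  c(-0.1541100143, -0.9880057763, 0.0097308574))

#' Default 14-volume acquisition scheme
#'
#' One unweighted (b = 0) volume followed by 13 non-collinear directions at
#' b = 1000 s/mm^2, matching the single-shell clinical DTI-ALPS protocol.
#' The direction set is a fixed electrostatic-repulsion table.
#'
#' @param b Diffusion weighting for the encoded volumes (s/mm^2).
#' @return An `alps_gradient_table` with 14 volumes.
#' @export
default_gradient_table <- function(b = 1000) {
  gradient_table(c(0, rep(b, nrow(ALPS_DIRECTIONS_13))),
                 rbind(c(0, 0, 0), ALPS_DIRECTIONS_13))
}

#' Log-linear tensor design matrix
#'
#' Maps the parameter vector (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) to the
#' log-signal of each volume under the single-tensor model
#' ln S = ln S0 - b g' D g. The b = 0 rows have zero diffusion coefficients.
#'
#' @param gtab An `alps_gradient_table`.
#' @return Numeric matrix with one row per volume and columns
#'   `log_s0`, `dxx`, `dyy`, `dzz`, `dxy`, `dxz`, `dyz`.
#' @export
design_matrix <- function(gtab) {
  stopifnot(inherits(gtab, "alps_gradient_table"))
  g <- gtab$bvecs
  b <- gtab$bvals
  X <- cbind(
    log_s0 = 1,
    dxx = -b * g[, 1]^2,
    dyy = -b * g[, 2]^2,
    dzz = -b * g[, 3]^2,
    dxy = -2 * b * g[, 1] * g[, 2],
    dxz = -2 * b * g[, 1] * g[, 3],
    dyz = -2 * b * g[, 2] * g[, 3])
  X
}

# Fit-readiness: at least one b0 and a full-rank diffusion design
# (>= 6 non-collinear directions).
check_fit_ready <- function(gtab) {
  if (!any(gtab$bvals == 0)) {
    abort("Gradient table has no b = 0 volume; tensor fitting needs one.",
          class = "alps_validation_error")
  }
  X <- design_matrix(gtab)
  if (qr(X)$rank < ncol(X)) {
    dirs <- apply(gtab$bvecs[gtab$bvals > 0, , drop = FALSE], 1,
                  function(v) sprintf("(%.3f, %.3f, %.3f)", v[1], v[2], v[3]))
    abort(paste0(
      "Rank-deficient diffusion design: the non-zero-b direction set {",
      paste(unique(dirs), collapse = ", "),
      "} does not span the 6 tensor components (need >= 6 non-collinear directions)."),
      class = "alps_estimation_error")
  }
  invisible(gtab)
}

read_bval <- function(path) {
  as.numeric(scan(path, quiet = TRUE))
}

read_bvec <- function(path) {
  rows <- readLines(path)
  rows <- rows[nzchar(trimws(rows))]
  vals <- lapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
  len <- unique(vapply(vals, length, integer(1)))
  if (length(len) != 1) {
    abort("Ragged bvec file: rows have unequal lengths.", class = "alps_format_error")
  }
  m <- do.call(rbind, vals)
  if (nrow(m) == 3) {
    t(m)                    # FSL dialect: 3 rows x N columns
  } else if (ncol(m) == 3) {
    warn("bvec file is in N x 3 layout; transposing to the FSL convention.")
    m
  } else {
    abort(sprintf("bvec file must be 3 x N or N x 3, got %d x %d.",
                  nrow(m), ncol(m)), class = "alps_format_error")
  }
}

write_bval <- function(bvals, path) {
  writeLines(paste(format(bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), path)
}

write_bvec <- function(bvecs, path) {
  lines <- apply(t(bvecs), 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, path)
}
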