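# Internal helpers shared across modules.

# Quantile transform onto a normal truncated to [lower, upper] whose
# TRUNCATED mean and SD equal the targets (the underlying Gaussian
# parameters are moment-matched first). Monotone in z, so rank
# correlations set on the latent Gaussian scale survive the truncation
# exactly.
truncnorm_transform <- function(z, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), length(z)))
  }
  par <- truncnorm_params(mean, sd, lower, upper)
  p_lo <- pnorm(lower, par[1], par[2])
  p_hi <- pnorm(upper, par[1], par[2])
  p <- pnorm(z)
  q <- qnorm(p_lo + p * (p_hi - p_lo), par[1], par[2])
  pmin(pmax(q, lower), upper)
}

# Closed-form mean/SD of a truncated normal.
truncnorm_moments <- function(mu, s, lower, upper) {
  a <- (lower - mu) / s
  b <- (upper - mu) / s
  Z <- pnorm(b) - pnorm(a)
  pa <- stats::dnorm(a)
  pb <- stats::dnorm(b)
  apa <- if (is.finite(a)) a * pa else 0
  bpb <- if (is.finite(b)) b * pb else 0
  m <- mu + s * (pa - pb) / Z
  v <- s^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

.truncnorm_cache <- new.env(parent = emptyenv())

# Underlying Gaussian (mu, sigma) whose [lower, upper]-truncation has the
# requested mean and SD; identity when truncation mass is negligible.
truncnorm_params <- function(mean, sd, lower, upper) {
  if ((!is.finite(lower) || lower < mean - 6 * sd) &&
      (!is.finite(upper) || upper > mean + 6 * sd)) {
    return(c(mean, sd))
  }
  key <- paste(mean, sd, lower, upper)
  hit <- .truncnorm_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), lower, upper)
    if (any(!is.finite(mo))) return(1e10)
    ((mo["mean"] - mean)^2 + (mo["sd"] - sd)^2) / sd^2
  }
  o <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  out <- c(o$par[1], exp(o$par[2]))
  assign(key, out, envir = .truncnorm_cache)
  out
}

# Deterministic sub-seed for a named stage, derived from one root seed.
# Keeps every stream below 2^31 - 1.
derive_seed <- function(seed, stage) {
  offsets <- c(phantom = 11L, dwi = 23L, cohort = 37L, stats = 53L,
               alps = 71L, noise = 89L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off * 9973) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# World coordinates of voxel centres along one axis (0-based indexing rule:
# world = voxel_size * index + origin; R arrays are 1-based so index = i - 1).
axis_world <- function(n, vox, origin) (seq_len(n) - 1) * vox + origin

default_origin <- function(dims, voxel_size) -(dims - 1) * voxel_size / 2

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
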