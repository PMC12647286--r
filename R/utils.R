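# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded simulation helpers do not perturb the global random stream.
#' A `NULL` seed evaluates `code` under the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# quantile function of a normal truncated to [lower, upper]; exact for the
# unbounded case so unbounded marginals stay an affine map of the latent draw
qtnorm <- function(p, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (is.infinite(lower) && is.infinite(upper)) {
    return(stats::qnorm(p, mean = mean, sd = sd))
  }
  pa <- stats::pnorm(lower, mean = mean, sd = sd)
  pb <- stats::pnorm(upper, mean = mean, sd = sd)
  stats::qnorm(pa + p * (pb - pa), mean = mean, sd = sd)
}

axis_index <- function(axis) {
  i <- match(axis, c("x", "y", "z"))
  if (any(is.na(i))) stop("axis must be one of 'x', 'y', 'z'", call. = FALSE)
  i
}

# cylindrically symmetric tensor with principal axis `axis`
axial_tensor <- function(axis, lambda_par, lambda_perp) {
  D <- diag(rep(lambda_perp, 3L))
  i <- axis_index(axis)
  D[i, i] <- lambda_par
  D
}

is_psd <- function(D, tol = 1e-12) {
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev), 1)
}

# pack/unpack symmetric 3x3 tensors as length-6 vectors
# order: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz
tensor_to_vec <- function(D) c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])

vec_to_tensor <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3L, 3L)
}

stop_stage <- function(stage, msg) {
  stop(sprintf("[stage %s] %s", stage, msg), call. = FALSE)
}
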