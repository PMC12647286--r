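# Single-tensor estimation by log-linear least squares and derived maps.

#' Fit a diffusion tensor per voxel by log-linear least squares
#'
#' Estimates the six unique components of a symmetric diffusion tensor in
#' every voxel by ordinary least squares on the log-signal model
#' `ln(S/S0) = -b g' D g`. `S0` is the mean of the `b = 0` volumes (signal
#' averaging of the duplicate non-diffusion images). Signals at or below
#' zero — possible under magnitude noise — are clamped to `1e-6 * S0` before
#' the logarithm and the voxel is flagged. The estimator is exact for
#' noiseless single-compartment data.
#'
#' @param dwi a `dwi_volume` from [simulate_dwi()] or [read_dwi()].
#' @return An object of class `tensor_field`: list with `D` (4D array,
#'   last dimension the components `Dxx, Dyy, Dzz, Dxy, Dxz, Dyz` in
#'   mm^2/s), `s0` (3D array), `clipped` (logical 3D array of flagged
#'   voxels), `grid_dim` and `labels` (carried through if present).
#' @examples
#' ph <- build_phantom(phantom_spec(grid_dim = c(8, 8, 8), roi_size = 1,
#'   roi_origin = list(proj_L = c(1, 4, 5), proj_R = c(7, 4, 5),
#'     assoc_L = c(1, 4, 2), assoc_R = c(7, 4, 2), ccg = c(4, 7, 4),
#'     ccb = c(4, 4, 7), ccs = c(4, 1, 4)), pvs_fraction = 0))
#' field <- fit_tensor(simulate_dwi(ph, snr = Inf))
#' @export
fit_tensor <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  scheme <- dwi$scheme
  grid_dim <- dim(dwi$signal)[1:3]
  nvox <- prod(grid_dim)
  V <- matrix(dwi$signal, nrow = nvox)
  if (any(!is.finite(V))) stop("DWI signal contains non-finite values", call. = FALSE)
  b0 <- which(scheme$bvalues == 0)
  dwi_idx <- which(scheme$bvalues > 0)
  s0 <- rowMeans(V[, b0, drop = FALSE])
  if (any(s0 <= 0)) stop("all-zero voxel: S0 <= 0", call. = FALSE)
  S <- V[, dwi_idx, drop = FALSE]
  floor_val <- 1e-6 * s0
  clipped <- rowSums(S <= floor_val) > 0
  S <- pmax(S, floor_val)
  X <- fit_design(scheme)
  if (qr(X)$rank < 6L) stop("rank-deficient design matrix", call. = FALSE)
  L <- log(S / s0)
  B <- t(qr.coef(qr(X), t(L)))           # nvox x 6, tensor components
  colnames(B) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  structure(list(D = array(B, dim = c(grid_dim, 6L),
                           dimnames = list(NULL, NULL, NULL, colnames(B))),
                 s0 = array(s0, dim = grid_dim),
                 clipped = array(clipped, dim = grid_dim),
                 grid_dim = grid_dim,
                 labels = dwi$labels),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("Tensor field: %s voxels, %d flagged (clipped signal)\n",
              paste(x$grid_dim, collapse = "x"), sum(x$clipped)))
  invisible(x)
}

# sorted (descending) eigenvalues of packed symmetric tensors, nvox x 3
tensor_eigenvalues <- function(D6) {
  t(vapply(seq_len(nrow(D6)), function(i) {
    sort(eigen(vec_to_tensor(D6[i, ]), symmetric = TRUE,
               only.values = TRUE)$values, decreasing = TRUE)
  }, numeric(3L)))
}

# FA from eigenvalue triples (rows); negative eigenvalues are clamped to 0
# here only — axial diffusivities elsewhere stay unclamped
fa_from_eigenvalues <- function(L) {
  L <- pmax(L, 0)
  lbar <- rowMeans(L)
  num <- rowSums((L - lbar)^2)
  den <- rowSums(L^2)
  fa <- sqrt(1.5) * sqrt(num) / sqrt(den)
  fa[den == 0] <- 0
  fa
}

#' Derive diffusivity and anisotropy maps from a tensor field
#'
#' Computes the axial diffusivity maps `Dxx`, `Dyy`, `Dzz` (tensor diagonal,
#' reported unclamped because they feed the ALPS ratios), mean diffusivity
#' `MD = trace/3`, sorted eigenvalues and fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((l - lbar)^2)) / sqrt(sum(l^2))`. Negative
#' eigenvalues (noise-induced) are clamped to zero inside the FA computation
#' only, and such voxels are flagged in `negative_ev`.
#'
#' @param field a [fit_tensor()] result.
#' @return An object of class `diffusivity_maps`: list of 3D arrays `Dxx`,
#'   `Dyy`, `Dzz`, `MD`, `FA`, `L1`, `L2`, `L3`, logical `negative_ev` and
#'   `clipped`, plus `grid_dim` and `labels`.
#' @export
tensor_maps <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  grid_dim <- field$grid_dim
  D6 <- matrix(field$D, nrow = prod(grid_dim), ncol = 6L)
  if (any(!is.finite(D6))) stop("tensor field contains non-finite values", call. = FALSE)
  L <- tensor_eigenvalues(D6)
  fa <- fa_from_eigenvalues(L)
  as3d <- function(v) array(v, dim = grid_dim)
  structure(list(Dxx = as3d(D6[, 1]), Dyy = as3d(D6[, 2]), Dzz = as3d(D6[, 3]),
                 MD = as3d(rowMeans(L)),
                 FA = as3d(fa),
                 L1 = as3d(L[, 1]), L2 = as3d(L[, 2]), L3 = as3d(L[, 3]),
                 negative_ev = as3d(L[, 3] < 0),
                 clipped = field$clipped,
                 grid_dim = grid_dim,
                 labels = field$labels),
            class = "diffusivity_maps")
}

#' @export
print.diffusivity_maps <- function(x, ...) {
  cat(sprintf("Diffusivity maps: %s voxels; FA range [%.3f, %.3f]; %d voxels with negative eigenvalues\n",
              paste(x$grid_dim, collapse = "x"),
              min(x$FA), max(x$FA), sum(x$negative_ev)))
  invisible(x)
}
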