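# Shared fixtures: a small fast phantom, and independent single-voxel
# signal/fit oracles used to cross-check the package's vectorised paths.

# 8^3 grid with single-voxel regions: two orders of magnitude faster than
# the default phantom, same geometry
tiny_phantom_spec <- function(...) {
  phantom_spec(grid_dim = c(8L, 8L, 8L), roi_size = 1L,
               roi_origin = list(proj_L = c(2, 4, 5), proj_R = c(7, 4, 5),
                                 assoc_L = c(2, 4, 2), assoc_R = c(7, 4, 2),
                                 ccg = c(4, 7, 4), ccb = c(4, 4, 7),
                                 ccs = c(4, 1, 4)),
               ...)
}

# independent oracle: analytic mixture signal for one voxel
# comps: list of list(fraction, tensor)
oracle_signal <- function(comps, dirs, bvals, s0 = 100) {
  vapply(seq_along(bvals), function(j) {
    g <- dirs[j, ]
    s0 * sum(vapply(comps, function(cm) {
      cm$fraction * exp(-bvals[j] * drop(t(g) %*% cm$tensor %*% g))
    }, numeric(1)))
  }, numeric(1))
}

# independent oracle: log-linear LS tensor fit of one voxel's signals,
# written from the normal equations
oracle_fit_voxel <- function(signals, dirs, bvals) {
  b0 <- bvals == 0
  s0 <- mean(signals[b0])
  g <- dirs[!b0, , drop = FALSE]
  b <- bvals[!b0]
  X <- -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                  2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  y <- log(signals[!b0] / s0)
  stats::setNames(as.numeric(solve(t(X) %*% X, t(X) %*% y)),
                  c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz"))
}

# wrap raw signals of a single voxel as a dwi_volume for fit_tensor()
as_single_voxel_dwi <- function(signals, scheme, s0 = 100) {
  structure(list(signal = array(signals, dim = c(1L, 1L, 1L, length(signals))),
                 scheme = scheme, s0 = s0, snr = Inf, voxel_size = 2,
                 labels = NULL),
            class = "dwi_volume")
}

# fitted tensor components of one labelled voxel of a phantom
fit_phantom_region <- function(spec, region, snr = Inf, seed = NULL) {
  ph <- build_phantom(spec)
  dwi <- simulate_dwi(ph, snr = snr, seed = seed)
  fld <- fit_tensor(dwi)
  vox <- which(ph$labels == ph$region_codes[[region]])[1L]
  idx <- arrayInd(vox, dim(ph$labels))
  fld$D[idx[1], idx[2], idx[3], ]
}
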