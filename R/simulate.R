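# DWI signal simulation (multi-compartment monoexponential mixture, Rician
# noise) and rigid head-motion traces.

# noiseless attenuation of one region's mixture for every volume of a scheme:
# S/S0 = sum_i f_i exp(-b g' D_i g)
region_attenuation <- function(compartments, scheme) {
  Q <- design_matrix_rows(scheme$directions)   # n_vol x 6 quadratic forms
  att <- numeric(scheme$n_volumes)
  for (cm in compartments) {
    qf <- as.vector(Q %*% tensor_to_vec(cm$tensor))
    att <- att + cm$fraction * exp(-scheme$bvalues * qf)
  }
  att
}

#' Simulate a diffusion-weighted volume series from a phantom
#'
#' Generates the analytic compartment-mixture signal
#' `S = S0 * sum_i f_i exp(-b g' D_i g)` for every voxel and volume, then
#' applies Rician noise: the magnitude of the complex signal after adding
#' independent Gaussian noise of standard deviation `sigma = S0 / snr` to
#' both quadrature channels. With `snr = Inf` the noiseless signal is
#' returned. Output is bit-reproducible for a fixed seed.
#'
#' @param phantom a [build_phantom()] result.
#' @param scheme a [gradient_scheme()]; defaults to [default_gradient_scheme()].
#' @param snr signal-to-noise ratio `S0 / sigma`; `Inf` for noiseless.
#'   Defaults to the phantom spec's `snr`.
#' @param seed integer seed for the noise draw (ignored when noiseless).
#' @return An object of class `dwi_volume`: list with `signal` (4D array,
#'   x, y, z, volume), `scheme`, `s0`, `snr`, `voxel_size` and `labels`.
#' @examples
#' ph <- build_phantom(phantom_spec(grid_dim = c(8, 8, 8), roi_size = 1,
#'   roi_origin = list(proj_L = c(1, 4, 5), proj_R = c(7, 4, 5),
#'     assoc_L = c(1, 4, 2), assoc_R = c(7, 4, 2), ccg = c(4, 7, 4),
#'     ccb = c(4, 4, 7), ccs = c(4, 1, 4))))
#' dwi <- simulate_dwi(ph, snr = Inf)
#' @export
simulate_dwi <- function(phantom, scheme = default_gradient_scheme(),
                         snr = NULL, seed = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(scheme, "gradient_scheme"))
  snr <- snr %||% phantom$spec$snr
  if (!(is.numeric(snr) && length(snr) == 1L && snr > 0)) {
    stop("snr must be a single positive number (Inf for noiseless)", call. = FALSE)
  }
  s0 <- phantom$spec$s0
  labels <- phantom$labels
  nvox <- length(labels)
  code_of <- c(background = 0L, phantom$region_codes)
  sig <- matrix(0, nrow = nvox, ncol = scheme$n_volumes)
  for (region in names(phantom$compartments)) {
    vox <- which(as.vector(labels) == code_of[[region]])
    if (!length(vox)) next
    att <- region_attenuation(phantom$compartments[[region]], scheme)
    sig[vox, ] <- matrix(s0 * att, nrow = length(vox),
                         ncol = scheme$n_volumes, byrow = TRUE)
  }
  if (is.finite(snr)) {
    sigma <- s0 / snr
    sig <- with_seed(seed, {
      n1 <- matrix(stats::rnorm(nvox * scheme$n_volumes, sd = sigma), nvox)
      n2 <- matrix(stats::rnorm(nvox * scheme$n_volumes, sd = sigma), nvox)
      sqrt((sig + n1)^2 + n2^2)
    })
  }
  structure(list(signal = array(sig, dim = c(dim(labels), scheme$n_volumes)),
                 scheme = scheme, s0 = s0, snr = snr,
                 voxel_size = phantom$spec$voxel_size, labels = labels),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("DWI volume series: %dx%dx%d voxels, %d volumes, SNR %s\n",
              d[1], d[2], d[3], d[4],
              if (is.finite(x$snr)) format(x$snr) else "Inf (noiseless)"))
  invisible(x)
}

#' Simulate a rigid-body head-motion trace
#'
#' Gaussian random-walk motion: per-volume rigid parameters (3 translations
#' in mm, 3 rotations in radians) start at zero and accumulate independent
#' Gaussian increments. The default step sizes are calibrated so that a
#' cohort of traces has mean framewise displacement near 0.18 mm (see
#' [simulate_motion_cohort()]).
#'
#' @param n_volumes number of volumes (rows) in the trace.
#' @param step_sd_trans per-step translation SD (mm).
#' @param step_sd_rot per-step rotation SD (radians).
#' @param seed integer seed.
#' @return A `motion_trace`: numeric matrix `n_volumes` x 6 with columns
#'   `tx, ty, tz, rx, ry, rz`.
#' @export
simulate_motion <- function(n_volumes, step_sd_trans = 0.05,
                            step_sd_rot = 5e-4, seed = NULL) {
  stopifnot(n_volumes >= 1L, step_sd_trans >= 0, step_sd_rot >= 0)
  tr <- with_seed(seed, {
    steps <- cbind(
      matrix(stats::rnorm(3L * n_volumes, sd = step_sd_trans), ncol = 3L),
      matrix(stats::rnorm(3L * n_volumes, sd = step_sd_rot), ncol = 3L))
    steps[1L, ] <- 0
    apply(steps, 2L, cumsum)
  })
  tr <- matrix(tr, nrow = n_volumes, ncol = 6L)
  colnames(tr) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  class(tr) <- c("motion_trace", class(tr))
  tr
}

#' Simulate motion traces for a cohort of subjects
#'
#' Draws one [simulate_motion()] trace per subject, with per-subject
#' log-normal scaling of the step sizes (unit mean) to give realistic
#' between-subject spread of mean framewise displacement. The defaults are
#' calibrated to a cohort mean FD of about 0.18 mm with SD about 0.07 mm.
#'
#' @param n_subjects number of traces.
#' @param n_volumes volumes per trace; default matches the default 14-volume
#'   gradient scheme.
#' @param step_sd_trans,step_sd_rot population-level step SDs as in
#'   [simulate_motion()].
#' @param subject_sdlog SD of the log-normal per-subject scale factor
#'   (meanlog is set to `-subject_sdlog^2/2` so the scale has unit mean).
#' @param seed integer seed.
#' @return List of `motion_trace` matrices, length `n_subjects`.
#' @export
simulate_motion_cohort <- function(n_subjects, n_volumes = 14L,
                                   step_sd_trans = 0.05, step_sd_rot = 5e-4,
                                   subject_sdlog = 0.3763, seed = NULL) {
  stopifnot(n_subjects >= 1L, subject_sdlog >= 0)
  with_seed(seed, {
    scales <- stats::rlnorm(n_subjects, meanlog = -subject_sdlog^2 / 2,
                            sdlog = subject_sdlog)
    lapply(seq_len(n_subjects), function(i) {
      simulate_motion(n_volumes,
                      step_sd_trans = step_sd_trans * scales[i],
                      step_sd_rot = step_sd_rot * scales[i])
    })
  })
}

#' Write / read a motion trace as 6-column whitespace-delimited text
#'
#' Column order is translations (mm) then rotations (radians), one row per
#' volume, the layout produced by common eddy-current-correction tools.
#'
#' @param trace a motion trace matrix.
#' @param path output file.
#' @return `path` (write) or the trace matrix (read), invisibly for write.
#' @export
write_motion_trace <- function(trace, path) {
  utils::write.table(unclass(trace), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_trace
#' @export
read_motion_trace <- function(path) {
  tr <- as.matrix(utils::read.table(path))
  if (ncol(tr) != 6L) stop("motion trace must have 6 columns", call. = FALSE)
  dimnames(tr) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  class(tr) <- c("motion_trace", class(tr))
  tr
}
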