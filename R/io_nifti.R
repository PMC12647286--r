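# NIfTI interchange for DWI series, label maps and derived maps.

#' Write a simulated DWI series as NIfTI plus bvec/bval
#'
#' Writes `<prefix>.nii.gz` (4D signal), `<prefix>.bvec` / `<prefix>.bval`
#' (FSL layout) and, when labels are attached, `<prefix>_labels.nii.gz`.
#'
#' @param dwi a `dwi_volume`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_volume"))
  img <- RNifti::asNifti(dwi$signal, pixdim = rep(dwi$voxel_size, 3L))
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  write_gradient_scheme(dwi$scheme, prefix)
  if (!is.null(dwi$labels)) {
    lab <- RNifti::asNifti(dwi$labels + 0L, pixdim = rep(dwi$voxel_size, 3L))
    RNifti::writeNifti(lab, paste0(prefix, "_labels.nii.gz"), datatype = "int16")
  }
  invisible(prefix)
}

#' Read a DWI series written by [write_dwi()]
#'
#' @param prefix path prefix as used by [write_dwi()].
#' @return A `dwi_volume` (with `snr = NA`, unknown for external data).
#' @export
read_dwi <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  scheme <- read_gradient_scheme(prefix)
  sig <- array(as.numeric(img), dim = dim(img))
  if (length(dim(sig)) != 4L || dim(sig)[4L] != scheme$n_volumes) {
    stop("signal volume count does not match the gradient scheme", call. = FALSE)
  }
  if (any(sig < 0)) stop("negative signal in DWI volume", call. = FALSE)
  labels_path <- paste0(prefix, "_labels.nii.gz")
  labels <- NULL
  if (file.exists(labels_path)) {
    lab <- RNifti::readNifti(labels_path)
    labels <- array(as.integer(lab), dim = dim(lab))
  }
  b0 <- scheme$bvalues == 0
  s0 <- mean(sig[, , , b0, drop = FALSE])
  structure(list(signal = sig, scheme = scheme, s0 = s0, snr = NA_real_,
                 voxel_size = RNifti::pixdim(img)[1L], labels = labels),
            class = "dwi_volume")
}

#' Write diffusivity maps as one 3D NIfTI volume per map
#'
#' Writes `<prefix>_<map>.nii.gz` for Dxx, Dyy, Dzz, MD and FA.
#'
#' @param maps a [tensor_maps()] result.
#' @param prefix output path prefix.
#' @param voxel_size voxel edge in mm.
#' @return `prefix`, invisibly.
#' @export
write_maps <- function(maps, prefix, voxel_size = 2) {
  stopifnot(inherits(maps, "diffusivity_maps"))
  for (m in c("Dxx", "Dyy", "Dzz", "MD", "FA")) {
    img <- RNifti::asNifti(maps[[m]], pixdim = rep(voxel_size, 3L))
    RNifti::writeNifti(img, paste0(prefix, "_", m, ".nii.gz"))
  }
  invisible(prefix)
}
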