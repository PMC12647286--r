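# Two-compartment diffusion phantoms with ALPS-ROI / corpus-callosum geometry.
#
# Coordinate convention throughout: axis order (x, y, z) =
# (right-left, anterior-posterior, inferior-superior), so Dxx/Dyy/Dzz always
# refer to these anatomical axes.

# region codes shared by label maps and regional summaries
.alpsim_regions <- c(proj_L = 1L, proj_R = 2L, assoc_L = 3L, assoc_R = 4L,
                     ccg = 5L, ccb = 6L, ccs = 7L)

# fixed fiber / medullary-vessel axes per region:
#  - projection fibers (corticospinal) run inferior-superior (z), association
#    fibers (superior longitudinal fasciculus) anterior-posterior (y), and in
#    both ALPS regions the medullary vessels run right-left (x);
#  - corpus callosum fibers run right-left (x) in genu, body and splenium,
#    with vessels anterior-posterior (y) in genu/splenium and
#    inferior-superior (z) in the body.
.alpsim_fiber_axis  <- c(proj_L = "z", proj_R = "z", assoc_L = "y", assoc_R = "y",
                         ccg = "x", ccb = "x", ccs = "x")
.alpsim_vessel_axis <- c(proj_L = "x", proj_R = "x", assoc_L = "x", assoc_R = "x",
                         ccg = "y", ccb = "z", ccs = "y")

# default 2x2x2-voxel ROI cubes inside the 20^3 grid (start voxel of each
# cube; purely schematic placement, no anatomical template exists for it)
.alpsim_roi_origin <- list(proj_L = c(4L, 10L, 12L), proj_R = c(16L, 10L, 12L),
                           assoc_L = c(3L, 10L, 8L), assoc_R = c(17L, 10L, 8L),
                           ccg = c(10L, 15L, 10L), ccb = c(10L, 10L, 14L),
                           ccs = c(10L, 4L, 10L))

#' Specify a synthetic diffusion phantom
#'
#' Defines the geometry and diffusion properties of a voxel phantom carrying
#' the regions used by the ALPS analysis: left/right projection and
#' association ALPS regions and the genu, body and splenium of the corpus
#' callosum. Each labelled voxel mixes a fiber compartment (cylindrical
#' tensor along the region's fiber axis, weight `1 - pvs_fraction`) with a
#' perivascular compartment (cylindrical tensor along the region's
#' medullary-vessel axis, weight `pvs_fraction`). Fiber and vessel axes are
#' fixed anatomical facts of the geometry and are not configurable:
#' projection fibers run along z and association fibers along y with vessels
#' along x, while callosal fibers run along x with vessels along y
#' (genu/splenium) or z (body).
#'
#' @param grid_dim integer triple, phantom grid size in voxels.
#' @param roi_size edge length (voxels) of each cubic region.
#' @param roi_origin named list of integer triples, start voxel of each
#'   region cube; defaults place seven non-overlapping cubes in a rough
#'   anatomical arrangement.
#' @param lambda_par,lambda_perp fiber-compartment axial and radial
#'   eigenvalues (mm^2/s).
#' @param pvs_fraction perivascular volume fraction `f` in \[0, 1\], either a
#'   single value or a named vector/list with one entry per region.
#' @param pvs_lambda_par,pvs_lambda_perp perivascular-compartment eigenvalues
#'   (mm^2/s); the fast axial value models facilitated diffusion along the
#'   perivascular space.
#' @param d_background isotropic diffusivity of unlabelled voxels (mm^2/s).
#' @param s0 non-diffusion-weighted signal amplitude (arbitrary units).
#' @param snr default signal-to-noise ratio `s0 / sigma` used by
#'   [simulate_dwi()] when none is given; `Inf` means noiseless.
#' @param voxel_size voxel edge length in mm (isotropic).
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(pvs_fraction = 0.1)
#' ph <- build_phantom(spec)
#' @export
phantom_spec <- function(grid_dim = c(20L, 20L, 20L),
                         roi_size = 2L,
                         roi_origin = NULL,
                         lambda_par = 1.7e-3,
                         lambda_perp = 0.3e-3,
                         pvs_fraction = 0.1,
                         pvs_lambda_par = 3.0e-3,
                         pvs_lambda_perp = 0.3e-3,
                         d_background = 0.8e-3,
                         s0 = 100,
                         snr = 20,
                         voxel_size = 2) {
  grid_dim <- as.integer(grid_dim)
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 1L), roi_size >= 1L)
  roi_origin <- roi_origin %||% .alpsim_roi_origin
  regions <- names(.alpsim_regions)
  unknown <- setdiff(names(roi_origin), regions)
  if (length(unknown)) {
    stop("unknown region label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!setequal(names(roi_origin), regions)) {
    stop("roi_origin must name all regions: ", paste(regions, collapse = ", "),
         call. = FALSE)
  }
  f <- pvs_fraction
  if (length(f) == 1L && is.null(names(f))) {
    f <- stats::setNames(rep(as.numeric(f), length(regions)), regions)
  } else {
    f <- unlist(f)
    if (!setequal(names(f), regions)) {
      stop("per-region pvs_fraction must name all regions", call. = FALSE)
    }
    f <- f[regions]
  }
  if (any(f < 0 | f > 1)) stop("pvs_fraction must lie in [0, 1]", call. = FALSE)
  if (!(lambda_par >= lambda_perp && lambda_perp >= 0)) {
    stop("fiber eigenvalues must satisfy lambda_par >= lambda_perp >= 0", call. = FALSE)
  }
  if (!(pvs_lambda_par >= pvs_lambda_perp && pvs_lambda_perp >= 0)) {
    stop("perivascular eigenvalues must satisfy pvs_lambda_par >= pvs_lambda_perp >= 0",
         call. = FALSE)
  }
  stopifnot(d_background >= 0, s0 > 0, snr > 0, voxel_size > 0)
  for (r in regions) {
    o <- as.integer(roi_origin[[r]])
    if (length(o) != 3L || any(o < 1L) || any(o + roi_size - 1L > grid_dim)) {
      stop("region '", r, "' does not fit inside the grid", call. = FALSE)
    }
  }
  structure(list(grid_dim = grid_dim, roi_size = as.integer(roi_size),
                 roi_origin = roi_origin,
                 fiber_axis = .alpsim_fiber_axis,
                 vessel_axis = .alpsim_vessel_axis,
                 lambda_par = lambda_par, lambda_perp = lambda_perp,
                 pvs_fraction = f,
                 pvs_lambda_par = pvs_lambda_par,
                 pvs_lambda_perp = pvs_lambda_perp,
                 d_background = d_background, s0 = s0, snr = snr,
                 voxel_size = voxel_size),
            class = "phantom_spec")
}

#' Build the voxelwise compartment field of a phantom
#'
#' Realises a [phantom_spec()] as an integer label map plus a per-region
#' compartment mixture. Background voxels get a single isotropic
#' compartment; each labelled voxel gets the region's fiber compartment with
#' weight `1 - f` and perivascular compartment with weight `f`. All
#' compartment tensors are checked to be positive semi-definite and fractions
#' to sum to one.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom`: list with `labels` (3D integer
#'   array), `region_codes`, `compartments` (named list; per region a list of
#'   `list(fraction, tensor)`), and the originating `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- array(0L, dim = spec$grid_dim)
  for (r in names(.alpsim_regions)) {
    o <- as.integer(spec$roi_origin[[r]])
    idx <- lapply(1:3, function(a) o[a]:(o[a] + spec$roi_size - 1L))
    labels[idx[[1]], idx[[2]], idx[[3]]] <- .alpsim_regions[[r]]
  }
  comps <- list(
    background = list(list(fraction = 1,
                           tensor = diag(rep(spec$d_background, 3L))))
  )
  for (r in names(.alpsim_regions)) {
    f <- spec$pvs_fraction[[r]]
    fib <- axial_tensor(spec$fiber_axis[[r]], spec$lambda_par, spec$lambda_perp)
    pvs <- axial_tensor(spec$vessel_axis[[r]], spec$pvs_lambda_par,
                        spec$pvs_lambda_perp)
    cl <- list()
    if (f < 1) cl <- c(cl, list(list(fraction = 1 - f, tensor = fib)))
    if (f > 0) cl <- c(cl, list(list(fraction = f, tensor = pvs)))
    comps[[r]] <- cl
  }
  for (region in names(comps)) {
    fr <- vapply(comps[[region]], `[[`, numeric(1), "fraction")
    if (abs(sum(fr) - 1) > 1e-9) {
      stop("compartment fractions in region '", region, "' do not sum to 1",
           call. = FALSE)
    }
    for (cm in comps[[region]]) {
      if (!is_psd(cm$tensor)) {
        stop("non-positive-semi-definite tensor in region '", region, "'",
             call. = FALSE)
      }
    }
  }
  structure(list(labels = labels, region_codes = .alpsim_regions,
                 compartments = comps, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Diffusion phantom: %s grid, %d labelled voxels in %d regions\n",
              paste(dim(x$labels), collapse = "x"),
              sum(x$labels > 0L), length(x$region_codes)))
  f <- x$spec$pvs_fraction
  cat(sprintf("  perivascular fraction: %s\n",
              if (length(unique(f)) == 1L) format(f[[1]])
              else paste(names(f), format(f), sep = "=", collapse = ", ")))
  invisible(x)
}
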