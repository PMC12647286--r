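# Regional aggregation, ALPS and corpus-callosum variant indices, session
# deltas, framewise displacement.

#' Regional mean diffusivities and FA
#'
#' Averages the directional diffusivity maps over each analysis region.
#' Left and right ALPS regions of the same class are pooled into single
#' `proj` and `assoc` regions before averaging, so one value per class feeds
#' the index ratios. The corpus-callosum regions `ccg`, `ccb`, `ccs` are
#' summarised individually.
#'
#' @param maps a [tensor_maps()] result.
#' @param labels integer 3D label array on the same grid, coded as in
#'   [build_phantom()] (1/2 projection L/R, 3/4 association L/R, 5 genu,
#'   6 body, 7 splenium); defaults to the labels carried by `maps`.
#' @return An object of class `regional_diffusivity`: named list with
#'   `projDxx ... ccsDzz`, `projFA ... ccsFA`, `projMD ... ccsMD` and a
#'   `voxels` count per region.
#' @export
regional_means <- function(maps, labels = NULL) {
  stopifnot(inherits(maps, "diffusivity_maps"))
  labels <- labels %||% maps$labels
  if (is.null(labels)) stop("no label map supplied", call. = FALSE)
  if (!identical(dim(labels), as.integer(maps$grid_dim)) &&
      !identical(dim(labels), maps$grid_dim)) {
    stop("label map grid does not match the diffusivity maps", call. = FALSE)
  }
  pooled <- list(proj = c(1L, 2L), assoc = c(3L, 4L),
                 ccg = 5L, ccb = 6L, ccs = 7L)
  out <- list()
  voxels <- integer(0)
  for (region in names(pooled)) {
    vox <- which(labels %in% pooled[[region]])
    if (!length(vox)) stop("empty region: ", region, call. = FALSE)
    voxels[region] <- length(vox)
    for (m in c("Dxx", "Dyy", "Dzz", "FA", "MD")) {
      out[[paste0(region, m)]] <- mean(maps[[m]][vox])
    }
  }
  structure(c(out, list(voxels = voxels)), class = "regional_diffusivity")
}

#' @export
print.regional_diffusivity <- function(x, ...) {
  cat("Regional diffusivities (mm^2/s):\n")
  for (region in names(x$voxels)) {
    cat(sprintf("  %-5s (%2d voxels): Dxx %.3e  Dyy %.3e  Dzz %.3e  FA %.3f\n",
                region, x$voxels[[region]],
                x[[paste0(region, "Dxx")]], x[[paste0(region, "Dyy")]],
                x[[paste0(region, "Dzz")]], x[[paste0(region, "FA")]]))
  }
  invisible(x)
}

#' The ALPS index
#'
#' `ALPS = mean(projDxx, assocDxx) / mean(projDyy, assocDzz)`: the ratio of
#' perivascular-axis (x) diffusivity in the projection and association
#' regions to the diffusivity perpendicular to both the fibers and the
#' vessels. A value of 1 indicates no preferential diffusivity along the
#' perivascular axis.
#'
#' @param reg a [regional_means()] result (or any named list carrying
#'   `projDxx`, `assocDxx`, `projDyy`, `assocDzz`).
#' @return The ALPS index (unitless scalar).
#' @examples
#' alps_index(list(projDxx = 1.2e-3, assocDxx = 1.0e-3,
#'                 projDyy = 0.8e-3, assocDzz = 0.7e-3))  # 1.4667
#' @export
alps_index <- function(reg) {
  num <- mean(c(reg$projDxx, reg$assocDxx))
  den <- mean(c(reg$projDyy, reg$assocDzz))
  if (!is.finite(den) || den <= 0) stop("non-positive denominator", call. = FALSE)
  num / den
}

#' Corpus-callosum variant ALPS indices
#'
#' Ratios of diffusivity along the medullary-vessel direction to the
#' direction perpendicular to both the vessels and the left-right callosal
#' fibers: `ccgALPS = ccgDyy/ccgDzz` (genu), `ccbALPS = ccbDzz/ccbDyy`
#' (body), `ccsALPS = ccsDyy/ccsDzz` (splenium).
#'
#' @param reg a [regional_means()] result.
#' @param region one of `"ccg"`, `"ccb"`, `"ccs"`.
#' @return The variant index (unitless scalar).
#' @export
variant_alps <- function(reg, region = c("ccg", "ccb", "ccs")) {
  region <- match.arg(region)
  num_axis <- if (region == "ccb") "Dzz" else "Dyy"
  den_axis <- if (region == "ccb") "Dyy" else "Dzz"
  num <- reg[[paste0(region, num_axis)]]
  den <- reg[[paste0(region, den_axis)]]
  if (!is.finite(den) || den <= 0) stop("non-positive denominator", call. = FALSE)
  num / den
}

#' All four ALPS indices for one scan
#'
#' @param reg a [regional_means()] result.
#' @param session session label, `"4PM"` or `"9AM"`.
#' @return An object of class `alps_indices`: list with `alps`, `ccgALPS`,
#'   `ccbALPS`, `ccsALPS` and `session`.
#' @export
alps_indices <- function(reg, session = c("4PM", "9AM")) {
  session <- match.arg(session)
  structure(list(alps = alps_index(reg),
                 ccgALPS = variant_alps(reg, "ccg"),
                 ccbALPS = variant_alps(reg, "ccb"),
                 ccsALPS = variant_alps(reg, "ccs"),
                 session = session),
            class = "alps_indices")
}

#' @export
print.alps_indices <- function(x, ...) {
  cat(sprintf("ALPS indices (%s): ALPS %.3f  ccgALPS %.3f  ccbALPS %.3f  ccsALPS %.3f\n",
              x$session, x$alps, x$ccgALPS, x$ccbALPS, x$ccsALPS))
  invisible(x)
}

#' Session differences (9 AM minus 4 PM)
#'
#' Computes Delta values for every shared numeric field of two per-session
#' records (indices and/or regional diffusivities): Delta = morning value
#' minus evening value.
#'
#' @param scan_4pm,scan_9am per-session records: `alps_indices`,
#'   `regional_diffusivity`, or named lists/vectors of numeric metrics.
#' @return Named list of Delta values for all shared numeric fields.
#' @examples
#' delta_metrics(list(alps = 1.40), list(alps = 1.45))  # Delta alps = 0.05
#' @export
delta_metrics <- function(scan_4pm, scan_9am) {
  if (is.null(scan_4pm) || is.null(scan_9am)) {
    stop("both sessions must be present", call. = FALSE)
  }
  f <- function(x) {
    x <- unclass(x)
    x[vapply(x, function(v) is.numeric(v) && length(v) == 1L, logical(1))]
  }
  a <- f(scan_4pm); b <- f(scan_9am)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) stop("sessions share no numeric fields", call. = FALSE)
  stats::setNames(lapply(shared, function(nm) b[[nm]] - a[[nm]]), shared)
}

#' Framewise displacement from a rigid motion trace
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations plus the rotation differences converted to arc length on a
#' sphere, `FD_t = |dtx| + |dty| + |dtz| + r (|drx| + |dry| + |drz|)`.
#' The first volume's FD is 0 by convention.
#'
#' @param trace motion trace matrix (volumes x 6: translations mm, rotations
#'   radians), e.g. from [simulate_motion()].
#' @param sphere_radius rotation-to-displacement radius r in mm.
#' @return An object of class `fd_series`: list with per-volume `fd`,
#'   `mean_fd` (over frames 2..T) and `max_fd`.
#' @export
framewise_displacement <- function(trace, sphere_radius = 50) {
  trace <- as.matrix(unclass(trace))
  if (ncol(trace) != 6L) stop("motion trace must have 6 columns", call. = FALSE)
  if (any(!is.finite(trace))) stop("motion trace contains non-finite values", call. = FALSE)
  n <- nrow(trace)
  if (n < 2L) {
    warning("single-volume trace: mean FD set to 0")
    return(structure(list(fd = rep(0, n), mean_fd = 0, max_fd = 0),
                     class = "fd_series"))
  }
  d <- abs(diff(trace))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            sphere_radius * rowSums(d[, 4:6, drop = FALSE]))
  structure(list(fd = fd, mean_fd = mean(fd[-1L]), max_fd = max(fd)),
            class = "fd_series")
}

#' @export
print.fd_series <- function(x, ...) {
  cat(sprintf("Framewise displacement: %d frames, mean %.3f mm, max %.3f mm\n",
              length(x$fd), x$mean_fd, x$max_fd))
  invisible(x)
}
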