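# Gradient schemes: direction tables + b-values, FSL bvec/bval interchange.

# Fixed 12-direction table obtained by electrostatic-repulsion optimisation on
# the half-sphere (antipodally symmetric Coulomb energy, BFGS, best of 8
# restarts), frozen here so every simulation and fit shares one scheme.
# The scanner protocol this emulates states only "12 axes"; no vendor table is
# published, so this stand-in is flagged in the scheme metadata.
.alpsim_dir12 <- matrix(c(
   0.375580, -0.030108, 0.926301,
  -0.246779,  0.286068, 0.925886,
  -0.364834, -0.415537, 0.833202,
   0.223269,  0.741792, 0.632373,
   0.410711, -0.662720, 0.626193,
  -0.731325,  0.459142, 0.504333,
   0.854588,  0.210772, 0.474610,
  -0.904477, -0.222784, 0.363716,
  -0.179936, -0.917404, 0.354955,
   0.889719, -0.421840, 0.174502,
  -0.316375,  0.934545, 0.162887,
   0.664482,  0.744331, 0.066598), ncol = 3L, byrow = TRUE)
# re-normalise to unit rows: the table is stored at 6 decimals
.alpsim_dir12 <- .alpsim_dir12 / sqrt(rowSums(.alpsim_dir12^2))

#' Construct a diffusion gradient scheme
#'
#' A gradient scheme couples one unit direction and one b-value to every
#' volume of a DWI acquisition. At least one `b = 0` volume and at least six
#' unique, non-collinear `b > 0` directions are required so that the six
#' unique components of a symmetric diffusion tensor are estimable; the
#' quadratic-form design matrix built from the scheme is checked for full
#' column rank at construction time.
#'
#' @param directions numeric matrix with one row per volume and columns
#'   (x, y, z). Rows with `b > 0` must have unit norm (tolerance `1e-9`);
#'   rows with `b = 0` may be zero vectors.
#' @param bvalues numeric vector of b-values in s/mm^2, one per volume.
#' @return An object of class `gradient_scheme`: a list with elements
#'   `directions`, `bvalues` and `n_volumes`.
#' @examples
#' sch <- default_gradient_scheme()
#' sch$n_volumes
#' @seealso [default_gradient_scheme()], [write_gradient_scheme()]
#' @export
gradient_scheme <- function(directions, bvalues) {
  directions <- as.matrix(directions)
  storage.mode(directions) <- "double"
  bvalues <- as.numeric(bvalues)
  if (ncol(directions) != 3L) stop("directions must have 3 columns", call. = FALSE)
  if (nrow(directions) != length(bvalues)) {
    stop("directions and bvalues describe different numbers of volumes", call. = FALSE)
  }
  if (any(!is.finite(directions)) || any(!is.finite(bvalues)) || any(bvalues < 0)) {
    stop("directions and bvalues must be finite and b-values non-negative", call. = FALSE)
  }
  if (!any(bvalues == 0)) stop("scheme must include at least one b = 0 volume", call. = FALSE)
  dwi <- bvalues > 0
  nrm <- sqrt(rowSums(directions[dwi, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("every direction with b > 0 must have unit norm (tolerance 1e-9)", call. = FALSE)
  }
  X <- design_matrix_rows(directions[dwi, , drop = FALSE])
  if (qr(X)$rank < 6L) {
    stop("gradient scheme is rank deficient: need >= 6 non-collinear b > 0 directions",
         call. = FALSE)
  }
  structure(list(directions = directions, bvalues = bvalues,
                 n_volumes = length(bvalues)),
            class = "gradient_scheme")
}

#' Default 12-direction, single-shell gradient scheme
#'
#' Two `b = 0` volumes followed by twelve electrostatically spread
#' `b = 1000` s/mm^2 directions, mirroring a conventional 12-axis clinical
#' DTI protocol with two signal averages of the non-diffusion image.
#'
#' @param bvalue shell b-value in s/mm^2.
#' @param n_b0 number of `b = 0` volumes (averaged before tensor fitting).
#' @return A [gradient_scheme()] object.
#' @export
default_gradient_scheme <- function(bvalue = 1000, n_b0 = 2L) {
  stopifnot(bvalue > 0, n_b0 >= 1L)
  dirs <- rbind(matrix(0, nrow = n_b0, ncol = 3L), .alpsim_dir12)
  gradient_scheme(dirs, c(rep(0, n_b0), rep(bvalue, nrow(.alpsim_dir12))))
}

# rows of the tensor design: (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)
design_matrix_rows <- function(G) {
  cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
        2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3], 2 * G[, 2] * G[, 3])
}

# full least-squares design for log-signal fitting: -b * quadratic form,
# restricted to b > 0 rows
fit_design <- function(scheme) {
  dwi <- scheme$bvalues > 0
  X <- design_matrix_rows(scheme$directions[dwi, , drop = FALSE])
  -scheme$bvalues[dwi] * X
}

#' @export
print.gradient_scheme <- function(x, ...) {
  nb0 <- sum(x$bvalues == 0)
  cat(sprintf("Gradient scheme: %d volumes (%d b=0, %d diffusion-weighted)\n",
              x$n_volumes, nb0, x$n_volumes - nb0))
  cat(sprintf("  shells (s/mm^2): %s\n",
              paste(sort(unique(x$bvalues[x$bvalues > 0])), collapse = ", ")))
  invisible(x)
}

#' Write a gradient scheme as FSL-style bvec/bval files
#'
#' `bvec` holds three whitespace-delimited rows (x, y, z components, one
#' column per volume); `bval` holds one row of b-values.
#'
#' @param scheme a [gradient_scheme()].
#' @param prefix file path prefix; `<prefix>.bvec` and `<prefix>.bval` are written.
#' @return `prefix`, invisibly.
#' @export
write_gradient_scheme <- function(scheme, prefix) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  fmt <- function(x) paste(formatC(x, format = "g", digits = 17), collapse = " ")
  writeLines(apply(t(scheme$directions), 1L, fmt), paste0(prefix, ".bvec"))
  writeLines(fmt(scheme$bvalues), paste0(prefix, ".bval"))
  invisible(prefix)
}

#' Read a gradient scheme from FSL-style bvec/bval files
#'
#' @param prefix file path prefix as in [write_gradient_scheme()].
#' @return A [gradient_scheme()].
#' @export
read_gradient_scheme <- function(prefix) {
  bvec <- as.matrix(utils::read.table(paste0(prefix, ".bvec")))
  bval <- as.numeric(utils::read.table(paste0(prefix, ".bval"))[1L, ])
  dirs <- t(bvec)
  # bvec files in the wild carry 5-6 decimals; restore unit norm on load
  dwi <- bval > 0
  nrm <- sqrt(rowSums(dirs[dwi, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 0.01)) {
    stop("b > 0 directions in ", prefix, ".bvec are far from unit norm",
         call. = FALSE)
  }
  dirs[dwi, ] <- dirs[dwi, , drop = FALSE] / nrm
  gradient_scheme(dirs, bval)
}
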