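# Bootstrap causal mediation (product-of-coefficients, linear models) and
# the ten-model battery relating regional diffusivities to the ALPS index.

# point estimates from one sample: a-path, b-path, direct and total effects
mediation_paths <- function(d, x, m, y, covariates) {
  fm_m <- stats::reformulate(c(x, covariates), response = m)
  fm_y <- stats::reformulate(c(x, m, covariates), response = y)
  fm_t <- stats::reformulate(c(x, covariates), response = y)
  fit_m <- stats::lm(fm_m, data = d)
  fit_y <- stats::lm(fm_y, data = d)
  fit_t <- stats::lm(fm_t, data = d)
  a <- stats::coef(fit_m)[[x]]
  b <- stats::coef(fit_y)[[m]]
  cprime <- stats::coef(fit_y)[[x]]
  total <- stats::coef(fit_t)[[x]]
  list(a = a, b = b, acme = a * b, ade = cprime, total = total,
       fit_m = fit_m, fit_y = fit_y)
}

#' Bootstrap causal mediation analysis for one X -> M -> Y model
#'
#' Fits the mediator model `M ~ X + covariates` and the outcome model
#' `Y ~ X + M + covariates` by least squares. The average causal mediation
#' effect (ACME, indirect effect) is the product of the a-path (X on M) and
#' b-path (M on Y given X) coefficients; the average direct effect (ADE) is
#' the X coefficient of the outcome model; the total effect is the X
#' coefficient of the reduced model `Y ~ X + covariates`. For nested linear
#' fits on the same cases these satisfy `ACME + ADE = total` exactly.
#' Percentile 95 percent confidence intervals are obtained by nonparametric
#' case resampling. Resamples in which X, M or Y degenerates to zero
#' variance are redrawn (and counted); more than 10 percent redraws is an
#' error.
#'
#' @param table data.frame of observations.
#' @param x,m,y names of the independent variable, mediator and outcome.
#' @param covariates adjustment variables (default `"age"` if present).
#' @param n_boot bootstrap draws.
#' @param seed integer seed for resampling.
#' @param standardize z-score x, m, y and continuous covariates first
#'   (`FALSE` by default: effects in raw units).
#' @param level confidence level.
#' @return An object of class `mediation`: list with `acme`, `ade`,
#'   `total` (each a list `estimate`, `ci`), `prop_mediated`, a-path and
#'   b-path coefficients with p-values, `n`, `n_boot`, `seed`, `redraws`
#'   and the path labels.
#' @examples
#' set.seed(1)
#' n <- 200
#' x <- rnorm(n); m <- 0.5 * x + rnorm(n); y <- 0.4 * m + 0.3 * x + rnorm(n)
#' fit <- mediate(data.frame(x = x, m = m, y = y), "x", "m", "y",
#'                covariates = character(0), n_boot = 199, seed = 1)
#' fit$acme$estimate
#' @export
mediate <- function(table, x, m, y, covariates = NULL, n_boot = 1000L,
                    seed = 1L, standardize = FALSE, level = 0.95) {
  covariates <- covariates %||% intersect("age", names(table))
  vars <- unique(c(x, m, y, covariates))
  missing_vars <- setdiff(vars, names(table))
  if (length(missing_vars)) {
    stop("variable(s) not in table: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  d <- table[, vars, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 20L) stop("fewer than 20 complete cases", call. = FALSE)
  for (v in vars) {
    if (stats::var(d[[v]]) == 0) stop("zero-variance variable: ", v, call. = FALSE)
  }
  if (standardize) {
    for (v in vars) {
      if (!all(d[[v]] %in% c(0, 1))) d[[v]] <- as.numeric(scale(d[[v]]))
    }
  }
  pt <- mediation_paths(d, x, m, y, covariates)
  sm_m <- summary(pt$fit_m)$coefficients
  sm_y <- summary(pt$fit_y)$coefficients
  boot <- matrix(NA_real_, nrow = n_boot, ncol = 3L,
                 dimnames = list(NULL, c("acme", "ade", "total")))
  redraws <- 0L
  with_seed(seed, {
    i <- 1L
    while (i <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      db <- d[idx, , drop = FALSE]
      if (any(vapply(db[c(x, m, y)], stats::var, numeric(1)) == 0)) {
        redraws <- redraws + 1L
        if (redraws > 0.1 * n_boot) {
          stop("more than 10% of bootstrap resamples were degenerate",
               call. = FALSE)
        }
        next
      }
      pb <- mediation_paths(db, x, m, y, covariates)
      boot[i, ] <- c(pb$acme, pb$ade, pb$total)
      i <- i + 1L
    }
  })
  alpha <- (1 - level) / 2
  ci <- function(col) unname(stats::quantile(boot[, col], c(alpha, 1 - alpha)))
  prop <- if (abs(pt$total) < 1e-8 * max(1, abs(pt$acme))) NA_real_ else
    pt$acme / pt$total
  structure(list(
    x = x, m = m, y = y, covariates = covariates,
    acme = list(estimate = pt$acme, ci = ci("acme")),
    ade = list(estimate = pt$ade, ci = ci("ade")),
    total = list(estimate = pt$total, ci = ci("total")),
    prop_mediated = prop,
    a_path = list(estimate = pt$a, p = sm_m[x, 4L]),
    b_path = list(estimate = pt$b, p = sm_y[m, 4L]),
    n = n, n_boot = n_boot, seed = seed, redraws = redraws,
    standardized = standardize, boot = boot),
    class = "mediation")
}

#' @export
print.mediation <- function(x, digits = 4, ...) {
  fmt <- function(e) sprintf("%.*g [%.*g, %.*g]", digits, e$estimate,
                             digits, e$ci[1], digits, e$ci[2])
  cat(sprintf("Mediation %s -> %s -> %s (n = %d, %d bootstrap draws)\n",
              x$x, x$m, x$y, x$n, x$n_boot))
  cat("  ACME : ", fmt(x$acme), "\n", sep = "")
  cat("  ADE  : ", fmt(x$ade), "\n", sep = "")
  cat("  Total: ", fmt(x$total), "\n", sep = "")
  cat(sprintf("  a-path %.4g (p = %.3g), b-path %.4g (p = %.3g), prop. mediated %s\n",
              x$a_path$estimate, x$a_path$p, x$b_path$estimate, x$b_path$p,
              if (is.na(x$prop_mediated)) "undefined"
              else sprintf("%.3g", x$prop_mediated)))
  invisible(x)
}

# the ten published X -> M -> Y combinations, in table order
.mediation_paths_table <- data.frame(
  x = c("assocDxx", "assocDxx", "projDxx", "projDxx",
        "assocDxx", "assocDxx", "assocDxx",
        "projDxx", "projDxx", "projDxx"),
  m = c("assocDyy", "assocDzz", "projDyy", "projDzz",
        "ccbDxx", "ccbDyy", "ccbDzz",
        "ccbDxx", "ccbDyy", "ccbDzz"),
  y = "alps",
  stringsAsFactors = FALSE)

#' The ten-model mediation battery
#'
#' Runs the full set of ten X -> M -> Y mediation models probing how
#' diffusivity components orthogonal to the perivascular axis, and corpus
#' callosum body diffusivities, mediate the association between
#' perivascular-axis diffusivity and the ALPS index: two association-region
#' internal models, two projection-region internal models, and three
#' callosal mediators for each of `assocDxx` and `projDxx`. All models are
#' age-adjusted and share one base seed.
#'
#' @param table data.frame with `alps` and the seven diffusivity columns.
#' @param covariates adjustment variables (default `"age"`).
#' @param n_boot bootstrap draws per model.
#' @param seed base seed; model `i` uses `seed + i`.
#' @param standardize passed to [mediate()].
#' @return An object of class `mediation_battery`: list of ten `mediation`
#'   fits in the published order, with an `as.data.frame()` method that
#'   emits the ACME/ADE/total summary table.
#' @export
mediation_battery <- function(table, covariates = NULL, n_boot = 1000L,
                              seed = 1L, standardize = FALSE) {
  needed <- unique(c(.mediation_paths_table$x, .mediation_paths_table$m, "alps"))
  missing_vars <- setdiff(needed, names(table))
  if (length(missing_vars)) {
    stop("missing variable(s): ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  fits <- lapply(seq_len(nrow(.mediation_paths_table)), function(i) {
    p <- .mediation_paths_table[i, ]
    mediate(table, p$x, p$m, p$y, covariates = covariates, n_boot = n_boot,
            seed = seed + i, standardize = standardize)
  })
  structure(list(models = fits, seed = seed), class = "mediation_battery")
}

#' @export
as.data.frame.mediation_battery <- function(x, ...) {
  rows <- lapply(x$models, function(m) {
    data.frame(path = sprintf("%s -> %s -> %s", m$x, m$m, m$y),
               acme = m$acme$estimate,
               acme_lo = m$acme$ci[1], acme_hi = m$acme$ci[2],
               ade = m$ade$estimate,
               ade_lo = m$ade$ci[1], ade_hi = m$ade$ci[2],
               total = m$total$estimate,
               total_lo = m$total$ci[1], total_hi = m$total$ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.mediation_battery <- function(x, digits = 4, ...) {
  cat(sprintf("Mediation battery: %d models, outcome '%s'\n",
              length(x$models), x$models[[1]]$y))
  df <- as.data.frame(x)
  for (cn in names(df)[-1L]) df[[cn]] <- signif(df[[cn]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}
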