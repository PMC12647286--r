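# Standardized multiple regression with VIF, the forest-plot analysis.

#' Standardized multiple regression with confidence intervals and VIF
#'
#' Ordinary least squares of an outcome on predictors plus covariates, with
#' all continuous variables z-scored (mean 0, SD 1) beforehand; 0/1 dummy
#' variables are left on their original scale. Reports standardized
#' coefficients, normal-approximation 95 percent confidence intervals
#' (`beta +/- 1.96 SE`), t-test p-values, and the variance inflation factor
#' of every non-intercept term. Significance corresponds to the CI
#' excluding zero.
#'
#' @param table data.frame of observations.
#' @param outcome outcome variable name.
#' @param predictors character vector of predictor names.
#' @param covariates additional adjustment variables (default: age plus any
#'   `dx_*` diagnosis dummies present in `table`).
#' @param standardize z-score continuous variables (default `TRUE`).
#' @param level confidence level.
#' @return An object of class `std_ols`: list with `coefficients`
#'   (data.frame: term, beta, se, ci_lower, ci_upper, p, vif, significant),
#'   `outcome`, `n` and the underlying `lm` fit.
#' @examples
#' d <- data.frame(y = rnorm(50), x = rnorm(50), age = rnorm(50, 50, 10))
#' fit <- standardized_ols(d, "y", "x", covariates = "age")
#' coef(fit)
#' @export
standardized_ols <- function(table, outcome, predictors,
                             covariates = NULL, standardize = TRUE,
                             level = 0.95) {
  covariates <- covariates %||%
    intersect(c("age", grep("^dx_", names(table), value = TRUE)), names(table))
  terms_all <- unique(c(predictors, covariates))
  vars <- c(outcome, terms_all)
  missing_vars <- setdiff(vars, names(table))
  if (length(missing_vars)) {
    stop("variable(s) not in table: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  d <- table[, vars, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(terms_all) + 2L) stop("too few observations for the model",
                                        call. = FALSE)
  is_dummy <- vapply(d, function(x) all(x %in% c(0, 1)), logical(1))
  if (standardize) {
    for (v in vars[!is_dummy[vars]]) {
      s <- stats::sd(d[[v]])
      if (s == 0) stop("zero-variance variable: ", v, call. = FALSE)
      d[[v]] <- (d[[v]] - mean(d[[v]])) / s
    }
  }
  X <- as.matrix(d[, terms_all, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    C <- abs(stats::cor(X))
    diag(C) <- 0
    bad <- which(C > 1 - 1e-8, arr.ind = TRUE)
    pair <- if (nrow(bad)) {
      paste(terms_all[bad[1, 1]], "and", terms_all[bad[1, 2]])
    } else "unidentified terms"
    stop("perfect collinearity between ", pair, call. = FALSE)
  }
  fml <- stats::reformulate(terms_all, response = outcome)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  vifs <- if (length(terms_all) >= 2L) car::vif(fit) else
    stats::setNames(1, terms_all)
  cf <- data.frame(term = rownames(sm)[-1L],
                   beta = sm[-1L, 1L], se = sm[-1L, 2L],
                   ci_lower = sm[-1L, 1L] - z * sm[-1L, 2L],
                   ci_upper = sm[-1L, 1L] + z * sm[-1L, 2L],
                   p = sm[-1L, 4L],
                   vif = as.numeric(vifs[rownames(sm)[-1L]]),
                   stringsAsFactors = FALSE)
  cf$significant <- cf$ci_lower > 0 | cf$ci_upper < 0
  rownames(cf) <- NULL
  structure(list(coefficients = cf, outcome = outcome, n = n,
                 standardized = standardize, fit = fit),
            class = "std_ols")
}

#' @export
print.std_ols <- function(x, digits = 3, ...) {
  cat(sprintf("%s multiple regression: %s ~ %s  (n = %d)\n",
              if (x$standardized) "Standardized" else "Unstandardized",
              x$outcome, paste(x$coefficients$term, collapse = " + "), x$n))
  df <- x$coefficients
  for (cn in c("beta", "se", "ci_lower", "ci_upper", "vif")) {
    df[[cn]] <- round(df[[cn]], digits)
  }
  df$p <- signif(df$p, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.std_ols <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' @export
confint.std_ols <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  M <- cbind(cf$ci_lower, cf$ci_upper)
  dimnames(M) <- list(cf$term, c("2.5 %", "97.5 %"))
  if (!missing(parm)) M <- M[parm, , drop = FALSE]
  M
}

#' Forest-plot data for a set of predictors against one outcome
#'
#' Runs [standardized_ols()] either with all predictors entered jointly
#' (default) or as separate models per predictor, and returns the tidy
#' (term, beta, CI) table that forest plots are drawn from.
#'
#' @param table data.frame of observations.
#' @param outcome outcome variable name.
#' @param predictors character vector of predictors.
#' @param joint enter predictors jointly (`TRUE`) or one model per
#'   predictor (`FALSE`).
#' @param ... passed to [standardized_ols()].
#' @return data.frame of coefficient rows (one per predictor/covariate).
#' @export
forest_data <- function(table, outcome, predictors, joint = TRUE, ...) {
  if (joint) {
    fit <- standardized_ols(table, outcome, predictors, ...)
    out <- fit$coefficients
    out$model <- "joint"
    return(out)
  }
  res <- lapply(predictors, function(p) {
    cf <- standardized_ols(table, outcome, p, ...)$coefficients
    cf$model <- p
    cf
  })
  do.call(rbind, res)
}
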