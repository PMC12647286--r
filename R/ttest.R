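# One-sample t tests against the isotropic reference.

#' One-sample t test against a reference value
#'
#' `t = (mean - reference) / (SD / sqrt(n))` with `n - 1` degrees of freedom
#' and a two-tailed p-value; the reference defaults to 1, the value every
#' ALPS-type ratio takes under isotropic diffusion.
#'
#' @param values numeric sample (length >= 2, non-degenerate).
#' @param reference null value.
#' @return An object of class `one_sample_t`: list with `t`, `df`, `p`,
#'   `mean`, `sd`, `n`, `reference` and the 95 percent `conf.int`.
#' @examples
#' one_sample_t(c(1.1, 1.2, 1.3))  # t = 3.46, p = 0.074
#' @export
one_sample_t <- function(values, reference = 1) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 finite values", call. = FALSE)
  if (stats::sd(values) == 0) stop("degenerate sample: zero standard deviation",
                                   call. = FALSE)
  ht <- stats::t.test(values, mu = reference, alternative = "two.sided")
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean = mean(values), sd = stats::sd(values),
                 n = length(values), reference = reference,
                 conf.int = as.numeric(ht$conf.int)),
            class = "one_sample_t")
}

#' @export
print.one_sample_t <- function(x, ...) {
  cat(sprintf("One-sample t test vs %.3g: mean %.4g, t(%d) = %.3f, p = %.4g\n",
              x$reference, x$mean, x$df, x$t, x$p))
  invisible(x)
}
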