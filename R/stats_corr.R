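# Pearson correlation grids with Benjamini-Hochberg FDR and strength
# categories.

.strength_breaks <- c(0, 0.2, 0.4, 0.6, 0.8, 1 + 1e-9)
.strength_labels <- c("very weak", "weak", "moderate", "strong", "very strong")

strength_category <- function(r) {
  cut(abs(r), breaks = .strength_breaks, labels = .strength_labels,
      right = FALSE, include.lowest = TRUE)
}

#' Pairwise Pearson correlations with BH-FDR correction
#'
#' Computes pairwise complete-case Pearson correlations between two variable
#' sets with two-tailed p-values, applies Benjamini-Hochberg false discovery
#' rate adjustment within the declared family (by default, all pairs
#' computed in the call — one heatmap panel), and labels each coefficient
#' with the conventional strength category (very weak 0-0.19, weak
#' 0.20-0.39, moderate 0.40-0.59, strong 0.60-0.79, very strong 0.80-1.00).
#'
#' @param table data.frame of observations (e.g. a `scan_table`).
#' @param row_vars,col_vars character vectors of variable names; every
#'   row-by-column pair (excluding self-pairs) is tested.
#' @param family FDR family scope: `"panel"` adjusts across all pairs in
#'   this call; `"none"` leaves `q = p`.
#' @return An object of class `corr_fdr`: data.frame with columns `var1`,
#'   `var2`, `n`, `r`, `p`, `q`, `category`.
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1, z = rnorm(10))
#' pearson_matrix_fdr(d, "x", c("y", "z"))
#' @export
pearson_matrix_fdr <- function(table, row_vars, col_vars,
                               family = c("panel", "none")) {
  family <- match.arg(family)
  all_vars <- unique(c(row_vars, col_vars))
  missing_vars <- setdiff(all_vars, names(table))
  if (length(missing_vars)) {
    stop("variable(s) not in table: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  for (v in all_vars) {
    x <- table[[v]][is.finite(table[[v]])]
    if (length(x) < 3L) stop("variable '", v, "' has fewer than 3 complete values",
                             call. = FALSE)
    if (stats::var(x) == 0) stop("zero-variance variable: ", v, call. = FALSE)
  }
  rows <- list()
  for (rv in row_vars) {
    for (cv in col_vars) {
      if (rv == cv) next
      ok <- is.finite(table[[rv]]) & is.finite(table[[cv]])
      ct <- stats::cor.test(table[[rv]][ok], table[[cv]][ok],
                            method = "pearson", alternative = "two.sided")
      rows[[length(rows) + 1L]] <- data.frame(
        var1 = rv, var2 = cv, n = sum(ok),
        r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- if (family == "panel") stats::p.adjust(out$p, method = "BH") else out$p
  out$category <- strength_category(out$r)
  rownames(out) <- NULL
  class(out) <- c("corr_fdr", class(out))
  out
}

#' @export
print.corr_fdr <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlations (%d pairs, BH-FDR within panel):\n", nrow(x)))
  df <- as.data.frame(x)
  df$r <- round(df$r, digits); df$p <- signif(df$p, digits)
  df$q <- signif(df$q, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Reshape a correlation result into r/p/q matrices
#'
#' @param result a [pearson_matrix_fdr()] result.
#' @return list of three matrices (`r`, `p`, `q`) with row/column variables
#'   as dimnames — the heatmap export format.
#' @export
corr_matrices <- function(result) {
  stopifnot(inherits(result, "corr_fdr"))
  rows <- unique(result$var1); cols <- unique(result$var2)
  one <- function(field) {
    M <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
    for (i in seq_len(nrow(result))) {
      M[result$var1[i], result$var2[i]] <- result[[field]][i]
    }
    M
  }
  list(r = one("r"), p = one("p"), q = one("q"))
}

#' Square marker-correlation matrix, r above / p below the diagonal
#'
#' The publication-style layout for a small set of imaging markers:
#' Pearson r in the upper triangle, unadjusted two-tailed p in the lower
#' triangle, ones on the diagonal.
#'
#' @param table data.frame of observations.
#' @param vars variables to cross (order preserved).
#' @return numeric matrix with dimnames `vars`.
#' @export
marker_correlation_table <- function(table, vars) {
  res <- pearson_matrix_fdr(table, vars, vars, family = "none")
  M <- diag(length(vars))
  dimnames(M) <- list(vars, vars)
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (i == j) next
      row <- res[res$var1 == vars[i] & res$var2 == vars[j], ]
      M[i, j] <- if (i < j) row$r else row$p
    }
  }
  M
}

#' Motion-bias check: correlation between mean FD and the ALPS index
#'
#' A single pre-specified Pearson test, reported outside any FDR family.
#'
#' @param table data.frame with `mean_fd` and `alps` columns.
#' @param fd_var,alps_var column names.
#' @return A one-row `corr_fdr` data.frame (with `q = p`), plus attribute
#'   `conf.int` (95\% CI for r).
#' @export
fd_alps_check <- function(table, fd_var = "mean_fd", alps_var = "alps") {
  out <- pearson_matrix_fdr(table, fd_var, alps_var, family = "none")
  ok <- is.finite(table[[fd_var]]) & is.finite(table[[alps_var]])
  ct <- stats::cor.test(table[[fd_var]][ok], table[[alps_var]][ok])
  attr(out, "conf.int") <- as.numeric(ct$conf.int)
  out
}
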