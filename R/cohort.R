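# Gaussian-copula synthetic cohort: two sessions per subject, planted
# marginals and correlation structure, diagnosis and CPAP flags.

# Default per-variable marginals. `level` is "subject" (one draw shared by
# both sessions: demographics, the single overnight PSG) or "scan" (session
# correlation applies). Bounded variables get truncated-normal marginals.
# The index and volumetric targets reproduce published cohort descriptives;
# PSG targets are plausible clinical values for a psychiatric OSA cohort and
# are configuration, not literature anchors.
default_cohort_variables <- function() {
  v <- function(name, mean, sd, lower = -Inf, upper = Inf, level = "scan") {
    data.frame(name = name, mean = mean, sd = sd, lower = lower, upper = upper,
               level = level, stringsAsFactors = FALSE)
  }
  rbind(
    v("alps",     1.391, 0.261, 0),            # session-specific, see alps_sessions
    v("ccgALPS",  1.06, 0.08, 0),
    v("ccbALPS",  1.05, 0.07, 0),
    v("ccsALPS",  1.07, 0.08, 0),
    v("rCPV",     1.3e-3, 4e-4, 0),
    v("rWMHV",    2.0e-3, 9e-4, 0),
    v("age",      50.0, 14.0, 20, Inf, "subject"),
    v("mean_fd",  0.18, 0.07, 0),
    # overnight PSG (one night per subject)
    v("total_sleep_time", 380, 60, 0, Inf, "subject"),
    v("sleep_latency",     20, 15, 0, Inf, "subject"),
    v("rem_latency",      110, 55, 0, Inf, "subject"),
    v("waso",              60, 40, 0, Inf, "subject"),
    v("sleep_efficiency",  82, 10, 0, 100, "subject"),
    v("pct_n1",            15,  8, 0, 100, "subject"),
    v("pct_n2",            50, 10, 0, 100, "subject"),
    v("pct_n3",            10,  7, 0, 100, "subject"),
    v("pct_rem",           18,  6, 0, 100, "subject"),
    v("arousal_index",     25, 12, 0, Inf, "subject"),
    v("apnea_index",       10, 10, 0, Inf, "subject"),
    v("hypopnea_index",    15, 10, 0, Inf, "subject"),
    v("ahi",               25, 18, 0, Inf, "subject"),
    v("lowest_spo2",       82,  8, 40, 100, "subject"),
    v("odi3",              20, 15, 0, Inf, "subject"),
    v("t_spo2_below_90",   15, 25, 0, Inf, "subject"),
    v("plm_index",         10, 15, 0, Inf, "subject"),
    # regional diffusivities (mm^2/s) and FA, realistic white-matter values
    v("projDxx",  0.50e-3, 0.06e-3, 0),
    v("projDyy",  0.40e-3, 0.05e-3, 0),
    v("projDzz",  1.10e-3, 0.12e-3, 0),
    v("assocDxx", 0.55e-3, 0.07e-3, 0),
    v("assocDyy", 1.05e-3, 0.12e-3, 0),
    v("assocDzz", 0.40e-3, 0.05e-3, 0),
    v("ccgDxx",   1.30e-3, 0.15e-3, 0),
    v("ccgDyy",   0.45e-3, 0.06e-3, 0),
    v("ccgDzz",   0.42e-3, 0.06e-3, 0),
    v("ccbDxx",   1.25e-3, 0.15e-3, 0),
    v("ccbDyy",   0.44e-3, 0.06e-3, 0),
    v("ccbDzz",   0.46e-3, 0.06e-3, 0),
    v("ccsDxx",   1.35e-3, 0.15e-3, 0),
    v("ccsDyy",   0.45e-3, 0.06e-3, 0),
    v("ccsDzz",   0.42e-3, 0.06e-3, 0),
    v("projFA",   0.55, 0.06, 0, 1),
    v("assocFA",  0.50, 0.06, 0, 1),
    v("ccgFA",    0.75, 0.05, 0, 1),
    v("ccbFA",    0.65, 0.05, 0, 1),
    v("ccsFA",    0.78, 0.05, 0, 1),
    v("tiv",      1.45e6, 1.3e5, 0, Inf, "subject")
  )
}

#' Default planted correlation matrix
#'
#' Unit-diagonal correlation matrix over the cohort variables with the
#' published pairwise values planted: the imaging-marker correlation table
#' (ALPS and variant indices vs relative choroid plexus and white-matter
#' hypointensity volumes), the reported ALPS-sleep correlations (REM latency
#' -0.47, total sleep time 0.33, sleep efficiency 0.29), and the age
#' correlations of the volumetric ratios (0.61, 0.65). All other pairs
#' default to 0, including ALPS-age and mean FD-ALPS, which were reported
#' as null.
#'
#' @param var_names character vector of variable names (default: all cohort
#'   variables).
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
default_planted_correlations <- function(var_names = default_cohort_variables()$name) {
  K <- length(var_names)
  R <- diag(K)
  dimnames(R) <- list(var_names, var_names)
  set_r <- function(a, b, value) {
    if (a %in% var_names && b %in% var_names) {
      R[a, b] <<- value
      R[b, a] <<- value
    }
  }
  # imaging-marker correlation table (upper triangle as published)
  set_r("rCPV", "rWMHV",    0.547435)
  set_r("rCPV", "alps",    -0.44001)
  set_r("rCPV", "ccgALPS", -0.38065)
  set_r("rCPV", "ccbALPS",  0.126145)
  set_r("rCPV", "ccsALPS", -0.17691)
  set_r("rWMHV", "alps",   -0.38406)
  set_r("rWMHV", "ccgALPS", -0.28280)
  set_r("rWMHV", "ccbALPS",  0.083471)
  set_r("rWMHV", "ccsALPS", -0.07244)
  set_r("alps", "ccgALPS",  0.24106)
  set_r("alps", "ccbALPS",  0.03503)
  set_r("alps", "ccsALPS", -0.09133)
  set_r("ccgALPS", "ccbALPS", -0.02314)
  set_r("ccgALPS", "ccsALPS", -0.08105)
  set_r("ccbALPS", "ccsALPS",  0.00302)
  # reported sleep correlations of the ALPS index
  set_r("alps", "rem_latency",      -0.47)
  set_r("alps", "total_sleep_time",  0.33)
  set_r("alps", "sleep_efficiency",  0.29)
  # volumetric ratios and age
  set_r("rCPV", "age",  0.61)
  set_r("rWMHV", "age", 0.65)
  R
}

#' Cohort generator configuration
#'
#' @param n_subjects number of subjects (two scans each).
#' @param seed integer seed for the whole generation.
#' @param variables marginal table as returned by
#'   [default_cohort_variables()]: columns `name, mean, sd, lower, upper,
#'   level`.
#' @param planted planted correlation matrix over `variables$name`
#'   (default [default_planted_correlations()]).
#' @param session_cor within-subject correlation of scan-level variables
#'   between the 4 PM and 9 AM sessions. The default 0.7, combined with the
#'   session-specific ALPS marginals, reproduces the published SD of the
#'   session difference (about 0.199).
#' @param alps_sessions list with per-session ALPS marginals,
#'   `mean`/`sd` for `"4PM"` and `"9AM"`.
#' @param diagnosis_counts named integer vector of mutually exclusive
#'   diagnosis groups for `n_subjects = 50`; scaled proportionally (largest
#'   remainder) for other cohort sizes.
#' @param n_cpap number of subjects flagged as having prior CPAP treatment
#'   (scaled like the diagnosis counts for other cohort sizes).
#' @param n_male number of male subjects at `n_subjects = 50`.
#' @param max_repair_shift largest tolerated change of any planted
#'   correlation during nearest-positive-definite repair.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 50L,
                          seed = 1L,
                          variables = default_cohort_variables(),
                          planted = NULL,
                          session_cor = 0.7,
                          alps_sessions = list(
                            "4PM" = c(mean = 1.391, sd = 0.261),
                            "9AM" = c(mean = 1.419, sd = 0.253)),
                          diagnosis_counts = c(bipolar = 14L, depression = 14L,
                                               schizophrenia = 7L, adhd = 6L,
                                               ocd = 1L, none = 8L),
                          n_cpap = 9L,
                          n_male = 33L,
                          max_repair_shift = 0.05) {
  stopifnot(n_subjects >= 2L, session_cor >= 0, session_cor <= 1)
  need <- c("name", "mean", "sd", "lower", "upper", "level")
  if (!all(need %in% names(variables))) {
    stop("variables table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  planted <- planted %||% default_planted_correlations(variables$name)
  if (!isTRUE(all.equal(planted, t(planted))) || any(diag(planted) != 1)) {
    stop("planted correlation matrix must be symmetric with unit diagonal",
         call. = FALSE)
  }
  if (!identical(sort(rownames(planted)), sort(variables$name))) {
    stop("planted matrix must be indexed by the variable names", call. = FALSE)
  }
  if (sum(diagnosis_counts) != 50L) {
    stop("diagnosis_counts must describe the 50-subject reference cohort",
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), seed = seed,
                 variables = variables,
                 planted = planted[variables$name, variables$name],
                 session_cor = session_cor,
                 alps_sessions = alps_sessions,
                 diagnosis_counts = diagnosis_counts,
                 n_cpap = as.integer(n_cpap), n_male = as.integer(n_male),
                 max_repair_shift = max_repair_shift),
            class = "cohort_config")
}

# nearest-positive-definite repair; errors if any planted entry moves by
# more than the configured budget, naming the offending pairs
repair_correlation <- function(R, max_shift) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= 1e-10) {
    return(list(R = R, max_shift = 0, min_eigenvalue = min(ev), repaired = FALSE))
  }
  Rp <- as.matrix(Matrix::nearPD(R, corr = TRUE, maxit = 500)$mat)
  dimnames(Rp) <- dimnames(R)
  shift <- abs(Rp - R)
  if (max(shift) > max_shift) {
    bad <- which(shift == max(shift), arr.ind = TRUE)[1L, ]
    off <- which(shift > max_shift & upper.tri(shift), arr.ind = TRUE)
    pairs <- apply(off, 1L, function(ij) {
      paste0(rownames(R)[ij[1]], "-", colnames(R)[ij[2]])
    })
    stop("infeasible planted correlation matrix: repair shifts ",
         paste(unique(pairs), collapse = ", "), " by more than ",
         max_shift, call. = FALSE)
  }
  list(R = Rp, max_shift = max(shift),
       min_eigenvalue = min(eigen(Rp, symmetric = TRUE, only.values = TRUE)$values),
       repaired = TRUE)
}

# largest-remainder scaling of reference counts (defined at n = 50) to n
scale_counts <- function(counts, n) {
  raw <- counts * n / sum(counts)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

#' Generate the synthetic two-session cohort
#'
#' Draws one latent multivariate-normal vector per subject under the
#' repaired planted correlation matrix, plus independent session innovations
#' for scan-level variables (`z_session = sqrt(rho) z_subject +
#' sqrt(1-rho) z_innovation`, giving within-scan correlation equal to the
#' planted matrix and between-session correlation `rho` for scan-level
#' pairs). Latents are then pushed through per-variable (truncated-) normal
#' marginals; the ALPS index uses session-specific marginals so the morning
#' scans are shifted upward. Diagnosis groups, CPAP history and sex are
#' assigned as mutually exclusive labels with the configured counts.
#' Absolute volumes are derived from the generated ratios
#' (`cpv = rCPV * tiv`, `wmhv = rWMHV * tiv`), keeping the ratio identities
#' exact. The result is deterministic for a fixed config seed.
#'
#' @param config a [cohort_config()].
#' @return A `data.frame` of class `scan_table` with one row per scan
#'   (subject x session) and attributes `config`, `repair` (correlation
#'   repair diagnostics) and `mode` (`"tabular"`).
#' @examples
#' tab <- generate_cohort(cohort_config(n_subjects = 10, seed = 7))
#' nrow(tab)  # 20 scans
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  vars <- config$variables
  K <- nrow(vars)
  n <- config$n_subjects
  rep_diag <- repair_correlation(config$planted, config$max_repair_shift)
  R <- rep_diag$R
  rho <- ifelse(vars$level == "subject", 1, config$session_cor)
  # exact second-moment calibration of the latent blocks when the cohort is
  # large enough to support it (sample covariance of each block then equals
  # the planted matrix exactly; cross-block products, the copula transforms
  # and the session mixing keep the realised table stochastic)
  emp <- n > K
  out <- with_seed(config$seed, {
    z_subj <- MASS::mvrnorm(n, mu = rep(0, K), Sigma = R, empirical = emp)
    z_in1 <- MASS::mvrnorm(n, mu = rep(0, K), Sigma = R, empirical = emp)
    z_in2 <- MASS::mvrnorm(n, mu = rep(0, K), Sigma = R, empirical = emp)
    zs <- function(z_in) {
      sweep(z_subj, 2L, sqrt(rho), `*`) + sweep(z_in, 2L, sqrt(1 - rho), `*`)
    }
    z1 <- zs(z_in1)
    z2 <- zs(z_in2)
    groups <- sample(rep(names(config$diagnosis_counts),
                         scale_counts(config$diagnosis_counts, n)))
    cpap <- seq_len(n) %in% sample.int(n, scale_counts(
      c(cpap = config$n_cpap, no = 50L - config$n_cpap), n)[["cpap"]])
    male <- seq_len(n) %in% sample.int(n, scale_counts(
      c(m = config$n_male, f = 50L - config$n_male), n)[["m"]])
    list(z1 = z1, z2 = z2, groups = groups, cpap = cpap, male = male)
  })
  marginal <- function(z, k, session) {
    m <- vars$mean[k]; s <- vars$sd[k]
    if (vars$name[k] == "alps") {
      ms <- config$alps_sessions[[session]]
      m <- ms[["mean"]]; s <- ms[["sd"]]
    }
    qtnorm(stats::pnorm(z), mean = m, sd = s,
           lower = vars$lower[k], upper = vars$upper[k])
  }
  session_frame <- function(z, session) {
    df <- as.data.frame(lapply(seq_len(K), function(k) marginal(z[, k], k, session)))
    names(df) <- vars$name
    df
  }
  d1 <- session_frame(out$z1, "4PM")
  d2 <- session_frame(out$z2, "9AM")
  subj <- sprintf("S%03d", seq_len(n))
  groups <- factor(out$groups, levels = names(config$diagnosis_counts))
  dummies <- stats::model.matrix(~ 0 + groups)
  colnames(dummies) <- paste0("dx_", levels(groups))
  dummies <- dummies[, colnames(dummies) != "dx_none", drop = FALSE]
  base <- data.frame(subject = subj,
                     sex = ifelse(out$male, "M", "F"),
                     diagnosis = as.character(groups),
                     cpap = out$cpap,
                     stringsAsFactors = FALSE)
  base <- cbind(base, as.data.frame(dummies))
  tab <- rbind(cbind(base, session = "4PM", d1),
               cbind(base, session = "9AM", d2))
  tab <- tab[order(tab$subject, tab$session), ]
  rownames(tab) <- NULL
  tab$cpv <- tab$rCPV * tab$tiv
  tab$wmhv <- tab$rWMHV * tab$tiv
  attr(tab, "config") <- config
  attr(tab, "repair") <- rep_diag[c("max_shift", "min_eigenvalue", "repaired")]
  attr(tab, "mode") <- "tabular"
  class(tab) <- c("scan_table", class(tab))
  tab
}

#' Restrict a cohort to a sensitivity-analysis subset
#'
#' `"no_psych"` keeps subjects without psychiatric comorbidity (all
#' diagnosis dummies zero); `"no_cpap"` drops subjects with prior CPAP
#' treatment. Both sessions of every kept subject are retained.
#'
#' @param table a `scan_table`.
#' @param which `"no_psych"` or `"no_cpap"`.
#' @return The filtered `scan_table`.
#' @export
subset_sensitivity <- function(table, which = c("no_psych", "no_cpap")) {
  which <- match.arg(which)
  keep <- if (which == "no_psych") {
    if (!"diagnosis" %in% names(table)) return(table)
    table$diagnosis == "none"
  } else {
    if (!"cpap" %in% names(table)) return(table)
    !table$cpap
  }
  out <- table[keep, , drop = FALSE]
  if (!nrow(out)) stop("empty result set for subset '", which, "'", call. = FALSE)
  rownames(out) <- NULL
  for (a in c("config", "repair", "mode")) attr(out, a) <- attr(table, a)
  out
}

#' Per-subject session differences for a cohort table
#'
#' Computes 9 AM minus 4 PM differences of every numeric metric column,
#' one row per subject.
#'
#' @param table a `scan_table` with both sessions per subject.
#' @return data.frame with `subject` and `d_<metric>` columns.
#' @export
cohort_deltas <- function(table) {
  t4 <- table[table$session == "4PM", , drop = FALSE]
  t9 <- table[table$session == "9AM", , drop = FALSE]
  if (!identical(t4$subject, t9$subject)) {
    stop("missing session: every subject needs one 4PM and one 9AM scan",
         call. = FALSE)
  }
  skip <- c("cpap", grep("^dx_", names(table), value = TRUE))
  num <- setdiff(names(table)[vapply(table, is.numeric, logical(1))], skip)
  d <- as.data.frame(lapply(num, function(nm) t9[[nm]] - t4[[nm]]))
  names(d) <- paste0("d_", num)
  cbind(data.frame(subject = t4$subject, stringsAsFactors = FALSE), d)
}

#' @export
print.scan_table <- function(x, ...) {
  cat(sprintf("Synthetic scan table: %d scans, %d subjects, %d columns, mode '%s'\n",
              nrow(x), length(unique(x$subject)), ncol(x),
              attr(x, "mode") %||% "tabular"))
  if ("alps" %in% names(x)) {
    for (s in unique(x$session)) {
      a <- x$alps[x$session == s]
      cat(sprintf("  ALPS %s: mean %.3f (SD %.3f)\n", s, mean(a), stats::sd(a)))
    }
  }
  invisible(x)
}

#' Write / read a cohort table as CSV with a YAML sidecar
#'
#' The sidecar `<path>.yaml` records the generation seed, cohort size,
#' generation mode and correlation-repair diagnostics.
#'
#' @param table a `scan_table`.
#' @param path CSV output path.
#' @return `path` (write); the table (read).
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  cfg <- attr(table, "config")
  side <- list(seed = cfg$seed %||% NA,
               n_subjects = cfg$n_subjects %||% length(unique(table$subject)),
               mode = attr(table, "mode") %||% "tabular",
               repair = lapply(attr(table, "repair") %||% list(), identity))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  side_path <- paste0(path, ".yaml")
  if (file.exists(side_path)) {
    side <- yaml::read_yaml(side_path)
    attr(tab, "mode") <- side$mode
    attr(tab, "sidecar") <- side
  }
  class(tab) <- c("scan_table", class(tab))
  tab
}
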