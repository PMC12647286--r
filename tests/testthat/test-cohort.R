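test_that("cohort generation is deterministic and structurally sound", {
  cfg <- cohort_config(n_subjects = 50, seed = 11)
  tab <- generate_cohort(cfg)
  expect_identical(as.data.frame(tab), as.data.frame(generate_cohort(cfg)))
  expect_equal(nrow(tab), 100L)
  expect_equal(unname(table(tab$session)), c(50L, 50L), ignore_attr = TRUE)
  expect_true(all(table(tab$subject) == 2L))
  # diagnosis groups are mutually exclusive with the configured counts
  subj <- tab[tab$session == "4PM", ]
  expect_equal(sort(as.integer(table(subj$diagnosis))),
               sort(c(14L, 14L, 7L, 6L, 1L, 8L)))
  expect_equal(sum(subj$cpap), 9L)
  dx <- as.matrix(subj[, grep("^dx_", names(subj))])
  expect_true(all(rowSums(dx) <= 1))
  expect_equal(sum(rowSums(dx) == 0), 8L)
})

test_that("volume-ratio identities hold to machine precision", {
  tab <- generate_cohort(cohort_config(n_subjects = 20, seed = 3))
  expect_equal(tab$rCPV, tab$cpv / tab$tiv, tolerance = 1e-12)
  expect_equal(tab$rWMHV, tab$wmhv / tab$tiv, tolerance = 1e-12)
})

test_that("marginals are recovered and bounded variables stay in bounds", {
  # closed-form moments of the doubly truncated normal: the generator's
  # marginal law, hence the recovery target for bounded variables
  tnorm_moments <- function(m, s, lo, hi) {
    a <- (lo - m) / s; b <- (hi - m) / s
    Z <- stats::pnorm(b) - stats::pnorm(a)
    da <- stats::dnorm(a); db <- stats::dnorm(b)
    fa <- ifelse(is.finite(a), a * da, 0)
    fb <- ifelse(is.finite(b), b * db, 0)
    mu <- m + s * (da - db) / Z
    v <- s^2 * (1 + (fa - fb) / Z - ((da - db) / Z)^2)
    c(mean = mu, sd = sqrt(v))
  }
  cfg <- cohort_config(n_subjects = 50, seed = 21)
  tab <- generate_cohort(cfg)
  vars <- cfg$variables
  t4 <- tab[tab$session == "4PM", ]
  for (k in seq_len(nrow(vars))) {
    nm <- vars$name[k]
    m <- if (nm == "alps") 1.391 else vars$mean[k]
    s <- if (nm == "alps") 0.261 else vars$sd[k]
    tm <- tnorm_moments(m, s, vars$lower[k], vars$upper[k])
    x <- t4[[nm]]
    expect_lt(abs(mean(x) - tm[["mean"]]), 3 * tm[["sd"]] / sqrt(50) + 0.05 * s)
    expect_lt(abs(stats::sd(x) - tm[["sd"]]), 0.25 * tm[["sd"]])
    expect_true(all(x >= vars$lower[k] & x <= vars$upper[k]))
  }
  expect_true(all(tab$sleep_efficiency >= 0 & tab$sleep_efficiency <= 100))
  expect_true(all(tab$lowest_spo2 <= 100))
})

test_that("an identity planted matrix yields near-independent columns", {
  vars <- default_cohort_variables()
  cfg <- cohort_config(n_subjects = 50, seed = 5,
                       planted = diag(nrow(vars)) |>
                         (\(M) {dimnames(M) <- list(vars$name, vars$name); M})())
  tab <- generate_cohort(cfg)
  probe <- c("alps", "rCPV", "rWMHV", "age", "rem_latency")
  C <- stats::cor(tab[, probe])
  expect_true(all(abs(C[upper.tri(C)]) < 0.3))
})

test_that("correlation repair is bounded and infeasible matrices error", {
  tab <- generate_cohort(cohort_config(n_subjects = 10, seed = 2))
  rep_diag <- attr(tab, "repair")
  expect_lt(rep_diag$max_shift, 0.05)
  expect_gte(rep_diag$min_eigenvalue, 0)
  # wildly inconsistent planted entries cannot be repaired within budget
  vars <- default_cohort_variables()
  R <- default_planted_correlations(vars$name)
  R["alps", "rCPV"] <- R["rCPV", "alps"] <- 0.95
  R["alps", "rWMHV"] <- R["rWMHV", "alps"] <- 0.95
  R["rCPV", "rWMHV"] <- R["rWMHV", "rCPV"] <- -0.95
  cfg_bad <- cohort_config(n_subjects = 10, seed = 2, planted = R)
  expect_error(generate_cohort(cfg_bad), "infeasible")
})

test_that("sensitivity subsets select the documented subgroups", {
  tab <- generate_cohort(cohort_config(n_subjects = 50, seed = 13))
  np <- subset_sensitivity(tab, "no_psych")
  expect_equal(length(unique(np$subject)), 8L)
  expect_equal(nrow(np), 16L)
  expect_true(all(np$diagnosis == "none"))
  nc <- subset_sensitivity(tab, "no_cpap")
  expect_equal(length(unique(nc$subject)), 41L)
  expect_true(all(table(nc$subject) == 2L))
  # table without flags is passed through unchanged
  plain <- as.data.frame(tab)[, c("subject", "session", "alps")]
  expect_identical(subset_sensitivity(plain, "no_psych"), plain)
})

test_that("attach_imaging records provenance; voxel mode tracks targets", {
  tab <- generate_cohort(cohort_config(n_subjects = 3, seed = 4))
  t_tab <- attach_imaging(tab, mode = "tabular")
  expect_identical(attr(t_tab, "mode"), "tabular")
  expect_equal(t_tab$alps, tab$alps)
  # voxel mode with fixed super-isotropic targets: measured indices track
  # the tabulated values through the fraction inversion
  tgt <- data.frame(subject = rep(c("a", "b", "c"), each = 2),
                    session = rep(c("4PM", "9AM"), 3),
                    alps = seq(1.1, 1.6, by = 0.1),
                    ccgALPS = seq(1.05, 1.30, by = 0.05),
                    ccbALPS = seq(1.6, 1.1, by = -0.1),
                    ccsALPS = seq(1.2, 1.45, by = 0.05))
  t_vox <- attach_imaging(tgt, mode = "voxel", spec = tiny_phantom_spec(),
                          snr = Inf, seed = 10)
  expect_identical(attr(t_vox, "mode"), "voxel")
  expect_gt(stats::cor(t_vox$alps, tgt$alps), 0.95)
  expect_gt(stats::cor(t_vox$ccbALPS, tgt$ccbALPS), 0.95)
  expect_true(all(c("projDxx", "ccbDyy", "ccgFA") %in% names(t_vox)))
})

test_that("cohort CSV + YAML sidecar round-trips", {
  dir <- withr::local_tempdir()
  tab <- generate_cohort(cohort_config(n_subjects = 5, seed = 6))
  path <- file.path(dir, "cohort.csv")
  write_cohort(tab, path)
  expect_true(file.exists(paste0(path, ".yaml")))
  back <- read_cohort(path)
  expect_equal(back$alps, tab$alps, tolerance = 1e-12)
  expect_equal(attr(back, "sidecar")$seed, 6)
  expect_identical(attr(back, "mode"), "tabular")
})
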