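# shared linear-Gaussian generator for mediation tests
make_mediation_data <- function(n, a, b, cprime, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  m <- a * x + stats::rnorm(n)
  y <- b * m + cprime * x + stats::rnorm(n)
  data.frame(x = x, m = m, y = y, age = stats::rnorm(n, 50, 10))
}

test_that("ACME + ADE = total exactly, and a null a-path gives null ACME", {
  d <- make_mediation_data(200, a = 0.5, b = 0.4, cprime = 0.3, seed = 2)
  fit <- mediate(d, "x", "m", "y", covariates = "age", n_boot = 199, seed = 3)
  expect_lt(abs(fit$acme$estimate + fit$ade$estimate - fit$total$estimate), 1e-9)
  expect_true(fit$acme$ci[1] <= fit$acme$estimate &&
              fit$acme$estimate <= fit$acme$ci[2])
  # mediator independent of x: ACME near zero, CI covers 0
  d0 <- make_mediation_data(300, a = 0, b = 0.4, cprime = 0.3, seed = 4)
  fit0 <- mediate(d0, "x", "m", "y", covariates = "age", n_boot = 199, seed = 5)
  expect_lt(abs(fit0$acme$estimate), 0.1)
  expect_true(fit0$acme$ci[1] <= 0 && fit0$acme$ci[2] >= 0)
})

test_that("planted effects are recovered within 3 SE at large n", {
  d <- make_mediation_data(2000, a = 0.5, b = 0.4, cprime = 0.3, seed = 6)
  fit <- mediate(d, "x", "m", "y", covariates = character(0), n_boot = 199,
                 seed = 7)
  # delta-method SE of the a*b product from the two path fits
  sm_a <- summary(stats::lm(m ~ x, d))$coefficients
  sm_b <- summary(stats::lm(y ~ x + m, d))$coefficients
  se_ab <- sqrt(sm_b["m", 1]^2 * sm_a["x", 2]^2 +
                sm_a["x", 1]^2 * sm_b["m", 2]^2)
  expect_lt(abs(fit$acme$estimate - 0.20), 3 * se_ab)
  expect_lt(abs(fit$ade$estimate - 0.30), 3 * sm_b["x", 2])
  expect_lt(abs(fit$total$estimate - 0.50),
            3 * summary(stats::lm(y ~ x, d))$coefficients["x", 2])
  expect_equal(fit$prop_mediated,
               fit$acme$estimate / fit$total$estimate, tolerance = 1e-12)
})

test_that("bootstrap is reproducible and guards degenerate inputs", {
  d <- make_mediation_data(60, a = 0.5, b = 0.4, cprime = 0.3, seed = 8)
  f1 <- mediate(d, "x", "m", "y", n_boot = 99, seed = 11)
  f2 <- mediate(d, "x", "m", "y", n_boot = 99, seed = 11)
  expect_identical(f1$acme, f2$acme)
  d$flat <- 5
  expect_error(mediate(d, "x", "flat", "y", n_boot = 49, seed = 1),
               "zero-variance")
  expect_error(mediate(d[1:10, ], "x", "m", "y", n_boot = 49, seed = 1),
               "fewer than 20")
})

test_that("the battery runs the ten published paths in order", {
  set.seed(12)
  n <- 120
  tab <- data.frame(assocDxx = rnorm(n), projDxx = rnorm(n),
                    assocDyy = rnorm(n), assocDzz = rnorm(n),
                    projDyy = rnorm(n), projDzz = rnorm(n),
                    ccbDxx = rnorm(n), ccbDyy = rnorm(n), ccbDzz = rnorm(n),
                    alps = rnorm(n), age = rnorm(n, 50, 12))
  bat <- mediation_battery(tab, n_boot = 59, seed = 13)
  df <- as.data.frame(bat)
  expect_equal(nrow(df), 10L)
  expect_equal(df$path, c(
    "assocDxx -> assocDyy -> alps", "assocDxx -> assocDzz -> alps",
    "projDxx -> projDyy -> alps", "projDxx -> projDzz -> alps",
    "assocDxx -> ccbDxx -> alps", "assocDxx -> ccbDyy -> alps",
    "assocDxx -> ccbDzz -> alps", "projDxx -> ccbDxx -> alps",
    "projDxx -> ccbDyy -> alps", "projDxx -> ccbDzz -> alps"))
  # identity holds for every model
  expect_true(all(abs(df$acme + df$ade - df$total) < 1e-9))
  expect_error(mediation_battery(tab[, -1]), "missing variable")
})

test_that("a planted callosal chain is recovered by its battery row", {
  set.seed(14)
  n <- 500
  assocDxx <- rnorm(n)
  ccbDyy <- 0.5 * assocDxx + rnorm(n)
  alps <- 0.4 * ccbDyy + 0.2 * assocDxx + rnorm(n)
  tab <- data.frame(assocDxx = assocDxx, ccbDyy = ccbDyy, alps = alps,
                    projDxx = rnorm(n), assocDyy = rnorm(n),
                    assocDzz = rnorm(n), projDyy = rnorm(n),
                    projDzz = rnorm(n), ccbDxx = rnorm(n), ccbDzz = rnorm(n),
                    age = rnorm(n, 50, 12))
  bat <- mediation_battery(tab, n_boot = 99, seed = 15)
  row <- as.data.frame(bat)[6L, ]   # assocDxx -> ccbDyy -> alps
  sm_a <- summary(stats::lm(ccbDyy ~ assocDxx + age, tab))$coefficients
  sm_b <- summary(stats::lm(alps ~ assocDxx + ccbDyy + age, tab))$coefficients
  se_ab <- sqrt(sm_b["ccbDyy", 1]^2 * sm_a["assocDxx", 2]^2 +
                sm_a["assocDxx", 1]^2 * sm_b["ccbDyy", 2]^2)
  expect_lt(abs(row$acme - 0.5 * 0.4), 3 * se_ab)
})
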