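test_that("perfect linear association gives r = 1 with tiny p", {
  d <- data.frame(x = 1:20, y = 2 * (1:20) + 1)
  res <- pearson_matrix_fdr(d, "x", "y")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-12)
  expect_equal(as.character(res$category), "very strong")
})

test_that("BH adjustment and strength categories follow their definitions", {
  # hand-worked BH: p = .01, .02, .03, .04 in one family -> all q = .04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # q >= p elementwise and consistent categories on a generated panel
  set.seed(8)
  d <- as.data.frame(matrix(rnorm(200), 20))
  names(d) <- paste0("v", 1:10)
  res <- pearson_matrix_fdr(d, paste0("v", 1:5), paste0("v", 6:10))
  expect_true(all(res$q >= res$p - 1e-15))
  expect_true(all(res$q <= 1))
  bands <- c("very weak", "weak", "moderate", "strong", "very strong")
  expect_equal(as.character(res$category),
               bands[findInterval(abs(res$r), c(0, .2, .4, .6, .8))])
  expect_equal(as.character(strength_category(-0.47)), "moderate")
  expect_equal(as.character(strength_category(0.2)), "weak")
  # zero-variance error names the column
  d$flat <- 1
  expect_error(pearson_matrix_fdr(d, "v1", "flat"), "zero-variance.*flat")
})

test_that("marker correlation table is r above and p below the diagonal", {
  set.seed(2)
  d <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  M <- marker_correlation_table(d, c("a", "b", "c"))
  ct <- stats::cor.test(d$a, d$b)
  expect_equal(M["a", "b"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(M["b", "a"], ct$p.value, tolerance = 1e-12)
  expect_equal(diag(M), c(a = 1, b = 1, c = 1))
})

test_that("standardized simple regression equals the Pearson correlation", {
  set.seed(4)
  d <- data.frame(x = rnorm(100), y = rnorm(100))
  d$y <- 0.6 * d$x + sqrt(1 - 0.36) * d$y
  fit <- standardized_ols(d, "y", "x", covariates = character(0))
  expect_equal(unname(coef(fit)["x"]), stats::cor(d$x, d$y), tolerance = 1e-12)
  expect_equal(fit$coefficients$vif, 1)
})

test_that("planted regression coefficients are recovered with correct VIF", {
  set.seed(5)
  n <- 500
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- -0.4 * d$x1 + 0.5 * d$x2 + stats::rnorm(n, sd = sqrt(1 - 0.41))
  fit <- standardized_ols(d, "y", c("x1", "x2"), covariates = character(0))
  cf <- fit$coefficients
  expect_lt(abs(cf$beta[cf$term == "x1"] + 0.4), 3 * cf$se[cf$term == "x1"])
  expect_lt(abs(cf$beta[cf$term == "x2"] - 0.5), 3 * cf$se[cf$term == "x2"])
  expect_true(all(cf$significant == (cf$ci_lower > 0 | cf$ci_upper < 0)))
  # VIF against the 1/(1 - R^2) closed form
  r2 <- summary(stats::lm(x1 ~ x2, data = d))$r.squared
  expect_equal(cf$vif[cf$term == "x1"], 1 / (1 - r2), tolerance = 1e-8)
  # degenerate outcome in noiseless identity model
  d$z <- d$x1
  fit_id <- suppressWarnings(
    standardized_ols(d, "z", c("x1", "x2"), covariates = character(0)))
  expect_equal(unname(coef(fit_id)["x1"]), 1, tolerance = 1e-9)
})

test_that("perfect collinearity is reported with the offending pair", {
  set.seed(6)
  d <- data.frame(x1 = rnorm(50))
  d$x2 <- 2 * d$x1
  d$y <- rnorm(50)
  expect_error(standardized_ols(d, "y", c("x1", "x2"),
                                covariates = character(0)),
               "collinearity between x[12] and x[12]")
})

test_that("one-sample t test matches its closed form and error contracts", {
  res <- one_sample_t(c(1.1, 1.2, 1.3), reference = 1)
  expect_equal(res$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * stats::pt(-res$t, df = 2), tolerance = 1e-12)
  sym <- one_sample_t(c(0.9, 1.1, 0.8, 1.2), reference = 1)
  expect_equal(sym$t, 0, tolerance = 1e-12)
  expect_equal(sym$p, 1, tolerance = 1e-12)
  expect_error(one_sample_t(rep(1.3, 5)), "degenerate sample")
})

test_that("the t test holds its nominal type-I error rate", {
  set.seed(7)
  n_sim <- 2000L
  rej <- vapply(seq_len(n_sim), function(i) {
    one_sample_t(stats::rnorm(20, mean = 1, sd = 0.2), reference = 1)$p < 0.05
  }, logical(1))
  rate <- mean(rej)
  band <- 2.576 * sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rate - 0.05), band)
})

test_that("motion-bias check behaves under dependence and independence", {
  d <- data.frame(mean_fd = seq(0.1, 0.3, length.out = 30))
  d$alps <- d$mean_fd
  res <- fd_alps_check(d)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$q, res$p)
  # Fisher-z coverage: with independent columns the 95% CI for r covers 0
  # in at least 90% of replicates
  set.seed(9)
  cover <- vapply(1:100, function(i) {
    di <- data.frame(mean_fd = rnorm(100), alps = rnorm(100))
    ci <- attr(fd_alps_check(di), "conf.int")
    ci[1] <= 0 && ci[2] >= 0
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})
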