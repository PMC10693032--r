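test_that("symmetric outcomes give a zero intercept", {
  y <- rep(c(0.4, 0.5, 0.6), 40)
  cohort <- data.frame(dummy = seq_along(y))
  fit <- fit_beta_regression(y, cohort, exposures = character())
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["(Intercept)"]]), 1e-6)
})

test_that("the analytic score matches finite differences of the likelihood", {
  set.seed(5)
  n <- 150
  x <- rnorm(n)
  mu <- plogis(-0.8 + 0.4 * x)
  y <- rbeta(n, mu * 40, (1 - mu) * 40)
  fit <- fit_beta_regression(y, data.frame(xv = x), exposures = "xv",
                             standardize_exposures = FALSE)
  th <- c(fit$coefficients, log(fit$phi))
  expect_lt(max(abs(fit$score)), 1e-6)
  fd <- vapply(seq_along(th), function(j) {
    h <- 1e-6 * max(1, abs(th[j]))
    up <- th; up[j] <- up[j] + h
    dn <- th; dn[j] <- dn[j] - h
    (beta_loglik(up, fit$y, fit$X) - beta_loglik(dn, fit$y, fit$X)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(beta_score(th, fit$y, fit$X) - fd)), 1e-4)
})

test_that("the accepted-step log-likelihood trace is monotone", {
  set.seed(6)
  sim <- generate_cohort(150, seed = 6)
  for (ct in c("syncytiotrophoblast", "hofbauer", "nrbc")) {
    fit <- fit_beta_regression(sim$truth$compositions[, ct], sim$cohort,
                               covariates = "sex")
    expect_true(fit$converged)
    expect_true(all(diff(fit$loglik_trace) >= 0))
  }
})

test_that("known beta-regression truth is recovered within Wald error", {
  set.seed(7)
  x <- rnorm(2000)
  mu <- plogis(-1 + 0.3 * x)
  y <- rbeta(2000, mu * 50, (1 - mu) * 50)
  fit <- fit_beta_regression(y, data.frame(xv = x), exposures = "xv",
                             standardize_exposures = FALSE)
  w <- wald_summary(fit)
  expect_true(all(abs(w$estimate - c(-1, 0.3)) <= 3 * w$se))
  expect_lt(abs(fit$phi - 50) / 50, 0.2)
  expect_true(all(w$se > 0))
})

test_that("a zero coefficient has Wald p-value one", {
  set.seed(8)
  y <- rbeta(200, 20, 20)
  fit <- fit_beta_regression(y, data.frame(xv = rnorm(200)), exposures = "xv",
                             standardize_exposures = FALSE)
  fit$coefficients["xv"] <- 0
  w <- wald_summary(fit)
  expect_equal(w$p[w$term == "xv"], 1)
})

test_that("flipping a binary covariate's coding flips its coefficient only", {
  set.seed(9)
  n <- 300
  grp <- rep(c("a", "b"), n / 2)
  mu <- plogis(-0.5 + 0.6 * (grp == "b"))
  y <- rbeta(n, mu * 60, (1 - mu) * 60)
  f1 <- fit_beta_regression(y, data.frame(g = grp), exposures = character(),
                            covariates = "g")
  grp2 <- ifelse(grp == "a", "z_a", "a_b")   # reverses the reference level
  f2 <- fit_beta_regression(y, data.frame(g = grp2), exposures = character(),
                            covariates = "g")
  b1 <- f1$coefficients; b2 <- f2$coefficients
  expect_equal(unname(b1[2]), -unname(b2[2]), tolerance = 1e-6)
  expect_equal(unname(b1[1]), unname(b2[1] + b2[2]), tolerance = 1e-6)
  mu1 <- plogis(drop(f1$X %*% b1))
  mu2 <- plogis(drop(f2$X %*% b2))
  expect_lt(max(abs(mu1 - mu2)), 1e-8)
})

test_that("large precision approaches the linear model on logit(y)", {
  set.seed(10)
  n <- 1500
  x <- rnorm(n)
  mu <- plogis(-0.7 + 0.25 * x)
  y <- rbeta(n, mu * 5000, (1 - mu) * 5000)
  fit <- fit_beta_regression(y, data.frame(xv = x), exposures = "xv",
                             standardize_exposures = FALSE)
  ref <- coef(lm(qlogis(y) ~ x))
  expect_lt(max(abs(fit$coefficients - ref) / abs(ref)), 0.02)
})

test_that("boundary outcomes error by default and squeeze on request", {
  y <- c(0, runif(100, 0.2, 0.8))
  cohort <- data.frame(xv = rnorm(101))
  expect_error(fit_beta_regression(y, cohort, exposures = "xv",
                                   standardize_exposures = FALSE),
               "boundary.*sample\\(s\\) 1")
  fit <- fit_beta_regression(y, cohort, exposures = "xv",
                             standardize_exposures = FALSE, squeeze = TRUE)
  expect_true(fit$converged)
  expect_error(fit_beta_regression(rep(0.3, 50), data.frame(xv = rnorm(50)),
                                   exposures = "xv",
                                   standardize_exposures = FALSE),
               "constant")
})

test_that("bootstrap percentile intervals bracket the Wald ones", {
  set.seed(12)
  x <- rnorm(250)
  mu <- plogis(-1 + 0.4 * x)
  y <- rbeta(250, mu * 50, (1 - mu) * 50)
  bs <- bootstrap_beta(y, data.frame(xv = x), exposures = "xv",
                       standardize_exposures = FALSE, B = 120, seed = 2)
  expect_true(all(bs$ci_lower < bs$estimate & bs$estimate < bs$ci_upper))
  expect_gt(bs$n_converged[1], 100)
  bs2 <- bootstrap_beta(y, data.frame(xv = x), exposures = "xv",
                        standardize_exposures = FALSE, B = 120, seed = 2)
  expect_identical(bs, bs2)
})
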