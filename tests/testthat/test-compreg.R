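test_that("pivot ilr basis is orthonormal with zero column sums", {
  b2 <- ilr_basis(c("a", "b"))
  expect_equal(unname(b2$V), matrix(c(1, -1) / sqrt(2), 2, 1))
  for (K in c(2, 3, 6, 7)) {
    b <- ilr_basis(paste0("p", seq_len(K)))
    expect_lt(max(abs(crossprod(b$V) - diag(K - 1))), 1e-12)
    expect_lt(max(abs(colSums(b$V))), 1e-12)
  }
  expect_error(ilr_basis(c("a", "a")), "duplicate")
})

test_that("ilr transform matches the closed form and inverts exactly", {
  b <- ilr_basis(c("a", "b"))
  expect_equal(unname(drop(ilr_transform(c(a = 0.5, b = 0.5), b))), 0,
               tolerance = 1e-14)
  z <- unname(drop(ilr_transform(c(a = 0.8, b = 0.2), b)))
  expect_equal(z, log(4) / sqrt(2), tolerance = 1e-12)  # 0.98026
  set.seed(8)
  for (K in c(2, 4, 6)) {
    bb <- ilr_basis(paste0("p", seq_len(K)))
    x <- runif_simplex(10, K)
    colnames(x) <- bb$cell_types
    back <- ilr_inverse(ilr_transform(x, bb), bb)
    expect_lt(max(abs(back - x)), 1e-10)
  }
  expect_error(ilr_transform(c(a = 1, b = 0), b), "replace_zeros")
})

test_that("noiseless linear truth is recovered exactly", {
  g1 <- c(0.3, -0.2, 0.1, 0, 0.05)
  g3 <- c(-0.1, 0, 0.2, -0.15, 0)
  sim <- generate_cohort(80, effect_spec = list(pm25_t1 = g1, pm25_t3 = g3),
                         composition_noise_sd = 0, seed = 10)
  fit <- fit_compositional(sim$truth$compositions, sim$cohort,
                           covariates = "sex")
  expect_lt(max(abs(fit$coefficients["pm25_t1", ] - g1)), 1e-8)
  expect_lt(max(abs(fit$coefficients["pm25_t2", ])), 1e-8)
  expect_lt(max(abs(fit$coefficients["pm25_t3", ] - g3)), 1e-8)
})

test_that("null simulations show no spurious exposure signal", {
  sim <- generate_cohort(500, seed = 77)
  fit <- fit_compositional(sim$truth$compositions, sim$cohort,
                           covariates = "sex")
  se <- sqrt(outer(diag(fit$XtXinv), diag(fit$residual_covariance)))
  tmat <- fit$coefficients / se
  expect_lt(max(abs(tmat[c("pm25_t1", "pm25_t2", "pm25_t3"), ])), 4)
})

test_that("composition effects sum to zero and vanish without an effect", {
  for (sd in c(31, 32)) {
    sim <- generate_cohort(150, seed = sd,
                           effect_spec = list(pm25_t2 = c(0.2, 0, -0.1, 0, 0)))
    fit <- fit_compositional(sim$truth$compositions, sim$cohort,
                             covariates = "sex")
    for (tr in c("t1", "t2", "t3"))
      expect_lt(abs(sum(composition_effect(fit, tr))), 1e-10)
  }
  # a zeroed coefficient row gives an exactly zero effect vector
  fit$coefficients["pm25_t1", ] <- 0
  expect_equal(unname(composition_effect(fit, "t1")), rep(0, 6))
  expect_error(composition_effect(fit, "t9"), "unknown trimester")
})

test_that("a known single-trimester effect maps to its simplex-scale truth", {
  g <- c(-0.25, 0.15, 0, 0, 0)
  b <- ilr_basis(placental_cell_types())
  bl <- default_baseline_composition()$male
  z0 <- as.numeric(ilr_transform(bl, b))
  truth_delta <- drop(ilr_inverse(z0 + g, b) - ilr_inverse(z0, b))
  sim <- generate_cohort(2000, sex_ratio = 0, composition_noise_sd = 0.1,
                         effect_spec = list(pm25_t1 = g), seed = 14)
  fit <- fit_compositional(sim$truth$compositions, sim$cohort)
  expect_lt(max(abs(composition_effect(fit, "t1") - truth_delta)), 0.01)
})

test_that("with two parts the multivariate F is the squared t of lm", {
  set.seed(41)
  n <- 60
  x <- rnorm(n); u <- rnorm(n)
  z <- 0.4 * x + rnorm(n)                      # single ilr coordinate
  b <- ilr_basis(c("a", "b"))
  comp <- ilr_inverse(matrix(z, ncol = 1), b)
  cohort <- data.frame(sample_id = seq_len(n), xv = x, uv = u)
  fit <- fit_compositional(comp, cohort, exposures = c("xv", "uv"),
                           standardize_exposures = FALSE)
  f <- multivariate_f(fit, "t1")
  ref <- summary(lm(z ~ x + u))$coefficients["x", ]
  expect_equal(unname(f["statistic"]), unname(ref["t value"]^2),
               tolerance = 1e-10)
  expect_equal(pf(f["statistic"], f["df1"], f["df2"], lower.tail = FALSE),
               c(statistic = unname(ref["Pr(>|t|)"])), tolerance = 1e-10)
  # Pillai and Wilks agree for a one-row hypothesis
  expect_equal(multivariate_f(fit, "t1", "pillai"), f, tolerance = 1e-10)
})

test_that("with two parts the fit reduces to lm on the log-ratio", {
  set.seed(42)
  n <- 50
  x <- rnorm(n)
  lr <- 1 + 0.5 * x + rnorm(n, 0, 0.3)          # log(p1/p2)
  comp <- cbind(a = plogis(lr), b = 1 - plogis(lr))
  cohort <- data.frame(xv = x)
  fit <- fit_compositional(comp, cohort, exposures = "xv",
                           standardize_exposures = FALSE)
  ref <- lm(lr ~ x)
  expect_equal(unname(fit$coefficients[, 1]), unname(coef(ref)) / sqrt(2),
               tolerance = 1e-10)
})

test_that("reported quantities are invariant to the pivot order", {
  sim <- generate_cohort(180, seed = 55,
                         effect_spec = list(pm25_t1 = c(-0.2, 0.1, 0, 0.05, 0)))
  ct <- placental_cell_types()
  fit0 <- fit_compositional(sim$truth$compositions, sim$cohort,
                            covariates = "sex", basis = ilr_basis(ct))
  set.seed(1)
  for (r in 1:3) {
    perm <- sample(ct)
    fitp <- fit_compositional(sim$truth$compositions, sim$cohort,
                              covariates = "sex", basis = ilr_basis(perm))
    for (tr in c("t1", "t2", "t3")) {
      expect_lt(max(abs(composition_effect(fit0, tr) -
                          composition_effect(fitp, tr)[ct])), 1e-8)
      expect_lt(abs(multivariate_f(fit0, tr)["statistic"] -
                      multivariate_f(fitp, tr)["statistic"]), 1e-8)
    }
  }
})

test_that("outputs are invariant to pre-closure scaling of the input", {
  sim <- generate_cohort(120, seed = 66)
  W <- sim$truth$compositions
  f1 <- fit_compositional(W, sim$cohort, covariates = "sex")
  f2 <- fit_compositional((3 * W) / rowSums(3 * W), sim$cohort,
                          covariates = "sex")
  expect_equal(f1$composition_effects, f2$composition_effects,
               tolerance = 1e-12)
  expect_equal(multivariate_f(f1, "t2"), multivariate_f(f2, "t2"),
               tolerance = 1e-12)
})

test_that("null multivariate p-values are approximately uniform", {
  pv <- numeric(300)
  for (r in seq_len(300)) {
    sim <- generate_cohort(100, sex_ratio = 0, seed = 9000 + r)
    fit <- fit_compositional(sim$truth$compositions, sim$cohort)
    f <- multivariate_f(fit, "t1")
    pv[r] <- pf(f["statistic"], f["df1"], f["df2"], lower.tail = FALSE)
  }
  expect_lt(suppressWarnings(ks.test(pv, "punif")$statistic), 0.08)
})

test_that("rank-deficient designs are reported with the collinear columns", {
  sim <- generate_cohort(50, seed = 3)
  cohort <- sim$cohort
  cohort$pm25_dup <- cohort$pm25_t1
  expect_error(
    fit_compositional(sim$truth$compositions, cohort,
                      exposures = c("pm25_t1", "pm25_t2", "pm25_t3",
                                    "pm25_dup")),
    "collinear.*pm25_dup")
  expect_error(
    fit_compositional(sim$truth$compositions[1:8, ], cohort[1:8, ],
                      covariates = "sex"),
    "too few samples")
})

test_that("bootstrap inference is seed-deterministic", {
  sim <- generate_cohort(80, seed = 23)
  f1 <- bootstrap_inference(sim$truth$compositions, sim$cohort,
                            covariates = "sex", B = 100, seed = 11)
  f2 <- bootstrap_inference(sim$truth$compositions, sim$cohort,
                            covariates = "sex", B = 100, seed = 11)
  expect_identical(f1$ci, f2$ci)
  expect_identical(f1$overall_p, f2$overall_p)
  expect_identical(f1$bootstrap_draws, f2$bootstrap_draws)
  f3 <- bootstrap_inference(sim$truth$compositions, sim$cohort,
                            covariates = "sex", B = 100, seed = 12)
  expect_false(identical(f1$overall_p, f3$overall_p))
  expect_error(bootstrap_inference(sim$truth$compositions, sim$cohort,
                                   B = 50), "at least 100")
})

test_that("bootstrap intervals shrink at roughly the root-n rate", {
  ratios <- sapply(1:6, function(r) {
    s1 <- generate_cohort(100, seed = 100 + r)
    s4 <- generate_cohort(400, seed = 100 + r)
    f1 <- bootstrap_inference(s1$truth$compositions, s1$cohort,
                              covariates = "sex", B = 200, seed = r)
    f4 <- bootstrap_inference(s4$truth$compositions, s4$cohort,
                              covariates = "sex", B = 200, seed = r)
    mean(f1$ci[, , "upper"] - f1$ci[, , "lower"]) /
      mean(f4$ci[, , "upper"] - f4$ci[, , "lower"])
  })
  expect_gt(mean(ratios), 1.7)
  expect_lt(mean(ratios), 2.3)
})
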