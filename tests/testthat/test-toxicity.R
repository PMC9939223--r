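test_that("a symmetric design gives a zero intercept", {
  df <- data.frame(x = rep(c(-1, 1), each = 40),
                   y = rep(c(0, 1), each = 40))
  fit <- fit_logistic(df, "y", "x")
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), 0,
               tolerance = 1e-6)
})

test_that("estimates agree with a brute-force likelihood maximizer", {
  set.seed(71)
  x <- c(-2.1, -1.4, -0.8, -0.3, 0.1, 0.5, 0.9, 1.4, 1.8, 2.3)
  y <- c(0, 0, 1, 0, 0, 1, 1, 0, 1, 1)
  fit <- fit_logistic(data.frame(x = x, y = y), "y", "x")
  oracle <- oracle_logistic_grid(x, y)
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-4)
})

test_that("probability, odds and odds ratio follow the logit algebra", {
  fake <- structure(list(
    coefficients = c("(Intercept)" = 0, x = log(4)),
    vcov = matrix(c(0.04, 0, 0, 0.01), 2, 2,
                  dimnames = list(c("(Intercept)", "x"),
                                  c("(Intercept)", "x"))),
    covariates = "x", outcome = "y"), class = "fu_logistic")
  expect_equal(probability(fake, data.frame(x = 0)), 0.5)
  expect_equal(probability(fake, data.frame(x = 1)), 0.8)
  expect_equal(probability(fake, data.frame(x = 1e3)), 1, tolerance = 1e-6)

  expect_equal(odds(0.5), 1)
  expect_equal(odds(0.8), 4)
  expect_equal(odds(0), 0)
  expect_warning(o1 <- odds(1), "infinite")
  expect_equal(o1, Inf)
  expect_error(odds(1.2), "p")

  # odds(probability(x)) == exp(z) to numerical precision
  xs <- data.frame(x = seq(-3, 3, by = 0.5))
  expect_equal(odds(probability(fake, xs)), exp(log(4) * xs$x),
               tolerance = 1e-12)

  or <- odds_ratio(fake, "x")
  expect_equal(or$or, 4)
  expect_equal(or$conf.low, exp(log(4) - 1.96 * 0.1), tolerance = 1e-3)
})

test_that("reported per-unit reductions match the published effect sizes", {
  fake <- structure(list(
    coefficients = c("(Intercept)" = 0, x = log(0.52)),
    vcov = diag(2), covariates = "x", outcome = "y"),
    class = "fu_logistic")
  dimnames(fake$vcov) <- list(c("(Intercept)", "x"), c("(Intercept)", "x"))
  or <- odds_ratio(fake, "x")
  expect_equal(or$or, 0.52)
  expect_equal(or$percent_change, 48)

  fake$coefficients["x"] <- -1.8971
  or2 <- odds_ratio(fake, "x")
  expect_equal(or2$or, 0.150, tolerance = 1e-3)
  expect_equal(or2$percent_change, 85, tolerance = 1e-2)

  fake$coefficients["x"] <- 0
  expect_equal(odds_ratio(fake, "x")$or, 1)
})

test_that("probability band is a delta-method interval inside (0,1)", {
  Sigma <- matrix(c(0.09, -0.02, -0.02, 0.04), 2, 2,
                  dimnames = list(c("(Intercept)", "x"),
                                  c("(Intercept)", "x")))
  fake <- structure(list(
    coefficients = c("(Intercept)" = -0.5, x = 0.8),
    vcov = Sigma, covariates = "x", outcome = "y"), class = "fu_logistic")
  band <- probability_band(fake, data.frame(x = 2))
  xvec <- c(1, 2)
  z <- sum(xvec * fake$coefficients)
  sdz <- sqrt(drop(t(xvec) %*% Sigma %*% xvec))
  expect_equal(band$p, plogis(z))
  expect_equal(band$conf.low, plogis(z - 1.96 * sdz), tolerance = 1e-3)
  expect_equal(band$conf.high, plogis(z + 1.96 * sdz), tolerance = 1e-3)

  grid <- data.frame(x = seq(-12, 12, by = 2))
  b <- probability_band(fake, grid)
  expect_true(all(b$conf.low > 0 & b$conf.high < 1))
  expect_true(all(b$conf.low <= b$p & b$p <= b$conf.high))

  # zero covariance collapses the band onto the estimate
  fake0 <- fake
  fake0$vcov[] <- 0
  b0 <- probability_band(fake0, grid)
  expect_equal(b0$conf.low, b0$p)
})

test_that("odds ratio is invariant to centering of the covariate", {
  set.seed(73)
  x <- rnorm(300, 2, 1)
  y <- rbinom(300, 1, plogis(1 - 0.9 * x))
  f1 <- fit_logistic(data.frame(x = x, y = y), "y", "x")
  f2 <- fit_logistic(data.frame(x = x - mean(x), y = y), "y", "x")
  expect_equal(unname(f1$coefficients[["x"]]),
               unname(f2$coefficients[["x"]]), tolerance = 1e-6)
})

test_that("degenerate outcomes and separation are surfaced", {
  expect_error(fit_logistic(data.frame(x = 1:10, y = 0), "y", "x"),
               "constant")
  expect_error(fit_logistic(data.frame(x = 1:10, y = 0.5), "y", "x"),
               "0/1")
  df <- data.frame(x = c(1:5, 11:15), y = rep(c(0, 1), each = 5))
  expect_warning(fit <- fit_logistic(df, "y", "x"), "separation")
  expect_true(fit$separation)
})

test_that("the AE/SMI grid reports one univariable fit per pair", {
  ds <- generate_cohort(cohort_spec(n_subjects = 300), seed = 77)
  truth <- reference_ae_truth()
  sim <- simulate_adverse_events(ds, truth, seed = 77)
  res <- run_all_ae(sim)
  expect_equal(nrow(res), 2 * 4)  # 2 AE types present x 4 SMI measures
  expect_equal(attr(res, "p_adjust"), "none")
  # the simulated true pairs come out strongly protective
  fat <- res[res$ae_type == "fatigue" & res$smi == "smi_psoas", ]
  expect_lt(fat$or, 1)
  expect_lt(fat$p.value, 0.05)
  pol <- res[res$ae_type == "polyneuropathy" & res$smi == "smi_back", ]
  expect_lt(pol$or, 1)
  expect_lt(pol$p.value, 0.05)

  # empty AE table -> empty grid
  empty <- run_all_ae(generate_cohort(cohort_spec(n_subjects = 5), seed = 1))
  expect_equal(nrow(empty), 0)
})

test_that("degenerate outcome rows are flagged without affecting others", {
  ds <- generate_cohort(cohort_spec(n_subjects = 60), seed = 79)
  truth <- dplyr::bind_rows(
    reference_ae_truth()[1, ],
    tibble::tibble(ae_type = "emesis", covariate = "smi_psoas",
                   beta0 = -50, beta1 = 0)  # never severe
  )
  sim <- simulate_adverse_events(ds, truth, seed = 79)
  res <- run_all_ae(sim, smi_measures = "smi_psoas")
  expect_equal(res$note[res$ae_type == "emesis"], "degenerate outcome")
  expect_false(is.na(res$or[res$ae_type == "fatigue"]))
})

test_that("probability plot builds", {
  set.seed(81)
  df <- data.frame(smi_psoas = runif(80, 0.5, 3.5))
  df$outcome <- rbinom(80, 1, plogis(2 - 1.5 * df$smi_psoas))
  fit <- fit_logistic(df, "outcome", "smi_psoas")
  expect_s3_class(plot_probability(fit, df), "ggplot")
})
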