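test_that("with no IIV the OFV is the closed-form weighted least squares", {
  ds <- make_toy_dataset(n_sub = 1, obs_per_sub = 1, dv = 1100)
  m <- pop_model(cl_pop = 200, omega_cl = 0, sigma_prop = 0.2)
  pred <- 200 / 200 * 1000
  byhand <- log((0.2 * pred)^2) + (1100 - pred)^2 / (0.2 * pred)^2
  expect_equal(ofv(m, ds), byhand)
})

test_that("OFV is additive over subjects", {
  set.seed(7)
  ds <- make_toy_dataset(n_sub = 3, obs_per_sub = 2)
  m <- pop_model(cl_pop = 200, omega_cl = 0.2, sigma_prop = 0.2)
  sim <- simulate_concentrations(ds, m, seed = 7)
  doubled <- fu_dataset(
    dplyr::bind_rows(sim$subjects,
                     dplyr::mutate(sim$subjects,
                                   subject_id = paste0(subject_id, "b"))),
    dplyr::bind_rows(sim$doses,
                     dplyr::mutate(sim$doses,
                                   subject_id = paste0(subject_id, "b"))),
    dplyr::bind_rows(sim$observations,
                     dplyr::mutate(sim$observations,
                                   subject_id = paste0(subject_id, "b")))
  )
  expect_equal(ofv(m, doubled), 2 * ofv(m, sim), tolerance = 1e-8)
})

test_that("marginal likelihood matches the adaptive quadrature oracle", {
  cases <- list(
    list(sigma = 0.214, omega = cv_to_omega(20.9), seed = 1),
    list(sigma = 0.10, omega = 0.35, seed = 2),
    list(sigma = 0.30, omega = 0.15, seed = 3)
  )
  for (cs in cases) {
    set.seed(cs$seed)
    ds <- make_toy_dataset(n_sub = 5, obs_per_sub = 3,
                           bsa = runif(5, 1.5, 2.5),
                           smi_back = runif(5, 1.5, 7))
    m <- pop_model(cl_pop = 210, effects = list(
      covariate_effect("bsa", "linear_proportional", 0.7, 1.97),
      covariate_effect("smi_back", "exponential", 0.05, 3.78)),
      omega_cl = cs$omega, sigma_prop = cs$sigma)
    sim <- simulate_concentrations(ds, m, seed = cs$seed)
    expect_lt(abs(ofv(m, sim) - oracle_ofv_gh(m, sim)), 1e-3)
  }
})

test_that("noise-free data identify the population clearance exactly", {
  ds <- make_toy_dataset(n_sub = 4, obs_per_sub = 2)
  truth <- pop_model(cl_pop = 200, omega_cl = 0, sigma_prop = 1e-9)
  sim <- simulate_concentrations(ds, truth, seed = 1)
  init <- pop_model(cl_pop = 150, omega_cl = 0, sigma_prop = 1e-9,
                    fixed = c("v", "omega_v", "sigma_prop"))
  fit <- fit_pk(sim, init, compute_se = FALSE)
  expect_equal(unname(fit$par[["cl_pop"]]), 200, tolerance = 1e-5)
})

test_that("the fitted model is at least as likely as the truth", {
  set.seed(9)
  ds <- make_toy_dataset(n_sub = 8, obs_per_sub = 3,
                         bsa = runif(8, 1.5, 2.5))
  truth <- pop_model(cl_pop = 220, omega_cl = 0.2, sigma_prop = 0.2)
  sim <- simulate_concentrations(ds, truth, seed = 9)
  fit <- fit_pk(sim, truth, compute_se = FALSE)
  expect_lte(fit$ofv, ofv(truth, sim) + 1e-6)
  expect_true(fit$converged)
})

test_that("empirical Bayes estimates match a 1-D grid/optimize oracle", {
  set.seed(13)
  ds <- make_toy_dataset(n_sub = 3, obs_per_sub = 3)
  m <- pop_model(cl_pop = 200, omega_cl = 0.25, sigma_prop = 0.2)
  sim <- simulate_concentrations(ds, m, seed = 13)
  fit <- fit_pk(sim, m, fixed = c("v", "omega_v", "cl_pop", "omega_cl",
                                  "sigma_prop"), compute_se = FALSE)
  ebes <- empirical_bayes(fit, sim)
  for (i in seq_len(3)) {
    id <- sim$subjects$subject_id[i]
    obs <- sim$observations[sim$observations$subject_id == id, ]
    rate <- 4800 / 24
    negjoint <- function(eta) {
      pred <- rate / (200 * exp(eta)) * 1000
      v <- (0.2 * pred)^2
      sum(log(v) + (obs$dv - pred)^2 / v) + eta^2 / 0.25^2
    }
    oracle <- optimize(negjoint, c(-2, 2), tol = 1e-10)$minimum
    expect_equal(ebes$eta_cl[ebes$subject_id == id], oracle,
                 tolerance = 1e-4)
  }
})

test_that("subjects without observations get an EBE of exactly zero", {
  ds <- make_toy_dataset(n_sub = 3, obs_per_sub = 2)
  ds$observations <- ds$observations[ds$observations$subject_id != "T02", ]
  ds <- fu_dataset(ds$subjects, ds$doses, ds$observations)
  m <- pop_model(cl_pop = 200, omega_cl = 0.25, sigma_prop = 0.2)
  sim <- simulate_concentrations(ds, m, seed = 3)
  fit <- fit_pk(sim, m, compute_se = FALSE)
  expect_equal(fit$ebes$eta_cl[fit$ebes$subject_id == "T02"], 0)
})

test_that("eta shrinkage follows 100*(1 - SD(ebe)/omega), eta_V is 100%", {
  set.seed(17)
  ds <- make_toy_dataset(n_sub = 3, obs_per_sub = 3)
  m <- pop_model(cl_pop = 200, omega_cl = 0.25, sigma_prop = 0.2)
  sim <- simulate_concentrations(ds, m, seed = 17)
  fit <- fit_pk(sim, m, compute_se = FALSE)
  shr <- shrinkage(fit, sim)
  expect_equal(shr$eta_cl, 100 * (1 - sd(fit$ebes$eta_cl) / fit$model$omega_cl))
  expect_equal(shr$eta_v, 100)
  # informative-data limit: shrinkage falls with many observations
  ds_rich <- make_toy_dataset(n_sub = 6, obs_per_sub = 25)
  sim_rich <- simulate_concentrations(ds_rich, m, seed = 18)
  fit_rich <- fit_pk(sim_rich, m, compute_se = FALSE)
  expect_lt(shrinkage(fit_rich, sim_rich)$eta_cl, 25)
})

test_that("standard errors agree with an independent closed-form OFV", {
  # omega = 0, sigma fixed: the OFV is the analytic WLS form and the SE of
  # CL can be computed by hand-differentiating that expression
  set.seed(19)
  ds <- make_toy_dataset(n_sub = 4, obs_per_sub = 3)
  truth <- pop_model(cl_pop = 200, omega_cl = 0, sigma_prop = 0.1)
  sim <- simulate_concentrations(ds, truth, seed = 19)
  fit <- fit_pk(sim, truth,
                fixed = c("v", "omega_v", "omega_cl", "sigma_prop"))
  ofv_hand <- function(cl) {
    pred <- 4800 / 24 / cl * 1000
    sum(log((0.1 * pred)^2) + (sim$observations$dv - pred)^2 /
          (0.1 * pred)^2)
  }
  h <- 1e-3 * fit$par[["cl_pop"]]
  hess <- (ofv_hand(fit$par[["cl_pop"]] + h) -
             2 * ofv_hand(fit$par[["cl_pop"]]) +
             ofv_hand(fit$par[["cl_pop"]] - h)) / h^2 / 2
  expect_equal(unname(fit$se[["cl_pop"]]), 1 / sqrt(hess), tolerance = 1e-3)
  # fixed parameters carry no RSE
  expect_false("sigma_prop" %in% names(fit$rse_percent))
  expect_true(all(fit$rse_percent > 0))
})

test_that("likelihood-ratio test reproduces the chi-square calibration", {
  expect_equal(signif(lrt(3.84, 0, 1), 3), 0.05)
  expect_equal(lrt(10, 10, 1), 1)
  expect_equal(signif(lrt(6.63, 0, 1), 2), 0.01)
  expect_error(lrt(5, 0, 0), "df")
  expect_warning(p <- lrt(0, 5, 1), "full model")
  expect_equal(p, 1)
})

test_that("adding a truly informative covariate lowers the OFV", {
  set.seed(23)
  spec <- cohort_spec(n_subjects = 40)
  truth <- pop_model(cl_pop = 223, effects = list(
    covariate_effect("bsa", "linear_proportional", 0.794, 1.97)),
    omega_cl = cv_to_omega(20.9), sigma_prop = 0.214)
  sim <- simulate_concentrations(generate_cohort(spec, seed = 23), truth,
                                 seed = 23)
  base <- fit_pk(sim, pop_model(cl_pop = 200, omega_cl = 0.25,
                                sigma_prop = 0.25), compute_se = FALSE)
  with_cov <- fit_pk(sim, pop_model(cl_pop = 200, effects = list(
    covariate_effect("bsa", "linear_proportional", 0, 1.97)),
    omega_cl = 0.25, sigma_prop = 0.25), compute_se = FALSE)
  expect_lt(with_cov$ofv, base$ofv)
})

test_that("legacy residual-variability IIV model fits with two random effects", {
  set.seed(29)
  ds <- make_toy_dataset(n_sub = 15, obs_per_sub = 4)
  truth <- pop_model(cl_pop = 200, omega_cl = 0.2, sigma_prop = 0.2,
                     omega_eps = 0.3)
  sim <- simulate_concentrations(ds, truth, seed = 29)
  fit <- fit_pk(sim, truth, compute_se = FALSE)
  expect_true(fit$converged)
  expect_true("omega_eps" %in% names(fit$par))
  expect_true("eta_eps" %in% names(fit$ebes))
  expect_gt(fit$par[["omega_eps"]], 0)
})
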