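# Shared fixtures and independent oracles.

# A tiny hand-built dataset: steady-state TDM draws with known dosing.
make_toy_dataset <- function(n_sub = 2, obs_per_sub = 2, dose = 4800,
                             duration = 24, dv = NULL, bsa = NULL,
                             smi_back = NULL) {
  ids <- sprintf("T%02d", seq_len(n_sub))
  subjects <- tibble::tibble(
    subject_id = ids, sex = rep(c("male", "female"), length.out = n_sub),
    age = 60, height = 1.75,
    bsa = bsa %||% rep(1.97, n_sub),
    smi_psoas = 1.48, smi_back = smi_back %||% rep(3.78, n_sub),
    smi_total_hu = 9.58, smi_total_seg = 50.26,
    ct_offset_days = 0
  )
  doses <- tibble::tibble(
    subject_id = ids, cycle = 1L, dose_amount = dose,
    infusion_duration = duration, start_time = 0
  )
  obs <- tibble::tibble(
    subject_id = rep(ids, each = obs_per_sub),
    cycle = 1L,
    time = rep(duration - 1, n_sub * obs_per_sub),
    dv = dv %||% rep(1000, n_sub * obs_per_sub),
    steady_state = TRUE
  )
  fu_dataset(subjects, doses, obs)
}

`%||%` <- rlang::`%||%`

# Independent adaptive Gauss-Hermite oracle for the marginal -2 log
# likelihood of the one-compartment steady-state model with lognormal IIV on
# clearance. Written from the model formulas directly (no calls into the
# package's likelihood path). NONMEM-style constant convention: n*log(2*pi)
# omitted.
oracle_ofv_gh <- function(model, dataset, n_nodes = 64) {
  gh <- pracma::gaussHermite(n_nodes)
  subj <- dataset$subjects
  total <- 0
  for (i in seq_len(nrow(subj))) {
    id <- subj$subject_id[i]
    obs <- dataset$observations[dataset$observations$subject_id == id, ]
    if (nrow(obs) == 0) next
    dose <- dataset$doses[dataset$doses$subject_id == id, ]
    rate <- dose$dose_amount[match(obs$cycle, dose$cycle)] /
      dose$infusion_duration[match(obs$cycle, dose$cycle)]
    rate[is.na(rate)] <- dose$dose_amount[1] / dose$infusion_duration[1]
    tvcl <- model$cl_pop
    for (e in model$effects) {
      x <- subj[[e$covariate]][i]
      tvcl <- tvcl * switch(e$form,
        linear_proportional = 1 + e$theta * (x - e$center),
        exponential = exp(e$theta * (x - e$center)),
        power = (x / e$center)^e$theta,
        piecewise_linear = 1 + (if (x < e$center) e$theta[1] else
          e$theta[2]) * (x - e$center))
    }
    om <- model$omega_cl
    loglik_cond <- function(eta) {
      cl <- tvcl * exp(eta)
      pred <- rate / cl * 1000
      pred <- ifelse(obs$steady_state, pred,
                     pred * (1 - exp(-(cl / model$v) * obs$time)))
      v <- model$sigma_add^2 + (model$sigma_prop * pred)^2
      sum(dnorm(obs$dv, mean = pred, sd = sqrt(v), log = TRUE))
    }
    if (om == 0) {
      total <- total + (-2 * loglik_cond(0)) - nrow(obs) * log(2 * pi)
      next
    }
    # adaptive centering: mode and curvature of the joint log density
    negjoint <- function(eta) -loglik_cond(eta) - dnorm(eta, 0, om, log = TRUE)
    opt <- optimize(negjoint, interval = c(-8 * om - 1, 8 * om + 1))
    mode <- opt$minimum
    hh <- 1e-4
    curv <- (negjoint(mode + hh) - 2 * negjoint(mode) + negjoint(mode - hh)) /
      hh^2
    s <- 1 / sqrt(max(curv, 1e-8))
    nodes <- mode + sqrt(2) * s * gh$x
    logf <- vapply(nodes, function(e) {
      loglik_cond(e) + dnorm(e, 0, om, log = TRUE)
    }, numeric(1))
    # log integral = log( sqrt(2) s sum_k w_k exp(x_k^2) f(node_k) )
    m <- max(logf + gh$x^2)
    log_integral <- log(sqrt(2) * s) + m +
      log(sum(gh$w * exp(logf + gh$x^2 - m)))
    total <- total + (-2) * log_integral - nrow(obs) * log(2 * pi)
  }
  total
}

# Brute-force logistic log-likelihood maximizer on a parameter grid, refined
# by Nelder-Mead from the best grid point (still independent of glm/IRLS).
oracle_logistic_grid <- function(x, y) {
  nll <- function(b) {
    z <- b[1] + b[2] * x
    -sum(y * z - log1p(exp(z)))
  }
  grid <- expand.grid(b0 = seq(-5, 5, by = 0.25), b1 = seq(-5, 5, by = 0.25))
  vals <- apply(grid, 1, nll)
  best <- as.numeric(grid[which.min(vals), ])
  optim(best, nll, method = "Nelder-Mead",
        control = list(reltol = 1e-12, maxit = 5000))$par
}

# Base model without covariates, used widely in tests
base_model <- function(...) {
  pop_model(cl_pop = 200, omega_cl = 0.2, sigma_prop = 0.2, sigma_add = 0,
            ...)
}

# Small cohort spec for fast fits in resampling-heavy tests
small_spec <- function(n = 40) {
  cohort_spec(n_subjects = n)
}
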