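#' @keywords internal
#' @noRd
#' Precompute the flat observation/dosing/covariate structure used by the
#' likelihood. Observations are matched to the dose of their cycle (falling
#' back to the subject's first dose) and ordered by subject.
fu_prep <- function(dataset, model) {
  stopifnot(inherits(dataset, "fu_dataset"))
  subj <- dataset$subjects
  n_sub <- nrow(subj)
  for (e in model$effects) {
    if (!e$covariate %in% names(subj)) {
      abort(paste0("Covariate \"", e$covariate,
                   "\" required by the model is missing from the dataset."))
    }
    bad <- subj$subject_id[is.na(subj[[e$covariate]])]
    if (length(bad)) {
      abort(paste0("Covariate \"", e$covariate, "\" missing for subject(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  obs <- dataset$observations
  doses <- dataset$doses |>
    dplyr::mutate(rate = .data$dose_amount / .data$infusion_duration)
  first_dose <- doses |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", first_rate = "rate")
  obs <- obs |>
    dplyr::left_join(doses |>
                       dplyr::distinct(.data$subject_id, .data$cycle,
                                       .keep_all = TRUE) |>
                       dplyr::select("subject_id", "cycle", "rate"),
                     by = c("subject_id", "cycle")) |>
    dplyr::left_join(first_dose, by = "subject_id") |>
    dplyr::mutate(rate = dplyr::coalesce(.data$rate, .data$first_rate))
  idx <- match(obs$subject_id, subj$subject_id)
  ord <- order(idx)
  obs <- obs[ord, , drop = FALSE]
  idx <- idx[ord]
  # block boundaries of each subject's (sorted, contiguous) observations,
  # for fast groupwise sums in the likelihood
  ends <- which(c(idx[-1] != idx[-length(idx)], TRUE))
  list(
    subjects = subj, n_sub = n_sub, n_obs = nrow(obs),
    idx = idx, u_idx = idx[ends], ends = ends,
    dv = obs$dv, rate = obs$rate, time = obs$time,
    ss = obs$steady_state, all_ss = all(obs$steady_state)
  )
}

# Per-subject -2*log joint density (constants n_i*log(2pi) and d*log(2pi)
# omitted; they cancel in the Laplace approximation and in the NONMEM-style
# OFV convention). Returns a length-n_sub vector.
h_subjects <- function(prep, tvcl, v, sig_a, sig_p, om, ome,
                       eta_cl, eta_eps) {
  cl_i <- tvcl * exp(eta_cl)
  cl_o <- cl_i[prep$idx]
  pred <- prep$rate / cl_o * 1000
  if (!prep$all_ss) {
    ns <- !prep$ss
    pred[ns] <- pred[ns] * (1 - exp(-(cl_o[ns] / v) * prep$time[ns]))
  }
  var_o <- sig_a^2 + (sig_p * pred)^2
  if (!is.null(eta_eps)) var_o <- var_o * exp(2 * eta_eps[prep$idx])
  if (any(var_o <= 0)) return(rep(Inf, prep$n_sub))
  res <- prep$dv - pred
  cs <- cumsum(log(var_o) + res^2 / var_o)
  out <- numeric(prep$n_sub)
  out[prep$u_idx] <- cs[prep$ends] - c(0, cs[prep$ends[-length(prep$ends)]])
  if (om > 0) out <- out + eta_cl^2 / om^2 + log(om^2)
  if (!is.null(eta_eps)) out <- out + eta_eps^2 / ome^2 + log(ome^2)
  out
}

# Gauss-Hermite nodes/weights by Golub-Welsch on the Jacobi matrix; cached.
gh_cache <- new.env(parent = emptyenv())
gauss_hermite_rule <- function(n) {
  key <- as.character(n)
  if (!is.null(gh_cache[[key]])) return(gh_cache[[key]])
  if (n == 1) {
    rule <- list(x = 0, w = sqrt(pi))
  } else {
    off <- sqrt(seq_len(n - 1) / 2)
    J <- matrix(0, n, n)
    J[cbind(seq_len(n - 1), 2:n)] <- off
    J[cbind(2:n, seq_len(n - 1))] <- off
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    rule <- list(x = e$values[ord],
                 w = sqrt(pi) * (e$vectors[1, ord])^2)
  }
  gh_cache[[key]] <- rule
  rule
}

# Vectorized per-subject Newton search of the conditional modes (1 or 2
# random-effect dimensions), followed by the Laplace log-determinant term,
# optionally refined by adaptive Gauss-Hermite quadrature centered and
# scaled at the mode (n_agq > 1; one random-effect dimension only).
laplace_ofv <- function(prep, tvcl, v, sig_a, sig_p, om, ome,
                        eta_start = NULL, n_agq = 21) {
  n <- prep$n_sub
  dims <- c(cl = om > 0, eps = ome > 0)
  d <- sum(dims)
  hf <- function(eta) {
    h_subjects(prep, tvcl, v, sig_a, sig_p, om, ome,
               eta_cl = if (dims["cl"]) eta[, 1] else rep(0, n),
               eta_eps = if (dims["eps"]) eta[, d] else NULL)
  }
  if (d == 0) {
    h <- hf(matrix(0, n, 1))
    return(list(ofv = sum(h), eta = matrix(0, n, 0), per_subject = h,
                ok = all(is.finite(h))))
  }
  eta <- if (!is.null(eta_start) && all(dim(eta_start) == c(n, d))) {
    eta_start
  } else {
    matrix(0, n, d)
  }
  delta <- 1e-4
  cap <- 8 * max(c(om, ome)[c(dims["cl"], dims["eps"])]) + 1
  h0 <- hf(eta)
  if (!all(is.finite(h0))) {
    eta <- matrix(0, n, d)
    h0 <- hf(eta)
    if (!all(is.finite(h0))) {
      return(list(ofv = Inf, eta = eta, ok = FALSE))
    }
  }
  shift <- function(k, s) {
    e <- eta
    e[, k] <- e[, k] + s
    e
  }
  for (iter in seq_len(60)) {
    hp1 <- hf(shift(1, delta)); hm1 <- hf(shift(1, -delta))
    g1 <- (hp1 - hm1) / (2 * delta)
    H11 <- (hp1 - 2 * h0 + hm1) / delta^2
    if (d == 2) {
      hp2 <- hf(shift(2, delta)); hm2 <- hf(shift(2, -delta))
      g2 <- (hp2 - hm2) / (2 * delta)
      H22 <- (hp2 - 2 * h0 + hm2) / delta^2
      epp <- eta; epp[, 1] <- epp[, 1] + delta; epp[, 2] <- epp[, 2] + delta
      emm <- eta; emm[, 1] <- emm[, 1] - delta; emm[, 2] <- emm[, 2] - delta
      epm <- eta; epm[, 1] <- epm[, 1] + delta; epm[, 2] <- epm[, 2] - delta
      emp <- eta; emp[, 1] <- emp[, 1] - delta; emp[, 2] <- emp[, 2] + delta
      H12 <- (hf(epp) + hf(emm) - hf(epm) - hf(emp)) / (4 * delta^2)
      det2 <- H11 * H22 - H12^2
      bad <- !is.finite(det2) | det2 <= 1e-10 | H11 <= 0
      H11[bad] <- pmax(H11[bad], 1) + 1
      H22[bad] <- pmax(H22[bad], 1) + 1
      H12[bad] <- 0
      det2 <- H11 * H22 - H12^2
      s1 <- -(H22 * g1 - H12 * g2) / det2
      s2 <- -(H11 * g2 - H12 * g1) / det2
      step <- cbind(s1, s2)
    } else {
      H11 <- ifelse(is.finite(H11) & H11 > 1e-10, H11, 1)
      step <- cbind(-g1 / H11)
    }
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -2), 2)
    # backtracking where the step does not decrease h
    new_eta <- pmin(pmax(eta + step, -cap), cap)
    h_new <- hf(new_eta)
    for (bt in seq_len(25)) {
      worse <- !is.finite(h_new) | h_new > h0 + 1e-10
      if (!any(worse)) break
      step[worse, ] <- step[worse, , drop = FALSE] / 2
      new_eta <- pmin(pmax(eta + step, -cap), cap)
      h_new <- hf(new_eta)
    }
    improved <- is.finite(h_new) & h_new <= h0
    eta[improved, ] <- new_eta[improved, , drop = FALSE]
    h0[improved] <- h_new[improved]
    if (max(abs(step[improved, , drop = FALSE]), 0) < 1e-9) break
  }
  # curvature at the mode for the Laplace determinant
  hp1 <- hf(shift(1, delta)); hm1 <- hf(shift(1, -delta))
  H11 <- pmax((hp1 - 2 * h0 + hm1) / delta^2, 1e-10)
  if (d == 2) {
    hp2 <- hf(shift(2, delta)); hm2 <- hf(shift(2, -delta))
    H22 <- pmax((hp2 - 2 * h0 + hm2) / delta^2, 1e-10)
    epp <- eta; epp[, 1] <- epp[, 1] + delta; epp[, 2] <- epp[, 2] + delta
    emm <- eta; emm[, 1] <- emm[, 1] - delta; emm[, 2] <- emm[, 2] - delta
    epm <- eta; epm[, 1] <- epm[, 1] + delta; epm[, 2] <- epm[, 2] - delta
    emp <- eta; emp[, 1] <- emp[, 1] - delta; emp[, 2] <- emp[, 2] + delta
    H12 <- (hf(epp) + hf(emm) - hf(epm) - hf(emp)) / (4 * delta^2)
    det_half <- pmax(H11 * H22 - H12^2, 1e-20) / 4
  } else {
    det_half <- H11 / 2
  }
  per_subject <- h0 + log(det_half)
  if (d == 1 && n_agq > 1) {
    # adaptive Gauss-Hermite refinement: eta_k = mode + sqrt(2) s x_k with
    # s^2 = 2 / h''(mode); n_agq = 1 reproduces the Laplace term exactly
    rule <- gauss_hermite_rule(n_agq)
    s <- sqrt(2 / H11)
    lse <- matrix(NA_real_, n, n_agq)
    for (k in seq_len(n_agq)) {
      hk <- hf(cbind(eta[, 1] + sqrt(2) * s * rule$x[k]))
      lse[, k] <- log(rule$w[k]) + rule$x[k]^2 - hk / 2
    }
    mx <- apply(lse, 1, max)
    log_int <- log(sqrt(2) * s) + mx + log(rowSums(exp(lse - mx)))
    per_subject <- -2 * log_int + log(2 * pi)
  }
  list(ofv = sum(per_subject), eta = eta, per_subject = per_subject,
       ok = all(is.finite(per_subject)), dims = dims)
}

engine_ofv <- function(model, prep, eta_start = NULL, n_agq = 21) {
  tvcl <- tryCatch(typical_clearance(model, prep$subjects),
                   error = function(e) NULL)
  if (is.null(tvcl)) return(list(ofv = Inf, ok = FALSE))
  laplace_ofv(prep, tvcl, model$v, model$sigma_add, model$sigma_prop,
              model$omega_cl, model$omega_eps, eta_start = eta_start,
              n_agq = n_agq)
}

#' Objective function value of a population model on a dataset
#'
#' Minus twice the Laplace-approximated marginal log-likelihood, with the
#' residual variance evaluated at the individual prediction (the
#' "interaction" convention) and the additive constant `n * log(2*pi)`
#' omitted, so that differences between nested models follow the familiar
#' chi-square calibration. With zero interindividual variability the value
#' reduces to the closed-form weighted least-squares -2 log-likelihood.
#'
#' @param model An [pop_model()].
#' @param dataset An [fu_dataset()] with observations.
#' @param n_agq Number of adaptive Gauss-Hermite nodes refining the Laplace
#'   expansion (1 = pure Laplace; default 21).
#' @return A single number (lower is better).
#' @export
ofv <- function(model, dataset, n_agq = 21) {
  prep <- fu_prep(dataset, model)
  if (model$sigma_add == 0) {
    # proportional-only error: a zero prediction would give zero residual
    # variance and an undefined likelihood
    zero_pred <- (!prep$ss) & prep$time == 0
    if (any(zero_pred)) {
      abort(paste0("Zero residual variance at a zero prediction for subject ",
                   prep$subjects$subject_id[prep$idx[which(zero_pred)[1]]],
                   "."))
    }
  }
  res <- engine_ofv(model, prep, n_agq = n_agq)
  if (!is.finite(res$ofv)) {
    abort("Non-finite likelihood; check residual-error model and covariates.")
  }
  res$ofv
}

#' Fitting control parameters
#'
#' @param rel_tol Relative OFV convergence tolerance of the outer optimizer.
#' @param max_iter Maximum outer iterations.
#' @param n_agq Number of adaptive Gauss-Hermite nodes for the marginal
#'   likelihood (1 = pure Laplace).
#' @return A list.
#' @export
fit_control <- function(rel_tol = 1e-6, max_iter = 500, n_agq = 21) {
  list(rel_tol = rel_tol, max_iter = max_iter, n_agq = n_agq)
}

#' Fit a population pharmacokinetic model by maximum likelihood
#'
#' Minimizes the Laplace (FOCE-with-interaction-style) [ofv()] over the
#' non-fixed parameters, with positive parameters estimated on the log scale.
#' Non-convergence is reported in the result, not raised; an estimate driven
#' to (near) zero is flagged as a boundary estimate. The volume of
#' distribution and its interindividual variability are fixed by default:
#' with steady-state-only observations the likelihood carries no information
#' on either, and the random effect on volume is marginalized out
#' analytically (its empirical Bayes estimates are identically zero, i.e.
#' 100% shrinkage).
#'
#' @param dataset An [fu_dataset()].
#' @param model Initial [pop_model()] (structure + starting values).
#' @param fixed Character vector of parameters to hold fixed; defaults to the
#'   model's own `fixed` set.
#' @param compute_se Compute standard errors / RSE by a finite-difference
#'   Hessian of OFV/2 (disable inside resampling loops for speed).
#' @param control See [fit_control()].
#' @return An object of class `fu_fit`; see [tidy.fu_fit()] and
#'   [glance.fu_fit()].
#' @export
fit_pk <- function(dataset, model, fixed = NULL, compute_se = TRUE,
                   control = fit_control()) {
  if (!is.null(fixed)) model$fixed <- fixed
  prep <- fu_prep(dataset, model)
  est_names <- estimated_par_names(model)
  if (prep$n_obs < length(est_names)) {
    abort("Fewer observations than estimated parameters.")
  }
  start <- model_get_par(model, est_names)
  tstart <- par_to_trans(start)
  warm <- new.env(parent = emptyenv())
  warm$eta <- NULL
  objective <- function(tpar) {
    m <- model_set_par(model, trans_to_par(tpar, est_names))
    res <- engine_ofv(m, prep, eta_start = warm$eta, n_agq = control$n_agq)
    if (is.finite(res$ofv)) warm$eta <- res$eta
    if (!is.finite(res$ofv)) 1e10 else res$ofv
  }
  lower <- ifelse(par_is_log(est_names), log(1e-8), -Inf)
  upper <- ifelse(par_is_log(est_names), log(1e8), Inf)
  opt <- if (length(est_names)) {
    nlminb(tstart, objective, lower = lower, upper = upper,
           control = list(rel.tol = control$rel_tol,
                          iter.max = control$max_iter,
                          eval.max = 4 * control$max_iter))
  } else {
    # nothing to estimate: evaluate at the supplied values
    list(par = tstart, convergence = 0L, message = "all parameters fixed",
         iterations = 0L, evaluations = c(`function` = 1L, gradient = 0L))
  }
  est <- trans_to_par(opt$par, est_names)
  final_model <- model_set_par(model, est)
  final <- engine_ofv(final_model, prep, eta_start = warm$eta,
                      n_agq = control$n_agq)

  boundary <- par_is_log(est_names) &
    (est < pmax(1e-4 * abs(start), 1e-7))
  converged <- opt$convergence == 0 && is.finite(final$ofv)

  ebes <- ebe_table(prep, final, final_model)
  fit <- structure(
    list(
      model = final_model, ofv = final$ofv, par = est,
      boundary = setNames(as.logical(boundary), est_names),
      converged = converged,
      convergence = list(code = opt$convergence, message = opt$message,
                         iterations = opt$iterations,
                         evaluations = opt$evaluations),
      ebes = ebes, n_agq = control$n_agq,
      n_subjects = prep$n_sub, n_obs = prep$n_obs,
      all_steady_state = prep$all_ss,
      se = NULL, rse_percent = NULL, cov = NULL, cov_ok = NA
    ),
    class = "fu_fit"
  )
  shr <- shrinkage(fit, dataset)
  fit$shrinkage <- shr
  if (compute_se) {
    se <- standard_errors(fit, dataset)
    fit$se <- se$se
    fit$rse_percent <- se$rse_percent
    fit$cov <- se$cov
    fit$cov_ok <- se$ok
  }
  fit
}

ebe_table <- function(prep, final, model) {
  out <- tibble(subject_id = prep$subjects$subject_id)
  d <- 0
  if (model$omega_cl > 0) {
    d <- d + 1
    out$eta_cl <- if (ncol(final$eta) >= d) final$eta[, d] else 0
  } else {
    out$eta_cl <- 0
  }
  if (model$omega_eps > 0) {
    d <- d + 1
    out$eta_eps <- if (ncol(final$eta) >= d) final$eta[, d] else 0
  }
  out
}

#' @export
print.fu_fit <- function(x, ...) {
  cat("<fu_fit> ", x$n_subjects, " subjects, ", x$n_obs, " observations\n",
      sep = "")
  cat("  OFV: ", format(x$ofv, digits = 8),
      if (!x$converged) "  (NOT converged)" else "", "\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a population-model fit
#'
#' @param x An `fu_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `std.error`, `rse_percent`, `fixed`, `boundary`.
#' @method tidy fu_fit
#' @export
tidy.fu_fit <- function(x, ...) {
  m <- x$model
  est_names <- names(x$par)
  all_names <- unique(c(model_par_names(m), "v", "omega_v"))
  tibble(
    term = all_names,
    estimate = as.numeric(model_get_par_full(m, all_names)),
    std.error = vapply(all_names, function(nm) {
      if (!is.null(x$se) && nm %in% names(x$se)) x$se[[nm]] else NA_real_
    }, double(1)),
    rse_percent = vapply(all_names, function(nm) {
      if (!is.null(x$rse_percent) && nm %in% names(x$rse_percent)) {
        x$rse_percent[[nm]]
      } else {
        NA_real_
      }
    }, double(1)),
    fixed = !all_names %in% est_names,
    boundary = vapply(all_names, function(nm) {
      nm %in% names(x$boundary) && isTRUE(x$boundary[[nm]])
    }, logical(1))
  )
}

model_get_par_full <- function(model, names) {
  vapply(names, function(nm) {
    if (nm %in% c("v", "omega_v")) model[[nm]] else
      model_get_par(model, nm)
  }, double(1))
}

#' One-line summary of a population-model fit
#'
#' @param x An `fu_fit`.
#' @param ... Unused.
#' @return A one-row tibble: OFV, sizes, convergence and shrinkage summaries.
#' @method glance fu_fit
#' @export
glance.fu_fit <- function(x, ...) {
  tibble(
    ofv = x$ofv, n_subjects = x$n_subjects, n_obs = x$n_obs,
    n_par = length(x$par), converged = x$converged,
    cov_step_ok = x$cov_ok,
    eta_shrinkage_cl = x$shrinkage$eta_cl,
    eta_shrinkage_v = x$shrinkage$eta_v,
    eps_shrinkage = x$shrinkage$eps,
    iiv_cl_cv = omega_to_cv(x$model$omega_cl)
  )
}

#' Empirical Bayes estimates of the subject-level random effects
#'
#' Modes of the per-subject conditional density at the fitted population
#' parameters. Subjects without informative observations have an estimate of
#' exactly zero.
#'
#' @param fit An `fu_fit`.
#' @param dataset The dataset the model was fitted to.
#' @return Tibble `subject_id`, `eta_cl` (and `eta_eps` when the model has
#'   residual-variability IIV).
#' @export
empirical_bayes <- function(fit, dataset) {
  prep <- fu_prep(dataset, fit$model)
  res <- engine_ofv(fit$model, prep)
  ebe_table(prep, res, fit$model)
}

#' Eta and epsilon shrinkage
#'
#' Eta shrinkage is `100 * (1 - SD(ebe) / omega)`; epsilon shrinkage is
#' `100 * (1 - SD(IWRES))` with `IWRES = (DV - IPRED) / SD_residual(IPRED)`.
#' With steady-state-only observations the random effect on the volume of
#' distribution cannot affect any prediction, so its shrinkage is 100%.
#'
#' @param fit An `fu_fit`.
#' @param dataset The fitted dataset.
#' @return List with `eta_cl`, `eta_v`, `eps` (percent; `NA` when undefined).
#' @export
shrinkage <- function(fit, dataset) {
  m <- fit$model
  eta_cl <- if (m$omega_cl > 0) {
    100 * (1 - sd(fit$ebes$eta_cl) / m$omega_cl)
  } else {
    NA_real_
  }
  eta_v <- if (m$omega_v > 0 && fit$all_steady_state) 100 else NA_real_
  g <- gof_tables(fit, dataset)
  eps <- if (nrow(g) > 1) 100 * (1 - sd(g$iwres)) else NA_real_
  list(eta_cl = eta_cl, eta_v = eta_v, eps = eps)
}

#' Standard errors and relative standard errors
#'
#' Observed-information standard errors from a central finite-difference
#' Hessian of OFV/2 at the estimates (natural scale);
#' `RSE = 100 * SE / |estimate|`. A singular or non-positive-definite
#' Hessian is reported via `ok = FALSE` rather than an error.
#'
#' @param fit An `fu_fit`.
#' @param dataset The fitted dataset.
#' @return List with `se`, `rse_percent` (named), `cov` matrix, `ok` flag.
#' @export
standard_errors <- function(fit, dataset) {
  model <- fit$model
  prep <- fu_prep(dataset, model)
  est_names <- names(fit$par)
  x0 <- as.numeric(fit$par)
  p <- length(x0)
  n_agq <- fit$n_agq %||% 21
  f <- function(x) {
    m <- model_set_par(model, setNames(x, est_names))
    res <- engine_ofv(m, prep, n_agq = n_agq)
    if (!is.finite(res$ofv)) NA_real_ else res$ofv / 2
  }
  hstep <- pmax(1e-3 * abs(x0), 1e-6)
  f0 <- f(x0)
  H <- matrix(NA_real_, p, p)
  fp <- fm <- numeric(p)
  for (k in seq_len(p)) {
    xk <- x0; xk[k] <- x0[k] + hstep[k]; fp[k] <- f(xk)
    xk <- x0; xk[k] <- x0[k] - hstep[k]; fm[k] <- f(xk)
    H[k, k] <- (fp[k] - 2 * f0 + fm[k]) / hstep[k]^2
  }
  if (p > 1) {
    for (j in seq_len(p - 1)) {
      for (k in (j + 1):p) {
        xpp <- x0; xpp[j] <- xpp[j] + hstep[j]; xpp[k] <- xpp[k] + hstep[k]
        xmm <- x0; xmm[j] <- xmm[j] - hstep[j]; xmm[k] <- xmm[k] - hstep[k]
        xpm <- x0; xpm[j] <- xpm[j] + hstep[j]; xpm[k] <- xpm[k] - hstep[k]
        xmp <- x0; xmp[j] <- xmp[j] - hstep[j]; xmp[k] <- xmp[k] + hstep[k]
        H[j, k] <- H[k, j] <-
          (f(xpp) + f(xmm) - f(xpm) - f(xmp)) / (4 * hstep[j] * hstep[k])
      }
    }
  }
  ok <- all(is.finite(H))
  cov <- NULL
  se <- rep(NA_real_, p)
  if (ok) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cov) || any(diag(cov) <= 0)) {
      ok <- FALSE
    } else {
      se <- sqrt(diag(cov))
    }
  }
  list(se = setNames(se, est_names),
       rse_percent = setNames(100 * se / abs(x0), est_names),
       cov = cov, ok = ok)
}

#' Likelihood-ratio test between nested models
#'
#' The difference in OFV between nested models is referred to a chi-square
#' distribution; a drop of 3.84 points at one degree of freedom corresponds
#' to p = 0.05.
#'
#' @param ofv_reduced OFV of the reduced (smaller) model.
#' @param ofv_full OFV of the full model.
#' @param df Degrees of freedom (number of additional parameters).
#' @return Upper-tail chi-square p-value.
#' @export
lrt <- function(ofv_reduced, ofv_full, df) {
  if (df < 1) abort("`df` must be >= 1.")
  delta <- ofv_reduced - ofv_full
  if (delta < 0) {
    warn("OFV of the full model exceeds the reduced model; p set to 1.")
    return(1)
  }
  pchisq(delta, df = df, lower.tail = FALSE)
}
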