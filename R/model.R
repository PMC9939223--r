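#' Covariate effect on a population parameter
#'
#' A multiplicative covariate effect on clearance, centered at a reference
#' value (the study median). Available forms:
#' \describe{
#'   \item{`linear_proportional`}{`1 + theta * (x - center)`}
#'   \item{`exponential`}{`exp(theta * (x - center))`}
#'   \item{`power`}{`(x / center)^theta` (requires `x > 0`)}
#'   \item{`piecewise_linear`}{two slopes hinged at `center`:
#'     `1 + theta[1] * (x - center)` below and `1 + theta[2] * (x - center)`
#'     above; `theta` has length 2}
#' }
#'
#' @param covariate Name of a subject-level covariate column, e.g. `"bsa"`.
#' @param form One of `"linear_proportional"`, `"exponential"`, `"power"`,
#'   `"piecewise_linear"`.
#' @param theta Effect coefficient(s); length 2 for `piecewise_linear`.
#' @param center Reference (centering) value, typically the study median.
#' @return An object of class `fu_effect`.
#' @export
covariate_effect <- function(covariate, form = c("linear_proportional",
                                                 "exponential", "power",
                                                 "piecewise_linear"),
                             theta = 0, center) {
  form <- match.arg(form)
  n_theta <- if (form == "piecewise_linear") 2L else 1L
  if (length(theta) != n_theta) {
    abort(paste0("`theta` must have length ", n_theta, " for form \"", form,
                 "\"."))
  }
  if (!is.finite(center)) abort("`center` must be finite.")
  structure(list(covariate = covariate, form = form,
                 theta = as.numeric(theta), center = as.numeric(center)),
            class = "fu_effect")
}

effect_multiplier <- function(effect, x) {
  d <- x - effect$center
  switch(effect$form,
    linear_proportional = 1 + effect$theta * d,
    exponential = exp(effect$theta * d),
    power = {
      if (any(x <= 0)) abort(paste0("Covariate ", effect$covariate,
                                    " must be > 0 for a power effect."))
      (x / effect$center)^effect$theta
    },
    piecewise_linear = 1 + ifelse(d < 0, effect$theta[1], effect$theta[2]) * d
  )
}

n_effect_par <- function(effect) length(effect$theta)

#' Population pharmacokinetic model specification
#'
#' One-compartment model with linear elimination for a continuous infusion.
#' Interindividual variability (IIV) is lognormal on clearance (and,
#' nominally, on the volume of distribution, which carries no information
#' when only steady-state concentrations are observed and is therefore fixed
#' by default). Residual error combines an additive and a proportional term;
#' an optional subject-level lognormal multiplier on the residual standard
#' deviation represents IIV of residual variability (off by default).
#'
#' Variability parameters are stored as standard deviations on the log /
#' proportional scale; use [omega_to_cv()] / [cv_to_omega()] to convert
#' between the internal SD and the conventionally reported percent
#' coefficient of variation.
#'
#' @param cl_pop Population clearance (L/h).
#' @param v Volume of distribution (L); fixed by default.
#' @param effects List of [covariate_effect()]s on clearance.
#' @param omega_cl SD of the lognormal IIV on clearance.
#' @param omega_v SD of the lognormal IIV on volume (fixed by default).
#' @param sigma_prop Proportional residual error (fraction).
#' @param sigma_add Additive residual error (ng/ml); 0 disables the term.
#' @param omega_eps SD of the subject-level lognormal multiplier on residual
#'   SD (IIV of residual variability); 0 disables the term.
#' @param fixed Character vector of parameter names that are not estimated;
#'   defaults to `c("v", "omega_v")`.
#' @return An object of class `fu_model`.
#' @export
pop_model <- function(cl_pop = 200, v = 46.1, effects = list(),
                      omega_cl = 0.2, omega_v = cv_to_omega(51.1),
                      sigma_prop = 0.2, sigma_add = 0, omega_eps = 0,
                      fixed = c("v", "omega_v")) {
  if (cl_pop <= 0) abort("`cl_pop` must be > 0.")
  if (v <= 0) abort("`v` must be > 0.")
  if (any(c(omega_cl, omega_v, sigma_prop, sigma_add, omega_eps) < 0)) {
    abort("Variability parameters must be >= 0.")
  }
  if (sigma_prop == 0 && sigma_add == 0) {
    abort("At least one of `sigma_prop`, `sigma_add` must be > 0.")
  }
  if (length(effects) && inherits(effects, "fu_effect")) {
    effects <- list(effects)
  }
  covs <- vapply(effects, function(e) e$covariate, character(1))
  if (anyDuplicated(covs)) {
    abort("At most one effect per covariate on clearance.")
  }
  structure(list(cl_pop = cl_pop, v = v, effects = effects,
                 omega_cl = omega_cl, omega_v = omega_v,
                 sigma_prop = sigma_prop, sigma_add = sigma_add,
                 omega_eps = omega_eps, fixed = fixed),
            class = "fu_model")
}

#' @export
print.fu_model <- function(x, ...) {
  cat("<fu_model> one-compartment infusion model\n")
  cat(sprintf("  CL_pop  %.4g L/h%s\n", x$cl_pop,
              if ("cl_pop" %in% x$fixed) " (fixed)" else ""))
  cat(sprintf("  V       %.4g L%s\n", x$v,
              if ("v" %in% x$fixed) " (fixed)" else ""))
  for (e in x$effects) {
    cat(sprintf("  effect  %s [%s] theta=%s center=%.4g\n", e$covariate,
                e$form, paste(signif(e$theta, 4), collapse = ","), e$center))
  }
  cat(sprintf("  IIV CL  %.3g SD (%.3g %%CV)%s\n", x$omega_cl,
              omega_to_cv(x$omega_cl),
              if ("omega_cl" %in% x$fixed) " (fixed)" else ""))
  cat(sprintf("  IIV V   %.3g SD (%.3g %%CV)%s\n", x$omega_v,
              omega_to_cv(x$omega_v),
              if ("omega_v" %in% x$fixed) " (fixed)" else ""))
  cat(sprintf("  sigma   prop %.3g, add %.3g ng/ml\n", x$sigma_prop,
              x$sigma_add))
  if (x$omega_eps > 0) {
    cat(sprintf("  IIV res %.3g SD (%.3g %%CV)\n", x$omega_eps,
                omega_to_cv(x$omega_eps)))
  }
  invisible(x)
}

#' Convert between lognormal SD and percent CV
#'
#' IIV magnitudes are conventionally reported as a percent coefficient of
#' variation; for a lognormal random effect with SD `omega` on the log scale,
#' `%CV = 100 * sqrt(exp(omega^2) - 1)`.
#'
#' @param omega SD on the log scale.
#' @param cv Percent coefficient of variation.
#' @return The converted value.
#' @export
omega_to_cv <- function(omega) 100 * sqrt(exp(omega^2) - 1)

#' @rdname omega_to_cv
#' @export
cv_to_omega <- function(cv) sqrt(log(1 + (cv / 100)^2))

#' Typical (population) clearance for a covariate vector
#'
#' The typical clearance is the population clearance multiplied by one
#' centered covariate factor per effect; with every covariate at its center
#' the typical clearance equals `cl_pop`.
#'
#' @param model An [pop_model()].
#' @param covariates A one-row data frame (or named list) holding every
#'   covariate referenced by the model's effects; vectorized over rows.
#' @return Typical clearance in L/h.
#' @export
typical_clearance <- function(model, covariates) {
  stopifnot(inherits(model, "fu_model"))
  covariates <- as_tibble(as.list(covariates) |> lapply(unlist))
  cl <- rep(model$cl_pop, max(1L, nrow(covariates)))
  for (e in model$effects) {
    if (!e$covariate %in% names(covariates)) {
      abort(paste0("Covariate \"", e$covariate,
                   "\" required by the model is missing."))
    }
    x <- covariates[[e$covariate]]
    if (anyNA(x)) {
      abort(paste0("Covariate \"", e$covariate, "\" contains missing values."))
    }
    cl <- cl * effect_multiplier(e, x)
  }
  if (any(cl <= 0)) {
    abort("A covariate effect drives the clearance multiplier <= 0.")
  }
  cl
}

#' Individual clearance from a typical value and a random effect
#'
#' @param typical_cl Typical clearance (L/h, > 0).
#' @param eta Subject-level random effect on the log scale.
#' @return `typical_cl * exp(eta)`.
#' @export
individual_clearance <- function(typical_cl, eta) {
  if (any(typical_cl <= 0)) abort("`typical_cl` must be > 0.")
  typical_cl * exp(eta)
}

#' Concentration during/at steady state of a continuous infusion
#'
#' One-compartment model with linear elimination under a zero-order infusion
#' at rate `rate`: at steady state `C = rate / cl`; before steady state
#' `C = (rate / cl) * (1 - exp(-(cl / v) * t))`. Concentrations are returned
#' in ng/ml (mg/L * 1000).
#'
#' @param cl Clearance (L/h, > 0).
#' @param v Volume of distribution (L, > 0).
#' @param rate Infusion rate (mg/h).
#' @param time_since_start Time since infusion start (h).
#' @param steady_state Logical; `TRUE` returns the steady-state value.
#' @return Concentration in ng/ml.
#' @export
predict_concentration <- function(cl, v, rate, time_since_start,
                                  steady_state = TRUE) {
  if (any(cl <= 0) || any(v <= 0)) abort("`cl` and `v` must be > 0.")
  css <- rate / cl * 1000
  ifelse(steady_state, css,
         css * (1 - exp(-(cl / v) * time_since_start)))
}

#' Residual-error variance at a prediction
#'
#' Combined additive and proportional residual error:
#' `var = sigma_add^2 + (sigma_prop * pred)^2`.
#'
#' @param pred Model prediction (ng/ml, >= 0).
#' @param model An [pop_model()] (its `sigma_add`, `sigma_prop` are used).
#' @return Residual variance in (ng/ml)^2.
#' @export
residual_variance <- function(pred, model) {
  if (any(pred < 0)) abort("`pred` must be >= 0.")
  model$sigma_add^2 + (model$sigma_prop * pred)^2
}

#' Reference final-model parameter set
#'
#' The fluorouracil population model used as the default simulation truth:
#' population clearance 223 L/h with a linear-proportional body-surface-area
#' effect (0.794, centered at 1.97 m^2) and an exponential back-muscle SMI
#' effect (0.0570, centered at 3.78 cm^2/m^2); IIV on clearance 20.9 %CV;
#' proportional residual error 21.4%; volume of distribution fixed at 46.1 L
#' with 51.1 %CV IIV.
#'
#' @return An [pop_model()].
#' @export
fu_reference_model <- function() {
  pop_model(
    cl_pop = 223, v = 46.1,
    effects = list(
      covariate_effect("bsa", "linear_proportional", 0.794, center = 1.97),
      covariate_effect("smi_back", "exponential", 0.0570, center = 3.78)
    ),
    omega_cl = cv_to_omega(20.9), omega_v = cv_to_omega(51.1),
    sigma_prop = 0.214, sigma_add = 0
  )
}

#' Read a model specification from YAML
#'
#' The YAML layout mirrors [pop_model()]: top-level keys `cl_pop`, `v`,
#' `omega_cl` (or `iiv_cl_cv` in %CV), `omega_v`/`iiv_v_cv`, `sigma_prop`,
#' `sigma_add`, `omega_eps`, `fixed`, and an `effects` list of
#' `{covariate, form, theta, center}` entries.
#'
#' @param path YAML file path.
#' @return An [pop_model()].
#' @export
read_model <- function(path) {
  y <- yaml::read_yaml(path)
  effects <- lapply(y$effects %||% list(), function(e) {
    covariate_effect(e$covariate, e$form, unlist(e$theta), e$center)
  })
  omega_cl <- if (!is.null(y$iiv_cl_cv)) cv_to_omega(y$iiv_cl_cv) else
    y$omega_cl %||% 0.2
  omega_v <- if (!is.null(y$iiv_v_cv)) cv_to_omega(y$iiv_v_cv) else
    y$omega_v %||% cv_to_omega(51.1)
  pop_model(
    cl_pop = y$cl_pop %||% 200, v = y$v %||% 46.1, effects = effects,
    omega_cl = omega_cl, omega_v = omega_v,
    sigma_prop = y$sigma_prop %||% 0.2, sigma_add = y$sigma_add %||% 0,
    omega_eps = y$omega_eps %||% 0,
    fixed = unlist(y$fixed) %||% c("v", "omega_v")
  )
}

# --- internal parameter vector <-> model mapping (used by estimation) -------

model_par_names <- function(model) {
  nm <- c("cl_pop")
  for (e in model$effects) {
    nm <- c(nm, if (n_effect_par(e) == 1) paste0("theta_", e$covariate) else
      paste0("theta_", e$covariate, c("_lo", "_hi")))
  }
  nm <- c(nm, "omega_cl")
  if (model$sigma_prop > 0) nm <- c(nm, "sigma_prop")
  if (model$sigma_add > 0) nm <- c(nm, "sigma_add")
  if (model$omega_eps > 0) nm <- c(nm, "omega_eps")
  nm
}

# parameters estimated = all parameters minus fixed ones; v / omega_v are
# handled outside the vector (fixed by default, and with steady-state-only
# data the likelihood does not depend on them)
estimated_par_names <- function(model) {
  setdiff(model_par_names(model), model$fixed)
}

model_get_par <- function(model, names) {
  vals <- numeric(length(names))
  for (i in seq_along(names)) {
    nm <- names[i]
    vals[i] <- if (nm %in% c("cl_pop", "omega_cl", "sigma_prop", "sigma_add",
                             "omega_eps")) {
      model[[nm]]
    } else {
      hit <- find_theta(model, nm)
      model$effects[[hit$idx]]$theta[hit$k]
    }
  }
  setNames(vals, names)
}

find_theta <- function(model, nm) {
  for (i in seq_along(model$effects)) {
    e <- model$effects[[i]]
    if (n_effect_par(e) == 1 && nm == paste0("theta_", e$covariate)) {
      return(list(idx = i, k = 1L))
    }
    if (n_effect_par(e) == 2) {
      if (nm == paste0("theta_", e$covariate, "_lo")) {
        return(list(idx = i, k = 1L))
      }
      if (nm == paste0("theta_", e$covariate, "_hi")) {
        return(list(idx = i, k = 2L))
      }
    }
  }
  abort(paste0("Unknown parameter \"", nm, "\"."))
}

model_set_par <- function(model, par) {
  for (nm in names(par)) {
    if (nm %in% c("cl_pop", "omega_cl", "sigma_prop", "sigma_add",
                  "omega_eps")) {
      model[[nm]] <- unname(par[[nm]])
    } else {
      hit <- find_theta(model, nm)
      model$effects[[hit$idx]]$theta[hit$k] <- unname(par[[nm]])
    }
  }
  model
}

# log transform for positive parameters, identity for covariate coefficients
par_is_log <- function(names) {
  names %in% c("cl_pop", "omega_cl", "sigma_prop", "sigma_add", "omega_eps")
}

par_to_trans <- function(par) {
  ifelse(par_is_log(names(par)), log(pmax(par, 1e-12)), par)
}

trans_to_par <- function(tpar, names) {
  setNames(ifelse(par_is_log(names), exp(tpar), tpar), names)
}
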