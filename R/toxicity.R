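#' Logistic regression of a severe-adverse-event outcome
#'
#' Maximum-likelihood logistic regression of a binary severe-event indicator
#' (CTCAE grade >= 2) on one or more covariates, with Wald covariance from
#' the inverse observed information. Complete (quasi-)separation is flagged
#' with a warning rather than an error; a constant outcome (no events or
#' all events) is an error.
#'
#' @param data Data frame holding the outcome and covariate columns.
#' @param outcome Name of the binary (0/1) outcome column.
#' @param covariates Character vector of covariate column names.
#' @return An object of class `fu_logistic` with elements `coefficients`,
#'   `vcov`, `n`, `n_events`, `loglik`, `converged`, `separation`,
#'   `outcome`, `covariates`.
#' @export
fit_logistic <- function(data, outcome, covariates) {
  data <- as.data.frame(data)
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) abort("`outcome` must be coded 0/1.")
  if (length(unique(y)) < 2) {
    abort("Outcome is constant (no events or all events).")
  }
  if (nrow(data) <= length(covariates) + 1) {
    abort("Need more observations than coefficients.")
  }
  f <- as.formula(paste(outcome, "~", paste(covariates, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation) {
    warn("Possible complete separation; estimates may be unstable.")
  }
  structure(
    list(coefficients = coef(fit), vcov = vcov(fit), n = nrow(data),
         n_events = sum(y), loglik = as.numeric(logLik(fit)),
         converged = fit$converged, separation = separation,
         outcome = outcome, covariates = covariates, glm = fit),
    class = "fu_logistic"
  )
}

#' @export
print.fu_logistic <- function(x, ...) {
  cat("<fu_logistic> ", x$n, " subjects, ", x$n_events, " events\n",
      sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname fit_logistic
#' @param x An `fu_logistic`.
#' @param ... Unused.
#' @return `tidy()`: tibble `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (Wald).
#' @method tidy fu_logistic
#' @export
tidy.fu_logistic <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = unname(se), statistic = unname(z),
         p.value = unname(2 * stats::pnorm(-abs(z))))
}

#' @rdname fit_logistic
#' @method glance fu_logistic
#' @export
glance.fu_logistic <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
         converged = x$converged, separation = x$separation)
}

linear_predictor <- function(fit, newdata) {
  X <- model.matrix(
    as.formula(paste("~", paste(fit$covariates, collapse = " + "))),
    data = as.data.frame(newdata)
  )
  if (!identical(colnames(X), names(fit$coefficients))) {
    X <- X[, names(fit$coefficients), drop = FALSE]
  }
  list(X = X, z = as.numeric(X %*% fit$coefficients))
}

#' Severe-event probability at covariate values
#'
#' `P = 1 / (1 + exp(-z))` with `z` the fitted linear predictor.
#'
#' @param fit An `fu_logistic`.
#' @param newdata Data frame of covariate values.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
probability <- function(fit, newdata) {
  plogis(linear_predictor(fit, newdata)$z)
}

#' Odds of an event probability
#'
#' `odds = p / (1 - p)`; `p = 1` yields `Inf` with a warning.
#'
#' @param p Probabilities in `[0, 1]`.
#' @return Odds.
#' @export
odds <- function(p) {
  if (any(p < 0 | p > 1)) abort("`p` must be in [0, 1].")
  if (any(p == 1)) warn("p = 1 gives infinite odds.")
  p / (1 - p)
}

#' Odds ratio per covariate increment, with confidence interval
#'
#' The multiplicative change in the odds of a severe event when the
#' covariate increases by `delta` (1 cm^2/m^2 for an SMI): `exp(beta *
#' delta)`, with a Wald confidence interval. For protective effects
#' (OR < 1) the percent reduction `100 * (1 - OR)` is also reported.
#'
#' @param fit An `fu_logistic`.
#' @param covariate Covariate name (default: the single covariate).
#' @param delta Covariate increment (default 1).
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `covariate`, `delta`, `or`, `conf.low`,
#'   `conf.high`, `percent_change`, `p.value`.
#' @export
odds_ratio <- function(fit, covariate = NULL, delta = 1, level = 0.95) {
  covariate <- covariate %||% fit$covariates[1]
  if (!covariate %in% names(fit$coefficients)) {
    abort(paste0("No fitted slope for \"", covariate, "\"."))
  }
  b <- fit$coefficients[[covariate]]
  se <- sqrt(fit$vcov[covariate, covariate])
  zc <- qnorm(1 - (1 - level) / 2)
  or <- exp(b * delta)
  tibble(
    covariate = covariate, delta = delta, or = or,
    conf.low = exp((b - zc * se) * delta),
    conf.high = exp((b + zc * se) * delta),
    percent_change = ifelse(or < 1, 100 * (1 - or), 100 * (or - 1)),
    p.value = 2 * stats::pnorm(-abs(b / se))
  )
}

#' Probability curve with pointwise confidence band
#'
#' Delta-method band on the logit scale, transformed through the inverse
#' logit so the band is always inside (0, 1): `var(z) = x' Sigma x`,
#' `band = plogis(z +/- z_crit * sd)`.
#'
#' @param fit An `fu_logistic`.
#' @param newdata Data frame grid of covariate values.
#' @param level Confidence level (default 0.95).
#' @return Tibble: `newdata` columns plus `p`, `conf.low`, `conf.high`.
#' @export
probability_band <- function(fit, newdata, level = 0.95) {
  if (is.null(fit$vcov)) abort("Fit has no covariance matrix.")
  lp <- linear_predictor(fit, newdata)
  sdz <- sqrt(pmax(rowSums((lp$X %*% fit$vcov) * lp$X), 0))
  zc <- qnorm(1 - (1 - level) / 2)
  dplyr::bind_cols(
    as_tibble(newdata),
    tibble(p = unname(plogis(lp$z)),
           conf.low = unname(plogis(lp$z - zc * sdz)),
           conf.high = unname(plogis(lp$z + zc * sdz)))
  )
}

#' Univariable odds ratios for every adverse-event / SMI pair
#'
#' Dichotomizes each adverse-event type (grade >= 2 severe) and fits one
#' univariable logistic regression per requested (adverse event, SMI
#' measure) pair, reporting the per-unit odds ratio with Wald confidence
#' interval and p-value. No multiplicity adjustment is applied (recorded in
#' the `p_adjust` attribute). Pairs with a degenerate outcome (no or only
#' events) are flagged and left `NA`.
#'
#' @param dataset An [fu_dataset()] with adverse events and SMI columns.
#' @param ae_types Adverse-event types (default: all of [fu_ae_types] that
#'   appear in the dataset).
#' @param smi_measures SMI columns (default: the four standard measures
#'   present in the dataset).
#' @param delta Covariate increment for the odds ratio (default 1 cm^2/m^2).
#' @return Tibble with one row per pair: `ae_type`, `smi`, `n`, `n_events`,
#'   `or`, `conf.low`, `conf.high`, `percent_change`, `p.value`, `note`.
#' @export
run_all_ae <- function(dataset, ae_types = NULL, smi_measures = NULL,
                       delta = 1) {
  stopifnot(inherits(dataset, "fu_dataset"))
  ae_types <- ae_types %||%
    intersect(fu_ae_types, unique(dataset$adverse_events$ae_type))
  smi_measures <- smi_measures %||%
    intersect(c("smi_psoas", "smi_back", "smi_total_hu", "smi_total_seg"),
              names(dataset$subjects))
  grid <- tidyr::expand_grid(ae_type = ae_types, smi = smi_measures)
  out <- purrr::pmap(grid, function(ae_type, smi) {
    outc <- dichotomize_grades(dataset, ae_type)
    df <- dplyr::left_join(outc, dataset$subjects, by = "subject_id")
    df <- df[!is.na(df[[smi]]), , drop = FALSE]
    base <- tibble(ae_type = ae_type, smi = smi, n = nrow(df),
                   n_events = sum(df$outcome), or = NA_real_,
                   conf.low = NA_real_, conf.high = NA_real_,
                   percent_change = NA_real_, p.value = NA_real_,
                   note = NA_character_)
    if (length(unique(df$outcome)) < 2) {
      base$note <- "degenerate outcome"
      return(base)
    }
    fit <- tryCatch(fit_logistic(df, "outcome", smi),
                    error = function(e) NULL)
    if (is.null(fit)) {
      base$note <- "fit failed"
      return(base)
    }
    orr <- odds_ratio(fit, smi, delta = delta)
    base$or <- orr$or
    base$conf.low <- orr$conf.low
    base$conf.high <- orr$conf.high
    base$percent_change <- orr$percent_change
    base$p.value <- orr$p.value
    if (fit$separation) base$note <- "separation"
    base
  })
  res <- dplyr::bind_rows(out)
  attr(res, "p_adjust") <- "none"
  res
}

#' Plot fitted severe-event probability versus an SMI measure
#'
#' Fitted probability curve with its 95% confidence band over the observed
#' SMI range, with the observed binary outcomes as points.
#'
#' @param fit An `fu_logistic` with a single covariate.
#' @param data The data the model was fitted to.
#' @param level Confidence level for the band.
#' @return A ggplot.
#' @export
plot_probability <- function(fit, data, level = 0.95) {
  cv <- fit$covariates[1]
  grid <- tibble(x = seq(min(data[[cv]]), max(data[[cv]]),
                         length.out = 200))
  names(grid) <- cv
  band <- probability_band(fit, grid, level = level)
  ggplot2::ggplot(band, ggplot2::aes(.data[[cv]], .data$p)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = as_tibble(data),
      ggplot2::aes(.data[[cv]], .data[[fit$outcome]]), alpha = 0.4) +
    ggplot2::labs(x = paste0(cv, " (cm²/m²)"),
                  y = "P(severe adverse event)") +
    ggplot2::theme_minimal()
}
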