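default_fit_fun <- function(control = fit_control()) {
  function(dataset, model) {
    fit <- fit_pk(dataset, model, compute_se = FALSE, control = control)
    list(ofv = fit$ofv, model = fit$model, converged = fit$converged,
         fit = fit)
  }
}

add_candidate <- function(model, covariate, form, center, theta_init = NULL) {
  theta <- theta_init %||%
    (if (form == "piecewise_linear") c(0, 0) else 0)
  model$effects <- c(model$effects,
                     list(covariate_effect(covariate, form, theta, center)))
  model
}

drop_covariate <- function(model, covariate) {
  keep <- vapply(model$effects, function(e) e$covariate != covariate,
                 logical(1))
  model$effects <- model$effects[keep]
  model
}

candidate_df <- function(form) if (form == "piecewise_linear") 2L else 1L

#' Stepwise covariate modeling (forward inclusion / backward elimination)
#'
#' Starting from a base model, repeatedly adds the candidate covariate
#' effect with the largest significant OFV drop (likelihood-ratio test at
#' `alpha_fwd`, degrees of freedom = number of new parameters) until no
#' candidate is significant, then repeatedly removes the least significant
#' included covariate whose removal is not significant at the stricter
#' `alpha_bwd`. Ties are broken by OFV drop and then candidate order. A
#' candidate whose fit fails is skipped with a warning and recorded in the
#' trace.
#'
#' @param dataset An [fu_dataset()].
#' @param base_model Base [pop_model()].
#' @param candidates Tibble with columns `covariate`, `form` and optionally
#'   `center` (default: covariate median in the dataset). Candidates whose
#'   covariate column is missing are skipped with a warning.
#' @param alpha_fwd Forward-inclusion significance level (default 0.05).
#' @param alpha_bwd Backward-elimination significance level (default 0.01).
#' @param fit_fun Fitting backend, `function(dataset, model)` returning
#'   `list(ofv=, model=)`; replaceable for testing. Defaults to [fit_pk()]
#'   without the covariance step.
#' @return An object of class `fu_scm`: `trace` (tibble of every decision),
#'   `final_model`, `included` (character), `base_ofv`, `final_ofv`.
#' @export
scm <- function(dataset, base_model, candidates, alpha_fwd = 0.05,
                alpha_bwd = 0.01, fit_fun = default_fit_fun()) {
  candidates <- as_tibble(candidates)
  if (!all(c("covariate", "form") %in% names(candidates))) {
    abort("`candidates` needs columns `covariate` and `form`.")
  }
  if (!"center" %in% names(candidates)) candidates$center <- NA_real_
  keep <- candidates$covariate %in% names(dataset$subjects)
  if (any(!keep)) {
    warn(paste0("Candidate covariate(s) not in dataset, skipped: ",
                paste(unique(candidates$covariate[!keep]), collapse = ", ")))
    candidates <- candidates[keep, , drop = FALSE]
  }
  candidates$center <- ifelse(
    is.na(candidates$center),
    vapply(candidates$covariate,
           function(cv) median(dataset$subjects[[cv]]), double(1)),
    candidates$center
  )

  base <- fit_fun(dataset, base_model)
  trace <- list()
  step <- 0L
  current <- base
  pool <- candidates
  repeat {
    if (!nrow(pool)) break
    step <- step + 1L
    evals <- purrr::pmap(pool, function(covariate, form, center, ...) {
      m <- add_candidate(current$model, covariate, form, center)
      res <- tryCatch(fit_fun(dataset, m), error = function(e) NULL)
      if (is.null(res) || !is.finite(res$ofv)) {
        warn(paste0("Fit failed for candidate ", covariate, " [", form,
                    "]; skipped."))
        return(list(ok = FALSE, delta = NA_real_, p = NA_real_, res = NULL))
      }
      delta <- current$ofv - res$ofv
      list(ok = TRUE, delta = delta,
           p = lrt_quiet(current$ofv, res$ofv, candidate_df(form)),
           res = res)
    })
    delta <- vapply(evals, function(e) e$delta %||% NA_real_, double(1))
    pval <- vapply(evals, function(e) e$p %||% NA_real_, double(1))
    for (i in seq_len(nrow(pool))) {
      trace[[length(trace) + 1L]] <- tibble(
        step = step, phase = "forward", covariate = pool$covariate[i],
        form = pool$form[i], delta_ofv = delta[i],
        df = candidate_df(pool$form[i]), p_value = pval[i],
        decision = if (!evals[[i]]$ok) "skipped" else "tested"
      )
    }
    sig <- which(!is.na(pval) & pval < alpha_fwd)
    if (!length(sig)) break
    best <- sig[order(-delta[sig], sig)][1]
    trace[[length(trace) + 1L]] <- tibble(
      step = step, phase = "forward", covariate = pool$covariate[best],
      form = pool$form[best], delta_ofv = delta[best],
      df = candidate_df(pool$form[best]), p_value = pval[best],
      decision = "included"
    )
    current <- evals[[best]]$res
    pool <- pool[-best, , drop = FALSE]
  }

  repeat {
    incl <- vapply(current$model$effects, function(e) e$covariate,
                   character(1))
    incl <- incl[incl %in% candidates$covariate]
    if (!length(incl)) break
    step <- step + 1L
    evals <- lapply(incl, function(cv) {
      m <- drop_covariate(current$model, cv)
      res <- tryCatch(fit_fun(dataset, m), error = function(e) NULL)
      if (is.null(res) || !is.finite(res$ofv)) {
        warn(paste0("Fit failed when removing ", cv, "; covariate kept."))
        return(list(ok = FALSE, delta = NA_real_, p = NA_real_, res = NULL))
      }
      delta <- res$ofv - current$ofv
      eff <- current$model$effects[[
        which(vapply(current$model$effects, function(e) e$covariate,
                     character(1)) == cv)]]
      list(ok = TRUE, delta = delta,
           p = lrt_quiet(res$ofv, current$ofv, n_effect_par(eff)),
           df = n_effect_par(eff), res = res)
    })
    pval <- vapply(evals, function(e) e$p %||% NA_real_, double(1))
    for (i in seq_along(incl)) {
      trace[[length(trace) + 1L]] <- tibble(
        step = step, phase = "backward", covariate = incl[i],
        form = NA_character_, delta_ofv = evals[[i]]$delta %||% NA_real_,
        df = evals[[i]]$df %||% NA_integer_, p_value = pval[i],
        decision = if (!evals[[i]]$ok) "skipped" else "tested"
      )
    }
    removable <- which(!is.na(pval) & pval >= alpha_bwd)
    if (!length(removable)) break
    worst <- removable[order(-pval[removable])][1]
    trace[[length(trace) + 1L]] <- tibble(
      step = step, phase = "backward", covariate = incl[worst],
      form = NA_character_, delta_ofv = evals[[worst]]$delta,
      df = evals[[worst]]$df, p_value = pval[worst], decision = "removed"
    )
    current <- evals[[worst]]$res
  }

  included <- vapply(current$model$effects, function(e) e$covariate,
                     character(1))
  structure(
    list(trace = dplyr::bind_rows(trace), final_model = current$model,
         included = intersect(included, candidates$covariate),
         base_ofv = base$ofv, final_ofv = current$ofv),
    class = "fu_scm"
  )
}

lrt_quiet <- function(ofv_reduced, ofv_full, df) {
  suppressWarnings(lrt(ofv_reduced, ofv_full, df))
}

#' @export
print.fu_scm <- function(x, ...) {
  cat("<fu_scm> stepwise covariate modeling\n")
  cat("  base OFV:  ", format(x$base_ofv, digits = 8), "\n")
  cat("  final OFV: ", format(x$final_ofv, digits = 8), "\n")
  cat("  included:  ",
      if (length(x$included)) paste(x$included, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Likelihood-ratio test of a single covariate effect
#'
#' Fits the base model and the base model plus one covariate effect and
#' reports the OFV drop, its p-value, and the interindividual variability
#' (%CV) of clearance before and after inclusion — the reduction in IIV is
#' how much between-subject variability the covariate explains.
#'
#' @inheritParams scm
#' @param covariate Covariate column name.
#' @param form Effect form (see [covariate_effect()]).
#' @param center Centering value; default is the covariate median.
#' @return A list: `delta_ofv`, `df`, `p_value`, `fit` (the extended-model
#'   fit), `base_fit`, `iiv_cv_before`, `iiv_cv_after`.
#' @export
test_single_covariate <- function(dataset, base_model, covariate,
                                  form = "exponential", center = NULL,
                                  fit_fun = default_fit_fun()) {
  center <- center %||% median(dataset$subjects[[covariate]])
  base <- fit_fun(dataset, base_model)
  ext <- fit_fun(dataset,
                 add_candidate(base$model, covariate, form, center))
  list(
    delta_ofv = base$ofv - ext$ofv,
    df = candidate_df(form),
    p_value = lrt_quiet(base$ofv, ext$ofv, candidate_df(form)),
    fit = ext, base_fit = base,
    iiv_cv_before = omega_to_cv(base$model$omega_cl),
    iiv_cv_after = omega_to_cv(ext$model$omega_cl)
  )
}

resample_subjects <- function(dataset, ids) {
  new_id <- sprintf("B%04d", seq_along(ids))
  pick <- function(tbl) {
    parts <- lapply(seq_along(ids), function(k) {
      rows <- tbl[tbl$subject_id == ids[k], , drop = FALSE]
      rows$subject_id <- rep(new_id[k], nrow(rows))
      rows
    })
    dplyr::bind_rows(parts)
  }
  fu_dataset(pick(dataset$subjects), pick(dataset$doses),
             pick(dataset$observations), pick(dataset$adverse_events))
}

#' Non-parametric bootstrap of a population-model fit
#'
#' Resamples whole subjects with replacement (no stratification) to the
#' original subject count, refits the model to each replicate starting from
#' the supplied estimates, and summarizes each parameter by the replicate
#' median and 2.5/97.5 percentiles. Replicates whose fit fails or does not
#' converge are counted and excluded from the percentiles. A covariate
#' effect whose 95% confidence interval includes zero is flagged
#' `unreliable` — the rationale used to drop such effects from a final
#' model.
#'
#' @param dataset An [fu_dataset()].
#' @param model Fitted [pop_model()] used both as the point estimate and as
#'   starting values for every replicate.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling stream.
#' @param control See [fit_control()].
#' @return An object of class `fu_boot`: `replicates` (tibble `replicate`,
#'   `term`, `estimate`), `summary` (tibble `term`, `estimate`, `median`,
#'   `conf.low`, `conf.high`, `unreliable`), `n_requested`, `n_failed`.
#' @export
bootstrap_pk <- function(dataset, model, n_replicates = 1000, seed = 1,
                         control = fit_control()) {
  est_names <- estimated_par_names(model)
  ids <- dataset$subjects$subject_id
  id_draws <- withr::with_seed(seed, {
    matrix(sample(ids, length(ids) * n_replicates, replace = TRUE),
           nrow = n_replicates)
  })
  reps <- vector("list", n_replicates)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    ds <- resample_subjects(dataset, id_draws[r, ])
    fit <- tryCatch(
      fit_pk(ds, model, compute_se = FALSE, control = control),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    reps[[r]] <- tibble(replicate = r, term = est_names,
                        estimate = as.numeric(fit$par[est_names]))
  }
  replicates <- dplyr::bind_rows(reps)
  point <- model_get_par(model, est_names)
  summary <- replicates |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      median = median(.data$estimate),
      conf.low = quantile(.data$estimate, 0.025, names = FALSE),
      conf.high = quantile(.data$estimate, 0.975, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      estimate = as.numeric(point[.data$term]),
      unreliable = grepl("^theta_", .data$term) &
        sign(.data$conf.low) * sign(.data$conf.high) <= 0
    ) |>
    dplyr::select("term", "estimate", "median", "conf.low", "conf.high",
                  "unreliable")
  summary <- summary[match(est_names, summary$term), , drop = FALSE]
  structure(
    list(replicates = replicates, summary = summary,
         n_requested = n_replicates, n_failed = n_failed),
    class = "fu_boot"
  )
}

#' @export
print.fu_boot <- function(x, ...) {
  cat("<fu_boot> ", x$n_requested, " replicates (", x$n_failed,
      " failed)\n", sep = "")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname bootstrap_pk
#' @param x An `fu_boot`.
#' @param ... Unused.
#' @method tidy fu_boot
#' @export
tidy.fu_boot <- function(x, ...) x$summary
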