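#' Specification of a synthetic therapeutic-drug-monitoring cohort
#'
#' Describes the covariate structure of a virtual 5FU TDM population:
#' lognormal covariate distributions matched to published medians and
#' truncated to the published ranges, a shared latent "muscularity" factor
#' inducing positive correlation between the four skeletal-muscle-index
#' measures, BSA-proportional dosing, and a distribution of the number of
#' observed treatment cycles (one steady-state sample per cycle by default).
#'
#' @param n_subjects Number of subjects (default 111).
#' @param cycle_probs Probabilities for 1-5 observed cycles per subject
#'   (mode at 2 cycles by default; the default mean gives roughly 370
#'   concentration observations for 111 subjects).
#' @param obs_per_cycle Steady-state samples per cycle (default 1).
#' @param infusion_duration Infusion length in h (default 24).
#' @param dose_per_bsa `c(median, min, max)` of the BSA-normalized dose in
#'   mg/m^2 (default 2283, 1441-3641).
#' @param bsa,age,smi_psoas,smi_back,smi_total_hu,smi_total_seg Each
#'   `c(median, min, max)` of the respective covariate distribution.
#' @param p_male Proportion of male subjects (default 75/111).
#' @param smi_latent_cor Pairwise correlation of the SMI measures on the log
#'   scale, induced by one latent factor (default 0.8).
#' @param ct_offset_range Range of the (integer, uniform) CT-scan-to-sampling
#'   offset in days.
#' @return An object of class `fu_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 111,
                        cycle_probs = c(0.08, 0.30, 0.22, 0.20, 0.20),
                        obs_per_cycle = 1,
                        infusion_duration = 24,
                        dose_per_bsa = c(2283, 1441, 3641),
                        bsa = c(1.97, 1.47, 2.85),
                        age = c(64, 35, 84),
                        smi_psoas = c(1.48, 0.46, 3.78),
                        smi_back = c(3.78, 0.94, 8.41),
                        smi_total_hu = c(9.58, 4.12, 18.82),
                        smi_total_seg = c(50.26, 25.47, 92.67),
                        p_male = 75 / 111,
                        smi_latent_cor = 0.8,
                        ct_offset_range = c(-150, 150)) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  if (length(cycle_probs) != 5 || any(cycle_probs < 0)) {
    abort("`cycle_probs` must be 5 non-negative probabilities.")
  }
  if (p_male < 0 || p_male > 1) abort("`p_male` must be in [0, 1].")
  if (smi_latent_cor < 0 || smi_latent_cor > 1) {
    abort("`smi_latent_cor` must be in [0, 1].")
  }
  for (nm in c("dose_per_bsa", "bsa", "age", "smi_psoas", "smi_back",
               "smi_total_hu", "smi_total_seg")) {
    v <- get(nm)
    if (length(v) != 3 || v[2] > v[1] || v[1] > v[3]) {
      abort(paste0("`", nm, "` must be c(median, min, max) with ",
                   "min <= median <= max."))
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         cycle_probs = cycle_probs / sum(cycle_probs),
         obs_per_cycle = as.integer(obs_per_cycle),
         infusion_duration = infusion_duration,
         dose_per_bsa = dose_per_bsa, bsa = bsa, age = age,
         smi_psoas = smi_psoas, smi_back = smi_back,
         smi_total_hu = smi_total_hu, smi_total_seg = smi_total_seg,
         p_male = p_male, smi_latent_cor = smi_latent_cor,
         ct_offset_range = ct_offset_range),
    class = "fu_cohort_spec"
  )
}

# sdlog such that the expected extremes of `n_ref` lognormal draws roughly
# span (min, max); draws are clamped to the published range afterwards
range_sdlog <- function(spec3, n_ref = 111) {
  z <- qnorm(1 - 0.5 / n_ref)
  (log(spec3[3]) - log(spec3[2])) / (2 * z)
}

draw_trunc_lnorm <- function(n, spec3, z = rnorm(n)) {
  pmin(pmax(spec3[1] * exp(range_sdlog(spec3) * z), spec3[2]), spec3[3])
}

#' Generate a virtual cohort (covariates and dosing, no concentrations)
#'
#' Draws per-subject covariates and BSA-proportional dosing according to a
#' [cohort_spec()]. The four SMI measures share a latent muscularity factor
#' so they are positively correlated; every draw is truncated to the
#' configured range. Reproducible given `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return An [fu_dataset()] with subjects, doses and observation rows whose
#'   `dv` is `NA` (fill with [simulate_concentrations()]).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "fu_cohort_spec"))
  withr::with_seed(seed, {
    n <- spec$n_subjects
    id <- sprintf("S%03d", seq_len(n))
    sex <- ifelse(runif(n) < spec$p_male, "male", "female")
    height <- ifelse(sex == "male", rnorm(n, 1.76, 0.07),
                     rnorm(n, 1.63, 0.06))
    height <- pmin(pmax(height, 1.45), 2.10)
    lam <- sqrt(spec$smi_latent_cor)
    z0 <- rnorm(n)
    smi_draw <- function(spec3) {
      draw_trunc_lnorm(n, spec3, z = lam * z0 + sqrt(1 - lam^2) * rnorm(n))
    }
    subjects <- tibble(
      subject_id = id, sex = sex,
      age = round(draw_trunc_lnorm(n, spec$age)),
      height = height,
      bsa = draw_trunc_lnorm(n, spec$bsa),
      smi_psoas = smi_draw(spec$smi_psoas),
      smi_back = smi_draw(spec$smi_back),
      smi_total_hu = smi_draw(spec$smi_total_hu),
      smi_total_seg = smi_draw(spec$smi_total_seg),
      ct_offset_days = sample(spec$ct_offset_range[1]:spec$ct_offset_range[2],
                              n, replace = TRUE)
    )
    n_cycles <- sample(1:5, n, replace = TRUE, prob = spec$cycle_probs)
    dose_per_bsa <- draw_trunc_lnorm(n, spec$dose_per_bsa)
    dose <- dose_per_bsa * subjects$bsa
    doses <- tibble(
      subject_id = rep(id, n_cycles),
      cycle = unlist(lapply(n_cycles, seq_len)),
      dose_amount = rep(dose, n_cycles),
      infusion_duration = spec$infusion_duration,
      start_time = 0
    )
    obs <- doses[rep(seq_len(nrow(doses)), each = spec$obs_per_cycle), ] |>
      dplyr::transmute(
        subject_id = .data$subject_id, cycle = .data$cycle,
        time = spec$infusion_duration - 1,
        dv = NA_real_, steady_state = TRUE
      )
    fu_dataset(subjects, doses, obs)
  })
}

#' Simulate steady-state concentrations under a population model
#'
#' For each subject draws a lognormal clearance random effect, computes the
#' individual prediction from the covariate model and the one-compartment
#' infusion model, and adds combined proportional/additive residual error
#' (scaled by a subject-level lognormal multiplier if the model carries IIV
#' on residual variability). Simulated concentrations that come out negative
#' under additive error are dropped with a warning, since concentrations are
#' non-negative.
#'
#' @param dataset An [fu_dataset()] with dosing and observation rows.
#' @param truth An [pop_model()] used as simulation truth.
#' @param seed Integer seed.
#' @return The dataset with `dv` filled in. The per-subject simulated
#'   random effects are attached as attribute `"eta"`.
#' @export
simulate_concentrations <- function(dataset, truth = fu_reference_model(),
                                    seed = 1) {
  stopifnot(inherits(dataset, "fu_dataset"), inherits(truth, "fu_model"))
  prep <- fu_prep(dataset, truth)
  withr::with_seed(seed, {
    n <- prep$n_sub
    eta_cl <- rnorm(n, 0, truth$omega_cl)
    eta_eps <- if (truth$omega_eps > 0) rnorm(n, 0, truth$omega_eps) else
      rep(0, n)
    tvcl <- typical_clearance(truth, prep$subjects)
    cl_i <- individual_clearance(tvcl, eta_cl)
    cl_o <- cl_i[prep$idx]
    pred <- predict_concentration(cl_o, truth$v, prep$rate, prep$time,
                                  prep$ss)
    sd_o <- sqrt(residual_variance(pred, truth)) * exp(eta_eps[prep$idx])
    dv <- pred + sd_o * rnorm(length(pred))
    neg <- dv < 0
    obs <- dataset$observations
    # fu_prep reorders observations by subject; map the draws back
    ord <- order(match(obs$subject_id, dataset$subjects$subject_id))
    obs$dv[ord] <- dv
    if (any(neg)) {
      warn(paste0(sum(neg), " simulated concentration(s) were negative and ",
                  "set missing."))
      keep <- rep(TRUE, nrow(obs))
      keep[ord][neg] <- FALSE
      obs <- obs[keep, , drop = FALSE]
    }
    out <- fu_dataset(dataset$subjects, dataset$doses, obs,
                      dataset$adverse_events)
    attr(out, "eta") <- tibble(subject_id = prep$subjects$subject_id,
                               eta_cl = eta_cl, eta_eps = eta_eps)
    out
  })
}

#' Logistic simulation truth for adverse events
#'
#' Per adverse-event type, the probability of a severe (CTCAE grade >= 2)
#' event is `plogis(beta0 + beta1 * SMI)`. The default truths reproduce the
#' reported effect sizes: an odds ratio of 0.15 per cm^2/m^2 of psoas SMI
#' for severe fatigue (an 85% reduction per unit) and 0.52 per cm^2/m^2 of
#' back-muscle SMI for severe polyneuropathy (a 48% reduction per unit),
#' with intercepts placing the severe-event probability near 0.3 at the
#' median SMI.
#'
#' @param ae_type Adverse-event types.
#' @param covariate SMI column used per type.
#' @param beta0,beta1 Intercept and slope per type.
#' @return Tibble `ae_type`, `covariate`, `beta0`, `beta1`.
#' @export
reference_ae_truth <- function(ae_type = c("fatigue", "polyneuropathy"),
                               covariate = c("smi_psoas", "smi_back"),
                               beta0 = c(log(0.15) * -1.48 + qlogis(0.3),
                                         log(0.52) * -3.78 + qlogis(0.3)),
                               beta1 = c(log(0.15), log(0.52))) {
  tibble(ae_type = ae_type, covariate = covariate,
         beta0 = beta0, beta1 = beta1)
}

#' Simulate severe adverse events from a logistic truth
#'
#' Draws one Bernoulli severe-event indicator per subject and adverse-event
#' type and records it as CTCAE grade 2 (severe) or 0 (not severe).
#'
#' @param dataset An [fu_dataset()].
#' @param truth Tibble as returned by [reference_ae_truth()].
#' @param seed Integer seed.
#' @return The dataset with adverse-event records appended.
#' @export
simulate_adverse_events <- function(dataset, truth = reference_ae_truth(),
                                    seed = 1) {
  stopifnot(inherits(dataset, "fu_dataset"))
  subj <- dataset$subjects
  withr::with_seed(seed, {
    recs <- purrr::pmap(truth, function(ae_type, covariate, beta0, beta1) {
      if (!ae_type %in% fu_ae_types) {
        abort(paste0("Unknown ae_type \"", ae_type, "\" in truth."))
      }
      if (!covariate %in% names(subj)) {
        abort(paste0("Unknown covariate \"", covariate, "\" in AE truth."))
      }
      p <- plogis(beta0 + beta1 * subj[[covariate]])
      tibble(subject_id = subj$subject_id, ae_type = ae_type,
             grade = ifelse(rbinom(nrow(subj), 1, p) == 1, 2L, 0L))
    })
    fu_dataset(subj, dataset$doses, dataset$observations,
               dplyr::bind_rows(dataset$adverse_events, recs))
  })
}

#' Read a cohort specification from YAML
#'
#' Top-level keys mirror the arguments of [cohort_spec()].
#'
#' @param path YAML file path.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(cohort_spec)))]
  do.call(cohort_spec, lapply(args, unlist))
}
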