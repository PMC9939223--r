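#' Analysis dataset container
#'
#' An `fu_dataset` bundles the four tables of a therapeutic-drug-monitoring
#' pharmacokinetic analysis: per-subject covariates, dosing events,
#' steady-state concentration observations, and adverse-event records.
#' All downstream functions (simulation, estimation, covariate modeling,
#' diagnostics, toxicity regression) consume this container.
#'
#' @param subjects Tibble with one row per subject: `subject_id`, `sex`
#'   (`"male"`/`"female"`), `age` (years), `height` (m), `bsa` (m^2), the four
#'   skeletal-muscle-index measures `smi_psoas`, `smi_back`, `smi_total_hu`,
#'   `smi_total_seg` (cm^2/m^2), `ct_offset_days` (signed days between CT scan
#'   and sampling), and optional laboratory columns.
#' @param doses Tibble: `subject_id`, `cycle`, `dose_amount` (mg),
#'   `infusion_duration` (h), `start_time` (h within cycle).
#' @param observations Tibble: `subject_id`, `cycle`, `time` (h since infusion
#'   start), `dv` (concentration, ng/ml), `steady_state` (logical).
#' @param adverse_events Tibble: `subject_id`, `ae_type`, `grade` (CTCAE 0-4).
#'
#' @return An object of class `fu_dataset`.
#' @export
fu_dataset <- function(subjects,
                       doses = empty_doses(),
                       observations = empty_observations(),
                       adverse_events = empty_adverse_events()) {
  x <- structure(
    list(
      subjects = as_tibble(subjects),
      doses = as_tibble(doses),
      observations = as_tibble(observations),
      adverse_events = as_tibble(adverse_events)
    ),
    class = "fu_dataset"
  )
  validate_fu_dataset(x)
}

empty_doses <- function() {
  tibble(subject_id = character(), cycle = integer(),
         dose_amount = double(), infusion_duration = double(),
         start_time = double())
}

empty_observations <- function() {
  tibble(subject_id = character(), cycle = integer(), time = double(),
         dv = double(), steady_state = logical())
}

empty_adverse_events <- function() {
  tibble(subject_id = character(), ae_type = character(), grade = integer())
}

#' Recognised adverse-event types
#'
#' The adverse events documented at patient visits and analysed in the
#' toxicity regressions.
#' @export
fu_ae_types <- c("polyneuropathy", "stomatitis", "hand_foot_syndrome",
                 "fatigue", "diarrhea", "nausea", "emesis")

validate_fu_dataset <- function(x) {
  s <- x$subjects
  if (!"subject_id" %in% names(s)) {
    abort("`subjects` must have a `subject_id` column.")
  }
  if (anyDuplicated(s$subject_id)) {
    abort("Duplicated subject_id in subjects table.")
  }
  if ("height" %in% names(s) && any(!is.na(s$height) & s$height <= 0)) {
    abort("All heights must be positive.")
  }
  if ("bsa" %in% names(s) && any(!is.na(s$bsa) & s$bsa <= 0)) {
    abort("All BSA values must be positive.")
  }
  for (col in c("smi_psoas", "smi_back", "smi_total_hu", "smi_total_seg")) {
    if (col %in% names(s) && any(!is.na(s[[col]]) & s[[col]] <= 0)) {
      abort(paste0("All present `", col, "` values must be positive."))
    }
  }
  if ("sex" %in% names(s) && !all(s$sex %in% c("male", "female", NA))) {
    abort("`sex` must be coded \"male\" or \"female\".")
  }
  for (tbl in c("doses", "observations", "adverse_events")) {
    bad <- setdiff(unique(x[[tbl]]$subject_id), s$subject_id)
    if (length(bad)) {
      abort(paste0("subject_id in `", tbl, "` not found in subjects table: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  if (nrow(x$doses) && any(x$doses$dose_amount <= 0)) {
    abort("All dose amounts must be positive.")
  }
  if (nrow(x$doses) && any(x$doses$infusion_duration <= 0)) {
    abort("All infusion durations must be positive.")
  }
  if (nrow(x$observations)) {
    if (any(x$observations$time < 0)) abort("Observation times must be >= 0.")
    no_dose <- setdiff(unique(x$observations$subject_id),
                       unique(x$doses$subject_id))
    if (length(no_dose)) {
      abort(paste0("Subjects with observations but no dosing record: ",
                   paste(head(no_dose, 5), collapse = ", ")))
    }
  }
  if (nrow(x$adverse_events) &&
      !all(x$adverse_events$grade %in% 0:4)) {
    abort("CTCAE grades must be integers 0-4.")
  }
  x
}

#' @export
print.fu_dataset <- function(x, ...) {
  cat("<fu_dataset>\n")
  cat("  subjects:       ", nrow(x$subjects), "\n")
  cat("  doses:          ", nrow(x$doses), "\n")
  cat("  observations:   ", nrow(x$observations), "\n")
  cat("  adverse events: ", nrow(x$adverse_events), "\n")
  invisible(x)
}

#' Column mapping for the rectangular CSV layout
#'
#' The on-disk layout follows the NONMEM convention: one rectangular table
#' with `ID`, `CYCLE`, `TIME`, `EVID`, `MDV`, `AMT`, `RATE`, `DV`, `SS`
#' event columns plus per-subject covariate columns. `fu_dialect()` returns
#' the default mapping from internal names to CSV column names; pass a
#' modified copy to [read_dataset()]/[write_dataset()] for files with other
#' headers. Sex is coded 0 = male, 1 = female on disk.
#'
#' @param ... Named overrides, e.g. `fu_dialect(bsa = "BSAM2")`.
#' @return Named character vector mapping internal field -> CSV column.
#' @export
fu_dialect <- function(...) {
  d <- c(
    subject_id = "ID", cycle = "CYCLE", time = "TIME", evid = "EVID",
    mdv = "MDV", amt = "AMT", rate = "RATE", dv = "DV", ss = "SS",
    height = "HT", bsa = "BSA", age = "AGE", sex = "SEX",
    smi_psoas = "SMIPM", smi_back = "SMIBM", smi_total_hu = "SMITH",
    smi_total_seg = "SMITS", ct_offset_days = "CTDAYS",
    creatinine = "CREA", bilirubin = "BILI", alt = "ALT", ast = "AST",
    ggt = "GGT", ldh = "LDH", ca199 = "CA199", cea = "CEA"
  )
  over <- c(...)
  if (length(over)) d[names(over)] <- over
  d
}

fu_covariate_fields <- c("height", "bsa", "age", "sex", "smi_psoas",
                         "smi_back", "smi_total_hu", "smi_total_seg",
                         "ct_offset_days", "creatinine", "bilirubin", "alt",
                         "ast", "ggt", "ldh", "ca199", "cea")

#' Read a NONMEM-style rectangular dataset
#'
#' Reads a rectangular CSV of dosing events (`EVID = 1`) and concentration
#' observations (`EVID = 0`, `MDV = 0`) with per-subject covariate columns
#' into an [fu_dataset()]. Rows with `MDV = 1` are excluded from the
#' observation table but still contribute dosing and covariate information.
#' Covariates are taken as constant per subject: the first value wins, with a
#' warning if later rows conflict. Quantifiable observations below the assay's
#' lower limit of quantification are dropped with a warning.
#'
#' @param path CSV file path.
#' @param ae_path Optional CSV of adverse events with columns
#'   `subject_id,ae_type,grade`.
#' @param dialect Column mapping, see [fu_dialect()].
#' @param lloq Lower limit of quantification in ng/ml (assay default 86);
#'   `NULL` disables the filter.
#' @return An `fu_dataset`.
#' @export
read_dataset <- function(path, ae_path = NULL, dialect = fu_dialect(),
                         lloq = 86) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("subject_id", "time", "dv", "amt", "rate", "evid", "mdv")
  missing_cols <- dialect[required][!dialect[required] %in% names(raw)]
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  col <- function(field) raw[[dialect[[field]]]]
  has <- function(field) dialect[[field]] %in% names(raw)

  num <- function(field, what = field) {
    v <- col(field)
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "." & is.na(out))
    if (length(bad)) {
      abort(paste0("Non-numeric ", what, " value ", v[bad[1]], " in row ",
                   bad[1], " of column ", dialect[[field]], "."))
    }
    out
  }

  id <- as.character(col("subject_id"))
  evid <- num("evid")
  if (!all(evid %in% c(0, 1))) {
    abort(paste0("Unknown EVID code(s): ",
                 paste(unique(evid[!evid %in% c(0, 1)]), collapse = ", ")))
  }
  mdv <- num("mdv")
  time <- num("time")
  amt <- num("amt")
  rate <- num("rate")
  cycle <- if (has("cycle")) as.integer(num("cycle")) else 1L
  ss <- if (has("ss")) num("ss") else NULL

  # DV must be numeric only where it is an actual observation
  dv_raw <- col("dv")
  dv <- suppressWarnings(as.numeric(ifelse(dv_raw %in% c(".", "NA"), NA, dv_raw)))
  bad_dv <- which(evid == 0 & mdv == 0 &
                    !is.na(dv_raw) & !dv_raw %in% c(".", "NA") & is.na(dv))
  if (length(bad_dv)) {
    abort(paste0("Non-numeric DV value \"", dv_raw[bad_dv[1]],
                 "\" in row ", bad_dv[1], "."))
  }

  ev <- tibble(subject_id = id, cycle = cycle, time = time, evid = evid,
               mdv = mdv, amt = amt, rate = rate, dv = dv,
               ss = if (is.null(ss)) 1 else ss)

  subjects <- tibble(subject_id = unique(id))
  for (field in fu_covariate_fields) {
    if (!has(field)) next
    v <- num(field, what = field)
    first <- tapply(v, factor(id, levels = subjects$subject_id),
                    function(z) z[!is.na(z)][1])
    conflict <- tapply(v, factor(id, levels = subjects$subject_id),
                       function(z) length(unique(z[!is.na(z)])) > 1)
    if (any(conflict, na.rm = TRUE)) {
      warn(paste0("Covariate ", field, " varies within subject(s) ",
                  paste(head(subjects$subject_id[which(conflict)], 3),
                        collapse = ", "),
                  "; first value used."))
    }
    subjects[[field]] <- as.numeric(first)
  }
  if ("sex" %in% names(subjects)) {
    subjects$sex <- ifelse(is.na(subjects$sex), NA_character_,
                           ifelse(subjects$sex == 0, "male", "female"))
  }

  doses <- ev |>
    dplyr::filter(.data$evid == 1) |>
    dplyr::transmute(
      subject_id = .data$subject_id, cycle = .data$cycle,
      dose_amount = .data$amt,
      infusion_duration = .data$amt / .data$rate,
      start_time = .data$time
    )

  obs <- ev |>
    dplyr::filter(.data$evid == 0, .data$mdv == 0) |>
    dplyr::transmute(
      subject_id = .data$subject_id, cycle = .data$cycle, time = .data$time,
      dv = .data$dv, steady_state = .data$ss == 1
    )
  if (!is.null(lloq) && nrow(obs)) {
    below <- !is.na(obs$dv) & obs$dv < lloq
    if (any(below)) {
      warn(paste0(sum(below), " observation(s) below the LLOQ of ", lloq,
                  " ng/ml were excluded."))
      obs <- obs[!below, , drop = FALSE]
    }
  }

  ae <- empty_adverse_events()
  if (!is.null(ae_path)) {
    ae <- readr::read_csv(ae_path,
                          col_types = readr::cols(
                            subject_id = "c", ae_type = "c", grade = "i"),
                          progress = FALSE)
  }
  fu_dataset(subjects, doses, obs, ae)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

#' Write a dataset to the rectangular CSV layout
#'
#' Inverse of [read_dataset()]: dosing rows (`EVID = 1`, `MDV = 1`) and
#' observation rows (`EVID = 0`, `MDV = 0`) with covariates repeated on every
#' row. Rows are ordered deterministically by subject, cycle, time with dose
#' events before observations at equal times; numeric fields are written with
#' enough digits for a lossless round trip.
#'
#' @inheritParams read_dataset
#' @param dataset An [fu_dataset()].
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, ae_path = NULL,
                          dialect = fu_dialect()) {
  stopifnot(inherits(dataset, "fu_dataset"))
  d <- dataset$doses |>
    dplyr::transmute(subject_id = .data$subject_id, cycle = .data$cycle,
                     time = .data$start_time, evid = 1, mdv = 1,
                     amt = .data$dose_amount,
                     rate = .data$dose_amount / .data$infusion_duration,
                     dv = NA_real_, ss = NA_real_)
  o <- dataset$observations |>
    dplyr::transmute(subject_id = .data$subject_id, cycle = .data$cycle,
                     time = .data$time, evid = 0, mdv = 0,
                     amt = NA_real_, rate = NA_real_, dv = .data$dv,
                     ss = as.numeric(.data$steady_state))
  ev <- dplyr::bind_rows(d, o) |>
    dplyr::arrange(.data$subject_id, .data$cycle, .data$time, -.data$evid)

  subj <- dataset$subjects
  cov_fields <- intersect(fu_covariate_fields, names(subj))
  ev <- dplyr::left_join(ev, subj[, c("subject_id", cov_fields)],
                         by = "subject_id")
  if ("sex" %in% cov_fields) {
    ev$sex <- ifelse(is.na(ev$sex), NA_real_, as.numeric(ev$sex == "female"))
  }

  out <- tibble(.rows = nrow(ev))
  for (field in c("subject_id", "cycle", "time", "evid", "mdv", "amt",
                  "rate", "dv", "ss", cov_fields)) {
    v <- ev[[field]]
    out[[dialect[[field]]]] <- if (is.numeric(v)) fmt_num(v) else
      ifelse(is.na(v), "", as.character(v))
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  if (!is.null(ae_path)) {
    readr::write_csv(dataset$adverse_events, ae_path, progress = FALSE)
  }
  invisible(path)
}

#' Filter subjects by CT-scan-to-sampling time window
#'
#' Muscle status is only comparable to drug exposure if the CT scan was taken
#' close in time to the blood sampling. Subjects whose absolute CT offset
#' exceeds `max_days` are excluded together with all their dosing,
#' observation and adverse-event records; the window is inclusive
#' (`|offset| <= max_days` is retained).
#'
#' @param dataset An [fu_dataset()] whose subjects carry `ct_offset_days`.
#' @param max_days Window half-width in days (default 205).
#' @return A list with elements `dataset` (the filtered `fu_dataset`) and
#'   `excluded` (tibble `subject_id`, `ct_offset_days`, `reason`).
#' @export
apply_time_window_filter <- function(dataset, max_days = 205) {
  stopifnot(inherits(dataset, "fu_dataset"))
  s <- dataset$subjects
  if (!"ct_offset_days" %in% names(s) || anyNA(s$ct_offset_days)) {
    bad <- if (!"ct_offset_days" %in% names(s)) s$subject_id else
      s$subject_id[is.na(s$ct_offset_days)]
    abort(paste0("Missing ct_offset_days for subject(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  keep <- abs(s$ct_offset_days) <= max_days
  excluded <- tibble(
    subject_id = s$subject_id[!keep],
    ct_offset_days = s$ct_offset_days[!keep],
    reason = paste0("|ct_offset_days| > ", max_days)
  )
  ids <- s$subject_id[keep]
  out <- fu_dataset(
    s[keep, , drop = FALSE],
    dataset$doses[dataset$doses$subject_id %in% ids, , drop = FALSE],
    dataset$observations[dataset$observations$subject_id %in% ids, ,
                         drop = FALSE],
    dataset$adverse_events[dataset$adverse_events$subject_id %in% ids, ,
                           drop = FALSE]
  )
  list(dataset = out, excluded = excluded)
}

#' Skeletal-muscle cross-sectional area from a Hounsfield-unit grid
#'
#' Counts pixels whose attenuation falls in the skeletal-muscle Hounsfield
#' window (35-50 HU, inclusive at both ends) inside an optional region of
#' interest, and converts the pixel count to an area in cm^2.
#'
#' @param grid Numeric matrix of Hounsfield units.
#' @param pixel_spacing Length-2 numeric, pixel spacing in mm (row, column).
#' @param roi_mask Optional logical matrix of the same shape; pixels outside
#'   the mask are ignored.
#' @param hu_low,hu_high Window bounds in HU (defaults 35 and 50).
#' @return Area in cm^2.
#' @export
muscle_area_from_hu_grid <- function(grid, pixel_spacing, roi_mask = NULL,
                                     hu_low = 35, hu_high = 50) {
  if (!is.matrix(grid) || length(grid) == 0) {
    abort("`grid` must be a non-empty matrix of Hounsfield units.")
  }
  if (length(pixel_spacing) != 2 || any(pixel_spacing <= 0)) {
    abort("`pixel_spacing` must be two positive spacings in mm.")
  }
  if (!is.null(roi_mask)) {
    if (!identical(dim(roi_mask), dim(grid))) {
      abort("`roi_mask` shape must match `grid`.")
    }
  } else {
    roi_mask <- array(TRUE, dim(grid))
  }
  inside <- grid >= hu_low & grid <= hu_high & roi_mask
  n_pix <- sum(inside, na.rm = TRUE)
  # mm^2 -> cm^2
  n_pix * pixel_spacing[1] * pixel_spacing[2] / 100
}

#' Skeletal muscle index
#'
#' SMI is the muscle cross-sectional area at the L3 level normalized to the
#' squared body height.
#'
#' @param muscle_area Area in cm^2 (>= 0).
#' @param height Body height in m (> 0).
#' @return SMI in cm^2/m^2.
#' @export
compute_smi <- function(muscle_area, height) {
  if (any(muscle_area < 0)) abort("`muscle_area` must be >= 0.")
  if (any(height <= 0)) abort("`height` must be > 0.")
  muscle_area / height^2
}

#' Steady-state area under the concentration-time curve
#'
#' For a continuous infusion at steady state, AUC over one administration is
#' the steady-state concentration times the infusion duration; concentrations
#' in ng/ml are converted to mg/L.
#'
#' @param css Steady-state concentration in ng/ml (>= 0).
#' @param infusion_duration Infusion duration in h (> 0).
#' @return AUC in mg*h/L.
#' @export
compute_auc <- function(css, infusion_duration) {
  if (any(css < 0)) abort("`css` must be >= 0.")
  if (any(infusion_duration <= 0)) abort("`infusion_duration` must be > 0.")
  css * 1e-3 * infusion_duration
}

#' Dichotomize CTCAE grades into severe/non-severe outcomes
#'
#' CTCAE grades 0-1 are coded 0 and grades 2-4 (clinically relevant) are
#' coded 1. A subject's multiple gradings across visits are collapsed by the
#' maximum recorded grade. Subjects with no record of the queried type are
#' coded 0 and flagged `observed = FALSE`.
#'
#' @param dataset An [fu_dataset()] (uses its `adverse_events` and the full
#'   subject list) or a tibble of adverse-event records; in the latter case
#'   supply `subject_ids` to define the subject universe.
#' @param ae_type One of [fu_ae_types].
#' @param subject_ids Optional character vector of subject ids.
#' @return Tibble `subject_id`, `outcome` (0/1), `observed` (logical).
#' @export
dichotomize_grades <- function(dataset, ae_type, subject_ids = NULL) {
  if (!ae_type %in% fu_ae_types) {
    abort(paste0("Unknown ae_type \"", ae_type, "\"; expected one of: ",
                 paste(fu_ae_types, collapse = ", ")))
  }
  if (inherits(dataset, "fu_dataset")) {
    records <- dataset$adverse_events
    subject_ids <- subject_ids %||% dataset$subjects$subject_id
  } else {
    records <- as_tibble(dataset)
    subject_ids <- subject_ids %||% unique(records$subject_id)
  }
  if (length(subject_ids) == 0) {
    return(tibble(subject_id = character(), outcome = integer(),
                  observed = logical()))
  }
  rec <- records[records$ae_type == ae_type, , drop = FALSE]
  max_grade <- tapply(rec$grade, factor(rec$subject_id, levels = subject_ids),
                      max)
  max_grade <- as.numeric(max_grade)
  tibble(
    subject_id = subject_ids,
    outcome = as.integer(!is.na(max_grade) & max_grade >= 2),
    observed = !is.na(max_grade)
  )
}
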