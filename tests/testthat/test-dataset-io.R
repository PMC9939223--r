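test_that("read_dataset parses a NONMEM-style toy file and keeps counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ID,CYCLE,TIME,EVID,MDV,AMT,RATE,DV,BSA,HT,SEX,CTDAYS",
    "1,1,0,1,1,4800,200,NA,1.8,1.75,0,10",
    "1,1,23,0,0,,,900,1.8,1.75,0,10",
    "1,1,23.5,0,0,,,950,1.8,1.75,0,10",
    "2,1,0,1,1,5000,208.3,NA,2.1,1.82,1,-30",
    "2,1,23,0,0,,,1100,2.1,1.82,1,-30",
    "2,1,23.5,0,0,,,1050,2.1,1.82,1,-30"
  ), path)
  ds <- read_dataset(path)
  expect_s3_class(ds, "fu_dataset")
  expect_equal(nrow(ds$subjects), 2)
  expect_equal(nrow(ds$doses), 2)
  expect_equal(nrow(ds$observations), 4)
  expect_equal(ds$subjects$sex, c("male", "female"))
  expect_equal(ds$doses$infusion_duration[1], 4800 / 200)
  # MDV=1 rows with missing DV are dosing rows, not observations
  expect_false(any(is.na(ds$observations$dv)))
})

test_that("read_dataset raises named schema/parse/validation errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,EVID,MDV,AMT,RATE", "1,0,1,1,100,10"), path)
  expect_error(read_dataset(path), "DV")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,EVID,MDV,AMT,RATE,DV",
               "1,0,1,1,100,10,NA", "1,23,0,0,,,abc"), path2)
  expect_error(read_dataset(path2), "row 2")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,EVID,MDV,AMT,RATE,DV",
               "1,0,7,1,100,10,NA"), path3)
  expect_error(read_dataset(path3), "EVID")
})

test_that("covariates are constant per subject, first value wins", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,EVID,MDV,AMT,RATE,DV,BSA",
               "1,0,1,1,4800,200,NA,1.8",
               "1,23,0,0,,,900,1.9"), path)
  expect_warning(ds <- read_dataset(path), "bsa")
  expect_equal(ds$subjects$bsa, 1.8)
})

test_that("observations below the LLOQ are excluded with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,EVID,MDV,AMT,RATE,DV",
               "1,0,1,1,4800,200,NA",
               "1,22,0,0,,,50",
               "1,23,0,0,,,900"), path)
  expect_warning(ds <- read_dataset(path), "LLOQ")
  expect_equal(nrow(ds$observations), 1)
  expect_silent(ds2 <- read_dataset(path, lloq = NULL))
  expect_equal(nrow(ds2$observations), 2)
})

test_that("write/read round trip is lossless for all numeric fields", {
  set.seed(11)
  ds <- make_toy_dataset(n_sub = 3, obs_per_sub = 2,
                         dv = 900 + runif(6) * 300,
                         bsa = 1.5 + runif(3), smi_back = 1 + runif(3) * 7)
  ds$observations$dv <- ds$observations$dv * exp(rnorm(6, 0, 1e-9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  for (col in c("bsa", "smi_back", "height", "age", "ct_offset_days")) {
    expect_identical(back$subjects[[col]], ds$subjects[[col]])
  }
  expect_identical(back$observations$dv, ds$observations$dv)
  expect_identical(back$observations$time, ds$observations$time)
  expect_identical(back$doses$dose_amount, ds$doses$dose_amount)
  expect_identical(back$doses$infusion_duration, ds$doses$infusion_duration)
  expect_identical(back$subjects$sex, ds$subjects$sex)
})

test_that("writing an empty dataset yields a header-only readable file", {
  ds <- fu_dataset(tibble::tibble(subject_id = character()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  lines <- readLines(path)
  expect_length(lines, 1)
  back <- read_dataset(path)
  expect_equal(nrow(back$subjects), 0)
  expect_equal(nrow(back$observations), 0)
})

test_that("time-window filter keeps |offset| <= max_days inclusively", {
  ds <- make_toy_dataset(n_sub = 3)
  ds$subjects$ct_offset_days <- c(10, 205, 206)
  res <- apply_time_window_filter(ds, max_days = 205)
  expect_equal(res$dataset$subjects$subject_id, c("T01", "T02"))
  expect_equal(res$excluded$subject_id, "T03")
  expect_equal(res$excluded$ct_offset_days, 206)
  # child records of excluded subjects are dropped
  expect_false("T03" %in% res$dataset$observations$subject_id)

  ds$subjects$ct_offset_days <- c(0, -1, 0)
  res0 <- apply_time_window_filter(ds, max_days = 0)
  expect_equal(nrow(res0$dataset$subjects), 2)

  ds$subjects$ct_offset_days <- c(0, 0, 0)
  resid <- apply_time_window_filter(ds, max_days = 205)
  expect_equal(resid$dataset$subjects, ds$subjects)
  expect_equal(nrow(resid$excluded), 0)
})

test_that("time-window filter is idempotent and monotone in max_days", {
  ds <- make_toy_dataset(n_sub = 5)
  ds$subjects$ct_offset_days <- c(-300, -100, 0, 150, 400)
  once <- apply_time_window_filter(ds, 205)$dataset
  twice <- apply_time_window_filter(once, 205)$dataset
  expect_equal(once$subjects, twice$subjects)
  narrow <- apply_time_window_filter(ds, 120)$dataset$subjects$subject_id
  wide <- apply_time_window_filter(ds, 205)$dataset$subjects$subject_id
  expect_true(all(narrow %in% wide))

  ds$subjects$ct_offset_days[2] <- NA
  expect_error(apply_time_window_filter(ds, 205), "T02")
})

test_that("muscle area counts in-window pixels inclusively and scales", {
  g <- matrix(-100, 3, 3)
  g[c(1, 3, 5, 7)] <- 40
  expect_equal(muscle_area_from_hu_grid(g, c(5, 5)), 1.00)
  expect_equal(muscle_area_from_hu_grid(matrix(0, 4, 4), c(5, 5)), 0)
  g2 <- matrix(c(35, 50, -100, 200), 2, 2)
  expect_equal(muscle_area_from_hu_grid(g2, c(1, 1)), 0.02)
  expect_error(muscle_area_from_hu_grid(matrix(numeric(0), 0, 0), c(1, 1)),
               "empty")
  expect_error(muscle_area_from_hu_grid(g, c(1, 1), roi_mask = matrix(TRUE, 2, 2)),
               "shape")
})

test_that("muscle area is additive over disjoint ROIs and window-invariant", {
  set.seed(21)
  g <- matrix(runif(100, -150, 150), 10, 10)
  m1 <- matrix(FALSE, 10, 10); m1[1:5, ] <- TRUE
  m2 <- !m1
  a_all <- muscle_area_from_hu_grid(g, c(2, 2))
  expect_equal(muscle_area_from_hu_grid(g, c(2, 2), m1) +
                 muscle_area_from_hu_grid(g, c(2, 2), m2), a_all)
  # values outside the window do not matter
  g2 <- g
  g2[g < 35 | g > 50] <- -1000
  expect_equal(muscle_area_from_hu_grid(g2, c(2, 2)), a_all)
})

test_that("SMI and AUC arithmetic are exact and degree-1 homogeneous", {
  expect_equal(compute_smi(15.12, 2.0), 3.78)
  expect_equal(compute_smi(0, 1.7), 0)
  expect_equal(compute_smi(42, 1.0), 42)
  expect_error(compute_smi(10, 0), "height")
  expect_equal(compute_smi(2 * 15.12, 2.0), 2 * compute_smi(15.12, 2.0))

  expect_equal(compute_auc(1000, 24), 24.0)
  expect_equal(compute_auc(0, 24), 0)
  expect_equal(compute_auc(821, 24), 19.704)
  expect_error(compute_auc(-1, 24), "css")
  expect_equal(compute_auc(3 * 821, 24), 3 * compute_auc(821, 24))
})

test_that("grade dichotomization codes grade >= 2 as severe, max over visits", {
  ds <- make_toy_dataset(n_sub = 3)
  ds$adverse_events <- tibble::tibble(
    subject_id = c("T01", "T01", "T02", "T02"),
    ae_type = "fatigue",
    grade = c(0L, 1L, 1L, 3L)
  )
  ds <- fu_dataset(ds$subjects, ds$doses, ds$observations, ds$adverse_events)
  out <- dichotomize_grades(ds, "fatigue")
  expect_equal(out$outcome, c(0L, 1L, 0L))
  expect_equal(out$observed, c(TRUE, TRUE, FALSE))
  expect_error(dichotomize_grades(ds, "headache"), "Unknown ae_type")
  empty <- dichotomize_grades(tibble::tibble(subject_id = character(),
                                             ae_type = character(),
                                             grade = integer()), "fatigue")
  expect_equal(nrow(empty), 0)
})
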