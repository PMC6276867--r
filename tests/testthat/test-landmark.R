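sw <- c(2005, 2015)

test_that("toy registry membership, time and event match hand computation", {
  reg <- toy_registry()
  ## L = 26: A eligible (dies 2.5y later), B transplanted at 25 -> excluded,
  ## C's and E's age-26 dates precede the window, D lost at 24
  d26 <- build_landmark_dataset(reg, 26, w = 10, study_window = sw)
  expect_equal(d26$patient_id, "A")
  expect_equal(d26$time, 2.5)
  expect_equal(d26$event, 1L)
  expect_equal(d26$fev1_pct, 60)           # LOCF from the age-25 review
  expect_equal(d26$lag_fev1_pct, 1)
  log26 <- attr(d26, "exclusion_log")
  expect_equal(unname(log26["transplanted_before_landmark"]), 1L)  # B
  expect_equal(unname(log26["lost_before_landmark"]), 1L)          # D
  expect_equal(unname(log26["outside_window"]), 2L)                # C, E
  ## E joined the registry at 28: inside the window but not yet entered
  d27 <- build_landmark_dataset(reg, 27.5, w = 10, study_window = sw)
  expect_equal(unname(attr(d27, "exclusion_log")["not_entered"]), 1L)

  ## L = 24: B still untransplanted -> included, censored at age 33
  d24 <- build_landmark_dataset(reg, 24, w = 10, study_window = sw)
  b <- d24[d24$patient_id == "B", ]
  expect_equal(b$time, 9)
  expect_equal(b$event, 0L)
  expect_equal(b$fev1_pct, 40)
  expect_equal(b$lag_fev1_pct, 1)

  ## L = 30: C included with lag-0 LOCF, death 6 years later
  d30 <- build_landmark_dataset(reg, 30, w = 10, study_window = sw)
  cc <- d30[d30$patient_id == "C", ]
  expect_equal(cc$time, 6)
  expect_equal(cc$event, 1L)
  expect_equal(cc$lag_fev1_pct, 0)

  ## L = 29: A dead at 28.5 -> excluded
  d29 <- build_landmark_dataset(reg, 29, w = 10, study_window = sw)
  expect_false("A" %in% d29$patient_id)
  expect_equal(unname(attr(d29, "exclusion_log")["dead_before_landmark"]), 1L)

  ## included + excluded counts account for every patient
  for (d in list(d24, d26, d29, d30)) {
    expect_equal(nrow(d) + sum(attr(d, "exclusion_log")), 5L)
  }
})

test_that("administrative censoring at the horizon and half-open edges", {
  mk <- function(death_age) {
    patients <- tibble::tibble(
      id = "X", sex = 0L, genotype_class = 2L, birth = 1970,
      diagnosis_age = 1, registry_entry_age = 35, death_age = death_age,
      transplant_age = NA_real_, loss_age = NA_real_)
    reviews <- toy_registry()$reviews[1, ]
    reviews$patient_id <- "X"; reviews$age <- 35
    structure(list(patients = patients, reviews = reviews, config = NULL),
              class = "registry")
  }
  ## death after L + w -> administratively censored at the horizon
  d <- build_landmark_dataset(mk(47.5), 36, w = 10, study_window = c(2005, 2030))
  expect_equal(d$time, 10); expect_equal(d$event, 0L)
  ## death exactly at L + w counts as an event with time w
  d <- build_landmark_dataset(mk(46), 36, w = 10, study_window = c(2005, 2030))
  expect_equal(d$time, 10); expect_equal(d$event, 1L)
  ## death exactly at L: not alive at the landmark
  d <- build_landmark_dataset(mk(36), 36, w = 10, study_window = c(2005, 2030))
  expect_equal(nrow(d), 0L)
  expect_equal(unname(attr(d, "exclusion_log")["dead_before_landmark"]), 1L)
})

test_that("locf_covariates implements last-observation-carried-forward", {
  rv <- tibble::tibble(patient_id = "p", age = c(19.2, 21.1),
                       fev1_pct = c(80, 74))
  out <- locf_covariates(rv, 21, vars = "fev1_pct")
  expect_equal(unname(out$values["fev1_pct"]), 80)
  expect_equal(unname(out$lags["fev1_pct"]), 1.8)
  ## review exactly at L -> used with lag 0
  out <- locf_covariates(rv, 21.1, vars = "fev1_pct")
  expect_equal(unname(out$values["fev1_pct"]), 74)
  expect_equal(unname(out$lags["fev1_pct"]), 0)
  ## only post-landmark reviews -> missing-history signal
  expect_error(locf_covariates(rv, 19, vars = "fev1_pct"),
               class = "landmarker_missing_history")
  ## per-variable carry-forward skips missing measurements
  rv2 <- tibble::tibble(patient_id = "p", age = c(19, 20),
                        fev1_pct = c(80, NA), weight = c(NA, 55))
  out <- locf_covariates(rv2, 20, vars = c("fev1_pct", "weight"))
  expect_equal(unname(out$values), c(80, 55))
  expect_equal(unname(out$lags), c(1, 0))
})

test_that("the default grid yields 33 landmark datasets stacked", {
  reg <- small_registry(120, seed = 2)
  datasets <- lapply(18:50, build_landmark_dataset, registry = reg, w = 10)
  expect_length(datasets, 33)
  st <- stack_landmarks(datasets)
  expect_equal(attr(st, "landmark_grid"), 18:50)
  expect_equal(length(unique(st$L)), sum(sapply(datasets, nrow) > 0))
  ## stacking a single dataset is the identity
  one <- stack_landmarks(datasets[10])
  expect_equal(nrow(one), nrow(datasets[[10]]))
  ## duplicate landmark ages are rejected
  expect_error(stack_landmarks(datasets[c(1, 1)]), "distinct")
  ## (patient, L) pairs unique
  expect_equal(anyDuplicated(st[, c("patient_id", "L")]), 0L)
})

test_that("a patient alive from entry 20 to death at 29.5 appears 10 times", {
  patients <- tibble::tibble(
    id = "Z", sex = 0L, genotype_class = 1L, birth = 1985,
    diagnosis_age = 0.5, registry_entry_age = 20, death_age = 29.5,
    transplant_age = NA_real_, loss_age = NA_real_)
  reviews <- toy_registry()$reviews[1, ]
  reviews$patient_id <- "Z"; reviews$age <- 20
  reg <- structure(list(patients = patients, reviews = reviews, config = NULL),
                   class = "registry")
  st <- build_stacked(reg, grid = 18:50, w = 10, study_window = sw)
  expect_equal(nrow(st), 10)
  expect_equal(sort(unique(st$L)), 20:29)
})

test_that("eligibility is monotone: exclusions for past events persist", {
  reg <- small_registry(300, seed = 6)
  sets <- lapply(25:32, function(L) {
    build_landmark_dataset(reg, L, w = 10)$patient_id
  })
  pat <- reg$patients
  gone <- function(L) {
    pat$id[(!is.na(pat$death_age) & pat$death_age <= L) |
             (!is.na(pat$transplant_age) & pat$transplant_age <= L) |
             (!is.na(pat$loss_age) & pat$loss_age <= L)]
  }
  for (i in seq_along(sets)) {
    L <- (25:32)[i]
    expect_length(intersect(sets[[i]], gone(L)), 0)
    if (i > 1) {
      ## nobody excluded for a pre-L event at L-1 reappears at L
      expect_length(intersect(sets[[i]], gone(L - 1)), 0)
    }
  }
})

test_that("no record violates the outcome range and truth accounting holds", {
  reg <- small_registry(400, seed = 7)
  st <- build_stacked(reg, grid = c(20, 30, 40), w = 10)
  expect_true(all(st$time > 0 & st$time <= 10))
  expect_true(all(st$event %in% 0:1))
  ## event flags agree with the generative truth
  dth <- reg$patients$death_age[match(st$patient_id, reg$patients$id)]
  expect_true(all(is.na(dth[st$event == 0]) |
                    dth[st$event == 0] > st$L[st$event == 0] + st$time[st$event == 0] - 1e-9))
  expect_equal(st$time[st$event == 1],
               (dth - st$L)[st$event == 1], tolerance = 1e-12)
})

test_that("stacked data round-trip through the delimited file", {
  reg <- small_registry(80, seed = 4)
  st <- build_stacked(reg, grid = 24:26, w = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stacked(st, path)
  back <- read_stacked(path)
  expect_equal(attr(back, "landmark_grid"), c(24, 25, 26))
  expect_equal(back$time, st$time, tolerance = 1e-12)
  expect_equal(back$fev1_pct, st$fev1_pct, tolerance = 1e-12)
})
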