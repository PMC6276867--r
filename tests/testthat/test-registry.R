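test_that("simulation is deterministic given the config seed", {
  cfg <- registry_config(n_individuals = 150, seed = 11)
  r1 <- simulate_registry(cfg)
  r2 <- simulate_registry(cfg)
  expect_identical(r1$patients, r2$patients)
  expect_identical(r1$reviews, r2$reviews)
  expect_identical(r1$latents, r2$latents)
  r3 <- simulate_registry(registry_config(n_individuals = 150, seed = 12))
  expect_false(identical(r1$patients, r3$patients))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(42); before <- rnorm(3)
  set.seed(42); invisible(simulate_registry(registry_config(50, seed = 1)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("an empty cohort yields a valid empty registry", {
  reg <- simulate_registry(registry_config(n_individuals = 0, seed = 1))
  expect_s3_class(reg, "registry")
  expect_equal(nrow(reg$patients), 0)
  expect_equal(nrow(reg$reviews), 0)
  expect_true(all(c("patient_id", "age", "fev1_pct", "iv_days_home")
                  %in% names(reg$reviews)))
})

test_that("config validation names the offending field", {
  expect_error(registry_config(n_individuals = -1, seed = 1), "n_individuals")
  expect_error(registry_config(100, seed = NULL), "seed")
  expect_error(registry_config(100, visit_interval = 0, seed = 1),
               "visit_interval")
  expect_error(registry_config(100, study_window = c(2015, 2005), seed = 1),
               "study_window")
  bs <- default_binary_states(); bs$cfrd$p_on <- 1.5
  expect_error(registry_config(100, binary_states = bs, seed = 1),
               "cfrd")
})

test_that("generated records satisfy the structural invariants", {
  reg <- small_registry(600, seed = 5)
  rv <- reg$reviews
  ## visit ages strictly increasing within patient
  inc <- tapply(rv$age, rv$patient_id, function(a) all(diff(a) > 0))
  expect_true(all(inc))
  ## value ranges
  expect_true(all(rv$fev1_pct > 0 & rv$fvc_pct > 0))
  expect_true(all(rv$weight > 0 & rv$height > 0))
  expect_true(all(rv$iv_days_hospital >= 0 & rv$iv_days_hospital <= 366))
  expect_true(all(rv$iv_days_home >= 0 & rv$iv_days_home <= 366))
  expect_true(all(rv$pseudomonas %in% 0:1 & rv$cfrd %in% 0:1))
  ## no review postdates death, transplant or loss
  pat <- reg$patients
  last <- tapply(rv$age, rv$patient_id, max)
  stopage <- pmin(ifelse(is.na(pat$death_age), Inf, pat$death_age),
                  ifelse(is.na(pat$transplant_age), Inf, pat$transplant_age),
                  ifelse(is.na(pat$loss_age), Inf, pat$loss_age))
  expect_true(all(last[pat$id] <= stopage + 1e-12, na.rm = TRUE))
  ## referential integrity and event ordering
  expect_true(all(rv$patient_id %in% pat$id))
  both <- !is.na(pat$transplant_age) & !is.na(pat$death_age)
  expect_true(all(pat$transplant_age[both] < pat$death_age[both]))
  expect_true(all(is.na(pat$death_age) | is.na(pat$loss_age)))
  ## observation starts at entry
  first <- tapply(rv$age, rv$patient_id, min)
  expect_equal(as.numeric(first[pat$id]), pat$registry_entry_age,
               tolerance = 1e-12)
})

test_that("with zero hazard coefficients death is independent of covariates", {
  hz <- default_hazard()
  hz$coefs[] <- 0
  hz$calendar_coef <- 0
  hz$baseline_breaks <- 18
  hz$baseline_loghaz <- log(0.03)
  cfg <- registry_config_constant(4000, seed = 8, hazard = hz)
  reg <- simulate_registry(cfg)
  first <- reg$reviews |>
    dplyr::group_by(patient_id) |> dplyr::slice(1) |> dplyr::ungroup()
  pat <- dplyr::left_join(reg$patients, first, by = c(id = "patient_id"))
  time <- pmin(ifelse(is.na(pat$death_age), Inf, pat$death_age),
               cfg$study_window[2] - pat$birth) - pat$registry_entry_age
  event <- as.integer(!is.na(pat$death_age) &
                        pat$death_age <= cfg$study_window[2] - pat$birth)
  grp <- pat$fev1_pct > median(pat$fev1_pct)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- 1 - stats::pchisq(sd$chisq, 1)
  expect_gt(p, 0.01)
})

test_that("with zero effects Kaplan-Meier matches the closed-form baseline", {
  hz <- default_hazard()
  hz$coefs[] <- 0
  hz$calendar_coef <- 0
  hz$baseline_breaks <- 18
  hz$baseline_loghaz <- log(0.05)
  cfg <- registry_config_constant(10000, seed = 9, hazard = hz)
  reg <- simulate_registry(cfg)
  pat <- reg$patients
  exit <- cfg$study_window[2] - pat$birth
  time <- pmin(ifelse(is.na(pat$death_age), Inf, pat$death_age), exit) -
    pat$registry_entry_age
  event <- as.integer(!is.na(pat$death_age) & pat$death_age <= exit)
  km <- km_curve(tibble::tibble(time = time, event = event))
  ## Kolmogorov-Smirnov style band at alpha = 0.01
  band <- 1.63 / sqrt(nrow(pat))
  expect_lt(max(abs(km$survival - exp(-0.05 * km$time))), band)
})

test_that("binary-state chains hold their stationary prevalence", {
  ## zero hazard coefficients remove survivorship selection, so review-level
  ## prevalence must sit at the stationary distribution at all ages
  hz <- default_hazard(); hz$coefs[] <- 0; hz$calendar_coef <- 0
  cfg <- registry_config(10000, seed = 10, hazard = hz,
                         transplant = list(log_rate = -Inf, fev1_coef = 0,
                                           fev1_ref = 75,
                                           post_death_loghaz = log(0.06)))
  reg <- simulate_registry(cfg)
  ## one review per patient (the last at age >= 30): the state of a patient
  ## at a fixed time is exactly stationary, and patients are independent --
  ## review-level pooling would understate the variance (serial correlation)
  late <- reg$reviews |>
    dplyr::filter(.data$age >= 30) |>
    dplyr::group_by(patient_id) |> dplyr::slice(dplyr::n()) |> dplyr::ungroup()
  for (v in names(default_binary_states())) {
    pi <- landmarker:::stationary_prevalence(cfg$binary_states[[v]])
    se <- sqrt(pi * (1 - pi) / nrow(late))
    expect_lt(abs(mean(late[[v]]) - pi), 3 * se + 1e-12)
  }
})

test_that("an off-stationary fast-mixing chain converges to stationarity", {
  bs <- default_binary_states()
  bs$other_hospitalization$init <- 0  # start everyone off
  hz <- default_hazard(); hz$coefs[] <- 0; hz$calendar_coef <- 0
  cfg <- registry_config(8000, seed = 13, binary_states = bs, hazard = hz)
  reg <- simulate_registry(cfg)
  entry <- reg$patients$registry_entry_age[
    match(reg$reviews$patient_id, reg$patients$id)]
  late <- reg$reviews[reg$reviews$age - entry >= 6, ] |>   # >= 6 transitions
    dplyr::group_by(patient_id) |> dplyr::slice(dplyr::n()) |> dplyr::ungroup()
  pi <- with(bs$other_hospitalization, p_on / (p_on + p_off))
  se <- sqrt(pi * (1 - pi) / nrow(late))
  expect_lt(abs(mean(late$other_hospitalization) - pi), 3 * se)
})

test_that("registry round-trips through the delimited files", {
  reg <- small_registry(60, seed = 3)
  dir <- withr::local_tempdir()
  write_registry(reg, dir)
  expect_true(file.exists(file.path(dir, "patients.csv")))
  back <- read_registry(dir)
  expect_equal(back$patients, reg$patients, tolerance = 1e-12)
  expect_equal(back$reviews$fev1_pct, reg$reviews$fev1_pct, tolerance = 1e-12)
  expect_equal(back$config$seed, reg$config$seed)
})
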