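test_that("concordance equals exhaustive pair enumeration", {
  ## 4-record fixture with one censoring, worked by the brute-force oracle
  d <- tibble::tibble(risk = c(0.9, 0.4, 0.7, 0.2),
                      time = c(1, 3, 2, 8), event = c(1, 0, 1, 1))
  expect_equal(as.numeric(c_index(d, risk, time, event, horizon = 10)),
               brute_c_index(d$risk, d$time, d$event, 10))
  ## random datasets, including ties in both risk and time
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    d <- tibble::tibble(risk = sample(seq(0, 1, 0.1), n, TRUE),
                        time = sample(1:8, n, TRUE),
                        event = rbinom(n, 1, 0.6))
    for (h in c(3, 6, 10)) {
      expect_equal(as.numeric(c_index(d, risk, time, event, horizon = h)),
                   brute_c_index(d$risk, d$time, d$event, h))
    }
  }
})

test_that("concordance limiting cases", {
  ## risks perfectly ordered against event times, no censoring -> 1
  d <- tibble::tibble(risk = c(5, 4, 3, 2, 1), time = 1:5, event = 1)
  expect_equal(as.numeric(c_index(d, risk, time, event, horizon = 10)), 1)
  ## all risks equal -> 0.5 by the tie convention
  d$risk <- 1
  expect_equal(as.numeric(c_index(d, risk, time, event, horizon = 10)), 0.5)
  ## monotone transformation of risks leaves the index unchanged
  set.seed(12)
  d2 <- tibble::tibble(risk = runif(50), time = rexp(50) + 0.1,
                       event = rbinom(50, 1, 0.7))
  c1 <- c_index(d2, risk, time, event, horizon = 5)
  d2$risk <- stats::qlogis(d2$risk * 0.98 + 0.01)
  expect_equal(as.numeric(c_index(d2, risk, time, event, horizon = 5)),
               as.numeric(c1))
  ## no evaluable pairs -> NA with the undefined-metric signal
  d3 <- tibble::tibble(risk = c(1, 2), time = c(5, 5), event = c(0, 0))
  expect_warning(ci <- c_index(d3, risk, time, event, horizon = 10),
                 class = "landmarker_undefined_metric")
  expect_true(is.na(ci))
})

test_that("Brier score limiting cases and hand-computed IPCW fixture", {
  ## no censoring, perfect 0/1 predictions -> 0
  d <- tibble::tibble(pred = c(0, 1, 0, 1), time = c(1, 9, 2, 12), event = 1)
  expect_equal(brier_score(d, pred, time, event, horizon = 8), 0)
  ## no censoring, constant 0.5 -> 0.25 regardless of outcomes
  d$pred <- 0.5
  expect_equal(brier_score(d, pred, time, event, horizon = 8), 0.25)
  ## 6-record fixture with censoring: hand-computed weighted sum.
  ## censoring KM G drops at 4 (risk 5), 7 (risk 3), 9 (risk 2):
  ## G(4) = 4/5, G(7) = 4/5 * 2/3, G(8-) = 8/15; deaths at 2 and 5 get
  ## weights 1/G(2-) = 1 and 1/G(5-) = 5/4; survivors weight 15/8.
  d6 <- tibble::tibble(time = c(2, 4, 5, 7, 9, 11),
                       event = c(1, 0, 1, 0, 0, 1),
                       pred = c(0.9, 0.8, 0.6, 0.5, 0.3, 0.4))
  hand <- (1 * (0 - 0.9)^2 + (5 / 4) * (0 - 0.6)^2 +
             (15 / 8) * ((1 - 0.3)^2 + (1 - 0.4)^2)) / 6
  expect_equal(brier_score(d6, pred, time, event, horizon = 8), hand,
               tolerance = 1e-12)
  ## without censoring the IPCW path equals the plain mean squared error
  set.seed(21)
  dn <- tibble::tibble(pred = runif(60), time = rexp(60) * 5 + 0.1, event = 1)
  h <- 4
  mse <- mean((as.numeric(dn$time > h) - dn$pred)^2)
  expect_equal(brier_score(dn, pred, time, event, horizon = h), mse,
               tolerance = 1e-12)
  ## out-of-range predictions are rejected
  expect_error(brier_score(dplyr::mutate(d6, pred = pred * 2), pred, time,
                           event, horizon = 8), "0, 1")
})

test_that("percentage reduction arithmetic and sign convention", {
  expect_equal(percent_reduction(0.075, 0.100), 25)
  expect_equal(percent_reduction(0.1, 0.1), 0)
  expect_lt(percent_reduction(0.12, 0.1), 0)
  expect_error(percent_reduction(0.1, 0), "positive")
})

test_that("Kaplan-Meier estimator on fixtures", {
  ## single event at 2 among 2 subjects
  km <- km_curve(tibble::tibble(time = c(2, 5), event = c(1, 0)))
  expect_equal(km$survival[km$time == 2], 0.5)
  ## no events -> survival identically 1
  km <- km_curve(tibble::tibble(time = 1:4, event = 0))
  expect_true(all(km$survival == 1))
  ## 5-record fixture: products by hand
  km <- km_curve(tibble::tibble(time = c(1, 2, 3, 4, 5),
                                event = c(1, 0, 1, 1, 0)))
  expect_equal(km$survival[km$time == 1], 4 / 5)
  expect_equal(km$survival[km$time == 3], 4 / 5 * 2 / 3)
  expect_equal(km$survival[km$time == 4], 4 / 5 * 2 / 3 * 1 / 2)
  expect_error(km_curve(tibble::tibble(time = numeric(), event = integer())),
               "empty")
})

test_that("stratified split partitions records and hits the fraction", {
  reg <- small_registry(800, seed = 51)
  st <- build_stacked(reg, grid = 22:34, w = 10)
  sp <- split_stacked(st, fraction = 0.8, seed = 99)
  expect_equal(nrow(sp$training) + nrow(sp$holdout), nrow(st))
  expect_equal(nrow(dplyr::intersect(
    dplyr::select(sp$training, patient_id, L),
    dplyr::select(sp$holdout, patient_id, L))), 0)
  ## per-landmark training share within 2 percentage points of 80%
  share <- sapply(22:34, function(l) {
    sum(sp$training$L == l) / sum(st$L == l)
  })
  expect_true(all(abs(share - 0.8) < 0.02))
  ## deterministic under the seed
  sp2 <- split_stacked(st, fraction = 0.8, seed = 99)
  expect_identical(sp$training$patient_id, sp2$training$patient_id)
  ## fraction 1 -> empty holdout
  spf <- split_stacked(st, fraction = 1, seed = 1)
  expect_equal(nrow(spf$holdout), 0)
  expect_error(split_stacked(st, fraction = 0, seed = 1), "fraction")
})

test_that("Monte-Carlo cross-validation summarises repetitions", {
  reg <- small_registry(600, seed = 52)
  st <- build_stacked(reg, grid = 24:28, w = 10)
  opts <- variant_options(2, predictors = c("sex", "fev1_pct", "weight"))
  cv <- monte_carlo_cv(st, opts, n_reps = 2, seed = 5, horizons = c(5, 10))
  expect_s3_class(cv, "cv_report")
  expect_equal(cv$n_failed, 0)
  expect_equal(sort(unique(cv$summary$horizon)), c(5, 10))
  expect_true(all(c("mean", "sd") %in% names(cv$summary)))
  ## a single repetition reproduces the direct split-fit-evaluate value
  cv1 <- monte_carlo_cv(st, opts, n_reps = 1, seed = 7, horizons = 5)
  sd1 <- derive_seeds(7, 1)
  sp <- split_stacked(st, fraction = 0.8, seed = sd1)
  ref <- evaluate_fit(fit_variant(sp$training, opts), sp$holdout, horizons = 5)
  expect_equal(cv1$summary$mean[cv1$summary$metric == "c_index"],
               ref$overall$c_index, tolerance = 1e-12)
  ## degenerate inner fraction leaves no validation records
  expect_error(monte_carlo_cv(st, opts, n_reps = 1, inner_fraction = 1,
                              seed = 1), "validation")
})

test_that("pooled metrics with a single landmark equal the per-landmark ones", {
  reg <- small_registry(400, seed = 53)
  st <- build_stacked(reg, grid = 26, w = 10)
  fit <- fit_variant(st, variant_options(2, predictors = c("fev1_pct", "weight")))
  rep <- evaluate_fit(fit, st, horizons = c(2, 5))
  expect_equal(rep$overall$c_index, rep$per_landmark$c_index)
  expect_equal(rep$overall$brier, rep$per_landmark$brier)
  expect_equal(rep$overall$pct_reduction, rep$per_landmark$pct_reduction)
})
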