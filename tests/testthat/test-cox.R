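test_that("coefficients maximise the written-out partial likelihood", {
  ## several small hand-written datasets, 1-2 covariates, no ties
  sets <- list(
    list(time = c(2, 4, 5, 7, 9, 12), event = c(1, 1, 0, 1, 0, 1),
         X = cbind(x = c(1, 0, 1, 0, 1, 0))),
    list(time = c(1, 3, 4, 6, 8), event = c(1, 0, 1, 1, 0),
         X = cbind(x = c(0.5, -1, 2, 0, 1))),
    list(time = c(1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5),
         event = c(1, 1, 1, 0, 1, 0, 1),
         X = cbind(x = c(2, 1, 0, 1, 2, 0, 1), z = c(0, 1, 0, 1, 1, 0, 0)))
  )
  for (s in sets) {
    d <- tibble::tibble(time = s$time, event = s$event)
    for (j in seq_len(ncol(s$X))) d[[colnames(s$X)[j]]] <- s$X[, j]
    fit <- fit_cox(d, cox_spec(colnames(s$X)))
    bref <- brute_cox_fit(s$time, s$event, scale(s$X, scale = FALSE))
    expect_equal(unname(coef(fit)), bref, tolerance = 1e-6)
    ## the reported optimum really is a stationary point of the brute loglik
    expect_equal(
      brute_cox_loglik(coef(fit), s$time, s$event, scale(s$X, scale = FALSE)),
      unname(fit$loglik["model"]), tolerance = 1e-10)
    expect_gte(fit$loglik["model"], fit$loglik["null"])
  }
})

test_that("the null model baseline equals the Nelson-Aalen estimator", {
  set.seed(2)
  d <- tibble::tibble(time = round(rexp(60, 0.2), 1) + 0.1,
                      event = rbinom(60, 1, 0.7))
  f0 <- fit_cox(d, cox_spec(character()))
  bh <- baseline_cumhaz(f0)
  na <- survival::survfit(survival::Surv(time, event) ~ 1, data = d,
                          stype = 2, ctype = 1)
  expect_equal(bh$cumhaz, na$cumhaz[na$n.event > 0], tolerance = 1e-12)
  ## a single subject dying at t = 3 jumps the hazard by exactly 1
  one <- fit_cox(tibble::tibble(time = 3, event = 1), cox_spec(character()))
  expect_equal(baseline_cumhaz(one)$haz, 1)
  expect_equal(baseline_cumhaz(one)$time, 3)
})

test_that("a 3-subject baseline matches hand-computed Breslow increments", {
  ## subjects: (t=1, event, x=1), (t=2, event, x=0), (t=3, censored, x=1)
  d <- tibble::tibble(time = 1:3, event = c(1, 1, 0), x = c(1, 0, 1))
  fit <- fit_cox(d, cox_spec("x"))
  b <- unname(coef(fit))
  xc <- c(1, 0, 1) - 2 / 3           # centered covariate
  w <- exp(b * xc)
  bh <- baseline_cumhaz(fit)
  expect_equal(bh$haz, c(1 / sum(w), 1 / sum(w[2:3])), tolerance = 1e-12)
})

test_that("record duplication leaves beta and robust variance unchanged", {
  set.seed(4)
  d <- tibble::tibble(time = rexp(40) + 0.1, event = rbinom(40, 1, 0.6),
                      x = rnorm(40), id = sprintf("p%02d", 1:40))
  f1 <- fit_cox(d, cox_spec("x", cluster = "id"))
  d2 <- dplyr::bind_rows(d, d)
  f2 <- fit_cox(d2, cox_spec("x", cluster = "id"))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-8)
  expect_equal(vcov(f2), vcov(f1), tolerance = 1e-8)
  expect_equal(vcov(f2, "naive"), vcov(f1, "naive") / 2, tolerance = 1e-8)
})

test_that("fits are equivariant under covariate rescaling", {
  set.seed(5)
  d <- tibble::tibble(time = rexp(80) + 0.1, event = rbinom(80, 1, 0.5),
                      x = rnorm(80, 50, 10))
  d$x10 <- d$x / 10
  f <- fit_cox(d, cox_spec("x"))
  f10 <- fit_cox(d, cox_spec("x10"))
  expect_equal(unname(coef(f10)), unname(coef(f)) * 10, tolerance = 1e-7)
  expect_equal(unname(vcov(f10)), unname(vcov(f)) * 100, tolerance = 1e-6)
})

test_that("a single stratum equals the unstratified fit", {
  set.seed(6)
  d <- tibble::tibble(time = rexp(60) + 0.1, event = rbinom(60, 1, 0.6),
                      x = rnorm(60), g = "only")
  f1 <- fit_cox(d, cox_spec("x"))
  f2 <- fit_cox(d, cox_spec("x", strata = "g"))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-12)
})

test_that("engine agrees with coxph on stratified clustered data", {
  reg <- small_registry(500, seed = 31)
  st <- build_stacked(reg, grid = 24:30, w = 10)
  preds <- c("sex", "fev1_pct", "weight", "cfrd", "b_cepacia")
  fit <- fit_cox(st, cox_spec(preds, strata = "L", cluster = "patient_id"))
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~", paste(preds, collapse = "+"),
    "+ survival::strata(L) + survival::cluster(patient_id)"))
  cfit <- survival::coxph(fml, data = st, ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(cfit)), tolerance = 1e-9)
  expect_equal(unname(vcov(fit)), unname(vcov(cfit)), tolerance = 1e-9)
  expect_equal(unname(diag(vcov(fit, "naive"))),
               unname(diag(cfit$naive.var)), tolerance = 1e-9)
  ## with singleton clusters the sandwich agrees with coxph's robust variance
  d <- st[st$L == 25, ]
  d$rowid <- seq_len(nrow(d))
  fr <- fit_cox(d, cox_spec(preds, cluster = "rowid"))
  cr <- survival::coxph(survival::Surv(time, event) ~ sex + fev1_pct +
                          weight + cfrd + b_cepacia, data = d,
                        robust = TRUE, ties = "breslow")
  expect_equal(unname(vcov(fr)), unname(cr$var), tolerance = 1e-6)
})

test_that("Efron tie handling matches coxph", {
  set.seed(7)
  d <- tibble::tibble(time = sample(1:6, 90, TRUE), event = rbinom(90, 1, 0.6),
                      x = rnorm(90), z = rbinom(90, 1, 0.5))
  fe <- fit_cox(d, cox_spec(c("x", "z"), ties = "efron"))
  ce <- survival::coxph(survival::Surv(time, event) ~ x + z, data = d,
                        ties = "efron")
  expect_equal(unname(coef(fe)), unname(coef(ce)), tolerance = 1e-9)
  expect_equal(unname(vcov(fe, "naive")), unname(vcov(ce)), tolerance = 1e-9)
})

test_that("time-varying coefficient terms match coxph tt()", {
  set.seed(8)
  d <- tibble::tibble(time = rexp(250) * 4 + 0.1, event = rbinom(250, 1, 0.7),
                      x = rnorm(250))
  tm <- list(cox_term("x"),
             cox_term("x", label = "x:t", tv_basis = function(t) t / 10))
  ftv <- fit_cox(d, cox_spec(tm))
  ctv <- survival::coxph(survival::Surv(time, event) ~ x + tt(x), data = d,
                         ties = "breslow", tt = function(x, t, ...) x * t / 10)
  expect_equal(unname(coef(ftv)), unname(coef(ctv)), tolerance = 1e-9)
  expect_equal(unname(vcov(ftv, "naive")), unname(vcov(ctv)), tolerance = 1e-9)
})

test_that("degenerate designs and strata are reported", {
  set.seed(9)
  d <- tibble::tibble(time = rexp(30) + 0.1, event = rbinom(30, 1, 0.6),
                      x = rnorm(30))
  d$x2 <- 2 * d$x
  expect_error(fit_cox(d, cox_spec(c("x", "x2"))), "collinear.*x2")
  d$g <- rep(c("a", "b"), each = 15)
  d$event[d$g == "b"] <- 0
  expect_warning(fit_cox(d, cox_spec("x", strata = "g")), "no events")
  expect_error(fit_cox(dplyr::mutate(d, time = time - min(time)),
                       cox_spec("x")), "positive")
})

test_that("predicted survival curves behave structurally", {
  reg <- small_registry(400, seed = 32)
  st <- build_stacked(reg, grid = 25:28, w = 10)
  fit <- fit_cox(st, cox_spec(c("fev1_pct", "weight", "cfrd"),
                              strata = "L", cluster = "patient_id"))
  prof <- st[5, ]
  sc <- predict_survival(fit, prof, L = prof$L)
  expect_equal(sc$survival[sc$time == 0], 1)
  expect_true(all(diff(sc$survival) <= 1e-12))
  expect_true(all(sc$survival >= 0 & sc$survival <= 1))
  ## reference profile (covariates at the centering means) -> exp(-H0)
  ref <- as.list(fit$center)
  ref$L <- prof$L
  sref <- predict_survival(fit, ref, L = prof$L)
  bh <- baseline_cumhaz(fit, as.character(prof$L))
  expect_equal(sref$survival[-1], exp(-bh$cumhaz), tolerance = 1e-10)
  ## unknown stratum suggests the nearest fitted one
  expect_error(predict_survival(fit, prof, L = 40), "Nearest.*28")
  ## vectorised horizon prediction agrees with the curve
  p5 <- predict_survival_at(fit, st[5, ], 5)
  expect_equal(p5, sc$survival[findInterval(5, sc$time)], tolerance = 1e-12)
})

test_that("fits round-trip through the JSON serialisation", {
  reg <- small_registry(300, seed = 33)
  st <- build_stacked(reg, grid = 25:27, w = 10)
  opts <- variant_options(3, landmark_degree = 1, grid_range = c(25, 27),
                          predictors = c("sex", "fev1_pct", "weight"))
  fit <- fit_variant(st, opts)
  path <- withr::local_tempfile(fileext = ".json")
  write_cox_fit(fit, path)
  back <- read_cox_fit(path)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  expect_equal(vcov(back), vcov(fit), tolerance = 1e-12)
  expect_equal(back$baseline$cumhaz, fit$baseline$cumhaz, tolerance = 1e-12)
  ## predictions from the restored fit are identical (terms rebuilt)
  p1 <- predict_survival_at(fit, st, 5)
  p2 <- predict_survival_at(back, st, 5)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("tidy and glance expose the fit in broom style", {
  set.seed(10)
  d <- tibble::tibble(time = rexp(50) + 0.1, event = rbinom(50, 1, 0.6),
                      x = rnorm(50), z = rnorm(50))
  fit <- fit_cox(d, cox_spec(c("x", "z")))
  td <- tidy(fit, conf.int = TRUE)
  expect_equal(td$term, c("x", "z"))
  expect_true(all(c("estimate", "std.error", "statistic", "p.value",
                    "conf.low", "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 50)
  expect_true(gl$converged)
  expect_lte(gl$loglik_null, gl$loglik)
})
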