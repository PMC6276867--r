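#' Discrimination and prediction error of a fitted variant
#'
#' Scores a fitted dynamic-prediction model on a set of landmark records:
#' the truncated concordance index and IPCW Brier score at each horizon,
#' per landmark age and pooled over all records ("overall"), plus the
#' percentage reduction in Brier score against the reference predictor
#' (the per-landmark Kaplan-Meier survival probability applied to every
#' record of that landmark).  Predicted risk at a horizon is `1 - S(h)`
#' from the fitted model.  In pooled evaluations the censoring
#' distribution for the IPCW weights is estimated per landmark age.
#'
#' @param fits A `"landmark_coxfit"` or `"landmark_coxfit_list"` (variant 1).
#' @param data Evaluation records (landmark or stacked dataset).
#' @param horizons Evaluation horizons in years.
#' @return An object of class `"performance_report"`: tibbles
#'   `per_landmark` (`L`, `horizon`, `c_index`, `brier`,
#'   `brier_reference`, `pct_reduction`, `n`, `n_events`) and `overall`
#'   (same without `L`).
#' @export
evaluate_fit <- function(fits, data, horizons = c(2, 5, 10)) {
  Ls <- sort(unique(data$L))
  per_rows <- list()
  overall_rows <- list()
  for (h in horizons) {
    pred <- predict_variant_at(fits, data, h)
    risk <- 1 - pred
    km_ref <- numeric(nrow(data))
    for (l in Ls) {
      rows <- which(data$L == l)
      cv <- km_curve(data[rows, ], time, event)
      km_ref[rows] <- km_at(cv, h)
      ci <- withCallingHandlers(
        cindex_num(risk[rows], data$time[rows], data$event[rows], h),
        warning = function(w) {
          if (inherits(w, "landmarker_undefined_metric"))
            invokeRestart("muffleWarning")
        })
      br <- brier_num(pred[rows], data$time[rows], data$event[rows], h)
      br_ref <- brier_num(km_ref[rows], data$time[rows], data$event[rows], h)
      per_rows[[length(per_rows) + 1L]] <- tibble(
        L = l, horizon = h, c_index = as.numeric(ci), brier = br,
        brier_reference = br_ref,
        pct_reduction = if (br_ref > 0) percent_reduction(br, br_ref)
                        else NA_real_,
        n = length(rows),
        n_events = sum(data$event[rows] == 1 & data$time[rows] <= h))
    }
    ci_all <- cindex_num(risk, data$time, data$event, h)
    br_all <- brier_num(pred, data$time, data$event, h, group = data$L)
    br_ref_all <- brier_num(km_ref, data$time, data$event, h, group = data$L)
    overall_rows[[length(overall_rows) + 1L]] <- tibble(
      horizon = h, c_index = as.numeric(ci_all), brier = br_all,
      brier_reference = br_ref_all,
      pct_reduction = percent_reduction(br_all, br_ref_all),
      n = nrow(data),
      n_events = sum(data$event == 1 & data$time <= h))
  }
  structure(list(per_landmark = bind_rows(per_rows),
                 overall = bind_rows(overall_rows),
                 horizons = horizons,
                 variant = attr(fits, "variant")),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("<performance_report>",
      if (!is.null(x$variant)) sprintf("(variant %s)", x$variant), "\n")
  print(x$overall)
  invisible(x)
}

#' Stratified patient-level train/holdout split of a stacked dataset
#'
#' Draws a random sample of the records within each landmark-age stratum
#' (each patient contributes at most one record per landmark age, so
#' sampling records within stratum is sampling patients within stratum),
#' so the fraction of records per landmark age matches the target
#' fraction.  Deterministic under `seed`; the two parts partition the
#' stacked records.
#'
#' @param stacked Stacked landmark dataset.
#' @param fraction Training fraction in (0, 1].
#' @param seed Integer seed.
#' @param stratify_by Stratification column (default `"L"`).
#' @return A list with tibbles `training` and `holdout`.
#' @export
split_stacked <- function(stacked, fraction = 0.8, seed, stratify_by = "L") {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  strata <- stacked[[stratify_by]]
  take <- local_seed(seed, {
    sel <- logical(nrow(stacked))
    for (l in unique(strata)) {
      idx <- which(strata == l)
      if (length(idx) < 2L && fraction < 1) {
        warn(sprintf("stratum %s too small to split; all records to training.",
                     l))
        sel[idx] <- TRUE
        next
      }
      k <- round(fraction * length(idx))
      sel[sample(idx, k)] <- TRUE
    }
    sel
  })
  grid <- attr(stacked, "landmark_grid")
  w <- attr(stacked, "w")
  out <- list(training = stacked[take, , drop = FALSE],
              holdout = stacked[!take, , drop = FALSE])
  for (nm in names(out)) {
    attr(out[[nm]], "landmark_grid") <- grid
    attr(out[[nm]], "w") <- w
  }
  out
}

#' Monte-Carlo cross-validation of a model variant
#'
#' Repeatedly splits the training data (stratified by landmark age, as in
#' [split_stacked()]), fits the variant on the inner-training part and
#' scores it on the inner-validation part at the given horizons, per
#' landmark age and pooled; reports mean and standard deviation across
#' repetitions.  Repetitions whose fit fails are recorded and skipped;
#' more than 50% failures is an error.
#'
#' @param training Stacked training records.
#' @param options A [variant_options()].
#' @param n_reps Number of Monte-Carlo repetitions.
#' @param inner_fraction Inner training fraction.
#' @param seed Integer seed (child seeds per repetition are derived from it).
#' @param horizons Evaluation horizons.
#' @return An object of class `"cv_report"`: `summary` (per horizon: mean
#'   and sd of overall C-index, Brier, percentage reduction),
#'   `per_landmark_summary`, the per-repetition `reps` tibble, and the
#'   count of failed repetitions.
#' @export
monte_carlo_cv <- function(training, options, n_reps = 50,
                           inner_fraction = 0.8, seed,
                           horizons = c(2, 5, 10)) {
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  seeds <- derive_seeds(seed, n_reps)
  rep_overall <- list()
  rep_perland <- list()
  failures <- character(0)
  for (r in seq_len(n_reps)) {
    sp <- split_stacked(training, fraction = inner_fraction, seed = seeds[r])
    if (nrow(sp$holdout) == 0L) {
      abort("inner split left no validation records.")
    }
    res <- tryCatch({
      fit <- fit_variant(sp$training, options)
      evaluate_fit(fit, sp$holdout, horizons = horizons)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    rep_overall[[length(rep_overall) + 1L]] <- res$overall |> mutate(rep = r)
    rep_perland[[length(rep_perland) + 1L]] <- res$per_landmark |> mutate(rep = r)
  }
  if (length(failures) > n_reps / 2) {
    abort(sprintf("more than half of the CV repetitions failed (%d/%d): %s",
                  length(failures), n_reps, failures[1]))
  }
  reps <- bind_rows(rep_overall)
  summarise_cv <- function(df, keys) {
    df |>
      tidyr::pivot_longer(c("c_index", "brier", "pct_reduction"),
                          names_to = "metric", values_to = "value") |>
      group_by(across(all_of(c(keys, "metric")))) |>
      summarise(mean = mean(.data$value, na.rm = TRUE),
                sd = stats::sd(.data$value, na.rm = TRUE),
                n_reps = sum(!is.na(.data$value)), .groups = "drop")
  }
  structure(list(summary = summarise_cv(reps, "horizon"),
                 per_landmark_summary =
                   summarise_cv(bind_rows(rep_perland), c("L", "horizon")),
                 reps = reps,
                 n_reps = n_reps, n_failed = length(failures),
                 failures = failures),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d repetitions (%d failed)\n",
              x$n_reps, x$n_failed))
  print(x$summary)
  invisible(x)
}

#' Calibration table at a horizon
#'
#' Groups records into (by default) deciles of the predicted survival
#' probability at the horizon and compares the mean predicted probability
#' per group with the "observed" probability: the Kaplan-Meier survival
#' estimate at the horizon within the group, with its Greenwood confidence
#' band.  Groups in which no subject remains under observation to the
#' horizon are flagged (observed probability undefined/unreliable).
#'
#' @param fits A fitted variant (`"landmark_coxfit"` or fit list).
#' @param records Evaluation records.
#' @param horizon Horizon in years.
#' @param n_groups Number of predicted-probability groups (default 10);
#'   tied quantile edges are collapsed, so constant predictions give a
#'   single group.
#' @return Tibble of class `"calibration_table"`: `group`, `n`,
#'   `mean_predicted`, `observed`, `conf.low`, `conf.high`, `flagged`.
#' @export
calibration_table <- function(fits, records, horizon, n_groups = 10) {
  pred <- predict_variant_at(fits, records, horizon)
  edges <- unique(quantile(pred, probs = seq(0, 1, length.out = n_groups + 1)))
  grp <- if (length(edges) < 2L) factor(rep(1L, length(pred)))
         else cut(pred, edges, include.lowest = TRUE)
  rows_out <- list()
  for (g in levels(droplevels(grp))) {
    rows <- which(grp == g)
    tt <- records$time[rows]; ee <- records$event[rows]
    sf <- survival::survfit(survival::Surv(tt, ee) ~ 1)
    sm <- summary(sf, times = horizon, extend = TRUE)
    rows_out[[length(rows_out) + 1L]] <- tibble(
      group = g, n = length(rows), mean_predicted = mean(pred[rows]),
      observed = sm$surv, conf.low = sm$lower, conf.high = sm$upper,
      flagged = max(tt) < horizon)
  }
  structure(bind_rows(rows_out),
            class = c("calibration_table", "tbl_df", "tbl", "data.frame"),
            horizon = horizon)
}
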