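#' Construct a landmark dataset at one landmark age
#'
#' Restricts the registry to individuals at risk at landmark age `L` and
#' builds one record per eligible individual with
#' last-observation-carried-forward (LOCF) covariate summaries and the
#' time-since-landmark survival outcome.
#'
#' Eligibility at landmark age `L` requires, following the cohort
#' definition of a landmarking analysis on a calendar study window:
#' * the individual's age-`L` date falls within the study window;
#' * diagnosis and registry entry at or before age `L`;
#' * alive, untransplanted and not lost to follow-up at age `L`
#'   (an event exactly at `L` makes the individual ineligible);
#' * at least one measurement of every required time-dependent variable at
#'   or before age `L` (otherwise the individual is excluded and counted in
#'   the exclusion log).
#'
#' The outcome is `time = min(death age, loss age, age at end of study,
#' L + w) - L` with `event = 1` iff death occurs at or before that minimum;
#' censoring at the horizon `L + w` is administrative, and a death exactly
#' at `L + w` counts as an event.  Individuals transplanted after `L` stay
#' in the dataset and their deaths count as events.
#'
#' @param registry A `"registry"` object (see [simulate_registry()],
#'   [read_registry()]).
#' @param L Landmark age in years.
#' @param w Prediction horizon in years (default 10).
#' @param study_window Calendar window `c(start, end)`; defaults to the
#'   window in `registry$config`.
#' @return A tibble with one row per eligible individual: `patient_id`,
#'   `L`, `time`, `event`, the baseline covariates, `calendar_year` at `L`,
#'   the 13 LOCF covariate values and their staleness `lag_*` columns
#'   (years since the measurement carried forward).  The exclusion counts
#'   are in attribute `"exclusion_log"`.
#' @export
build_landmark_dataset <- function(registry, L, w = 10, study_window = NULL) {
  if (w <= 0) abort("`w` must be positive.")
  study_window <- study_window %||% registry$config$study_window
  if (is.null(study_window)) {
    abort("`study_window` must be given when the registry has no config.")
  }
  pat <- registry$patients
  start <- study_window[1]; end <- study_window[2]
  age_at_end <- end - pat$birth

  reason <- rep(NA_character_, nrow(pat))
  in_window <- (pat$birth + L) >= start & (pat$birth + L) <= end
  reason[!in_window] <- "outside_window"
  entered <- pat$registry_entry_age <= L & pat$diagnosis_age <= L
  reason[is.na(reason) & !entered] <- "not_entered"
  dead <- !is.na(pat$death_age) & pat$death_age <= L
  reason[is.na(reason) & dead] <- "dead_before_landmark"
  txp <- !is.na(pat$transplant_age) & pat$transplant_age <= L
  reason[is.na(reason) & txp] <- "transplanted_before_landmark"
  lost <- !is.na(pat$loss_age) & pat$loss_age <= L
  reason[is.na(reason) & lost] <- "lost_before_landmark"
  no_fup <- age_at_end <= L
  reason[is.na(reason) & no_fup] <- "no_followup"

  cand <- pat[is.na(reason), , drop = FALSE]
  tdv <- time_dependent_vars()

  locf <- locf_summarise(registry$reviews, cand$id, L, tdv)
  miss <- setdiff(cand$id, locf$patient_id)
  reason[match(miss, pat$id)] <- "missing_history"
  cand <- cand[cand$id %in% locf$patient_id, , drop = FALSE]

  log_counts <- table(factor(reason, levels = c(
    "outside_window", "not_entered", "dead_before_landmark",
    "transplanted_before_landmark", "lost_before_landmark",
    "no_followup", "missing_history")))

  if (nrow(cand) == 0L) {
    out <- tibble(patient_id = character(), L = numeric(), time = numeric(),
                  event = integer())
    attr(out, "exclusion_log") <- as.integer(log_counts) |>
      setNames(names(log_counts))
    attr(out, "L") <- L
    attr(out, "w") <- w
    return(out)
  }

  cens_age <- pmin(ifelse(is.na(cand$loss_age), Inf, cand$loss_age),
                   end - cand$birth, L + w)
  dth <- ifelse(is.na(cand$death_age), Inf, cand$death_age)
  time <- pmin(dth, cens_age) - L
  event <- as.integer(dth <= cens_age)

  out <- tibble(patient_id = cand$id, L = L, time = time, event = event,
                sex = cand$sex, genotype_class = cand$genotype_class,
                diagnosis_age = cand$diagnosis_age,
                calendar_year = cand$birth + L) |>
    left_join(locf, by = "patient_id")
  attr(out, "exclusion_log") <- as.integer(log_counts) |>
    setNames(names(log_counts))
  attr(out, "L") <- L
  attr(out, "w") <- w
  out
}

# Vectorised LOCF over all candidate patients: for each time-dependent
# variable, the value at the latest review at or before L with a non-missing
# measurement.  Patients missing any required variable are dropped.
locf_summarise <- function(reviews, ids, L, vars) {
  pre <- reviews$patient_id %in% ids & reviews$age <= L
  if (!any(pre)) return(tibble(patient_id = character()))
  rv <- reviews[pre, , drop = FALSE]
  o <- order(rv$patient_id, rv$age)
  rv <- rv[o, , drop = FALSE]
  out_ids <- unique(rv$patient_id)
  vals <- vector("list", length(vars))
  lags <- vector("list", length(vars))
  keep <- rep(TRUE, length(out_ids))
  for (j in seq_along(vars)) {
    v <- vars[j]
    ok <- !is.na(rv[[v]])
    pid <- rv$patient_id[ok]
    last <- !duplicated(pid, fromLast = TRUE)   # last (latest) row per patient
    m <- match(out_ids, pid[last])
    vals[[j]] <- rv[[v]][ok][last][m]
    lags[[j]] <- L - rv$age[ok][last][m]
    keep <- keep & !is.na(m)
  }
  out <- tibble(patient_id = out_ids)
  for (j in seq_along(vars)) out[[vars[j]]] <- vals[[j]]
  for (j in seq_along(vars)) out[[paste0("lag_", vars[j])]] <- lags[[j]]
  out[keep, , drop = FALSE]
}

#' LOCF covariate summary for a single patient
#'
#' Last-observation-carried-forward values of the time-dependent variables
#' at a landmark age, with the staleness (lag) of each carried-forward
#' measurement.  Signals a `"landmarker_missing_history"` condition when
#' some required variable has no measurement at or before `L`.
#'
#' @param reviews Tibble of the patient's annual reviews.
#' @param L Landmark age.
#' @param vars Required variables (default: the 13 time-dependent ones).
#' @return A list with named vectors `values` and `lags`.
#' @export
locf_covariates <- function(reviews, L, vars = time_dependent_vars()) {
  pre <- reviews |> filter(.data$age <= L) |> arrange(.data$age)
  values <- setNames(rep(NA_real_, length(vars)), vars)
  lags <- values
  for (v in vars) {
    ok <- which(!is.na(pre[[v]]))
    if (length(ok)) {
      i <- ok[length(ok)]
      values[v] <- pre[[v]][i]
      lags[v] <- L - pre$age[i]
    }
  }
  miss <- vars[is.na(values)]
  if (length(miss)) stop(missing_history(miss))
  list(values = values, lags = lags)
}

#' Stack landmark datasets into one supermodel dataset
#'
#' @param datasets List of landmark datasets (from
#'   [build_landmark_dataset()]) with distinct landmark ages.
#' @return A tibble of all records with the ordered landmark grid in
#'   attribute `"landmark_grid"` and the horizon in `"w"`.
#' @export
stack_landmarks <- function(datasets) {
  Ls <- map_dbl(datasets, ~ attr(.x, "L") %||% unique(.x$L))
  if (anyDuplicated(Ls)) abort("landmark datasets must have distinct L values.")
  ws <- unique(unlist(map(datasets, ~ attr(.x, "w"))))
  out <- bind_rows(datasets[order(Ls)])
  attr(out, "landmark_grid") <- sort(Ls)
  if (length(ws) == 1L) attr(out, "w") <- ws
  out
}

#' Build and stack landmark datasets over a grid of landmark ages
#'
#' Convenience wrapper running [build_landmark_dataset()] over a landmark
#' grid (default: integer ages 18-50, giving 33 datasets) and stacking the
#' results with [stack_landmarks()].
#'
#' @inheritParams build_landmark_dataset
#' @param grid Landmark ages (default `18:50`).
#' @return A stacked tibble; per-landmark exclusion logs are kept in
#'   attribute `"exclusion_logs"` (a named list).
#' @export
build_stacked <- function(registry, grid = 18:50, w = 10, study_window = NULL) {
  datasets <- lapply(grid, function(L) {
    build_landmark_dataset(registry, L, w = w, study_window = study_window)
  })
  out <- stack_landmarks(datasets)
  attr(out, "exclusion_logs") <-
    setNames(lapply(datasets, attr, "exclusion_log"), grid)
  out
}

#' Write / read a stacked landmark dataset as delimited text
#'
#' @param stacked Stacked tibble from [build_stacked()] or
#'   [stack_landmarks()].
#' @param path File path (comma-separated, header row, missing = empty).
#' @return `write_stacked()` returns `path` invisibly; `read_stacked()`
#'   returns the tibble with the landmark grid attribute restored from the
#'   `L` column.
#' @export
write_stacked <- function(stacked, path) {
  write_csv_precise(stacked, path)
  invisible(path)
}

#' @rdname write_stacked
#' @export
read_stacked <- function(path) {
  out <- as_tibble(read.csv(path, na.strings = "",
                            colClasses = c(patient_id = "character")))
  attr(out, "landmark_grid") <- sort(unique(out$L))
  out
}
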