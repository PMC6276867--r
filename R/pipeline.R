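#' Run the full landmarking workflow
#'
#' Orchestrates simulate (or load) -> landmark/stack -> fit -> evaluate ->
#' predict as one reproducible, logged run writing all artifacts to a
#' directory: the registry as delimited files (when simulated), the
#' stacked dataset, one serialised fit per requested variant, the
#' performance report, calibration tables for the first variant, the
#' predicted-survival distribution summary per landmark age, and a
#' manifest with the master seed, derived stage seeds, package version and
#' a checksum per artifact (so two runs with the same config and seed can
#' be compared file by file).
#'
#' A single master seed drives the run; per-stage child seeds are derived
#' deterministically from it and recorded in the manifest.
#'
#' @param out_dir Output directory (created; must be empty or absent).
#' @param generator A [registry_config()] (its seed is overridden by the
#'   derived stage seed), or `NULL` when `registry_dir` is given.
#' @param registry_dir Directory with existing `patients.csv` /
#'   `reviews.csv` (exactly one of `generator` / `registry_dir`).
#' @param grid Landmark-age grid.
#' @param w Prediction horizon (years).
#' @param variants Variant numbers to fit (subset of 1:6; variant 6 adds
#'   the two-stage mixed-model features automatically).
#' @param horizons Evaluation horizons.
#' @param predictors Predictor columns used by every variant.
#' @param split_fraction Training fraction of the stacked data (stratified
#'   by landmark age); the holdout is used for the performance report.
#' @param cv_reps Monte-Carlo cross-validation repetitions on the training
#'   part (0 = skip).
#' @param seed Master seed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory artifacts (`registry`,
#'   `stacked`, `split`, `fits`, `reports`, `cv`, `manifest`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(out_dir,
                         generator = NULL, registry_dir = NULL,
                         grid = 18:50, w = 10,
                         variants = c(1, 2),
                         predictors = default_predictors(),
                         horizons = c(2, 5, 10),
                         split_fraction = 0.8,
                         cv_reps = 0,
                         seed,
                         quiet = FALSE) {
  if (is.null(generator) == is.null(registry_dir)) {
    abort("give exactly one data source: `generator` or `registry_dir`.")
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_seeds <- derive_seeds(seed, 3L)
  names(stage_seeds) <- c("simulate", "split", "cv")

  ## stage 1: data
  if (!is.null(generator)) {
    generator$seed <- stage_seeds[["simulate"]]
    say("simulate: %d individuals", generator$n_individuals)
    registry <- simulate_registry(generator)
    write_registry(registry, file.path(out_dir, "registry"))
  } else {
    say("load registry: %s", registry_dir)
    registry <- read_registry(registry_dir)
  }

  ## stage 2: landmark datasets
  say("landmark: grid %s..%s, horizon %s", min(grid), max(grid), w)
  stacked <- if (6 %in% variants) {
    build_stacked_two_stage(registry, grid = grid, w = w)
  } else {
    build_stacked(registry, grid = grid, w = w)
  }
  write_stacked(stacked, file.path(out_dir, "stacked.csv"))

  ## stage 3: split
  sp <- split_stacked(stacked, fraction = split_fraction,
                      seed = stage_seeds[["split"]])
  say("split: %d training / %d holdout records",
      nrow(sp$training), nrow(sp$holdout))

  ## stage 4: fits + evaluation
  fits <- list(); reports <- list()
  dir.create(file.path(out_dir, "fits"), showWarnings = FALSE)
  for (v in variants) {
    say("fit variant %d", v)
    opts <- variant_options(v, w = w, predictors = predictors)
    fit <- fit_variant(sp$training, opts)
    fits[[as.character(v)]] <- fit
    if (inherits(fit, "landmark_coxfit")) {
      write_cox_fit(fit, file.path(out_dir, "fits",
                                   sprintf("variant_%d.json", v)))
    } else {
      for (l in names(fit)) {
        write_cox_fit(fit[[l]],
                      file.path(out_dir, "fits",
                                sprintf("variant_%d_L%s.json", v, l)))
      }
    }
    if (nrow(sp$holdout)) {
      reports[[as.character(v)]] <- evaluate_fit(fit, sp$holdout,
                                                 horizons = horizons)
    }
  }
  if (length(reports)) {
    perf <- bind_rows(lapply(names(reports), function(v) {
      reports[[v]]$overall |> mutate(variant = as.integer(v), .before = 1)
    }))
    write.csv(perf, file.path(out_dir, "performance_overall.csv"),
              row.names = FALSE, na = "")
    perf_l <- bind_rows(lapply(names(reports), function(v) {
      reports[[v]]$per_landmark |> mutate(variant = as.integer(v), .before = 1)
    }))
    write.csv(perf_l, file.path(out_dir, "performance_per_landmark.csv"),
              row.names = FALSE, na = "")
  }

  ## stage 5: cross-validation (optional)
  cv <- NULL
  if (cv_reps > 0) {
    say("cv: %d repetitions on the training part", cv_reps)
    cv <- monte_carlo_cv(sp$training,
                         variant_options(max(variants), w = w,
                                         predictors = predictors),
                         n_reps = cv_reps, seed = stage_seeds[["cv"]],
                         horizons = horizons)
    write.csv(cv$summary, file.path(out_dir, "cv_summary.csv"),
              row.names = FALSE, na = "")
  }

  ## stage 6: calibration + predicted-probability distributions
  first_fit <- fits[[1]]
  if (nrow(sp$holdout)) {
    cal <- bind_rows(lapply(horizons, function(h) {
      calibration_table(first_fit, sp$holdout, h) |>
        mutate(horizon = h, .before = 1)
    }))
    write.csv(cal, file.path(out_dir, "calibration.csv"),
              row.names = FALSE, na = "")
    rd <- risk_distribution(first_fit, sp$holdout, horizons = horizons)
    write.csv(rd, file.path(out_dir, "risk_distribution.csv"),
              row.names = FALSE, na = "")
  }

  ## manifest
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("landmarker")),
    master_seed = seed,
    stage_seeds = as.list(stage_seeds),
    grid = grid, w = w, variants = variants, horizons = horizons,
    split_fraction = split_fraction, cv_reps = cv_reps,
    checksums = as.list(setNames(unname(tools::md5sum(files)),
                                 sub(paste0("^", out_dir, "/?"), "",
                                     files, fixed = FALSE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %s", out_dir)
  invisible(list(registry = registry, stacked = stacked, split = sp,
                 fits = fits, reports = reports, cv = cv,
                 manifest = manifest, out_dir = out_dir))
}
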