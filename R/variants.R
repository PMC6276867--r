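#' Options for the six dynamic-prediction model variants
#'
#' The variants span the model structures commonly compared in a
#' landmarking analysis:
#' 1. separate Cox models fitted from each landmark age;
#' 2. a supermodel on the stacked data: separate baseline hazard per
#'    landmark age (stratification), common coefficients;
#' 3. variant 2 plus coefficients varying smoothly with landmark age
#'    (interactions with a polynomial basis in the scaled landmark age
#'    `u = (L - lo)/(hi - lo)`);
#' 4. variant 2 plus coefficients varying with time since landmark
#'    (interactions with a deterministic time basis evaluated at event
#'    times inside the partial likelihood);
#' 5. a common baseline hazard with landmark age entering the log hazard
#'    as regression terms `u, u^2`;
#' 6. variant 2 plus mixed-model fitted values and slopes at the landmark
#'    age for FEV1%, FVC% and weight (two-stage landmarking; see
#'    [fit_multivariate_mixed()]), by default alongside the LOCF values.
#'
#' @param variant Integer 1-6.
#' @param w Prediction horizon in years (default 10).
#' @param landmark_degree Polynomial degree of the landmark-age basis for
#'   variants 3 and 5 (default 2; degree 0 in variant 3 degenerates to
#'   variant 2).
#' @param time_basis `"linear"` (`f(t) = t/w`, default) or `"ns"` (natural
#'   cubic spline basis on `[0, w]`) for variant 4.
#' @param fev1_only_time_varying Restrict variant 4's time-varying
#'   coefficients to FEV1%, the strongest predictor.
#' @param include_locf_with_mixed Keep the LOCF values of FEV1%, FVC% and
#'   weight alongside the mixed-model terms in variant 6.
#' @param grid_range Landmark-age range `c(lo, hi)` used to scale `u`.
#' @param predictors Predictor columns (default: the three baseline
#'   variables, calendar year, and the 13 LOCF time-dependent variables).
#' @return An object of class `"variant_options"`.
#' @export
variant_options <- function(variant, w = 10, landmark_degree = 2,
                            time_basis = c("linear", "ns"),
                            fev1_only_time_varying = FALSE,
                            include_locf_with_mixed = TRUE,
                            grid_range = c(18, 50),
                            predictors = default_predictors()) {
  if (!variant %in% 1:6) abort("`variant` must be an integer in 1..6.")
  if (landmark_degree < 0) abort("`landmark_degree` must be >= 0.")
  structure(list(variant = as.integer(variant), w = w,
                 landmark_degree = landmark_degree,
                 time_basis = match.arg(time_basis),
                 fev1_only_time_varying = fev1_only_time_varying,
                 include_locf_with_mixed = include_locf_with_mixed,
                 grid_range = grid_range, predictors = predictors),
            class = "variant_options")
}

#' Default predictor set
#'
#' Three baseline variables (sex, F508del genotype class, age of
#' diagnosis), calendar year at the landmark age, and the 13 LOCF
#' time-dependent variables: 17 candidate predictor columns.
#'
#' @return Character vector of column names.
#' @export
default_predictors <- function() {
  c(baseline_vars(), "calendar_year", time_dependent_vars())
}

mixed_feature_cols <- function() {
  as.vector(t(outer(c("fev1_pct", "fvc_pct", "weight"),
                    c("_fit", "_slope"), paste0)))
}

# Rebuild a cox_term from its serialisable descriptor.
term_from_meta <- function(meta) {
  meta <- lapply(meta, function(x) if (is.list(x)) unlist(x) else x)
  switch(meta$type,
    plain = cox_term(meta$col),
    landmark_interaction = {
      col <- meta$col; d <- as.numeric(meta$degree)
      lo <- as.numeric(meta$lo); hi <- as.numeric(meta$hi)
      cox_term(col, label = sprintf("%s:u%d", col, as.integer(d)),
               transform = function(data) {
                 data[[col]] * ((data$L - lo) / (hi - lo))^d
               },
               meta = list(type = "landmark_interaction", col = col,
                           degree = d, lo = lo, hi = hi))
    },
    landmark_main = {
      d <- as.numeric(meta$degree)
      lo <- as.numeric(meta$lo); hi <- as.numeric(meta$hi)
      cox_term(sprintf("u%d", as.integer(d)),
               label = sprintf("u%d", as.integer(d)),
               transform = function(data) ((data$L - lo) / (hi - lo))^d,
               meta = list(type = "landmark_main", degree = d,
                           lo = lo, hi = hi))
    },
    time_interaction = {
      col <- meta$col; w <- as.numeric(meta$w)
      cox_term(col, label = sprintf("%s:t", col),
               tv_basis = function(t) t / w,
               meta = list(type = "time_interaction", col = col, w = w))
    },
    time_ns = {
      col <- meta$col; w <- as.numeric(meta$w)
      j <- as.integer(meta$index)
      knots <- as.numeric(meta$knots)
      cox_term(col, label = sprintf("%s:ns%d", col, j),
               tv_basis = function(t) {
                 splines::ns(t, knots = knots,
                             Boundary.knots = c(0, w))[, j]
               },
               meta = list(type = "time_ns", col = col, w = w, index = j,
                           knots = knots))
    },
    abort(sprintf("unknown term descriptor type `%s`", meta$type))
  )
}

#' Build the Cox model specification for a variant
#'
#' @param options A [variant_options()].
#' @return A [cox_spec()].  Variant 1 returns the unstratified
#'   per-landmark spec (the same spec is fitted separately to each
#'   landmark dataset by [fit_variant()]); variants 2-6 return the single
#'   supermodel spec fitted to the stacked data.
#' @export
build_variant <- function(options) {
  stopifnot(inherits(options, "variant_options"))
  v <- options$variant
  preds <- options$predictors
  lo <- options$grid_range[1]; hi <- options$grid_range[2]
  base_terms <- lapply(preds, cox_term)

  if (v == 1L) {
    return(cox_spec(base_terms, strata = NULL, cluster = "patient_id"))
  }
  if (v == 2L) {
    return(cox_spec(base_terms, strata = "L", cluster = "patient_id"))
  }
  if (v == 3L) {
    extra <- list()
    for (d in seq_len(options$landmark_degree)) {
      extra <- c(extra, lapply(preds, function(p) {
        term_from_meta(list(type = "landmark_interaction", col = p,
                            degree = d, lo = lo, hi = hi))
      }))
    }
    return(cox_spec(c(base_terms, extra), strata = "L", cluster = "patient_id"))
  }
  if (v == 4L) {
    tv_cols <- if (options$fev1_only_time_varying) "fev1_pct" else preds
    extra <- if (options$time_basis == "linear") {
      lapply(tv_cols, function(p) {
        term_from_meta(list(type = "time_interaction", col = p, w = options$w))
      })
    } else {
      knots <- options$w * c(1 / 3, 2 / 3)
      unlist(lapply(tv_cols, function(p) {
        lapply(1:3, function(j) {
          term_from_meta(list(type = "time_ns", col = p, w = options$w,
                              index = j, knots = knots))
        })
      }), recursive = FALSE)
    }
    return(cox_spec(c(base_terms, extra), strata = "L", cluster = "patient_id"))
  }
  if (v == 5L) {
    extra <- lapply(seq_len(max(1, options$landmark_degree)), function(d) {
      term_from_meta(list(type = "landmark_main", degree = d, lo = lo, hi = hi))
    })
    return(cox_spec(c(base_terms, extra), strata = NULL,
                    cluster = "patient_id"))
  }
  ## variant 6: mixed-model fitted values and slopes as extra predictors
  preds6 <- preds
  if (!options$include_locf_with_mixed) {
    preds6 <- setdiff(preds6, c("fev1_pct", "fvc_pct", "weight"))
  }
  terms6 <- lapply(c(preds6, mixed_feature_cols()), cox_term)
  cox_spec(terms6, strata = "L", cluster = "patient_id")
}

#' Fit a dynamic-prediction model variant
#'
#' Fits the requested variant to a stacked landmark dataset: variant 1 as
#' separate per-landmark Cox fits, variants 2-6 as a single supermodel via
#' [fit_cox()].  Variant 6 requires the mixed-model feature columns (see
#' [attach_mixed_features()]).
#'
#' @param data Stacked landmark dataset (or a single landmark dataset).
#' @param options A [variant_options()].
#' @param ... Passed to [fit_cox()].
#' @return For variant 1 a named list of `"landmark_coxfit"` objects
#'   (class `"landmark_coxfit_list"`), otherwise one `"landmark_coxfit"`.
#'   The variant number is attached as attribute `"variant"`.
#' @export
fit_variant <- function(data, options, ...) {
  stopifnot(inherits(options, "variant_options"))
  if (options$variant == 6L &&
      !all(mixed_feature_cols() %in% names(data))) {
    abort(paste("variant 6 requires mixed-model feature columns;",
                "run fit_multivariate_mixed() and attach_mixed_features()."))
  }
  spec <- build_variant(options)
  if (options$variant == 1L) {
    Ls <- sort(unique(data$L))
    fits <- lapply(Ls, function(l) {
      fit <- fit_cox(data[data$L == l, , drop = FALSE], spec, ...)
      attr(fit, "variant") <- 1L
      fit
    })
    names(fits) <- as.character(Ls)
    return(structure(fits, class = "landmark_coxfit_list", variant = 1L))
  }
  fit <- fit_cox(data, spec, ...)
  attr(fit, "variant") <- options$variant
  fit
}

#' @export
print.landmark_coxfit_list <- function(x, ...) {
  cat(sprintf("<landmark_coxfit_list> %d per-landmark fits (L = %s..%s)\n",
              length(x), names(x)[1], names(x)[length(x)]))
  invisible(x)
}

#' Predicted survival at a horizon from a variant fit
#'
#' Dispatch helper covering both supermodel fits and the per-landmark fit
#' list of variant 1.
#'
#' @param fits A `"landmark_coxfit"` or `"landmark_coxfit_list"`.
#' @param data Records to predict for (must carry `L`).
#' @param horizon Years since landmark.
#' @return Numeric vector of survival probabilities.
#' @export
predict_variant_at <- function(fits, data, horizon) {
  if (inherits(fits, "landmark_coxfit_list")) {
    out <- rep(NA_real_, nrow(data))
    for (l in unique(data$L)) {
      fit <- fits[[as.character(l)]]
      if (is.null(fit)) {
        abort(sprintf("no per-landmark fit for L = %s.", l))
      }
      rows <- which(data$L == l)
      out[rows] <- predict_survival_at(fit, data[rows, , drop = FALSE], horizon)
    }
    return(out)
  }
  predict_survival_at(fits, data, horizon)
}
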