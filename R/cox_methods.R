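#' @export
print.landmark_coxfit <- function(x, ...) {
  cat(sprintf("<landmark_coxfit> %d records, %d events, %d clusters, %d strat%s\n",
              x$n, x$n_events, x$n_clusters, x$n_strata,
              if (x$n_strata == 1) "um" else "a"))
  if (length(x$coefficients)) {
    print(tidy(x), n = length(x$coefficients))
  } else {
    cat("  (null model: baseline hazards only)\n")
  }
  invisible(x)
}

#' @export
coef.landmark_coxfit <- function(object, ...) object$coefficients

#' Covariance of a fitted landmark Cox model
#'
#' @param object A `"landmark_coxfit"`.
#' @param type `"robust"` (clustered sandwich; default) or `"naive"`
#'   (inverse information).
#' @param ... Unused.
#' @return Covariance matrix of the coefficients.
#' @export
vcov.landmark_coxfit <- function(object, type = c("robust", "naive"), ...) {
  type <- match.arg(type)
  if (type == "robust") object$robust_cov else object$naive_cov
}

#' Tidy a fitted landmark Cox model
#'
#' @param x A `"landmark_coxfit"`.
#' @param conf.int Add Wald confidence limits?
#' @param conf.level Confidence level.
#' @param robust Use the clustered sandwich standard errors (default) or
#'   the naive ones.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (log hazard ratio),
#'   `std.error`, `statistic`, `p.value` (and confidence limits).
#' @export
tidy.landmark_coxfit <- function(x, conf.int = FALSE, conf.level = 0.95,
                                 robust = TRUE, ...) {
  se <- sqrt(diag(if (robust) x$robust_cov else x$naive_cov))
  out <- tibble(term = names(x$coefficients),
                estimate = unname(x$coefficients),
                std.error = unname(se),
                statistic = unname(x$coefficients / se),
                p.value = 2 * pnorm(-abs(unname(x$coefficients / se))))
  if (conf.int) {
    z <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' @export
glance.landmark_coxfit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, n_clusters = x$n_clusters,
         n_strata = x$n_strata, loglik = unname(x$loglik["model"]),
         loglik_null = unname(x$loglik["null"]),
         iter = x$iter, converged = x$converged, ties = x$spec$ties)
}

# Linear predictor pieces for new data: centered fixed part and the
# centered base columns of any time-varying terms.
lp_pieces <- function(fit, data) {
  des <- build_design(data, fit$spec)
  Xc <- sweep(des$X, 2L, fit$center)
  is_tv <- !map_lgl(des$tv, is.null)
  beta <- fit$coefficients
  lp_fixed <- if (any(!is_tv)) {
    drop(Xc[, !is_tv, drop = FALSE] %*% beta[!is_tv])
  } else {
    rep(0, nrow(Xc))
  }
  list(lp_fixed = lp_fixed, Ztv = Xc[, is_tv, drop = FALSE],
       beta_tv = beta[is_tv], tv_fun = des$tv[is_tv], is_tv = is_tv)
}

stratum_key_for <- function(fit, L, data) {
  sv <- fit$spec$strata
  if (is.null(sv)) return(rep("all", nrow(data)))
  if (!is.null(L)) return(rep(as.character(L), nrow(data)))
  as.character(data[[sv]])
}

check_stratum <- function(fit, key) {
  have <- fit$strata_levels %||% unique(fit$baseline$stratum)
  bad <- setdiff(unique(key), have)
  if (length(bad)) {
    num <- suppressWarnings(as.numeric(have))
    sug <- if (!anyNA(num)) {
      paste0(" Nearest fitted stratum: ",
             have[which.min(abs(num - suppressWarnings(as.numeric(bad[1]))))], ".")
    } else ""
    abort(sprintf("stratum `%s` was not fitted (no extrapolation).%s",
                  bad[1], sug))
  }
}

#' Predicted survival curve from a fitted landmark model
#'
#' Computes `S(t | landmark age, covariates)` on the step grid of the
#' fitted baseline hazard: `S(t) = exp(-H0(t) exp(lp))` for the stratified
#' supermodel, and for fits with time-varying coefficient terms the sum
#' over baseline jumps with the time basis evaluated at each jump.
#'
#' @param fit A `"landmark_coxfit"`.
#' @param newdata A one-row data frame (or named list) of covariate values.
#' @param L Landmark age selecting the baseline-hazard stratum (required
#'   when the fit is stratified and `newdata` lacks the strata column); for
#'   landmark-interaction terms it is also injected as the `L` column.
#' @param times Evaluation grid (default: 0 and the baseline jump times).
#' @return A tibble of class `"survival_curve"` with `time` and `survival`.
#' @export
predict_survival <- function(fit, newdata, L = NULL, times = NULL) {
  newdata <- as_tibble(as.list(newdata))
  if (nrow(newdata) != 1L) abort("`newdata` must describe one profile.")
  if (!is.null(L)) newdata$L <- L
  key <- stratum_key_for(fit, L, newdata)
  check_stratum(fit, key)
  bl <- fit$baseline[fit$baseline$stratum == key, , drop = FALSE]
  pieces <- lp_pieces(fit, newdata)
  times <- times %||% sort(unique(c(0, bl$time)))
  if (ncol(pieces$Ztv) == 0L) {
    H <- step_eval(bl$time, cumsum(bl$haz), times)
    surv <- exp(-H * exp(pieces$lp_fixed))
  } else {
    tvw <- tv_jump_weights(pieces, bl$time)  # 1 x K
    inc <- drop(tvw) * bl$haz
    Hc <- cumsum(inc)
    surv <- exp(-exp(pieces$lp_fixed) * step_eval(bl$time, Hc, times))
  }
  structure(tibble(time = times, survival = surv),
            class = c("survival_curve", "tbl_df", "tbl", "data.frame"),
            L = if (!is.null(L)) L else key[1])
}

# exp of the time-varying part at each baseline jump, rows = profiles
tv_jump_weights <- function(pieces, taus) {
  J <- length(pieces$beta_tv)
  B <- vapply(seq_len(J),
              function(j) pieces$beta_tv[j] * pieces$tv_fun[[j]](taus),
              numeric(length(taus)))
  if (is.null(dim(B))) B <- matrix(B, nrow = length(taus))
  exp(pieces$Ztv %*% t(B))
}

#' Predicted survival probability at one horizon for many records
#'
#' Vectorised version of [predict_survival()] evaluating `S(horizon)` for
#' every row of a landmark or stacked dataset (each row's stratum taken
#' from its own strata column).
#'
#' @param fit A `"landmark_coxfit"`.
#' @param data Landmark/stacked records carrying the model's covariate
#'   columns (and the strata column for stratified fits).
#' @param horizon Years since landmark.
#' @return Numeric vector of survival probabilities, one per row.
#' @export
predict_survival_at <- function(fit, data, horizon) {
  key <- stratum_key_for(fit, NULL, data)
  check_stratum(fit, key)
  pieces <- lp_pieces(fit, data)
  out <- numeric(nrow(data))
  for (s in unique(key)) {
    rows <- which(key == s)
    bl <- fit$baseline[fit$baseline$stratum == s, , drop = FALSE]
    keep <- bl$time <= horizon
    if (ncol(pieces$Ztv) == 0L) {
      H <- sum(bl$haz[keep])
      out[rows] <- exp(-H * exp(pieces$lp_fixed[rows]))
    } else {
      taus <- bl$time[keep]
      sub <- pieces
      sub$Ztv <- pieces$Ztv[rows, , drop = FALSE]
      E <- tv_jump_weights(sub, taus)        # n_s x K
      integral <- drop(E %*% bl$haz[keep])
      out[rows] <- exp(-exp(pieces$lp_fixed[rows]) * integral)
    }
  }
  out
}

#' Baseline cumulative hazard of a fitted stratum
#'
#' @param fit A `"landmark_coxfit"`.
#' @param stratum Stratum label (default: the single stratum of an
#'   unstratified fit).
#' @return Tibble with `time`, `haz` (jump), `cumhaz` and `var_cumhaz`
#'   (the Breslow variance of the cumulative hazard), a right-continuous
#'   step function with `H(0) = 0`, referring to the centered covariate
#'   reference stored in `fit$center`.
#' @export
baseline_cumhaz <- function(fit, stratum = NULL) {
  stratum <- as.character(stratum %||% unique(fit$baseline$stratum)[1])
  check_stratum(fit, stratum)
  fit$baseline[fit$baseline$stratum == stratum,
               c("time", "haz", "cumhaz", "var_cumhaz"), drop = FALSE]
}

#' Simulate outcomes from a fitted landmark model
#'
#' Draws a death time for every record from its own predicted survival
#' curve (inverse-transform sampling on the fitted step function), with
#' administrative censoring at the horizon `w`: a parametric-bootstrap
#' outcome generator used, e.g., to verify calibration machinery on data
#' that are correctly calibrated by construction.
#'
#' @param fit A `"landmark_coxfit"`.
#' @param data Records carrying the model covariates (and strata column).
#' @param w Administrative censoring horizon (years since landmark).
#' @param seed Integer seed (caller's RNG state preserved).
#' @return A tibble: `data` with `time` and `event` replaced by the
#'   simulated outcome.
#' @export
simulate_outcomes <- function(fit, data, w = 10, seed) {
  key <- stratum_key_for(fit, NULL, data)
  check_stratum(fit, key)
  pieces <- lp_pieces(fit, data)
  if (ncol(pieces$Ztv) > 0L) {
    abort("outcome simulation supports time-fixed coefficient fits only.")
  }
  u <- local_seed(seed, runif(nrow(data)))
  time <- rep(w, nrow(data))
  event <- integer(nrow(data))
  for (s in unique(key)) {
    rows <- which(key == s)
    bl <- fit$baseline[fit$baseline$stratum == s, , drop = FALSE]
    keep <- bl$time <= w
    H <- cumsum(bl$haz[keep])
    taus <- bl$time[keep]
    ## death at the first jump where S(tau) <= u, i.e. H(tau) >= target
    target <- -log(u[rows]) / exp(pieces$lp_fixed[rows])
    idx <- findInterval(target, c(0, H), left.open = TRUE)
    hit <- idx <= length(taus)
    time[rows[hit]] <- taus[idx[hit]]
    event[rows[hit]] <- 1L
  }
  out <- data
  out$time <- time
  out$event <- event
  out
}

#' Serialise / restore a fitted landmark Cox model as JSON
#'
#' The document mirrors a published full model specification: term labels
#' and descriptors, centering vector, coefficients, naive and robust
#' covariances, ties method, counts, and the per-stratum baseline
#' cumulative hazard as (breakpoints, values) arrays.  Term descriptors
#' (`meta`) allow landmark-basis and time-basis interaction terms to be
#' rebuilt on read.
#'
#' @param fit A `"landmark_coxfit"`.
#' @param path File path for the JSON document.
#' @return `write_cox_fit()` returns `path` invisibly; `read_cox_fit()`
#'   returns a `"landmark_coxfit"`.
#' @export
write_cox_fit <- function(fit, path) {
  doc <- list(
    coefficients = as.list(fit$coefficients),
    center = as.list(fit$center),
    naive_cov = fit$naive_cov,
    robust_cov = fit$robust_cov,
    terms = lapply(fit$spec$terms, function(tm) tm$meta),
    strata = fit$spec$strata,
    strata_levels = fit$strata_levels,
    cluster = fit$spec$cluster,
    ties = fit$spec$ties,
    loglik = as.list(fit$loglik),
    n = fit$n, n_events = fit$n_events, n_clusters = fit$n_clusters,
    n_strata = fit$n_strata, converged = fit$converged, iter = fit$iter,
    variant = attr(fit, "variant"),
    baseline = lapply(split(fit$baseline, fit$baseline$stratum), function(b) {
      list(stratum = b$stratum[1], time = b$time, haz = b$haz,
           var_cumhaz = b$var_cumhaz)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_cox_fit
#' @export
read_cox_fit <- function(path) {
  doc <- jsonlite::read_json(path)
  sc <- function(x) if (is.null(x) || length(x) == 0L) NULL else x[[1]]
  term_objs <- lapply(doc$terms, term_from_meta)
  spec <- cox_spec(term_objs, strata = sc(doc$strata),
                   cluster = sc(doc$cluster), ties = sc(doc$ties))
  labels <- unlist(map(term_objs, "label"))
  p <- length(labels)
  beta <- setNames(unlist(doc$coefficients), labels)
  as_mat <- function(x) {
    if (p == 0L) return(matrix(0, 0, 0))
    m <- do.call(rbind, lapply(x, unlist))
    dimnames(m) <- list(labels, labels)
    m
  }
  nv <- as_mat(doc$naive_cov)
  rb <- as_mat(doc$robust_cov)
  bls <- doc$baseline
  baseline <- bind_rows(lapply(bls, function(b) {
    tm <- unlist(b$time); hz <- unlist(b$haz)
    vc <- unlist(b$var_cumhaz)
    k <- length(tm %||% numeric(0))
    tibble(stratum = as.character(b$stratum[[1]]),
           time = as.numeric(tm %||% numeric(0)),
           haz = as.numeric(hz %||% numeric(0)),
           cumhaz = cumsum(as.numeric(hz %||% numeric(0))),
           var_cumhaz = as.numeric(vc %||% rep(NA_real_, k)))
  }))
  fit <- structure(list(
    coefficients = beta, naive_cov = nv, robust_cov = rb,
    baseline = baseline,
    center = setNames(as.numeric(unlist(doc$center) %||% numeric(0)), labels),
    spec = spec,
    loglik = c(null = doc$loglik$null[[1]], model = doc$loglik$model[[1]]),
    n = doc$n[[1]], n_events = doc$n_events[[1]],
    n_clusters = doc$n_clusters[[1]], n_strata = doc$n_strata[[1]],
    strata_levels = as.character(unlist(doc$strata_levels)),
    converged = doc$converged[[1]], iter = doc$iter[[1]],
    trace = NULL), class = "landmark_coxfit")
  attr(fit, "variant") <- sc(doc$variant)
  fit
}
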