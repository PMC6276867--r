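#' Multivariate linear mixed model for pre-landmark trajectories
#'
#' Fits, by maximum likelihood, a joint linear mixed model to the
#' measurement histories of up to three continuous time-dependent variables
#' (by default FEV1%, FVC% and weight) up to a landmark age `L`:
#' for outcome k of patient i at age `a`,
#' `y_k(a) = alpha_k + beta_k (a - L) + a_ik + b_ik (a - L) + e`,
#' with the per-patient random intercepts and slopes of all outcomes
#' jointly Gaussian with an unstructured covariance (6 x 6 for three
#' outcomes) and independent residuals with outcome-specific variances.
#'
#' Outcomes are standardised (z-scored on the pre-landmark data) before
#' joint fitting, which conditions the covariance estimation, and
#' back-transformed afterwards.  Estimation is by an expectation-
#' conditional-maximisation algorithm on the stacked outcome-indicator
#' representation: a generalised-least-squares update of the fixed effects
#' given the variance components, then an EM update of the random-effect
#' covariance and residual variances; the profiled Gaussian log-likelihood
#' is non-decreasing across iterations and its trace is stored.  Near-
#' singular covariance iterates are handled by a small diagonal inflation
#' when inverting.
#'
#' Empirical best linear unbiased predictors (BLUPs) give each patient's
#' fitted value at the landmark age and slope per outcome, the features
#' used by the two-stage landmarking variant.
#'
#' @param reviews Annual-review tibble (`patient_id`, `age`, outcome
#'   columns); only rows with `age <= L` are used.
#' @param L Landmark age.
#' @param outcomes Continuous outcome columns to model jointly.
#' @param patient_ids Optional restriction to these patients (e.g. the
#'   patients eligible at `L`).
#' @param max_iter,tol Iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return An object of class `"landmark_mixedfit"`: `fixed_effects`
#'   (per-outcome population value at `L` and slope), `re_covariance`
#'   (unstructured random-effect covariance, original scale),
#'   `resid_sd`, `blups` (wide tibble of `<outcome>_fit` and
#'   `<outcome>_slope` per patient), the log-likelihood trace and
#'   convergence flag.
#' @export
fit_multivariate_mixed <- function(reviews, L,
                                   outcomes = c("fev1_pct", "fvc_pct", "weight"),
                                   patient_ids = NULL,
                                   max_iter = 200L, tol = 1e-7) {
  rv <- reviews |> filter(.data$age <= L)
  if (!is.null(patient_ids)) rv <- rv |> filter(.data$patient_id %in% patient_ids)
  m <- length(outcomes)
  if (m < 1L) abort("at least one outcome is required.")
  long <- bind_rows(lapply(seq_along(outcomes), function(k) {
    v <- outcomes[k]
    sub <- rv[!is.na(rv[[v]]), c("patient_id", "age")]
    sub$k <- k
    sub$y <- rv[[v]][!is.na(rv[[v]])]
    sub
  }))
  if (length(unique(long$age)) < 2L) {
    abort("fewer than 2 distinct observation ages: slope unidentifiable.")
  }
  long$t <- long$age - L
  ## standardise per outcome
  mu <- map_dbl(seq_len(m), ~ mean(long$y[long$k == .x]))
  sds <- map_dbl(seq_len(m), ~ stats::sd(long$y[long$k == .x]))
  sds[!is.finite(sds) | sds == 0] <- 1
  long$z <- (long$y - mu[long$k]) / sds[long$k]

  ids <- sort(unique(long$patient_id))
  n <- length(ids)
  long$pi <- match(long$patient_id, ids)

  ## per-patient, per-outcome sufficient statistics
  suff <- array(0, c(n, m, 6L),
                dimnames = list(NULL, outcomes,
                                c("n", "St", "Stt", "Sy", "Sty", "Syy")))
  gi <- interaction(long$pi, long$k, drop = FALSE)
  agg <- function(x) {
    r <- rowsum(x, group = long$pi + n * (long$k - 1L))
    full <- numeric(n * m)
    full[as.integer(rownames(r))] <- r
    matrix(full, n, m)
  }
  suff[, , "n"] <- agg(rep(1, nrow(long)))
  suff[, , "St"] <- agg(long$t)
  suff[, , "Stt"] <- agg(long$t^2)
  suff[, , "Sy"] <- agg(long$z)
  suff[, , "Sty"] <- agg(long$t * long$z)
  suff[, , "Syy"] <- agg(long$z^2)
  N_k <- colSums(suff[, , "n", drop = FALSE][, , 1, drop = TRUE] |>
                   matrix(n, m))

  q <- 2L * m
  beta <- numeric(q)
  ## start from per-outcome OLS
  for (k in seq_len(m)) {
    nk <- sum(suff[, k, "n"]); st <- sum(suff[, k, "St"])
    stt <- sum(suff[, k, "Stt"]); sy <- sum(suff[, k, "Sy"])
    sty <- sum(suff[, k, "Sty"])
    A <- matrix(c(nk, st, st, stt), 2, 2)
    if (abs(det(A)) > 1e-12) {
      b <- solve(A, c(sy, sty))
    } else b <- c(sy / max(nk, 1), 0)
    beta[c(2 * k - 1, 2 * k)] <- b
  }
  D <- diag(0.5, q)
  sig2 <- rep(0.5, m)

  ll_trace <- numeric(0)
  converged <- FALSE
  ll_old <- -Inf
  blk <- lapply(seq_len(m), function(k) c(2 * k - 1, 2 * k))

  for (iter in seq_len(max_iter)) {
    Dinv <- tryCatch(solve(D), error = function(e) solve(D + diag(1e-8, q)))

    ## pass 1: GLS update of the fixed effects given (D, sigma2)
    A <- matrix(0, q, q); bv <- numeric(q)
    C_list <- vector("list", n)
    Om_list <- vector("list", n)
    for (i in seq_len(n)) {
      C <- matrix(0, q, q); u <- numeric(q)
      for (k in seq_len(m)) {
        s <- suff[i, k, ]
        if (s[["n"]] == 0) next
        C[blk[[k]], blk[[k]]] <- matrix(c(s[["n"]], s[["St"]],
                                          s[["St"]], s[["Stt"]]), 2, 2) / sig2[k]
        u[blk[[k]]] <- c(s[["Sy"]], s[["Sty"]]) / sig2[k]
      }
      Om <- solve(C + Dinv)
      CO <- C %*% Om
      A <- A + C - CO %*% C
      bv <- bv + u - CO %*% u
      C_list[[i]] <- C; Om_list[[i]] <- Om
    }
    beta <- drop(solve(A, bv))

    ## pass 2: E-step at the new beta; M-step accumulators
    ll <- 0
    SumB <- matrix(0, q, q)
    num_sig <- numeric(m)
    for (i in seq_len(n)) {
      C <- C_list[[i]]; Om <- Om_list[[i]]
      v <- numeric(q); rss <- numeric(m); ni <- numeric(m)
      for (k in seq_len(m)) {
        s <- suff[i, k, ]
        if (s[["n"]] == 0) next
        b0 <- beta[2 * k - 1]; b1 <- beta[2 * k]
        Sr <- s[["Sy"]] - b0 * s[["n"]] - b1 * s[["St"]]
        Str <- s[["Sty"]] - b0 * s[["St"]] - b1 * s[["Stt"]]
        Srr <- s[["Syy"]] - 2 * b0 * s[["Sy"]] - 2 * b1 * s[["Sty"]] +
          b0^2 * s[["n"]] + 2 * b0 * b1 * s[["St"]] + b1^2 * s[["Stt"]]
        v[blk[[k]]] <- c(Sr, Str) / sig2[k]
        rss[k] <- Srr
        ni[k] <- s[["n"]]
      }
      bhat <- drop(Om %*% v)
      SumB <- SumB + tcrossprod(bhat) + Om
      ## log-likelihood: log det V and quadratic form via Woodbury
      ld <- sum(ni * log(2 * pi * sig2)) +
        determinant(diag(q) + C %*% D, logarithm = TRUE)$modulus
      quad <- sum(rss / sig2) - drop(crossprod(v, Om %*% v))
      ll <- ll - 0.5 * (ld + quad)
      ## residual-variance numerators
      for (k in seq_len(m)) {
        s <- suff[i, k, ]
        if (s[["n"]] == 0) next
        bb <- bhat[blk[[k]]]
        ZtZ <- matrix(c(s[["n"]], s[["St"]], s[["St"]], s[["Stt"]]), 2, 2)
        Sr <- v[blk[[k]]] * sig2[k]
        e2 <- rss[k] - 2 * sum(bb * Sr) + drop(crossprod(bb, ZtZ %*% bb))
        num_sig[k] <- num_sig[k] +
          e2 + sum(diag(Om[blk[[k]], blk[[k]]] %*% ZtZ))
      }
    }
    D <- SumB / n
    D <- (D + t(D)) / 2
    sig2 <- pmax(num_sig / N_k, 1e-10)

    ll <- as.numeric(ll)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  ## final BLUPs at the converged parameters
  Dinv <- tryCatch(solve(D), error = function(e) solve(D + diag(1e-8, q)))
  fitted_mat <- matrix(NA_real_, n, m)
  slope_mat <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    C <- matrix(0, q, q); v <- numeric(q)
    for (k in seq_len(m)) {
      s <- suff[i, k, ]
      if (s[["n"]] == 0) next
      b0 <- beta[2 * k - 1]; b1 <- beta[2 * k]
      C[blk[[k]], blk[[k]]] <- matrix(c(s[["n"]], s[["St"]],
                                        s[["St"]], s[["Stt"]]), 2, 2) / sig2[k]
      v[blk[[k]]] <- c(s[["Sy"]] - b0 * s[["n"]] - b1 * s[["St"]],
                       s[["Sty"]] - b0 * s[["St"]] - b1 * s[["Stt"]]) / sig2[k]
    }
    bhat <- drop(solve(C + Dinv) %*% v)
    for (k in seq_len(m)) {
      fitted_mat[i, k] <- mu[k] + sds[k] * (beta[2 * k - 1] + bhat[2 * k - 1])
      slope_mat[i, k] <- sds[k] * (beta[2 * k] + bhat[2 * k])
    }
  }

  blups <- tibble(patient_id = ids)
  for (k in seq_len(m)) {
    blups[[paste0(outcomes[k], "_fit")]] <- fitted_mat[, k]
    blups[[paste0(outcomes[k], "_slope")]] <- slope_mat[, k]
  }

  S <- diag(rep(sds, each = 2L))
  D_orig <- S %*% D %*% S
  re_names <- as.vector(t(outer(outcomes, c("_fit", "_slope"), paste0)))
  dimnames(D_orig) <- list(re_names, re_names)

  ## report the log-likelihood on the original data scale (the fit itself is
  ## on z-scores; the Jacobian of the scaling is sum_k N_k log sd_k)
  ll_adj <- sum(N_k * log(sds))
  ll_trace <- ll_trace - ll_adj

  structure(list(
    fixed_effects = tibble(
      outcome = outcomes,
      value_at_L = mu + sds * beta[seq(1, q, by = 2)],
      slope = sds * beta[seq(2, q, by = 2)]),
    re_covariance = D_orig,
    resid_sd = setNames(sds * sqrt(sig2), outcomes),
    blups = blups, L = L, outcomes = outcomes,
    n_patients = n, n_obs = nrow(long),
    loglik = if (length(ll_trace)) ll_trace[length(ll_trace)] else NA_real_,
    ll_trace = ll_trace, converged = converged,
    scaling = list(mean = setNames(mu, outcomes), sd = setNames(sds, outcomes))),
    class = "landmark_mixedfit")
}

#' @export
print.landmark_mixedfit <- function(x, ...) {
  cat(sprintf("<landmark_mixedfit> L = %s: %d patients, %d observations, %s\n",
              format(x$L), x$n_patients, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  print(x$fixed_effects)
  invisible(x)
}

#' @export
tidy.landmark_mixedfit <- function(x, ...) {
  x$fixed_effects |>
    tidyr::pivot_longer(c("value_at_L", "slope"),
                        names_to = "effect", values_to = "estimate")
}

#' @export
glance.landmark_mixedfit <- function(x, ...) {
  tibble(n_patients = x$n_patients, n_obs = x$n_obs, loglik = x$loglik,
         iter = length(x$ll_trace), converged = x$converged)
}

#' Attach mixed-model features to a landmark dataset
#'
#' Appends each patient's BLUP fitted value at the landmark age and slope
#' per outcome (columns `<outcome>_fit`, `<outcome>_slope`) to a landmark
#' dataset; records without BLUPs are dropped (their count is kept in
#' attribute `"n_dropped_no_blup"`).
#'
#' @param landmark_ds A landmark dataset from [build_landmark_dataset()].
#' @param fit A `"landmark_mixedfit"` with matching landmark age.
#' @return The landmark dataset with the feature columns appended.
#' @export
attach_mixed_features <- function(landmark_ds, fit) {
  L <- attr(landmark_ds, "L") %||% unique(landmark_ds$L)
  if (length(L) != 1L || !isTRUE(all.equal(L, fit$L))) {
    abort("landmark ages of the dataset and the mixed fit do not match.")
  }
  out <- landmark_ds |> dplyr::inner_join(fit$blups, by = "patient_id")
  attr(out, "n_dropped_no_blup") <- nrow(landmark_ds) - nrow(out)
  attr(out, "L") <- L
  attr(out, "w") <- attr(landmark_ds, "w")
  attr(out, "exclusion_log") <- attr(landmark_ds, "exclusion_log")
  out
}

#' Build a stacked dataset with two-stage mixed-model features
#'
#' For each landmark age in the grid, fits the multivariate mixed model to
#' the eligible patients' pre-landmark histories and attaches the BLUP
#' features, then stacks.  This is the data preparation for variant 6.
#'
#' @inheritParams build_stacked
#' @inheritParams fit_multivariate_mixed
#' @return A stacked tibble including the `_fit`/`_slope` columns; the
#'   per-landmark mixed fits are in attribute `"mixed_fits"`.
#' @export
build_stacked_two_stage <- function(registry, grid = 18:50, w = 10,
                                    outcomes = c("fev1_pct", "fvc_pct", "weight"),
                                    study_window = NULL, ...) {
  fits <- list()
  datasets <- lapply(grid, function(L) {
    ds <- build_landmark_dataset(registry, L, w = w, study_window = study_window)
    if (nrow(ds) == 0L) return(ds)
    mf <- fit_multivariate_mixed(registry$reviews, L, outcomes = outcomes,
                                 patient_ids = ds$patient_id, ...)
    fits[[as.character(L)]] <<- mf
    attach_mixed_features(ds, mf)
  })
  out <- stack_landmarks(datasets)
  attr(out, "mixed_fits") <- fits
  out
}
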