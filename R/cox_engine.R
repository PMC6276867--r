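#' Model terms and specifications for the landmark Cox engine
#'
#' `cox_term()` describes one column of the Cox design: a data column,
#' an optional transform building the column from the data (used for
#' landmark-age interaction terms), and an optional time basis making the
#' term's coefficient vary with time since landmark (evaluated at event
#' times inside the partial likelihood).  `cox_spec()` assembles terms with
#' the stratification and clustering structure of a landmark supermodel.
#'
#' @param col Name of the data column the term is built from (or a label
#'   when `transform` is given).
#' @param label Display label for the coefficient.
#' @param transform Optional `function(data)` returning the numeric column.
#' @param tv_basis Optional `function(t)` by which the (centered) column is
#'   multiplied at each event time, making the coefficient time-varying.
#' @param meta Optional serialisable descriptor used to round-trip variant
#'   terms through JSON.
#' @return `cox_term()`: an object of class `"cox_term"`;
#'   `cox_spec()`: an object of class `"cox_spec"`.
#' @export
cox_term <- function(col, label = col, transform = NULL, tv_basis = NULL,
                     meta = NULL) {
  structure(list(col = col, label = label, transform = transform,
                 tv_basis = tv_basis,
                 meta = meta %||% list(type = "plain", col = col)),
            class = "cox_term")
}

#' @rdname cox_term
#' @param terms A character vector of column names and/or a list of
#'   [cox_term()] objects (may be empty: the null model).
#' @param strata Name of the stratification column (separate baseline
#'   hazard per level), or `NULL` for a common baseline.
#' @param cluster Name of the clustering identifier for the robust
#'   sandwich variance (typically the patient id, since the same patient
#'   contributes correlated rows across landmark ages), or `NULL` for
#'   independent rows.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @export
cox_spec <- function(terms = character(), strata = NULL, cluster = NULL,
                     ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (is.character(terms)) terms <- lapply(terms, cox_term)
  if (inherits(terms, "cox_term")) terms <- list(terms)
  labels <- map(terms, "label")
  if (anyDuplicated(unlist(labels))) abort("term labels must be unique.")
  structure(list(terms = terms, strata = strata, cluster = cluster,
                 ties = ties), class = "cox_spec")
}

# Evaluate the design: base columns (centered later), tv flags, labels.
build_design <- function(data, spec) {
  p <- length(spec$terms)
  n <- nrow(data)
  X <- matrix(0, n, p)
  labels <- character(p)
  tv <- vector("list", p)
  for (j in seq_len(p)) {
    tm <- spec$terms[[j]]
    xj <- if (!is.null(tm$transform)) tm$transform(data) else data[[tm$col]]
    if (is.null(xj)) abort(sprintf("column `%s` not found in data.", tm$col))
    if (anyNA(xj)) abort(sprintf("term `%s` contains missing values.", tm$label))
    X[, j] <- as.numeric(xj)
    labels[j] <- tm$label
    tv[j] <- list(tm$tv_basis)   # [[<- would drop NULL entries
  }
  colnames(X) <- labels
  list(X = X, labels = labels, tv = tv, has_tv = any(!map_lgl(tv, is.null)))
}

#' Fit a (stratified, clustered) Cox proportional-hazards model
#'
#' Maximises the stratified Cox partial likelihood by Newton-Raphson with
#' step-halving, with the Breslow (default) or Efron approximation for tied
#' event times, supporting terms whose coefficient varies with time since
#' landmark (evaluated at the event times inside the partial likelihood,
#' the landmarking device for time-varying covariate effects).  Covariates
#' are centered at their data means before fitting; the centering vector is
#' stored with the fit and the exported baseline hazards refer to the
#' centered reference.  The robust variance is the clustered sandwich
#' `I^-1 (sum over clusters of summed score residuals, outer product) I^-1`;
#' with singleton clusters it reduces to the usual
#' Lin-Wei sandwich, which approximates (and with ties differs slightly
#' from) the naive inverse information.
#'
#' Convergence is declared when the score max-norm falls below
#' `tol * max(1, number of events)` or the relative change in partial
#' log-likelihood falls below `1e-13`; non-convergence after `max_iter`
#' iterations is an error carrying the iteration trace.
#'
#' @param data A landmark or stacked landmark dataset: tibble with `time`,
#'   `event`, the term columns and any strata/cluster columns.
#' @param spec A [cox_spec()].
#' @param max_iter Maximum Newton-Raphson iterations.
#' @param tol Score tolerance (scaled by the number of events).
#' @return An object of class `"landmark_coxfit"`: coefficients, naive and
#'   robust covariance, per-stratum Breslow baseline cumulative hazards,
#'   partial log-likelihoods (null and at the optimum), counts and
#'   convergence information.
#' @examples
#' d <- tibble::tibble(time = c(2, 4, 5, 7, 9, 12),
#'                     event = c(1, 1, 0, 1, 0, 1),
#'                     x = c(1, 0, 1, 0, 1, 0))
#' fit <- fit_cox(d, cox_spec("x"))
#' tidy(fit)
#' @export
fit_cox <- function(data, spec, max_iter = 50L, tol = 1e-9) {
  stopifnot(inherits(spec, "cox_spec"))
  if (!all(c("time", "event") %in% names(data))) {
    abort("data must contain `time` and `event` columns.")
  }
  if (any(data$time <= 0)) abort("all `time` values must be positive.")
  if (!all(data$event %in% c(0, 1))) abort("`event` must be 0/1.")

  des <- build_design(data, spec)
  p <- ncol(des$X)
  n <- nrow(data)
  strata <- if (!is.null(spec$strata)) as.character(data[[spec$strata]])
            else rep("all", n)
  cluster <- if (!is.null(spec$cluster)) as.character(data[[spec$cluster]])
             else as.character(seq_len(n))
  n_events <- sum(data$event)

  center <- if (p) colMeans(des$X) else numeric(0)
  Xc <- if (p) sweep(des$X, 2L, center) else des$X

  ## collinearity check on the time-fixed part of the design (a term with a
  ## time basis shares its base column with the main effect by construction)
  fixed_idx <- which(map_lgl(des$tv, is.null))
  if (length(fixed_idx)) {
    Xf <- Xc[, fixed_idx, drop = FALSE]
    qr_x <- qr(Xf)
    if (qr_x$rank < ncol(Xf)) {
      bad <- des$labels[fixed_idx][qr_x$pivot[(qr_x$rank + 1L):ncol(Xf)]]
      abort(sprintf("design matrix is rank deficient; collinear terms: %s",
                    paste(bad, collapse = ", ")))
    }
  }

  ## pre-split per stratum
  s_levels <- sort(unique(strata))
  parts <- lapply(s_levels, function(s) {
    idx <- which(strata == s)
    o <- idx[order(data$time[idx])]
    time <- data$time[o]; event <- data$event[o]
    ut <- unique(time[event == 1])
    if (length(ut) == 0L) {
      warn(sprintf("stratum `%s` has no events; its baseline hazard is flat.", s))
    }
    list(s = s, rows = o, time = time, event = event,
         ki = findInterval(time, ut), ut = ut,
         X = Xc[o, , drop = FALSE],
         tv = des$tv, has_tv = des$has_tv)
  })

  lik <- function(beta, want = c("ll", "grad")) {
    ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
    for (pt in parts) {
      res <- if (pt$has_tv) stratum_lik_tv(pt, beta, spec$ties)
             else stratum_lik_fast(pt, beta, spec$ties)
      ll <- ll + res$ll
      if (p) { U <- U + res$U; I <- I + res$I }
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- numeric(p)
  trace <- tibble(iter = integer(), loglik = numeric(), max_score = numeric())
  converged <- TRUE
  iter <- 0L
  cur <- lik(beta)
  ll_null <- cur$ll
  if (p) {
    converged <- FALSE
    plateau <- FALSE
    tol_score <- tol * max(1, n_events)
    last_rel <- Inf
    repeat {
      iter <- iter + 1L
      trace <- bind_rows(trace, tibble(iter = iter, loglik = cur$ll,
                                       max_score = max(abs(cur$U))))
      if (max(abs(cur$U)) < tol_score) { converged <- TRUE; break }
      step <- tryCatch(solve(cur$I, cur$U), error = function(e) {
        abort(paste("information matrix is singular (separated or",
                    "rank-deficient data)."),
              class = "landmarker_cox_no_convergence", trace = trace)
      })
      new <- NULL
      for (h in 0:30) {
        cand <- beta + step / 2^h
        new <- lik(cand)
        ## only accept finite improving iterates; with a monotone partial
        ## likelihood the loop then plateaus at a large finite coefficient
        ## (handled below), as coxph does
        if (is.finite(new$ll) && all(is.finite(new$U)) &&
            all(is.finite(new$I)) && new$ll >= cur$ll - 1e-12) break
        new <- NULL
      }
      if (is.null(new)) {
        converged <- last_rel < 1e-8 || max(abs(cur$U)) < tol_score * 10
        plateau <- converged
        break
      }
      last_rel <- abs(new$ll - cur$ll) / (abs(cur$ll) + 1)
      beta <- cand; cur <- new
      if (last_rel < 1e-13) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) {
        converged <- plateau <- last_rel < 1e-8
        break
      }
    }
    if (!converged) {
      abort("Cox partial-likelihood maximisation did not converge.",
            class = "landmarker_cox_no_convergence", trace = trace)
    }
    if (plateau) {
      warn(paste("partial likelihood plateaued with the score still nonzero;",
                 "a coefficient may be diverging (separated data)."))
    }
  }

  names(beta) <- des$labels
  ## pseudo-inverse guards the separated-data plateau, where the
  ## information can be numerically singular (variances are then huge)
  inv_sym <- function(M) {
    tryCatch(solve(M), error = function(e) {
      ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
      pos <- ev$values > max(ev$values, 0) * 1e-12
      ev$vectors[, pos, drop = FALSE] %*%
        (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    })
  }
  naive_cov <- if (p) inv_sym(cur$I) else matrix(0, 0, 0)
  if (p) dimnames(naive_cov) <- list(des$labels, des$labels)

  ## score residuals -> clustered sandwich
  robust_cov <- naive_cov
  if (p) {
    resid <- matrix(0, n, p)
    for (pt in parts) {
      r <- if (pt$has_tv) stratum_resid_tv(pt, beta)
           else stratum_resid_fast(pt, beta)
      resid[pt$rows, ] <- r
    }
    Uclust <- rowsum(resid, cluster)
    robust_cov <- naive_cov %*% crossprod(Uclust) %*% naive_cov
    dimnames(robust_cov) <- dimnames(naive_cov)
  }

  ## Breslow (or Efron) baseline cumulative hazard per stratum, with the
  ## standard Breslow variance (sum over event times of d_k / S0_k^2,
  ## ignoring the beta-uncertainty cross-term)
  baseline <- bind_rows(lapply(parts, function(pt) {
    bh <- stratum_baseline(pt, beta, spec$ties)
    tibble(stratum = pt$s, time = bh$time, haz = bh$haz,
           cumhaz = cumsum(bh$haz), var_cumhaz = cumsum(bh$var))
  }))

  structure(list(
    coefficients = beta,
    naive_cov = naive_cov,
    robust_cov = robust_cov,
    baseline = baseline,
    center = setNames(center, des$labels),
    spec = spec,
    loglik = c(null = ll_null, model = cur$ll),
    n = n, n_events = n_events,
    n_clusters = length(unique(cluster)),
    n_strata = length(s_levels), strata_levels = s_levels,
    converged = converged, iter = iter, trace = trace),
    class = "landmark_coxfit")
}

## ---- per-stratum partial likelihood, fixed covariates (vectorised) --------

revcum <- function(m) {
  # reverse cumulative sum down the rows of a matrix (or vector)
  if (is.null(dim(m))) return(rev(cumsum(rev(m))))
  k <- nrow(m)
  if (k == 0L) return(m)
  out <- m[k:1, , drop = FALSE]
  out <- apply(out, 2L, cumsum)
  if (is.null(dim(out))) out <- matrix(out, nrow = k)
  out[k:1, , drop = FALSE]
}

stratum_sums <- function(pt, beta, need_S1 = TRUE, need_S2 = TRUE,
                         ties = "breslow") {
  X <- pt$X
  p <- ncol(X)
  lp <- if (p) drop(X %*% beta) else numeric(nrow(X))
  w <- exp(lp)
  K <- length(pt$ut)
  if (K == 0L) return(NULL)
  ki <- pt$ki
  in_risk <- ki >= 1L
  kf <- factor(ki[in_risk], levels = seq_len(K))
  g0 <- as.numeric(rowsum(w[in_risk], kf))
  S0 <- rev(cumsum(rev(g0)))
  ev <- pt$event == 1
  evf <- factor(ki[ev], levels = seq_len(K))
  d <- as.numeric(rowsum(rep(1, sum(ev)), evf))
  out <- list(lp = lp, w = w, K = K, S0 = S0, d = d, ev = ev, ki = ki)
  out$S0D <- as.numeric(rowsum(w[ev], evf))
  if (p && need_S1) {
    g1 <- rowsum(w[in_risk] * X[in_risk, , drop = FALSE], kf)
    out$S1 <- revcum(g1)
    out$sx <- rowsum(X[ev, , drop = FALSE], evf)
    out$S1D <- rowsum(w[ev] * X[ev, , drop = FALSE], evf)
  }
  if (p && need_S2) {
    ## per-block weighted crossproducts, reverse-accumulated
    S2 <- array(0, c(K, p, p))
    acc <- matrix(0, p, p)
    idx_by_k <- split(which(in_risk), kf)
    for (k in K:1) {
      rows <- idx_by_k[[k]]
      if (length(rows)) {
        Xi <- X[rows, , drop = FALSE]
        acc <- acc + crossprod(Xi * sqrt(w[rows]))
      }
      S2[k, , ] <- acc
    }
    out$S2 <- S2
    if (ties == "efron") {
      S2D <- array(0, c(K, p, p))
      ev_by_k <- split(which(ev), evf)
      for (k in seq_len(K)) {
        rows <- ev_by_k[[k]]
        if (length(rows)) {
          Xi <- X[rows, , drop = FALSE]
          S2D[k, , ] <- crossprod(Xi * sqrt(w[rows]))
        }
      }
      out$S2D <- S2D
    }
  }
  out
}

stratum_lik_fast <- function(pt, beta, ties) {
  p <- ncol(pt$X)
  if (ties == "efron") return(stratum_lik_efron(pt, beta))
  s <- stratum_sums(pt, beta, need_S2 = FALSE)
  if (is.null(s)) {
    return(list(ll = 0, U = numeric(p), I = matrix(0, p, p)))
  }
  ll <- sum(s$lp[s$ev]) - sum(s$d * log(s$S0))
  if (!p) return(list(ll = ll, U = numeric(0), I = matrix(0, 0, 0)))
  ## cumulative-weight identities avoid any loop over event times:
  ## sum_k (d_k/S0_k) S_r(k) = sum_i w_i A_i x_i^(r), A_i = cum of d/S0 at t_i
  om <- s$d / s$S0
  Acum <- cumsum(om)
  A <- c(0, Acum)[s$ki + 1L]
  wA <- s$w * A
  U <- colSums(s$sx) - colSums(pt$X * wA)
  M <- s$S1 / s$S0
  I <- crossprod(pt$X * sqrt(wA)) - crossprod(M * sqrt(s$d))
  list(ll = ll, U = U, I = I)
}

stratum_lik_efron <- function(pt, beta) {
  p <- ncol(pt$X)
  s <- stratum_sums(pt, beta, ties = "efron")
  if (is.null(s)) {
    return(list(ll = 0, U = numeric(p), I = matrix(0, p, p)))
  }
  ll <- sum(s$lp[s$ev])
  U <- numeric(p); I <- matrix(0, p, p)
  for (k in seq_len(s$K)) {
    dk <- s$d[k]
    if (dk == 0) next
    for (l in seq_len(dk) - 1) {
      den <- s$S0[k] - (l / dk) * s$S0D[k]
      ll <- ll - log(den)
      if (p) {
        num <- s$S1[k, ] - (l / dk) * s$S1D[k, ]
        m <- num / den
        U <- U - m
        S2e <- s$S2[k, , ] - (l / dk) * s$S2D[k, , ]
        I <- I + S2e / den - tcrossprod(m)
      }
    }
    if (p) U <- U + s$sx[k, ]
  }
  list(ll = ll, U = U, I = I)
}

stratum_baseline <- function(pt, beta, ties) {
  if (pt$has_tv) return(stratum_baseline_tv(pt, beta, ties))
  s <- stratum_sums(pt, beta, need_S1 = FALSE, need_S2 = FALSE)
  if (is.null(s)) {
    return(list(time = numeric(0), haz = numeric(0), var = numeric(0)))
  }
  K <- s$K
  haz <- numeric(K)
  for (k in seq_len(K)) {
    dk <- s$d[k]
    if (ties == "breslow" || dk <= 1) {
      haz[k] <- dk / s$S0[k]
    } else {
      haz[k] <- sum(1 / (s$S0[k] - ((seq_len(dk) - 1) / dk) * s$S0D[k]))
    }
  }
  list(time = pt$ut, haz = haz, var = s$d / s$S0^2)
}

stratum_resid_fast <- function(pt, beta) {
  # Breslow-form score residuals (exact without ties; with Efron ties a
  # documented approximation used only for the sandwich variance)
  p <- ncol(pt$X)
  s <- stratum_sums(pt, beta, need_S2 = FALSE)
  n <- nrow(pt$X)
  if (is.null(s)) return(matrix(0, n, p))
  dS0 <- s$d / s$S0
  A <- cumsum(dS0)
  B <- apply(s$S1 * (s$d / s$S0^2), 2L, cumsum)
  if (is.null(dim(B))) B <- matrix(B, ncol = p)
  M <- s$S1 / s$S0
  res <- matrix(0, n, p)
  ki <- s$ki
  pos <- ki >= 1L
  res[s$ev & pos, ] <- pt$X[s$ev & pos, , drop = FALSE] -
    M[ki[s$ev & pos], , drop = FALSE]
  res[pos, ] <- res[pos, , drop = FALSE] -
    s$w[pos] * (pt$X[pos, , drop = FALSE] * A[ki[pos]] -
                  B[ki[pos], , drop = FALSE])
  res
}

## ---- per-stratum partial likelihood with time-varying terms ----------------

tv_design_at <- function(pt, t) {
  Xe <- pt$X
  for (j in seq_along(pt$tv)) {
    f <- pt$tv[[j]]
    if (!is.null(f)) Xe[, j] <- Xe[, j] * f(t)
  }
  Xe
}

stratum_lik_tv <- function(pt, beta, ties) {
  if (ties == "efron") {
    abort("Efron ties are not supported with time-varying coefficient terms.")
  }
  p <- ncol(pt$X)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  for (k in seq_along(pt$ut)) {
    tk <- pt$ut[k]
    risk <- pt$time >= tk
    Xe <- tv_design_at(pt, tk)
    lp <- drop(Xe %*% beta)
    w <- exp(lp)
    S0 <- sum(w[risk])
    S1 <- colSums(w[risk] * Xe[risk, , drop = FALSE])
    S2 <- crossprod(Xe[risk, , drop = FALSE] * sqrt(w[risk]))
    ev_k <- pt$event == 1 & pt$time == tk
    dk <- sum(ev_k)
    ll <- ll + sum(lp[ev_k]) - dk * log(S0)
    m <- S1 / S0
    U <- U + colSums(Xe[ev_k, , drop = FALSE]) - dk * m
    I <- I + dk * (S2 / S0 - tcrossprod(m))
  }
  list(ll = ll, U = U, I = I)
}

stratum_resid_tv <- function(pt, beta) {
  p <- ncol(pt$X)
  n <- nrow(pt$X)
  res <- matrix(0, n, p)
  for (k in seq_along(pt$ut)) {
    tk <- pt$ut[k]
    risk <- pt$time >= tk
    Xe <- tv_design_at(pt, tk)
    w <- exp(drop(Xe %*% beta))
    S0 <- sum(w[risk])
    S1 <- colSums(w[risk] * Xe[risk, , drop = FALSE])
    m <- S1 / S0
    ev_k <- pt$event == 1 & pt$time == tk
    dk <- sum(ev_k)
    res[ev_k, ] <- res[ev_k, , drop = FALSE] +
      sweep(Xe[ev_k, , drop = FALSE], 2L, m)
    res[risk, ] <- res[risk, , drop = FALSE] -
      (w[risk] * dk / S0) * sweep(Xe[risk, , drop = FALSE], 2L, m)
  }
  res
}

stratum_baseline_tv <- function(pt, beta, ties) {
  K <- length(pt$ut)
  haz <- numeric(K)
  varh <- numeric(K)
  for (k in seq_len(K)) {
    tk <- pt$ut[k]
    risk <- pt$time >= tk
    Xe <- tv_design_at(pt, tk)
    w <- exp(drop(Xe %*% beta))
    dk <- sum(pt$event == 1 & pt$time == tk)
    haz[k] <- dk / sum(w[risk])
    varh[k] <- dk / sum(w[risk])^2
  }
  list(time = pt$ut, haz = haz, var = varh)
}
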