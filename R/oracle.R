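#' Generative conditional survival oracle
#'
#' Computes the ground-truth conditional survival probability
#' `S(L + t | alive at L, current state)` implied by a generator
#' configuration, for use as an independent oracle when testing fitted
#' prediction models.  Continuous covariates follow their expected
#' conditional latent trajectory given the current value (the best linear
#' predictor of the random slope given the random-effect realisation at the
#' landmark age); binary states, IV-day redraws and the competing transplant
#' process are marginalised by Monte Carlo with a fixed inner seed.  Each
#' draw contributes `exp(-integral of the death hazard along its covariate
#' path)`, so the estimator is exact conditional on the simulated path
#' (a Rao-Blackwellised average with much smaller Monte-Carlo error than an
#' empirical survival proportion at the same number of draws).
#'
#' The integration uses the same conventions as [simulate_registry()]:
#' covariate values are held constant over each (unjittered) visit interval,
#' evaluated at the interval start, while the baseline hazard piece changes
#' exactly at its age breakpoints.
#'
#' @param state Named list or vector of current covariate values at the
#'   landmark age: the continuous variables (latent scale), the binary
#'   states, `iv_days_hospital`, `iv_days_home`, `sex`, `genotype_class`,
#'   `diagnosis_age`, and `birth` (to anchor calendar time).  The individual
#'   is assumed untransplanted at the landmark age.
#' @param landmark_age Age (years) from which the prediction is made.
#' @param t Vector of horizons (years, >= 0).
#' @param config A [registry_config()].
#' @param n_draws Monte-Carlo draws for the binary-state/transplant paths.
#' @param seed Inner seed; the caller's RNG state is preserved.
#' @return Numeric vector of survival probabilities, one per element of
#'   `t`, with the Monte-Carlo standard errors in attribute `"mc_se"`.
#' @export
oracle_survival <- function(state, landmark_age, t, config,
                            n_draws = 2000, seed = 1L) {
  config <- validate_registry_config(config)
  if (any(t < 0)) abort("`t` must be non-negative.")
  state <- as.list(state)
  local_seed(seed, oracle_impl(state, landmark_age, t, config, n_draws))
}

oracle_impl <- function(state, L, t_req, cfg, n_draws) {
  hz <- cfg$hazard
  cont_vars <- names(cfg$trajectories)
  bin_vars <- names(cfg$binary_states)
  tmax <- max(t_req)
  out <- numeric(length(t_req))
  out_se <- numeric(length(t_req))
  if (tmax == 0) {
    out[] <- 1; attr(out, "mc_se") <- out_se; return(out)
  }

  ## expected conditional slope of each continuous variable given its value
  cond_path <- function(v, u) {
    # value of variable v at L + u along the expected conditional trajectory
    tr <- cfg$trajectories[[v]]
    x <- state[[v]]
    tl <- L - 18
    s2 <- tr$ri_sd^2 + 2 * tr$cor * tr$ri_sd * tr$rs_sd * tl + (tr$rs_sd * tl)^2
    dev <- x - (tr$intercept + tr$slope * tl)
    slope <- tr$slope +
      if (s2 > 0) (tr$cor * tr$ri_sd * tr$rs_sd + tr$rs_sd^2 * tl) / s2 * dev else 0
    x + slope * u
  }

  ## covariate-update steps (visit grid without jitter) and integration grid
  step_starts <- seq(0, tmax, by = cfg$visit_interval)
  brk_off <- hz$baseline_breaks - L
  grid <- sort(unique(c(0, step_starts, t_req, tmax,
                        brk_off[brk_off > 0 & brk_off < tmax])))
  grid <- grid[grid <= tmax]
  cell_lo <- grid[-length(grid)]
  cell_hi <- grid[-1]
  cell_step <- findInterval(cell_lo, step_starts)  # which visit interval
  base_log <- hz$baseline_loghaz[pmax(findInterval(L + cell_lo,
                                                   hz$baseline_breaks), 1L)]

  ## Monte-Carlo state across draws
  bstate <- matrix(0L, n_draws, length(bin_vars),
                   dimnames = list(NULL, bin_vars))
  for (v in bin_vars) bstate[, v] <- as.integer(rep(state[[v]], n_draws))
  iv_h <- rep(as.numeric(state[["iv_days_hospital"]] %||% 0), n_draws)
  iv_m <- rep(as.numeric(state[["iv_days_home"]] %||% 0), n_draws)
  txp_time <- rep(Inf, n_draws)
  draw_iv <- function(m, par) {
    nz <- runif(m) < par$p_nonzero
    outv <- numeric(m)
    if (par$mean_days > 0 && any(nz)) {
      outv[nz] <- pmin(366, rexp(sum(nz), 1 / par$mean_days))
    }
    outv
  }

  lam_post <- exp(cfg$transplant$post_death_loghaz)
  cov_names <- names(hz$coefs)
  fixed_vals <- list(sex = state[["sex"]] %||% 0,
                     genotype_class = state[["genotype_class"]] %||% 0,
                     diagnosis_age = state[["diagnosis_age"]] %||% 0)
  birth <- state[["birth"]] %||% (hz$calendar_ref - L)

  ## per-step covariate log-relative hazard (vector over draws)
  step_lp <- function(u) {
    lp <- rep(0, n_draws)
    for (nm in cov_names) {
      cf <- hz$coefs[[nm]]
      if (cf == 0) next
      x <- if (nm %in% cont_vars) rep(cond_path(nm, u), n_draws)
      else if (nm %in% bin_vars) bstate[, nm]
      else if (nm == "iv_days_hospital") iv_h
      else if (nm == "iv_days_home") iv_m
      else rep(fixed_vals[[nm]] %||% 0, n_draws)
      lp <- lp + cf * (x - hz$refs[[nm]])
    }
    lp + hz$calendar_coef * (birth + L + u - hz$calendar_ref)
  }

  cum_haz <- matrix(0, n_draws, length(grid))  # cumulative at each boundary
  cur_lp <- NULL
  last_step <- -1L
  for (ci in seq_along(cell_lo)) {
    k <- cell_step[ci]
    if (k != last_step) {
      u0 <- step_starts[k]
      if (k > 1L) {
        ## covariate update at the start of a new visit interval
        for (v in bin_vars) {
          bs <- cfg$binary_states[[v]]
          on <- bstate[, v] == 1L
          u <- runif(n_draws)
          bstate[on, v] <- as.integer(u[on] >= bs$p_off)
          bstate[!on, v] <- as.integer(u[!on] < bs$p_on)
        }
        if (cfg$iv_days$redraw %||% TRUE) {
          iv_h <- draw_iv(n_draws, cfg$iv_days$hospital)
          iv_m <- draw_iv(n_draws, cfg$iv_days$home)
        }
      }
      cur_lp <- step_lp(u0)
      ## transplant within this visit interval (constant hazard per step)
      fev1_now <- cond_path("fev1_pct", u0)
      lam_t <- exp(cfg$transplant$log_rate +
                     cfg$transplant$fev1_coef * (fev1_now - cfg$transplant$fev1_ref))
      untx <- is.infinite(txp_time)
      if (any(untx) && lam_t > 0) {
        cand <- u0 + rexp(sum(untx), lam_t)
        u1 <- if (k < length(step_starts)) step_starts[k + 1L] else tmax
        hitt <- cand < u1
        txp_time[which(untx)[hitt]] <- cand[hitt]
      }
      last_step <- k
    }
    a <- cell_lo[ci]; b <- cell_hi[ci]
    lam_pre <- exp(base_log[ci] + cur_lp)
    len_pre <- pmax(0, pmin(txp_time, b) - a)
    len_post <- pmax(0, b - pmax(txp_time, a))
    cum_haz[, ci + 1L] <- cum_haz[, ci] + lam_pre * len_pre + lam_post * len_post
  }

  for (j in seq_along(t_req)) {
    gi <- match(t_req[j], grid)
    if (t_req[j] == 0 || is.na(gi)) {
      out[j] <- 1; out_se[j] <- 0; next
    }
    s <- exp(-cum_haz[, gi])
    out[j] <- mean(s)
    out_se[j] <- stats::sd(s) / sqrt(n_draws)
  }
  attr(out, "mc_se") <- out_se
  out
}
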