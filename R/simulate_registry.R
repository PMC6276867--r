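#' Simulate a longitudinal registry with known ground truth
#'
#' Generates a synthetic patient registry emulating the structure of a
#' national cystic-fibrosis registry: adults observed at roughly annual
#' review visits within a calendar study window, continuous lung-function
#' and anthropometric trajectories with patient-level random intercepts and
#' slopes, persistent binary infection/comorbidity states, zero-inflated
#' IV-antibiotic days, and death, transplant and loss-to-follow-up times
#' drawn from hazards that depend on the current latent covariate values
#' (see [registry_config()] for the generative model).
#'
#' Individuals enter observation at `max(18, diagnosis age, age at the
#' start of the study window)` and are administratively censored at the end
#' of the window.  Individuals whose entry age would fall at or after their
#' age at the end of the window are never observed and are dropped from the
#' cohort.  Event times are simulated exactly for the stated generative
#' model by piecewise-constant inversion sampling: within each inter-visit
#' interval the covariate part of the hazard is held at the interval-start
#' latent values while the baseline piece changes at its age breakpoints.
#' After a transplant no further reviews are generated; the death hazard
#' switches to the configured constant post-transplant rate.
#'
#' The generator is fully deterministic given the config (including its
#' seed) and leaves the caller's RNG state untouched.
#'
#' @param config A [registry_config()].
#' @return An object of class `"registry"`: a list with tibbles `patients`
#'   (one row per individual: `id`, `sex`, `genotype_class`, `birth`,
#'   `diagnosis_age`, `registry_entry_age`, `death_age`, `transplant_age`,
#'   `loss_age`) and `reviews` (one row per annual review with the 13
#'   time-dependent variables), plus `config` (the configuration used) and
#'   `latents` (the ground-truth latent trajectory coefficients per
#'   patient, for validation against the generative truth).
#' @examples
#' reg <- simulate_registry(registry_config(n_individuals = 50, seed = 1))
#' reg$patients
#' @export
simulate_registry <- function(config) {
  config <- validate_registry_config(config)
  local_seed(config$seed, simulate_registry_impl(config))
}

simulate_registry_impl <- function(cfg) {
  n0 <- cfg$n_individuals
  start <- cfg$study_window[1]
  end <- cfg$study_window[2]
  tdvars <- time_dependent_vars()
  cont_vars <- names(cfg$trajectories)
  bin_vars <- names(cfg$binary_states)

  empty <- function() {
    structure(list(
      patients = tibble(id = character(), sex = integer(),
                        genotype_class = integer(), birth = numeric(),
                        diagnosis_age = numeric(), registry_entry_age = numeric(),
                        death_age = numeric(), transplant_age = numeric(),
                        loss_age = numeric()),
      reviews = as_tibble(c(list(patient_id = character(), age = numeric(),
                                 calendar_year = numeric()),
                            setNames(rep(list(numeric()), length(tdvars)), tdvars))),
      config = cfg,
      latents = tibble(patient_id = character())), class = "registry")
  }
  if (n0 == 0L) return(empty())

  ## ---- patient-level draws -------------------------------------------------
  sex <- rbinom(n0, 1L, cfg$sex_prob)
  genotype <- sample(0:2, n0, replace = TRUE, prob = cfg$genotype_probs)
  birth <- cfg$birth_cohort_range[1] +
    diff(cfg$birth_cohort_range) * runif(n0)^(1 / cfg$birth_cohort_shape)
  infant <- runif(n0) < cfg$diagnosis$infant_prob
  diag_age <- ifelse(infant, rexp(n0, 1 / max(cfg$diagnosis$infant_mean, 1e-6)),
                     runif(n0, cfg$diagnosis$adult_min, cfg$diagnosis$adult_max))
  entry <- pmax(18, diag_age, start - birth)
  exit <- end - birth
  keep <- entry < exit
  if (!any(keep)) return(empty())
  idx <- which(keep)
  n <- length(idx)
  sex <- sex[idx]; genotype <- genotype[idx]; birth <- birth[idx]
  diag_age <- diag_age[idx]; entry <- entry[idx]; exit <- exit[idx]
  id <- sprintf("P%05d", idx)

  ## random intercepts/slopes per continuous variable (correlated pair)
  lat_int <- matrix(0, n, length(cont_vars), dimnames = list(NULL, cont_vars))
  lat_slo <- lat_int
  for (v in cont_vars) {
    tr <- cfg$trajectories[[v]]
    z1 <- rnorm(n); z2 <- rnorm(n)
    a <- tr$ri_sd * z1
    b <- tr$rs_sd * (tr$cor * z1 + sqrt(max(0, 1 - tr$cor^2)) * z2)
    lat_int[, v] <- tr$intercept + a
    lat_slo[, v] <- tr$slope + b
  }
  latent_at <- function(rows, age) {
    # latent value of each continuous variable at the given ages
    sweep_age <- age - 18
    lat_int[rows, , drop = FALSE] +
      lat_slo[rows, , drop = FALSE] * sweep_age
  }

  ## binary states at entry (stationary prevalence unless configured)
  bstate <- matrix(0L, n, length(bin_vars), dimnames = list(NULL, bin_vars))
  for (v in bin_vars) {
    bstate[, v] <- rbinom(n, 1L, stationary_prevalence(cfg$binary_states[[v]]))
  }
  draw_iv <- function(m, par) {
    nz <- runif(m) < par$p_nonzero
    out <- numeric(m)
    if (par$mean_days > 0 && any(nz)) {
      out[nz] <- pmin(366, rexp(sum(nz), 1 / par$mean_days))
    }
    out
  }
  iv_hosp <- draw_iv(n, cfg$iv_days$hospital)
  iv_home <- draw_iv(n, cfg$iv_days$home)

  ## ---- hazard machinery ----------------------------------------------------
  hz <- cfg$hazard
  cov_names <- names(hz$coefs)
  base_log_at <- function(age) {
    piece <- findInterval(age, hz$baseline_breaks)
    hz$baseline_loghaz[pmax(piece, 1L)]
  }
  # covariate log-relative-hazard at the current state, rows = active patients
  cov_lp <- function(rows, age) {
    lp <- rep(0, length(rows))
    latents <- latent_at(rows, age)
    vals <- list(sex = sex[rows], genotype_class = genotype[rows],
                 diagnosis_age = diag_age[rows],
                 iv_days_hospital = iv_hosp[rows], iv_days_home = iv_home[rows])
    for (nm in cov_names) {
      x <- if (nm %in% cont_vars) latents[, nm]
      else if (nm %in% bin_vars) bstate[rows, nm]
      else vals[[nm]]
      if (is.null(x)) next
      lp <- lp + hz$coefs[[nm]] * (x - hz$refs[[nm]])
    }
    lp + hz$calendar_coef * (birth[rows] + age - hz$calendar_ref)
  }

  death_age <- rep(NA_real_, n)
  txp_age <- rep(NA_real_, n)
  loss_age <- rep(NA_real_, n)

  ## ---- review storage ------------------------------------------------------
  rev_chunks <- list()
  emit_reviews <- function(rows, age) {
    latents <- latent_at(rows, age)
    meas <- latents
    for (v in cont_vars) {
      rsd <- cfg$trajectories[[v]]$resid_sd
      if (rsd > 0) meas[, v] <- meas[, v] + rnorm(length(rows), 0, rsd)
    }
    meas[, "fev1_pct"] <- pmax(meas[, "fev1_pct"], 5)
    meas[, "fvc_pct"] <- pmax(meas[, "fvc_pct"], 5)
    meas[, "weight"] <- pmax(meas[, "weight"], 25)
    meas[, "height"] <- pmax(meas[, "height"], 120)
    td <- lapply(time_dependent_vars(), function(v) {
      if (v %in% cont_vars) meas[, v]
      else if (v %in% bin_vars) bstate[rows, v]
      else if (v == "iv_days_hospital") iv_hosp[rows]
      else if (v == "iv_days_home") iv_home[rows]
      else rep(NA_real_, length(rows))
    })
    names(td) <- time_dependent_vars()
    chunk <- c(list(patient_id = id[rows], age = age,
                    calendar_year = birth[rows] + age), td)
    rev_chunks[[length(rev_chunks) + 1L]] <<- as_tibble(chunk)
  }

  ## first review at registry entry
  cur_age <- entry
  emit_reviews(seq_len(n), cur_age)

  ## ---- interval loop -------------------------------------------------------
  active <- rep(TRUE, n)
  guard <- 0L
  all_breaks <- hz$baseline_breaks
  while (any(active) && guard < 500L) {
    guard <- guard + 1L
    rows <- which(active)
    m <- length(rows)
    gap <- pmax(0.25, rnorm(m, cfg$visit_interval, cfg$visit_jitter_sd))
    next_age <- cur_age[rows] + gap
    seg_end <- pmin(next_age, exit[rows])

    lp <- cov_lp(rows, cur_age[rows])
    lam_txp <- exp(cfg$transplant$log_rate +
                     cfg$transplant$fev1_coef *
                     (latent_at(rows, cur_age[rows])[, "fev1_pct"] -
                        cfg$transplant$fev1_ref))
    lam_loss <- cfg$loss_rate

    ## piecewise integration of the total hazard across baseline age pieces
    a0 <- cur_age[rows]
    K <- length(all_breaks)
    seg_len <- matrix(0, m, K)
    lam_dth <- matrix(0, m, K)
    for (j in seq_len(K)) {
      lo <- all_breaks[j]
      hi <- if (j < K) all_breaks[j + 1] else Inf
      seg_len[, j] <- pmax(0, pmin(seg_end, hi) - pmax(a0, lo))
      lam_dth[, j] <- exp(hz$baseline_loghaz[j] + lp)
    }
    lam_tot <- lam_dth + lam_txp + lam_loss
    ut <- matrix(0, K, K); ut[upper.tri(ut, diag = TRUE)] <- 1
    cumH <- (lam_tot * seg_len) %*% ut
    E <- rexp(m)
    Htot <- cumH[, K]
    hit <- E < Htot
    ev_time <- rep(NA_real_, m)
    ev_piece <- rep(NA_integer_, m)
    if (any(hit)) {
      for (i in which(hit)) {
        j <- which(E[i] < cumH[i, ])[1]
        before <- if (j > 1L) cumH[i, j - 1L] else 0
        lo <- max(a0[i], all_breaks[j])
        ev_time[i] <- lo + (E[i] - before) / lam_tot[i, j]
        ev_piece[i] <- j
      }
      u_type <- runif(sum(hit))
      hi_rows <- which(hit)
      p_death <- lam_dth[cbind(hi_rows, ev_piece[hi_rows])] /
        lam_tot[cbind(hi_rows, ev_piece[hi_rows])]
      p_txp <- lam_txp[hi_rows] / lam_tot[cbind(hi_rows, ev_piece[hi_rows])]
      is_death <- u_type < p_death
      is_txp <- !is_death & u_type < p_death + p_txp
      is_loss <- !is_death & !is_txp

      gi <- rows[hi_rows]
      death_age[gi[is_death]] <- ev_time[hi_rows][is_death]
      loss_age[gi[is_loss]] <- ev_time[hi_rows][is_loss]
      ## transplanted: no further reviews; residual constant-hazard death
      if (any(is_txp)) {
        ti <- gi[is_txp]
        s <- ev_time[hi_rows][is_txp]
        txp_age[ti] <- s
        lam_post <- exp(cfg$transplant$post_death_loghaz)
        t2 <- rexp(length(ti), lam_post + lam_loss)
        obs <- s + t2 <= exit[ti]
        if (any(obs)) {
          u2 <- runif(sum(obs))
          dth <- u2 < lam_post / (lam_post + lam_loss)
          oi <- ti[obs]
          death_age[oi[dth]] <- (s + t2)[obs][dth]
          loss_age[oi[!dth]] <- (s + t2)[obs][!dth]
        }
      }
      active[gi] <- FALSE
    }

    ## survivors of the interval: visit (if still inside the window) or censor
    surv_rows <- rows[!hit]
    if (length(surv_rows)) {
      visit <- next_age[!hit] < exit[surv_rows]
      cens <- surv_rows[!visit]
      active[cens] <- FALSE
      vis <- surv_rows[visit]
      if (length(vis)) {
        vage <- next_age[!hit][visit]
        cur_age[vis] <- vage
        ## Markov update of binary states, redraw IV days
        for (v in bin_vars) {
          bs <- cfg$binary_states[[v]]
          on <- bstate[vis, v] == 1L
          u <- runif(length(vis))
          newstate <- integer(length(vis))
          newstate[on] <- as.integer(u[on] >= bs$p_off)
          newstate[!on] <- as.integer(u[!on] < bs$p_on)
          bstate[vis, v] <- newstate
        }
        if (cfg$iv_days$redraw %||% TRUE) {
          iv_hosp[vis] <- draw_iv(length(vis), cfg$iv_days$hospital)
          iv_home[vis] <- draw_iv(length(vis), cfg$iv_days$home)
        }
        emit_reviews(vis, vage)
      }
    }
  }

  patients <- tibble(
    id = id, sex = as.integer(sex), genotype_class = as.integer(genotype),
    birth = birth, diagnosis_age = diag_age, registry_entry_age = entry,
    death_age = death_age, transplant_age = txp_age, loss_age = loss_age)
  reviews <- bind_rows(rev_chunks) |> arrange(.data$patient_id, .data$age)
  ## ground-truth latent trajectory coefficients (value at age 18 and slope),
  ## exposed so tests and oracles can compare estimates with the truth
  latents <- tibble(patient_id = id)
  for (v in cont_vars) {
    latents[[paste0(v, "_intercept")]] <- lat_int[, v]
    latents[[paste0(v, "_slope")]] <- lat_slo[, v]
  }
  structure(list(patients = patients, reviews = reviews, config = cfg,
                 latents = latents),
            class = "registry")
}

#' @export
print.registry <- function(x, ...) {
  n_d <- sum(!is.na(x$patients$death_age))
  n_t <- sum(!is.na(x$patients$transplant_age))
  cat(sprintf("<registry> %d patients, %d reviews, %d deaths, %d transplants\n",
              nrow(x$patients), nrow(x$reviews), n_d, n_t))
  invisible(x)
}

#' Write / read a registry as delimited text files
#'
#' Two comma-separated files with header rows, UTF-8, missing values as
#' empty fields: `patients.csv` and `reviews.csv`, plus the generating
#' configuration as `config.json` when available.
#'
#' @param registry A `"registry"` object.
#' @param dir Directory to write to (created if needed).
#' @return `write_registry()` returns the directory invisibly;
#'   `read_registry()` returns a `"registry"` object (with `config = NULL`
#'   if no `config.json` is present).
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_precise(registry$patients, file.path(dir, "patients.csv"))
  write_csv_precise(registry$reviews, file.path(dir, "reviews.csv"))
  if (!is.null(registry$config)) {
    cfg <- registry$config
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  patients <- as_tibble(read.csv(file.path(dir, "patients.csv"),
                                 na.strings = "", colClasses = c(id = "character")))
  for (col in c("death_age", "transplant_age", "loss_age")) {
    patients[[col]] <- as.numeric(patients[[col]])
  }
  reviews <- as_tibble(read.csv(file.path(dir, "reviews.csv"), na.strings = "",
                                colClasses = c(patient_id = "character")))
  cfg_path <- file.path(dir, "config.json")
  cfg <- NULL
  if (file.exists(cfg_path)) {
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    cfg$hazard$coefs <- unlist(cfg$hazard$coefs)
    cfg$hazard$refs <- unlist(cfg$hazard$refs)
    class(cfg) <- "registry_config"
  }
  structure(list(patients = patients, reviews = reviews, config = cfg),
            class = "registry")
}
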