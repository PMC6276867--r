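# Independent oracles and small fixture builders shared across tests.

# Written-out Cox partial log-likelihood (Breslow ties), summed directly
# from its definition -- the brute-force oracle for the fitting engine.
brute_cox_loglik <- function(beta, time, event, X, strata = NULL) {
  strata <- strata %||% rep(1L, length(time))
  ll <- 0
  for (s in unique(strata)) {
    rows <- which(strata == s)
    lp <- drop(X[rows, , drop = FALSE] %*% beta)
    tt <- time[rows]; ee <- event[rows]
    for (tk in unique(tt[ee == 1])) {
      D <- which(tt == tk & ee == 1)
      R <- which(tt >= tk)
      ll <- ll + sum(lp[D]) - length(D) * log(sum(exp(lp[R])))
    }
  }
  ll
}

# Maximise the brute-force partial likelihood numerically.
brute_cox_fit <- function(time, event, X, strata = NULL) {
  p <- ncol(X)
  opt <- optim(rep(0, p), function(b) -brute_cox_loglik(b, time, event, X, strata),
               method = "BFGS", control = list(reltol = 1e-14, maxit = 500))
  opt$par
}

# Exhaustive-pair concordance oracle (double loop, no shortcuts).
brute_c_index <- function(risk, time, event, horizon) {
  th <- pmin(time, horizon)
  eh <- as.integer(event == 1 & time <= horizon)
  n <- length(risk)
  conc <- 0; usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      case <- if (th[i] < th[j] && eh[i] == 1) i
      else if (th[j] < th[i] && eh[j] == 1) j
      else if (th[i] == th[j] && eh[i] + eh[j] == 1) {
        if (eh[i] == 1) i else j
      } else next
      other <- if (case == i) j else i
      usable <- usable + 1
      conc <- conc + (risk[case] > risk[other]) + 0.5 * (risk[case] == risk[other])
    }
  }
  if (usable == 0) return(NA_real_)
  conc / usable
}

# A hand-written 5-patient registry exercising every eligibility rule.
toy_registry <- function() {
  patients <- tibble::tibble(
    id = c("A", "B", "C", "D", "E"),
    sex = c(0L, 1L, 0L, 1L, 0L),
    genotype_class = c(2L, 1L, 0L, 2L, 1L),
    birth = c(1980, 1982, 1975, 1985, 1978),
    diagnosis_age = c(0.5, 1, 2, 0.3, 25),
    registry_entry_age = c(25, 23, 30, 20, 28),
    death_age = c(28.5, NA, 36, NA, NA),
    transplant_age = c(NA, 25, NA, NA, NA),
    loss_age = c(NA, NA, NA, 24, NA))
  rv <- function(id, ages, fev1) {
    tibble::tibble(patient_id = id, age = ages, calendar_year = NA_real_,
                   fev1_pct = fev1, fvc_pct = 80, weight = 55, height = 165,
                   pseudomonas = 0L, staph_aureus = 0L, b_cepacia = 0L,
                   mrsa = 0L, cfrd = 0L, pancreatic_insufficiency = 1L,
                   iv_days_hospital = 0, iv_days_home = 0,
                   other_hospitalization = 0L)
  }
  reviews <- dplyr::bind_rows(
    rv("A", c(25, 26.2, 27.9), c(60, 55, 50)),
    rv("B", c(23, 24.5), c(40, 35)),
    rv("C", c(30, 31, 33.5), c(70, 68, 64)),
    rv("D", c(20, 21.5, 23.2), c(85, 84, 80)),
    rv("E", c(28, 28.9), c(75, 74)))
  reviews$calendar_year <- reviews$age +
    patients$birth[match(reviews$patient_id, patients$id)]
  structure(list(patients = patients, reviews = reviews,
                 config = NULL, latents = NULL), class = "registry")
}

# Small default-dynamics registry shared by several test files.
small_registry <- function(n = 400, seed = 123) {
  simulate_registry(registry_config(n_individuals = n, seed = seed))
}
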