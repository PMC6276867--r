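#' Configuration for the synthetic registry generator
#'
#' Builds the parameter set that defines the generative model for
#' [simulate_registry()]: a cohort of adults with cystic-fibrosis-like
#' longitudinal health records observed at roughly annual review visits over
#' a calendar study window, with death, lung transplant and (rare) loss to
#' follow-up driven by hazards that depend on the current latent covariate
#' values.
#'
#' The generative model is:
#' * Continuous variables (FEV1%, FVC%, weight, height) follow latent
#'   linear-in-age trajectories with correlated patient-level random
#'   intercepts and slopes; emitted review values add independent Gaussian
#'   measurement error (`resid_sd`), while the hazards act on the latent
#'   value.
#' * Binary states evolve as discrete-time Markov chains with per-visit
#'   (approximately annual) on/off transition probabilities; default initial
#'   prevalences sit at each chain's stationary distribution
#'   `p_on / (p_on + p_off)`, as expected for a prevalent adult cohort.
#' * Annual IV-antibiotic days are zero-inflated: zero with probability
#'   `1 - p_nonzero`, otherwise exponential with the given mean, redrawn at
#'   every review.
#' * The death hazard is piecewise-constant in age (`baseline_breaks`,
#'   `baseline_loghaz`) multiplied by `exp(sum coef * (value - ref))` over
#'   the current latent covariate values plus a calendar-year trend.
#'   Centering at the reference values `refs` is a reparameterisation of the
#'   baseline that keeps the log-hazard scale interpretable.
#' * Transplant competes with death; after transplant no further reviews are
#'   generated and the death hazard switches to a constant
#'   (`post_death_loghaz`).
#'
#' @param n_individuals Number of individuals to draw (>= 0).
#' @param study_window Calendar years `c(start, end)` of the observation
#'   window; observation is administratively censored at the end.
#' @param visit_interval Mean years between reviews.
#' @param visit_jitter_sd Standard deviation of the jitter on the interval.
#' @param birth_cohort_range Calendar years `c(min, max)` of births.
#' @param birth_cohort_shape Skew of the birth-year density within the
#'   range: births are drawn as `min + (max - min) * U^(1/shape)` with `U`
#'   uniform, so `shape = 1` is uniform and larger values put more mass on
#'   recent births.  The default 2 (linearly increasing density) emulates
#'   the age structure of an adult cystic-fibrosis registry cohort, which
#'   thins steeply with age through survivorship: landmark ages in the 40s
#'   are data-sparse relative to the 20s, as in the emulated registry.
#' @param sex_prob Probability of `sex = 1` (female).
#' @param genotype_probs Probabilities of carrying 0, 1 or 2 F508del alleles.
#' @param diagnosis Mixture for age of diagnosis: probability mass of
#'   infant diagnosis (exponential with `infant_mean` years) and an adult
#'   tail uniform on `c(adult_min, adult_max)`.
#' @param trajectories Named list (per continuous variable) of
#'   `intercept` (population value at age 18), `slope` (per year of age),
#'   `ri_sd`, `rs_sd`, `cor` (random intercept/slope), `resid_sd`
#'   (measurement error sd).
#' @param binary_states Named list (per binary variable) of `p_on`, `p_off`
#'   per-visit transition probabilities and optional `init` prevalence
#'   (default: stationary).
#' @param iv_days Zero-inflation parameters for the two IV-days variables.
#' @param hazard Death-hazard parameters: `baseline_breaks` (ages opening
#'   each piece), `baseline_loghaz` (log hazard per piece), `coefs` and
#'   `refs` (named, per covariate), and `calendar_coef` per year since
#'   `calendar_ref`.
#' @param transplant Transplant-hazard parameters: `log_rate`, `fev1_coef`
#'   on latent FEV1% minus `fev1_ref`, and the constant post-transplant
#'   death log-hazard `post_death_loghaz`.
#' @param loss_rate Constant hazard of loss to follow-up (near zero by
#'   default: registries of this kind have little loss to follow-up).
#' @param seed Mandatory integer seed; the generator is fully deterministic
#'   given the config.
#'
#' @return A validated list of class `"registry_config"`.
#' @seealso [simulate_registry()], [oracle_survival()]
#' @export
registry_config <- function(n_individuals = 1000,
                            study_window = c(2005, 2015),
                            visit_interval = 1.0,
                            visit_jitter_sd = 0.1,
                            birth_cohort_range = c(1960, 1995),
                            birth_cohort_shape = 2,
                            sex_prob = 0.48,
                            genotype_probs = c(0.12, 0.38, 0.50),
                            diagnosis = list(infant_prob = 0.85,
                                             infant_mean = 0.75,
                                             adult_min = 18,
                                             adult_max = 40),
                            trajectories = default_trajectories(),
                            binary_states = default_binary_states(),
                            iv_days = list(
                              hospital = list(p_nonzero = 0.35, mean_days = 14),
                              home = list(p_nonzero = 0.30, mean_days = 12)),
                            hazard = default_hazard(),
                            transplant = list(log_rate = log(0.002),
                                              fev1_coef = -0.05,
                                              fev1_ref = 75,
                                              post_death_loghaz = log(0.06)),
                            loss_rate = 1e-4,
                            seed = NULL) {
  cfg <- structure(
    list(n_individuals = n_individuals, study_window = study_window,
         visit_interval = visit_interval, visit_jitter_sd = visit_jitter_sd,
         birth_cohort_range = birth_cohort_range,
         birth_cohort_shape = birth_cohort_shape, sex_prob = sex_prob,
         genotype_probs = genotype_probs, diagnosis = diagnosis,
         trajectories = trajectories, binary_states = binary_states,
         iv_days = iv_days, hazard = hazard, transplant = transplant,
         loss_rate = loss_rate, seed = seed),
    class = "registry_config")
  validate_registry_config(cfg)
}

#' Default latent trajectory parameters
#'
#' Population intercepts are values at age 18; slopes are per year of age.
#' Defaults emulate adult cystic-fibrosis trajectories: lung function
#' declining by 1-2 percentage points per year with wide between-patient
#' spread, slowly drifting weight, essentially flat adult height.
#'
#' @return Named list of per-variable trajectory parameter lists.
#' @export
default_trajectories <- function() {
  list(
    fev1_pct = list(intercept = 75, slope = -1.5, ri_sd = 15, rs_sd = 0.8,
                    cor = -0.2, resid_sd = 4),
    fvc_pct  = list(intercept = 85, slope = -1.2, ri_sd = 14, rs_sd = 0.7,
                    cor = -0.2, resid_sd = 4),
    weight   = list(intercept = 58, slope = 0.15, ri_sd = 9, rs_sd = 0.25,
                    cor = 0, resid_sd = 1.5),
    height   = list(intercept = 166, slope = 0, ri_sd = 8, rs_sd = 0.02,
                    cor = 0, resid_sd = 0.5)
  )
}

#' Default binary-state Markov parameters
#'
#' Per-visit (approximately annual) on/off transition probabilities.
#' `init = NULL` starts each chain at its stationary prevalence
#' `p_on / (p_on + p_off)`.
#'
#' @return Named list of per-variable transition parameter lists.
#' @export
default_binary_states <- function() {
  list(
    pseudomonas = list(p_on = 0.10, p_off = 0.06, init = NULL),
    staph_aureus = list(p_on = 0.10, p_off = 0.18, init = NULL),
    b_cepacia = list(p_on = 0.004, p_off = 0.10, init = NULL),
    mrsa = list(p_on = 0.008, p_off = 0.15, init = NULL),
    cfrd = list(p_on = 0.020, p_off = 0.045, init = NULL),
    pancreatic_insufficiency = list(p_on = 0.045, p_off = 0.008, init = NULL),
    other_hospitalization = list(p_on = 0.20, p_off = 0.60, init = NULL)
  )
}

#' Default death-hazard parameters
#'
#' The hazard is a piecewise-constant baseline in age times
#' `exp(sum coef * (value - ref))` over the current latent covariate
#' values.  Effect directions follow the qualitative epidemiology of adult
#' cystic fibrosis: higher FEV1%, FVC% and weight protective; B. cepacia
#' infection, CF-related diabetes and hospital IV-antibiotic days harmful;
#' survival improving with calendar time.  The baseline itself is nearly
#' flat and low (about 0.3% per year at the reference covariate values):
#' most of the rise of mortality with age is produced by the declining
#' lung-function and weight trajectories acting through the coefficients,
#' giving typical all-in death rates around 1% per year in the mid-20s
#' rising to about 4% per year by age 50.
#'
#' @return List with `baseline_breaks`, `baseline_loghaz`, `coefs`, `refs`,
#'   `calendar_coef`, `calendar_ref`.
#' @export
default_hazard <- function() {
  list(
    baseline_breaks = c(18, 25, 35, 45),
    baseline_loghaz = log(c(0.0032, 0.0032, 0.0030, 0.0028)),
    coefs = c(fev1_pct = -0.030, fvc_pct = -0.012, weight = -0.020,
              height = 0, sex = 0.15, genotype_class = 0.10,
              diagnosis_age = -0.010,
              pseudomonas = 0.10, staph_aureus = 0, b_cepacia = 0.80,
              mrsa = 0.30, cfrd = 0.35, pancreatic_insufficiency = 0.20,
              iv_days_hospital = 0.020, iv_days_home = 0.005,
              other_hospitalization = 0.20),
    refs = c(fev1_pct = 75, fvc_pct = 85, weight = 58, height = 166,
             sex = 0, genotype_class = 0, diagnosis_age = 0,
             pseudomonas = 0, staph_aureus = 0, b_cepacia = 0, mrsa = 0,
             cfrd = 0, pancreatic_insufficiency = 0, iv_days_hospital = 0,
             iv_days_home = 0, other_hospitalization = 0),
    calendar_coef = -0.02,
    calendar_ref = 2010
  )
}

#' Time-constant covariate (proportional-hazards) validation scenario
#'
#' A [registry_config()] in which every covariate is constant within
#' patient after registry entry: trajectory slopes, random slopes and
#' measurement error are zero (between-patient spread via the random
#' intercepts remains), binary states are frozen at realistic prevalences
#' (the stationary distributions of the default dynamic chains), IV days
#' are drawn once at entry and never redrawn, and transplant and loss to
#' follow-up are switched off.  Under this scenario the landmark supermodel
#' with stratified baselines and LOCF covariates is exactly correctly
#' specified (the hazard is proportional within each landmark stratum with
#' the configured coefficients as the truth), which makes it the reference
#' scenario for parameter-recovery and prediction-oracle validation.
#'
#' @param n_individuals,seed See [registry_config()].
#' @param ... Further overrides passed to [registry_config()].
#' @return A validated `"registry_config"`.
#' @export
registry_config_constant <- function(n_individuals, seed, ...) {
  traj <- lapply(default_trajectories(), function(tr) {
    tr$slope <- 0; tr$rs_sd <- 0; tr$resid_sd <- 0; tr$cor <- 0
    tr
  })
  bs <- lapply(default_binary_states(), function(b) {
    list(p_on = 0, p_off = 0, init = stationary_prevalence(b))
  })
  args <- list(
    n_individuals = n_individuals, seed = seed,
    trajectories = traj, binary_states = bs,
    iv_days = list(hospital = list(p_nonzero = 0.35, mean_days = 14),
                   home = list(p_nonzero = 0.30, mean_days = 12),
                   redraw = FALSE),
    transplant = list(log_rate = -Inf, fev1_coef = 0, fev1_ref = 75,
                      post_death_loghaz = log(0.06)),
    loss_rate = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(registry_config, args)
}

validate_registry_config <- function(cfg) {
  if (!is.numeric(cfg$n_individuals) || length(cfg$n_individuals) != 1L ||
      is.na(cfg$n_individuals) || cfg$n_individuals < 0 ||
      cfg$n_individuals != round(cfg$n_individuals)) {
    abort_field("n_individuals", "must be a single non-negative integer.")
  }
  if (length(cfg$study_window) != 2L || !is.numeric(cfg$study_window) ||
      cfg$study_window[1] >= cfg$study_window[2]) {
    abort_field("study_window", "must be c(start, end) with start < end.")
  }
  if (!is.numeric(cfg$visit_interval) || cfg$visit_interval <= 0) {
    abort_field("visit_interval", "must be > 0.")
  }
  assert_nonneg(cfg$visit_jitter_sd, "visit_jitter_sd")
  if (length(cfg$birth_cohort_range) != 2L ||
      cfg$birth_cohort_range[1] > cfg$birth_cohort_range[2]) {
    abort_field("birth_cohort_range", "must be c(min, max) with min <= max.")
  }
  if (is.null(cfg$birth_cohort_shape) || !is.numeric(cfg$birth_cohort_shape) ||
      cfg$birth_cohort_shape <= 0) {
    abort_field("birth_cohort_shape", "must be positive.")
  }
  assert_prob(cfg$sex_prob, "sex_prob")
  if (length(cfg$genotype_probs) != 3L ||
      abs(sum(cfg$genotype_probs) - 1) > 1e-8 ||
      any(cfg$genotype_probs < 0)) {
    abort_field("genotype_probs", "must be 3 non-negative values summing to 1.")
  }
  assert_prob(cfg$diagnosis$infant_prob, "diagnosis$infant_prob")
  assert_nonneg(cfg$diagnosis$infant_mean, "diagnosis$infant_mean")
  for (v in names(cfg$trajectories)) {
    tr <- cfg$trajectories[[v]]
    for (f in c("intercept", "slope", "ri_sd", "rs_sd", "cor", "resid_sd")) {
      if (is.null(tr[[f]]) || !is.numeric(tr[[f]])) {
        abort_field(paste0("trajectories$", v, "$", f), "must be numeric.")
      }
    }
    assert_nonneg(tr$ri_sd, paste0("trajectories$", v, "$ri_sd"))
    assert_nonneg(tr$rs_sd, paste0("trajectories$", v, "$rs_sd"))
    assert_nonneg(tr$resid_sd, paste0("trajectories$", v, "$resid_sd"))
    if (abs(tr$cor) > 1) {
      abort_field(paste0("trajectories$", v, "$cor"), "must be in [-1, 1].")
    }
  }
  for (v in names(cfg$binary_states)) {
    bs <- cfg$binary_states[[v]]
    assert_prob(bs$p_on, paste0("binary_states$", v, "$p_on"))
    assert_prob(bs$p_off, paste0("binary_states$", v, "$p_off"))
    if (!is.null(bs$init)) assert_prob(bs$init, paste0("binary_states$", v, "$init"))
  }
  for (v in c("hospital", "home")) {
    assert_prob(cfg$iv_days[[v]]$p_nonzero, paste0("iv_days$", v, "$p_nonzero"))
    assert_nonneg(cfg$iv_days[[v]]$mean_days, paste0("iv_days$", v, "$mean_days"))
  }
  hz <- cfg$hazard
  if (length(hz$baseline_breaks) != length(hz$baseline_loghaz) ||
      is.unsorted(hz$baseline_breaks, strictly = TRUE)) {
    abort_field("hazard$baseline_breaks",
                "must be strictly increasing and match baseline_loghaz length.")
  }
  if (!all(names(hz$coefs) %in% names(hz$refs))) {
    abort_field("hazard$refs", "must name every covariate in hazard$coefs.")
  }
  assert_nonneg(cfg$loss_rate, "loss_rate")
  if (is.null(cfg$seed)) abort_field("seed", "is mandatory.")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    abort_field("seed", "must be a single integer.")
  }
  cfg
}

#' @export
print.registry_config <- function(x, ...) {
  cat("<registry_config>\n")
  cat("  n_individuals:", x$n_individuals, "\n")
  cat("  study window:", x$study_window[1], "-", x$study_window[2], "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Stationary prevalence of a binary on/off chain (used as default init).
stationary_prevalence <- function(bs) {
  if (!is.null(bs$init)) return(bs$init)
  if (bs$p_on + bs$p_off == 0) return(0)
  bs$p_on / (bs$p_on + bs$p_off)
}

# Names of the 13 time-dependent variables, in schema order.
time_dependent_vars <- function() {
  c("fev1_pct", "fvc_pct", "weight", "height",
    "pseudomonas", "staph_aureus", "b_cepacia", "mrsa",
    "cfrd", "pancreatic_insufficiency",
    "iv_days_hospital", "iv_days_home", "other_hospitalization")
}

# Baseline (time-fixed) predictor names.
baseline_vars <- function() c("sex", "genotype_class", "diagnosis_age")
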