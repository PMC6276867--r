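#' Truncated concordance index (Harrell pair counting)
#'
#' Discrimination at a horizon: all (time, event) pairs are
#' administratively censored at the horizon, a pair is evaluable iff the
#' smaller censored time is an event (or the times are tied with exactly
#' one event), and it is concordant iff the earlier-failing subject has
#' the higher predicted risk; ties in predicted risk count 1/2.
#'
#' @param data Records tibble.
#' @param risk Column of predicted risks (higher = worse prognosis).
#' @param time,event Outcome columns (years since landmark; 0/1).
#' @param horizon Evaluation horizon in years.
#' @return The concordant share among evaluable pairs, with the number of
#'   evaluable pairs in attribute `"n_pairs"`.  When no pair is evaluable
#'   the result is `NA` with a `"landmarker_undefined_metric"` warning
#'   (undefined, as distinct from 0).
#' @export
c_index <- function(data, risk = risk, time = time, event = event, horizon) {
  cindex_num(dplyr::pull(data, {{ risk }}),
             dplyr::pull(data, {{ time }}),
             dplyr::pull(data, {{ event }}), horizon)
}

cindex_num <- function(risk, time, event, horizon) {
  ## administrative truncation at the horizon defines the evaluable pairs;
  ## the pair counting itself (Harrell conventions: the pair is evaluable
  ## iff the smaller time is an event or tied with exactly one event; risk
  ## ties score 1/2) is delegated to survival::concordance
  th <- pmin(time, horizon)
  eh <- as.integer(event == 1 & time <= horizon)
  cc <- survival::concordance(survival::Surv(th, eh) ~ risk,
                              data = data.frame(th, eh, risk),
                              reverse = TRUE)
  usable <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (usable == 0 || is.na(cc$concordance)) {
    warn("no evaluable pairs: concordance undefined.",
         class = "landmarker_undefined_metric")
    return(structure(NA_real_, n_pairs = 0))
  }
  structure(unname(cc$concordance), n_pairs = usable)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator (via the survival package) returned as a tidy
#' right-continuous step curve.
#'
#' @param data Records tibble.
#' @param time,event Outcome columns.
#' @return Tibble of class `"km_curve"` with `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_curve <- function(data, time = time, event = event) {
  tt <- dplyr::pull(data, {{ time }})
  ee <- dplyr::pull(data, {{ event }})
  if (length(tt) == 0L) abort("empty input: no survival curve.")
  sf <- survival::survfit(survival::Surv(tt, ee) ~ 1)
  structure(tibble(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                   survival = sf$surv),
            class = c("km_curve", "tbl_df", "tbl", "data.frame"))
}

# Kaplan-Meier evaluated at times (right-continuous; left = left limit).
km_at <- function(curve, at, left = FALSE) {
  step_eval(curve$time, curve$survival, at, left = left, init = 1)
}

#' IPCW Brier score at a horizon
#'
#' Inverse-probability-of-censoring-weighted mean squared error between
#' the survival-status indicator at the horizon and the predicted survival
#' probability.  Subjects dead by the horizon are weighted by
#' `1/G(time-)`, survivors past the horizon by `1/G(horizon-)`, and
#' subjects censored before the horizon get weight 0, where `G` is the
#' Kaplan-Meier estimator of the censoring distribution on the evaluation
#' records (estimated within `group`, e.g. per landmark age, when given;
#' left limits keep records censored exactly at the horizon evaluable).
#'
#' @param data Records tibble.
#' @param pred Column of predicted survival probabilities at the horizon.
#' @param time,event Outcome columns.
#' @param horizon Evaluation horizon in years.
#' @param group Optional grouping column for the censoring distribution
#'   (per-landmark estimation in pooled evaluations).
#' @return The weighted Brier score (weighted sum over all records divided
#'   by the number of records).
#' @export
brier_score <- function(data, pred = pred, time = time, event = event,
                        horizon, group = NULL) {
  pp <- dplyr::pull(data, {{ pred }})
  tt <- dplyr::pull(data, {{ time }})
  ee <- dplyr::pull(data, {{ event }})
  gq <- rlang::enquo(group)
  gg <- if (rlang::quo_is_null(gq)) rep(1L, nrow(data))
        else dplyr::pull(data, !!gq)
  brier_num(pp, tt, ee, horizon, gg)
}

brier_num <- function(pred, time, event, horizon, group = NULL) {
  if (any(pred < 0 | pred > 1)) abort("predictions must be in [0, 1].")
  group <- group %||% rep(1L, length(pred))
  total <- 0; n_total <- length(pred)
  for (g in unique(group)) {
    rows <- which(group == g)
    tt <- time[rows]; ee <- event[rows]; pp <- pred[rows]
    cens_curve <- km_curve(tibble(time = tt, event = 1 - ee))
    dead <- ee == 1 & tt <= horizon
    alive <- tt > horizon | (tt == horizon & ee == 0)
    w <- numeric(length(rows))
    if (any(dead)) w[dead] <- 1 / km_at(cens_curve, tt[dead], left = TRUE)
    if (any(alive)) w[alive] <- 1 / km_at(cens_curve, rep(horizon, sum(alive)),
                                          left = TRUE)
    if (any(!is.finite(w))) {
      abort(paste("censoring survival reaches 0 before the horizon;",
                  "reduce the horizon."))
    }
    surv_ind <- as.numeric(alive)
    total <- total + sum(w * (surv_ind - pp)^2)
  }
  total / n_total
}

#' Percentage reduction in prediction error
#'
#' `100 * (1 - brier_model / brier_reference)`, the improvement of a model
#' over a reference predictor (here the per-landmark Kaplan-Meier survival
#' probability applied to every record).  Negative values (model worse
#' than reference) are allowed.
#'
#' @param brier_model,brier_reference Brier scores.
#' @return Percentage reduction.
#' @export
percent_reduction <- function(brier_model, brier_reference) {
  if (!is.finite(brier_reference) || brier_reference <= 0) {
    abort("`brier_reference` must be positive.")
  }
  100 * (1 - brier_model / brier_reference)
}
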