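#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_line
#'   geom_abline geom_errorbar geom_col labs facet_wrap ylim
NULL

#' @export
ggplot2::autoplot

#' Plot a predicted survival curve
#'
#' @param object A `"survival_curve"` from [predict_survival()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.survival_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$survival)) +
    geom_step() +
    ylim(0, 1) +
    labs(x = "Years since landmark", y = "Predicted survival probability")
}

#' Plot a calibration table against the identity line
#'
#' @param object A `"calibration_table"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_table <- function(object, ...) {
  ggplot(object, aes(x = .data$mean_predicted, y = .data$observed)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_errorbar(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                  width = 0) +
    geom_point() +
    labs(x = "Mean predicted survival probability",
         y = "Observed (Kaplan-Meier) survival probability",
         title = sprintf("Calibration at %s years", attr(object, "horizon")))
}

#' Plot per-landmark performance profiles
#'
#' @param object A `"performance_report"`.
#' @param metric `"c_index"` or `"brier"`.
#' @param ... Unused.
#' @return A ggplot of the metric against landmark age, one panel per
#'   horizon.
#' @export
autoplot.performance_report <- function(object, metric = c("c_index", "brier"),
                                        ...) {
  metric <- match.arg(metric)
  ggplot(object$per_landmark,
         aes(x = .data$L, y = .data[[metric]])) +
    geom_line() + geom_point(size = 0.8) +
    facet_wrap(~horizon, labeller = ggplot2::label_both) +
    labs(x = "Landmark age (years)",
         y = if (metric == "c_index") "C-index" else "Brier score")
}

#' Distribution of predicted survival probabilities
#'
#' Counts of individuals by bins of predicted survival probability at each
#' horizon, per landmark age: the summary used to show how a dynamic
#' prediction model separates a population into prognosis groups.
#'
#' @param fits A fitted variant.
#' @param records Records to predict for.
#' @param horizons Horizons in years.
#' @param breaks Probability bin edges.
#' @return Tibble of class `"risk_distribution"`: `L`, `horizon`, `bin`,
#'   `n`, `prop`.
#' @export
risk_distribution <- function(fits, records, horizons = c(2, 5, 10),
                              breaks = seq(0, 1, by = 0.05)) {
  out <- list()
  for (h in horizons) {
    pred <- predict_variant_at(fits, records, h)
    for (l in sort(unique(records$L))) {
      rows <- which(records$L == l)
      bins <- cut(pred[rows], breaks, include.lowest = TRUE)
      tab <- table(bins)
      out[[length(out) + 1L]] <- tibble(
        L = l, horizon = h, bin = names(tab), n = as.integer(tab),
        prop = as.integer(tab) / length(rows))
    }
  }
  structure(bind_rows(out),
            class = c("risk_distribution", "tbl_df", "tbl", "data.frame"))
}

#' @export
autoplot.risk_distribution <- function(object, ...) {
  ggplot(object, aes(x = .data$bin, y = .data$prop)) +
    geom_col() +
    facet_wrap(~ .data$L + .data$horizon, labeller = ggplot2::label_both) +
    labs(x = "Predicted survival probability", y = "Proportion of individuals") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
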