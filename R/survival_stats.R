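# Kaplan-Meier estimation and the two-group log-rank test used for the
# larval infection experiments. The product-limit and log-rank computations
# are delegated to the survival package; this module adapts them to the
# (subject_id, group, time_days, event) records the pipeline uses.

#' Kaplan-Meier survivor curve for one group
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i/n_i)`; subjects
#' censored at an event time are counted at risk for that time (censoring
#' processed after the event). With no censoring this equals the empirical
#' survivor function.
#'
#' @param data Survival data.frame: `subject_id`, `group`, `time_days`,
#'   `event` (1 = death, 0 = censored).
#' @param group Group label to estimate (default: all records).
#' @return A `km_curve` data.frame: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, with the final estimate in attribute
#'   `final_survival`.
#' @export
km_estimate <- function(data, group = NULL) {
  if (!is.null(group)) {
    data <- data[data$group == group, , drop = FALSE]
    if (!nrow(data)) stop("group '", group, "' not present")
  }
  if (!nrow(data)) stop("empty survival dataset")
  if (any(data$time_days <= 0)) stop("time_days must be positive")
  fit <- survival::survfit(
    survival::Surv(data$time_days, data$event) ~ 1,
    conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  attr(out, "final_survival") <- if (nrow(out)) out$survival[nrow(out)] else 1
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Chi-square statistic `(sum(O - E))^2 / sum(V)` over the shared event
#' times, with expectations and hypergeometric variances from the combined
#' risk sets; the p-value is the df = 1 upper chi-square tail. A dataset
#' with no information (zero total variance) yields chi-square 0 and p = 1
#' with a warning rather than an error.
#'
#' @param data Survival data.frame (see [km_estimate()]).
#' @param group_a,group_b The two group labels to compare.
#' @return data.frame: `chi_square`, `df`, `p_value`.
#' @export
logrank_test <- function(data, group_a, group_b) {
  sel <- data$group %in% c(group_a, group_b)
  d <- data[sel, , drop = FALSE]
  for (g in c(group_a, group_b))
    if (!any(d$group == g)) stop("group '", g, "' not present")
  if (sum(d$event) < 1) stop("log-rank requires at least one event")
  chisq <- tryCatch({
    sd_fit <- survival::survdiff(
      survival::Surv(d$time_days, d$event) ~ d$group)
    unname(sd_fit$chisq)
  }, error = function(e) NaN)
  if (!is.finite(chisq)) {
    warning("log-rank has zero variance (no information); p = 1")
    chisq <- 0
  }
  data.frame(chi_square = chisq, df = 1,
             p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}
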