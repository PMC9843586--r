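#' Kaplan-Meier product-limit estimate
#'
#' Thin tidy wrapper around [survival::survfit()]: censored times reduce the
#' risk set without creating a step. With no censoring the estimate equals
#' the empirical survival function exactly.
#'
#' @param times Positive follow-up times.
#' @param events Event indicator (1 = death observed, 0 = censored).
#' @return Tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0)) abort("Negative survival time.")
  fit <- survfit(Surv(times, events) ~ 1)
  tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
}

#' Two-group log-rank test
#'
#' Standard two-sided log-rank test via [survival::survdiff()], with the
#' p-value from a chi-square reference on 1 degree of freedom.
#'
#' @param times,events Survival outcome.
#' @param groups Binary group labels (two levels required).
#' @return List with `statistic`, `df` and `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  if (length(unique(groups)) < 2) abort("Two groups are required.")
  if (sum(events) < 1) abort("At least one event is required.")
  sd <- survdiff(Surv(times, events) ~ groups)
  stat <- unname(sd$chisq)
  list(statistic = stat, df = 1L, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Harrell's concordance index for a risk score
#'
#' Probability that, of a comparable pair of samples (ordering of event times
#' determinable under censoring), the one with the higher risk score dies
#' earlier. Tied scores count one half. Computed via
#' [survival::concordance()] with the risk-score convention
#' (`reverse = TRUE`), so `scores = -times` with no censoring gives C = 1.
#'
#' @param scores Numeric risk scores (higher = riskier).
#' @param times,events Survival outcome.
#' @return Concordance index in \[0, 1\].
#' @export
concordance_index <- function(scores, times, events) {
  fit <- concordance(Surv(times, events) ~ scores, reverse = TRUE)
  n_comparable <- sum(fit$count[c("concordant", "discordant", "tied.x")])
  if (n_comparable == 0 || is.na(fit$concordance)) {
    abort("No comparable sample pairs under censoring.")
  }
  unname(fit$concordance)
}

#' ROC AUC for death by a fixed horizon
#'
#' Cases are samples with an observed event at or before `horizon`; controls
#' are samples still under observation beyond `horizon` (whether or not they
#' die later); samples censored at or before the horizon are excluded, since
#' their case status is unknown. The AUC is the rank statistic of the scores
#' (tied scores count one half), i.e. the probability that a random case
#' outscores a random control.
#'
#' @param scores Numeric risk scores (higher = riskier).
#' @param times,events Survival outcome.
#' @param horizon Prediction horizon, in the time units of `times`.
#' @return AUC in \[0, 1\].
#' @export
auc_at_horizon <- function(scores, times, events, horizon) {
  case <- events == 1 & times <= horizon
  control <- times > horizon
  keep <- case | control
  n1 <- sum(case)
  n0 <- sum(control)
  if (n1 == 0 || n0 == 0) {
    abort(sprintf(
      "Horizon %g has %d case(s) and %d control(s); both must be positive.",
      horizon, n1, n0
    ))
  }
  r <- rank(scores[keep])
  (sum(r[case[keep]]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization via [survival::coxph()] with the Efron
#' approximation for tied event times. Returns the hazard ratio with its Wald
#' 95% confidence interval. Monotone partial likelihood (complete separation,
#' diverging coefficient) is flagged rather than silently reported.
#'
#' @param covariate Numeric or binary covariate (must vary).
#' @param times,events Survival outcome (at least one event).
#' @return Tibble with columns `log_hr`, `hr`, `conf_low`, `conf_high`,
#'   `se`, `p_value`, `n`, `n_event`, `monotone_likelihood`.
#' @export
cox_univariate_hr <- function(covariate, times, events) {
  if (length(unique(covariate)) < 2) abort("Covariate is constant.")
  if (sum(events) < 1) abort("At least one event is required.")
  monotone <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(times, events) ~ covariate, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)
  beta <- unname(coef(fit))
  se <- unname(sqrt(diag(fit$var)))[1]
  if (!is.finite(beta) || abs(beta) > 15) monotone <- TRUE
  tibble(
    log_hr = beta,
    hr = exp(beta),
    conf_low = exp(beta - 1.96 * se),
    conf_high = exp(beta + 1.96 * se),
    se = se,
    p_value = unname(sm$coefficients[1, "Pr(>|z|)"]),
    n = length(times),
    n_event = sum(events),
    monotone_likelihood = monotone
  )
}

#' Evaluate a risk model against survival outcomes
#'
#' Assembles the full prognostic report for a classified cohort: Kaplan-Meier
#' curves per risk group, the two-group log-rank test, Harrell's C-index,
#' ROC AUC at each requested horizon and the univariate Cox hazard ratio of
#' the high-risk group. When only binary labels are available they are
#' evaluated as scores in \{0, 1\} (high = 1).
#'
#' @param risk Tibble with `sample_id`, a `risk` column (`"high"`/`"low"`)
#'   and optionally a numeric `score` or `vote_fraction` column used as the
#'   continuous score.
#' @param clinical Clinical tibble with `sample_id`, `os_time`, `event`.
#' @param horizons Numeric horizons for fixed-time AUC, in the units of
#'   `os_time` (default `c(1, 3, 5)`).
#' @return A `survival_eval` object with components `km`, `logrank`,
#'   `cindex`, `auc`, `cox` and `counts`; see [tidy.survival_eval()].
#' @export
evaluate_model <- function(risk, clinical, horizons = c(1, 3, 5)) {
  dat <- dplyr::inner_join(risk, clinical, by = "sample_id") |>
    filter(!is.na(.data$os_time) & !is.na(.data$event))
  if (nrow(dat) == 0) abort("No samples with both risk labels and survival data.")
  score <- if ("score" %in% colnames(dat)) {
    dat$score
  } else if ("vote_fraction" %in% colnames(dat)) {
    dat$vote_fraction
  } else {
    as.numeric(dat$risk == "high")
  }
  high <- as.integer(dat$risk == "high")

  km <- dat |>
    group_by(.data$risk) |>
    dplyr::reframe(km_estimate(.data$os_time, .data$event)) |>
    ungroup()

  logrank <- if (length(unique(high)) == 2) {
    logrank_test(dat$os_time, dat$event, high)
  } else {
    list(statistic = NA_real_, df = 1L, p_value = NA_real_)
  }
  cindex <- concordance_index(score, dat$os_time, dat$event)
  auc <- tibble(
    horizon = horizons,
    auc = purrr::map_dbl(
      horizons,
      function(h) auc_at_horizon(score, dat$os_time, dat$event, h)
    )
  )
  cox <- if (length(unique(high)) == 2) {
    cox_univariate_hr(high, dat$os_time, dat$event)
  } else {
    NULL
  }
  structure(
    list(
      km = km,
      logrank = logrank,
      cindex = cindex,
      auc = auc,
      cox = cox,
      counts = list(
        n = nrow(dat),
        n_high = sum(high),
        n_low = sum(high == 0),
        n_event = sum(dat$event)
      ),
      horizons = horizons
    ),
    class = "survival_eval"
  )
}

#' @export
print.survival_eval <- function(x, ...) {
  cat(sprintf(
    "<survival_eval> n = %d (%d high / %d low risk), %d events\n",
    x$counts$n, x$counts$n_high, x$counts$n_low, x$counts$n_event
  ))
  cat(sprintf(
    "  C-index %.3f; log-rank p %s\n",
    x$cindex, format(x$logrank$p_value, digits = 3)
  ))
  if (!is.null(x$cox)) {
    cat(sprintf(
      "  HR (high vs low) %.3f [%.3f, %.3f]\n",
      x$cox$hr, x$cox$conf_low, x$cox$conf_high
    ))
  }
  for (i in seq_len(nrow(x$auc))) {
    cat(sprintf("  AUC at t=%g: %.3f\n", x$auc$horizon[i], x$auc$auc[i]))
  }
  invisible(x)
}

#' Tidy / summarize a survival evaluation report
#'
#' `tidy()` returns one row per metric (long format); `glance()` returns a
#' one-row summary; `autoplot()` draws the Kaplan-Meier curves per risk
#' group.
#'
#' @param x,object A `survival_eval` object.
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @method tidy survival_eval
#' @export
tidy.survival_eval <- function(x, ...) {
  bind_rows(
    tibble(metric = "cindex", horizon = NA_real_, value = x$cindex),
    tibble(metric = "logrank_p", horizon = NA_real_, value = x$logrank$p_value),
    tibble(metric = "auc", horizon = x$auc$horizon, value = x$auc$auc),
    if (!is.null(x$cox)) {
      tibble(
        metric = c("hr", "hr_conf_low", "hr_conf_high", "cox_p"),
        horizon = NA_real_,
        value = c(x$cox$hr, x$cox$conf_low, x$cox$conf_high, x$cox$p_value)
      )
    }
  )
}

#' @rdname tidy.survival_eval
#' @method glance survival_eval
#' @export
glance.survival_eval <- function(x, ...) {
  tibble(
    n = x$counts$n,
    n_event = x$counts$n_event,
    cindex = x$cindex,
    logrank_p = x$logrank$p_value,
    hr = if (is.null(x$cox)) NA_real_ else x$cox$hr
  )
}

#' @rdname tidy.survival_eval
#' @method autoplot survival_eval
#' @export
autoplot.survival_eval <- function(object, ...) {
  km <- object$km |>
    group_by(.data$risk) |>
    dplyr::group_modify(function(df, key) {
      bind_rows(tibble(
        time = 0, n_risk = max(df$n_risk), n_event = 0L,
        n_censor = 0L, survival = 1
      ), df)
    }) |>
    ungroup()
  ggplot2::ggplot(km, ggplot2::aes(
    x = .data$time, y = .data$survival, colour = .data$risk
  )) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time", y = "Survival probability", colour = "Risk group",
      title = "Kaplan-Meier curves by risk group"
    )
}

#' Serialize an evaluation report to JSON
#'
#' @param report A `survival_eval` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  obj <- list(
    schema_version = pairsig_schema_version,
    type = "survival_eval",
    km = as.list(report$km),
    logrank = report$logrank,
    cindex = report$cindex,
    auc = as.list(report$auc),
    cox = if (is.null(report$cox)) NULL else as.list(report$cox),
    counts = report$counts,
    horizons = report$horizons
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a serialized evaluation report
#'
#' @param path Path to a JSON file written by [write_eval_report()].
#' @return A `survival_eval` object.
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(obj$schema_version), pairsig_schema_version) ||
    !identical(obj$type, "survival_eval")) {
    abort("Not a supported survival_eval JSON file.")
  }
  structure(
    list(
      km = as_tibble(obj$km),
      logrank = as.list(obj$logrank),
      cindex = obj$cindex,
      auc = as_tibble(obj$auc),
      cox = if (is.null(obj$cox)) NULL else as_tibble(obj$cox),
      counts = as.list(obj$counts),
      horizons = obj$horizons
    ),
    class = "survival_eval"
  )
}
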