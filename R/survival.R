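#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function under right censoring,
#' with Greenwood-based confidence intervals on the complementary log-log
#' scale (`conf.type = "log-log"`), the transformation that keeps the bands
#' inside \[0, 1\]. Subjects censored exactly at an event time remain in the
#' risk set for that time (the standard convention).
#'
#' @param data Data frame with one row per subject.
#' @param time,event Column names (unquoted) holding the follow-up time and
#'   the event indicator (1 = event, 0 = censored). Default `time`, `event`.
#' @param conf_level Confidence level, default 0.95.
#'
#' @return A tibble with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `estimate`, `conf_low`, `conf_high`.
#' @export
#'
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1))
#' km_estimate(d)
km_estimate <- function(data, time = time, event = event, conf_level = 0.95) {
  tm <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ event }})
  if (length(tm) < 1L) abort("Need at least one subject.")
  if (any(!is.finite(tm)) || any(tm < 0)) abort("Times must be finite and >= 0.")
  if (!all(ev %in% c(0, 1))) abort("`event` must be 0 or 1.")
  fit <- survival::survfit(survival::Surv(tm, ev) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    estimate = fit$surv,
    conf_low = ifelse(is.na(fit$lower), NA_real_, fit$lower),
    conf_high = ifelse(is.na(fit$upper), NA_real_, fit$upper)
  )
}

#' Two-group log-rank test
#'
#' Unweighted Mantel-Haenszel log-rank test: at each distinct event time
#' the observed events in group 1 are compared with their hypergeometric
#' expectation given the risk sets, and `(sum(O - E))^2 / sum(V)` is
#' referred to a chi-square distribution with 1 degree of freedom.
#'
#' @inheritParams km_estimate
#' @param group Column (unquoted) with exactly two distinct group labels.
#'
#' @return One-row tibble: `statistic` (chi-square), `df`, `p_value`,
#'   `n_group1`, `n_group2`, `method`.
#' @export
logrank_test <- function(data, group, time = time, event = event) {
  tm <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ event }})
  gr <- dplyr::pull(data, {{ group }})
  if (!all(ev %in% c(0, 1))) abort("`event` must be 0 or 1.")
  lev <- sort(unique(gr))
  if (length(lev) != 2L) {
    abort(sprintf("`group` must have exactly 2 non-empty levels, got %d.",
                  length(lev)))
  }
  if (sum(ev) == 0L) abort("No events: the log-rank test is undefined.")
  sd <- survival::survdiff(survival::Surv(tm, ev) ~ gr)
  chisq <- unname(sd$chisq)
  tibble::tibble(
    statistic = chisq, df = 1L,
    p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
    n_group1 = sum(gr == lev[1]), n_group2 = sum(gr == lev[2]),
    method = "Mantel-Haenszel log-rank"
  )
}

#' Cox proportional-hazards fit for a binary status covariate
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling) for a single
#' binary covariate and reports the hazard ratio with a Wald confidence
#' interval and p-value. Monotone-likelihood / non-convergence is flagged
#' via `converged` instead of returning a runaway estimate.
#'
#' @inheritParams km_estimate
#' @param status Column (unquoted) with the binary covariate (0/1 or a
#'   two-level factor); the hazard ratio is for level 1 vs level 0.
#' @param conf_level Confidence level for the Wald interval.
#'
#' @return An object of class `resistm_cox`; see [tidy.resistm_cox()] and
#'   [glance.resistm_cox()].
#' @export
cox_fit <- function(data, status, time = time, event = event,
                    conf_level = 0.95) {
  tm <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ event }})
  st <- dplyr::pull(data, {{ status }})
  if (!all(ev %in% c(0, 1))) abort("`event` must be 0 or 1.")
  if (length(unique(st)) < 2L) abort("No variation in status covariate.")
  if (sum(ev) == 0L) abort("All subjects censored: Cox model is undefined.")
  st <- as.numeric(factor(st)) - 1

  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(tm, ev) ~ st, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|coefficient may be infinite",
                conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit, conf.int = conf_level)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  log_hr <- unname(stats::coef(fit))
  se <- unname(sqrt(fit$var[1, 1]))
  structure(
    list(
      log_hr = log_hr, hr = exp(log_hr), se = se,
      ci_lower = exp(log_hr - z * se), ci_upper = exp(log_hr + z * se),
      p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
      conf_level = conf_level,
      converged = converged && is.finite(log_hr),
      n = fit$n, n_events = fit$nevent,
      loglik = fit$loglik, fit = fit
    ),
    class = "resistm_cox"
  )
}

#' @export
print.resistm_cox <- function(x, ...) {
  cat(sprintf("<resistm_cox> HR = %.3f (%d%% CI %.3f-%.3f), p = %.3g, %d events / %d subjects%s\n",
              x$hr, round(100 * x$conf_level), x$ci_lower, x$ci_upper,
              x$p_value, x$n_events, x$n,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A `resistm_cox` object.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate` (log hazard ratio),
#'   `std.error`, `statistic`, `p.value`, `hr`, `conf.low`, `conf.high`
#'   (hazard-ratio scale).
#' @export
tidy.resistm_cox <- function(x, ...) {
  tibble::tibble(
    term = "status", estimate = x$log_hr, std.error = x$se,
    statistic = x$log_hr / x$se, p.value = x$p_value,
    hr = x$hr, conf.low = x$ci_lower, conf.high = x$ci_upper
  )
}

#' Glance at a Cox fit
#'
#' @inheritParams tidy.resistm_cox
#' @return One-row tibble with `n`, `n_events`, `logLik`, `converged`.
#' @export
glance.resistm_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 logLik = x$loglik[2], converged = x$converged)
}

#' Score, median-split and compare survival between signature risk groups
#'
#' The full single-signature stratification used for cohort Kaplan-Meier
#' panels: scores every sample with [score_signature], splits at the cohort
#' median with [assign_status], maps the split to risk groups via the
#' score's polarity ([risk_groups]), and compares the groups with
#' per-group Kaplan-Meier curves, the log-rank test, and a Cox
#' proportional-hazards model of risk-group membership (HR > 1 means the
#' signature-defined risk group does worse).
#'
#' @param expr Expression table (tibble with `gene` column).
#' @param clinical Clinical tibble with `sample_id`, `time`, `event`.
#' @param signature A [gene_signature] (or name from
#'   [builtin_signatures()]).
#' @param method Scoring method, as in [score_signature].
#' @param conf_level Confidence level for intervals.
#' @param strict Missing-gene policy passed to [score_signature].
#'
#' @return A `stratification_report` with elements `scores`, `status`,
#'   `km` (per-group curves, long tibble), `logrank`, `cox`, `group_sizes`;
#'   supports [tidy()], [glance()] and [autoplot()].
#' @export
#'
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_samples = 120, seed = 3))
#' rep <- stratified_km_report(cohort$expression, cohort$clinical, "RESIST-M")
#' glance(rep)
stratified_km_report <- function(expr, clinical, signature,
                                 method = c("reflected_median", "mean"),
                                 conf_level = 0.95, strict = FALSE) {
  method <- match.arg(method)
  if (is.character(signature)) {
    registry <- builtin_signatures()
    if (!signature %in% names(registry)) {
      abort(sprintf("Unknown signature '%s'; see builtin_signatures().", signature))
    }
    signature <- registry[[signature]]
  }
  validate_clinical(clinical)
  check_matched_ids(expr, clinical)

  scores <- score_signature(expr, signature, method = method, strict = strict)
  status <- risk_groups(assign_status(scores))
  joined <- dplyr::inner_join(status, clinical, by = "sample_id")
  grp <- factor(ifelse(joined$risk == 1L, "high-risk", "low-risk"),
                levels = c("low-risk", "high-risk"))

  km <- dplyr::bind_rows(lapply(levels(grp), function(g) {
    dplyr::mutate(
      km_estimate(joined[grp == g, , drop = FALSE], conf_level = conf_level),
      group = g, .before = 1)
  }))
  lr <- logrank_test(dplyr::mutate(joined, .grp = grp), group = .grp)
  cox <- cox_fit(dplyr::mutate(joined, .risk = joined$risk), status = .risk,
                 conf_level = conf_level)

  structure(
    list(
      signature = signature$name, method = method,
      scores = scores, status = status,
      km = km, logrank = lr, cox = cox,
      group_sizes = c(`low-risk` = sum(grp == "low-risk"),
                      `high-risk` = sum(grp == "high-risk")),
      conf_level = conf_level
    ),
    class = "stratification_report"
  )
}

#' @export
print.stratification_report <- function(x, ...) {
  cat(sprintf("<stratification_report> %s (%s)\n", x$signature, x$method))
  cat(sprintf("  groups: %d high-risk / %d low-risk\n",
              x$group_sizes[["high-risk"]], x$group_sizes[["low-risk"]]))
  cat(sprintf("  log-rank chi-square = %.3f, p = %.3g\n",
              x$logrank$statistic, x$logrank$p_value))
  print(x$cox)
  invisible(x)
}

#' @rdname stratified_km_report
#' @param x A `stratification_report`.
#' @param ... Unused.
#' @export
tidy.stratification_report <- function(x, ...) x$km

#' @rdname stratified_km_report
#' @export
glance.stratification_report <- function(x, ...) {
  tibble::tibble(
    signature = x$signature, method = x$method,
    n_high = unname(x$group_sizes[["high-risk"]]),
    n_low = unname(x$group_sizes[["low-risk"]]),
    logrank_chisq = x$logrank$statistic, logrank_p = x$logrank$p_value,
    hr = x$cox$hr, hr_conf_low = x$cox$ci_lower, hr_conf_high = x$cox$ci_upper,
    cox_p = x$cox$p_value, cox_converged = x$cox$converged
  )
}

#' Kaplan-Meier plot of a stratification report
#'
#' @param object A `stratification_report`.
#' @param ... Unused.
#' @return A ggplot with per-group step curves and log-log CI ribbons.
#' @export
autoplot.stratification_report <- function(object, ...) {
  km <- object$km
  # anchor curves at S(0) = 1 for plotting
  origin <- dplyr::distinct(km, .data$group) |>
    dplyr::mutate(time = 0, estimate = 1, conf_low = 1, conf_high = 1)
  km2 <- dplyr::bind_rows(origin, km)
  ggplot2::ggplot(km2, ggplot2::aes(.data$time, .data$estimate,
                                    colour = .data$group, fill = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.15, colour = NA, stat = StatStepribbon,
                         na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("%s (%s): log-rank p = %.2g", object$signature,
                      object$method, object$logrank$p_value),
      x = "Time", y = "Survival probability",
      colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

# step-ribbon stat for KM confidence bands
StatStepribbon <- ggplot2::ggproto(
  "StatStepribbon", ggplot2::Stat,
  compute_group = function(data, scales, ...) {
    data <- data[order(data$x), , drop = FALSE]
    if (nrow(data) <= 1) return(data)
    n <- nrow(data)
    xs <- rep(seq_len(n), each = 2)[-2 * n]
    ys <- c(1, rep(2:n, each = 2))
    out <- data[xs, , drop = FALSE]
    out$ymin <- data$ymin[ys]
    out$ymax <- data$ymax[ys]
    out
  },
  required_aes = c("x", "ymin", "ymax")
)
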