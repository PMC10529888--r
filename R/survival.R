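#' Univariable Cox proportional-hazards fit
#'
#' Fits a single continuous covariate by partial likelihood with Breslow
#' handling of tied event times, and reports the Wald estimate on the
#' log-hazard scale with its 95% confidence interval
#' `exp(beta -/+ 1.96 se)`. The covariate enters untransformed, so the
#' hazard ratio is per unit (e.g. per %/min-equivalent of estimated
#' remnant function).
#'
#' @param data Data frame containing the survival columns.
#' @param covariate Name of the covariate column (character).
#' @param time,event Names of the time (days, > 0) and event indicator
#'   (`TRUE` = death observed) columns.
#' @return An `erlf_cox` object; see [tidy.erlf_cox()] and
#'   [glance.erlf_cox()].
#' @examples
#' cohort <- generate_cohort(generator_params(n = 200, seed = 7))
#' cohort <- score_cohort(cohort)
#' cox_univariable(cohort, "erlf")
#' @export
cox_univariable <- function(data, covariate, time = "time_days", event = "event") {
  for (col in c(covariate, time, event)) {
    if (!col %in% names(data)) abort(sprintf("Column `%s` not found.", col))
  }
  x <- data[[covariate]]
  t <- data[[time]]
  ev <- as.logical(data[[event]])
  if (anyNA(x) || anyNA(t) || anyNA(ev)) abort("Missing values are not allowed.")
  if (any(t <= 0)) abort("Survival times must be strictly positive.")
  if (sum(ev) < 2) abort("At least 2 observed events are required.")
  if (var(x) == 0) abort("Covariate has zero variance; the hazard ratio is unidentifiable.")

  fit <- survival::coxph(survival::Surv(t, ev) ~ x, ties = "breslow")
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se)) {
    abort("Cox fit did not converge to a finite estimate.")
  }
  structure(
    list(covariate = covariate, beta = beta, se = se,
         hr = exp(beta),
         ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
         p_value = 2 * pnorm(-abs(beta / se)),
         n = length(t), n_events = sum(ev),
         converged = fit$iter < 20),
    class = "erlf_cox"
  )
}

#' @export
print.erlf_cox <- function(x, ...) {
  cat(sprintf("Univariable Cox fit: %s (n = %d, events = %d)\n",
              x$covariate, x$n, x$n_events))
  cat(sprintf("  HR %.3f per unit (95%% CI %.3f; %.3f), p = %.4g\n",
              x$hr, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Tidiers for univariable Cox fits
#'
#' @param x An `erlf_cox` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per term with the log-hazard
#'   estimate, its standard error, Wald statistic and p-value, and the
#'   hazard ratio with 95% confidence bounds; `glance()` returns the fit
#'   summary (n, events, convergence).
#' @export
tidy.erlf_cox <- function(x, ...) {
  tibble::tibble(term = x$covariate, estimate = x$beta, std.error = x$se,
                 statistic = x$beta / x$se, p.value = x$p_value,
                 hr = x$hr, conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname tidy.erlf_cox
#' @export
glance.erlf_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, converged = x$converged)
}

#' Kaplan-Meier product-limit estimator
#'
#' Censored times reduce the risk set without producing a step. The
#' returned curve includes an anchor row at time 0 with survival 1 per
#' stratum.
#'
#' @inheritParams cox_univariable
#' @param stratum Optional name of a stratification column; one curve
#'   per non-empty stratum.
#' @return A tibble of class `erlf_km` with columns `stratum`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @examples
#' kaplan_meier(data.frame(time_days = c(3, 5, 7, 9), event = TRUE))
#' @export
kaplan_meier <- function(data, time = "time_days", event = "event",
                         stratum = NULL) {
  if (nrow(data) == 0) abort("`data` must be non-empty.")
  t <- data[[time]]
  ev <- as.logical(data[[event]])
  if (is.null(t) || is.null(ev)) abort("Time/event columns not found.")
  if (any(t <= 0) || anyNA(t) || anyNA(ev)) {
    abort("Survival times must be positive and complete.")
  }
  if (is.null(stratum)) {
    grp <- factor(rep("all", length(t)))
  } else {
    grp <- data[[stratum]]
    if (is.null(grp)) abort(sprintf("Column `%s` not found.", stratum))
    grp <- droplevels(factor(grp))
  }
  curves <- purrr::map_dfr(levels(grp), function(g) {
    sel <- grp == g
    sf <- survival::survfit(survival::Surv(t[sel], ev[sel]) ~ 1)
    tibble::tibble(
      stratum = g,
      time = c(0, sf$time),
      n_risk = c(sum(sel), sf$n.risk),
      n_event = c(0, sf$n.event),
      n_censor = c(0, sf$n.censor),
      survival = c(1, sf$surv)
    )
  })
  tibble::new_tibble(curves, class = "erlf_km")
}

#' Kaplan-Meier curves stratified by remnant-function class
#'
#' One product-limit curve per erLF class (`PNLF` / `at_risk` / `PLDF`);
#' empty classes are omitted with a warning.
#'
#' @inheritParams kaplan_meier
#' @param classes Factor of erLF classes aligned with `data` rows;
#'   defaults to the `erlf_class` column.
#' @return An `erlf_km` tibble with one stratum per non-empty class.
#' @export
km_by_class <- function(data, classes = NULL, time = "time_days", event = "event") {
  if (nrow(data) == 0) abort("`data` must be non-empty.")
  classes <- classes %||% data[["erlf_class"]]
  if (is.null(classes)) abort("No `erlf_class` column found and no `classes` given.")
  if (length(classes) != nrow(data)) {
    abort("`classes` must align with the rows of `data`.")
  }
  classes <- factor(classes, levels = postop_levels)
  empty <- setdiff(postop_levels, unique(as.character(classes)))
  if (length(empty) > 0) {
    warn(paste0("Empty strata omitted: ", paste(empty, collapse = ", "), "."))
  }
  data$.erlf_class <- classes
  kaplan_meier(data, time = time, event = event, stratum = ".erlf_class")
}

#' @param object An `erlf_km` curve set.
#' @param ... Unused.
#' @rdname kaplan_meier
#' @export
autoplot.erlf_km <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival,
                                       colour = .data$stratum,
                                       linetype = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Days since resection", y = "Survival probability",
                  colour = "erLF class", linetype = "erLF class") +
    ggplot2::theme_minimal()
}

#' @param object An `icg_curve`.
#' @param ... Unused.
#' @rdname icg_curve
#' @export
autoplot.icg_curve <- function(object, ...) {
  fit <- if (nrow(object) >= 3) fit_monoexponential(object) else NULL
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min,
                                            y = .data$conc_mg_per_l)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (min)", y = "ICG concentration (mg/L)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- tibble::tibble(
      time_min = seq(min(object$time_min), max(object$time_min), length.out = 100))
    grid$conc_mg_per_l <- fit$c0 * exp(-fit$decay_k * grid$time_min)
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}
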