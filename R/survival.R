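#' Univariate Cox proportional-hazards fit for one covariate
#'
#' Fits `Surv(time, event) ~ covariate` with the partial likelihood
#' (Breslow tie handling by default, Efron behind the flag) assuming a
#' linear functional form of the covariate. The risk per unit covariate
#' increase is reported as a hazard ratio with its 95% Wald confidence
#' interval. Monotone-likelihood degeneracy (diverging coefficient) is
#' reported as `converged = FALSE`.
#'
#' @param records survival data.frame (`patient_id`, `time`, `event`,
#'   covariate columns), e.g. from [read_survival()].
#' @param covariate_name column to fit.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return One-row data.frame of class `survival_fit`: covariate_name,
#'   beta, se, hr, ci_low, ci_high, p, n, n_events, converged.
#' @export
cox_fit_univariate <- function(records, covariate_name, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (!covariate_name %in% colnames(records)) {
    stop("covariate '", covariate_name, "' not found")
  }
  x <- records[[covariate_name]]
  if (sum(records$event) < 2) stop("need >= 2 events")
  if (stats::sd(x) == 0) stop("constant covariate: Cox fit undefined")
  df <- data.frame(time = records$time, event = records$event, x = x)
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, data = df, ties = ties),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  converged <- !warned && is.finite(beta) && is.finite(se) && abs(beta) < 15
  z <- beta / se
  out <- data.frame(covariate_name = covariate_name, beta = beta, se = se,
                    hr = exp(beta),
                    ci_low = exp(beta - 1.96 * se),
                    ci_high = exp(beta + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(z)),
                    n = nrow(records), n_events = sum(records$event),
                    converged = converged, stringsAsFactors = FALSE)
  class(out) <- c("survival_fit", "data.frame")
  out
}

#' Bonferroni family-wise control
#'
#' `bonferroni_alpha` gives the per-test significance level
#' `family_alpha / m`; `bonferroni_adjust` gives adjusted p-values
#' `min(1, m p)`.
#'
#' @param family_alpha family-wise error rate (default 0.05).
#' @param m number of tests.
#' @return Per-test alpha.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  family_alpha / m
}

#' @rdname bonferroni_alpha
#' @param pvalues numeric vector.
#' @export
bonferroni_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "bonferroni")
}

#' Kaplan-Meier curves per group with median survival
#'
#' Product-limit estimator per group; the median is the first time at which
#' the survival function drops to 0.5 or below (undefined — `NA` — if never
#' reached).
#'
#' @param records survival data.frame.
#' @param group_labels vector (one per record) of group assignments, e.g.
#'   from [dichotomize_median()].
#' @return List of class `km_result`: `curves` (data.frame: group, time,
#'   n_risk, n_event, surv) and `median` (named vector per group).
#' @export
km_curve <- function(records, group_labels) {
  if (length(group_labels) != nrow(records)) {
    stop("one group label per record required")
  }
  groups <- unique(as.character(group_labels))
  curves <- list(); med <- stats::setNames(rep(NA_real_, length(groups)), groups)
  for (g in groups) {
    sub <- records[as.character(group_labels) == g, , drop = FALSE]
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
    curves[[g]] <- data.frame(group = g, time = fit$time, n_risk = fit$n.risk,
                              n_event = fit$n.event, surv = fit$surv,
                              stringsAsFactors = FALSE)
    hit <- which(fit$surv <= 0.5 & fit$n.event > 0)
    if (length(hit)) med[g] <- fit$time[min(hit)]
  }
  structure(list(curves = do.call(rbind, curves), median = med),
            class = "km_result")
}

#' Median dichotomization of a continuous covariate
#'
#' Splits at the median; values at or below the median are `"low"`, above
#' it `"high"` (ties go to low).
#'
#' @param values numeric vector.
#' @return Character vector of `"low"` / `"high"`.
#' @export
dichotomize_median <- function(values) {
  ifelse(values <= stats::median(values), "low", "high")
}

#' Univariate Cox screening of a miRNA panel with Bonferroni control
#'
#' One univariate fit per miRNA, Bonferroni-adjusted over the panel size.
#' Both the adjusted p-value (`m * p`, capped at 1) and the per-test alpha
#' (`family_alpha / m`) view of the correction are reported.
#'
#' @param records survival data.frame (`patient_id`, `time`, `event`).
#' @param levels data.frame of per-patient miRNA levels: a `patient_id`
#'   column plus one column per miRNA. May be `NULL` if the covariates
#'   already live in `records`.
#' @param mirnas character vector of miRNA column names to screen.
#' @param family_alpha family-wise error rate (default 0.05).
#' @return data.frame: one [cox_fit_univariate()] row per miRNA plus
#'   `p_adjusted` and `significant` (adjusted p below `family_alpha`,
#'   equivalently raw p below the per-test alpha), sorted by adjusted p.
#'   Attribute `per_test_alpha` records the screening level.
#' @export
screen_mirnas <- function(records, levels = NULL, mirnas, family_alpha = 0.05) {
  if (!length(mirnas)) {
    out <- cox_fit_univariate(
      data.frame(patient_id = c("a", "b", "c", "d"), time = 1:4,
                 event = c(1L, 1L, 1L, 1L), x = c(1, 2, 1, 2)), "x")[0, ]
    out$p_adjusted <- numeric(0); out$significant <- logical(0)
    return(out)
  }
  if (!is.null(levels)) {
    idx <- match(records$patient_id, levels$patient_id)
    if (anyNA(idx)) stop("patient(s) missing from the miRNA level table")
    records <- cbind(records[, c("patient_id", "time", "event")],
                     levels[idx, mirnas, drop = FALSE])
  }
  fits <- do.call(rbind, lapply(mirnas, function(m) cox_fit_univariate(records, m)))
  fits$p_adjusted <- bonferroni_adjust(fits$p)
  alpha <- bonferroni_alpha(family_alpha, length(mirnas))
  fits$significant <- fits$p < alpha
  fits <- fits[order(fits$p_adjusted), , drop = FALSE]
  rownames(fits) <- NULL
  attr(fits, "per_test_alpha") <- alpha
  fits
}
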