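# Time-to-treatment-discontinuation and overall-survival endpoints and the
# comparison statistics: Kaplan-Meier, log-rank, Cox proportional hazards
# (Breslow ties), two-proportion z and Fisher's exact test. The survival
# machinery stands on the survival package; the endpoint definitions and the
# event/censoring logic are this module's own.

#' Time to treatment discontinuation for a therapy line
#'
#' TTD runs from the first day of therapy to whichever comes first of the
#' estimated last day of therapy, the last claim activity date, or death.
#' The discontinuation is an observed event when the endpoint is death, or
#' when it is the estimated end of therapy and at least 90 further days of
#' claims follow-up confirm that no therapy resumed; with less follow-up
#' (including a last claim before the estimated end) the record is censored.
#'
#' @param line One-row line record with `start_date` and `est_end_date`.
#' @param last_claim Day of last claim activity (must be >= line start).
#' @param death Death day or `NA`.
#' @param confirm_days Follow-up after the estimated end required to call the
#'   discontinuation an event. Default 90.
#' @return List with `time` (days), `event` (logical).
#' @export
compute_ttd <- function(line, last_claim, death = NA,
                        confirm_days = 90) {
  start <- line$start_date
  est_end <- line$est_end_date
  if (last_claim < start) stop("last claim precedes line start")
  endpoint <- min(est_end, last_claim, death, na.rm = TRUE)
  event <- FALSE
  if (!is.na(death) && endpoint == death) {
    event <- TRUE
  } else if (endpoint == est_end && (last_claim - est_end) >= confirm_days) {
    event <- TRUE
  }
  list(time = endpoint - start, event = event)
}

#' Overall survival from the ctDNA report date
#'
#' Event at death; otherwise censored at the last claim activity date. The
#' death registry is authoritative: a death after the last claim date is
#' still an event.
#'
#' @param report_date Day of the index ctDNA report.
#' @param death Death day or `NA`.
#' @param last_claim Day of last claim activity (>= report date).
#' @return List with `time` (days), `event` (logical).
#' @export
compute_os <- function(report_date, death = NA, last_claim) {
  if (last_claim < report_date) stop("last claim precedes report date")
  if (!is.na(death)) {
    if (death < report_date) stop("death precedes report date")
    return(list(time = death - report_date, event = TRUE))
  }
  list(time = last_claim - report_date, event = FALSE)
}

#' Kaplan-Meier fit
#'
#' Product-limit estimate with Greenwood standard errors, overall or by
#' group, with medians reported in months (30.4375 days/month).
#'
#' @param records `data.frame` with `time` (days), `event` (logical) and
#'   optionally `group`.
#' @param by_group Stratify by `records$group`.
#' @return Object of class `km_curve`: the underlying `survfit` plus a
#'   `medians` table (per-group median in months with 95% CI).
#' @export
km_fit <- function(records, by_group = "group" %in% names(records)) {
  stopifnot(nrow(records) >= 1, all(records$time >= 0))
  if (by_group) {
    fit <- survival::survfit(
      survival::Surv(time, event) ~ group, data = records)
  } else {
    fit <- survival::survfit(
      survival::Surv(time, event) ~ 1, data = records)
  }
  q <- stats::quantile(fit, probs = 0.5)
  med <- if (is.list(q)) q$quantile else q
  lo <- if (is.list(q)) q$lower else NA
  hi <- if (is.list(q)) q$upper else NA
  medians <- data.frame(
    group = if (by_group) sub("^group=", "", names(fit$strata)) else "all",
    median_months = days_to_months(as.numeric(med)),
    lower_months = days_to_months(as.numeric(lo)),
    upper_months = days_to_months(as.numeric(hi)),
    stringsAsFactors = FALSE)
  structure(list(fit = fit, medians = medians, by_group = by_group),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier fit (", sum(x$fit$n), " records)\n", sep = "")
  print(x$medians, row.names = FALSE)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Months", ylab = "Survival probability",
                          col = NULL, ...) {
  ns <- if (is.null(x$fit$strata)) 1L else length(x$fit$strata)
  if (is.null(col)) col <- seq_len(ns)
  plot(x$fit, xscale = DAYS_PER_MONTH, xlab = xlab, ylab = ylab, col = col,
       ...)
  if (ns > 1) {
    legend("topright", legend = sub("^group=", "", names(x$fit$strata)),
           col = col, lty = 1, bty = "n")
  }
  invisible(x)
}

#' Log-rank test across groups
#'
#' @param records `data.frame` with `time`, `event`, `group` (>= 2 non-empty
#'   groups).
#' @return List with `chisq`, `df` (k-1), `p.value`.
#' @export
logrank_test <- function(records) {
  k <- length(unique(records$group))
  if (k < 2) stop("log-rank needs at least two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  df <- k - 1
  list(chisq = unname(sd$chisq), df = df,
       p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards model with pairwise hazard ratios
#'
#' Fits a Cox model on a group factor (Breslow tie handling) and reports
#' every pairwise hazard ratio with Wald 95% confidence intervals and
#' p-values. Contrasts involving a level with no events are flagged
#' non-estimable.
#'
#' @param records `data.frame` with `time`, `event`, `group`.
#' @param reference Reference level; default the first sorted level.
#' @return List with `model` (the `coxph` fit) and `pairwise` (data frame:
#'   `group`, `vs`, `hr`, `lower`, `upper`, `p.value`, `estimable`).
#' @export
cox_ph <- function(records, reference = NULL) {
  levels_ <- sort(unique(as.character(records$group)))
  if (length(levels_) < 2) stop("need at least two groups")
  if (is.null(reference)) reference <- levels_[1]
  records$group <- factor(records$group,
                          levels = c(reference, setdiff(levels_, reference)))
  events_by <- tapply(records$event, records$group, sum)
  fit <- survival::coxph(survival::Surv(time, event) ~ group,
                         data = records, ties = "breslow")
  beta <- c(0, stats::coef(fit))
  names(beta) <- levels(records$group)
  V <- matrix(0, length(beta), length(beta),
              dimnames = list(names(beta), names(beta)))
  V[-1, -1] <- stats::vcov(fit)
  pw <- list()
  lv <- levels(records$group)
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i == j) next
    d <- beta[i] - beta[j]
    se <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
    estimable <- is.finite(d) && is.finite(se) && se > 0 &&
      events_by[lv[i]] > 0 && events_by[lv[j]] > 0
    pw[[length(pw) + 1]] <- data.frame(
      group = lv[i], vs = lv[j],
      hr = exp(d), lower = exp(d - 1.96 * se), upper = exp(d + 1.96 * se),
      p.value = 2 * stats::pnorm(-abs(d / se)),
      estimable = estimable, stringsAsFactors = FALSE)
  }
  pairwise <- do.call(rbind, pw)
  rownames(pairwise) <- NULL
  list(model = fit, pairwise = pairwise)
}

#' Two-proportion z-test / Fisher's exact test
#'
#' `method = "z"` is the pooled-variance two-sided normal test; `"fisher"`
#' the exact two-sided test; `"auto"` selects Fisher whenever any expected
#' cell count (under the margins) is below 5.
#'
#' @param x1,n1 Successes and trials in the first group.
#' @param x2,n2 Successes and trials in the second group.
#' @param method One of `"z"`, `"fisher"`, `"auto"`.
#' @return List with `p.value`, `method` (the method actually used) and
#'   `statistic` (z statistic, `NA` for Fisher).
#' @export
two_prop_test <- function(x1, n1, x2, n2, method = c("auto", "z", "fisher")) {
  method <- match.arg(method)
  if (n1 < 1 || n2 < 1) stop("both groups must have at least one trial")
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  if (method == "auto") {
    p_marg <- (x1 + x2) / (n1 + n2)
    expected <- c(n1 * p_marg, n1 * (1 - p_marg),
                  n2 * p_marg, n2 * (1 - p_marg))
    method <- if (any(expected < 5)) "fisher" else "z"
  }
  if (method == "fisher") {
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(tab)$p.value
    return(list(p.value = p, method = "fisher", statistic = NA_real_))
  }
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(p.value = 2 * stats::pnorm(-abs(z)), method = "z", statistic = z)
}
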