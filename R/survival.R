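#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator with Greenwood variance. At tied times,
#' events precede censorings (a patient censored at an event time is still
#' at risk for that event). Times are measured in months.
#'
#' @param time non-negative event/censoring times.
#' @param event 0/1 indicator (1 = event).
#' @return object of class `km_curve`: data.frame `steps` with columns
#'   time, n_risk, n_event, n_censor, surv, var (Greenwood), se; plus `n`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0), all(event %in% 0:1))
  if (length(time) == 0) {
    slaml_stop("no records", "slaml_argument_error")
  }
  if (all(time == 0) && all(event == 0)) {
    slaml_stop("degenerate curve: all times zero with no events",
               "slaml_degenerate_error")
  }
  ut <- sort(unique(time))
  n <- length(time)
  surv <- 1
  gw <- 0  # running Greenwood sum
  rows <- lapply(ut, function(t0) {
    n_risk <- sum(time >= t0)
    d <- sum(time == t0 & event == 1)
    cns <- sum(time == t0 & event == 0)
    if (d > 0) {
      surv <<- surv * (1 - d / n_risk)
      if (n_risk > d) gw <<- gw + d / (n_risk * (n_risk - d))
    }
    data.frame(time = t0, n_risk = n_risk, n_event = d, n_censor = cns,
               surv = surv, var = surv^2 * gw)
  })
  steps <- do.call(rbind, rows)
  steps$se <- sqrt(steps$var)
  structure(list(steps = steps, n = n), class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve [km_estimate()] result.
#' @param times numeric vector.
#' @return survival probabilities (1 before the first step).
#' @export
km_at <- function(curve, times) {
  vapply(times, function(t0) {
    idx <- which(curve$steps$time <= t0)
    if (!length(idx)) 1 else curve$steps$surv[max(idx)]
  }, numeric(1))
}

#' Median survival time from a Kaplan-Meier curve
#'
#' Smallest event time at which the estimate drops to 0.5 or below; NA when
#' the curve never reaches 0.5.
#'
#' @param curve [km_estimate()] result.
#' @return numeric (months) or NA.
#' @export
km_median <- function(curve) {
  hit <- which(curve$steps$surv <= 0.5)
  if (!length(hit)) NA_real_ else curve$steps$time[min(hit)]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d event times, median %.1f\n",
              x$n, sum(x$steps$n_event > 0), km_median(x)))
  invisible(x)
}

#' k-group log-rank test
#'
#' Delegated to the standard implementation (`survival::survdiff`, rho = 0).
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels (>= 2 non-empty groups).
#' @return list: `statistic` (chi-square), `df` (k - 1), `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) {
    slaml_stop("log-rank test needs >= 2 groups", "slaml_test_error")
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- length(fit$n) - 1
  list(statistic = unname(fit$chisq), df = df,
       p = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Aalen-Johansen cumulative incidence with death as competing event
#'
#' Cause-specific cumulative incidence of relapse and of death without
#' relapse, from complete remission. At every event time the identity
#' CI_relapse + CI_death + event-free survival = 1 holds to within 1e-9.
#'
#' @param time non-negative times from CR.
#' @param event_type one of "relapse", "death", "censored" per patient.
#' @return object of class `cir_curves`: data.frame `steps` with columns
#'   time, n_risk, n_relapse, n_death, n_censor, ci_relapse, ci_death,
#'   event_free.
#' @export
cumulative_incidence <- function(time, event_type) {
  allowed <- c("relapse", "death", "censored")
  if (!all(event_type %in% allowed)) {
    slaml_stop(paste("unknown event_type code(s):",
                     paste(setdiff(unique(event_type), allowed), collapse = ", ")),
               "slaml_argument_error")
  }
  stopifnot(length(time) == length(event_type), all(time >= 0))
  ut <- sort(unique(time))
  s <- 1          # overall (any-event) KM, left-continuous use
  ci_r <- 0
  ci_d <- 0
  rows <- lapply(ut, function(t0) {
    n_risk <- sum(time >= t0)
    dr <- sum(time == t0 & event_type == "relapse")
    dd <- sum(time == t0 & event_type == "death")
    cns <- sum(time == t0 & event_type == "censored")
    if (n_risk > 0) {
      ci_r <<- ci_r + s * dr / n_risk
      ci_d <<- ci_d + s * dd / n_risk
      s <<- s * (1 - (dr + dd) / n_risk)
    }
    data.frame(time = t0, n_risk = n_risk, n_relapse = dr, n_death = dd,
               n_censor = cns, ci_relapse = ci_r, ci_death = ci_d,
               event_free = s)
  })
  structure(list(steps = do.call(rbind, rows), n = length(time)),
            class = "cir_curves")
}

#' Evaluate cumulative incidence curves at given times
#'
#' @param curves [cumulative_incidence()] result.
#' @param times numeric vector.
#' @param cause "relapse" or "death".
#' @return cumulative incidence values (0 before the first step).
#' @export
cir_at <- function(curves, times, cause = "relapse") {
  col <- if (cause == "relapse") "ci_relapse" else "ci_death"
  vapply(times, function(t0) {
    idx <- which(curves$steps$time <= t0)
    if (!length(idx)) 0 else curves$steps[[col]][max(idx)]
  }, numeric(1))
}

#' Compare cumulative incidence of relapse across groups
#'
#' Test of equality of the relapse subdistribution across groups, fulfilled
#' by the Fine-Gray construction: `survival::finegray` reweights the data
#' for the subdistribution hazard of relapse and a Cox model Wald test on
#' the group factor provides the k-group comparison (the "Fine and Gray
#' test"; Gray's test is its score-test analogue).
#'
#' @param time,event_type as in [cumulative_incidence()].
#' @param group group labels (>= 2 non-empty groups).
#' @return list: `statistic` (Wald chi-square), `df`, `p`.
#' @export
compare_cir <- function(time, event_type, group) {
  group <- droplevels(as.factor(as.character(group)))
  if (nlevels(group) < 2) {
    slaml_stop("competing-risks comparison needs >= 2 groups", "slaml_test_error")
  }
  status <- factor(ifelse(event_type == "censored", "censor", event_type),
                   levels = c("censor", "relapse", "death"))
  df0 <- data.frame(time = time, status = status, group = group)
  fg <- survival::finegray(survival::Surv(time, status) ~ ., data = df0,
                           etype = "relapse")
  fit <- survival::coxph(
    survival::Surv(fgstart, fgstop, fgstatus) ~ group,
    data = fg, weights = fg$fgwt)
  k <- length(stats::coef(fit))
  wald <- tryCatch(
    drop(t(stats::coef(fit)) %*% solve(stats::vcov(fit)) %*% stats::coef(fit)),
    error = function(e) 0)
  list(statistic = wald, df = k,
       p = pchisq(wald, k, lower.tail = FALSE))
}
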