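#' Classify a gap area into a prognostic group
#'
#' Four prognostic groups defined on the 3D gap area with default boundaries
#' 150, 550 and 1000 mm^2: excellent (0-150], good (150-550], moderate
#' (550-1000], poor (> 1000). Boundaries are treated as half-open intervals
#' on the continuous measurement scale; each boundary value itself belongs to
#' the lower group.
#'
#' Note one deliberate asymmetry preserved from clinical usage: the
#' high-risk flag ([high_risk_flag()]) is defined as gap area >= 550 mm^2,
#' so a gap area of exactly 550 is "good" here but high-risk there.
#'
#' @param gap_area gap area(s) in mm^2; non-negative.
#' @param boundaries strictly increasing length-3 numeric vector of group
#'   boundaries (mm^2).
#' @return A factor with levels `excellent`, `good`, `moderate`, `poor`.
#' @export
classify_prognosis <- function(gap_area, boundaries = c(150, 550, 1000)) {
  gap_area <- as.numeric(gap_area)
  if (any(!is.finite(gap_area)) || any(gap_area < 0))
    stop("gap_area must be non-negative and finite")
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 3L || any(diff(boundaries) <= 0))
    stop("boundaries must be three strictly increasing values")
  cut(gap_area, breaks = c(-Inf, boundaries, Inf),
      labels = c("excellent", "good", "moderate", "poor"), right = TRUE)
}

#' High-risk flag for conversion to TKA
#'
#' @param gap_area gap area(s) in mm^2; non-negative.
#' @param cutoff critical cut-off in mm^2; default 550.
#' @return Logical: `TRUE` when `gap_area >= cutoff`.
#' @export
high_risk_flag <- function(gap_area, cutoff = 550) {
  gap_area <- as.numeric(gap_area)
  if (any(!is.finite(gap_area)) || any(gap_area < 0))
    stop("gap_area must be non-negative and finite")
  gap_area >= cutoff
}

#' Youden's J statistic
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @return `sensitivity + specificity - 1`.
#' @export
youden_j <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  sensitivity + specificity - 1
}

#' Empirical ROC curve
#'
#' Computes the empirical ROC for a continuous score against a binary
#' outcome, with the orientation used for fracture displacement: a larger
#' score (gap area) is more indicative of the event (TKA conversion). A case
#' is called positive at threshold `t` when `score >= t`; thresholds run
#' over all observed scores plus `-Inf`/`Inf` sentinels. The AUC is computed
#' by the trapezoidal rule and equals the normalized Mann-Whitney rank-sum
#' statistic (ties counted 1/2).
#'
#' @param scores numeric scores (e.g. gap areas in mm^2).
#' @param labels binary outcome (logical or 0/1); both classes must occur.
#' @return An object of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present")
  thr <- c(-Inf, sort(unique(scores)), Inf)
  pos <- scores[labels]
  neg <- scores[!labels]
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(sens)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = length(pos), n_neg = length(neg)),
            class = "roc_curve")
}

#' @exportS3Method base::print
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC ", format(x$auc, digits = 4), " (", x$n_pos,
      " events / ", x$n_neg, " non-events)\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  o <- order(1 - x$specificity, x$sensitivity)
  graphics::plot(1 - x$specificity[o], x$sensitivity[o], type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Select the critical cut-off by maximal Youden's J
#'
#' Accepts either a cut-off table (columns `cutoff`, `sensitivity`,
#' `specificity`, percentages) or raw scores plus outcomes, in which case
#' candidates are all observed score values. The candidate with maximal J is
#' returned; ties go to the smallest cut-off.
#'
#' @param x a data frame with columns `cutoff`, `sensitivity`, `specificity`
#'   (in percent), or a numeric vector of scores.
#' @param labels binary outcomes, required when `x` is a score vector.
#' @return The selected cut-off (same units as the scores / `cutoff`
#'   column), with the achieved J as attribute `"youden_j"`.
#' @export
select_cutoff <- function(x, labels = NULL) {
  if (is.data.frame(x)) {
    if (nrow(x) == 0) stop("empty cut-off table")
    j <- youden_j(x$sensitivity / 100, x$specificity / 100)
    cand <- x$cutoff
  } else {
    if (is.null(labels)) stop("labels are required with raw scores")
    roc <- roc_curve(x, labels)
    keep <- is.finite(roc$thresholds)
    if (!any(keep)) stop("no finite candidate cut-off")
    j <- youden_j(roc$sensitivity[keep], roc$specificity[keep])
    cand <- roc$thresholds[keep]
  }
  best <- which(j == max(j))
  pick <- best[which.min(cand[best])]
  structure(cand[pick], youden_j = j[pick])
}

#' Reference cut-off table for the 3D gap area
#'
#' Operating points of the gap-area classifier for conversion to TKA:
#' candidate cut-off values with their sensitivity, specificity (percent)
#' and Youden's J. 550 mm^2 is the critical cut-off (maximal J).
#'
#' @return A data frame with columns `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
gap_cutoff_table <- function() {
  data.frame(cutoff = c(150, 350, 550, 750, 950),
             sensitivity = c(91.5, 81.4, 76.3, 59.3, 49.2),
             specificity = c(41.4, 61.7, 73.9, 81.2, 86.3),
             youden_j = c(0.33, 0.43, 0.50, 0.41, 0.36))
}

#' Kaplan-Meier estimate of native-knee survivorship
#'
#' Product-limit estimator of the probability of still having the native
#' knee (no TKA conversion) at time t, overall or per group. Backed by
#' [survival::survfit()].
#'
#' @param time follow-up times (> 0), years.
#' @param event event indicator (1/TRUE = TKA conversion; 0/FALSE =
#'   censored at end of follow-up).
#' @param group optional group assignment (factor-like).
#' @return An object of class `km_curve`: per group, a data frame with
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop("times must be positive")
  event <- as.integer(as.logical(event))
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(group)
  if (any(table(group) == 0) || length(time) == 0) stop("empty group")
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(fit$strata)) {
    setNames(list(seq_along(fit$time)), levels(group)[1])
  } else {
    idx <- split(seq_along(fit$time),
                 rep(seq_along(fit$strata), fit$strata))
    setNames(idx, sub("^group=", "", names(fit$strata)))
  }
  curves <- lapply(strata, function(i) {
    data.frame(time = fit$time[i], n_risk = fit$n.risk[i],
               n_event = fit$n.event[i], n_censor = fit$n.censor[i],
               surv = fit$surv[i])
  })
  structure(list(curves = curves), class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a `km_curve` from [km_estimate()].
#' @param t time(s) at which to evaluate S(t).
#' @param group which group curve (name or index); default the first.
#' @return Survival probabilities S(t) (right-continuous step function,
#'   S(0) = 1).
#' @export
km_surv <- function(km, t, group = 1) {
  cv <- km$curves[[group]]
  ev <- cv[cv$n_event > 0, , drop = FALSE]
  vapply(t, function(tt) {
    if (nrow(ev) == 0 || tt < ev$time[1]) return(1)
    ev$surv[max(which(ev$time <= tt))]
  }, numeric(1))
}

#' @exportS3Method base::print
print.km_curve <- function(x, ...) {
  for (g in names(x$curves)) {
    cv <- x$curves[[g]]
    cat(g, ": ", sum(cv$n_event), " events over ", nrow(cv),
        " distinct times, final S = ",
        format(min(cv$surv), digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  cols <- seq_along(x$curves)
  graphics::plot(NULL, xlim = c(0, max(unlist(lapply(x$curves, `[[`,
                                                     "time")))),
                 ylim = c(0, 1), xlab = "years",
                 ylab = "native knee survival", ...)
  for (i in cols) {
    cv <- x$curves[[i]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)), col = i,
                    do.points = FALSE)
  }
  graphics::legend("bottomleft", legend = names(x$curves), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Log-rank test between survival curves
#'
#' Standard observed-minus-expected log-rank statistic over the pooled event
#' times, via [survival::survdiff()]; df = number of groups - 1.
#'
#' @param time follow-up times (> 0).
#' @param event event indicator.
#' @param group group assignment (>= 2 non-empty groups).
#' @return A list: `statistic` (chi-square), `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stop("need >= 2 non-empty groups")
  if (any(table(group) == 0)) stop("empty group")
  event <- as.integer(as.logical(event))
  df <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- nlevels(group) - 1L
  list(statistic = unname(sd$chisq), df = k,
       p_value = unname(pchisq(sd$chisq, k, lower.tail = FALSE)))
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model of time to TKA conversion on the given covariates by
#' maximizing the partial likelihood (Newton-Raphson, Breslow tie handling
#' by default), via [survival::coxph()]. Covariates with no variation raise
#' an error; fits showing signs of monotone likelihood (complete
#' separation) are flagged, not silently reported.
#'
#' @param data a data frame (e.g. a cohort from [simulate_cohort()]).
#' @param covariates character vector of covariate column names.
#' @param time,event names of the follow-up time and event columns.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An object of class `cox_fit`: `coefficients` (data frame with
#'   `coef`, `se`, `hr`, `hr_lower`, `hr_upper`, `p`), `loglik`,
#'   `converged`, `separation`, `n`, `n_events`.
#' @export
cox_fit <- function(data, covariates, time = "followup_years", event = "tka",
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(all(c(covariates, time, event) %in% names(data)))
  ev <- as.integer(as.logical(data[[event]]))
  if (sum(ev) < 1) stop("need at least one event")
  for (cv in covariates) {
    v <- data[[cv]]
    if (length(unique(v[!is.na(v)])) < 2)
      stop("covariate '", cv, "' has no variation")
  }
  fml <- stats::as.formula(paste0("survival::Surv(", time, ", ", event,
                                  ") ~ ", paste(covariates, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  z <- qnorm(0.975)
  coefs <- data.frame(term = rownames(co), coef = co[, "coef"],
                      se = co[, "se(coef)"], hr = exp(co[, "coef"]),
                      hr_lower = exp(co[, "coef"] - z * co[, "se(coef)"]),
                      hr_upper = exp(co[, "coef"] + z * co[, "se(coef)"]),
                      p = co[, "Pr(>|z|)"], row.names = NULL)
  if (any(abs(coefs$coef) > 15)) separation <- TRUE
  converged <- is.null(fit$info) && fit$iter < 100 && !separation
  structure(list(coefficients = coefs, loglik = fit$loglik[2],
                 converged = converged, separation = separation,
                 n = fit$n, n_events = fit$nevent, ties = ties),
            class = "cox_fit")
}

#' @exportS3Method base::print
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards (", x$ties, " ties), ", x$n, " subjects / ",
      x$n_events, " events\n", sep = "")
  if (x$separation) cat("  WARNING: possible complete separation\n")
  df <- x$coefficients
  df$hr_ci <- sprintf("%.2f (%.2f-%.2f)", df$hr, df$hr_lower, df$hr_upper)
  print(df[, c("term", "coef", "se", "hr_ci", "p")], digits = 3,
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  setNames(object$coefficients$coef, object$coefficients$term)
}

#' Adequacy of articular reduction
#'
#' A reduction is adequate when both the maximum residual gap and the
#' maximum step-off are at most 2 mm (inclusive).
#'
#' @param max_gap,max_stepoff maximum residual gap and step-off, mm;
#'   non-negative.
#' @return Logical: `TRUE` when adequate.
#' @export
reduction_adequacy <- function(max_gap, max_stepoff) {
  if (any(max_gap < 0) || any(max_stepoff < 0))
    stop("gap and step-off must be non-negative")
  max_gap <= 2 & max_stepoff <= 2
}
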