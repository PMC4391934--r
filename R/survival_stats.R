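# Evaluation statistics: Kaplan-Meier, log-rank, Cox PH, ROC/AUC.
# KM, log-rank and Cox are computed by the survival package behind this
# module's tidy interfaces; the ROC/AUC (Mann-Whitney with tie correction,
# Hanley-McNeil confidence interval) is implemented here.

#' Kaplan-Meier product-limit curve
#'
#' @param time Follow-up times in months (> 0).
#' @param event Event indicators (0/1); censored subjects at a time are
#'   counted at risk at that time (standard convention).
#' @return An object of class `km_curve`: a data frame with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival` at every observed time.
#' @examples
#' km_fit(c(1, 3, 3, 5, 7, 8), c(1, 1, 0, 1, 1, 0))
#' @export
km_fit <- function(time, event) {
  if (length(time) < 1) stop("at least one record is required", call. = FALSE)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("events must be 0/1 flags", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    n_censor = sf$n.censor, survival = sf$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, final survival %.4f\n",
              nrow(x), x$survival[nrow(x)]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Log-rank test between groups
#'
#' Standard O-E log-rank test (hypergeometric variance, tied events pooled)
#' across two or more groups.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicators (0/1).
#' @param group Grouping vector (>= 2 non-empty groups, >= 1 event overall).
#' @return An object of class `logrank_result` with `chi_square`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("at least two non-empty groups are required", call. = FALSE)
  if (sum(event) < 1) stop("at least one event is required", call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  structure(list(chi_square = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square %.4f on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model on the supplied covariate table by partial-likelihood
#' maximisation (Breslow tie handling by default, matching common clinical
#' software; Efron available). Wald confidence intervals use
#' `exp(b +/- 1.96 se)`.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicators (0/1).
#' @param covariates Data frame of numeric covariates, one column per model
#'   term (code ordered stages as integer scores and binary factors as 0/1).
#' @param ties Tie handling, `"breslow"` (default) or `"efron"`.
#' @return An object of class `cox_fit_table`: a data frame with one row per
#'   covariate (`term`, `coef`, `se`, `hr`, `ci_low`, `ci_high`, `p`) and
#'   attributes `loglik` and `n_events`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (any(vapply(covariates, function(x) length(unique(x)) < 2, logical(1))))
    stop("constant covariate in the design", call. = FALSE)
  if (sum(event) < ncol(covariates))
    warning("fewer events than covariates; estimates will be unstable", call. = FALSE)
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(iter.max = 100, eps = 1e-10))
  if (fit$iter >= 100)
    stop("Cox fit did not converge in 100 iterations", call. = FALSE)
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(b)) || any(abs(b) > 15) || any(!is.finite(se)))
    warning("monotone partial likelihood (perfect separation?) - coefficients unreliable",
            call. = FALSE)
  out <- data.frame(term = names(covariates), coef = unname(b), se = unname(se),
                    hr = exp(unname(b)),
                    ci_low = exp(unname(b) - 1.96 * unname(se)),
                    ci_high = exp(unname(b) + 1.96 * unname(se)),
                    p = 2 * stats::pnorm(-abs(unname(b) / unname(se))),
                    stringsAsFactors = FALSE)
  attr(out, "loglik") <- unname(fit$loglik[2])
  attr(out, "n_events") <- sum(event)
  class(out) <- c("cox_fit_table", "data.frame")
  out
}

#' @export
print.cox_fit_table <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards fit (%d events, log-likelihood %.3f)\n",
              attr(x, "n_events"), attr(x, "loglik")))
  y <- data.frame(term = x$term,
                  `HR (95%CI)` = sprintf("%.3f (%.3f-%.3f)", x$hr, x$ci_low, x$ci_high),
                  p = signif(x$p, digits), check.names = FALSE)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' ROC analysis of a prognostic factor
#'
#' AUC as the Mann-Whitney concordance probability (ties counted half),
#' confidence interval by the Hanley-McNeil standard error, and a normal test
#' of AUC = 0.5.
#'
#' @param predictor Ordinal predictor values (higher = predicted higher
#'   risk).
#' @param outcome Binary outcome flags (1 = case, e.g. recurrence within the
#'   follow-up horizon); both classes must be present.
#' @return An object of class `roc_result` with `auc`, `se`, `ci` (length-2),
#'   `p`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(predictor, outcome) {
  if (length(predictor) != length(outcome))
    stop("predictor and outcome must have equal length", call. = FALSE)
  if (!all(outcome %in% c(0, 1)) || length(unique(outcome)) < 2)
    stop("outcome must contain both classes as 0/1 flags", call. = FALSE)
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  r <- rank(predictor)                      # midranks handle ties
  auc <- (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(1, pmax(0, auc + c(-1.96, 1.96) * se))
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else as.numeric(auc != 0.5) * 0
  structure(list(auc = auc, se = se, ci = ci, p = p, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%%CI %.3f-%.3f), p = %.4g (%d cases / %d controls)\n",
              x$auc, x$ci[1], x$ci[2], x$p, x$n_pos, x$n_neg))
  invisible(x)
}

#' Recurrence outcome for ROC analysis
#'
#' Converts survival records into the binary outcome "recurrence within the
#' horizon". Subjects censored before the horizon are uninformative for this
#' dichotomy and are excluded with a message.
#'
#' @param time Follow-up times in months.
#' @param event Event indicators (0/1).
#' @param horizon Months; default 60 (five-year window).
#' @return A list with `keep` (logical inclusion mask) and `outcome` (0/1 for
#'   the kept records).
#' @export
roc_outcome <- function(time, event, horizon = 60) {
  case <- event == 1 & time <= horizon
  control <- time >= horizon | (event == 1 & time > horizon)
  keep <- case | control
  if (any(!keep))
    message(sprintf("excluded %d records censored before %g months from ROC",
                    sum(!keep), horizon))
  list(keep = keep, outcome = as.integer(case[keep]))
}
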