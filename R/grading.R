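# Best-P dichotomisation of a continuous biomarker: scan all feasible
# cut-points, keep the one maximising the two-group log-rank statistic, and
# correct the minimal p for the implicit multiple testing
# (Miller-Siegmund).

#' Fast two-group log-rank chi-square
#'
#' Standard O-E statistic with hypergeometric variance at each distinct event
#' time (tied events pooled), for two groups. Used internally by the
#' cut-point scan and by permutation references; agrees exactly with
#' `survival::survdiff`.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicators (0/1).
#' @param group Logical or two-level grouping vector.
#' @return The chi-square statistic (1 df).
#' @keywords internal
logrank_chi2 <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  if (length(unique(g)) != 2) stop("exactly two non-empty groups required", call. = FALSE)
  et <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g == 2L)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 2L)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(0)
  (o - e)^2 / v
}

#' Feasible cut-point candidates
#'
#' Candidates are the observed biomarker values themselves (split rule:
#' `value <= c` is the low group) whose split leaves both groups at least
#' `ceiling(min_group_frac * n)` patients.
#'
#' @param values Biomarker values (n >= 10).
#' @param min_group_frac Minimum group fraction, in (0, 0.5); default 0.10.
#' @return Sorted numeric vector of feasible candidate cut-points.
#' @examples
#' candidate_cutpoints(1:100)  # 10 .. 90
#' @export
candidate_cutpoints <- function(values, min_group_frac = 0.10) {
  if (length(values) < 10) stop("at least 10 values are required", call. = FALSE)
  if (min_group_frac <= 0 || min_group_frac >= 0.5)
    stop("min_group_frac must lie in (0, 0.5)", call. = FALSE)
  n <- length(values)
  m <- ceiling(min_group_frac * n)
  sv <- sort(unique(values))
  n_low <- vapply(sv, function(c) sum(values <= c), numeric(1))
  cand <- sv[n_low >= m & (n - n_low) >= m]
  if (length(cand) == 0)
    stop("infeasible scan: no cut-point leaves both groups large enough", call. = FALSE)
  cand
}

#' Miller-Siegmund correction of a minimal p-value
#'
#' Adjusts the smallest p-value from a maximally selected log-rank scan for
#' the multiplicity of candidate cut-points. With `z` the standard-normal
#' quantile of `1 - p_raw/2`,
#' `p_corrected = phi(z) (z - 1/z) log(high(1-low) / (low(1-high))) + 4 phi(z)/z`,
#' where `low`/`high` are the quantile bounds of the scanned splits. The
#' result is clamped into `(p_raw, 1]`.
#'
#' @param p_raw Raw minimal p-value, in (0, 1).
#' @param low_frac,high_frac Smallest and largest low-group fraction scanned;
#'   `0 < low_frac < high_frac < 1`.
#' @return Corrected p-value.
#' @export
miller_siegmund_correct <- function(p_raw, low_frac = 0.10, high_frac = 0.90) {
  if (any(!is.finite(p_raw)) || any(p_raw <= 0) || any(p_raw >= 1))
    stop("p_raw must lie strictly between 0 and 1", call. = FALSE)
  if (!is.finite(low_frac) || !is.finite(high_frac) ||
      low_frac <= 0 || high_frac >= 1 || low_frac >= high_frac)
    stop("fractions must satisfy 0 < low_frac < high_frac < 1", call. = FALSE)
  z <- stats::qnorm(1 - p_raw / 2)
  span <- log(high_frac * (1 - low_frac) / (low_frac * (1 - high_frac)))
  pc <- stats::dnorm(z) * (z - 1 / z) * span + 4 * stats::dnorm(z) / z
  pmin(1, pmax(p_raw, pc))
}

#' Optimal cut-point by the best-P log-rank principle
#'
#' For every feasible candidate (see [candidate_cutpoints()]) computes the
#' two-group log-rank chi-square for the split `value <= c` versus
#' `value > c` and returns the candidate with the largest statistic (ties
#' broken towards the smaller cut-point). The raw minimal p is reported next
#' to its [miller_siegmund_correct()]ed version, using the smallest and
#' largest scanned low-group fraction as the quantile bounds.
#'
#' @param values Biomarker values, one per patient.
#' @param times Follow-up times in months.
#' @param events Event indicators (0/1); at least one event is required.
#' @param min_group_frac Minimum group fraction for a feasible split.
#' @return An object of class `cutpoint_result` with `cutoff`, `chi_square`,
#'   `p_raw`, `p_corrected`, `n_low`, `n_high` and the scan trace `scanned`
#'   (data frame: `cutoff`, `n_low`, `chi_square`).
#' @export
optimal_cutpoint <- function(values, times, events, min_group_frac = 0.10) {
  n <- length(values)
  if (length(times) != n || length(events) != n)
    stop("values, times and events must have equal length", call. = FALSE)
  if (any(!is.finite(values)) || any(!is.finite(times)) || any(times <= 0))
    stop("values must be finite and times positive", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1 flags", call. = FALSE)
  if (sum(events) < 1) stop("no signal: at least one event is required", call. = FALSE)
  cand <- candidate_cutpoints(values, min_group_frac)
  chi <- vapply(cand, function(c) logrank_chi2(times, events, values > c), numeric(1))
  n_low <- vapply(cand, function(c) sum(values <= c), numeric(1))
  best <- which.max(chi)             # first maximum = smallest cut-point
  p_raw <- stats::pchisq(chi[best], df = 1, lower.tail = FALSE)
  p_raw <- min(max(p_raw, .Machine$double.xmin), 1 - 1e-16)
  fr <- range(n_low / n)
  structure(list(
    cutoff = cand[best], chi_square = chi[best],
    p_raw = p_raw,
    p_corrected = miller_siegmund_correct(p_raw, fr[1], fr[2]),
    n_low = as.integer(n_low[best]), n_high = as.integer(n - n_low[best]),
    scanned = data.frame(cutoff = cand, n_low = as.integer(n_low), chi_square = chi)),
    class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(paste0("best-P cut-point: %.6g (chi-square %.3f, raw p %.3g, ",
                     "corrected p %.3g)\n  groups: %d low (grade I) / %d high (grade II), ",
                     "%d candidates scanned\n"),
              x$cutoff, x$chi_square, x$p_raw, x$p_corrected,
              x$n_low, x$n_high, nrow(x$scanned)))
  invisible(x)
}

#' Assign biomarker grades
#'
#' Dichotomises values at a cut-off: `value <= cutoff` is grade I (boundary
#' inclusive), `value > cutoff` grade II.
#'
#' @param value Biomarker value(s).
#' @param cutoff Cut-off in the same units.
#' @return Factor with levels `I`, `II`.
#' @examples
#' assign_grade(c(2.71e4, 2.88e8, 3.58e7), 3.58e7)  # I II I
#' @export
assign_grade <- function(value, cutoff) {
  if (any(!is.finite(value)) || !is.finite(cutoff))
    stop("value and cutoff must be finite", call. = FALSE)
  factor(ifelse(value <= cutoff, "I", "II"), levels = c("I", "II"))
}
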