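#' Harrell concordance index
#'
#' Fraction of permissible patient pairs whose predicted risk ordering
#' agrees with the observed survival ordering. A pair is permissible when
#' the shorter observed time carries an event (Harrell's rule): either
#' \eqn{t_i < t_j} with patient \eqn{i} deceased, or \eqn{t_i = t_j} with
#' exactly one death (the censored patient is known to have outlived the
#' other). Pairs tied in time with both events are not permissible. A
#' permissible pair is concordant when the shorter-surviving patient has
#' the strictly higher risk score; tied risk scores contribute 1/2.
#'
#' 0.5 corresponds to random prediction, 1 to perfect ranking, values
#' below 0.5 to systematically inverted predictions.
#'
#' @param risk Numeric vector of risk scores (higher = worse prognosis);
#'   either the linear predictor \eqn{\eta} or the hazard ratio
#'   \eqn{e^\eta} may be used, the index only depends on ranks.
#' @param time,event Survival outcome vectors.
#' @return A number in \[0, 1\].
#' @examples
#' concordanceIndex(c(3, 2, 1), time = c(1, 2, 3), event = c(1, 1, 1)) # 1
#' @export
concordanceIndex <- function(risk, time, event) {
  .checkOutcomes(time, event, n = length(risk))
  n <- length(risk)
  if (n < 2) stop("need at least two patients")
  dt <- outer(time, time, "<")            # dt[i,j]: t_i < t_j
  te <- outer(time, time, "==")
  ei <- matrix(event == 1, n, n)          # event of the row patient
  ej <- t(ei)
  perm <- (dt & ei) | (te & ei & !ej)     # row patient is the earlier death
  diag(perm) <- FALSE
  if (!any(perm)) stop("no permissible pairs (e.g. all patients censored): concordance undefined")
  ri <- matrix(risk, n, n)
  rj <- t(ri)
  conc <- sum(perm & (ri > rj)) + 0.5 * sum(perm & (ri == rj))
  conc / sum(perm)
}

#' Dichotomize risk scores at the median
#'
#' Splits a cohort into high- and low-risk groups by the median risk score,
#' the grouping used for the two-group log-rank evaluation. A patient is
#' high-risk (label 1) iff its score is strictly greater than the median;
#' this strict rule is deterministic for odd cohort sizes and tied medians.
#'
#' @param risk Numeric vector, length at least 2.
#' @return Integer vector of 0 (low-risk) / 1 (high-risk) labels.
#' @export
medianDichotomize <- function(risk) {
  if (length(risk) < 2) stop("need at least two risk scores")
  lab <- as.integer(risk > stats::median(risk))
  if (all(lab == 0L) || all(lab == 1L))
    stop("degenerate grouping: risk scores do not separate at the median ",
         "(constant scores?); log-rank test undefined")
  lab
}

#' Log-rank test across risk groups
#'
#' Standard (Mantel--Cox) log-rank test comparing survival distributions
#' across two or more groups, from observed-minus-expected event counts at
#' the ordered distinct event times. The chi-square statistic has
#' \eqn{G - 1} degrees of freedom for \eqn{G} groups. Computed via
#' [survival::survdiff()].
#'
#' @param groups Vector of group labels (at least two distinct levels, all
#'   groups non-empty by construction).
#' @param time,event Survival outcome vectors.
#' @return A list with `statistic` (chi-square), `df`, and `p.value`.
#' @examples
#' logrankTest(c(0, 0, 1, 1), time = c(1, 2, 3, 4), event = rep(1, 4))
#' @export
logrankTest <- function(groups, time, event) {
  .checkOutcomes(time, event, n = length(groups))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("log-rank test needs at least two groups")
  if (sum(event) == 0L) stop("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event, g = groups))
  df <- length(sd$n) - 1L
  p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  list(statistic = unname(sd$chisq), df = df, p.value = max(p, .Machine$double.xmin))
}

#' Kaplan--Meier survival curve
#'
#' Product-limit estimate of the survival function; right-continuous,
#' non-increasing, starting at 1. All-censored input yields the constant
#' function 1. Thin wrapper over [survival::survfit()] returning the step
#' coordinates.
#'
#' @param time,event Survival outcome vectors.
#' @return A data.frame with columns `time`, `n.risk`, `n.event`, `surv`.
#' @export
kaplanMeier <- function(time, event) {
  .checkOutcomes(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n.risk = fit$n.risk,
             n.event = fit$n.event, surv = fit$surv)
}
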