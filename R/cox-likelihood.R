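#' Negative log Cox partial likelihood
#'
#' Evaluates the negative log partial likelihood of the Cox proportional
#' hazards model for a vector of linear predictors \eqn{\eta_i} (so hazard
#' ratios are \eqn{\theta_i = e^{\eta_i}}):
#' \deqn{-\ell(\eta) = \sum_{i: C_i = 1} \left[\log \sum_{j: Y_j \ge Y_i}
#'   e^{\eta_j} - \eta_i\right]}
#' The risk set at an event time \eqn{Y_i} contains every patient still
#' under observation at that time (\eqn{Y_j \ge Y_i}, the patient itself
#' included). Tied event times are handled with the Breslow approximation:
#' tied events share the same risk-set denominator. The value is invariant
#' under adding a constant to all \eqn{\eta_i}, and each event contributes
#' a non-negative term.
#'
#' This is the data term of the training loss of every neural architecture
#' in the package, with the network output substituted for the classical
#' linear predictor.
#'
#' @param eta Numeric vector of per-patient linear predictors.
#' @param time Non-negative numeric vector of follow-up times (months).
#' @param event Binary vector, 1 = death observed, 0 = censored.
#' @return A single non-negative number. With zero events the empty product
#'   convention gives 0, with a warning.
#' @seealso [coxNegLogLikGrad()], [fitLinearCox()]
#' @examples
#' coxNegLogLik(c(0, 0, 0), time = c(1, 2, 3), event = c(1, 1, 1)) # log(6)
#' @export
coxNegLogLik <- function(eta, time, event) {
  .checkOutcomes(time, event, n = length(eta))
  if (sum(event) == 0L) {
    warning("no events in input: partial likelihood is an empty product, returning 0")
    return(0)
  }
  # stabilise: shift invariance lets us centre eta
  eta <- eta - max(eta)
  info <- .riskSetInfo(eta, time, event)
  sum(log(info$denom[info$eventIdx]) - eta[info$eventIdx])
}

# Shared risk-set bookkeeping.
# Returns, for each patient i, denom[i] = sum_{j: Y_j >= Y_i} exp(eta_j),
# and cumHaz[i] = sum over events k with Y_k <= Y_i of 1 / denom[k]
# (the Breslow cumulative hazard at Y_i), plus the event indices.
.riskSetInfo <- function(eta, time, event) {
  n <- length(eta)
  ord <- order(time)                  # ascending
  e <- exp(eta)[ord]
  # reverse cumulative sum gives sum over Y_j >= Y_(i) within the ordering;
  # ties must share the full tied block, so propagate per unique time
  revCum <- rev(cumsum(rev(e)))
  t_ord <- time[ord]
  firstOfTie <- !duplicated(t_ord)
  # every member of a tie block takes the denominator at the block's first index
  denomOrd <- revCum[which(firstOfTie)[match(t_ord, t_ord[firstOfTie])]]
  ev_ord <- event[ord] == 1
  # Breslow cumulative hazard at each sorted position
  inc <- ifelse(ev_ord, 1 / denomOrd, 0)
  cumOrd <- cumsum(inc)
  # patients tied in time share the same cumulative hazard (risk set uses >=),
  # take the value at the last position of each tie block
  lastOfTie <- rev(!duplicated(rev(t_ord)))
  cumTie <- cumOrd[which(lastOfTie)[match(t_ord, t_ord[lastOfTie])]]
  denom <- numeric(n); denom[ord] <- denomOrd
  cumHaz <- numeric(n); cumHaz[ord] <- cumTie
  list(denom = denom, cumHaz = cumHaz, eventIdx = which(event == 1))
}

#' Gradient of the negative log partial likelihood
#'
#' Analytic gradient of [coxNegLogLik()] with respect to `eta`:
#' \eqn{\partial(-\ell)/\partial\eta_i = e^{\eta_i} \Lambda_i - C_i},
#' where \eqn{\Lambda_i} is the Breslow cumulative hazard summed over event
#' times at or before \eqn{Y_i}. Used by the network training loop and the
#' Newton solver.
#'
#' @inheritParams coxNegLogLik
#' @return Numeric vector of the same length as `eta`.
#' @export
coxNegLogLikGrad <- function(eta, time, event) {
  .checkOutcomes(time, event, n = length(eta))
  if (sum(event) == 0L) return(numeric(length(eta)))
  etaC <- eta - max(eta)
  info <- .riskSetInfo(etaC, time, event)
  exp(etaC) * info$cumHaz - event
}

.checkOutcomes <- function(time, event, n = NULL) {
  if (!is.null(n) && (length(time) != n || length(event) != n))
    stop("risk scores and outcomes must have equal length")
  if (any(time < 0)) stop("follow-up times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0 (censored) or 1 (death)")
  invisible(TRUE)
}

#' Fit a linear (classical) Cox model by penalized partial likelihood
#'
#' Newton--Raphson minimization of
#' \deqn{-\ell(X\beta) + \lambda \|\beta\|_2^2}
#' with the Breslow convention for ties. This is the classical
#' maximum-(partial-)likelihood estimator when `penalty = 0`, and the exact
#' linear special case of the neural models: a network with no hidden layer
#' trained on the same loss converges to the same coefficients.
#'
#' Constant covariate columns carry no information about relative risk; the
#' fit reports a 0 coefficient for them with a non-identifiability warning.
#' With `penalty = 0` a monotone likelihood (perfect risk separation) makes
#' the estimate diverge; this is detected and reported as an error advising
#' a positive penalty.
#'
#' @param X Numeric matrix, samples in rows, covariates in columns.
#' @param time,event Survival outcome vectors (see [coxNegLogLik()]).
#' @param penalty Non-negative ridge weight \eqn{\lambda}.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param maxIter Maximum Newton iterations.
#' @return A list of class `coxFit` with elements `beta` (named
#'   coefficients), `penalty`, `loss` (the penalized objective at the
#'   solution), `gradNorm`, and `iterations`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 20, 2)
#' tt <- rexp(20, exp(X[, 1])); ev <- rbinom(20, 1, 0.8)
#' fitLinearCox(X, tt, ev)$beta
#' @export
fitLinearCox <- function(X, time, event, penalty = 0, tol = 1e-8, maxIter = 100) {
  X <- as.matrix(X)
  n <- nrow(X); K <- ncol(X)
  .checkOutcomes(time, event, n = n)
  if (n < 2) stop("need at least two samples")
  if (sum(event) == 0L) stop("need at least one event to fit a Cox model")
  if (penalty < 0) stop("penalty must be non-negative")

  constCol <- apply(X, 2, function(x) diff(range(x)) == 0)
  if (any(constCol))
    warning("constant covariate column(s) ", paste(which(constCol), collapse = ", "),
            " are non-identifiable; coefficients set to 0")
  active <- which(!constCol)
  beta <- numeric(K)
  obj <- function(b) coxNegLogLik(drop(X %*% b), time, event) + penalty * sum(b^2)

  if (length(active)) {
    Xa <- X[, active, drop = FALSE]
    b <- numeric(length(active))
    f <- obj(.expand(b, active, K))
    iter <- 0L
    repeat {
      iter <- iter + 1L
      eta <- drop(Xa %*% b)
      g_eta <- coxNegLogLikGrad(eta, time, event)
      H_eta <- .coxHessianEta(eta, time, event)
      g <- drop(crossprod(Xa, g_eta)) + 2 * penalty * b
      H <- crossprod(Xa, H_eta %*% Xa) + diag(2 * penalty, length(b))
      step <- tryCatch(solve(H, g), error = function(e) g / (max(diag(H)) + 1e-12))
      # step halving
      s <- 1
      repeat {
        bNew <- b - s * step
        fNew <- obj(.expand(bNew, active, K))
        if (is.finite(fNew) && fNew <= f + 1e-12) break
        s <- s / 2
        if (s < 1e-10) { bNew <- b; fNew <- f; break }
      }
      b <- bNew; f <- fNew
      gn <- max(abs(drop(crossprod(Xa, coxNegLogLikGrad(drop(Xa %*% b), time, event))) +
                      2 * penalty * b))
      # monotone likelihood: the estimate runs away (the gradient decays
      # exponentially in |beta|, so it can look "converged" at huge beta)
      if (penalty == 0 && max(abs(b)) > 15)
        stop("diverging coefficient estimates (perfect risk separation); ",
             "refit with a positive penalty")
      if (gn < tol || iter >= maxIter) break
    }
    beta[active] <- b
    gradNorm <- gn
    iterations <- iter
  } else {
    gradNorm <- 0; iterations <- 0L
  }
  names(beta) <- colnames(X)
  structure(list(beta = beta, penalty = penalty, loss = obj(beta),
                 gradNorm = gradNorm, iterations = iterations),
            class = "coxFit")
}

.expand <- function(b, active, K) { out <- numeric(K); out[active] <- b; out }

# Hessian of -l(eta) wrt eta (dense n x n), Breslow ties.
# H = diag(exp(eta) * cumHaz) - sum_k w_k w_k^T / denom_k  with
# w_k[j] = exp(eta_j) * [Y_j >= Y_k], summed over events k.
.coxHessianEta <- function(eta, time, event) {
  n <- length(eta)
  etaC <- eta - max(eta)
  info <- .riskSetInfo(etaC, time, event)
  e <- exp(etaC)
  H <- diag(e * info$cumHaz, n)
  for (k in which(event == 1)) {
    w <- e * (time >= time[k])
    H <- H - tcrossprod(w) / info$denom[k]^2
  }
  H
}

#' @export
print.coxFit <- function(x, ...) {
  cat("Penalized linear Cox fit\n")
  cat("  coefficients:", paste(signif(x$beta, 5), collapse = ", "), "\n")
  cat("  penalty:", x$penalty, " loss:", signif(x$loss, 8),
      " |grad|:", format(x$gradNorm, digits = 3), "\n")
  invisible(x)
}
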