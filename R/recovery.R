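#' Sigmoidal recovery model
#'
#' The lag-parameterised Gompertz-type sigmoid used to describe postictal
#' ADR restoration:
#' \deqn{f(t) = (U - A) + A \exp(-\exp(1 + (\lambda - t)/\tau))}
#' with lower asymptote \eqn{U - A} (the deeply suppressed start, close to
#' -1), upper asymptote \eqn{U}, recovery amplitude \eqn{A}, initial lag
#' \eqn{\lambda} (min) and time constant \eqn{\tau} (min). The curve is
#' non-decreasing with a single inflection at \eqn{t = \lambda + \tau},
#' which is the time of fastest recovery.
#'
#' @param t time since seizure offset (min); vectorised.
#' @param A recovery amplitude (> 0).
#' @param lam initial lag (min).
#' @param tau time constant (min, > 0).
#' @param U upper asymptote (ADR units).
#' @return Model value(s) in ADR units.
#' @examples
#' sigmoidEval(27, A = 1, lam = 5.9, tau = 21.1, U = 0.1)
#' @export
sigmoidEval <- function(t, A, lam, tau, U) {
  if (tau <= 0) stop("tau must be positive")
  (U - A) + A * exp(-exp(1 + (lam - t) / tau))
}

#' Derivative of the recovery model
#'
#' \eqn{df/dt = (A/\tau)\exp(u - e^{u})} with \eqn{u = 1 + (\lambda - t)/\tau};
#' maximal at \eqn{t = \lambda + \tau} where it equals \eqn{A/(\tau e)}.
#'
#' @inheritParams sigmoidEval
#' @return Derivative value(s), ADR units per minute.
#' @export
sigmoidDeriv <- function(t, A, lam, tau, U) {
  if (tau <= 0) stop("tau must be positive")
  u <- 1 + (lam - t) / tau
  (A / tau) * exp(u - exp(u))
}

#' Fit the sigmoidal recovery model to an ADR series
#'
#' Nonlinear least squares (Levenberg-Marquardt with box bounds) over the
#' non-missing minute bins, with five deterministic multi-start
#' initialisations; the start with the lowest residual sum of squares is
#' kept. Missing minutes are dropped from the loss. Sessions providing
#' fewer than \code{minMinutes} valid minutes are rejected with an error,
#' honouring the minimum 40-minute postictal span the model assumes.
#'
#' @param series an [ADRSeries-class].
#' @param gate goodness-of-fit gate on R^2 (default 0.7); fits below it are
#'   flagged \code{qcPass = FALSE}.
#' @param minMinutes minimum number of non-missing minute bins (default 40).
#' @return A [SigmoidFit-class].
#' @export
fitSigmoid <- function(series, gate = 0.7, minMinutes = 40) {
  stopifnot(is(series, "ADRSeries"))
  ok <- !is.na(series@adr)
  if (sum(ok) < minMinutes)
    stop("insufficient data: ", sum(ok), " valid minutes (< ", minMinutes,
         ") - session excluded")
  t <- as.numeric(series@minute[ok])
  y <- series@adr[ok]
  D <- max(t)

  U0 <- max(y)
  A0 <- max(diff(range(y)), 0.05)
  riseT <- t[y > min(y) + 0.1 * A0]
  lamCand <- unique(pmin(pmax(c(if (length(riseT)) riseT[1] else 2,
                                2, 5, 8, 12), 0), D))
  halfT <- t[y > min(y) + 0.5 * A0]
  half <- if (length(halfT)) halfT[1] else D / 2

  lower <- c(A = 1e-6, lam = 0, tau = 0.5, U = -1)
  upper <- c(A = 2.5, lam = D, tau = 60, U = 1.2)
  best <- NULL
  bestSSE <- Inf
  for (lam0 in lamCand) {
    tau0 <- min(max(half - lam0, 1), 40)
    start <- list(A = min(max(A0, 0.05), 2.5), lam = lam0, tau = tau0,
                  U = min(max(U0, -1), 1.2))
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ (U - A) + A * exp(-exp(1 + (lam - t) / tau)),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (sse < bestSSE) {
      bestSSE <- sse
      best <- fit
    }
  }
  if (is.null(best)) {
    return(new("SigmoidFit", A = NA_real_, lam = NA_real_, tau = NA_real_,
               U = NA_real_, rSquared = NA_real_, converged = FALSE,
               tMax = NA_real_, maxSlope = NA_real_, D = D,
               qcPass = FALSE, boundary = FALSE))
  }
  p <- stats::coef(best)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - bestSSE / sst else NA_real_
  tm <- unname(p["lam"] + p["tau"])
  boundary <- tm > D || tm < 0
  new("SigmoidFit",
      A = unname(p["A"]), lam = unname(p["lam"]), tau = unname(p["tau"]),
      U = unname(p["U"]), rSquared = r2, converged = TRUE,
      tMax = min(max(tm, 0), D),
      maxSlope = unname(p["A"] / (p["tau"] * exp(1))),
      D = D, qcPass = !is.na(r2) && r2 >= gate - 1e-9, boundary = boundary)
}

#' Goodness of fit of a sigmoid fit on its series
#'
#' R^2 = 1 - SSE/SST over the non-missing minutes. Sessions with
#' R^2 below the gate (0.7, inclusive bound: exactly 0.7 passes) are QC
#' failures and excluded from the association stage. A zero-variance series
#' has undefined R^2 and fails QC.
#'
#' @param series the fitted [ADRSeries-class].
#' @param fit the [SigmoidFit-class].
#' @param gate QC gate (default 0.7).
#' @return A list with \code{rSquared} and logical \code{qcPass}.
#' @export
goodnessOfFit <- function(series, fit, gate = 0.7) {
  stopifnot(is(series, "ADRSeries"), is(fit, "SigmoidFit"))
  if (!fit@converged) return(list(rSquared = NA_real_, qcPass = FALSE))
  ok <- !is.na(series@adr)
  t <- as.numeric(series@minute[ok])
  y <- series@adr[ok]
  pred <- sigmoidEval(t, fit@A, fit@lam, fit@tau, fit@U)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(list(rSquared = NA_real_, qcPass = FALSE))
  r2 <- 1 - sum((y - pred)^2) / sst
  list(rSquared = r2, qcPass = r2 >= gate - 1e-9)
}

#' Time of maximum recovery rate
#'
#' The argmax of the fitted derivative over the observed span [0, D]. For
#' this model form the unconstrained argmax is \eqn{\lambda + \tau}; when it
#' falls outside the span the value is capped at the boundary and the fit's
#' boundary flag is set.
#'
#' @param fit a converged [SigmoidFit-class].
#' @return T_max in minutes.
#' @examples
#' # lambda = 5.9, tau = 21.1 => T_max = 27 min
#' @export
tMax <- function(fit) {
  stopifnot(is(fit, "SigmoidFit"))
  if (!fit@converged) stop("fit did not converge: T_max undefined")
  if (fit@boundary)
    warning("derivative argmax at the boundary of [0, ", fit@D, "] min")
  fit@tMax
}

#' Numeric derivative argmax (grid oracle)
#'
#' Brute-force argmax of [sigmoidDeriv()] on a fine grid over [0, D];
#' cross-checks the analytic \eqn{\lambda + \tau}.
#'
#' @inheritParams sigmoidEval
#' @param D span (min).
#' @param by grid step (min), default 0.01.
#' @return Grid argmax (min).
#' @export
numericTmax <- function(A, lam, tau, U, D = 60, by = 0.01) {
  grid <- seq(0, D, by = by)
  grid[which.max(sigmoidDeriv(grid, A, lam, tau, U))]
}

#' Extract the EEG features forwarded to the association stage
#'
#' Returns \code{tMax}, \code{A} and \code{tau} for a QC-passed fit; QC
#' failures yield a missing row (NAs) so that the session drops out of the
#' session table.
#'
#' @param fit a [SigmoidFit-class].
#' @return Named numeric vector \code{c(tMax, A, tau)}.
#' @export
extractFeatures <- function(fit) {
  stopifnot(is(fit, "SigmoidFit"))
  if (!fit@converged || !fit@qcPass) {
    message("QC-failed fit: features withheld")
    return(c(tMax = NA_real_, A = NA_real_, tau = NA_real_))
  }
  c(tMax = fit@tMax, A = fit@A, tau = fit@tau)
}
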