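test_that("sigmoid form has the right asymptotes, lag value and monotonicity", {
  A <- 1; lam <- 5.9; tau <- 21; U <- 0.1
  expect_equal(sigmoidEval(1e6, A, lam, tau, U), U, tolerance = 1e-12)
  expect_equal(sigmoidEval(-1e6, A, lam, tau, U), U - A, tolerance = 1e-12)
  expect_equal(sigmoidEval(lam, A, lam, tau, U),
               (U - A) + A * exp(-exp(1)), tolerance = 1e-12)
  expect_error(sigmoidEval(1, A, lam, 0, U), "tau")

  set.seed(31)
  pars <- randomSigmoidParams(25)
  grid <- seq(0, 60, by = 0.01)
  for (i in seq_len(nrow(pars))) {
    f <- sigmoidEval(grid, pars$A[i], pars$lam[i], pars$tau[i], pars$U[i])
    expect_true(all(diff(f) >= -1e-12))
    expect_true(all(f >= pars$U[i] - pars$A[i] - 1e-9 & f <= pars$U[i] + 1e-9))
  }
})

test_that("noiseless curves are refit to high precision and refits are idempotent", {
  ser <- sigmoidSeries(A = 1.0, lam = 5.9, tau = 21, U = 0.1)
  fit <- fitSigmoid(ser)
  expect_true(fit@converged)
  expect_equal(unname(fitParams(fit)), c(1.0, 5.9, 21, 0.1),
               tolerance = 1e-3)
  expect_equal(fit@rSquared, 1, tolerance = 1e-6)

  # refitting the model to its own predictions reproduces the parameters
  pred <- sigmoidEval(0:59, fit@A, fit@lam, fit@tau, fit@U)
  fit2 <- fitSigmoid(ADRSeries(0:59, pred))
  expect_equal(fitParams(fit2), fitParams(fit), tolerance = 1e-6)
})

test_that("too few valid minutes rejects the session", {
  ser <- sigmoidSeries(minutes = 0:59)
  ser@adr[40:60] <- NA  # 39 valid minutes remain
  expect_error(fitSigmoid(ser), "insufficient data")
})

test_that("T_max equals lambda plus tau and matches the grid argmax", {
  f <- new("SigmoidFit", A = 1, lam = 5.9, tau = 21.1, U = 0.1,
           rSquared = 1, converged = TRUE, tMax = 27, maxSlope = 1,
           D = 60, qcPass = TRUE, boundary = FALSE)
  expect_equal(tMax(f), 27.0)

  set.seed(41)
  pars <- randomSigmoidParams(100)
  for (i in seq_len(nrow(pars))) {
    analytic <- pars$lam[i] + pars$tau[i]
    numeric <- numericTmax(pars$A[i], pars$lam[i], pars$tau[i], pars$U[i],
                           D = 60)
    expect_lt(abs(analytic - numeric), 0.05)
  }

  # fastest allowed time constant: T_max collapses to lam + 0.5
  serFast <- sigmoidSeries(A = 1, lam = 6, tau = 0.5, U = 0.1)
  fitFast <- fitSigmoid(serFast)
  expect_equal(fitFast@tMax, 6.5, tolerance = 0.05)
})

test_that("goodness of fit gates sessions inclusively at 0.7", {
  ser <- sigmoidSeries()
  fit <- fitSigmoid(ser)
  expect_equal(goodnessOfFit(ser, fit)$rSquared, 1, tolerance = 1e-6)

  # R^2 relative to the series mean model is 0 by construction
  flat <- ADRSeries(0:59, rep(-0.2, 60))
  gof <- goodnessOfFit(flat, fit)
  expect_true(is.na(gof$rSquared))  # zero-variance series: undefined
  expect_false(gof$qcPass)

  # construct a series whose R^2 against the fit is exactly 0.7:
  # inclusive bound must pass
  t <- 0:59
  fitE <- new("SigmoidFit", A = 1, lam = 5.9, tau = 21, U = 0.5,
              rSquared = 1, converged = TRUE, tMax = 26.9, maxSlope = 1,
              D = 59, qcPass = TRUE, boundary = FALSE)
  pred <- sigmoidEval(t, fitE@A, fitE@lam, fitE@tau, fitE@U)
  u <- rep(c(1, -1), 30)
  alpha <- uniroot(function(a) {
    y <- pred + a * u
    1 - sum((y - pred)^2) / sum((y - mean(y))^2) - 0.7
  }, c(1e-6, 1), tol = 1e-12)$root
  serEdge <- ADRSeries(t, pred + alpha * u)
  gofEdge <- goodnessOfFit(serEdge, fitE)
  expect_equal(gofEdge$rSquared, 0.7, tolerance = 1e-6)
  expect_true(gofEdge$qcPass)
})

test_that("the noisy-series estimator is unbiased and near the information bound", {
  # Cramer-Rao bound for T_max = lam + tau at sigma = 0.05, 60 minute bins,
  # truth (A = 1, lam = 5.9, tau = 21, U = 0.1): sd(T_max) = 1.92 min, so an
  # efficient estimator has median |error| ~ 0.6745 * 1.92 = 1.29 min
  crlbSd <- local({
    A <- 1; lam <- 5.9; tau <- 21; t <- 0:59
    u <- 1 + (lam - t) / tau
    E <- exp(-exp(u))
    G <- cbind(-1 + E, A * -exp(u) * E / tau,
               A * -exp(u) * E * (-(lam - t) / tau^2), 1)
    V <- solve(crossprod(G) / 0.05^2)
    sqrt(c(0, 1, 1, 0) %*% V %*% c(0, 1, 1, 0))
  })
  set.seed(51)
  reps <- 60
  err <- numeric(reps)
  r2 <- numeric(reps)
  for (i in seq_len(reps)) {
    ser <- sigmoidSeries(A = 1, lam = 5.9, tau = 21, U = 0.1,
                         noiseSd = 0.05)
    fit <- fitSigmoid(ser)
    err[i] <- fit@tMax - 26.9
    r2[i] <- fit@rSquared
  }
  expect_lt(abs(mean(err)), 0.75)                   # unbiased
  expect_lte(median(abs(err)), 0.6745 * crlbSd * 1.3)  # near-efficient
  expect_gte(mean(r2 >= 0.7), 0.95)                 # QC gate attainable
})

test_that("a flat series fails the gate and withholds features", {
  flat <- ADRSeries(0:59, rep(-0.9, 60) + rep(c(0, 1e-4), 30))
  fit <- fitSigmoid(flat)
  expect_false(fit@qcPass)
  expect_message(feats <- extractFeatures(fit), "withheld")
  expect_true(all(is.na(feats)))

  good <- fitSigmoid(sigmoidSeries())
  feats2 <- extractFeatures(good)
  expect_true(all(is.finite(feats2)))
  expect_true(feats2["A"] > 0 && feats2["A"] <= 2.5)
  expect_true(feats2["tau"] >= 0.5 && feats2["tau"] <= 60)
})
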