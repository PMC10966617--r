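test_that("session table joins, standardizes, and guards integrity", {
  study <- syntheticFeatureStudy(seed = 3)
  tab <- sessionTableFromStudy(study)
  expect_s3_class(tab, "SessionTable")
  expect_equal(nrow(tab), nrow(study$sessions))
  # z-scored continuous predictors
  expect_equal(mean(tab$age), 0, tolerance = 1e-10)
  expect_equal(sd(tab$age), 1, tolerance = 1e-10)
  expect_true(all(tab$midazolam %in% 0:1))

  dup <- study$sessions[c(1, 1), ]
  expect_error(
    buildSessionTable(dup[, c("session_id", "t_max", "A", "tau")],
                      dup, dup[, c("session_id", "rot_person", "rot_place",
                                   "rot_time")]),
    "duplicate")

  # a session missing one domain outcome drops from that model only
  tab2 <- tab
  tab2$rot_place[1] <- NA
  mPlace <- suppressMessages(fitDomainLMM(tab2, "place"))
  mPerson <- suppressMessages(fitDomainLMM(tab2, "person"))
  expect_equal(mPlace$nObs, nrow(tab2) - 1)
  expect_equal(mPerson$nObs, nrow(tab2))
})

test_that("noise-free latent outcomes reduce the mixed model to least squares", {
  cfg <- simConfig(seed = 5, randomEffectSds = c(intercept = 0, slope = 0),
                   residSd = 0)
  study <- simulateStudy(cfg)
  tab <- sessionTableFromStudy(study)
  # use the exact latent outcome: linear predictor with no noise at all
  tab$rot_person <- study$latentROT$true_person[
    match(tab$session_id, study$latentROT$session_id)]
  m <- suppressMessages(fitDomainLMM(tab, "person"))
  ols <- lm(rot_person ~ t_max + A + tau + charge_mc + seizure_duration_s +
              midazolam + placement_bl + session_number + sex_male + age,
            data = as.data.frame(tab))
  expect_equal(m$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
  # and both recover the generating coefficients exactly
  bt <- betaDefaults()
  est <- setNames(m$coefficients$estimate, m$coefficients$term)
  expect_equal(est[["t_max"]], bt$beta$person[["t_max"]], tolerance = 1e-6)
  expect_equal(est[["seizure_duration_s"]],
               bt$beta$person[["seizure_duration_s"]], tolerance = 1e-6)
  expect_equal(est[["(Intercept)"]], unname(bt$intercepts["person"]),
               tolerance = 1e-6)
})

test_that("the domain mixed model recovers generating effects with sane inference", {
  study <- syntheticFeatureStudy(seed = 6)
  tab <- sessionTableFromStudy(study)
  m <- fitDomainLMM(tab, "person")
  expect_equal(m$method, "REML")
  co <- m$coefficients
  expect_true(all(co$lower <= co$estimate & co$estimate <= co$upper))
  expect_true(all(co$p >= 0 & co$p <= 1))
  est <- setNames(co$estimate, co$term)
  bt <- betaDefaults()$beta$person
  # single-study estimates land near the generating values
  expect_lt(abs(est[["t_max"]] - bt[["t_max"]]), 1.5)
  expect_lt(abs(est[["midazolam"]] - bt[["midazolam"]]), 3)
  expect_true(all(m$vif$vif >= 1))
  # T_max = lam + tau by construction, with tau also a fixed effect: the
  # screen must detect this structural collinearity, while the remaining
  # covariates are independent by design
  expect_true(all(m$vif$flagged[m$vif$term %in% c("t_max", "tau")]))
  other <- !(m$vif$term %in% c("t_max", "tau"))
  expect_false(any(m$vif$flagged[other]))
})

test_that("a truly zero random slope triggers the downgrade without biasing effects", {
  cfg <- simConfig(seed = 8, randomEffectSds = c(intercept = 4, slope = 0))
  study <- simulateStudy(cfg)
  tab <- sessionTableFromStudy(study)
  m <- suppressMessages(fitDomainLMM(tab, "person"))
  expect_true(m$downgraded)
  est <- setNames(m$coefficients$estimate, m$coefficients$term)
  expect_lt(abs(est[["t_max"]] - 1.5), 1.5)
})

test_that("VIF screen matches the closed form and flags exact collinearity", {
  set.seed(13)
  n <- 400
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  v <- vifScreen(X, c("a", "b", "c"))
  expect_true(all(abs(v$vif - 1) < 0.15))  # independent: VIF ~ 1

  # generating correlation 0.6: VIF ~ 1/(1 - 0.36) = 1.5625, below 5
  X$d <- 0.6 * scale(X$a)[, 1] + sqrt(1 - 0.36) * rnorm(n)
  v2 <- vifScreen(X, c("a", "b", "d"))
  expect_equal(v2$vif[v2$term == "d"], 1 / (1 - 0.36), tolerance = 0.2)
  expect_false(any(v2$flagged))

  X$dup <- X$a
  v3 <- vifScreen(X, c("a", "b", "dup"))
  expect_true(is.infinite(v3$vif[v3$term == "dup"]))
  expect_true(v3$flagged[v3$term == "dup"])
  expect_error(vifScreen(X, "a"), "at least two")
})

test_that("midazolam-free sensitivity refits agree when midazolam has no true effect", {
  bt <- betaDefaults()
  for (d in names(bt$beta)) bt$beta[[d]]["midazolam"] <- 0
  cfg <- simConfig(seed = 9, betaTruth = bt)
  study <- simulateStudy(cfg)
  tab <- sessionTableFromStudy(study)
  full <- suppressMessages(fitDomainLMM(tab, "person"))
  sens <- suppressMessages(midazolamSensitivity(tab))
  expect_named(sens, c("person", "place", "time"))
  expect_equal(sens$person$nObs, sum(tab$midazolam == 0))
  eFull <- setNames(full$coefficients$estimate, full$coefficients$term)
  eSub <- setNames(sens$person$coefficients$estimate,
                   sens$person$coefficients$term)
  expect_lt(abs(eFull[["t_max"]] - eSub[["t_max"]]), 1.5)
  expect_false("midazolam" %in% sens$person$coefficients$term)

  allMid <- tab
  allMid$midazolam <- 1
  expect_warning(out <- midazolamSensitivity(allMid), "skipped")
  expect_null(out)
})
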