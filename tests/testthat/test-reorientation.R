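makeLog <- function(person = c(20, 30), place = 30, time = c(25, 35),
                    oriented = c(person = TRUE, place = TRUE, time = TRUE)) {
  data.frame(
    question_id = c("name", "birthday", "hospital", "age", "weekday"),
    minutes_to_correct = c(person, place, time),
    baseline_oriented = rep(oriented[c("person", "person", "place",
                                       "time", "time")], 1))
}

test_that("domain scoring averages two-question domains and excludes baseline disorientation", {
  log <- makeLog()
  expect_equal(as.numeric(timeToReorientation(log, "person")), 25)
  expect_equal(as.numeric(timeToReorientation(log, "place")), 30)
  expect_equal(as.numeric(timeToReorientation(log, "time")), 30)

  # the domain value always lies between its question times
  set.seed(61)
  for (i in 1:20) {
    qt <- sort(runif(2, 0, 60))
    v <- as.numeric(timeToReorientation(makeLog(person = qt), "person"))
    expect_gte(v, qt[1]); expect_lte(v, qt[2])
  }

  # baseline disorientation: ignored, not censored
  logB <- makeLog(oriented = c(person = TRUE, place = TRUE, time = FALSE))
  v <- timeToReorientation(logB, "time")
  expect_true(is.na(v))
  expect_false(attr(v, "censored"))

  # never answered within the window: censored
  logC <- makeLog(person = c(20, NA))
  v2 <- timeToReorientation(logC, "person")
  expect_true(is.na(v2))
  expect_true(attr(v2, "censored"))
})

test_that("multi-session log scoring produces one wide row per session", {
  log1 <- makeLog(); log1$session_id <- "a"
  log2 <- makeLog(person = c(10, 20)); log2$session_id <- "b"
  out <- scoreROTLog(rbind(log1, log2))
  expect_equal(nrow(out), 2)
  expect_equal(out$rot_person, c(25, 15))
})

test_that("domain order flags the classic person-place-time sequence", {
  o <- domainOrder(c(person = 24, place = 28.6, time = 33))
  expect_equal(o$order, c("person", "place", "time"))
  expect_true(o$classic)

  # ties are simultaneous and non-strict
  expect_true(domainOrder(c(person = 30, place = 30, time = 30))$classic)
  # time first falsifies the sequence
  expect_false(domainOrder(c(person = 30, place = 35, time = 20))$classic)
  # fewer than two domains: undefined
  expect_true(is.na(domainOrder(c(person = 20, place = NA,
                                  time = NA))$order[1]))
})

test_that("strict classic order arises in one sixth of exchangeable nulls", {
  set.seed(71)
  n <- 6000
  strict <- vapply(seq_len(n), function(i) {
    r <- runif(3)
    r[1] < r[2] && r[2] < r[3]
  }, logical(1))
  phat <- mean(strict)
  expect_equal(phat, 1 / 6, tolerance = 0.1)
  # and the package's non-strict flag agrees on those strict cases
  set.seed(72)
  agree <- vapply(seq_len(500), function(i) {
    r <- runif(3); names(r) <- c("person", "place", "time")
    domainOrder(r)$classic == (r[1] <= r[2] && r[2] <= r[3])
  }, logical(1))
  expect_true(all(agree))
})

test_that("paired signed-rank comparisons detect ordered domain shifts", {
  set.seed(81)
  hits <- replicate(40, {
    person <- rnorm(32, 24, 4)
    rots <- data.frame(subject_id = sprintf("S%02d", 1:32),
                       rot_person = person,
                       rot_place = person + 5 + rnorm(32, 0, 2),
                       rot_time = person + 10 + rnorm(32, 0, 2))
    all(compareDomains(rots)$p < 0.05)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("signed-rank p-values are symmetric, degenerate-safe, and need 6 pairs", {
  set.seed(82)
  rots <- data.frame(subject_id = sprintf("S%02d", 1:12),
                     rot_person = rnorm(12, 24, 4),
                     rot_place = rnorm(12, 28, 4),
                     rot_time = rnorm(12, 33, 4))
  fwd <- compareDomains(rots)
  swapped <- rots
  names(swapped)[2:3] <- names(rots)[3:2]
  rev <- compareDomains(swapped)
  expect_equal(fwd$p[1], rev$p[1])

  same <- rots
  same$rot_place <- same$rot_person
  out <- compareDomains(same)
  expect_true(out$degenerate[1])
  expect_true(is.na(out$p[1]))

  expect_error(compareDomains(rots[1, , drop = FALSE]), "fewer than 6")
})

test_that("response and remission flags follow the HDRS definitions", {
  o <- clinicalOutcome(23.5, 12)
  expect_false(o$response)  # 12 > 11.75
  expect_false(o$remission)
  o2 <- clinicalOutcome(20, 10)  # exactly 50% counts as response
  expect_true(o2$response)
  expect_false(o2$remission)
  o3 <- clinicalOutcome(20, 7)
  expect_true(o3$response)
  expect_true(o3$remission)
  expect_error(clinicalOutcome(-1, 5), "nonnegative")
})
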