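#' Truncated normal draws
#' @noRd
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Default per-domain fixed-effect truths
#'
#' Generating coefficients (minutes per standardized unit for continuous
#' predictors, minutes per level for binary ones) and intercepts used by
#' the reorientation-time generator. Effects the source analysis found
#' null are set to zero.
#'
#' @return A list with \code{intercepts} (named by domain) and \code{beta}
#'   (list of named coefficient vectors per domain).
#' @export
betaDefaults <- function() {
  nm <- c("t_max", "A", "tau", "charge_mc", "seizure_duration_s",
          "midazolam", "placement_bl", "session_number", "sex_male", "age")
  mk <- function(...) stats::setNames(c(...), nm)
  list(
    intercepts = c(person = 24.0, place = 28.6, time = 33.0),
    beta = list(
      person = mk(1.5, -1.2, 0.7, 0, 2.5, 4.4, 0, 0, 0, 0),
      place = mk(3.3, -1.2, -0.7, 2.6, 3.1, 8.3, 5.2, 0, 0, 0),
      time = mk(2.4, -2.8, -0.3, 0, 3.3, 5.6, 0, 0, 0, 4.0)
    )
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator with defaults that
#' emulate the clinical study conditions: 32 subjects averaging 8.5 ECT
#' sessions each (about 272 sessions), 12-channel recordings at 128 Hz for
#' 60 postictal minutes, sigmoid recovery truths centred on the reported
#' group parameters, and reorientation times generated from a linear
#' mixed model on the true EEG features and covariates, observed on a
#' 5-minute question grid starting 5 minutes after seizure offset.
#'
#' @param nSubjects number of subjects.
#' @param sessionsPerSubject mean sessions per subject (fractional means a
#'   random 50/50 split between the adjacent integers).
#' @param fs sampling rate (Hz, >= 128).
#' @param postictalDuration recorded postictal span (min, >= 40).
#' @param nChannels electrodes per recording.
#' @param seizureDurationDist mean and SD of seizure duration (s).
#' @param chargeDist mean and SD of stimulus charge (mC).
#' @param ageDist mean and SD of age (years).
#' @param sigmoidTruth list of c(mean, sd) for \code{A}, \code{lam},
#'   \code{tau} and the offset of the upper asymptote above \code{A - 1}.
#' @param betaTruth per-domain fixed-effect truths; see [betaDefaults()].
#' @param randomEffectSds SDs of the by-subject random intercept (min) and
#'   random T_max slope (min per standardized unit).
#' @param residSd residual SD of latent reorientation times (min).
#' @param questionInterval reorientation question spacing (min).
#' @param firstAssessment time of the first postictal question (min).
#' @param midazolamProb per-session probability of postictal midazolam.
#' @param placementProbBL per-session probability of bilateral placement.
#' @param sexProbMale per-subject probability of male sex.
#' @param adrNoiseSd per-minute ADR observation noise for the
#'   features-only path when series are materialised.
#' @param artifactRate injected artifact transients per minute (full path).
#' @param totalPower total alpha+delta signal power (uV^2).
#' @param seed root seed; all randomness derives from it.
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nSubjects = 32, sessionsPerSubject = 8.5,
                      fs = 128, postictalDuration = 60, nChannels = 12,
                      seizureDurationDist = c(58.5, 29.9),
                      chargeDist = c(349.3, 162.4),
                      ageDist = c(54.2, 13.9),
                      sigmoidTruth = list(A = c(0.33, 0.27),
                                          lam = c(6.3, 3.1),
                                          tau = c(23.1, 8.0),
                                          Uoffset = c(0.05, 0.05)),
                      betaTruth = betaDefaults(),
                      randomEffectSds = c(intercept = 4, slope = 1.5),
                      residSd = 5,
                      questionInterval = 5, firstAssessment = 5,
                      midazolamProb = 0.371, placementProbBL = 0.658,
                      sexProbMale = 0.44,
                      adrNoiseSd = 0.01, artifactRate = 2,
                      totalPower = 400, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$nSubjects >= 1, cfg$sessionsPerSubject > 0)
  if (cfg$fs < 128) stop("fs must be at least 128 Hz")
  if (cfg$postictalDuration < 40)
    stop("postictalDuration must be at least 40 min")
  if (cfg$questionInterval <= 0) stop("questionInterval must be positive")
  sds <- c(cfg$randomEffectSds, cfg$residSd, cfg$adrNoiseSd)
  if (any(sds < 0)) stop("all SDs must be nonnegative")
  class(cfg) <- "SimConfig"
  cfg
}

#' Synthesize a postictal EEG recording with programmed ADR trajectory
#'
#' Builds a multichannel microvolt-scale signal as the sum of two
#' independent band-limited Gaussian processes (delta 0.5-4 Hz, alpha
#' 8-13 Hz) whose time-varying gains are chosen so that the windowed
#' alpha/delta band-power balance tracks the programmed sigmoid exactly in
#' expectation. Gains are calibrated against the band power measured after
#' the standard 0.5-30 Hz first-order two-pass Butterworth, so the analysis
#' pipeline recovers the programmed trajectory without filter bias. All
#' channels share the gain laws with independent noise realisations.
#' Optional artifacts are 500-uV, 1-s half-sine transients on a random
#' single channel, flagged in the \code{"artifacts"} attribute.
#'
#' @param truth named vector or list with \code{A}, \code{lam}, \code{tau},
#'   \code{U}: the sigmoid ground truth.
#' @param duration postictal span (min, >= 40 unless \code{relaxed}).
#' @param fs sampling rate (Hz).
#' @param nChannels number of channels (>= 1).
#' @param totalPower constant alpha+delta power (uV^2).
#' @param artifactRate expected artifact transients per minute (0 disables).
#' @param deltaBand,alphaBand synthesis bands (Hz).
#' @param relaxed allow durations below 40 min (for unit-scale fixtures).
#' @return An [EEGRecording-class] starting at the seizure offset
#'   (\code{startTime = 0}, marker \code{offset = 0}).
#' @export
simulatePostictalEEG <- function(truth, duration = 60, fs = 128,
                                 nChannels = 12, totalPower = 400,
                                 artifactRate = 0,
                                 deltaBand = c(0.5, 4), alphaBand = c(8, 13),
                                 relaxed = FALSE) {
  truth <- as.list(truth)
  if (fs <= 0 || duration <= 0) stop("fs and duration must be positive")
  if (!relaxed && duration < 40) stop("duration must be at least 40 min")
  if (nChannels < 1) stop("need at least one channel")
  n <- round(duration * 60 * fs)
  tMin <- (seq_len(n) - 1) / fs / 60
  f <- sigmoidEval(tMin, truth$A, truth$lam, truth$tau, truth$U)
  f <- pmin(pmax(f, -1), 1)
  gAlpha <- sqrt(totalPower * (1 + f) / 2)
  gDelta <- sqrt(totalPower * (1 - f) / 2)

  calDelta <- bandGainCalibration(deltaBand, fs)
  calAlpha <- bandGainCalibration(alphaBand, fs)

  samples <- matrix(0, nChannels, n)
  for (ch in seq_len(nChannels)) {
    d <- bandNoise(n, fs, deltaBand) / sqrt(calDelta)
    a <- bandNoise(n, fs, alphaBand) / sqrt(calAlpha)
    samples[ch, ] <- gDelta * d + gAlpha * a
  }

  artifacts <- data.frame(time = numeric(0), channel = integer(0))
  if (artifactRate > 0) {
    nArt <- stats::rpois(1, artifactRate * duration)
    if (nArt > 0) {
      at <- sort(stats::runif(nArt, 0, duration * 60 - 1))
      achan <- sample.int(nChannels, nArt, replace = TRUE)
      pulse <- 500 * sin(pi * seq(0, 1, length.out = round(fs)))
      for (k in seq_len(nArt)) {
        i0 <- round(at[k] * fs) + 1L
        idx <- i0:(i0 + length(pulse) - 1L)
        samples[achan[k], idx] <- samples[achan[k], idx] + pulse
      }
      artifacts <- data.frame(time = at, channel = achan)
    }
  }
  rec <- EEGRecording(samples, fs = fs, startTime = 0,
                      markers = c(offset = 0))
  attr(rec, "artifacts") <- artifacts
  rec
}

#' Flat-spectrum band-limited unit-variance Gaussian noise (frequency-domain)
#' @noRd
bandNoise <- function(n, fs, band) {
  freq <- (0:(n - 1)) * fs / n
  half <- freq <= fs / 2
  inBand <- half & freq >= band[1] & freq <= band[2]
  X <- complex(real = rep(0, n), imaginary = rep(0, n))
  m <- sum(inBand)
  X[inBand] <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  # hermitian mirror for a real signal
  idx <- which(inBand)
  X[n - idx + 2L] <- Conj(X[idx])
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' In-band power fraction of a unit flat-band process after the standard
#' 0.5-30 Hz first-order two-pass Butterworth: mean |H|^4 over the band.
#' @noRd
bandGainCalibration <- function(band, fs, low = 0.5, high = 30) {
  bf <- signal::butter(1, c(low, high) / (fs / 2), type = "pass")
  w <- seq(band[1], band[2], length.out = 512) * 2 * pi / fs
  zk <- exp(-1i * outer(w, seq_along(bf$b) - 1))
  H <- as.vector(zk %*% bf$b) / as.vector(zk %*% bf$a)
  mean(Mod(H)^4)   # two passes: power transfer |H|^2 applied twice
}

#' Synthesize an ictal EEG segment ending in suppression
#'
#' A rhythmic 3-Hz spike-wave-like pattern (sharp spike plus slow wave,
#' several hundred uV) lasting \code{seizureDuration} seconds, followed by
#' a generalized suppression tail of low-amplitude noise. Used to exercise
#' the suppression-based seizure-offset proposal.
#'
#' @param seizureDuration ictal duration (s, > 0).
#' @param fs sampling rate (Hz).
#' @param nChannels number of channels.
#' @param suppressionDuration tail duration (s, >= 2).
#' @param suppressionAmp RMS amplitude of the suppressed tail (uV, < 10).
#' @return An [EEGRecording-class] with markers \code{onset = 0},
#'   \code{offset = seizureDuration}.
#' @export
simulateIctalSegment <- function(seizureDuration, fs = 128, nChannels = 12,
                                 suppressionDuration = 4,
                                 suppressionAmp = 2) {
  if (seizureDuration <= 0) stop("seizureDuration must be positive")
  if (suppressionDuration < 2)
    stop("suppression tail must last at least 2 s")
  nIct <- round(seizureDuration * fs)
  nSup <- round(suppressionDuration * fs)
  t <- (seq_len(nIct) - 1) / fs
  phase <- (t * 3) %% 1
  spike <- 600 * exp(-((phase - 0.1) / 0.03)^2)
  wave <- 250 * sin(2 * pi * pmin(pmax((phase - 0.2) / 0.8, 0), 1))
  base <- spike + wave
  samples <- matrix(0, nChannels, nIct + nSup)
  for (ch in seq_len(nChannels)) {
    samples[ch, seq_len(nIct)] <- base * stats::runif(1, 0.8, 1.2) +
      stats::rnorm(nIct, sd = 10)
    samples[ch, nIct + seq_len(nSup)] <- stats::rnorm(nSup,
                                                      sd = suppressionAmp)
  }
  EEGRecording(samples, fs = fs, startTime = 0,
               markers = c(onset = 0, offset = seizureDuration))
}

#' Generate reorientation times from the mixed-effects model
#'
#' The generative inverse of the association stage: for every session and
#' domain, a latent reorientation time is the domain intercept plus the
#' fixed-effect linear predictor on standardized covariates, a by-subject
#' random intercept, a by-subject random slope on standardized T_max, and
#' a Gaussian residual drawn per question. Latent times are floored at the
#' first assessment and observed as the smallest question-grid time at or
#' above the latent time; two-question domains average their two observed
#' times.
#'
#' @param sessions data.frame with columns \code{subject_id},
#'   \code{session_id}, the EEG features \code{t_max}, \code{A},
#'   \code{tau}, and covariates \code{charge_mc}, \code{seizure_duration_s},
#'   \code{midazolam}, \code{placement_bl}, \code{session_number},
#'   \code{sex_male}, \code{age}.
#' @param betaTruth per-domain truths, see [betaDefaults()].
#' @param randomEffects data.frame \code{subject_id}, \code{b0}, \code{b1};
#'   generated N(0, sd) when NULL.
#' @param randomEffectSds SDs used when generating random effects.
#' @param residSd residual SD (min, >= 0).
#' @param questionInterval question spacing (min).
#' @param firstAssessment first question time (min).
#' @param baselineDisorientProb probability that a session-domain was
#'   already disoriented at baseline (scored as missing).
#' @return list with \code{rotLog} (question-level log), \code{rot} (wide
#'   per-session domain times), \code{latent} (noise-free true per-domain
#'   times: linear predictor plus random effects), and
#'   \code{randomEffects}.
#' @export
simulateROT <- function(sessions, betaTruth = betaDefaults(),
                        randomEffects = NULL,
                        randomEffectSds = c(intercept = 4, slope = 1.5),
                        residSd = 5, questionInterval = 5,
                        firstAssessment = 5,
                        baselineDisorientProb = 0) {
  if (residSd < 0) stop("residSd must be nonnegative")
  subj <- unique(sessions$subject_id)
  if (is.null(randomEffects)) {
    randomEffects <- data.frame(
      subject_id = subj,
      b0 = stats::rnorm(length(subj), 0, randomEffectSds[["intercept"]]),
      b1 = stats::rnorm(length(subj), 0, randomEffectSds[["slope"]]))
  }
  zscore <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
                        else x * 0
  Z <- cbind(t_max = zscore(sessions$t_max),
             A = zscore(sessions$A),
             tau = zscore(sessions$tau),
             charge_mc = zscore(sessions$charge_mc),
             seizure_duration_s = zscore(sessions$seizure_duration_s),
             midazolam = sessions$midazolam,
             placement_bl = sessions$placement_bl,
             session_number = zscore(sessions$session_number),
             sex_male = sessions$sex_male,
             age = zscore(sessions$age))
  b0 <- randomEffects$b0[match(sessions$subject_id,
                               randomEffects$subject_id)]
  b1 <- randomEffects$b1[match(sessions$subject_id,
                               randomEffects$subject_id)]
  grid <- function(latent) {
    latent <- pmax(latent, firstAssessment)
    firstAssessment +
      questionInterval * ceiling((latent - firstAssessment) / questionInterval
                                 - 1e-9)
  }
  doms <- rotDomains()
  nS <- nrow(sessions)
  latent <- data.frame(session_id = sessions$session_id)
  logRows <- vector("list", 3 * nS)
  rot <- data.frame(session_id = sessions$session_id,
                    rot_person = NA_real_, rot_place = NA_real_,
                    rot_time = NA_real_)
  k <- 0L
  for (d in names(doms)) {
    eta <- betaTruth$intercepts[[d]] +
      as.vector(Z %*% betaTruth$beta[[d]]) + b0 + b1 * Z[, "t_max"]
    latent[[paste0("true_", d)]] <- eta
    for (i in seq_len(nS)) {
      oriented <- stats::runif(1) >= baselineDisorientProb
      qt <- grid(eta[i] + stats::rnorm(length(doms[[d]]), 0, residSd))
      k <- k + 1L
      logRows[[k]] <- data.frame(
        session_id = sessions$session_id[i],
        question_id = doms[[d]],
        domain = d,
        minutes_to_correct = if (oriented) qt else rep(NA_real_,
                                                       length(doms[[d]])),
        baseline_oriented = oriented)
      if (oriented) rot[i, paste0("rot_", d)] <- mean(qt)
    }
  }
  list(rotLog = do.call(rbind, logRows[seq_len(k)]), rot = rot,
       latent = latent, randomEffects = randomEffects)
}

#' Simulate a full synthetic ECT study
#'
#' Draws subjects, sessions, sigmoid recovery truths, covariates and
#' reorientation times from one root seed. Two paths are offered: the
#' features-only path places the true sigmoid features in the session
#' table (optionally materialising noisy per-minute ADR series), while the
#' full path synthesizes raw EEG per session and pushes it through the
#' complete analysis pipeline (filter, epoch, Welch, ADR, sigmoid fit),
#' using the fitted, QC-gated features.
#'
#' @param config a [simConfig()] object.
#' @param path \code{"features"} (default) or \code{"full"}.
#' @param materialiseADR if TRUE on the features path, also emit noisy
#'   per-minute ADR series and their sigmoid fits.
#' @param baselineDisorientProb passed to [simulateROT()].
#' @param verbose log per-session progress on the full path.
#' @return list of class \code{PostictalStudy}: \code{sessions} (the
#'   session table), \code{rotLog}, \code{truth} (per-session generating
#'   parameters incl. true \code{t_max}), \code{randomEffects},
#'   \code{latentROT}, \code{config}; on the full path also \code{fits}
#'   and \code{adr} (per-session [ADRSeries-class]), and QC exclusions in
#'   \code{exclusions}.
#' @export
simulateStudy <- function(config = simConfig(), path = c("features", "full"),
                          materialiseADR = FALSE,
                          baselineDisorientProb = 0, verbose = FALSE) {
  path <- match.arg(path)
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)

  nSub <- config$nSubjects
  spsFloor <- floor(config$sessionsPerSubject)
  frac <- config$sessionsPerSubject - spsFloor
  nSess <- spsFloor + stats::rbinom(nSub, 1, frac)
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(nSub)),
    age = rtnorm(nSub, config$ageDist[1], config$ageDist[2], 18, 85),
    sex_male = stats::rbinom(nSub, 1, config$sexProbMale))

  sessions <- do.call(rbind, lapply(seq_len(nSub), function(i) {
    data.frame(subject_id = subjects$subject_id[i],
               session_number = seq_len(nSess[i]))
  }))
  n <- nrow(sessions)
  sessions$session_id <- sprintf("%s_E%02d", sessions$subject_id,
                                 sessions$session_number)
  sidx <- match(sessions$subject_id, subjects$subject_id)
  sessions$age <- subjects$age[sidx]
  sessions$sex_male <- subjects$sex_male[sidx]

  st <- config$sigmoidTruth
  truth <- data.frame(
    session_id = sessions$session_id,
    subject_id = sessions$subject_id,
    A = rtnorm(n, st$A[1], st$A[2], 0.05, 1.5),
    lam = rtnorm(n, st$lam[1], st$lam[2], 0.5, 15),
    tau = rtnorm(n, st$tau[1], st$tau[2], 5, 45))
  truth$U <- truth$A - 1 + rtnorm(n, st$Uoffset[1], st$Uoffset[2], 0, 0.3)
  truth$t_max <- truth$lam + truth$tau

  sessions$charge_mc <- rtnorm(n, config$chargeDist[1],
                               config$chargeDist[2], 25, 1000)
  sessions$seizure_duration_s <- rtnorm(n, config$seizureDurationDist[1],
                                        config$seizureDurationDist[2],
                                        10, 180)
  sessions$midazolam <- stats::rbinom(n, 1, config$midazolamProb)
  sessions$placement_bl <- stats::rbinom(n, 1, config$placementProbBL)
  sessions$t_max <- truth$t_max
  sessions$A <- truth$A
  sessions$tau <- truth$tau

  sessionSeeds <- sample.int(.Machine$integer.max - 1L, n)

  rotSim <- simulateROT(
    sessions, betaTruth = config$betaTruth,
    randomEffectSds = config$randomEffectSds, residSd = config$residSd,
    questionInterval = config$questionInterval,
    firstAssessment = config$firstAssessment,
    baselineDisorientProb = baselineDisorientProb)
  ridx <- match(sessions$session_id, rotSim$rot$session_id)
  sessions$rot_person <- rotSim$rot$rot_person[ridx]
  sessions$rot_place <- rotSim$rot$rot_place[ridx]
  sessions$rot_time <- rotSim$rot$rot_time[ridx]

  out <- list(sessions = sessions, rotLog = rotSim$rotLog, truth = truth,
              randomEffects = rotSim$randomEffects,
              latentROT = rotSim$latent, config = config,
              exclusions = character(0))

  fitOne <- function(series) {
    tryCatch(fitSigmoid(series), error = function(e) NULL)
  }

  if (path == "features" && materialiseADR) {
    minutes <- 0:(config$postictalDuration - 1)
    out$adr <- vector("list", n)
    names(out$adr) <- sessions$session_id
    out$fits <- vector("list", n)
    names(out$fits) <- sessions$session_id
    for (i in seq_len(n)) {
      set.seed(sessionSeeds[i])
      y <- sigmoidEval(minutes, truth$A[i], truth$lam[i], truth$tau[i],
                       truth$U[i]) +
        stats::rnorm(length(minutes), 0, config$adrNoiseSd)
      series <- ADRSeries(minutes, pmin(pmax(y, -1), 1))
      out$adr[[i]] <- series
      out$fits[[i]] <- fitOne(series)
    }
  }

  if (path == "full") {
    out$adr <- vector("list", n)
    names(out$adr) <- sessions$session_id
    out$fits <- vector("list", n)
    names(out$fits) <- sessions$session_id
    fitted <- data.frame(session_id = sessions$session_id,
                         t_max = NA_real_, A = NA_real_, tau = NA_real_,
                         r2 = NA_real_, qc_pass = FALSE)
    for (i in seq_len(n)) {
      set.seed(sessionSeeds[i])
      rec <- simulatePostictalEEG(
        truth[i, c("A", "lam", "tau", "U")],
        duration = config$postictalDuration, fs = config$fs,
        nChannels = config$nChannels, totalPower = config$totalPower,
        artifactRate = config$artifactRate)
      series <- computeADRSeries(rec)
      out$adr[[i]] <- series
      fit <- fitOne(series)
      out$fits[[i]] <- fit
      if (!is.null(fit) && fit@converged) {
        fitted[i, c("t_max", "A", "tau")] <-
          c(fit@tMax, fit@A, fit@tau)
        fitted$r2[i] <- fit@rSquared
        fitted$qc_pass[i] <- fit@qcPass
      }
      if (verbose)
        message(sprintf("session %s: fitted t_max %.1f (true %.1f)",
                        sessions$session_id[i], fitted$t_max[i],
                        truth$t_max[i]))
    }
    drop <- !fitted$qc_pass
    out$exclusions <- sessions$session_id[drop]
    sessions$t_max <- fitted$t_max
    sessions$A <- fitted$A
    sessions$tau <- fitted$tau
    sessions$r2 <- fitted$r2
    out$sessions <- sessions[!drop, , drop = FALSE]
  }
  out
}
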