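# Fixtures built in code: no stored data.

# single- or multi-channel sinusoid recording
sinusoidRecording <- function(freq, amp = 20, fs = 256, duration = 60,
                              nChannels = 1, noiseSd = 0) {
  t <- (0:(duration * fs - 1)) / fs
  base <- amp * sin(2 * pi * freq * t)
  samples <- t(vapply(seq_len(nChannels),
                      function(i) base + rnorm(length(t), sd = noiseSd),
                      numeric(length(t))))
  EEGRecording(samples, fs = fs)
}

# noiseless minute-sampled sigmoid series
sigmoidSeries <- function(A = 1, lam = 5.9, tau = 21, U = 0.1,
                          minutes = 0:59, noiseSd = 0) {
  y <- sigmoidEval(minutes, A, lam, tau, U)
  if (noiseSd > 0)
    y <- pmin(pmax(y + rnorm(length(minutes), 0, noiseSd), -1), 1)
  ADRSeries(minutes, y)
}

# random valid sigmoid parameter draws for property loops
randomSigmoidParams <- function(n) {
  data.frame(A = runif(n, 0.1, 1.5),
             lam = runif(n, 0, 12),
             tau = runif(n, 1, 40),
             U = runif(n, -0.5, 0.8))
}

# minimal covariate table for association tests
syntheticFeatureStudy <- function(seed = 1, nSubjects = 32,
                                  sessionsPerSubject = 8.5, ...) {
  simulateStudy(simConfig(nSubjects = nSubjects,
                          sessionsPerSubject = sessionsPerSubject,
                          seed = seed, ...))
}

sessionTableFromStudy <- function(study) {
  sess <- study$sessions
  buildSessionTable(
    sess[, c("session_id", "t_max", "A", "tau")],
    sess[, c("session_id", "subject_id", "charge_mc", "seizure_duration_s",
             "midazolam", "placement_bl", "session_number", "sex_male",
             "age")],
    sess[, c("session_id", "rot_person", "rot_place", "rot_time")])
}
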