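#' Fixed effects of the per-domain mixed models
#' @noRd
lmmFixedEffects <- function() {
  c("t_max", "A", "tau", "charge_mc", "seizure_duration_s", "midazolam",
    "placement_bl", "session_number", "sex_male", "age")
}

lmmContinuous <- function() {
  c("t_max", "A", "tau", "charge_mc", "seizure_duration_s",
    "session_number", "age")
}

#' Assemble the session table for the association stage
#'
#' Inner-joins QC-passed EEG features, covariates and reorientation
#' outcomes on \code{session_id}, z-scores the continuous predictors
#' (minutes-per-SD effect scale; binary predictors stay 0/1 with reference
#' levels right-unilateral placement, no midazolam, female sex) and keeps
#' rows with a missing domain outcome so that they drop out of the
#' affected model only.
#'
#' @param features data.frame \code{session_id}, \code{t_max}, \code{A},
#'   \code{tau}; rows with any missing feature (QC failures) are dropped.
#' @param covariates data.frame keyed by \code{session_id} carrying
#'   \code{subject_id}, \code{charge_mc}, \code{seizure_duration_s},
#'   \code{midazolam}, \code{placement_bl}, \code{session_number},
#'   \code{sex_male}, \code{age}.
#' @param rots data.frame \code{session_id}, \code{rot_person},
#'   \code{rot_place}, \code{rot_time}.
#' @param standardize z-score continuous predictors (default TRUE; FALSE
#'   fits on raw units).
#' @return A data.frame of class \code{SessionTable} with scaling recorded
#'   in \code{attr(, "scaling")}.
#' @export
buildSessionTable <- function(features, covariates, rots,
                              standardize = TRUE) {
  for (d in list(features, covariates, rots))
    if (anyDuplicated(d$session_id))
      stop("duplicate session_id in input table")
  features <- features[stats::complete.cases(
    features[, c("t_max", "A", "tau")]), , drop = FALSE]
  ids <- Reduce(intersect, list(features$session_id, covariates$session_id,
                                rots$session_id))
  tab <- cbind(
    features[match(ids, features$session_id),
             c("session_id", "t_max", "A", "tau"), drop = FALSE],
    covariates[match(ids, covariates$session_id),
               setdiff(names(covariates), "session_id"), drop = FALSE],
    rots[match(ids, rots$session_id),
         c("rot_person", "rot_place", "rot_time"), drop = FALSE])
  rownames(tab) <- NULL
  cont <- lmmContinuous()
  if (!all(is.finite(as.matrix(tab[, cont]))))
    stop("continuous covariates must be finite")
  scaling <- NULL
  if (standardize) {
    scaling <- data.frame(term = cont,
                          mean = vapply(tab[cont], mean, 0),
                          sd = vapply(tab[cont], stats::sd, 0))
    for (k in seq_along(cont)) {
      s <- if (scaling$sd[k] > 0) scaling$sd[k] else 1
      tab[[cont[k]]] <- (tab[[cont[k]]] - scaling$mean[k]) / s
    }
  }
  attr(tab, "scaling") <- scaling
  class(tab) <- c("SessionTable", "data.frame")
  tab
}

#' Fit the linear mixed model for one cognitive domain
#'
#' Outcome: reorientation time (min) in the domain. Fixed effects: the
#' three EEG features (T_max, A, tau), stimulus charge, seizure duration,
#' midazolam, electrode placement, session number, sex, age. Random
#' effects: by-subject intercept and by-subject slope on (standardized)
#' T_max, estimated by REML. If the full random structure is singular the
#' slope is dropped with a logged downgrade; if mixed-model estimation
#' fails altogether the fixed effects fall back to ordinary least squares
#' (tagged in the result). Confidence intervals and p-values use a Wald
#' t approximation with \code{nObs - nFixed} degrees of freedom.
#'
#' @param table a \code{SessionTable} from [buildSessionTable()].
#' @param domain \code{"person"}, \code{"place"} or \code{"time"}.
#' @param dropTerms fixed effects to omit (used by the midazolam-free
#'   sensitivity analysis).
#' @param alpha significance level for the Wald intervals.
#' @return An object of class \code{LMMResult}: list with
#'   \code{coefficients} (term, estimate, se, lower, upper, p),
#'   \code{ranef} (random-effect SDs), \code{method}, \code{formula},
#'   \code{nObs}, \code{nSubjects}, \code{vif}, \code{singular},
#'   \code{downgraded}, \code{diagnostics} (normality checks), and the
#'   underlying \code{fit}.
#' @export
fitDomainLMM <- function(table, domain = c("person", "place", "time"),
                         dropTerms = character(0), alpha = 0.05) {
  domain <- match.arg(domain)
  outcome <- paste0("rot_", domain)
  fx <- setdiff(lmmFixedEffects(), dropTerms)
  dat <- as.data.frame(table)
  dat <- dat[!is.na(dat[[outcome]]), , drop = FALSE]
  nSubj <- length(unique(dat$subject_id))
  if (nSubj < 10 || nrow(dat) < 30)
    warning("small sample: ", nSubj, " subjects / ", nrow(dat),
            " sessions for domain '", domain, "'")

  vif <- vifScreen(dat, fx)

  fmlFull <- stats::as.formula(paste(
    outcome, "~", paste(fx, collapse = " + "), "+ (1 + t_max | subject_id)"))
  fmlInt <- stats::as.formula(paste(
    outcome, "~", paste(fx, collapse = " + "), "+ (1 | subject_id)"))

  fitQuiet <- function(fml) {
    tryCatch(
      withCallingHandlers(
        lme4::lmer(fml, data = dat, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     calc.derivs = FALSE)),
        warning = function(w) invokeRestart("muffleWarning"),
        message = function(m) invokeRestart("muffleMessage")),
      error = function(e) NULL)
  }

  method <- "REML"
  downgraded <- FALSE
  fit <- fitQuiet(fmlFull)
  singular <- !is.null(fit) && lme4::isSingular(fit, tol = 1e-4)
  if (is.null(fit) || singular) {
    fit2 <- fitQuiet(fmlInt)
    if (!is.null(fit2)) {
      if (!is.null(fit) && singular)
        message("singular random-effects fit for '", domain,
                "': dropping the by-subject t_max slope")
      fit <- fit2
      downgraded <- TRUE
      singular <- lme4::isSingular(fit, tol = 1e-4)
      fmlUsed <- fmlInt
    } else fmlUsed <- fmlFull
  } else fmlUsed <- fmlFull

  if (is.null(fit)) {
    message("mixed-model estimation failed for '", domain,
            "': falling back to ordinary least squares")
    fmlUsed <- stats::as.formula(paste(outcome, "~",
                                       paste(fx, collapse = " + ")))
    fit <- stats::lm(fmlUsed, data = dat)
    method <- "OLS"
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    ranefSd <- c(residual = stats::sigma(fit))
  } else {
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranefSd <- stats::setNames(vc$sdcor,
                               paste(vc$grp, ifelse(is.na(vc$var1), "",
                                                    vc$var1)))
  }
  df <- nrow(dat) - length(beta)
  tcrit <- stats::qt(1 - alpha / 2, df)
  tval <- beta / se
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se),
                      lower = unname(beta - tcrit * se),
                      upper = unname(beta + tcrit * se),
                      p = unname(2 * stats::pt(-abs(tval), df)))
  rownames(coefs) <- NULL

  diag <- list()
  res <- stats::residuals(fit)
  if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0)
    diag$residual_shapiro_p <- stats::shapiro.test(res)$p.value
  if (method == "REML") {
    re <- lme4::ranef(fit)$subject_id
    for (cn in colnames(re)) {
      v <- re[[cn]]
      if (length(v) >= 3 && stats::sd(v) > 0)
        diag[[paste0("ranef_", make.names(cn), "_shapiro_p")]] <-
          stats::shapiro.test(v)$p.value
    }
  }

  structure(list(coefficients = coefs, ranef = ranefSd, method = method,
                 formula = fmlUsed, domain = domain, nObs = nrow(dat),
                 nSubjects = nSubj, vif = vif, singular = singular,
                 downgraded = downgraded, df = df, diagnostics = diag,
                 fit = fit),
            class = "LMMResult")
}

#' @export
print.LMMResult <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), domain '%s': %d sessions, %d subjects%s\n",
              x$method, x$domain, x$nObs, x$nSubjects,
              if (x$downgraded) " [random slope dropped]" else ""))
  co <- x$coefficients
  co[, -1] <- round(co[, -1], 3)
  print(co, row.names = FALSE)
  invisible(x)
}

#' Variance-inflation-factor screen of the fixed-effects design
#'
#' VIF per predictor from auxiliary least-squares regressions of each
#' fixed-effect column on the remaining ones; a VIF below 5 is considered
#' tolerable collinearity. Perfectly collinear columns report Inf.
#'
#' @param table data.frame containing the fixed-effect columns.
#' @param fixedEffects predictor names (>= 2).
#' @return data.frame with \code{term}, \code{vif} and logical
#'   \code{flagged} (VIF >= 5).
#' @export
vifScreen <- function(table, fixedEffects = lmmFixedEffects()) {
  if (length(fixedEffects) < 2)
    stop("need at least two fixed effects for a VIF screen")
  X <- as.matrix(as.data.frame(table)[, fixedEffects, drop = FALSE])
  vif <- vapply(seq_along(fixedEffects), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    sst <- sum((X[, j] - mean(X[, j]))^2)
    if (sst == 0) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / sst
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(term = fixedEffects, vif = vif, flagged = vif >= 5)
}

#' Midazolam-free sensitivity analysis
#'
#' Refits the three per-domain mixed models on the subset of sessions
#' without postictal midazolam, dropping the midazolam term.
#'
#' @param table a \code{SessionTable}.
#' @param minSessions minimum subset size (default 10); below it the
#'   analysis is skipped with a warning.
#' @return Named list of [fitDomainLMM()] results (or NULL when skipped).
#' @export
midazolamSensitivity <- function(table, minSessions = 10) {
  sub <- table[table$midazolam == 0, , drop = FALSE]
  if (nrow(sub) < minSessions) {
    warning("only ", nrow(sub),
            " midazolam-free sessions: sensitivity analysis skipped")
    return(NULL)
  }
  attr(sub, "scaling") <- attr(table, "scaling")
  class(sub) <- class(table)
  out <- lapply(c(person = "person", place = "place", time = "time"),
                function(d) fitDomainLMM(sub, d, dropTerms = "midazolam"))
  out
}
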