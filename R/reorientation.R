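#' Cognitive domains and their questions
#'
#' The reorientation questionnaire has five questions across three domains:
#' person (name, birthday), place (hospital), time (age, weekday). Domains
#' with two questions are scored as the mean of the two first-correct times.
#' @return Named list mapping domain to its question ids.
#' @export
rotDomains <- function() {
  list(person = c("name", "birthday"),
       place = "hospital",
       time = c("age", "weekday"))
}

#' Time to reorientation for one session and domain
#'
#' Scores a question-level log: each question contributes the time (min) at
#' which it was first answered correctly; two-question domains average their
#' two times. If the patient was not oriented in the domain at baseline the
#' domain is ignored (NA). A question never answered correctly within the
#' observation window yields NA with a censoring attribute.
#'
#' @param log data.frame with columns \code{question_id},
#'   \code{minutes_to_correct} (NA if never correct) and
#'   \code{baseline_oriented} (logical) for one session.
#' @param domain one of \code{"person"}, \code{"place"}, \code{"time"}.
#' @return Reorientation time in minutes, or NA; attribute
#'   \code{censored} is TRUE when missingness is due to an unanswered
#'   question rather than baseline disorientation.
#' @examples
#' log <- data.frame(question_id = c("name", "birthday"),
#'                   minutes_to_correct = c(20, 30),
#'                   baseline_oriented = TRUE)
#' timeToReorientation(log, "person")  # 25
#' @export
timeToReorientation <- function(log, domain = c("person", "place", "time")) {
  domain <- match.arg(domain)
  qs <- rotDomains()[[domain]]
  rows <- log[log$question_id %in% qs, , drop = FALSE]
  if (nrow(rows) != length(qs))
    stop("log must contain exactly the questions ",
         paste(qs, collapse = ", "), " for domain '", domain, "'")
  if (!all(rows$baseline_oriented)) {
    out <- NA_real_
    attr(out, "censored") <- FALSE
    return(out)
  }
  if (anyNA(rows$minutes_to_correct)) {
    out <- NA_real_
    attr(out, "censored") <- TRUE
    return(out)
  }
  if (any(rows$minutes_to_correct < 0))
    stop("question times must be nonnegative")
  out <- mean(rows$minutes_to_correct)
  attr(out, "censored") <- FALSE
  out
}

#' Score a multi-session question log
#'
#' Applies [timeToReorientation()] to every session and domain of a long
#' question log.
#'
#' @param log data.frame with columns \code{session_id}, \code{question_id},
#'   \code{minutes_to_correct}, \code{baseline_oriented}.
#' @return data.frame with one row per session: \code{session_id},
#'   \code{rot_person}, \code{rot_place}, \code{rot_time}.
#' @export
scoreROTLog <- function(log) {
  ids <- unique(log$session_id)
  out <- data.frame(session_id = ids,
                    rot_person = NA_real_, rot_place = NA_real_,
                    rot_time = NA_real_)
  for (i in seq_along(ids)) {
    sub <- log[log$session_id == ids[i], , drop = FALSE]
    for (d in names(rotDomains()))
      out[i, paste0("rot_", d)] <- as.numeric(timeToReorientation(sub, d))
  }
  out
}

#' Order of domain recovery
#'
#' Sorts the per-domain reorientation times ascending and reports whether
#' the session followed the classic person-place-time sequence. Ties count
#' as simultaneous recovery and do not falsify the sequence (non-strict
#' comparison).
#'
#' @param rots named numeric vector with elements \code{person},
#'   \code{place}, \code{time} (NAs allowed).
#' @return list with \code{order} (domain names sorted by time) and
#'   \code{classic} (TRUE iff person <= place <= time); both NA when fewer
#'   than two domains are available.
#' @examples
#' domainOrder(c(person = 24, place = 28.6, time = 33))
#' @export
domainOrder <- function(rots) {
  stopifnot(all(c("person", "place", "time") %in% names(rots)))
  rots <- rots[c("person", "place", "time")]
  ok <- !is.na(rots)
  if (sum(ok) < 2)
    return(list(order = NA_character_, classic = NA))
  ord <- names(sort(rots[ok]))
  classic <- if (all(ok)) {
    rots["person"] <= rots["place"] && rots["place"] <= rots["time"]
  } else NA
  list(order = ord, classic = unname(classic))
}

#' Paired domain comparisons of reorientation times
#'
#' Two-sided Wilcoxon signed-rank tests on paired per-subject summaries
#' (medians across sessions by default) for person vs place, place vs time
#' and person vs time.
#'
#' @param rots data.frame with columns \code{subject_id},
#'   \code{rot_person}, \code{rot_place}, \code{rot_time}; one row per
#'   subject (pre-aggregated) or per session (then aggregated by
#'   \code{aggregate}).
#' @param aggregate subject-level summary when multiple rows per subject
#'   are supplied: \code{"median"} (default) or \code{"none"} to use rows
#'   as-is (session-level pairing).
#' @return data.frame with columns \code{comparison}, \code{n},
#'   \code{statistic}, \code{p}, \code{degenerate} (TRUE when all paired
#'   differences are zero, leaving the test undefined).
#' @export
compareDomains <- function(rots, aggregate = c("median", "none")) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(c("subject_id", "rot_person", "rot_place", "rot_time")
                %in% names(rots)))
  if (aggregate == "median" && anyDuplicated(rots$subject_id)) {
    rots <- do.call(rbind, lapply(split(rots, rots$subject_id), function(d)
      data.frame(subject_id = d$subject_id[1],
                 rot_person = stats::median(d$rot_person, na.rm = TRUE),
                 rot_place = stats::median(d$rot_place, na.rm = TRUE),
                 rot_time = stats::median(d$rot_time, na.rm = TRUE))))
  }
  pairs <- list(c("person", "place"), c("place", "time"),
                c("person", "time"))
  out <- data.frame(comparison = vapply(pairs, paste, "", collapse = "_vs_"),
                    n = NA_integer_, statistic = NA_real_, p = NA_real_,
                    degenerate = FALSE)
  for (i in seq_along(pairs)) {
    x <- rots[[paste0("rot_", pairs[[i]][1])]]
    y <- rots[[paste0("rot_", pairs[[i]][2])]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 6)
      stop("fewer than 6 subjects with both '", pairs[[i]][1], "' and '",
           pairs[[i]][2], "' present")
    out$n[i] <- sum(ok)
    if (all(x[ok] == y[ok])) {
      out$degenerate[i] <- TRUE
      out$p[i] <- NA_real_
      next
    }
    wt <- suppressWarnings(
      stats::wilcox.test(x[ok], y[ok], paired = TRUE, exact = NULL))
    out$statistic[i] <- unname(wt$statistic)
    out$p[i] <- wt$p.value
  }
  out
}

#' Clinical response and remission flags
#'
#' Response: the post-course depression score dropped to half the
#' pre-course score or lower. Remission: post-course score below 8.
#'
#' @param preHDRS pre-course HDRS score (>= 0).
#' @param postHDRS post-course HDRS score (>= 0).
#' @return list with \code{response} and \code{remission} logical flags.
#' @examples
#' clinicalOutcome(23.5, 12)  # neither response nor remission
#' clinicalOutcome(20, 7)     # both
#' @export
clinicalOutcome <- function(preHDRS, postHDRS) {
  if (any(c(preHDRS, postHDRS) < 0) || anyNA(c(preHDRS, postHDRS)))
    stop("HDRS scores must be nonnegative")
  list(response = postHDRS <= 0.5 * preHDRS,
       remission = postHDRS < 8)
}
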