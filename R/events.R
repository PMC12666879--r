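#' Event-detection configuration
#'
#' Windows (days) governing EDSS preprocessing and event classification:
#' scores within `exclusion_pre_days` before or `exclusion_post_days`
#' after a relapse onset are dropped before event detection; a confirmed
#' worsening whose onset falls within `raw_pre_days` before to
#' `raw_post_days` after a relapse onset is relapse-associated (RAW),
#' otherwise it is progression independent of relapse activity (PIRA).
#' Confirmation requires a sustaining visit at least `confirmation_days`
#' later.
#'
#' @param exclusion_pre_days,exclusion_post_days Score-exclusion window
#'   around relapses (default +/- 30 days).
#' @param raw_pre_days,raw_post_days RAW attribution window (default 30
#'   days before to 90 days after relapse onset).
#' @param confirmation_days Minimum onset-to-confirmation interval
#'   (default 180 days, i.e. 6 months).
#' @param baseline_mode "roving" (reference EDSS resets after each
#'   confirmed event) or "fixed" (reference stays at the first retained
#'   score).
#' @return List of class `ms_event_config`.
#' @export
event_config <- function(exclusion_pre_days = 30, exclusion_post_days = 30,
                         raw_pre_days = 30, raw_post_days = 90,
                         confirmation_days = 180,
                         baseline_mode = c("roving", "fixed")) {
  baseline_mode <- match.arg(baseline_mode)
  w <- c(exclusion_pre_days, exclusion_post_days, raw_pre_days,
         raw_post_days, confirmation_days)
  if (any(w < 0)) stop("configuration error: all windows must be >= 0")
  structure(list(exclusion_pre_days = exclusion_pre_days,
                 exclusion_post_days = exclusion_post_days,
                 raw_pre_days = raw_pre_days, raw_post_days = raw_post_days,
                 confirmation_days = confirmation_days,
                 baseline_mode = baseline_mode),
            class = "ms_event_config")
}

#' Required EDSS increase for confirmed worsening
#'
#' The minimum increase over the reference score that qualifies as
#' disability worsening: 1.5 points from a reference of 0, 1.0 point from
#' references 1.0-5.0, and 0.5 points from references of 5.5 or higher.
#'
#' @param reference_edss Reference EDSS value(s) on the legal grid.
#' @return Required increase (EDSS points), vectorized.
#' @export
#' @examples
#' required_increase(c(0, 4, 6))
required_increase <- function(reference_edss) {
  if (!all(is_edss(reference_edss))) {
    stop("input error: reference EDSS must be on the legal grid")
  }
  ifelse(reference_edss == 0, 1.5,
         ifelse(reference_edss <= 5.0, 1.0, 0.5))
}

#' Drop EDSS scores recorded near a relapse
#'
#' Removes every visit whose time falls within the exclusion window
#' (default 30 days before to 30 days after) of any relapse onset, to
#' avoid transient relapse-related elevation inflating worsening
#' detection. Visit order is preserved.
#'
#' @param visits data.frame with `time_years` (and usually `edss`).
#' @param relapse_times Numeric vector of relapse onset times (years).
#' @param config An `ms_event_config`.
#' @return The filtered visits data.frame.
#' @export
exclude_relapse_window_scores <- function(visits, relapse_times,
                                          config = event_config()) {
  if (!length(relapse_times) || !nrow(visits)) return(visits)
  pre <- days2years(config$exclusion_pre_days)
  post <- days2years(config$exclusion_post_days)
  eps <- 1e-9  # float-safe closed windows at exact day boundaries
  keep <- vapply(visits$time_years, function(t) {
    d <- t - relapse_times
    !any(d >= -pre - eps & d <= post + eps)
  }, logical(1))
  visits[keep, , drop = FALSE]
}

#' Apply the registry inclusion criteria
#'
#' Keeps only patients with at least 3 EDSS scores after relapse-window
#' exclusion, follow-up of at least 3 years, and a first assessment no
#' more than 1 year after disease onset.
#'
#' @param records List of `ms_patient` records (an `ms_cohort`).
#' @param config An `ms_event_config` used for the score exclusion.
#' @param min_visits,min_followup_years,max_first_visit_years The three
#'   thresholds.
#' @return The filtered list (class preserved).
#' @export
apply_inclusion_criteria <- function(records, config = event_config(),
                                     min_visits = 3,
                                     min_followup_years = 3,
                                     max_first_visit_years = 1) {
  keep <- vapply(records, function(p) {
    v <- exclude_relapse_window_scores(p$visits, p$relapses$onset_years, config)
    nrow(v) >= min_visits &&
      p$followup_years >= min_followup_years &&
      nrow(p$visits) > 0 && p$visits$time_years[1] <= max_first_visit_years
  }, logical(1))
  out <- records[keep]
  class(out) <- class(records)
  attributes(out)$config <- attr(records, "config")
  out
}

#' Detect confirmed disability worsening (CDW) events
#'
#' Scans a patient's relapse-window-filtered visit series against the
#' current reference EDSS. A visit at time t whose score exceeds the
#' reference by at least [required_increase()] is a candidate onset; it is
#' confirmed if some later visit at t' >= t + 180 days also meets the
#' threshold against the same reference and every retained visit in
#' (t, t'] stays at or above the threshold (worsening sustained to
#' confirmation). In roving mode the reference then resets to the event
#' EDSS and scanning resumes after the confirming visit, so a patient can
#' accrue several non-overlapping events; in fixed mode the reference
#' stays at the first retained score and each later event must exceed the
#' previous event's EDSS.
#'
#' @param visits data.frame (`time_years`, `edss`), already filtered with
#'   [exclude_relapse_window_scores()] and sorted.
#' @param relapse_times Relapse onset times, used to label events RAW or
#'   PIRA via [classify_event()].
#' @param config An `ms_event_config`.
#' @param patient_id Optional id copied into the result.
#' @return data.frame with one row per event: `patient_id`, `onset_years`,
#'   `reference_edss`, `event_edss`, `confirmation_years`, `label`.
#' @export
detect_cdw <- function(visits, relapse_times = numeric(0),
                       config = event_config(), patient_id = NA_character_) {
  empty <- data.frame(patient_id = character(0), onset_years = numeric(0),
                      reference_edss = numeric(0), event_edss = numeric(0),
                      confirmation_years = numeric(0), label = character(0),
                      stringsAsFactors = FALSE)
  n <- nrow(visits)
  if (is.null(n) || n < 2) return(empty)
  t <- visits$time_years
  y <- visits$edss
  conf_gap <- days2years(config$confirmation_days)
  roving <- config$baseline_mode == "roving"
  ref <- y[1]
  last_event_edss <- -Inf
  i <- 2
  events <- list()
  while (i <= n) {
    thr <- ref + required_increase(ref)
    if (y[i] >= thr && (roving || y[i] > last_event_edss)) {
      # find earliest confirming visit; sustained at all interim visits
      j <- i + 1
      conf <- NA_integer_
      while (j <= n && y[j] >= thr) {
        if (t[j] >= t[i] + conf_gap) { conf <- j; break }
        j <- j + 1
      }
      if (!is.na(conf)) {
        events[[length(events) + 1]] <- data.frame(
          patient_id = patient_id, onset_years = t[i],
          reference_edss = ref, event_edss = y[i],
          confirmation_years = t[conf], label = NA_character_,
          stringsAsFactors = FALSE)
        if (roving) ref <- y[i]
        last_event_edss <- y[i]
        i <- conf + 1
        next
      }
    }
    i <- i + 1
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  out$label <- vapply(out$onset_years, function(o) {
    classify_onset(o, relapse_times, config)
  }, character(1))
  out
}

classify_onset <- function(onset, relapse_times, config) {
  if (!length(relapse_times)) return("PIRA")
  pre <- days2years(config$raw_pre_days)
  post <- days2years(config$raw_post_days)
  eps <- 1e-9
  d <- onset - relapse_times
  if (any(d >= -pre - eps & d <= post + eps)) "RAW" else "PIRA"
}

#' Classify a confirmed event as RAW or PIRA
#'
#' An event is relapse-associated worsening (RAW) if its onset falls
#' within 30 days before to 90 days after any relapse onset (closed
#' interval); otherwise it is progression independent of relapse activity
#' (PIRA). Timing is assessed at the event onset.
#'
#' @param event One-row data.frame as returned by [detect_cdw()].
#' @param relapse_times Relapse onset times (years).
#' @param config An `ms_event_config`.
#' @return The event with its `label` field set.
#' @export
classify_event <- function(event, relapse_times, config = event_config()) {
  event$label <- vapply(event$onset_years, function(o) {
    classify_onset(o, relapse_times, config)
  }, character(1))
  event
}

#' Detect CDW events for every patient in a cohort
#'
#' Applies relapse-window score exclusion then [detect_cdw()] per patient.
#'
#' @param records List of `ms_patient` records.
#' @param config An `ms_event_config`.
#' @return data.frame of events across patients (possibly 0 rows).
#' @export
detect_cohort_events <- function(records, config = event_config()) {
  out <- lapply(records, function(p) {
    v <- exclude_relapse_window_scores(p$visits, p$relapses$onset_years, config)
    detect_cdw(v, p$relapses$onset_years, config, patient_id = p$id)
  })
  do.call(rbind, out)
}

#' Annualized relapse rate
#'
#' @param relapse_times Relapse onset times (or their count).
#' @param followup Follow-up duration in years (> 0).
#' @return Relapses per year: count / followup.
#' @export
#' @examples
#' annualized_relapse_rate(c(1.2, 4.5, 7.0), 10)
annualized_relapse_rate <- function(relapse_times, followup) {
  if (!is.numeric(followup) || length(followup) != 1 || followup <= 0) {
    stop("input error: followup must be a single positive duration")
  }
  length(relapse_times) / followup
}

#' Compare RAW versus PIRA composition across phenotypes
#'
#' Builds the phenotype x label contingency table and applies the
#' chi-square test (without continuity correction, matching the textbook
#' statistic on tables larger than 2x2 and kept uncorrected on 2x2 for
#' comparability with the hand formula).
#'
#' @param events data.frame of labelled events with a `phenotype` column.
#' @return List with `table` (counts), `proportions` (row-normalized),
#'   `statistic`, `df`, `p_value`.
#' @export
compare_raw_pira <- function(events) {
  if (!nrow(events)) stop("input error: no events to compare")
  tab <- table(events$phenotype, events$label)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("input error: need >= 2 phenotypes and both labels present")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(table = tab,
       proportions = prop.table(tab, margin = 1),
       statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Association between relapse activity and the rate of EDSS increase
#'
#' For each patient, consecutive retained visits define intervals with an
#' EDSS change rate (points/year); the model regresses that rate on the
#' patient's annualized relapse rate, interval midpoint time, and their
#' interaction, with a patient-level random intercept. A negative ARR x
#' time coefficient means the disability-accrual rate associated with
#' relapse activity declines over the disease course.
#'
#' @param visits Long data.frame (`patient_id`, `time_years`, `edss`),
#'   already relapse-window filtered.
#' @param arr Named vector (or data.frame patient_id/arr) of per-patient
#'   annualized relapse rates.
#' @return data.frame of fixed-effect terms: `term`, `beta`, `se`,
#'   `p_value`.
#' @export
arr_time_association <- function(visits, arr) {
  if (is.data.frame(arr)) arr <- setNames(arr$arr, arr$patient_id)
  sp <- split(visits, visits$patient_id)
  rows <- lapply(names(sp), function(id) {
    v <- sp[[id]]
    if (nrow(v) < 2) return(NULL)
    dt <- diff(v$time_years)
    data.frame(patient_id = id,
               rate = diff(v$edss) / dt,
               time = (head(v$time_years, -1) + tail(v$time_years, -1)) / 2,
               arr = unname(arr[id]), stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d) || length(unique(d$patient_id)) < 2) {
    stop("input error: need >= 2 patients with >= 2 time points each")
  }
  fit <- tryCatch(
    lme4::lmer(rate ~ arr * time + (1 | patient_id), data = d, REML = FALSE),
    error = function(e) stop("singular-fit error: ", conditionMessage(e)))
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), beta = s[, "Estimate"],
             se = s[, "Std. Error"],
             p_value = 2 * pnorm(-abs(s[, "t value"])),
             row.names = NULL, stringsAsFactors = FALSE)
}
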