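# Independent oracle implementations used to cross-check the package.
# These are deliberately naive (quadratic scans, explicit enumeration)
# and share no code with the implementations they test.

YEAR <- 365.25

# Quadratic-scan relapse-window filter: keep a visit iff no (visit,
# relapse) pair is within the window.
oracle_exclude <- function(visits, relapses, pre_days = 30, post_days = 30) {
  keep <- rep(TRUE, nrow(visits))
  for (i in seq_len(nrow(visits))) {
    for (r in relapses) {
      d <- (visits$time_years[i] - r) * YEAR
      if (d >= -pre_days - 1e-9 && d <= post_days + 1e-9) keep[i] <- FALSE
    }
  }
  visits[keep, , drop = FALSE]
}

oracle_required <- function(ref) {
  if (ref == 0) 1.5 else if (ref <= 5.0) 1.0 else 0.5
}

# Exhaustive-search CDW detector: enumerates all (onset, confirmation)
# visit pairs valid against the current reference, commits the earliest,
# re-baselines (roving), and repeats on the remaining suffix.
oracle_cdw <- function(visits, conf_days = 180, roving = TRUE) {
  t <- visits$time_years
  y <- visits$edss
  n <- length(t)
  events <- list()
  ref <- if (n) y[1] else NA
  start <- 2
  last_ev <- -Inf
  repeat {
    if (start > n) break
    thr <- ref + oracle_required(ref)
    found <- NULL
    for (i in start:n) {
      if (y[i] < thr) next
      if (!roving && y[i] <= last_ev) next
      for (j in seq_len(n)) {
        if (j <= i) next
        if ((t[j] - t[i]) * YEAR < conf_days) next
        if (all(y[(i + 1):j] >= thr)) {
          found <- c(i, j)
          break
        }
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) break
    i <- found[1]; j <- found[2]
    events[[length(events) + 1]] <-
      data.frame(onset_years = t[i], reference_edss = ref,
                 event_edss = y[i], confirmation_years = t[j])
    if (roving) ref <- y[i]
    last_ev <- y[i]
    start <- j + 1
  }
  if (!length(events)) {
    return(data.frame(onset_years = numeric(0), reference_edss = numeric(0),
                      event_edss = numeric(0), confirmation_years = numeric(0)))
  }
  do.call(rbind, events)
}

# Newton-Raphson (IRLS) logistic regression oracle.
oracle_logistic <- function(X, y, iter = 50) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    step <- solve(t(X) %*% (X * W) + diag(1e-10, ncol(X)),
                  t(X) %*% (y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  drop(1 / (1 + exp(-X %*% beta)))
}

# Naive greedy caliper matcher (descending treated logit, nearest
# available untreated, capacity max_ratio); returns the matched count.
oracle_match_count <- function(scores, caliper = 0.2, max_ratio = 4) {
  cal <- caliper * sd(scores$logit)
  tr <- scores[scores$treated, ]
  un <- scores[!scores$treated, ]
  tr <- tr[order(-tr$logit, tr$patient_id), ]
  cap <- rep(max_ratio, nrow(un))
  matched <- 0L
  for (i in seq_len(nrow(tr))) {
    best <- 0; bestd <- Inf
    for (j in seq_len(nrow(un))) {
      if (cap[j] == 0) next
      d <- abs(un$logit[j] - tr$logit[i])
      if (d < bestd - 1e-15 ||
          (abs(d - bestd) <= 1e-15 && best > 0 &&
           un$patient_id[j] < un$patient_id[best])) {
        best <- j; bestd <- d
      }
    }
    if (best > 0 && bestd <= cal) {
      cap[best] <- cap[best] - 1
      matched <- matched + 1L
    }
  }
  matched
}

# Random visit series on the EDSS grid for property tests.
random_series <- function(n_visits, seed) {
  set.seed(seed)
  t <- sort(runif(n_visits, 0, 12))
  while (any(diff(t) < 1e-3)) t <- sort(runif(n_visits, 0, 12))
  lv <- cumsum(c(runif(1, 0, 3), rnorm(n_visits - 1, 0.15, 0.8)))
  data.frame(time_years = t, edss = round_edss(lv))
}

# Small baseline table for matching/classifier tests.
toy_baseline <- function(n, seed = 1, shift = 0) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("X%04d", seq_len(n)),
    age_at_onset = rnorm(n, 33 + shift, 8),
    sex = sample(c("F", "M"), n, TRUE),
    optic_nerve = FALSE, brainstem = FALSE,
    spinal_cord = TRUE, hemispheric = FALSE,
    ocb = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.9, 0.1)),
    baseline_edss = round_edss(rnorm(n, 2 + shift / 10, 0.8)),
    brain_t2 = sample(c("1-2", "3-8", ">=9"), n, TRUE),
    brain_gd = sample(c(TRUE, FALSE), n, TRUE),
    sc_t2 = sample(c("0", "1-2", ">=3"), n, TRUE),
    sc_gd = sample(c(TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE
  )
}
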