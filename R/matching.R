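# Propensity-score matching of treated to untreated patients.

# Numeric design matrix from the baseline table (shared with the
# classifier): binary flags as 0/1, lesion categories as ordinals.
baseline_design <- function(baseline) {
  required <- c("age_at_onset", "sex", "optic_nerve", "brainstem",
                "spinal_cord", "hemispheric", "ocb", "baseline_edss",
                "brain_t2", "brain_gd", "sc_t2", "sc_gd")
  missing <- setdiff(required, names(baseline))
  if (length(missing)) {
    stop("schema mismatch: missing features [",
         paste(missing, collapse = ", "), "]")
  }
  data.frame(
    age_at_onset = baseline$age_at_onset,
    sex_f = as.numeric(baseline$sex == "F"),
    optic_nerve = as.numeric(baseline$optic_nerve),
    brainstem = as.numeric(baseline$brainstem),
    spinal_cord = as.numeric(baseline$spinal_cord),
    hemispheric = as.numeric(baseline$hemispheric),
    ocb = as.numeric(baseline$ocb),
    baseline_edss = baseline$baseline_edss,
    brain_t2 = match(baseline$brain_t2, c("1-2", "3-8", ">=9")),
    brain_gd = as.numeric(baseline$brain_gd),
    sc_t2 = match(baseline$sc_t2, c("0", "1-2", ">=3")) - 1,
    sc_gd = as.numeric(baseline$sc_gd)
  )
}

#' Estimate propensity scores for treatment
#'
#' Logistic regression of treated-versus-untreated membership on all
#' baseline covariates; returns both the probability and its logit per
#' patient. Requires complete cases (the registry analysis is
#' complete-case).
#'
#' @param baseline Baseline table (one row per patient, as from
#'   [cohort_baseline()]).
#' @param treated Logical vector (or "treated"/"untreated" labels)
#'   aligned with `baseline` rows.
#' @return data.frame: `patient_id`, `treated`, `score`, `logit`.
#' @export
estimate_propensity <- function(baseline, treated) {
  if (is.character(treated)) treated <- treated == "treated"
  X <- baseline_design(baseline)
  if (anyNA(X)) stop("input error: missing covariates; complete cases required")
  # drop constant columns (e.g. all-complete OCB in tiny fixtures)
  keep <- vapply(X, function(c) var(c) > 0, logical(1))
  d <- cbind(X[, keep, drop = FALSE], .treated = as.numeric(treated))
  fit <- suppressWarnings(glm(.treated ~ ., data = d, family = binomial()))
  p <- fitted(fit)
  if (any(p < 1e-10 | p > 1 - 1e-10)) {
    stop("perfect separation detected in the propensity model; ",
         "review the covariate set")
  }
  data.frame(patient_id = baseline$patient_id, treated = treated,
             score = as.numeric(p), logit = qlogis(as.numeric(p)),
             stringsAsFactors = FALSE)
}

#' Nearest-neighbor caliper matching with variable ratio
#'
#' Greedy nearest-neighbor matching on the logit of the propensity score,
#' without replacement of treated patients; an untreated patient may
#' anchor up to `max_ratio` treated patients. A pair forms only when the
#' logit distance is at most `caliper` standard deviations of the pooled
#' logit scores. Treated patients are processed in descending logit order
#' (hardest to match first), with ties broken by patient id; the
#' cumulative weight of each untreated anchor is capped at 1 by assigning
#' each of its m pairs weight 1/m.
#'
#' @param scores data.frame from [estimate_propensity()].
#' @param caliper Caliper width in SD units of the logit (default 0.2).
#' @param max_ratio Maximum treated per untreated anchor (default 4).
#' @return List of class `ms_match`: `pairs` (treated_id, untreated_id,
#'   distance, weight), `weights` (patient_id -> weight),
#'   `unmatched_treated`, `caliper_logit_sd`, `caliper_abs`.
#' @export
match_cohorts <- function(scores, caliper = 0.2, max_ratio = 4) {
  if (caliper <= 0) stop("configuration error: caliper must be > 0")
  tr <- scores[scores$treated, , drop = FALSE]
  un <- scores[!scores$treated, , drop = FALSE]
  if (!nrow(tr) || !nrow(un)) stop("input error: both cohorts must be non-empty")
  cal_abs <- caliper * sd(scores$logit)
  ord <- order(-tr$logit, tr$patient_id)
  tr <- tr[ord, , drop = FALSE]
  used <- setNames(integer(nrow(un)), un$patient_id)
  pairs <- list()
  unmatched <- character(0)
  for (i in seq_len(nrow(tr))) {
    avail <- used < max_ratio
    if (!any(avail)) { unmatched <- c(unmatched, tr$patient_id[i]); next }
    d <- abs(un$logit - tr$logit[i])
    d[!avail] <- Inf
    # nearest; ties to lowest untreated id
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[order(un$patient_id[best])][1]
    if (d[best] <= cal_abs) {
      pairs[[length(pairs) + 1]] <- data.frame(
        treated_id = tr$patient_id[i], untreated_id = un$patient_id[best],
        distance = d[best], stringsAsFactors = FALSE)
      used[best] <- used[best] + 1L
    } else {
      unmatched <- c(unmatched, tr$patient_id[i])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(treated_id = character(0), untreated_id = character(0),
               distance = numeric(0), stringsAsFactors = FALSE)
  m <- table(pairs$untreated_id)
  pairs$weight <- if (nrow(pairs)) 1 / as.numeric(m[pairs$untreated_id]) else numeric(0)
  weights <- c(setNames(pairs$weight, pairs$treated_id),
               setNames(rep(1, length(m)), names(m)))
  structure(list(pairs = pairs, weights = weights,
                 unmatched_treated = unmatched,
                 caliper_logit_sd = caliper, caliper_abs = cal_abs),
            class = "ms_match")
}

#' @export
print.ms_match <- function(x, ...) {
  cat(sprintf("ms_match: %d pairs, %d untreated anchors, %d unmatched treated\n",
              nrow(x$pairs), length(unique(x$pairs$untreated_id)),
              length(x$unmatched_treated)))
  invisible(x)
}

weighted_mean_var <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  list(mean = m, var = sum(w * (x - m)^2) / (1 - sum(w^2)))
}

#' Covariate balance before and after matching
#'
#' Weighted standardized mean differences (SMD) per covariate: the
#' treated-minus-untreated mean difference over the pooled SD. Post-match
#' SMDs use the matching weights; covariates with zero pooled variance
#' report SMD 0.
#'
#' @param baseline Baseline table.
#' @param treated Logical vector or cohort labels aligned with `baseline`.
#' @param match An `ms_match` from [match_cohorts()].
#' @return data.frame: `covariate`, `smd_before`, `smd_after`.
#' @export
covariate_balance <- function(baseline, treated, match) {
  if (is.character(treated)) treated <- treated == "treated"
  X <- baseline_design(baseline)
  ids <- baseline$patient_id
  smd <- function(x, tr, w) {
    a <- weighted_mean_var(x[tr], w[tr])
    b <- weighted_mean_var(x[!tr], w[!tr])
    pool <- sqrt((a$var + b$var) / 2)
    if (!is.finite(pool) || pool < 1e-12) return(0)
    (a$mean - b$mean) / pool
  }
  w_before <- rep(1, length(ids))
  w_after <- match$weights[ids]
  w_after[is.na(w_after)] <- 0
  in_match <- w_after > 0
  data.frame(
    covariate = names(X),
    smd_before = vapply(X, smd, numeric(1), tr = treated, w = w_before),
    smd_after = vapply(names(X), function(nm) {
      smd(X[[nm]][in_match], treated[in_match], w_after[in_match])
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
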