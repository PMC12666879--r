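# Observed-versus-expected treatment response.

#' Expected trajectory for an assigned phenotype
#'
#' Delegates to [mean_trajectory()] for the class matching the patient's
#' assigned label and carries the patient-level predictive SD.
#'
#' @param model An `ms_lcmm`.
#' @param label Assigned class: an index (1..K) or a class label present
#'   in `model$class_labels`.
#' @param times Times at which to evaluate (years).
#' @return data.frame (`time`, `mean_edss`, `lower`, `upper`) with
#'   attribute `predictive_sd`; class `ms_expected`.
#' @export
predict_trajectory <- function(model, label, times) {
  k <- if (is.numeric(label)) {
    as.integer(label)
  } else {
    match(label, model$class_labels)
  }
  if (is.na(k) || k < 1 || k > model$K) {
    stop("input error: unknown class label '", label, "'")
  }
  if (!length(times)) {
    out <- data.frame(time = numeric(0), mean_edss = numeric(0),
                      lower = numeric(0), upper = numeric(0))
    attr(out, "predictive_sd") <- sqrt(model$sigma_b^2 + model$sigma_e^2)
    class(out) <- c("ms_expected", class(out))
    return(out)
  }
  out <- mean_trajectory(model, k, times)
  class(out) <- c("ms_expected", class(out))
  out
}

#' Per-visit disability z-scores (personalized treatment response index)
#'
#' Standardizes each observed EDSS against the assigned phenotype's
#' expected trajectory: `z = (observed - expected_mean) / predictive_sd`,
#' where the predictive SD is the patient-level spread
#' `sqrt(sigma_b^2 + sigma_e^2)` of the trajectory model. Negative values
#' mean less disability than expected for the phenotype.
#'
#' @param observed data.frame (`time_years`, `edss`) of one patient.
#' @param expected An `ms_expected` covering the observed times
#'   (linear interpolation within its range is used).
#' @param patient_id Optional id.
#' @return data.frame in time order: `patient_id`, `time`,
#'   `observed_edss`, `expected_mean`, `z`.
#' @export
disability_zscore <- function(observed, expected, patient_id = NA_character_) {
  sdp <- attr(expected, "predictive_sd")
  if (is.null(sdp) || !is.finite(sdp) || sdp <= 0) {
    stop("input error: predictive_sd must be positive")
  }
  o <- observed[order(observed$time_years), , drop = FALSE]
  mu <- if (nrow(expected) == 1) {
    rep(expected$mean_edss, nrow(o))
  } else {
    stats::approx(expected$time, expected$mean_edss, xout = o$time_years,
                  rule = 2)$y
  }
  data.frame(patient_id = patient_id, time = o$time_years,
             observed_edss = o$edss, expected_mean = mu,
             z = (o$edss - mu) / sdp, stringsAsFactors = FALSE)
}

#' Bonferroni adjustment flags
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param family_size Number of comparisons in the family (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return List: `significant` (logical; strict inequality against
#'   `alpha / family_size`), `threshold`, `family_size`.
#' @export
bonferroni_adjust <- function(p, family_size, alpha = 0.05) {
  if (family_size < 1) stop("input error: family size must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("input error: p must be in [0, 1]")
  thr <- alpha / family_size
  list(significant = p < thr, threshold = thr, family_size = family_size)
}

#' Observed-versus-predicted mixed-model contrast
#'
#' Stacks each treated patient's observed EDSS series with the noise-free
#' predicted series from their assigned phenotype, and fits a linear
#' mixed model with fixed effects source (observed vs predicted), time,
#' time^2 (centered), the source interactions, and optionally
#' source x time x timing and source x time^2 x timing for a mean-centered
#' timing covariate (time to treatment, or time to switch for escalation);
#' random intercept per patient; optional matching weights. Negative
#' source x time coefficients indicate slower-than-expected worsening.
#'
#' @param stacked data.frame with columns `patient_id`, `time`, `edss`,
#'   `source` ("observed"/"predicted"), optionally `timing` (constant per
#'   patient) and `weight`.
#' @param min_patients Refuse to fit below this many patients (default 10).
#' @return List of class `ms_contrast`: `terms` (data.frame term, beta,
#'   se, p_value), `n_patients`, `fit` (the lmer object).
#' @export
fit_obs_vs_pred <- function(stacked, min_patients = 10) {
  np <- length(unique(stacked$patient_id))
  if (np < min_patients) {
    stop("refusing to fit: only ", np, " patients in stratum (< ",
         min_patients, "); estimates would be unstable")
  }
  d <- stacked
  d$source <- factor(d$source, levels = c("predicted", "observed"))
  d$time2 <- d$time^2 - mean(d$time^2)
  has_timing <- "timing" %in% names(d) && length(unique(d$timing)) > 1
  if (has_timing) d$timing <- d$timing - mean(d$timing)
  w <- if ("weight" %in% names(d)) d$weight else rep(1, nrow(d))
  form <- if (has_timing) {
    edss ~ source * time + source * time2 +
      source:time:timing + source:time2:timing + (1 | patient_id)
  } else {
    edss ~ source * time + source * time2 + (1 | patient_id)
  }
  fit <- lme4::lmer(form, data = d, weights = w, REML = FALSE)
  s <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(s), beta = s[, "Estimate"],
                      se = s[, "Std. Error"],
                      p_value = 2 * pnorm(-abs(s[, "t value"])),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms, n_patients = np, fit = fit),
            class = "ms_contrast")
}

#' @export
print.ms_contrast <- function(x, ...) {
  cat("ms_contrast on", x$n_patients, "patients\n")
  print(x$terms, digits = 3)
  invisible(x)
}

#' Build the stacked observed + predicted table for one stratum
#'
#' Convenience assembler for [fit_obs_vs_pred()]: for each treated
#' patient, emits the observed visit series and the predicted series of
#' the assigned phenotype evaluated at the same times.
#'
#' @param visits Long visits of the treated patients.
#' @param assignments data.frame `patient_id`, `label` (class index or
#'   label).
#' @param model An `ms_lcmm`.
#' @param timing Optional named vector patient_id -> timing covariate.
#' @param weights Optional named vector patient_id -> matching weight.
#' @return Stacked data.frame ready for [fit_obs_vs_pred()].
#' @export
stack_obs_pred <- function(visits, assignments, model, timing = NULL,
                           weights = NULL) {
  lab <- setNames(assignments$label, assignments$patient_id)
  sp <- split(visits, visits$patient_id)
  out <- lapply(names(sp), function(id) {
    v <- sp[[id]]
    exp_tr <- predict_trajectory(model, lab[[id]], v$time_years)
    base <- data.frame(patient_id = id,
                       time = rep(v$time_years, 2),
                       edss = c(v$edss, exp_tr$mean_edss),
                       source = rep(c("observed", "predicted"),
                                    each = nrow(v)),
                       stringsAsFactors = FALSE)
    if (!is.null(timing)) base$timing <- unname(timing[id])
    if (!is.null(weights)) base$weight <- unname(weights[id])
    base
  })
  do.call(rbind, out)
}
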