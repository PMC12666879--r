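#' Default disability worsening phenotype specifications
#'
#' Returns the four phenotype specifications used as generator defaults.
#' Each phenotype has a quadratic mean EDSS trajectory
#' `beta0 + beta1 t + beta2 t^2` in years since onset, capped at
#' `plateau_cap`; plus a mixing weight and an annualized relapse rate.
#' Coefficients are chosen so each curve is non-decreasing over the
#' follow-up support (vertices at or beyond 25 years for the concave
#' shapes) and encodes the named onset timing of worsening:
#' `minimal` stays near a plateau of EDSS 2 reached around year 10;
#' `late` accelerates so worsening (+1 point) begins around year 11;
#' `early` around year 5; `rapid` worsens steeply from disease onset.
#' Mixing weights default to 15/70/3/12 percent and relapse rates to
#' 0.23/0.24/0.28/0.36 per year.
#'
#' @return Named list of four `ms_phenotype_spec` objects
#'   (minimal, late, early, rapid).
#' @export
#' @examples
#' sapply(phenotype_specs(), function(s) s$mixing_weight)
phenotype_specs <- function() {
  mk <- function(name, w, b0, b1, b2, cap, arr) {
    structure(list(name = name, mixing_weight = w,
                   beta0 = b0, beta1 = b1, beta2 = b2,
                   plateau_cap = cap, arr = arr),
              class = "ms_phenotype_spec")
  }
  list(
    minimal = mk("minimal", 0.15, 1.95, 0.005,  0.0000, 2.5, 0.23),
    late    = mk("late",    0.70, 1.50, 0.000,  0.0130, 10., 0.24),
    early   = mk("early",   0.03, 2.50, 0.120,  0.0090, 10., 0.28),
    rapid   = mk("rapid",   0.12, 2.50, 0.400, -0.0080, 8.0, 0.36)
  )
}

#' Evaluate a phenotype's mean EDSS trajectory
#'
#' @param spec A `ms_phenotype_spec`.
#' @param t Numeric vector of times (years since onset).
#' @return Mean latent EDSS at `t` (quadratic, capped, in \[0, 10\]).
#' @export
phenotype_mean <- function(spec, t) {
  stopifnot(inherits(spec, "ms_phenotype_spec"), all(t >= 0))
  m <- spec$beta0 + spec$beta1 * t + spec$beta2 * t * t
  pmin(pmax(m, 0), min(spec$plateau_cap, 10))
}

#' Cohort generator configuration
#'
#' @param n_patients Number of patients to simulate.
#' @param treated_fraction Fraction of patients receiving a DMT strategy
#'   (default 0: the untreated registry cohort).
#' @param visit_interval_years Two-element range of inter-visit gaps
#'   (default 3 to 6 months).
#' @param followup_meanlog,followup_sdlog Log-normal parameters of the
#'   follow-up duration; defaults reproduce a median of 10.1 years with
#'   IQR roughly 7.3 to 13.7.
#' @param followup_range Truncation range for follow-up (years); the lower
#'   bound mirrors the 3-year minimum-follow-up inclusion criterion.
#' @param measurement_sd Visit-level EDSS measurement noise (points,
#'   before grid rounding).
#' @param intercept_sd Between-patient random intercept SD (points).
#' @param relapse_bump Transient EDSS elevation at a relapse (points).
#' @param bump_window_days Days over which the relapse bump decays
#'   linearly to zero.
#' @param incomplete_recovery_prob Probability a relapse leaves incomplete
#'   recovery.
#' @param strategy_probs Probabilities of DMT strategy (moderate,
#'   escalation, high) for treated patients.
#' @param effect_moderate,effect_high Post-initiation slope multipliers of
#'   moderate- and high-efficacy DMTs (1 = no effect).
#' @param seed Master seed; per-patient substreams derive from it.
#' @return A validated `ms_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 2563,
                          treated_fraction = 0,
                          visit_interval_years = c(0.25, 0.5),
                          followup_meanlog = log(10.1),
                          followup_sdlog = 0.466,
                          followup_range = c(3, 25),
                          measurement_sd = 0.4,
                          intercept_sd = 0.3,
                          relapse_bump = 1.0,
                          bump_window_days = 60,
                          incomplete_recovery_prob = 0.3,
                          strategy_probs = c(moderate = 0.54, escalation = 0.13, high = 0.33),
                          effect_moderate = 0.6,
                          effect_high = 0.35,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              treated_fraction = treated_fraction,
              visit_interval_years = visit_interval_years,
              followup_meanlog = followup_meanlog,
              followup_sdlog = followup_sdlog,
              followup_range = followup_range,
              measurement_sd = measurement_sd,
              intercept_sd = intercept_sd,
              relapse_bump = relapse_bump,
              bump_window_days = bump_window_days,
              incomplete_recovery_prob = incomplete_recovery_prob,
              strategy_probs = strategy_probs,
              effect_moderate = effect_moderate,
              effect_high = effect_high,
              seed = as.integer(seed))
  class(cfg) <- "ms_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1L) stop("configuration error: n_patients must be >= 1")
  if (cfg$treated_fraction < 0 || cfg$treated_fraction > 1) {
    stop("configuration error: treated_fraction must be in [0, 1]")
  }
  if (cfg$measurement_sd < 0) stop("configuration error: measurement_sd must be >= 0")
  if (cfg$intercept_sd < 0) stop("configuration error: intercept_sd must be >= 0")
  if (length(cfg$visit_interval_years) != 2 ||
      cfg$visit_interval_years[1] > cfg$visit_interval_years[2] ||
      cfg$visit_interval_years[1] <= 0) {
    stop("configuration error: visit_interval_years must be an increasing positive pair")
  }
  invisible(cfg)
}

#' Simulate relapse onset times
#'
#' Relapses follow a homogeneous Poisson process with the phenotype's
#' annualized rate, so the expected count over follow-up is
#' `arr * followup`.
#'
#' @param arr Annualized relapse rate (per year, >= 0).
#' @param followup Follow-up duration in years (>= 0).
#' @return Sorted numeric vector of onset times in \[0, followup\].
#' @export
simulate_relapses <- function(arr, followup) {
  if (!is.numeric(arr) || length(arr) != 1 || arr < 0) {
    stop("configuration error: arr must be a single non-negative rate")
  }
  if (followup < 0) stop("configuration error: followup must be >= 0")
  if (arr == 0 || followup == 0) return(numeric(0))
  n <- rpois(1, arr * followup)
  sort(runif(n, 0, followup))
}

# Per-phenotype baseline feature distributions. Contrasts follow the
# printed group differences: early-worsening has heavy spinal-cord
# involvement (84% with >= 1 SC lesion, 65% SC Gd+); rapid-worsening has
# the highest brain lesion load (35% with >= 9 T2 lesions) and older onset;
# late-worsening has the highest optic-neuritis frequency.
baseline_params <- function(phenotype) {
  p <- switch(phenotype,
    minimal = list(age_mean = 31.8, age_sd = 9.2,
                   onset = c(optic_nerve = 0.22, brainstem = 0.15,
                             spinal_cord = 0.35, hemispheric = 0.28),
                   brain_t2 = c(`1-2` = 0.19, `3-8` = 0.54, `>=9` = 0.27),
                   brain_gd = 0.48,
                   sc_any = 0.60, sc_ge3_given_any = 0.13,
                   sc_gd = 0.39),
    late    = list(age_mean = 32.2, age_sd = 9.9,
                   onset = c(optic_nerve = 0.28, brainstem = 0.13,
                             spinal_cord = 0.28, hemispheric = 0.31),
                   brain_t2 = c(`1-2` = 0.19, `3-8` = 0.54, `>=9` = 0.27),
                   brain_gd = 0.46,
                   sc_any = 0.59, sc_ge3_given_any = 0.13,
                   sc_gd = 0.34),
    early   = list(age_mean = 34.7, age_sd = 9.3,
                   onset = c(optic_nerve = 0.15, brainstem = 0.08,
                             spinal_cord = 0.59, hemispheric = 0.18),
                   brain_t2 = c(`1-2` = 0.15, `3-8` = 0.55, `>=9` = 0.30),
                   brain_gd = 0.62,
                   sc_any = 0.84, sc_ge3_given_any = 0.30,
                   sc_gd = 0.65),
    rapid   = list(age_mean = 36.0, age_sd = 10.8,
                   onset = c(optic_nerve = 0.21, brainstem = 0.12,
                             spinal_cord = 0.28, hemispheric = 0.39),
                   brain_t2 = c(`1-2` = 0.12, `3-8` = 0.53, `>=9` = 0.35),
                   brain_gd = 0.57,
                   sc_any = 0.77, sc_ge3_given_any = 0.25,
                   sc_gd = 0.43),
    stop("input error: unknown phenotype '", phenotype, "'")
  )
  p$female <- 0.67
  p$ocb <- 0.88
  p
}

#' Simulate baseline clinical and MRI features for one patient
#'
#' Draws demographic, onset-topography, CSF, and categorical MRI lesion
#' features from phenotype-specific distributions. Onset symptoms are
#' drawn as a single primary localization (optic nerve, brainstem, spinal
#' cord, or hemispheric), so exactly one onset flag is true. Age at onset
#' is truncated above 18 years.
#'
#' @param phenotype One of "minimal", "late", "early", "rapid".
#' @return List of class `ms_baseline` (without `baseline_edss`, which the
#'   cohort generator fills in from the first simulated visit).
#' @export
simulate_baseline_features <- function(phenotype) {
  p <- baseline_params(phenotype)
  age <- rnorm(1, p$age_mean, p$age_sd)
  while (age <= 18) age <- rnorm(1, p$age_mean, p$age_sd)
  site <- sample(names(p$onset), 1, prob = p$onset)
  sc_any <- runif(1) < p$sc_any
  sc_t2 <- if (!sc_any) "0" else if (runif(1) < p$sc_ge3_given_any) ">=3" else "1-2"
  structure(list(
    age_at_onset = age,
    sex = if (runif(1) < p$female) "F" else "M",
    optic_nerve = site == "optic_nerve",
    brainstem = site == "brainstem",
    spinal_cord = site == "spinal_cord",
    hemispheric = site == "hemispheric",
    ocb = runif(1) < p$ocb,
    baseline_edss = NA_real_,
    brain_t2 = sample(names(p$brain_t2), 1, prob = p$brain_t2),
    brain_gd = runif(1) < p$brain_gd,
    sc_t2 = sc_t2,
    sc_gd = if (sc_any) runif(1) < max(p$sc_gd, 0.05) else FALSE
  ), class = "ms_baseline")
}

# Latent disability at times t: class mean + random intercept + transient
# relapse bumps (linear decay over the bump window).
latent_edss <- function(spec, t, intercept, relapse_times, cfg,
                        mean_fun = NULL) {
  m <- if (is.null(mean_fun)) phenotype_mean(spec, t) else mean_fun(t)
  bump <- numeric(length(t))
  w <- days2years(cfg$bump_window_days)
  for (r in relapse_times) {
    d <- t - r
    active <- d >= 0 & d < w
    bump[active] <- bump[active] + cfg$relapse_bump * (1 - d[active] / w)
  }
  m + intercept + bump
}

#' Simulate one patient's visit-level EDSS series
#'
#' The latent disability at a visit is the phenotype mean trajectory plus
#' the patient's random intercept plus any transient relapse elevation;
#' Gaussian measurement noise is added and the result is clamped to
#' \[0, 10\] and rounded to the legal EDSS grid.
#'
#' @param spec Phenotype specification.
#' @param followup Follow-up duration (years).
#' @param visit_times Sorted visit times within \[0, followup\].
#' @param relapse_times Relapse onset times (years).
#' @param config A `ms_cohort_config`.
#' @param intercept Patient random intercept (drawn if `NULL`).
#' @param mean_fun Optional override of the mean curve (used for treated
#'   counterfactuals).
#' @return data.frame with columns `time_years`, `edss`.
#' @export
simulate_patient_trajectory <- function(spec, followup, visit_times,
                                        relapse_times = numeric(0),
                                        config = cohort_config(n_patients = 1),
                                        intercept = NULL, mean_fun = NULL) {
  if (is.unsorted(visit_times, strictly = TRUE)) {
    stop("input error: visit_times must be strictly increasing")
  }
  if (length(visit_times) &&
      (min(visit_times) < 0 || max(visit_times) > followup)) {
    stop("input error: visit_times must lie in [0, followup]")
  }
  if (is.null(intercept)) intercept <- rnorm(1, 0, config$intercept_sd)
  lat <- latent_edss(spec, visit_times, intercept, relapse_times, config,
                     mean_fun)
  obs <- lat + rnorm(length(visit_times), 0, config$measurement_sd)
  data.frame(time_years = visit_times, edss = round_edss(obs))
}

# Draw a truncated log-normal follow-up duration.
draw_followup <- function(cfg) {
  repeat {
    f <- rlnorm(1, cfg$followup_meanlog, cfg$followup_sdlog)
    if (f >= cfg$followup_range[1] && f <= cfg$followup_range[2]) return(f)
  }
}

# Draw the visit schedule: first assessment within 6 months of onset,
# then gaps uniform on the configured 3-6 month interval.
draw_visit_times <- function(cfg, followup) {
  t <- runif(1, 0, 0.5)
  out <- numeric(0)
  while (t <= followup) {
    out <- c(out, t)
    t <- t + runif(1, cfg$visit_interval_years[1], cfg$visit_interval_years[2])
  }
  out
}

simulate_patient <- function(id, phenotype, specs, cfg, pseed) {
  spec <- specs[[phenotype]]
  with_seed(pseed, {
    followup <- draw_followup(cfg)
    visit_times <- draw_visit_times(cfg, followup)
    relapse_times <- simulate_relapses(spec$arr, followup)
    intercept <- rnorm(1, 0, cfg$intercept_sd)
    baseline <- simulate_baseline_features(phenotype)
    recovery <- if (length(relapse_times)) {
      ifelse(runif(length(relapse_times)) < cfg$incomplete_recovery_prob,
             "incomplete", "complete")
    } else character(0)
    noise_seed <- substream_seed(pseed, 1L, salt = 17L)
  })
  visits <- with_seed(noise_seed, {
    simulate_patient_trajectory(spec, followup, visit_times, relapse_times,
                                cfg, intercept = intercept)
  })
  baseline$baseline_edss <- visits$edss[1]
  structure(list(
    id = id,
    cohort = "untreated",
    true_phenotype = phenotype,
    baseline = baseline,
    visits = visits,
    relapses = data.frame(onset_years = relapse_times,
                          recovery = recovery,
                          stringsAsFactors = FALSE),
    treatments = data.frame(product = character(0), efficacy = character(0),
                            start_years = numeric(0), stop_years = numeric(0),
                            stringsAsFactors = FALSE),
    followup_years = followup,
    .seed = pseed,
    .intercept = intercept,
    .noise_seed = noise_seed
  ), class = "ms_patient")
}

#' Apply a treatment strategy to an untreated ground-truth patient
#'
#' Assigns a treatment episode (or an escalation pair) and regenerates the
#' visit series from the modified latent curve: after initiation the mean
#' slope is multiplied by the strategy's effect multiplier (1 = none,
#' 0 = complete suppression). The same per-patient noise substream is
#' replayed, so a multiplier of 1 reproduces the untreated series exactly.
#'
#' @param record An `ms_patient` produced by the generator.
#' @param strategy One of "moderate", "high", "escalation".
#' @param config The cohort configuration (supplies effect multipliers).
#' @param start_years Treatment start (drawn if `NULL`).
#' @param switch_years Escalation switch time (drawn if `NULL`).
#' @return The modified `ms_patient` with `cohort = "treated"`.
#' @export
simulate_treatment <- function(record, strategy, config,
                               start_years = NULL, switch_years = NULL) {
  if (!strategy %in% c("moderate", "high", "escalation")) {
    stop("input error: unknown strategy '", strategy, "'")
  }
  spec <- phenotype_specs()[[record$true_phenotype]]
  fu <- record$followup_years
  with_seed(substream_seed(record$.seed, 2L, salt = 23L), {
    if (is.null(start_years)) {
      start_years <- min(max(rlnorm(1, log(1.5), 0.6), 0.25), fu * 0.5)
    }
    if (strategy == "escalation" && is.null(switch_years)) {
      switch_years <- min(start_years + max(rlnorm(1, log(3), 0.5), 0.5),
                          fu * 0.9)
    }
  })
  em <- config$effect_moderate
  eh <- config$effect_high
  base <- function(t) phenotype_mean(spec, t)
  mean_fun <- switch(strategy,
    moderate = treated_curve(base, start_years, em),
    high = treated_curve(base, start_years, eh),
    escalation = {
      f1 <- treated_curve(base, start_years, em)
      treated_curve(f1, switch_years, eh / em)
    })
  visits <- with_seed(record$.noise_seed, {
    simulate_patient_trajectory(spec, fu, record$visits$time_years,
                                record$relapses$onset_years, config,
                                intercept = record$.intercept,
                                mean_fun = mean_fun)
  })
  record$visits <- visits
  record$baseline$baseline_edss <- visits$edss[1]
  record$cohort <- "treated"
  eff1 <- if (strategy == "high") "high" else "moderate"
  prod1 <- if (eff1 == "high") "natalizumab" else "interferon-beta"
  record$treatments <- if (strategy == "escalation") {
    data.frame(product = c("interferon-beta", "ocrelizumab"),
               efficacy = c("moderate", "high"),
               start_years = c(start_years, switch_years),
               stop_years = c(switch_years, fu),
               stringsAsFactors = FALSE)
  } else {
    data.frame(product = prod1, efficacy = eff1,
               start_years = start_years, stop_years = fu,
               stringsAsFactors = FALSE)
  }
  record
}

# Compose a mean curve whose slope is multiplied by `mult` after `t0`.
treated_curve <- function(f, t0, mult) {
  function(t) {
    ifelse(t < t0, f(t), f(t0) + mult * (f(t) - f(t0)))
  }
}

#' Simulate a registry-style cohort with known ground truth
#'
#' Draws each patient's phenotype from the mixing weights, then simulates
#' follow-up duration, visit schedule, relapses, baseline features, and the
#' visit-level EDSS series. A `treated_fraction > 0` additionally assigns a
#' DMT strategy (moderate / escalation / high per
#' `config$strategy_probs`) and regenerates the treated series from the
#' attenuated latent curve. Each patient is generated on an independent
#' substream of the master seed, so patient `i` is reproducible regardless
#' of cohort size.
#'
#' @param config An `ms_cohort_config`.
#' @param phenotypes Named list of phenotype specs (mixing weights must
#'   sum to 1).
#' @return List of `ms_patient` records with class `ms_cohort`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_patients = 5, seed = 7))
#' sapply(coh, function(p) p$true_phenotype)
simulate_cohort <- function(config = cohort_config(),
                            phenotypes = phenotype_specs()) {
  validate_cohort_config(config)
  w <- vapply(phenotypes, function(s) s$mixing_weight, numeric(1))
  if (any(w < 0) || abs(sum(w) - 1) > 1e-12) {
    stop("configuration error: mixing weights must be non-negative and sum to 1")
  }
  n <- config$n_patients
  labels <- with_seed(substream_seed(config$seed, 0L), {
    list(ph = sample(names(phenotypes), n, replace = TRUE, prob = w),
         treated = runif(n) < config$treated_fraction,
         strategy = sample(names(config$strategy_probs), n, replace = TRUE,
                           prob = config$strategy_probs))
  })
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- simulate_patient(sprintf("P%05d", i), labels$ph[i], phenotypes,
                            config, substream_seed(config$seed, i))
    if (labels$treated[i]) {
      rec <- simulate_treatment(rec, labels$strategy[i], config)
    }
    cohort[[i]] <- rec
  }
  structure(cohort, class = "ms_cohort", config = config)
}

#' @export
print.ms_cohort <- function(x, ...) {
  ph <- table(vapply(x, function(p) p$true_phenotype, character(1)))
  cat("ms_cohort:", length(x), "patients\n")
  cat("  phenotypes:", paste(names(ph), ph, sep = "=", collapse = ", "), "\n")
  cat("  treated:", sum(vapply(x, function(p) p$cohort, character(1)) == "treated"), "\n")
  invisible(x)
}

# ---- long-format accessors ---------------------------------------------

#' Extract long-format tables from a cohort
#'
#' @param cohort An `ms_cohort` (or plain list of `ms_patient`).
#' @return `cohort_visits`: data.frame (patient_id, time_years, edss);
#'   `cohort_relapses`: (patient_id, onset_years, recovery);
#'   `cohort_treatments`: (patient_id, product, efficacy, start_years,
#'   stop_years); `cohort_baseline`: one row per patient;
#'   `cohort_truth`: (patient_id, true_phenotype, cohort, followup_years).
#' @export
cohort_visits <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    cbind(patient_id = p$id, p$visits, stringsAsFactors = FALSE)
  }))
}

#' @rdname cohort_visits
#' @export
cohort_relapses <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, function(p) {
    if (!nrow(p$relapses)) return(NULL)
    cbind(patient_id = p$id, p$relapses, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), onset_years = numeric(0),
                      recovery = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' @rdname cohort_visits
#' @export
cohort_treatments <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, function(p) {
    if (!nrow(p$treatments)) return(NULL)
    cbind(patient_id = p$id, p$treatments, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), product = character(0),
                      efficacy = character(0), start_years = numeric(0),
                      stop_years = numeric(0), stringsAsFactors = FALSE)
  }
  out
}

#' @rdname cohort_visits
#' @export
cohort_baseline <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    b <- p$baseline
    data.frame(patient_id = p$id, age_at_onset = b$age_at_onset, sex = b$sex,
               optic_nerve = b$optic_nerve, brainstem = b$brainstem,
               spinal_cord = b$spinal_cord, hemispheric = b$hemispheric,
               ocb = b$ocb, baseline_edss = b$baseline_edss,
               brain_t2 = b$brain_t2, brain_gd = b$brain_gd,
               sc_t2 = b$sc_t2, sc_gd = b$sc_gd,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname cohort_visits
#' @export
cohort_truth <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$id, true_phenotype = p$true_phenotype,
               cohort = p$cohort, followup_years = p$followup_years,
               stringsAsFactors = FALSE)
  }))
}

#' Write a cohort to delimited text tables
#'
#' Writes `visits.csv`, `relapses.csv`, `treatments.csv`, `baseline.csv`
#' and `truth.csv` (ground truth, for testing only) into `dir`.
#'
#' @param cohort An `ms_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("visits.csv", "relapses.csv", "treatments.csv",
                            "baseline.csv", "truth.csv"))
  write.csv(cohort_visits(cohort), paths[1], row.names = FALSE)
  write.csv(cohort_relapses(cohort), paths[2], row.names = FALSE)
  write.csv(cohort_treatments(cohort), paths[3], row.names = FALSE)
  write.csv(cohort_baseline(cohort), paths[4], row.names = FALSE)
  write.csv(cohort_truth(cohort), paths[5], row.names = FALSE)
  invisible(paths)
}
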