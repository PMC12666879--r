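# End-to-end orchestration: simulate -> filter -> events -> fit -> match ->
# classify -> treatment effect.

run_config_defaults <- function() {
  list(
    seed = 1L,
    n_untreated = 2563L,
    n_treated = 2952L,
    kmin = 1L, kmax = 6L,
    criterion = "BIC",
    n_starts = 5L,
    folds = 0L,                 # > 1 enables cross-validation of K_best
    caliper = 0.2, max_ratio = 4L,
    split = 0.7,
    ntree = 500L,
    min_stratum = 10L,
    baseline_mode = "roving"
  )
}

#' Build and validate a pipeline run configuration
#'
#' Unknown keys are rejected; values override the documented defaults
#' (master seed, cohort sizes, class-count range and criterion, matching
#' caliper and ratio, classifier split and forest size, contrast stratum
#' floor, event baseline mode).
#'
#' @param ... Named overrides of the defaults.
#' @return Validated list of class `ms_run_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("configuration error: unknown config keys: ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$kmin >= 1, cfg$kmax >= cfg$kmin,
            cfg$criterion %in% c("BIC", "AIC", "SABIC", "ICL"),
            cfg$baseline_mode %in% c("roving", "fixed"))
  structure(cfg, class = "ms_run_config")
}

#' Run the full phenotype-and-treatment-response pipeline
#'
#' Simulates the untreated and treated cohorts, applies inclusion
#' criteria and relapse-window score exclusion, detects CDW events and
#' labels them RAW/PIRA, fits latent-class trajectory models over the
#' configured K range and selects the class count, assigns phenotypes by
#' posterior, propensity-matches treated to untreated, trains the
#' random-forest classifier and transfers labels to the treated cohort,
#' fits observed-versus-predicted contrasts per phenotype and DMT
#' strategy, and writes per-patient disability z-scores. All outputs are
#' plain delimited text or JSON; a manifest records seeds and MD5 hashes
#' of every file.
#'
#' @param config An `ms_run_config`.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "ms_run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_msg <- function(...) message("[mstraj] ", sprintf(...))
  ev_cfg <- event_config(baseline_mode = config$baseline_mode)

  log_msg("stage simulate: n_untreated=%d n_treated=%d seed=%d",
          config$n_untreated, config$n_treated, config$seed)
  untreated <- simulate_cohort(cohort_config(
    n_patients = config$n_untreated, treated_fraction = 0,
    seed = config$seed))
  treated <- simulate_cohort(cohort_config(
    n_patients = config$n_treated, treated_fraction = 1,
    seed = substream_seed(config$seed, 1L, salt = 101L)))
  # disambiguate ids across the two cohorts
  treated[] <- lapply(treated, function(p) { p$id <- sub("^P", "T", p$id); p })
  untreated <- apply_inclusion_criteria(untreated, ev_cfg)
  treated <- apply_inclusion_criteria(treated, ev_cfg)
  write_cohort(untreated, file.path(out_dir, "untreated"))
  write_cohort(treated, file.path(out_dir, "treated"))

  log_msg("stage events")
  truth_u <- cohort_truth(untreated)
  events <- detect_cohort_events(untreated, ev_cfg)
  events$phenotype <- truth_u$true_phenotype[match(events$patient_id,
                                                   truth_u$patient_id)]
  write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)

  log_msg("stage fit-trajectories: K=%d..%d", config$kmin, config$kmax)
  vis_u <- do.call(rbind, lapply(untreated, function(p) {
    v <- exclude_relapse_window_scores(p$visits, p$relapses$onset_years, ev_cfg)
    if (!nrow(v)) return(NULL)
    cbind(patient_id = p$id, v, stringsAsFactors = FALSE)
  }))
  sel <- select_class_number(vis_u, K_range = config$kmin:config$kmax,
                             criterion = config$criterion,
                             n_starts = config$n_starts,
                             seed = substream_seed(config$seed, 2L, salt = 101L))
  write.csv(sel$summary, file.path(out_dir, "criteria.csv"), row.names = FALSE)
  model <- sel$models[[as.character(sel$K_best)]]
  write_model_json(model, file.path(out_dir, "model.json"))
  if (config$folds > 1) {
    cv <- cross_validate(vis_u, sel$K_best, folds = config$folds,
                         seed = substream_seed(config$seed, 3L, salt = 101L),
                         n_starts = 1)
    jsonlite::write_json(list(K = sel$K_best,
                              mean_loglik = cv$mean_loglik),
                         file.path(out_dir, "cv.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  post_u <- posterior_classify(model, vis_u)
  write.csv(post_u, file.path(out_dir, "assignments_untreated.csv"),
            row.names = FALSE)

  log_msg("stage match")
  base_u <- cohort_baseline(untreated)
  base_t <- cohort_baseline(treated)
  base_all <- rbind(base_u, base_t)
  treated_flag <- rep(c(FALSE, TRUE), c(nrow(base_u), nrow(base_t)))
  scores <- estimate_propensity(base_all, treated_flag)
  match <- match_cohorts(scores, caliper = config$caliper,
                         max_ratio = config$max_ratio)
  write.csv(match$pairs, file.path(out_dir, "matches.csv"), row.names = FALSE)
  write.csv(covariate_balance(base_all, treated_flag, match),
            file.path(out_dir, "balance.csv"), row.names = FALSE)

  log_msg("stage classify")
  labels_u <- post_u$class_label[match(base_u$patient_id, post_u$patient_id)]
  clf <- train_classifier(base_u, labels_u, split = config$split,
                          seed = substream_seed(config$seed, 4L, salt = 101L),
                          params = rf_params(ntree = config$ntree))
  assign_t <- assign_phenotypes(clf, base_t)
  write.csv(assign_t, file.path(out_dir, "assignments_treated.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(accuracy = clf$report$accuracy,
                            majority_baseline = clf$report$majority_baseline,
                            per_class = clf$report$per_class,
                            importance = clf$report$importance),
                       file.path(out_dir, "classifier_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  log_msg("stage treatment-effect")
  vis_t <- cohort_visits(treated)
  trt_t <- cohort_treatments(treated)
  first_trt <- do.call(rbind, lapply(split(trt_t, trt_t$patient_id), function(d) {
    d <- d[order(d$start_years), ]
    data.frame(patient_id = d$patient_id[1],
               strategy = if (nrow(d) > 1) "escalation" else
                 if (d$efficacy[1] == "high") "high" else "moderate",
               timing = if (nrow(d) > 1) d$start_years[2] else d$start_years[1],
               stringsAsFactors = FALSE)
  }))
  weights <- match$weights
  contrasts <- list()
  for (ph in unique(assign_t$label)) {
    for (strat in c("moderate", "escalation", "high")) {
      ids <- intersect(assign_t$patient_id[assign_t$label == ph],
                       first_trt$patient_id[first_trt$strategy == strat])
      v <- vis_t[vis_t$patient_id %in% ids, , drop = FALSE]
      res <- tryCatch({
        st <- stack_obs_pred(v, assign_t[assign_t$patient_id %in% ids, ],
                             model,
                             timing = setNames(first_trt$timing,
                                               first_trt$patient_id),
                             weights = weights)
        fit_obs_vs_pred(st, min_patients = config$min_stratum)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        log_msg("  %s/%s skipped: %s", ph, strat, conditionMessage(res))
        next
      }
      tr <- res$terms
      tr$phenotype <- ph
      tr$strategy <- strat
      tr$n_patients <- res$n_patients
      contrasts[[paste(ph, strat)]] <- tr
    }
  }
  if (length(contrasts)) {
    write.csv(do.call(rbind, contrasts), file.path(out_dir, "contrasts.csv"),
              row.names = FALSE)
  }
  zs <- do.call(rbind, lapply(split(vis_t, vis_t$patient_id), function(v) {
    id <- v$patient_id[1]
    lab <- assign_t$label[assign_t$patient_id == id]
    if (!length(lab)) return(NULL)
    k <- match(lab, model$class_labels)
    if (is.na(k)) k <- 1L
    exp_tr <- suppressWarnings(predict_trajectory(model, k, v$time_years))
    disability_zscore(v, exp_tr, patient_id = id)
  }))
  write.csv(zs, file.path(out_dir, "zscores.csv"), row.names = FALSE)

  log_msg("stage characterize")
  char <- characterize_phenotypes(base_u, labels_u)
  write.csv(char, file.path(out_dir, "phenotype_comparisons.csv"),
            row.names = FALSE)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    K_best = sel$K_best,
    n_untreated = length(untreated),
    n_treated = length(treated),
    files = data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Compare baseline features across phenotypes
#'
#' Pairwise group comparisons per feature: categorical features use the
#' chi-square test (Fisher's exact test when any expected cell count is
#' below 5); continuous features use Student's t test when a
#' Kolmogorov-Smirnov normality screen is not rejected in both groups,
#' and the Wilcoxon rank-sum test otherwise. P-values carry a Bonferroni
#' significance flag over the pairs within each feature.
#'
#' @param baseline Baseline table.
#' @param labels Phenotype label per row.
#' @param weights Optional per-patient analysis weights (currently used
#'   only to drop zero-weight rows).
#' @return data.frame: `feature`, `group1`, `group2`, `test`, `p_value`,
#'   `significant`.
#' @export
characterize_phenotypes <- function(baseline, labels, weights = NULL) {
  if (length(unique(labels)) < 2) {
    stop("input error: need >= 2 phenotypes to compare")
  }
  if (!is.null(weights)) {
    keep <- weights > 0
    baseline <- baseline[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  continuous <- c("age_at_onset", "baseline_edss")
  categorical <- c("sex", "optic_nerve", "brainstem", "spinal_cord",
                   "hemispheric", "ocb", "brain_t2", "brain_gd", "sc_t2",
                   "sc_gd")
  groups <- sort(unique(labels))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- list()
  for (feat in c(continuous, categorical)) {
    x <- baseline[[feat]]
    for (pr in pairs) {
      i1 <- labels == pr[1]; i2 <- labels == pr[2]
      if (feat %in% continuous) {
        x1 <- x[i1]; x2 <- x[i2]
        if (sd(x1) < 1e-12 || sd(x2) < 1e-12) {
          message("characterize: constant feature '", feat,
                  "' in a group; test skipped")
          next
        }
        normal <- suppressWarnings(
          ks.test(scale(x1), "pnorm")$p.value > 0.05 &&
            ks.test(scale(x2), "pnorm")$p.value > 0.05)
        res <- if (normal) {
          list(test = "t", p = t.test(x1, x2)$p.value)
        } else {
          list(test = "wilcoxon",
               p = suppressWarnings(wilcox.test(x1, x2)$p.value))
        }
      } else {
        tab <- table(factor(labels[i1 | i2]), x[i1 | i2])
        tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
        if (any(dim(tab) < 2)) {
          message("characterize: constant feature '", feat,
                  "' in pair; test skipped")
          next
        }
        expected <- suppressWarnings(chisq.test(tab)$expected)
        res <- if (any(expected < 5)) {
          list(test = "fisher",
               p = fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 10)$p.value)
        } else {
          list(test = "chisq",
               p = suppressWarnings(chisq.test(tab, correct = FALSE)$p.value))
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        feature = feat, group1 = pr[1], group2 = pr[2],
        test = res$test, p_value = res$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # Bonferroni family = the pairwise comparisons within each feature block
  out$significant <- bonferroni_adjust(out$p_value, length(pairs))$significant
  out
}
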