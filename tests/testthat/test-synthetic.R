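specs <- phenotype_specs()

test_that("phenotype specs form a valid mixture with sane curves", {
  w <- sapply(specs, function(s) s$mixing_weight)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(sapply(specs, function(s) s$arr) >= 0))
  grid <- seq(0, 25, by = 0.25)
  for (s in specs) {
    m <- phenotype_mean(s, grid)
    expect_true(all(diff(m) >= -1e-12), info = s$name)  # non-decreasing
    expect_true(all(m >= 0 & m <= 10), info = s$name)
  }
  # minimal-worsening plateaus at EDSS 2 around year 10
  expect_equal(phenotype_mean(specs$minimal, 10), 2.0, tolerance = 1e-9)
})

test_that("simulate_cohort honours config validation and degenerate mixtures", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(treated_fraction = 2), "treated_fraction")
  bad <- specs
  bad$minimal$mixing_weight <- 0.5
  expect_error(simulate_cohort(cohort_config(n_patients = 5), bad), "sum to 1")

  deg <- lapply(specs, function(s) { s$mixing_weight <- 0; s })
  deg$minimal$mixing_weight <- 1
  coh <- simulate_cohort(cohort_config(n_patients = 4, seed = 7), deg)
  expect_identical(vapply(coh, function(p) p$true_phenotype, character(1)),
                   rep("minimal", 4))
})

test_that("same seed gives byte-identical cohorts; records satisfy invariants", {
  cfg <- cohort_config(n_patients = 40, treated_fraction = 0.4, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  for (p in a) {
    expect_true(!is.unsorted(p$visits$time_years, strictly = TRUE))
    expect_true(all(is_edss(p$visits$edss)))
    expect_true(all(p$visits$time_years >= 0 &
                      p$visits$time_years <= p$followup_years))
    expect_true(all(p$relapses$onset_years >= 0 &
                      p$relapses$onset_years <= p$followup_years))
    if (nrow(p$treatments) > 1) {
      expect_true(all(diff(p$treatments$start_years) >= 0))
      expect_true(all(p$treatments$stop_years >= p$treatments$start_years))
    }
    expect_true(p$baseline$age_at_onset > 18)
    expect_true(sum(p$baseline$optic_nerve, p$baseline$brainstem,
                    p$baseline$spinal_cord, p$baseline$hemispheric) == 1)
  }
  # patient substreams: patient i identical regardless of cohort size
  small <- simulate_cohort(cohort_config(n_patients = 5, treated_fraction = 0.4,
                                         seed = 99))
  expect_identical(small[[3]]$visits, a[[3]]$visits)
})

test_that("empirical phenotype frequencies converge to the mixing weights", {
  coh <- simulate_cohort(cohort_config(n_patients = 10000, seed = 21))
  freq <- table(vapply(coh, function(p) p$true_phenotype, character(1))) / 10000
  w <- sapply(specs, function(s) s$mixing_weight)
  for (nm in names(w)) {
    expect_lt(abs(freq[[nm]] - w[[nm]]), 0.015)
  }
})

test_that("noise-free trajectories equal the class mean on the grid", {
  cfg <- cohort_config(n_patients = 1, measurement_sd = 0, intercept_sd = 0)
  tt <- seq(0.2, 14, by = 0.5)
  tr <- simulate_patient_trajectory(specs$minimal, 15, tt, numeric(0), cfg,
                                    intercept = 0)
  expect_equal(tr$edss, round_edss(phenotype_mean(specs$minimal, tt)))
  # minimal-worsening at 10 years, noise-free: EDSS 2.0
  tr10 <- simulate_patient_trajectory(specs$minimal, 12, 10, numeric(0), cfg,
                                      intercept = 0)
  expect_equal(tr10$edss, 2.0)
  # latent values beyond the scale are clamped
  hot <- specs$rapid; hot$beta0 <- 11.3; hot$plateau_cap <- 99
  tr2 <- simulate_patient_trajectory(hot, 5, 1, numeric(0), cfg, intercept = 0)
  expect_equal(tr2$edss, 10.0)
  expect_error(simulate_patient_trajectory(specs$minimal, 15, c(3, 1), numeric(0), cfg),
               "increasing")
})

test_that("relapse process is homogeneous Poisson with the stated rate", {
  expect_error(simulate_relapses(-0.1, 10), "non-negative")
  expect_identical(simulate_relapses(0, 10), numeric(0))
  set.seed(31)
  counts <- replicate(10000, length(simulate_relapses(0.36, 10)))
  expect_equal(mean(counts), 3.6, tolerance = 0.1)
  set.seed(32)
  r <- simulate_relapses(0.5, 7)
  expect_true(all(r >= 0 & r <= 7))
})

test_that("baseline features reproduce the stated phenotype contrasts", {
  expect_error(simulate_baseline_features("unknown"), "unknown phenotype")
  set.seed(41)
  early <- replicate(10000, simulate_baseline_features("early"),
                     simplify = FALSE)
  sc_any <- mean(sapply(early, function(b) b$sc_t2 != "0"))
  expect_lt(abs(sc_any - 0.84), 0.02)
  set.seed(42)
  rapid <- replicate(10000, simulate_baseline_features("rapid"),
                     simplify = FALSE)
  expect_lt(abs(mean(sapply(rapid, function(b) b$brain_t2 == ">=9")) - 0.35),
            0.02)
  expect_true(all(sapply(rapid, function(b) b$age_at_onset > 18)))
})

test_that("treatment effect multipliers behave as a dose on the slope", {
  cfg <- cohort_config(n_patients = 30, seed = 5)
  coh <- simulate_cohort(cfg)
  rec <- coh[[1]]
  # multiplier 1.0: treated trajectory identical to untreated counterfactual
  null_cfg <- cohort_config(n_patients = 30, seed = 5,
                            effect_moderate = 1, effect_high = 1)
  same <- simulate_treatment(rec, "moderate", null_cfg, start_years = 2)
  expect_identical(same$visits, rec$visits)
  expect_identical(same$cohort, "treated")
  expect_error(simulate_treatment(rec, "weird", cfg), "unknown strategy")

  # multiplier 0: latent curve flat after initiation (up to noise/rounding)
  rapid_spec <- lapply(specs, function(s) { s$mixing_weight <- 0; s })
  rapid_spec$rapid$mixing_weight <- 1
  zero_cfg <- cohort_config(n_patients = 40, seed = 6, measurement_sd = 0,
                            intercept_sd = 0, relapse_bump = 0,
                            effect_moderate = 0, effect_high = 0)
  coh0 <- simulate_cohort(zero_cfg, rapid_spec)
  for (p in coh0[1:10]) {
    tr <- simulate_treatment(p, "high", zero_cfg, start_years = 1)
    after <- tr$visits$edss[tr$visits$time_years >= 1]
    expect_lte(max(after) - min(after), 0.5)  # one grid step of wiggle
  }

  # multiplier 0.5 on rapid: 10-year mean strictly between baseline and
  # the untreated mean
  half_cfg <- cohort_config(n_patients = 200, seed = 8, effect_moderate = 0.5)
  coh_r <- simulate_cohort(half_cfg, rapid_spec)
  long <- Filter(function(p) p$followup_years >= 10, coh_r)
  at10 <- function(p) {
    v <- p$visits
    v$edss[which.min(abs(v$time_years - 10))]
  }
  untreated_mean <- mean(sapply(long, at10))
  treated <- lapply(long, simulate_treatment, strategy = "moderate",
                    config = half_cfg, start_years = 0.5)
  treated_mean <- mean(sapply(treated, at10))
  base_mean <- mean(sapply(long, function(p) p$visits$edss[1]))
  expect_gt(treated_mean, base_mean)
  expect_lt(treated_mean, untreated_mean)
})

test_that("cohort tables round-trip through CSV", {
  coh <- simulate_cohort(cohort_config(n_patients = 12, treated_fraction = 0.5,
                                       seed = 13))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  v <- read.csv(file.path(dir, "visits.csv"))
  expect_identical(nrow(v), nrow(cohort_visits(coh)))
  tr <- read.csv(file.path(dir, "truth.csv"))
  expect_setequal(tr$true_phenotype,
                  unique(vapply(coh, function(p) p$true_phenotype, character(1))))
})
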