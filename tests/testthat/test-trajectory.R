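# Small simulated worlds for the latent-class model tests.
two_class_world <- function(n = 200, seed = 1, sep = c(1, 6),
                            sb = 0.3, se = 0.3) {
  set.seed(seed)
  cls <- sample(1:2, n, TRUE)
  rows <- lapply(seq_len(n), function(i) {
    t <- seq(0, 10, by = 1)
    mu <- sep[cls[i]] + 0.1 * t
    data.frame(patient_id = sprintf("p%03d", i), time_years = t,
               edss = mu + rnorm(1, 0, sb) + rnorm(length(t), 0, se))
  })
  list(visits = do.call(rbind, rows), class = cls)
}

test_that("K=1 reduces to a single mixed model (lme4 oracle)", {
  w <- two_class_world(n = 60, seed = 11, sep = c(2, 2))
  fit <- fit_latent_classes(w$visits, K = 1, seed = 1)
  expect_equal(fit$pi, 1)
  expect_true(all(fit$posterior == 1))
  lmm <- lme4::lmer(edss ~ time_years + I(time_years^2) + (1 | patient_id),
                    data = w$visits, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lmm)), tolerance = 1e-5)
  expect_equal(unname(fit$B[1, ]), unname(lme4::fixef(lmm)), tolerance = 1e-4)
  expect_equal(fit$sigma_e, stats::sigma(lmm), tolerance = 1e-3)
})

test_that("EM log-likelihood is monotone and posteriors normalize", {
  for (seed in 1:5) {
    w <- two_class_world(n = 80, seed = seed)
    fit <- fit_latent_classes(w$visits, K = 2, n_starts = 2, seed = seed)
    expect_true(all(diff(fit$loglik_trace) > -1e-7 * abs(fit$loglik)))
    expect_equal(rowSums(fit$posterior), rep(1, fit$n_subjects),
                 tolerance = 1e-8)
    expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
    expect_gt(fit$sigma_b, 0)
    expect_gt(fit$sigma_e, 0)
  }
})

test_that("well-separated two-class world is recovered near the
           complete-data MLE", {
  w <- two_class_world(n = 200, seed = 42)
  fit <- fit_latent_classes(w$visits, K = 2, seed = 7)
  truth_w <- mean(w$class == 1)
  # weights within 0.05 of the truth (classes ordered by level)
  expect_equal(sort(fit$pi), sort(c(truth_w, 1 - truth_w)), tolerance = 0.05)
  # complete-data MLE oracle: per-class OLS with the true labels
  for (k in 1:2) {
    ids <- sprintf("p%03d", which(w$class == k))
    d <- w$visits[w$visits$patient_id %in% ids, ]
    ols <- coef(lm(edss ~ time_years + I(time_years^2), data = d))
    fitted_k <- which.min(abs(fit$B[, 1] - ols[1]))
    expect_equal(unname(fit$B[fitted_k, ]), unname(ols), tolerance = 0.15)
  }
  # modal assignment is essentially perfect at this separation
  modal <- max.col(fit$posterior)
  agree <- max(mean(modal == w$class), mean(modal == 3 - w$class))
  expect_gt(agree, 0.98)
})

test_that("information criteria match their formulas", {
  fake <- structure(list(K = 2, loglik = -100, n_params = 5,
                         posterior = matrix(c(1, 0, 0, 1), 2, 2),
                         n_subjects = 100), class = "ms_lcmm")
  ic <- information_criteria(fake)
  expect_equal(ic$AIC, 210)
  expect_equal(ic$BIC, 200 + 5 * log(100), tolerance = 1e-9)
  expect_equal(ic$SABIC, 200 + 5 * log(102 / 24), tolerance = 1e-9)
  # hard posteriors: zero entropy, ICL equals the log-likelihood
  expect_equal(ic$ICL, -100)
  expect_equal(ic$entropy, 0)
  expect_error(information_criteria(fake, n_subjects = 1), ">= 2")
  # monotone in p for fixed loglik
  fake2 <- fake; fake2$n_params <- 9
  expect_gt(information_criteria(fake2)$BIC, ic$BIC)
})

test_that("select_class_number picks K=1 for a one-class generator and
           breaks ties toward small K", {
  w <- two_class_world(n = 80, seed = 3, sep = c(2, 2))  # single curve
  sel <- select_class_number(w$visits, K_range = 1:3, n_starts = 2, seed = 5)
  expect_identical(sel$K_best, 1L)
  expect_identical(nrow(sel$summary), 3L)
})

test_that("cross_validate is seeded and supports leave-one-out", {
  w <- two_class_world(n = 24, seed = 9)
  cv1 <- cross_validate(w$visits, K = 2, folds = 4, seed = 33, n_starts = 1)
  cv2 <- cross_validate(w$visits, K = 2, folds = 4, seed = 33, n_starts = 1)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_equal(cv1$mean_loglik, cv2$mean_loglik)
  expect_error(cross_validate(w$visits, K = 2, folds = 1), ">= 2")
  loo <- cross_validate(w$visits[w$visits$patient_id %in%
                                   sprintf("p%03d", 1:6), ],
                        K = 1, folds = 6, seed = 1)
  expect_true(is.finite(loo$mean_loglik))
})

test_that("held-out likelihood prefers the generating class count", {
  wins <- sapply(1:6, function(s) {
    w <- two_class_world(n = 60, seed = s + 200)
    cv2 <- cross_validate(w$visits, K = 2, folds = 3, seed = s, n_starts = 2)
    cv1 <- cross_validate(w$visits, K = 1, folds = 3, seed = s, n_starts = 1)
    cv2$mean_loglik > cv1$mean_loglik
  })
  expect_gte(mean(wins), 5 / 6)
})

test_that("posterior_classify handles new patients and degenerate K", {
  w <- two_class_world(n = 100, seed = 15)
  fit <- fit_latent_classes(w$visits, K = 2, seed = 2)
  # a patient lying exactly on a class mean gets near-certain posterior
  k <- which.max(fit$B[, 1])
  t <- seq(0, 10, 0.5)
  exact <- data.frame(patient_id = "new", time_years = t,
                      edss = fit$B[k, 1] + fit$B[k, 2] * t + fit$B[k, 3] * t^2)
  pc <- posterior_classify(fit, exact)
  expect_identical(pc$label, k)
  expect_gt(pc[[paste0("p_", k)]], 0.99)
  probs <- as.matrix(pc[grepl("^p_", names(pc))])
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-8)
  one <- fit_latent_classes(w$visits, K = 1, seed = 2)
  expect_equal(posterior_classify(one, exact)$p_1, 1)
  expect_error(posterior_classify(fit, exact[0, ]), "no visits")
})

test_that("mean_trajectory evaluates the class polynomial with a sane band", {
  w <- two_class_world(n = 60, seed = 19)
  fit <- fit_latent_classes(w$visits, K = 2, seed = 3)
  fit$B[1, ] <- c(2, 0, 0)
  tr <- mean_trajectory(fit, 1, c(0, 5, 10))
  expect_equal(tr$mean_edss, rep(2, 3))
  expect_true(all(tr$lower <= tr$mean_edss & tr$mean_edss <= tr$upper))
  expect_equal(attr(tr, "predictive_sd"),
               sqrt(fit$sigma_b^2 + fit$sigma_e^2))
  expect_warning(mean_trajectory(fit, 2, 40), "extrapolat")
})

test_that("OLS limit: zero intercept variance reduces GLS to OLS", {
  w <- two_class_world(n = 50, seed = 23, sep = c(3, 3), sb = 0)
  ss <- mstraj:::build_suffstats(w$visits)
  bols <- mstraj:::ols_beta(ss$S, rep(1, ss$n_subjects))
  ref <- coef(lm(edss ~ time_years + I(time_years^2), data = w$visits))
  expect_equal(unname(bols), unname(ref), tolerance = 1e-6)
  # information with sigma_b = 0 equals X'X / sigma_e^2
  A <- mstraj:::gls_information(ss$S, rep(1, ss$n_subjects), 0, 0.25)
  X <- cbind(1, w$visits$time_years, w$visits$time_years^2)
  expect_equal(A, crossprod(X) / 0.25, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("class matching to generator curves is permutation-exact", {
  specs <- phenotype_specs()
  B <- t(sapply(specs[c(3, 1, 4, 2)], function(s) c(s$beta0, s$beta1, s$beta2)))
  fake <- structure(list(K = 4, B = B), class = "ms_lcmm")
  expect_identical(match_classes_to_phenotypes(fake),
                   c("early", "minimal", "rapid", "late"))
})

test_that("model JSON serialization round-trips the key parameters", {
  w <- two_class_world(n = 40, seed = 27)
  fit <- fit_latent_classes(w$visits, K = 2, seed = 4)
  path <- file.path(withr::local_tempdir(), "model.json")
  write_model_json(fit, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(got$K, 2)
  expect_equal(got$pi, fit$pi, tolerance = 1e-12)
  expect_equal(got$sigma_e, fit$sigma_e, tolerance = 1e-12)
})
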