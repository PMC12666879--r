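# Latent-class mixed models of EDSS versus time.
#
# Model: for patient i in class k, y_i = X_i B_k + b_i 1 + e_i with
# b_i ~ N(0, sigma_b^2) (shared across classes) and e_i ~ N(0, sigma_e^2 I);
# X_i = [1, t, t^2]. Marginally y_i | class k is multivariate normal with
# compound-symmetry covariance sigma_e^2 I + sigma_b^2 J, which admits
# closed-form determinant and inverse, so the whole EM runs on per-patient
# sufficient statistics (no per-visit matrices are ever formed).

# Per-patient sufficient statistics from a long table.
# Columns: n, st, st2, st3, st4, sy, sty, st2y, syy.
build_suffstats <- function(visits) {
  stopifnot(all(c("patient_id", "time_years", "edss") %in% names(visits)))
  g <- factor(visits$patient_id, levels = unique(visits$patient_id))
  t <- visits$time_years
  y <- visits$edss
  t2 <- t * t
  S <- rowsum(cbind(n = 1, st = t, st2 = t2, st3 = t * t2, st4 = t2 * t2,
                    sy = y, sty = t * y, st2y = t2 * y, syy = y * y),
              g, reorder = FALSE)
  list(S = S, ids = levels(g), n_subjects = nrow(S),
       n_obs = nrow(visits), max_time = max(t))
}

# r'r and 1'r for residuals r = y - X B, per patient, from suff stats.
resid_stats <- function(S, B) {
  B1 <- B[1]; B2 <- B[2]; B3 <- B[3]
  rTr <- S[, "syy"] - 2 * (B1 * S[, "sy"] + B2 * S[, "sty"] + B3 * S[, "st2y"]) +
    B1 * B1 * S[, "n"] + B2 * B2 * S[, "st2"] + B3 * B3 * S[, "st4"] +
    2 * B1 * B2 * S[, "st"] + 2 * B1 * B3 * S[, "st2"] + 2 * B2 * B3 * S[, "st3"]
  oneTr <- S[, "sy"] - (B1 * S[, "n"] + B2 * S[, "st"] + B3 * S[, "st2"])
  list(rTr = pmax(rTr, 0), oneTr = oneTr)
}

# Per-patient Gaussian log-density under class coefficients B.
class_logdens <- function(S, B, sb2, se2) {
  n <- S[, "n"]
  rs <- resid_stats(S, B)
  ci <- sb2 / (se2 + n * sb2)
  -0.5 * (n * log(2 * pi * se2) + log1p(n * sb2 / se2) +
            (rs$rTr - ci * rs$oneTr^2) / se2)
}

# E-step: log-likelihood and posterior matrix given parameters.
estep <- function(S, pi_k, B, sb2, se2) {
  K <- length(pi_k)
  L <- vapply(seq_len(K), function(k) {
    log(pi_k[k]) + class_logdens(S, B[k, ], sb2, se2)
  }, numeric(nrow(S)))
  L <- matrix(L, nrow = nrow(S))
  m <- apply(L, 1, max)
  W <- exp(L - m)
  rs <- rowSums(W)
  list(loglik = sum(m + log(rs)), W = W / rs)
}

# Posterior-weighted GLS information matrix for one class, used for the
# coefficient covariance reported by mean_trajectory().
gls_information <- function(S, w, sb2, se2) {
  n <- S[, "n"]
  ci <- sb2 / (se2 + n * sb2)
  A <- matrix(c(
    sum(w * (n - ci * n * n)),
    sum(w * (S[, "st"] - ci * n * S[, "st"])),
    sum(w * (S[, "st2"] - ci * n * S[, "st2"])),
    0,
    sum(w * (S[, "st2"] - ci * S[, "st"]^2)),
    sum(w * (S[, "st3"] - ci * S[, "st"] * S[, "st2"])),
    0, 0,
    sum(w * (S[, "st4"] - ci * S[, "st2"]^2))), 3, 3)
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  A / se2
}

# Weighted OLS of y - X B on X per class (c = 0 in the A matrix above),
# used to initialize coefficients from a hard assignment.
ols_beta <- function(S, w) {
  A <- matrix(c(sum(w * S[, "n"]), sum(w * S[, "st"]), sum(w * S[, "st2"]),
                0, sum(w * S[, "st2"]), sum(w * S[, "st3"]),
                0, 0, sum(w * S[, "st4"])), 3, 3)
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  b <- c(sum(w * S[, "sy"]), sum(w * S[, "sty"]), sum(w * S[, "st2y"]))
  solve(A, b)
}

# EM for the mixture of random-intercept models. Both the class labels
# and the random intercepts b_i are treated as missing data, and every
# expectation in the M-step is taken at the current parameters, so each
# iteration is a textbook EM step and the observed log-likelihood is
# non-decreasing.
run_em <- function(S, K, init, tol, max_iter) {
  n <- nrow(S)
  ntot <- S[, "n"]
  if (!is.null(init$assign)) {
    # initial parameters from a hard assignment
    W0 <- matrix(0, n, K)
    W0[cbind(seq_len(n), init$assign)] <- 1
    pi_k <- pmax(colMeans(W0), 1e-3)
    pi_k <- pi_k / sum(pi_k)
    B <- t(vapply(seq_len(K), function(k) ols_beta(S, W0[, k]), numeric(3)))
    sb2 <- 0.25
    se2 <- max(mean(S[, "syy"] / ntot - (S[, "sy"] / ntot)^2), 0.05)
  } else {
    # continuation from a parameter state
    pi_k <- init$pi; B <- init$B; sb2 <- init$sb2; se2 <- init$se2
    W0 <- matrix(1 / K, n, K)
  }
  trace <- numeric(0)
  converged <- FALSE
  degenerate <- FALSE
  ll_old <- -Inf
  W <- W0
  for (iter in seq_len(max_iter)) {
    # E-step at the current parameters
    es <- estep(S, pi_k, B, sb2, se2)
    W <- es$W
    trace <- c(trace, es$loglik)
    if (is.finite(ll_old) &&
        abs(es$loglik - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- es$loglik
    # conditional moments of b_i given class k, at current parameters
    ci <- sb2 / (se2 + ntot * sb2)
    v_i <- ci * se2
    M <- vapply(seq_len(K), function(k) {
      ci * resid_stats(S, B[k, ])$oneTr
    }, numeric(n))
    M <- matrix(M, nrow = n)
    # M-step: pi, then B_k by weighted OLS of (y - E[b]) on X, then
    # variances profiled at the new B
    pi_k <- colMeans(W)
    if (any(pi_k * n < 0.5) && iter > 3) { degenerate <- TRUE; break }
    B_new <- B
    for (k in seq_len(K)) {
      w <- W[, k]
      A <- matrix(c(sum(w * ntot), sum(w * S[, "st"]), sum(w * S[, "st2"]),
                    0, sum(w * S[, "st2"]), sum(w * S[, "st3"]),
                    0, 0, sum(w * S[, "st4"])), 3, 3)
      A[upper.tri(A)] <- t(A)[upper.tri(A)]
      b <- c(sum(w * (S[, "sy"] - M[, k] * ntot)),
             sum(w * (S[, "sty"] - M[, k] * S[, "st"])),
             sum(w * (S[, "st2y"] - M[, k] * S[, "st2"])))
      bk <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(bk)) { degenerate <- TRUE; break }
      B_new[k, ] <- bk
    }
    if (degenerate) break
    B <- B_new
    sb2 <- max(sum(W * (M^2 + v_i)) / n, 1e-8)
    num_e <- 0
    for (k in seq_len(K)) {
      rs <- resid_stats(S, B[k, ])
      num_e <- num_e + sum(W[, k] * (rs$rTr - 2 * M[, k] * rs$oneTr +
                                       ntot * (M[, k]^2 + v_i)))
    }
    se2 <- max(num_e / sum(ntot), 1e-8)
  }
  Ainfo <- lapply(seq_len(K), function(k) {
    gls_information(S, W[, k], sb2, se2)
  })
  list(pi = pi_k, B = B, sb2 = sb2, se2 = se2,
       loglik = if (length(trace)) trace[length(trace)] else -Inf,
       trace = trace, W = W, converged = converged, degenerate = degenerate,
       Ainfo = Ainfo)
}

# Per-patient initialization features: the ridge-regularized quadratic
# fit evaluated at fixed times, clamped to the EDSS range. Keeping all
# features in EDSS units (no standardization) stops pure-noise dimensions
# from diluting the k-means geometry.
init_features <- function(S, times = c(0, 5, 10)) {
  n <- nrow(S)
  Z <- matrix(0, n, length(times))
  X <- cbind(1, times, times^2)
  for (i in seq_len(n)) {
    A <- matrix(c(S[i, "n"], S[i, "st"], S[i, "st2"],
                  S[i, "st"], S[i, "st2"], S[i, "st3"],
                  S[i, "st2"], S[i, "st3"], S[i, "st4"]), 3, 3)
    b <- c(S[i, "sy"], S[i, "sty"], S[i, "st2y"])
    beta <- solve(A + diag(c(1e-3, 1e-2, 1e-1)), b)
    Z[i, ] <- drop(X %*% beta)
  }
  Z[!is.finite(Z)] <- 0
  pmin(pmax(Z, 0), 10)
}

# k-means on the per-patient quadratic features; jittered restarts.
init_assignments <- function(Z, K, start, n) {
  if (K == 1) return(rep(1L, n))
  a <- tryCatch(kmeans(Z, centers = K, nstart = 10,
                       iter.max = 30)$cluster,
                error = function(e) sample.int(K, n, replace = TRUE))
  if (start > 1) {
    # jitter: reassign a random 30% of patients
    idx <- sample.int(n, max(1, floor(0.3 * n)))
    a[idx] <- sample.int(K, length(idx), replace = TRUE)
  }
  # ensure all classes occupied
  for (k in seq_len(K)) if (!any(a == k)) a[sample.int(n, 1)] <- k
  as.integer(a)
}

#' Fit a latent-class mixed model of EDSS trajectories
#'
#' Fits a finite mixture of mixed-effects quadratic regressions of EDSS on
#' years since onset by EM on the per-patient marginal likelihood. Each
#' class has its own fixed coefficients (intercept, time, time^2); a
#' patient-level random intercept and the residual variance are shared
#' across classes. The E-step computes posterior class weights from the
#' class-specific multivariate-normal likelihood of each patient's EDSS
#' vector (compound-symmetry covariance); the M-step performs
#' posterior-weighted generalized-least-squares updates of the
#' coefficients and closed-form variance updates. The best of `n_starts`
#' jittered k-means initializations is kept; classes are reported in
#' canonical order of increasing mean EDSS at year 15.
#'
#' @param visits Long data.frame (`patient_id`, `time_years`, `edss`).
#' @param K Number of latent classes (>= 1).
#' @param n_starts Random initializations (default 5).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param seed Seed controlling all starts.
#' @return An `ms_lcmm` object: `K`, `pi`, `B` (K x 3), `sigma_b`,
#'   `sigma_e`, `loglik`, `n_params`, `converged`, `posterior` (n x K),
#'   `ids`, `loglik_trace`, per-class coefficient covariances `covB`,
#'   `n_subjects`, `n_obs`, `max_time`, and onset-timing `class_labels`.
#' @export
fit_latent_classes <- function(visits, K, n_starts = 5, tol = 1e-6,
                               max_iter = 500, seed = 1L) {
  stopifnot(K >= 1)
  ss <- build_suffstats(visits)
  if (any(ss$S[, "n"] < 1)) stop("input error: every patient needs >= 1 visit")
  best <- NULL
  with_seed(seed, {
    # short-run EM from each jittered start, then run the best start to
    # convergence (the usual emEM strategy against local optima)
    Z <- init_features(ss$S)
    for (s in seq_len(max(n_starts, 1))) {
      a <- init_assignments(Z, K, s, ss$n_subjects)
      fit <- run_em(ss$S, K, list(assign = a), tol,
                    min(if (K == 1) max_iter else 40L, max_iter))
      if (fit$degenerate) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
      if (K == 1) break
    }
    if (!is.null(best) && !best$converged) {
      cont <- run_em(ss$S, K, best[c("pi", "B", "sb2", "se2")], tol, max_iter)
      if (!cont$degenerate && cont$loglik >= best$loglik) {
        cont$trace <- c(best$trace, cont$trace)
        best <- cont
      }
    }
  })
  if (is.null(best)) {
    stop("all EM starts collapsed to an empty class; try smaller K")
  }
  if (!best$converged) {
    warning("EM did not converge within max_iter; returning best iterate")
  }
  # canonical order: increasing mean EDSS at year 15
  mu15 <- best$B[, 1] + 15 * best$B[, 2] + 225 * best$B[, 3]
  ord <- order(mu15)
  covB <- lapply(best$Ainfo[ord], solve)
  model <- structure(list(
    K = K,
    pi = best$pi[ord],
    B = best$B[ord, , drop = FALSE],
    sigma_b = sqrt(best$sb2),
    sigma_e = sqrt(best$se2),
    loglik = best$loglik,
    n_params = 3 * K + 2 + (K - 1),
    converged = best$converged,
    posterior = best$W[, ord, drop = FALSE],
    ids = ss$ids,
    loglik_trace = best$trace,
    covB = covB,
    n_subjects = ss$n_subjects,
    n_obs = ss$n_obs,
    max_time = ss$max_time
  ), class = "ms_lcmm")
  model$class_labels <- label_classes(model)
  model
}

#' @export
print.ms_lcmm <- function(x, ...) {
  cat(sprintf("ms_lcmm: %d classes, %d patients, logLik %.2f%s\n",
              x$K, x$n_subjects, x$loglik,
              if (x$converged) "" else " (not converged)"))
  cat("  weights:", paste(sprintf("%.3f", x$pi), collapse = ", "), "\n")
  cat("  labels :", paste(x$class_labels, collapse = ", "), "\n")
  invisible(x)
}

# Onset-timing heuristic: first time the class mean exceeds its starting
# level by 1.0 EDSS point maps to a phenotype name.
label_classes <- function(model, grid = seq(0, 25, by = 0.1)) {
  vapply(seq_len(model$K), function(k) {
    m <- model$B[k, 1] + model$B[k, 2] * grid + model$B[k, 3] * grid^2
    hit <- grid[m >= m[1] + 1.0]
    t0 <- if (length(hit)) hit[1] else Inf
    if (t0 <= 3) "rapid" else if (t0 <= 8) "early" else if (t0 <= 16) "late"
    else "minimal"
  }, character(1))
}

#' Information criteria for a fitted latent-class model
#'
#' AIC = -2l + 2p; BIC = -2l + p log(n); sample-adjusted BIC uses
#' log((n + 2) / 24); ICL is reported on the log scale
#' (loglik minus posterior classification entropy, higher is better) and
#' additionally on the BIC scale (`icl_bic = BIC + 2 * entropy`, lower is
#' better), since both conventions circulate.
#'
#' @param model An `ms_lcmm`.
#' @param n_subjects Number of subjects (defaults to the fit's).
#' @return One-row data.frame: `K`, `loglik`, `n_params`, `AIC`, `BIC`,
#'   `SABIC`, `ICL`, `icl_bic`, `entropy`.
#' @export
information_criteria <- function(model, n_subjects = model$n_subjects) {
  if (n_subjects < 2) stop("input error: n_subjects must be >= 2")
  ll <- model$loglik
  p <- model$n_params
  W <- model$posterior
  ent <- -sum(ifelse(W > 0, W * log(W), 0))
  bic <- -2 * ll + p * log(n_subjects)
  data.frame(K = model$K, loglik = ll, n_params = p,
             AIC = -2 * ll + 2 * p,
             BIC = bic,
             SABIC = -2 * ll + p * log((n_subjects + 2) / 24),
             ICL = ll - ent,
             icl_bic = bic + 2 * ent,
             entropy = ent)
}

#' Select the number of latent classes
#'
#' Fits models over `K_range` and selects the best by the chosen
#' criterion (minimum for AIC/BIC/SABIC, maximum for log-scale ICL), with
#' ties broken toward smaller K (parsimony).
#'
#' @param visits Long visits data.frame.
#' @param K_range Candidate class counts (default 1:10).
#' @param criterion One of "BIC", "AIC", "SABIC", "ICL".
#' @param ... Passed to [fit_latent_classes()].
#' @return List: `K_best`, `summary` (one row per K), `models` (list).
#' @export
select_class_number <- function(visits, K_range = 1:10,
                                criterion = c("BIC", "AIC", "SABIC", "ICL"),
                                ...) {
  criterion <- match.arg(criterion)
  models <- list()
  rows <- list()
  status <- character(0)
  for (K in K_range) {
    fit <- tryCatch(fit_latent_classes(visits, K, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      status <- c(status, sprintf("K=%d: %s", K, conditionMessage(fit)))
      next
    }
    models[[as.character(K)]] <- fit
    rows[[as.character(K)]] <- information_criteria(fit)
  }
  if (!length(rows)) {
    stop("no class count could be fitted:\n", paste(status, collapse = "\n"))
  }
  summary <- do.call(rbind, rows)
  crit <- summary[[criterion]]
  if (criterion == "ICL") crit <- -crit
  K_best <- summary$K[which.min(crit)]  # which.min takes the first = smallest K
  list(K_best = K_best, summary = summary, models = models,
       criterion = criterion, failed = status)
}

#' Cross-validated held-out log-likelihood
#'
#' Patient-level k-fold split: the model is fitted on the training folds
#' and the marginal mixture log-likelihood is evaluated on held-out
#' patients.
#'
#' @param visits Long visits data.frame.
#' @param K Class count.
#' @param folds Number of folds (>= 2; `folds = n` gives leave-one-out).
#' @param seed Seed for the fold assignment and the fits.
#' @param ... Passed to [fit_latent_classes()].
#' @return List: `mean_loglik` (mean per-patient held-out log-likelihood),
#'   `fold_logliks`, `fold_assignment`.
#' @export
cross_validate <- function(visits, K, folds = 10, seed = 1L, ...) {
  if (folds < 2) stop("input error: folds must be >= 2")
  ids <- unique(visits$patient_id)
  if (length(ids) < folds) stop("input error: need n_subjects >= folds")
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), length(ids))))
  names(fold) <- ids
  per_patient <- numeric(0)
  fold_ll <- numeric(folds)
  for (f in seq_len(folds)) {
    train <- visits[fold[visits$patient_id] != f, , drop = FALSE]
    test <- visits[fold[visits$patient_id] == f, , drop = FALSE]
    fit <- fit_latent_classes(train, K, seed = substream_seed(seed, f), ...)
    ss <- build_suffstats(test)
    es <- estep(ss$S, fit$pi, fit$B, fit$sigma_b^2, fit$sigma_e^2)
    fold_ll[f] <- es$loglik
    per_patient <- c(per_patient, es$loglik / ss$n_subjects)
  }
  list(mean_loglik = mean(per_patient), fold_logliks = fold_ll,
       fold_assignment = fold)
}

#' Posterior class probabilities for (new) patients
#'
#' @param model An `ms_lcmm`.
#' @param visits Long data.frame of one or more patients (each needs >= 1
#'   visit).
#' @return data.frame: `patient_id`, `label` (modal class index),
#'   `class_label` (onset-timing name), and posterior probability columns
#'   `p_1..p_K`.
#' @export
posterior_classify <- function(model, visits) {
  if (!nrow(visits)) stop("input error: no visits supplied")
  ss <- build_suffstats(visits)
  es <- estep(ss$S, model$pi, model$B, model$sigma_b^2, model$sigma_e^2)
  modal <- max.col(es$W)
  out <- data.frame(patient_id = ss$ids, label = modal,
                    class_label = model$class_labels[modal],
                    stringsAsFactors = FALSE)
  P <- as.data.frame(es$W)
  names(P) <- paste0("p_", seq_len(model$K))
  cbind(out, P)
}

#' Fitted class mean trajectory with confidence band
#'
#' Evaluates class k's quadratic mean at the requested times with a 95
#' percent delta-method band from the coefficient covariance, and carries
#' the patient-level predictive SD `sqrt(sigma_b^2 + sigma_e^2)` used for
#' disability z-scoring.
#'
#' @param model An `ms_lcmm`.
#' @param k Class index (1..K).
#' @param times Numeric times (years since onset).
#' @return data.frame (`time`, `mean_edss`, `lower`, `upper`) with
#'   attributes `predictive_sd` and `extrapolated`.
#' @export
mean_trajectory <- function(model, k, times) {
  stopifnot(k >= 1, k <= model$K)
  extrap <- times > model$max_time + 5 | times < 0
  if (any(extrap)) {
    warning("some times lie outside the fitted range + 5y; extrapolating")
  }
  X <- cbind(1, times, times^2)
  mu <- drop(X %*% model$B[k, ])
  se <- sqrt(pmax(rowSums((X %*% model$covB[[k]]) * X), 0))
  out <- data.frame(time = times, mean_edss = mu,
                    lower = mu - 1.96 * se, upper = mu + 1.96 * se)
  attr(out, "predictive_sd") <- sqrt(model$sigma_b^2 + model$sigma_e^2)
  attr(out, "extrapolated") <- extrap
  out
}

# All permutations of 1..n (n small).
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

#' Match fitted classes to generator phenotypes by trajectory shape
#'
#' Finds the assignment of fitted classes to phenotype specifications
#' minimizing the total L2 distance between fitted class means and
#' generator mean curves over a year grid (exhaustive over permutations
#' when K equals the number of phenotypes, greedy otherwise).
#'
#' @param model An `ms_lcmm`.
#' @param phenotypes Named list of phenotype specs.
#' @param grid Time grid for the L2 distance (default 0 to 15 years).
#' @return Character vector of length K: phenotype name per class.
#' @export
match_classes_to_phenotypes <- function(model, phenotypes = phenotype_specs(),
                                        grid = seq(0, 15, by = 0.5)) {
  X <- cbind(1, grid, grid^2)
  fitted <- X %*% t(model$B)               # |grid| x K
  truth <- vapply(phenotypes, phenotype_mean, numeric(length(grid)), t = grid)
  D <- matrix(0, model$K, length(phenotypes))
  for (k in seq_len(model$K)) {
    D[k, ] <- colSums((truth - fitted[, k])^2)
  }
  if (model$K == length(phenotypes)) {
    perms <- permutations(model$K)
    costs <- apply(perms, 1, function(p) sum(D[cbind(seq_len(model$K), p)]))
    p <- perms[which.min(costs), ]
    names(phenotypes)[p]
  } else {
    names(phenotypes)[apply(D, 1, which.min)]
  }
}

#' Serialize a fitted model to JSON
#'
#' @param model An `ms_lcmm`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  obj <- list(K = model$K, pi = model$pi, B = model$B,
              sigma_b = model$sigma_b, sigma_e = model$sigma_e,
              loglik = model$loglik, n_params = model$n_params,
              converged = model$converged,
              class_labels = model$class_labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
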