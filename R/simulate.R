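#' Scenario configuration for the synthetic two-phase study
#'
#' Describes one simulation scenario: a population with a rare binary
#' exposure (`P(x_e = 1) = 0.1`), five main features drawn independently
#' from one of four distribution families, and a rare outcome generated by
#' a logistic model whose intercept is calibrated so that
#' `P(Y = 1)` equals the target prevalence.  The exposure effect is fixed
#' at `log(0.5)` (exposure halves the odds); the main-feature slopes are
#' redrawn uniformly from `[-0.15, 0.15]` for every replicate, as are the
#' family parameters from their stated ranges: `mu in [1, 10]`,
#' `sigma in [1, 5]` (normal), `nu in {10, ..., 100}` (Student t),
#' `lambda in {1, ..., 5}` (Poisson), `pi in [0.4, 0.6]` (Bernoulli).
#'
#' @param family Feature distribution family: `"normal"`, `"student_t"`,
#'   `"poisson"` or `"bernoulli"`.
#' @param p Number of main features (default 5).
#' @param n_learn Size of the stratified learning sample.  Not dictated by
#'   the population model; the default 2000 mirrors a typical two-phase
#'   study with four strata of 500.
#' @param replicates Number of study replicates (default 1000).
#' @param N_pop Population size (default 1e5).
#' @param N_test Test-set size (default 1e4); test sets are generated the
#'   same way as the population, with the same replicate-specific
#'   parameters.
#' @param exposure_prob `P(x_e = 1)` (default 0.1).
#' @param prevalence Target `P(Y = 1)` (default 0.1).
#' @param beta_e Exposure log-odds effect (default `log(0.5)`).
#' @param beta_range Range of the uniform law for main-feature slopes.
#' @param feature_corr Optional feature correlation matrix (`p x p`); when
#'   given, features are coupled through a Gaussian copula.
#' @param families Optional per-feature family vector for mixed scenarios.
#' @param seed Master seed for [run_study()].
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(family = c("normal", "student_t", "poisson",
                                       "bernoulli"),
                            p = 5L, n_learn = 2000L, replicates = 1000L,
                            N_pop = 1e5, N_test = 1e4,
                            exposure_prob = 0.1, prevalence = 0.1,
                            beta_e = log(0.5), beta_range = c(-0.15, 0.15),
                            mu_range = c(1, 10), sigma_range = c(1, 5),
                            nu_set = 10:100, lambda_set = 1:5,
                            pi_range = c(0.4, 0.6),
                            feature_corr = NULL, families = NULL,
                            seed = NULL) {
  family <- match.arg(family)
  stopifnot(p >= 0, n_learn >= 4, replicates >= 1, N_pop >= 4, N_test >= 2,
            exposure_prob > 0, exposure_prob < 1,
            prevalence > 0, prevalence < 1)
  if (!is.null(families) && length(families) != p) {
    stop_ipcorr("`families` must have one entry per feature")
  }
  if (!is.null(feature_corr) &&
      (!isSymmetric(feature_corr) || nrow(feature_corr) != p)) {
    stop_ipcorr("`feature_corr` must be a symmetric p x p matrix")
  }
  structure(list(family = family, p = as.integer(p),
                 n_learn = as.integer(n_learn),
                 replicates = as.integer(replicates),
                 N_pop = N_pop, N_test = N_test,
                 exposure_prob = exposure_prob, prevalence = prevalence,
                 beta_e = beta_e, beta_range = beta_range,
                 mu_range = mu_range, sigma_range = sigma_range,
                 nu_set = nu_set, lambda_set = lambda_set,
                 pi_range = pi_range, feature_corr = feature_corr,
                 families = families, seed = seed),
            class = "scenario_config")
}

#' Draw replicate-specific scenario parameters
#'
#' Slopes and family parameters are redrawn once per replicate from the
#' ranges recorded in the configuration.
#'
#' @param config A [scenario_config()].
#' @param seed Optional seed.
#' @return A list with elements `betas` (main-feature slopes), `beta_e` and
#'   per-feature family parameters.
#' @export
draw_scenario_params <- function(config, seed = NULL) {
  with_seed_(seed, {
    p <- config$p
    fams <- config$families
    if (is.null(fams)) fams <- rep(config$family, p)
    par <- lapply(fams, function(f) {
      switch(f,
        normal = list(mu = stats::runif(1, config$mu_range[1], config$mu_range[2]),
                      sigma = stats::runif(1, config$sigma_range[1],
                                           config$sigma_range[2])),
        student_t = list(nu = sample(config$nu_set, 1L)),
        poisson = list(lambda = sample(config$lambda_set, 1L)),
        bernoulli = list(pi = stats::runif(1, config$pi_range[1],
                                           config$pi_range[2])),
        stop_ipcorr("unknown feature family '%s'", f))
    })
    list(families = fams, params = par,
         betas = stats::runif(p, config$beta_range[1], config$beta_range[2]),
         beta_e = config$beta_e)
  })
}

q_family <- function(u, fam, par) {
  switch(fam,
    normal = stats::qnorm(u, par$mu, par$sigma),
    student_t = stats::qt(u, par$nu),
    poisson = stats::qpois(u, par$lambda),
    bernoulli = stats::qbinom(u, 1L, par$pi))
}

r_family <- function(n, fam, par) {
  switch(fam,
    normal = stats::rnorm(n, par$mu, par$sigma),
    student_t = stats::rt(n, par$nu),
    poisson = stats::rpois(n, par$lambda),
    bernoulli = stats::rbinom(n, 1L, par$pi))
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' Finds `b0` such that the mean of `plogis(b0 + eta)` over the supplied
#' linear predictors equals the target prevalence, by bisection on
#' `[-50, 50]` to a tolerance of 1e-10 on the mean.  The map is strictly
#' increasing in `b0`, so the bracket cannot fail for finite predictors
#' and an attainable target.
#'
#' @param eta Numeric vector of linear predictors excluding the intercept.
#' @param target Target mean outcome probability, in (0, 1).
#' @return The calibrated intercept `b0`.
#' @export
calibrate_intercept <- function(eta, target, lower = -50, upper = 50,
                                tol = 1e-10) {
  if (target <= 0 || target >= 1) stop_ipcorr("`target` must be in (0, 1)")
  if (any(!is.finite(eta))) stop_ipcorr("`eta` must be finite")
  f <- function(b) mean(stats::plogis(b + eta)) - target
  lo <- lower; hi <- upper
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) {
    stop_ipcorr("bisection bracket [%g, %g] does not contain the solution",
                lower, upper)
  }
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic population
#'
#' Draws `n` individuals: exposure `x_e ~ Bernoulli(exposure_prob)`, main
#' features independently from the configured family (coupled through a
#' Gaussian copula when `feature_corr` is set), and the outcome from the
#' logistic model `P(Y = 1 | x) = plogis(beta_0 + x_e beta_e + x' beta)`
#' with the intercept calibrated on the generated covariates via
#' [calibrate_intercept()].
#'
#' @param config A [scenario_config()].
#' @param n Number of rows (defaults to `config$N_pop`; pass
#'   `config$N_test` for a test set).
#' @param params Replicate parameters from [draw_scenario_params()];
#'   drawn fresh when `NULL`.  Reusing the same `params` for population and
#'   test set reproduces the study design.
#' @param seed Optional seed.
#' @return A tibble with columns `y`, `x_e`, `x1..xp`; the replicate
#'   parameters (including the calibrated `beta_0`) are stored in
#'   `attr(, "params")`.
#' @export
generate_population <- function(config, n = config$N_pop, params = NULL,
                                seed = NULL) {
  if (!inherits(config, "scenario_config")) {
    stop_ipcorr("`config` must be a scenario_config()")
  }
  with_seed_(seed, {
    if (is.null(params)) params <- draw_scenario_params(config)
    p <- config$p
    xe <- stats::rbinom(n, 1L, config$exposure_prob)
    if (p > 0) {
      if (is.null(config$feature_corr)) {
        X <- vapply(seq_len(p), function(j) {
          r_family(n, params$families[j], params$params[[j]])
        }, numeric(n))
      } else {
        R <- chol(config$feature_corr)
        Z <- matrix(stats::rnorm(n * p), n, p) %*% R
        X <- vapply(seq_len(p), function(j) {
          q_family(stats::pnorm(Z[, j]), params$families[j],
                   params$params[[j]])
        }, numeric(n))
      }
      eta <- xe * params$beta_e + drop(X %*% params$betas)
    } else {
      X <- NULL
      eta <- xe * params$beta_e
    }
    beta_0 <- calibrate_intercept(eta, config$prevalence)
    y <- stats::rbinom(n, 1L, stats::plogis(beta_0 + eta))
    out <- tibble::tibble(y = as.numeric(y), x_e = xe)
    if (p > 0) {
      Xd <- tibble::as_tibble(as.data.frame(X))
      names(Xd) <- paste0("x", seq_len(p))
      out <- dplyr::bind_cols(out, Xd)
    }
    params$beta_0 <- beta_0
    attr(out, "params") <- params
    out
  })
}

#' Draw a two-phase stratified sample from a population
#'
#' Emulates the two-phase selection of a case-control study: the population
#' is partitioned into the cells of (stratum feature, outcome) and an equal
#' number `n / H` of members is drawn without replacement from each cell,
#' so that the sampled case fraction and exposed fraction are both exactly
#' 1/2 in the four-cell design.  Population cell counts provide the
#' selection probabilities and IP weights.
#'
#' @param population A data frame with outcome and stratum columns (e.g.
#'   from [generate_population()]).
#' @param n Sample size; must be divisible by the number of cells.
#' @param seed Optional seed.
#' @param outcome,stratum,features Column roles, as in [assign_strata()].
#' @return A list with elements `sample` (a `stratified_tbl`) and `table`
#'   (the stratum table, population counts filled in).
#' @export
two_phase_sample <- function(population, n, seed = NULL,
                             outcome = "y", stratum = "x_e",
                             features = NULL) {
  pop <- assign_strata(population, outcome = outcome, stratum = stratum,
                       features = features)
  ids <- sort(unique(pop$.stratum))
  H <- length(ids)
  if (n %% H != 0L) {
    stop_ipcorr("`n` = %d is not divisible by the number of strata (%d)", n, H)
  }
  n_cell <- n %/% H
  N_h <- tabulate(pop$.stratum, nbins = H)
  short <- which(N_h < n_cell)
  if (length(short) > 0L) {
    r <- roles(pop)
    info <- dplyr::distinct(tibble::tibble(
      id = pop$.stratum, stratum = as.character(pop[[r$stratum]]),
      outcome = pop[[r$outcome]]))
    lab <- info[match(short[1L], info$id), ]
    stop_ipcorr(
      "population cell (%s = %s, %s = %s) holds only %d members; %d needed",
      r$stratum, lab$stratum, r$outcome, lab$outcome, N_h[short[1L]], n_cell)
  }
  idx <- with_seed_(seed, {
    unlist(lapply(ids, function(h) {
      rows_h <- which(pop$.stratum == h)
      rows_h[sample.int(length(rows_h), n_cell, replace = FALSE)]
    }))
  })
  samp <- rebuild(tibble::as_tibble(pop)[idx, , drop = FALSE], pop, NULL)
  tab <- stratum_table(samp, N_h = N_h)
  list(sample = samp, table = tab)
}

#' Area under the ROC curve (rank formulation)
#'
#' The probability that a random case receives a higher score than a random
#' control, plus half the tie probability, computed exactly from rank sums
#' (the Mann-Whitney statistic).  Invariant under strictly increasing
#' transformations of the scores.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (0/1).
#' @return The AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- check_binary_outcome(labels, "labels")
  if (length(scores) != length(labels)) {
    stop_ipcorr("`scores` and `labels` must have equal length")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_ipcorr("both outcome classes must be present to compute an AUC")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param n_tests Family size.
#' @param alpha Family-wise level (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop_ipcorr("`n_tests` must be >= 1")
  alpha / n_tests
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scorers evaluated on the same labelled test
#' set, using the DeLong covariance estimate of the paired AUC difference
#' and a two-sided normal p value.  Identical scores (zero-variance
#' difference) return statistic 0 and p = 1 by convention.
#'
#' @param scores_a,scores_b Score vectors from the two scorers.
#' @param labels Binary labels of the common test set.
#' @param family_size Optional number of tests in the family; when given, a
#'   `significant` flag at the Bonferroni threshold
#'   `alpha / family_size` is added.
#' @param alpha Family-wise level (default 0.05).
#' @return A one-row tibble with `auc_a`, `auc_b`, `statistic`, `p_value`
#'   and optionally `threshold`, `significant`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels,
                               family_size = NULL, alpha = 0.05) {
  labels <- check_binary_outcome(labels, "labels")
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels)) {
    stop_ipcorr("scores and labels must have equal length")
  }
  a_a <- auc(scores_a, labels)
  a_b <- auc(scores_b, labels)
  if (isTRUE(all.equal(scores_a, scores_b))) {
    stat <- 0; pval <- 1
  } else {
    res <- tryCatch({
      ra <- pROC::roc(labels, scores_a, levels = c(0, 1), direction = "<",
                      quiet = TRUE)
      rb <- pROC::roc(labels, scores_b, levels = c(0, 1), direction = "<",
                      quiet = TRUE)
      tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
      list(stat = unname(tst$statistic), p = tst$p.value)
    }, error = function(e) list(stat = 0, p = 1))
    stat <- res$stat
    pval <- res$p
    if (!is.finite(stat) || !is.finite(pval)) {
      stat <- 0; pval <- 1
    }
  }
  out <- tibble::tibble(auc_a = a_a, auc_b = a_b, statistic = stat,
                        p_value = pval)
  if (!is.null(family_size)) {
    thr <- bonferroni_threshold(family_size, alpha)
    out$threshold <- thr
    out$significant <- out$p_value < thr
  }
  out
}

#' Compare correction strategies by linear regression on the AUC
#'
#' Fits, per classifier, the ordinary least-squares model
#' `AUC ~ correction` with the correction dummy-coded against the
#' reference level `"none"`.  Each coefficient is the mean AUC difference
#' of a strategy versus no correction; a strategy is flagged significant
#' when its t-based 95% confidence interval excludes zero.
#'
#' @param auc_table A data frame with columns `classifier`, `correction`,
#'   `auc` (e.g. a [run_study()] result).
#' @param classifier Optional single classifier to restrict to.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with one row per (classifier, correction): `estimate`
#'   (0 for the reference), `conf.low`, `conf.high`, `significant`, plus
#'   the no-correction mean AUC `ref_auc`.
#' @export
compare_methods <- function(auc_table, classifier = NULL,
                            conf_level = 0.95) {
  tbl <- tibble::as_tibble(auc_table)
  if (!all(c("classifier", "correction", "auc") %in% names(tbl))) {
    stop_ipcorr("`auc_table` needs columns classifier, correction, auc")
  }
  if (!is.null(classifier)) {
    tbl <- tbl[tbl$classifier %in% classifier, , drop = FALSE]
  }
  out <- lapply(split(tbl, tbl$classifier), function(d) {
    if (!"none" %in% d$correction) {
      stop_ipcorr("reference category 'none' missing for classifier '%s'",
                  d$classifier[1L])
    }
    d$correction <- stats::relevel(factor(d$correction), ref = "none")
    fit <- stats::lm(auc ~ correction, data = d)
    ci <- stats::confint(fit, level = conf_level)
    cf <- stats::coef(fit)
    lev <- levels(d$correction)
    rows <- paste0("correction", lev[-1L])
    tibble::tibble(
      classifier = d$classifier[1L],
      correction = lev,
      estimate = c(0, unname(cf[rows])),
      conf.low = c(NA_real_, ci[rows, 1L]),
      conf.high = c(NA_real_, ci[rows, 2L]),
      significant = c(FALSE, ci[rows, 1L] > 0 | ci[rows, 2L] < 0),
      ref_auc = unname(cf["(Intercept)"]))
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("ipcorr_comparison", class(res))
  res
}

#' Run the (scenario x classifier x correction) simulation study
#'
#' Per replicate: draw replicate parameters, generate a population and an
#' independent test set with those parameters, draw the two-phase
#' stratified learning sample, fit every classifier-correction cell, and
#' record the test AUC.  The special correction label `"population"`
#' trains the uncorrected classifier on the full population (the unbiased
#' reference unavailable in practice).  Each replicate runs under its own
#' child seed of `config$seed`, so the study is reproducible and
#' resumable replicate by replicate; per-cell failures are recorded in
#' `attr(, "failures")` and only that cell is skipped.
#'
#' @param config A [scenario_config()].
#' @param classifiers Character vector of classifier kinds.
#' @param corrections Character vector of correction methods (may include
#'   `"population"`).
#' @param m Ensemble repetitions for resampling corrections outside the
#'   forest.
#' @param n_trees Trees per random forest.
#' @param k SMOTE neighbour count.
#' @param verbose Print per-replicate progress to stderr.
#' @return A tibble of class `study_result` with columns `scenario`,
#'   `replicate`, `classifier`, `correction`, `auc`.
#' @export
run_study <- function(config, classifiers = "logistic",
                      corrections = c("none", "ip_oversampling",
                                      "ip_bagging", "costing", "smote",
                                      "stochastic_ip_oversampling",
                                      "parametric_ip_bagging"),
                      m = 100L, n_trees = 500L, k = 5L, verbose = FALSE) {
  rep_seeds <- child_seeds(config$seed, config$replicates)
  rows <- list()
  failures <- list()
  for (r_i in seq_len(config$replicates)) {
    res <- with_seed_(rep_seeds[r_i], {
      params <- draw_scenario_params(config)
      pop <- generate_population(config, n = config$N_pop, params = params)
      test <- generate_population(config, n = config$N_test, params = params)
      tp <- tryCatch(two_phase_sample(pop, config$n_learn),
                     error = function(e) e)
      if (inherits(tp, "error")) {
        list(rows = NULL,
             fail = tibble::tibble(replicate = r_i, classifier = NA_character_,
                                   correction = "two_phase",
                                   message = conditionMessage(tp)))
      } else {
        pop_s <- NULL
        cell_rows <- list()
        cell_fails <- list()
        for (cl in classifiers) {
          for (co in corrections) {
            a <- tryCatch({
              if (co == "population") {
                if (is.null(pop_s)) pop_s <- assign_strata(pop)
                scorer <- fit_corrected(pop_s, correction_spec("none"),
                                        classifier_spec(cl, n_trees = n_trees))
              } else {
                scorer <- fit_corrected(
                  tp$sample,
                  correction_spec(co, m = m, k = k),
                  classifier_spec(cl, n_trees = n_trees),
                  weights = tp$table)
              }
              auc(predict_score(scorer, test), test$y)
            }, error = function(e) e)
            if (inherits(a, "error")) {
              cell_fails[[length(cell_fails) + 1L]] <-
                tibble::tibble(replicate = r_i, classifier = cl,
                               correction = co,
                               message = conditionMessage(a))
            } else {
              cell_rows[[length(cell_rows) + 1L]] <-
                tibble::tibble(scenario = config$family, replicate = r_i,
                               classifier = cl, correction = co, auc = a)
            }
          }
        }
        list(rows = dplyr::bind_rows(cell_rows),
             fail = dplyr::bind_rows(cell_fails))
      }
    })
    if (!is.null(res$rows)) rows[[length(rows) + 1L]] <- res$rows
    if (!is.null(res$fail) && nrow(res$fail) > 0L) {
      failures[[length(failures) + 1L]] <- res$fail
    }
    if (verbose) {
      message(sprintf("replicate %d/%d done", r_i, config$replicates))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  attr(out, "failures") <- dplyr::bind_rows(failures)
  class(out) <- c("study_result", class(out))
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Study result: %d AUC rows (%s scenario, %d replicates attempted)\n",
              nrow(x), attr(x, "config")$family %||% "?",
              attr(x, "config")$replicates %||% NA_integer_))
  fails <- attr(x, "failures")
  if (!is.null(fails) && nrow(fails) > 0L) {
    cat(sprintf("  %d cell/replicate failure(s) recorded in attr(, \"failures\")\n",
                nrow(fails)))
  }
  NextMethod()
}
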