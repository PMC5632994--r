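#' Classifier specification
#'
#' @param kind One of `"logistic"`, `"logistic_interactions"`,
#'   `"naive_bayes_kde"`, `"random_forest"`.
#' @param n_trees Number of trees for the random forest.
#' @param mtry Features tried per split; default
#'   `floor(sqrt(#predictors))`.
#' @param bandwidth Bandwidth rule for the kernel-density naive Bayes;
#'   currently `"silverman"`.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("logistic", "logistic_interactions",
                                     "naive_bayes_kde", "random_forest"),
                            n_trees = 500L, mtry = NULL,
                            bandwidth = "silverman") {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_trees = as.integer(n_trees), mtry = mtry,
                 bandwidth = bandwidth),
            class = "classifier_spec")
}

as_classifier_spec <- function(x, ...) {
  if (inherits(x, "classifier_spec")) x else classifier_spec(x, ...)
}

predictor_cols <- function(sample) {
  r <- roles(sample)
  c(r$stratum, r$features)
}

#' Predict continuous risk scores
#'
#' All fitted classifiers in this package are *scorers*: they map feature
#' rows to a risk score in `[0, 1]` (an estimate of `P(Y = 1 | x)`, or for
#' ensembles the arithmetic mean of member scores).
#'
#' @param object A fitted scorer.
#' @param newdata A data frame containing the stratum feature and main
#'   features used at fit time.
#' @param ... Unused.
#' @return A numeric vector of scores in `[0, 1]`.
#' @export
predict_score <- function(object, newdata, ...) {
  UseMethod("predict_score")
}

#' @export
predict.ipcorr_scorer <- function(object, newdata, ...) {
  predict_score(object, newdata, ...)
}

clamp01 <- function(x) pmin(pmax(as.numeric(x), 0), 1)

#' Logistic regression scorer
#'
#' Maximum-likelihood logistic regression of the outcome on the stratum
#' feature and the main features (linear terms).  The stratum feature is
#' always included: it is a covariate of the assumed outcome model.
#' A fit showing signs of perfect separation is flagged
#' (`$separation`) but still returns scores from the terminal iterate.
#'
#' @param sample A `stratified_tbl` (typically a corrected sample).
#' @return An object of class `ipcorr_logistic`.
#' @export
fit_logistic <- function(sample) {
  fit_logistic_impl(sample, interactions = FALSE)
}

#' Logistic regression with all two-way interactions
#'
#' As [fit_logistic()], with every pairwise product among the stratum
#' feature and the main features added to the design (for `p` main features
#' that is `choose(p + 1, 2)` interaction columns).
#'
#' @inheritParams fit_logistic
#' @return An object of class `ipcorr_logistic`.
#' @export
fit_logistic_interactions <- function(sample) {
  fit_logistic_impl(sample, interactions = TRUE)
}

fit_logistic_impl <- function(sample, interactions) {
  r <- roles(sample)
  preds <- predictor_cols(sample)
  df <- as.data.frame(tibble::as_tibble(sample)[c(r$outcome, preds)])
  if (length(preds) == 0L) {
    fml <- stats::as.formula(paste(r$outcome, "~ 1"))
  } else {
    rhs <- paste(sprintf("`%s`", preds), collapse = " + ")
    if (interactions && length(preds) > 1L) rhs <- sprintf("(%s)^2", rhs)
    fml <- stats::as.formula(paste(r$outcome, "~", rhs))
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  structure(list(fit = fit, roles = r, interactions = interactions,
                 separation = separation || !fit$converged),
            class = c("ipcorr_logistic", "ipcorr_scorer"))
}

#' @export
predict_score.ipcorr_logistic <- function(object, newdata, ...) {
  clamp01(stats::predict(object$fit, newdata = as.data.frame(newdata),
                         type = "response"))
}

#' Naive Bayes scorer with kernel-density marginals
#'
#' For each class and each numeric main feature the class-conditional
#' density is estimated by univariate Gaussian-kernel density estimation
#' (Silverman's rule-of-thumb bandwidth, floored at
#' `1e-6 * (range + 1)` so degenerate features stay usable); the categorical
#' stratum feature contributes class-conditional frequencies.  Scores are
#' the posterior probabilities `prior(j) * prod_k f_jk(x_k)`, normalised
#' over the two classes.
#'
#' @inheritParams fit_logistic
#' @return An object of class `ipcorr_nb`.
#' @export
fit_naive_bayes_kde <- function(sample) {
  r <- roles(sample)
  tbl <- tibble::as_tibble(sample)
  y <- tbl[[r$outcome]]
  if (sum(y == 0) < 2L || sum(y == 1) < 2L) {
    stop_ipcorr("naive Bayes needs at least 2 observations per class")
  }
  priors <- c(`0` = mean(y == 0), `1` = mean(y == 1))
  xe <- as.character(tbl[[r$stratum]])
  freq <- lapply(c(0, 1), function(j) {
    tab <- table(xe[y == j])
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  names(freq) <- c("0", "1")
  dens <- lapply(c(0, 1), function(j) {
    out <- lapply(r$features, function(f) {
      x <- tbl[[f]][y == j]
      if (!is.numeric(x)) {
        stop_ipcorr("naive Bayes requires numeric main features ('%s' is not)", f)
      }
      h <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
      h <- max(h, 1e-6 * (diff(range(x)) + 1))
      d <- stats::density(x, bw = h, n = 512,
                          from = min(x) - 3 * h, to = max(x) + 3 * h)
      list(x = d$x, y = d$y)
    })
    stats::setNames(out, r$features)
  })
  names(dens) <- c("0", "1")
  structure(list(roles = r, priors = priors, freq = freq, dens = dens),
            class = c("ipcorr_nb", "ipcorr_scorer"))
}

#' @export
predict_score.ipcorr_nb <- function(object, newdata, ...) {
  r <- object$roles
  newdata <- tibble::as_tibble(newdata)
  eps <- 1e-12
  loglik <- function(j) {
    ll <- rep(log(object$priors[[j]]), nrow(newdata))
    fr <- object$freq[[j]]
    lev <- as.character(newdata[[r$stratum]])
    p_xe <- fr[lev]
    p_xe[is.na(p_xe)] <- eps
    ll <- ll + log(pmax(p_xe, eps))
    for (f in r$features) {
      d <- object$dens[[j]][[f]]
      fx <- stats::approx(d$x, d$y, xout = newdata[[f]],
                          yleft = 0, yright = 0)$y
      ll <- ll + log(pmax(fx, eps))
    }
    ll
  }
  l0 <- loglik("0")
  l1 <- loglik("1")
  clamp01(1 / (1 + exp(l0 - l1)))
}

#' Random forest with correction-aware per-tree resampling
#'
#' A random forest replaces its ordinary per-tree bootstrap with the bias
#' correction itself, so bagging is not nested inside bagging: each tree is
#' a fully grown CART (minimum node size 1, `mtry` features tried per
#' split) trained on one corrected sample.
#'
#' Per strategy, the per-tree sample is drawn as follows:
#' * `none`: ordinary bootstrap of size `n`;
#' * `ip_bagging`: bootstrap of size `n` with selection probabilities
#'   proportional to `w_h`;
#' * `ip_oversampling`: bootstrap of size `n'` with probabilities
#'   proportional to `w_h`, realised as an ordinary bootstrap of the
#'   IP-oversampled set (the two are the same sampling law, which is also
#'   why IP oversampling inside a forest *is* IP bagging at size `n'`);
#' * `smote`: the SMOTE-corrected set is built once, then each tree takes
#'   an ordinary bootstrap of it;
#' * `costing`, `stochastic_ip_oversampling`, `parametric_ip_bagging`: one
#'   fresh corrected sample per tree.
#'
#' The scorer averages per-tree class-1 leaf frequencies (a probability
#' forest), matching rank-based AUC evaluation.
#'
#' @inheritParams fit_logistic
#' @param correction A [correction_spec()] or method name.
#' @param weights Stratum table; required for every method but `"none"`.
#' @param n_trees Number of trees.
#' @param mtry Features tried per split (default `floor(sqrt(#predictors))`).
#' @param seed Master seed.
#' @param bootstrap Set `FALSE` (with `correction = "none"`) to train every
#'   tree on the sample itself instead of a bootstrap; useful for testing
#'   single trees.
#' @return An object of class `ipcorr_forest`.
#' @export
fit_random_forest_corrected <- function(sample, correction = "none",
                                        weights = NULL, n_trees = 500L,
                                        mtry = NULL, seed = NULL,
                                        bootstrap = TRUE) {
  spec <- as_correction_spec(correction)
  if (!is.null(seed)) spec$seed <- seed
  r <- roles(sample)
  preds <- predictor_cols(sample)
  if (length(preds) == 0L) {
    stop_ipcorr("the random forest needs at least one predictor column")
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(preds))))
  if (mtry > length(preds)) {
    stop_ipcorr("mtry = %d exceeds the number of predictors (%d)",
                mtry, length(preds))
  }
  if (spec$method != "none" && is.null(weights)) {
    stop_ipcorr("correction '%s' needs a stratum weight table", spec$method)
  }

  train_xy <- function(s) {
    tbl <- tibble::as_tibble(s)
    list(x = as.data.frame(tbl[preds]),
         y = factor(tbl[[r$outcome]], levels = c(0, 1)))
  }
  single_ranger <- function(data_s, case_weights = NULL, replace = TRUE,
                            rseed) {
    xy <- train_xy(data_s)
    ranger::ranger(x = xy$x, y = xy$y, num.trees = n_trees, mtry = mtry,
                   probability = TRUE, min.node.size = 1L,
                   replace = replace, sample.fraction = 1,
                   case.weights = case_weights,
                   num.threads = 1L, seed = rseed)
  }
  seeds <- child_seeds(spec$seed, n_trees + 1L)
  rseed <- seeds[n_trees + 1L]

  if (spec$method %in% c("none", "ip_bagging", "ip_oversampling", "smote")) {
    data_s <- switch(spec$method,
      none = sample,
      ip_bagging = sample,
      ip_oversampling = ip_oversample(sample, weights),
      smote = smote_stratified(sample, weights, k = spec$k, seed = seeds[1L]))
    cw <- if (spec$method == "ip_bagging") row_weights(sample, weights)
    repl <- if (spec$method == "none") bootstrap else TRUE
    fit <- single_ranger(data_s, case_weights = cw, replace = repl,
                         rseed = rseed)
    members <- NULL
    mode <- "single"
  } else {
    sampler <- switch(spec$method,
      costing = function(sd) costing_samples(sample, weights, m = 1L,
                                             seed = sd)[[1L]],
      stochastic_ip_oversampling = make_stochastic_sampler(sample, weights),
      parametric_ip_bagging =
        make_parametric_sampler(sample, weights, spec$family))
    members <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      data_i <- sampler(seeds[i])
      tries <- 0L
      while (length(unique(data_i[[r$outcome]])) < 2L) {
        tries <- tries + 1L
        if (tries > 100L) {
          stop_ipcorr("tree %d: corrected sample single-class after 100 redraws", i)
        }
        data_i <- sampler(seeds[i] + tries)
      }
      xy <- train_xy(data_i)
      members[[i]] <- ranger::ranger(
        x = xy$x, y = xy$y, num.trees = 1L, mtry = mtry, probability = TRUE,
        min.node.size = 1L, replace = FALSE, sample.fraction = 1,
        num.threads = 1L, seed = seeds[i])
    }
    fit <- NULL
    mode <- "pertree"
  }
  structure(list(fit = fit, members = members, mode = mode, roles = r,
                 predictors = preds, method = spec$method,
                 n_trees = n_trees, mtry = mtry),
            class = c("ipcorr_forest", "ipcorr_scorer"))
}

#' @export
predict_score.ipcorr_forest <- function(object, newdata, ...) {
  nd <- as.data.frame(tibble::as_tibble(newdata)[object$predictors])
  score_one <- function(fit) {
    pr <- stats::predict(fit, data = nd, num.threads = 1L)$predictions
    pr[, "1"]
  }
  if (object$mode == "single") {
    clamp01(score_one(object$fit))
  } else {
    clamp01(Reduce(`+`, lapply(object$members, score_one)) /
              length(object$members))
  }
}

new_ensemble <- function(members, kind, method) {
  structure(list(members = members, kind = kind, method = method),
            class = c("ipcorr_ensemble", "ipcorr_scorer"))
}

#' @export
predict_score.ipcorr_ensemble <- function(object, newdata, ...) {
  scores <- vapply(object$members, predict_score, newdata = newdata,
                   FUN.VALUE = numeric(nrow(newdata)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  clamp01(rowMeans(scores))
}

#' Fit a classifier under a bias-correction strategy
#'
#' Dispatch layer combining the seven correction strategies with the four
#' classifiers.  The random forest delegates to
#' [fit_random_forest_corrected()] (the correction replaces the per-tree
#' bootstrap).  For the other classifiers, single-sample strategies
#' (`none`, `ip_oversampling`, `smote`) fit one model on the corrected
#' sample; resampling strategies fit `m` models on `m` corrected samples
#' and return a score-averaging ensemble.
#'
#' @inheritParams fit_logistic
#' @param correction A [correction_spec()] or method name.
#' @param classifier A [classifier_spec()] or kind name.
#' @param weights Stratum table (required unless `correction = "none"`).
#' @return A fitted scorer.
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(y = rbinom(80, 1, 0.5), x_e = rbinom(80, 1, 0.5),
#'                     x1 = rnorm(80))
#' s <- assign_strata(d)
#' tab <- stratum_table(s, p_select = rep(1, length(unique(s$.stratum))))
#' fit <- fit_corrected(s, "none", "logistic", tab)
#' head(predict_score(fit, d))
#' @export
fit_corrected <- function(sample, correction, classifier = "logistic",
                          weights = NULL) {
  spec <- as_correction_spec(correction)
  cls <- as_classifier_spec(classifier)
  if (cls$kind == "random_forest") {
    return(fit_random_forest_corrected(sample, spec, weights,
                                       n_trees = cls$n_trees,
                                       mtry = cls$mtry, seed = spec$seed))
  }
  fitter <- switch(cls$kind,
    logistic = fit_logistic,
    logistic_interactions = fit_logistic_interactions,
    naive_bayes_kde = fit_naive_bayes_kde)
  samples <- corrected_samples(sample, spec, weights)
  if (length(samples) == 1L) {
    fit <- fitter(samples[[1L]])
    attr(fit, "correction") <- spec$method
    return(fit)
  }
  members <- lapply(samples, fitter)
  new_ensemble(members, kind = cls$kind, method = spec$method)
}
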