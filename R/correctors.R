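#' Correction strategy specification
#'
#' Bundles the choice among the seven bias-correction strategies with its
#' hyperparameters.  The resampling-based strategies (`ip_bagging`,
#' `costing`, `stochastic_ip_oversampling`, `parametric_ip_bagging`) produce
#' `m` corrected samples and an averaged ensemble; the single-sample
#' strategies (`none`, `ip_oversampling`, `smote`) always use `m = 1`
#' outside the random forest and `m` is forced to 1 for them.
#'
#' @param method One of `"none"`, `"ip_oversampling"`, `"ip_bagging"`,
#'   `"costing"`, `"smote"`, `"stochastic_ip_oversampling"`,
#'   `"parametric_ip_bagging"`.
#' @param m Ensemble repetitions (default 100 for resampling strategies, 1
#'   otherwise).  Inside the random forest the number of trees plays this
#'   role instead.
#' @param k Nearest-neighbour count for the stratified SMOTE (default 5).
#' @param family Distribution family for the parametric strategies;
#'   currently `"normal"` (multivariate normal per stratum).
#' @param seed Master seed; per-repetition child seeds are derived from it
#'   (first `m` draws of one integer stream, so increasing `m` leaves
#'   earlier repetitions unchanged).
#' @return A list of class `correction_spec`.
#' @export
correction_spec <- function(method = c("none", "ip_oversampling", "ip_bagging",
                                       "costing", "smote",
                                       "stochastic_ip_oversampling",
                                       "parametric_ip_bagging"),
                            m = NULL, k = 5L, family = "normal", seed = NULL) {
  method <- match.arg(method)
  single <- method %in% c("none", "ip_oversampling", "smote")
  if (is.null(m)) m <- if (single) 1L else 100L
  if (single) m <- 1L
  if (m < 1L) stop_ipcorr("`m` must be >= 1")
  if (k < 1L) stop_ipcorr("`k` must be >= 1")
  structure(list(method = method, m = as.integer(m), k = as.integer(k),
                 family = family, seed = seed),
            class = "correction_spec")
}

as_correction_spec <- function(x, ...) {
  if (inherits(x, "correction_spec")) x else correction_spec(x, ...)
}

#' @export
print.correction_spec <- function(x, ...) {
  cat(sprintf("Correction spec: %s (m = %d, k = %d, family = %s)\n",
              x$method, x$m, x$k, x$family))
  invisible(x)
}

# Reconstruct a stratified tibble from new rows, carrying roles and
# provenance (subsetting a tibble does not reliably preserve custom
# attributes).
rebuild <- function(rows, template, provenance) {
  r <- roles(template)
  out <- new_stratified(rows, outcome = r$outcome, stratum = r$stratum,
                        features = r$features)
  attr(out, "provenance") <- provenance
  out
}

#' Correction provenance of a corrected sample
#' @param x A corrected sample.
#' @return The name of the correction method that produced `x`, or `NULL`.
#' @export
provenance <- function(x) attr(x, "provenance")

#' No correction
#'
#' Returns the stratified sample unchanged (training on it simply ignores
#' the selection bias).  Valid for some bias types and classifiers, and the
#' reference point every other strategy is compared against.
#'
#' @param sample A `stratified_tbl`.
#' @return The same rows with provenance `"none"`.
#' @export
correct_none <- function(sample) {
  rebuild(tibble::as_tibble(sample), sample, "none")
}

#' Inverse-probability oversampling
#'
#' Deterministically replicates every observation of stratum *h* exactly
#' `w_h` times, yielding a reconstructed sample of size `n'` whose stratum
#' proportions match the population.  Equivalent, for likelihood-based
#' classifiers, to integer frequency weights.  Note that replication shrinks
#' the within-stratum covariance by the factor `w(n-1)/(wn-1)`; see
#' [stochastic_ip_oversample()] for the repaired variant.
#'
#' @param sample A `stratified_tbl`.
#' @param weights A stratum table from [stratum_table()].
#' @return A corrected sample of `n'` rows (row *i* occupies `w_h(i)`
#'   consecutive positions, original order preserved).
#' @export
ip_oversample <- function(sample, weights) {
  w <- row_weights(sample, weights)
  idx <- rep(seq_len(nrow(sample)), times = w)
  rebuild(tibble::as_tibble(sample)[idx, , drop = FALSE], sample,
          "ip_oversampling")
}

#' Inverse-probability bagging samples
#'
#' Draws `m` bootstrap samples of size `n` in which row *i* is selected with
#' probability proportional to its stratum weight `w_h(i)`.  Fitting one
#' model per sample and averaging the predictions gives the IP-bagging
#' ensemble.
#'
#' @inheritParams ip_oversample
#' @param m Number of bootstrap samples.
#' @param seed Master seed (see [correction_spec()] for the child-seed
#'   scheme).
#' @return A list of `m` corrected samples, each carrying the drawn row
#'   indices in `attr(, "rows")`.
#' @export
ip_bagging_samples <- function(sample, weights, m = 100L, seed = NULL) {
  w <- row_weights(sample, weights)
  n <- nrow(sample)
  tbl <- tibble::as_tibble(sample)
  seeds <- child_seeds(seed, m)
  lapply(seq_len(m), function(i) {
    idx <- with_seed_(seeds[i],
                      sample.int(n, n, replace = TRUE, prob = w))
    out <- rebuild(tbl[idx, , drop = FALSE], sample, "ip_bagging")
    attr(out, "rows") <- idx
    out
  })
}

#' Costing samples (rejection-sampling ensemble)
#'
#' Each subsample accepts every row independently, at most once, with
#' probability `w_h / max(w_h)`; subsample sizes therefore vary around
#' `sum(n_h w_h) / max(w_h)`.  Subsamples that miss a nonempty stratum
#' cannot support a full classification rule and are redrawn
#' (`require_complete = TRUE`), a modification whose induced bias is small;
#' the number of redraws is reported in `attr(, "redraws")` on the returned
#' list.
#'
#' @inheritParams ip_bagging_samples
#' @param require_complete Redraw subsamples that miss a stratum (default
#'   `TRUE`).
#' @param max_redraws Retry cap per subsample before erroring.
#' @return A list of `m` corrected samples with row indices in
#'   `attr(, "rows")`.
#' @export
costing_samples <- function(sample, weights, m = 100L, seed = NULL,
                            require_complete = TRUE, max_redraws = 1000L) {
  w <- row_weights(sample, weights)
  accept <- w / max(w)
  n <- nrow(sample)
  strata_present <- sort(unique(sample$.stratum))
  tbl <- tibble::as_tibble(sample)
  seeds <- child_seeds(seed, m)
  redraws <- 0L
  out <- lapply(seq_len(m), function(i) {
    idx <- with_seed_(seeds[i], {
      tries <- 0L
      repeat {
        keep <- which(stats::runif(n) < accept)
        if (!require_complete ||
            all(strata_present %in% sample$.stratum[keep])) {
          break
        }
        tries <- tries + 1L
        if (tries > max_redraws) {
          stop_ipcorr(paste0(
            "costing: no complete subsample within %d redraws; ",
            "strata are too small relative to their weights"), max_redraws)
        }
      }
      redraws <<- redraws + tries
      keep
    })
    s <- rebuild(tbl[idx, , drop = FALSE], sample, "costing")
    attr(s, "rows") <- idx
    s
  })
  attr(out, "redraws") <- redraws
  out
}

#' Stratified SMOTE
#'
#' Synthetic oversampling adapted to stratified samples: every stratum with
#' `w_h > 1` receives `n_h (w_h - 1)` synthetic observations so the total
#' reaches `n'`.  A synthetic row is `x + u (x_nn - x)` with
#' `u ~ Uniform(0, 1)` and `x_nn` one of the `k` Euclidean nearest
#' neighbours of `x` *within the same stratum* (ties broken by row order);
#' outcome and stratum feature are copied from `x`.
#'
#' @inheritParams ip_bagging_samples
#' @param k Neighbour count; must satisfy `k < n_h` for every enlarged
#'   stratum.
#' @return A corrected sample of `n'` rows: the original rows followed by
#'   the synthetic rows, stratum by stratum.
#' @export
smote_stratified <- function(sample, weights, k = 5L, seed = NULL) {
  r <- roles(sample)
  w_tab <- weights$w_h[match(sort(unique(sample$.stratum)),
                             weights$stratum_id)]
  row_w <- row_weights(sample, weights)
  feats <- r$features
  X <- as.matrix(tibble::as_tibble(sample)[feats])
  if (length(feats) > 0 && !is.numeric(X)) {
    stop_ipcorr("SMOTE requires numeric main features")
  }
  tbl <- tibble::as_tibble(sample)
  synth <- with_seed_(seed, {
    pieces <- list()
    for (h in sort(unique(sample$.stratum))) {
      wh <- weights$w_h[match(h, weights$stratum_id)]
      if (wh <= 1L) next
      rows_h <- which(sample$.stratum == h)
      n_h <- length(rows_h)
      if (k >= n_h) {
        stop_ipcorr("SMOTE: k = %d >= n_h = %d in stratum %d", k, n_h, h)
      }
      n_new <- n_h * (wh - 1L)
      base <- rep(seq_len(n_h), each = wh - 1L)
      if (length(feats) == 0L) {
        piece <- tbl[rows_h[base], , drop = FALSE]
      } else {
        Xh <- X[rows_h, , drop = FALSE]
        D <- as.matrix(stats::dist(Xh))
        nn_raw <- vapply(seq_len(n_h), function(i) {
          d <- D[i, ]
          d[i] <- Inf
          order(d)[seq_len(k)]          # stable: ties keep row order
        }, integer(k))
        nn <- if (k == 1L) matrix(nn_raw, ncol = 1L) else t(nn_raw)
        pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
        u <- stats::runif(n_new)
        Xs <- Xh[base, , drop = FALSE] +
          u * (Xh[pick, , drop = FALSE] - Xh[base, , drop = FALSE])
        piece <- tbl[rows_h[base], , drop = FALSE]
        piece[feats] <- as.data.frame(Xs)
      }
      pieces[[length(pieces) + 1L]] <- piece
    }
    pieces
  })
  out <- dplyr::bind_rows(c(list(tbl), synth))
  rebuild(out, sample, "smote")
}

#' Adjusted noise covariance for replicated strata
#'
#' When a stratum of `n_h` observations with covariance `Sigma` is
#' replicated `w_h` times, the empirical covariance of the replicated set
#' has expectation `w(n-1)/(wn-1) * Sigma < Sigma`.  Adding independent
#' noise with covariance `(w-1)/(wn-1) * Sigma` to every replicated row
#' restores the original covariance in expectation (and the mean is
#' untouched since the noise is centred).
#'
#' @param sigma_hat Symmetric positive-semidefinite `p x p` stratum
#'   covariance estimate.
#' @param w_h Integer IP weight of the stratum (`>= 1`).
#' @param n_h Stratum sample size (`>= 2`).
#' @return The `p x p` noise covariance `(w_h - 1) / (w_h n_h - 1) *
#'   sigma_hat`; the zero matrix when `w_h = 1`.
#' @export
noise_covariance <- function(sigma_hat, w_h, n_h) {
  sigma_hat <- as.matrix(sigma_hat)
  if (nrow(sigma_hat) != ncol(sigma_hat) ||
      !isSymmetric(sigma_hat, tol = 1e-8)) {
    stop_ipcorr("`sigma_hat` must be a symmetric matrix")
  }
  if (n_h < 2) stop_ipcorr("`n_h` must be >= 2 (covariance undefined otherwise)")
  if (w_h < 1) stop_ipcorr("`w_h` must be >= 1")
  if (nrow(sigma_hat) > 0) {
    ev <- eigen(sigma_hat, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8 * max(abs(ev), 1))) {
      stop_ipcorr("`sigma_hat` must be positive semidefinite")
    }
  }
  ((w_h - 1) / (w_h * n_h - 1)) * sigma_hat
}

# Cholesky factor with a ridge fallback for singular covariance estimates:
# lambda = 1e-8 * mean(diag(S)), or 1e-8 when that is zero.  Guarantees a
# valid sampler without materially changing the distribution.
chol_ridge <- function(S) {
  p <- nrow(S)
  if (p == 0L) return(NULL)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    lam <- 1e-8 * mean(diag(S))
    if (!is.finite(lam) || lam <= 0) lam <- 1e-8
    R <- chol(S + lam * diag(p))
  }
  R
}

# Per-stratum feature summaries used by the covariance-restoring methods.
stratum_moments <- function(sample) {
  r <- roles(sample)
  X <- as.matrix(tibble::as_tibble(sample)[r$features])
  ids <- sort(unique(sample$.stratum))
  mom <- lapply(ids, function(h) {
    Xh <- X[sample$.stratum == h, , drop = FALSE]
    if (nrow(Xh) < 2L) {
      stop_ipcorr("stratum %d has fewer than 2 observations; covariance undefined", h)
    }
    list(id = h, n_h = nrow(Xh), mu = colMeans(Xh),
         sigma = stats::cov(Xh))
  })
  names(mom) <- as.character(ids)
  mom
}

# Internal factory: returns function(seed) producing one stochastic IP
# oversampled data set.  The deterministic replication and per-stratum noise
# Cholesky factors are precomputed once, which matters when the random
# forest requests hundreds of repetitions.
make_stochastic_sampler <- function(sample, weights) {
  r <- roles(sample)
  base <- ip_oversample(sample, weights)
  feats <- r$features
  p <- length(feats)
  Xb <- if (p > 0) as.matrix(tibble::as_tibble(base)[feats]) else NULL
  mom <- if (p > 0) stratum_moments(sample) else list()
  noisy <- list()
  for (mo in mom) {
    w_h <- weights$w_h[match(mo$id, weights$stratum_id)]
    if (w_h > 1L) {
      S_adj <- noise_covariance(mo$sigma, w_h, mo$n_h)
      noisy[[as.character(mo$id)]] <-
        list(rows = which(base$.stratum == mo$id), R = chol_ridge(S_adj))
    }
  }
  base_tbl <- tibble::as_tibble(base)
  function(seed = NULL) {
    with_seed_(seed, {
      if (p == 0L || length(noisy) == 0L) {
        out <- base_tbl
      } else {
        Xn <- Xb
        for (nz in noisy) {
          nh <- length(nz$rows)
          Z <- matrix(stats::rnorm(nh * p), nh, p)
          Xn[nz$rows, ] <- Xn[nz$rows, , drop = FALSE] + Z %*% nz$R
        }
        out <- base_tbl
        out[feats] <- as.data.frame(Xn)
      }
      rebuild(out, sample, "stochastic_ip_oversampling")
    })
  }
}

#' Stochastic inverse-probability oversampling
#'
#' IP oversampling followed by a stochastic repair of the covariance it
#' biased: every replicated row of stratum *h* (originals included)
#' receives independent Gaussian noise with covariance
#' `(w_h - 1)/(w_h n_h - 1) * Sigma_hat_h`, where `Sigma_hat_h` is the
#' empirical stratum covariance (see [noise_covariance()]).  In expectation
#' the noisy replicated stratum recovers both the original mean and
#' covariance.  The noise-adding step is repeated `m` times; classifiers
#' average over the repetitions.  Features are treated as continuous
#' regardless of their true family (noisy values are neither rounded nor
#' clipped).
#'
#' @inheritParams ip_bagging_samples
#' @return A list of `m` corrected samples of `n'` rows each.  Strata with
#'   `w_h = 1` receive zero noise, so with all weights 1 every sample
#'   equals the input.
#' @export
stochastic_ip_oversample <- function(sample, weights, m = 100L, seed = NULL) {
  sampler <- make_stochastic_sampler(sample, weights)
  seeds <- child_seeds(seed, m)
  lapply(seq_len(m), function(i) sampler(seeds[i]))
}

# Internal factory for parametric IP bagging repetitions.
make_parametric_sampler <- function(sample, weights, family = "normal") {
  if (!family %in% c("normal", "gaussian", "mvnorm")) {
    stop_ipcorr("unsupported parametric family '%s' (only 'normal' is implemented)",
                family)
  }
  r <- roles(sample)
  feats <- r$features
  p <- length(feats)
  tbl <- tibble::as_tibble(sample)
  ids <- sort(unique(sample$.stratum))
  mom <- if (p > 0) stratum_moments(sample) else NULL
  strata <- lapply(ids, function(h) {
    rows_h <- which(sample$.stratum == h)
    w_h <- weights$w_h[match(h, weights$stratum_id)]
    if (is.na(w_h)) {
      stop_ipcorr("stratum id %s missing from the weight table", h)
    }
    proto <- tbl[rows_h[1L], setdiff(names(tbl), feats), drop = FALSE]
    list(id = h, n_draw = length(rows_h) * w_h, proto = proto,
         mu = if (p > 0) mom[[as.character(h)]]$mu else NULL,
         R = if (p > 0) chol_ridge(mom[[as.character(h)]]$sigma) else NULL)
  })
  function(seed = NULL) {
    with_seed_(seed, {
      pieces <- lapply(strata, function(st) {
        piece <- st$proto[rep(1L, st$n_draw), , drop = FALSE]
        if (p > 0) {
          Z <- matrix(stats::rnorm(st$n_draw * p), st$n_draw, p)
          piece[feats] <-
            as.data.frame(sweep(Z %*% st$R, 2L, st$mu, `+`))
        }
        piece
      })
      out <- dplyr::bind_rows(pieces)[names(tbl)]
      rebuild(out, sample, "parametric_ip_bagging")
    })
  }
}

#' Parametric inverse-probability bagging samples
#'
#' A fully parametric bootstrap of size `n'`: per repetition and per
#' stratum *h*, the stratum mean and covariance are estimated empirically
#' and `n_h w_h` feature vectors are drawn from the fitted multivariate
#' normal; the stratum's outcome and stratum-feature values are attached
#' and the strata concatenated.  Unlike replication-based corrections, the
#' drawn samples carry the estimated population covariance and contain no
#' repeated observations.
#'
#' @inheritParams ip_bagging_samples
#' @param family Parametric family; currently `"normal"`.
#' @return A list of `m` corrected samples of `n'` rows each.
#' @export
parametric_ip_bag_samples <- function(sample, weights, m = 100L,
                                      family = "normal", seed = NULL) {
  sampler <- make_parametric_sampler(sample, weights, family)
  seeds <- child_seeds(seed, m)
  lapply(seq_len(m), function(i) sampler(seeds[i]))
}

#' Draw corrected sample(s) for an arbitrary strategy
#'
#' Uniform entry point over the seven strategies: returns a list of
#' corrected samples (length 1 for the single-sample strategies).
#'
#' @param sample A `stratified_tbl`.
#' @param correction A [correction_spec()] or method name.
#' @param weights A stratum table; unused for `method = "none"`.
#' @return A list of corrected samples.
#' @export
corrected_samples <- function(sample, correction, weights = NULL) {
  spec <- as_correction_spec(correction)
  if (spec$method != "none" && is.null(weights)) {
    stop_ipcorr("correction '%s' needs a stratum weight table", spec$method)
  }
  switch(spec$method,
    none = list(correct_none(sample)),
    ip_oversampling = list(ip_oversample(sample, weights)),
    smote = list(smote_stratified(sample, weights, k = spec$k,
                                  seed = spec$seed)),
    ip_bagging = ip_bagging_samples(sample, weights, m = spec$m,
                                    seed = spec$seed),
    costing = costing_samples(sample, weights, m = spec$m, seed = spec$seed),
    stochastic_ip_oversampling =
      stochastic_ip_oversample(sample, weights, m = spec$m, seed = spec$seed),
    parametric_ip_bagging =
      parametric_ip_bag_samples(sample, weights, m = spec$m,
                                family = spec$family, seed = spec$seed))
}
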