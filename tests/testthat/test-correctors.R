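# The weight layout used throughout: four strata of equal size with
# w = (1, 5, 2, 9), i.e. p_select = (1, 1/5, 1/2, 1/9).
four_strata_weights <- function(sample) {
  make_table(sample, p_select = c(1, 1 / 5, 1 / 2, 1 / 9))
}

test_that("correct_none is the identity with provenance", {
  s <- make_four_strata(n_cell = 5L, p = 2L)
  out <- correct_none(s)
  expect_equal(bare(out), bare(s))
  expect_identical(provenance(out), "none")

  s0 <- make_four_strata(n_cell = 3L, p = 0L)  # no main features
  expect_equal(nrow(correct_none(s0)), nrow(s0))
})

test_that("ip_oversample replicates each row exactly w_h times", {
  s <- make_four_strata(n_cell = 500L, p = 1L)
  tab <- four_strata_weights(s)
  out <- ip_oversample(s, tab)
  expect_equal(nrow(out), 8500)
  expect_equal(unname(tabulate(out$.stratum)), c(500L, 2500L, 1000L, 4500L))

  # each individual row appears w_h times
  s2 <- make_four_strata(n_cell = 3L, p = 1L)
  tab2 <- make_table(s2, p_select = c(1, 1, 1, 1 / 2))
  out2 <- ip_oversample(s2, tab2)
  dup <- tibble::as_tibble(out2)[out2$.stratum == 4L, ]
  expect_equal(nrow(dup), 6L)
  expect_equal(sum(duplicated(dup)), 3L)

  # all weights one: identity
  tab1 <- make_table(s2, p_select = rep(1, 4))
  expect_equal(bare(ip_oversample(s2, tab1)), bare(s2))

  # a stratum missing from the weight table is an error
  expect_error(ip_oversample(s2, tab2[-2L, ]), "missing")
})

test_that("IP bagging draws rows with probability proportional to w_h", {
  s <- make_four_strata(n_cell = 10L, p = 1L)
  tab <- four_strata_weights(s)

  # closed-form oracle: expected stratum-2 rows per bootstrap sample of
  # size n is n * n_h w_h / n' = 40 * 50 / 170
  B <- 20000L
  draws <- ip_bagging_samples(s, tab, m = B, seed = 99L)
  counts <- vapply(draws, function(d) sum(d$.stratum == 2L), numeric(1))
  expected <- 40 * 50 / 170
  p2 <- 50 / 170
  se <- sqrt(40 * p2 * (1 - p2) / B)
  expect_lt(abs(mean(counts) - expected), 3 * se)

  # every sample has size n
  expect_true(all(vapply(draws[1:50], nrow, numeric(1)) == 40))

  # uniform weights reduce to the ordinary bootstrap law (size n, all rows
  # equally likely): empirical row-frequency spread consistent with uniform
  tab1 <- make_table(s, p_select = rep(1, 4))
  u <- ip_bagging_samples(s, tab1, m = 2000L, seed = 1L)
  freq <- tabulate(unlist(lapply(u, attr, "rows")), nbins = 40)
  expect_lt(max(abs(freq / (2000 * 40) - 1 / 40)), 4 * sqrt((1 / 40) / (2000 * 40)))
})

test_that("resampling correctors are reproducible and extendable in m", {
  s <- make_four_strata(n_cell = 10L, p = 2L)
  tab <- four_strata_weights(s)
  a <- ip_bagging_samples(s, tab, m = 3L, seed = 7L)
  b <- ip_bagging_samples(s, tab, m = 3L, seed = 7L)
  expect_identical(lapply(a, attr, "rows"), lapply(b, attr, "rows"))

  # growing m leaves earlier repetitions untouched
  c5 <- ip_bagging_samples(s, tab, m = 5L, seed = 7L)
  expect_identical(lapply(c5[1:3], attr, "rows"), lapply(a, attr, "rows"))

  st <- stochastic_ip_oversample(s, tab, m = 2L, seed = 11L)
  st2 <- stochastic_ip_oversample(s, tab, m = 2L, seed = 11L)
  expect_equal(st, st2)
  pb <- parametric_ip_bag_samples(s, tab, m = 2L, seed = 11L)
  pb2 <- parametric_ip_bag_samples(s, tab, m = 2L, seed = 11L)
  expect_equal(pb, pb2)
})

test_that("costing accepts rows with probability w_h / max(w_h)", {
  s <- make_four_strata(n_cell = 10L, p = 1L)
  tab <- four_strata_weights(s)

  # unfiltered oracle: E(size) = sum(n_h w_h) / w_max = 170 / 9
  B <- 20000L
  draws <- costing_samples(s, tab, m = B, seed = 5L,
                           require_complete = FALSE)
  sizes <- vapply(draws, nrow, numeric(1))
  p_acc <- c(1, 5, 2, 9) / 9
  expected <- sum(10 * p_acc)
  se <- sqrt(sum(10 * p_acc * (1 - p_acc)) / B)
  expect_lt(abs(mean(sizes) - expected), 3 * se)

  # the w_max stratum is always fully present; rows appear at most once
  filt <- costing_samples(s, tab, m = 200L, seed = 6L)
  expect_true(all(vapply(filt, function(d) sum(d$.stratum == 4L), 0) == 10))
  expect_true(all(vapply(filt, function(d) !anyDuplicated(attr(d, "rows")), TRUE)))
  # completeness: every stratum represented after redraws
  expect_true(all(vapply(filt, function(d) length(unique(d$.stratum)), 0) == 4))

  # equal weights: the full sample comes back
  tab1 <- make_table(s, p_select = rep(1, 4))
  full <- costing_samples(s, tab1, m = 3L, seed = 1L)
  expect_true(all(vapply(full, nrow, 0) == nrow(s)))
})

test_that("stratified SMOTE interpolates within strata up to size n'", {
  s <- make_four_strata(n_cell = 20L, p = 2L)
  tab <- four_strata_weights(s)
  out <- smote_stratified(s, tab, k = 5L, seed = 3L)
  expect_equal(nrow(out), n_prime(tab))
  expect_equal(unname(tabulate(out$.stratum)), 20L * c(1L, 5L, 2L, 9L))

  # synthetic rows lie on segments between stratum members: coordinate-wise
  # within the stratum's bounding box
  for (h in c(2L, 3L, 4L)) {
    orig <- tibble::as_tibble(s)[s$.stratum == h, c("x1", "x2")]
    synth <- tibble::as_tibble(out)[-seq_len(nrow(s)), ]
    synth <- synth[synth$.stratum == h, c("x1", "x2")]
    for (f in c("x1", "x2")) {
      expect_true(all(synth[[f]] >= min(orig[[f]]) - 1e-12))
      expect_true(all(synth[[f]] <= max(orig[[f]]) + 1e-12))
    }
  }

  # labels and stratum features are copied, never altered
  expect_identical(unique(out$y[out$.stratum == 2L]),
                   unique(s$y[s$.stratum == 2L]))

  # all weights one: identity
  tab1 <- make_table(s, p_select = rep(1, 4))
  expect_equal(bare(smote_stratified(s, tab1, seed = 1L)), bare(s))

  # two identical points, w = 3: all synthetics equal that point
  d <- tibble::tibble(y = c(0, 0, 1, 1), x_e = 0,
                      x1 = c(2, 2, 5, 6), x2 = c(-1, -1, 0, 1))
  s2 <- assign_strata(d)
  tab2 <- make_table(s2, p_select = c(1 / 3, 1))
  out2 <- smote_stratified(s2, tab2, k = 1L, seed = 2L)
  synth2 <- tibble::as_tibble(out2)[-seq_len(4L), ]
  expect_equal(nrow(synth2), 4L)
  expect_true(all(synth2$x1 == 2 & synth2$x2 == -1))

  # k >= n_h in an enlarged stratum is rejected with the stratum named
  expect_error(smote_stratified(s2, tab2, k = 2L), "stratum 1")
})

test_that("the adjusted noise covariance follows (w-1)/(wn-1) Sigma", {
  expect_equal(noise_covariance(diag(2), 1, 10), matrix(0, 2, 2))
  expect_equal(noise_covariance(diag(2), 2, 3), diag(2) / 5)
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(noise_covariance(S, 3, 50), (2 / 149) * S)
  expect_error(noise_covariance(S, 2, 1), ">= 2")
  expect_error(noise_covariance(matrix(c(1, 2, 0, 1), 2), 2, 10), "symmetric")
  expect_error(noise_covariance(matrix(c(1, 2, 2, 1), 2), 2, 10),
               "semidefinite")
})

test_that("stochastic IP oversampling preserves stratum mean and covariance in expectation", {
  # single stratum, n = 50, w = 3: over repetitions of the noise the mean
  # of each noisy sample stays at the stratum mean and the expected
  # empirical covariance equals the stratum covariance estimate
  Sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  fx <- make_weighted_stratum(50L, mu = c(1, -2), Sigma = Sigma, w = 3L,
                              seed = 42L)
  s <- fx$sample
  tab <- fx$table
  expect_identical(tab$w_h, c(3L, 1L))
  X <- as.matrix(tibble::as_tibble(s)[s$.stratum == 1L, c("x1", "x2")])
  mu_hat <- colMeans(X)
  S_hat <- cov(X)

  B <- 2000L
  reps <- stochastic_ip_oversample(s, tab, m = B, seed = 9L)
  stratum1 <- function(d) {
    as.matrix(tibble::as_tibble(d)[d$.stratum == 1L, c("x1", "x2")])
  }
  means <- t(vapply(reps, function(d) colMeans(stratum1(d)), numeric(2)))
  covs <- t(vapply(reps, function(d) as.vector(cov(stratum1(d))), numeric(4)))

  se_mean <- apply(means, 2L, sd) / sqrt(B)
  expect_true(all(abs(colMeans(means) - mu_hat) < 3 * se_mean + 1e-12))
  se_cov <- apply(covs, 2L, sd) / sqrt(B)
  expect_true(all(abs(colMeans(covs) - as.vector(S_hat)) < 3 * se_cov))

  # all weights one: zero noise, exact identity for every repetition
  tab1 <- make_table(s, p_select = c(1, 1))
  ident <- stochastic_ip_oversample(s, tab1, m = 3L, seed = 1L)
  for (d in ident) {
    expect_equal(bare(d), bare(s))
  }

  # a singleton stratum cannot supply a covariance
  bad <- assign_strata(tibble::tibble(y = c(0, 0, 1), x_e = 0,
                                      x1 = rnorm(3)))
  tabb <- make_table(bad, p_select = c(1, 1 / 2))
  expect_error(stochastic_ip_oversample(bad, tabb, m = 1L), "fewer than 2")
})

test_that("parametric IP bagging draws n_h w_h rows per stratum from the fitted normal", {
  s <- make_four_strata(n_cell = 5L, p = 2L)
  tab <- make_table(s, p_select = c(1, 1 / 4, 1, 1))
  out <- parametric_ip_bag_samples(s, tab, m = 2L, seed = 3L)
  expect_equal(nrow(out[[1L]]), n_prime(tab))
  expect_equal(sum(out[[1L]]$.stratum == 2L), 20L)
  # labels/stratum features attach the stratum's own values
  expect_identical(unique(out[[1L]]$y[out[[1L]]$.stratum == 2L]),
                   unique(s$y[s$.stratum == 2L]))

  # CLT oracle on the generator: mean of n_h w_h = 600 draws within
  # 4 sd/sqrt(600) of the estimated stratum mean, across seeds
  w <- 3L
  fx2 <- make_weighted_stratum(200L, mu = c(2, -1), Sigma = diag(2), w = w,
                               seed = 8L)
  s2 <- fx2$sample
  tab2 <- fx2$table
  X2 <- as.matrix(tibble::as_tibble(s2)[s2$.stratum == 1L, c("x1", "x2")])
  mu_hat <- colMeans(X2)
  sd_hat <- sqrt(diag(cov(X2)))
  for (seed in 1:10) {
    d <- parametric_ip_bag_samples(s2, tab2, m = 1L, seed = seed)[[1L]]
    Xd <- as.matrix(tibble::as_tibble(d)[d$.stratum == 1L, c("x1", "x2")])
    expect_equal(nrow(Xd), 600L)
    m_draw <- colMeans(Xd)
    expect_true(all(abs(m_draw - mu_hat) < 4 * sd_hat / sqrt(600)))
  }

  # degenerate stratum: all rows identical -> draws collapse to the point
  dd <- tibble::tibble(y = rep(c(0, 1), each = 3), x_e = 0,
                       x1 = rep(c(1, 4), each = 3), x2 = rep(c(2, 0), each = 3))
  sdg <- assign_strata(dd)
  tabd <- make_table(sdg, p_select = c(1 / 2, 1))
  outd <- parametric_ip_bag_samples(sdg, tabd, m = 1L, seed = 1L)[[1L]]
  expect_true(all(abs(outd$x1[outd$.stratum == 1L] - 1) < 1e-3))

  expect_error(parametric_ip_bag_samples(s, tab, family = "gamma"),
               "unsupported")
})

test_that("corrected samples keep every input stratum and its labels", {
  s <- make_four_strata(n_cell = 12L, p = 2L, seed = 5L)
  tab <- four_strata_weights(s)
  key <- function(d) {
    u <- dplyr::distinct(bare(d)[c(".stratum", "y", "x_e")])
    bare(u[order(u$.stratum), ])
  }
  ref <- key(s)
  specs <- list(
    correct_none(s),
    ip_oversample(s, tab),
    smote_stratified(s, tab, seed = 1L),
    ip_bagging_samples(s, tab, m = 2L, seed = 1L)[[1L]],
    costing_samples(s, tab, m = 2L, seed = 1L)[[1L]],
    stochastic_ip_oversample(s, tab, m = 1L, seed = 1L)[[1L]],
    parametric_ip_bag_samples(s, tab, m = 1L, seed = 1L)[[1L]])
  for (d in specs) {
    expect_equal(key(d), ref)
  }
})
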