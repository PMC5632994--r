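# Fixtures shared across test files; everything is generated in code.

# A stratified sample with the four (x_e, y) cells of a two-phase design,
# n_cell rows per cell and p Gaussian main features.
make_four_strata <- function(n_cell = 10L, p = 2L, seed = 1L,
                             mu_shift = 0.5) {
  withr::with_seed(seed, {
    cells <- expand.grid(x_e = c(0, 1), y = c(0, 1))
    rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      X <- matrix(rnorm(n_cell * p, mean = mu_shift * cells$y[i]), n_cell, p)
      d <- data.frame(y = cells$y[i], x_e = cells$x_e[i])
      if (p > 0) d <- cbind(d, as.data.frame(X))
      d
    }))
    if (p > 0) names(rows)[-(1:2)] <- paste0("x", seq_len(p))
    assign_strata(tibble::as_tibble(rows))
  })
}

# Weight table for a stratified sample, from explicit per-stratum selection
# probabilities (in stratum-id order).
make_table <- function(sample, p_select) {
  stratum_table(sample, p_select = p_select)
}

# Drop bookkeeping attributes (provenance, drawn rows) for whole-value
# comparisons.
bare <- function(d) {
  d <- tibble::as_tibble(d)
  for (a in setdiff(names(attributes(d)), c("names", "row.names", "class"))) {
    attr(d, a) <- NULL
  }
  class(d) <- class(tibble::tibble())
  d
}

# A studied stratum of n rows from N(mu, Sigma) with IP weight w, plus a
# two-row reference stratum holding the maximal selection probability (the
# weight normalisation pins w = 1 there).  The studied stratum has id 1.
make_weighted_stratum <- function(n, mu, Sigma, w, seed = NULL) {
  s <- make_single_stratum(n, mu, Sigma, seed = seed, y = 0, x_e = 0)
  ref <- tibble::as_tibble(s)[1:2, ]
  ref$y <- 1
  ref[paste0("x", seq_along(mu))] <- 0
  s_all <- assign_strata(dplyr::bind_rows(tibble::as_tibble(s), ref))
  tab <- stratum_table(s_all, p_select = c(1 / w, 1))
  list(sample = s_all, table = tab)
}

# A single-stratum sample of n rows from N(mu, Sigma), as a stratified_tbl.
make_single_stratum <- function(n, mu, Sigma, seed = NULL, y = 0, x_e = 0) {
  gen <- function() {
    p <- length(mu)
    R <- chol(Sigma)
    X <- matrix(rnorm(n * p), n, p) %*% R
    X <- sweep(X, 2L, mu, `+`)
    d <- tibble::tibble(y = rep(y, n), x_e = rep(x_e, n))
    Xd <- tibble::as_tibble(as.data.frame(X))
    names(Xd) <- paste0("x", seq_len(p))
    assign_strata(dplyr::bind_cols(d, Xd))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
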