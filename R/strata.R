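#' Assign stratum labels from an outcome and a categorical stratum feature
#'
#' In a stratified (e.g. two-phase case-control) sample, a *stratum* is a
#' group of observations sharing one selection probability.  Here strata are
#' the cells of (stratum feature, outcome): a study that enriches a rare
#' exposure and a rare outcome yields up to `levels(x_e) * 2` strata.
#' `assign_strata()` derives an integer stratum id per row, ordered
#' lexicographically by (stratum level, outcome), and records which columns
#' play which role so that downstream correction and fitting functions need
#' no further configuration.
#'
#' @param data A data frame with one row per observation.
#' @param outcome Name of the binary outcome column.  Accepted encodings:
#'   0/1 numeric, logical, or a factor/character with exactly two distinct
#'   values (mapped to 0/1 in sort order).  Stored as 0/1 numeric.
#' @param stratum Name of the categorical stratum feature (an exposure in a
#'   two-phase case-control design).  Factors, characters, logicals and
#'   integer-valued numerics are accepted; continuous values are rejected
#'   because selection probabilities are only constant within discrete cells.
#' @param features Character vector of main-feature column names.  Defaults
#'   to every remaining column.
#'
#' @return A tibble of class `stratified_tbl`: the input columns plus an
#'   integer `.stratum` column, with the column roles stored in
#'   `attr(, "roles")`.
#'
#' @examples
#' d <- tibble::tibble(y = c(0, 1, 0, 1), x_e = c(0, 0, 1, 1), x1 = rnorm(4))
#' s <- assign_strata(d, outcome = "y", stratum = "x_e")
#' s$.stratum
#' @export
assign_strata <- function(data, outcome = "y", stratum = "x_e",
                          features = NULL) {
  data <- tibble::as_tibble(data)
  for (col in c(outcome, stratum)) {
    if (!col %in% names(data)) {
      stop_ipcorr("column '%s' not found in `data`", col)
    }
  }
  y <- data[[outcome]]
  xe <- data[[stratum]]
  if (anyNA(y) || anyNA(xe)) {
    stop_ipcorr("missing values in outcome or stratum feature are not allowed")
  }
  data[[outcome]] <- check_binary_outcome(y, outcome)
  check_categorical(xe, stratum)

  if (is.null(features)) {
    features <- setdiff(names(data), c(outcome, stratum, ".stratum"))
  } else if (!all(features %in% names(data))) {
    stop_ipcorr("feature column(s) not found: %s",
                paste(setdiff(features, names(data)), collapse = ", "))
  }

  lev <- stratum_levels(xe)
  key <- paste(match(as.character(xe), lev), data[[outcome]])
  all_keys <- paste(rep(seq_along(lev), each = 2L), rep(c(0, 1), length(lev)))
  present <- all_keys[all_keys %in% key]
  data$.stratum <- match(key, present)
  new_stratified(data, outcome = outcome, stratum = stratum,
                 features = features)
}

new_stratified <- function(data, outcome, stratum, features) {
  data <- tibble::as_tibble(data)
  attr(data, "roles") <- list(outcome = outcome, stratum = stratum,
                              features = features)
  class(data) <- c("stratified_tbl", class(tibble::tibble()))
  data
}

#' @export
print.stratified_tbl <- function(x, ...) {
  r <- roles(x)
  cat(sprintf("Stratified sample: %d rows, %d strata (outcome '%s', stratum feature '%s', %d main features)\n",
              nrow(x), length(unique(x$.stratum)), r$outcome, r$stratum,
              length(r$features)))
  NextMethod()
}

#' Column roles of a stratified sample
#'
#' @param x A `stratified_tbl`.
#' @return A list with elements `outcome`, `stratum`, `features`.
#' @export
roles <- function(x) {
  r <- attr(x, "roles")
  if (is.null(r)) {
    stop_ipcorr("`x` carries no column roles; run assign_strata() first")
  }
  r
}

check_binary_outcome <- function(y, name) {
  if (is.logical(y)) return(as.numeric(y))
  if (is.factor(y) || is.character(y)) {
    vals <- sort(unique(as.character(y)))
    if (length(vals) != 2L) {
      stop_ipcorr("outcome '%s' must be binary; found %d distinct values",
                  name, length(vals))
    }
    return(as.numeric(as.character(y) == vals[2L]))
  }
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) {
      stop_ipcorr("outcome '%s' must be binary (0/1); found other values", name)
    }
    return(as.numeric(y))
  }
  stop_ipcorr("outcome '%s' has unsupported type '%s'", name, class(y)[1L])
}

check_categorical <- function(x, name) {
  if (is.factor(x) || is.character(x) || is.logical(x)) return(invisible(TRUE))
  if (is.numeric(x)) {
    if (all(abs(x - round(x)) < 1e-8)) return(invisible(TRUE))
    stop_ipcorr(
      "stratum feature '%s' looks continuous; selection strata require a categorical feature",
      name)
  }
  stop_ipcorr("stratum feature '%s' has unsupported type '%s'", name,
              class(x)[1L])
}

stratum_levels <- function(x) {
  if (is.factor(x)) levels(x)[levels(x) %in% as.character(unique(x))]
  else as.character(sort(unique(x)))
}

#' Per-stratum selection probabilities
#'
#' The selection probability of stratum *h* is `n_h / N_h`: the chance that a
#' population member of that cell entered the sample.
#'
#' @param n_h Integer vector of per-stratum sample sizes.
#' @param N_h Integer vector of per-stratum population sizes.
#' @return Numeric vector `n_h / N_h`.
#' @export
selection_probabilities <- function(n_h, N_h) {
  if (length(n_h) != length(N_h)) {
    stop_ipcorr("`n_h` and `N_h` must have equal length")
  }
  if (any(N_h <= 0)) stop_ipcorr("population counts `N_h` must be positive")
  if (any(n_h <= 0)) stop_ipcorr("sample counts `n_h` must be positive")
  if (any(n_h > N_h)) {
    stop_ipcorr("sample counts exceed population counts in stratum %s",
                paste(which(n_h > N_h), collapse = ", "))
  }
  n_h / N_h
}

#' Integer inverse-probability weights
#'
#' The IP weight of stratum *h* is the ratio of the largest selection
#' probability to the stratum's own, rounded to the closest integer (halves
#' away from zero).  The most strongly selected stratum always gets weight 1,
#' so the weights are replication factors that restore population
#' proportions with the smallest possible reconstructed sample.
#'
#' @param p_select Per-stratum selection probabilities in (0, 1].
#' @return Integer weights `w_h >= 1`.
#' @seealso [ip_weight_ratios()] for the unrounded ratios.
#' @export
ip_weights <- function(p_select) {
  r <- ip_weight_ratios(p_select)
  w <- round_half_up(r)
  w[w < 1L] <- 1L  # cannot occur for valid input, but guard anyway
  as.integer(w)
}

#' Unrounded inverse-probability weight ratios
#'
#' Diagnostic companion to [ip_weights()]: the raw ratios
#' `max(p_select) / p_select` before integer rounding, useful for judging how
#' much the rounding step distorts (e.g. a ratio of 1.5 rounds to 2).
#'
#' @inheritParams ip_weights
#' @return Numeric ratios `>= 1`.
#' @export
ip_weight_ratios <- function(p_select) {
  if (length(p_select) == 0L) stop_ipcorr("`p_select` is empty")
  if (any(!is.finite(p_select)) || any(p_select <= 0) || any(p_select > 1)) {
    stop_ipcorr("selection probabilities must lie in (0, 1]")
  }
  max(p_select) / p_select
}

#' Size of the reweighted sample
#'
#' `n' = sum(n_h * w_h)`, the number of observations after replicating each
#' stratum by its integer IP weight.  Always `>= n`, with equality iff all
#' weights are 1.
#'
#' @param n_h Per-stratum sample sizes.
#' @param w_h Per-stratum integer IP weights.
#' @return A single number `n'`.
#' @export
reweighted_size <- function(n_h, w_h) {
  if (length(n_h) != length(w_h)) {
    stop_ipcorr("`n_h` and `w_h` must have equal length")
  }
  if (any(n_h <= 0) || any(w_h < 1)) {
    stop_ipcorr("`n_h` must be positive and `w_h` >= 1")
  }
  sum(n_h * w_h)
}

#' Build the per-stratum weight table
#'
#' Combines stratum counts with either population counts or selection
#' probabilities into the table that every correction method consumes:
#' sample size `n_h`, population size `N_h`, selection probability
#' `p_select`, raw weight ratio and integer IP weight `w_h` per stratum.
#' The reweighted total `n'` is attached as attribute `n_prime`.
#'
#' @param sample A `stratified_tbl` from [assign_strata()].
#' @param N_h Optional per-stratum population counts, in stratum-id order.
#' @param p_select Optional per-stratum selection probabilities, in
#'   stratum-id order.  If both `N_h` and `p_select` are given they must
#'   agree to a relative tolerance of 1e-9.
#' @return A tibble with one row per stratum and columns `stratum_id`,
#'   `stratum`, `outcome`, `n_h`, `N_h`, `p_select`, `ratio`, `w_h`.
#' @examples
#' d <- tibble::tibble(y = rep(c(0, 1), each = 4), x_e = rep(c(0, 1), 4))
#' s <- assign_strata(d, features = character(0))
#' stratum_table(s, N_h = c(40, 4, 20, 2))
#' @export
stratum_table <- function(sample, N_h = NULL, p_select = NULL) {
  r <- roles(sample)
  info <- dplyr::distinct(
    tibble::tibble(stratum_id = sample$.stratum,
                   stratum = as.character(sample[[r$stratum]]),
                   outcome = sample[[r$outcome]]))
  info <- dplyr::arrange(info, .data$stratum_id)
  counts <- tabulate(sample$.stratum, nbins = nrow(info))
  H <- nrow(info)

  if (is.null(N_h) && is.null(p_select)) {
    stop_ipcorr("supply `N_h` (population counts) or `p_select` (selection probabilities)")
  }
  if (!is.null(N_h)) {
    if (length(N_h) != H) {
      stop_ipcorr("`N_h` must have one entry per stratum (%d)", H)
    }
    p_from_counts <- selection_probabilities(counts, N_h)
    if (!is.null(p_select)) {
      if (length(p_select) != H) {
        stop_ipcorr("`p_select` must have one entry per stratum (%d)", H)
      }
      if (any(abs(p_select - p_from_counts) > 1e-9 * pmax(p_from_counts, 1e-300))) {
        stop_ipcorr("`p_select` and `n_h / N_h` disagree beyond relative tolerance 1e-9")
      }
    }
    p_select <- p_from_counts
  } else {
    if (length(p_select) != H) {
      stop_ipcorr("`p_select` must have one entry per stratum (%d)", H)
    }
    if (any(p_select <= 0 | p_select > 1)) {
      stop_ipcorr("selection probabilities must lie in (0, 1]")
    }
    N_h <- rep(NA_real_, H)
  }

  out <- tibble::tibble(
    stratum_id = info$stratum_id,
    stratum = info$stratum,
    outcome = info$outcome,
    n_h = counts,
    N_h = as.numeric(N_h),
    p_select = p_select,
    ratio = ip_weight_ratios(p_select),
    w_h = ip_weights(p_select))
  attr(out, "n_prime") <- reweighted_size(out$n_h, out$w_h)
  class(out) <- c("stratum_tbl", class(out))
  out
}

#' @export
print.stratum_tbl <- function(x, ...) {
  NextMethod()
  cat(sprintf("n' (reweighted size) = %d\n", as.integer(n_prime(x))))
  invisible(x)
}

#' Reweighted size stored on a stratum table
#'
#' @param table A stratum table from [stratum_table()].
#' @return The scalar `n'`.
#' @export
n_prime <- function(table) {
  np <- attr(table, "n_prime")
  if (is.null(np)) np <- reweighted_size(table$n_h, table$w_h)
  np
}

# Per-row weight lookup; errors if a stratum present in `sample` is missing
# from the weight table.
row_weights <- function(sample, weights) {
  idx <- match(sample$.stratum, weights$stratum_id)
  if (anyNA(idx)) {
    stop_ipcorr("stratum id(s) %s missing from the weight table",
                paste(unique(sample$.stratum[is.na(idx)]), collapse = ", "))
  }
  weights$w_h[idx]
}
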