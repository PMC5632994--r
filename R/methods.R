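#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted logistic scorer
#'
#' @param x An `ipcorr_logistic` object.
#' @param conf.int Add Wald confidence intervals.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value` (and `conf.low`/`conf.high`).
#' @method tidy ipcorr_logistic
#' @export
tidy.ipcorr_logistic <- function(x, conf.int = FALSE, conf.level = 0.95,
                                 ...) {
  sm <- stats::coef(summary(x$fit))
  out <- tibble::tibble(term = rownames(sm), estimate = sm[, 1L],
                        std.error = sm[, 2L], statistic = sm[, 3L],
                        p.value = sm[, 4L])
  if (conf.int) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' Glance at a fitted logistic scorer
#'
#' @param x An `ipcorr_logistic` object.
#' @param ... Unused.
#' @return A one-row tibble: `nobs`, `deviance`, `aic`, `converged`,
#'   `separation`.
#' @method glance ipcorr_logistic
#' @export
glance.ipcorr_logistic <- function(x, ...) {
  tibble::tibble(nobs = stats::nobs(x$fit),
                 deviance = stats::deviance(x$fit),
                 aic = stats::AIC(x$fit),
                 converged = x$fit$converged,
                 separation = x$separation)
}

#' Tidy an averaged ensemble of logistic members
#'
#' @param x An `ipcorr_ensemble` object whose members are logistic fits.
#' @param ... Unused.
#' @return A tibble of coefficient means and standard deviations across
#'   ensemble members.
#' @method tidy ipcorr_ensemble
#' @export
tidy.ipcorr_ensemble <- function(x, ...) {
  if (!inherits(x$members[[1L]], "ipcorr_logistic")) {
    stop_ipcorr("tidy() is only defined for ensembles of logistic members")
  }
  cf <- vapply(x$members, function(mb) stats::coef(mb$fit),
               numeric(length(stats::coef(x$members[[1L]]$fit))))
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1L,
                                     dimnames = list(names(stats::coef(x$members[[1L]]$fit))))
  tibble::tibble(term = rownames(cf),
                 estimate = rowMeans(cf),
                 member_sd = apply(cf, 1L, stats::sd))
}

#' Glance at an ensemble scorer
#' @param x An `ipcorr_ensemble` object.
#' @param ... Unused.
#' @return A one-row tibble with the member count, classifier kind and
#'   correction method.
#' @method glance ipcorr_ensemble
#' @export
glance.ipcorr_ensemble <- function(x, ...) {
  tibble::tibble(members = length(x$members), kind = x$kind,
                 method = x$method)
}

#' Tidy a study result
#'
#' @param x A `study_result` from [run_study()].
#' @param ... Unused.
#' @return The long AUC table as a plain tibble.
#' @method tidy study_result
#' @export
tidy.study_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' Glance at a study result
#'
#' @param x A `study_result` from [run_study()].
#' @param ... Unused.
#' @return One row per (classifier, correction) with the replicate count
#'   and mean AUC.
#' @method glance study_result
#' @export
glance.study_result <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tidy(x), .data$classifier,
                                   .data$correction),
                   replicates = dplyr::n(),
                   mean_auc = mean(.data$auc), .groups = "drop")
}

#' Plot correction effects from a study result
#'
#' Per classifier, the 95% confidence interval of each correction's mean
#' AUC difference against no correction (the linear-model coefficients of
#' [compare_methods()]), with the reference at zero.
#'
#' @param object A `study_result`.
#' @param ... Passed to [compare_methods()].
#' @return A ggplot object.
#' @method autoplot study_result
#' @export
autoplot.study_result <- function(object, ...) {
  autoplot(compare_methods(tidy(object), ...))
}

#' @rdname autoplot.study_result
#' @method autoplot ipcorr_comparison
#' @export
autoplot.ipcorr_comparison <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$correction != "none")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = .data$correction)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high,
                                          colour = .data$significant)) +
    ggplot2::facet_wrap(~classifier) +
    ggplot2::labs(x = "AUC difference vs. no correction (95% CI)",
                  y = NULL, colour = "CI excludes 0") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.study_result
#' @param x A `study_result`.
#' @param y Unused.
#' @export
plot.study_result <- function(x, y, ...) print(autoplot(x, ...))
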