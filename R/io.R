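#' Read a learning sample from CSV
#'
#' Reads a comma-separated file (header row mandatory, `.` decimal, UTF-8)
#' and assigns strata from the named outcome and stratum columns.  Main
#' features must parse as numeric.
#'
#' @param path Path to the CSV file.
#' @param outcome,stratum,features Column roles, as in [assign_strata()];
#'   `features` defaults to every remaining column.
#' @return A `stratified_tbl`.
#' @export
read_sample <- function(path, outcome = "y", stratum = "x_e",
                        features = NULL) {
  if (!file.exists(path)) stop_ipcorr("file not found: %s", path)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0L) stop_ipcorr("empty input file: %s", path)
  for (col in c(outcome, stratum, features)) {
    if (!col %in% names(tbl)) {
      stop_ipcorr("column '%s' not found in %s", col, path)
    }
  }
  s <- assign_strata(tbl, outcome = outcome, stratum = stratum,
                     features = features)
  bad <- roles(s)$features[!vapply(tibble::as_tibble(s)[roles(s)$features],
                                   is.numeric, logical(1))]
  if (length(bad) > 0L) {
    stop_ipcorr("main feature column(s) not numeric: %s",
                paste(bad, collapse = ", "))
  }
  s
}

#' Write a (corrected) sample to CSV
#'
#' Adds a `provenance` column naming the correction that produced the
#' sample (when known) and writes with full round-trip precision.
#'
#' @param sample A `stratified_tbl` or corrected sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample <- function(sample, path) {
  tbl <- tibble::as_tibble(sample)
  prov <- provenance(sample)
  if (!is.null(prov)) tbl$provenance <- prov
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Serialize a stratum table to JSON
#'
#' Layout: `{stratum_id: {n_h, N_h, p_select, w_h}}`.
#'
#' @param table A stratum table from [stratum_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stratum_table <- function(table, path) {
  obj <- stats::setNames(lapply(seq_len(nrow(table)), function(i) {
    list(n_h = table$n_h[i], N_h = table$N_h[i],
         p_select = table$p_select[i], w_h = table$w_h[i])
  }), as.character(table$stratum_id))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a stratum table from JSON
#'
#' @param path A file written by [write_stratum_table()].
#' @return A tibble with columns `stratum_id`, `n_h`, `N_h`, `p_select`,
#'   `w_h` (and `ratio` recomputed).
#' @export
read_stratum_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- as.integer(names(obj))
  out <- tibble::tibble(
    stratum_id = ids,
    n_h = unname(vapply(obj, function(e) as.numeric(e$n_h), numeric(1))),
    N_h = unname(vapply(obj, function(e) as.numeric(e$N_h %||% NA_real_),
                        numeric(1))),
    p_select = unname(vapply(obj, function(e) as.numeric(e$p_select),
                             numeric(1))),
    w_h = unname(vapply(obj, function(e) as.integer(e$w_h), integer(1))))
  out <- out[order(out$stratum_id), ]
  out$ratio <- ip_weight_ratios(out$p_select)
  attr(out, "n_prime") <- reweighted_size(out$n_h, out$w_h)
  class(out) <- c("stratum_tbl", class(out))
  out
}

#' Serialize a correction spec to JSON
#' @param spec A [correction_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correction_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a correction spec from JSON
#' @param path A file written by [write_correction_spec()].
#' @return A [correction_spec()].
#' @export
read_correction_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  correction_spec(method = obj$method, m = obj$m, k = obj$k %||% 5L,
                  family = obj$family %||% "normal", seed = obj$seed)
}

#' Persist a fitted scorer
#'
#' Saves the scorer together with a package-version tag so stale artifacts
#' are detected at load time.
#'
#' @param object A fitted scorer.
#' @param path Output path (an RDS artifact).
#' @return `path`, invisibly.
#' @export
save_scorer <- function(object, path) {
  if (!inherits(object, "ipcorr_scorer")) {
    stop_ipcorr("`object` is not a fitted ipcorr scorer")
  }
  saveRDS(list(version = as.character(utils::packageVersion("ipcorr")),
               scorer = object), path)
  invisible(path)
}

#' Load a persisted scorer
#' @param path A file written by [save_scorer()].
#' @return The fitted scorer.
#' @export
load_scorer <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$version) ||
      !inherits(obj$scorer, "ipcorr_scorer")) {
    stop_ipcorr("%s is not an ipcorr scorer artifact", path)
  }
  obj$scorer
}
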