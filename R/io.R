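# Delimited-text I/O for count and composition tables, and JSON
# serialization of fitted models. TSV is the canonical dialect (tab
# separated, UTF-8, '.' decimal, first column = row labels, header = column
# labels); CSV is accepted on read via the file extension or `sep`.

#' @noRd
guess_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a count table from delimited text
#'
#' @param path TSV (default) or CSV file; first column holds row labels, the
#'   header holds column labels, cells are nonnegative integers.
#' @param transpose set `TRUE` when the file is taxa-by-samples; the result
#'   is always samples-as-rows.
#' @param sep field separator override (guessed from the extension).
#' @return validated integer count matrix (samples x taxa).
#' @export
read_count_table <- function(path, transpose = FALSE, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = guess_sep(path, sep),
                   row.names = 1, check.names = FALSE,
                   stringsAsFactors = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("non-numeric cells in ", path, call. = FALSE)
  if (transpose) M <- t(M)
  validate_counts(M, require_positive_totals = FALSE)
}

#' Write a count or composition table as TSV
#'
#' @param M matrix with row and column labels.
#' @param path output file.
#' @param label header name of the row-label column.
#' @export
write_count_table <- function(M, path, label = "sample_id") {
  df <- data.frame(rownames(M), M, check.names = FALSE)
  names(df)[1] <- label
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a composition table (simplex-valued rows)
#'
#' @inheritParams read_count_table
#' @return validated composition matrix.
#' @export
read_composition_table <- function(path, transpose = FALSE, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = guess_sep(path, sep),
                   row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  if (transpose) M <- t(M)
  validate_composition(M)
}

#' Serialize a fitted model to JSON
#'
#' Writes all hyperparameters, variational parameters, the objective trace
#' and the fit configuration to a single structured text file that
#' [read_bmdd_fit()] restores exactly.
#'
#' @param fit a [bmdd_fit()] object.
#' @param path output `.json` file.
#' @export
write_bmdd_fit <- function(fit, path) {
  payload <- list(
    package_version = as.character(packageVersion("bmdd")),
    pi = unname(fit$pi), alpha0 = unname(fit$alpha0),
    alpha1 = unname(fit$alpha1),
    beta = fit$beta, gamma = fit$gamma,
    objective_trace = fit$objective_trace,
    converged = fit$converged, n_iter = fit$n_iter,
    sample_ids = fit$sample_ids, taxon_ids = fit$taxon_ids,
    config = unclass(fit$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a fitted model written by [write_bmdd_fit()]
#'
#' @param path `.json` file.
#' @return a `bmdd_fit` object.
#' @export
read_bmdd_fit <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- as.matrix(p$beta)
  gamma <- as.matrix(p$gamma)
  dimnames(beta) <- dimnames(gamma) <- list(p$sample_ids, p$taxon_ids)
  structure(list(
    pi = setNames(p$pi, p$taxon_ids),
    alpha0 = setNames(p$alpha0, p$taxon_ids),
    alpha1 = setNames(p$alpha1, p$taxon_ids),
    beta = beta, gamma = gamma,
    objective_trace = p$objective_trace,
    converged = p$converged, n_iter = p$n_iter,
    config = do.call(bmdd_config, p$config[setdiff(names(p$config), NULL)]),
    sample_ids = p$sample_ids, taxon_ids = p$taxon_ids,
    n = nrow(beta), m = ncol(beta)
  ), class = "bmdd_fit")
}
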