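# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# log(sum(exp(x))) without overflow; -Inf-safe
#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# x*log(y) with the 0*log(0) = 0 convention, vectorized
#' @noRd
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

# Bernoulli entropy, elementwise, safe at 0 and 1
#' @noRd
bern_entropy <- function(g) {
  -xlogy(g, g) - xlogy(1 - g, 1 - g)
}

# Run code with a temporary RNG state seeded at `seed`; restores the
# caller's .Random.seed so library code does not perturb user scripts.
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Validate a count matrix
#'
#' Checks the invariants every modeling function in the package relies on:
#' a numeric matrix of finite, nonnegative, integral entries with unique
#' sample (row) and taxon (column) labels and strictly positive per-sample
#' totals. Missing dimnames are filled in with `sample1..n` / `taxon1..m`.
#'
#' @param W numeric matrix, samples in rows, taxa in columns.
#' @param require_positive_totals error on samples with zero total reads
#'   (default `TRUE`; raw observed tables should never contain them).
#' @return the validated matrix (with dimnames), invisibly usable downstream.
#' @export
validate_counts <- function(W, require_positive_totals = TRUE) {
  if (!is.matrix(W) || !is.numeric(W)) {
    stop("counts must be a numeric matrix (samples x taxa)", call. = FALSE)
  }
  if (anyNA(W) || any(!is.finite(W))) {
    stop("counts contain missing or non-finite values", call. = FALSE)
  }
  if (any(W < 0)) {
    bad <- which(W < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row %d (sample '%s'), column %d",
                 bad[1], rownames(W)[bad[1]] %||% bad[1], bad[2]),
         call. = FALSE)
  }
  if (any(abs(W - round(W)) > 1e-8)) {
    bad <- which(abs(W - round(W)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at row %d, column %d", bad[1], bad[2]),
         call. = FALSE)
  }
  if (is.null(rownames(W))) rownames(W) <- paste0("sample", seq_len(nrow(W)))
  if (is.null(colnames(W))) colnames(W) <- paste0("taxon", seq_len(ncol(W)))
  if (anyDuplicated(rownames(W))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(W))) stop("duplicate taxon ids", call. = FALSE)
  if (require_positive_totals && any(rowSums(W) <= 0)) {
    stop("samples with zero total reads: ",
         paste(rownames(W)[rowSums(W) <= 0], collapse = ", "), call. = FALSE)
  }
  W
}

# Validate a hyperparameter list(pi, alpha0, alpha1); returns it.
#' @noRd
validate_hyperparams <- function(hp, m = NULL) {
  stopifnot(is.list(hp), all(c("pi", "alpha0", "alpha1") %in% names(hp)))
  if (!is.null(m) &&
      (length(hp$pi) != m || length(hp$alpha0) != m || length(hp$alpha1) != m)) {
    stop("hyperparameter vectors must have one entry per taxon", call. = FALSE)
  }
  if (any(!is.finite(hp$pi)) || any(hp$pi < 0) || any(hp$pi >= 1)) {
    stop("pi must satisfy 0 <= pi < 1", call. = FALSE)
  }
  if (any(!is.finite(hp$alpha0)) || any(hp$alpha0 <= 0) ||
      any(!is.finite(hp$alpha1)) || any(hp$alpha1 <= 0)) {
    stop("alpha0 and alpha1 must be strictly positive", call. = FALSE)
  }
  hp
}

# Validate a composition matrix: rows on the simplex within tol.
#' @noRd
validate_composition <- function(X, tol = 1e-8) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("composition must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop("composition contains non-finite values", call. = FALSE)
  }
  if (any(X < -tol)) stop("composition has negative entries", call. = FALSE)
  rs <- rowSums(X)
  if (any(rs <= 0)) stop("composition has all-zero rows", call. = FALSE)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("composition rows must sum to 1", call. = FALSE)
  }
  X
}
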