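# Fifteen-metric battery comparing an estimated composition matrix against
# the truth. Three families: (i) raw matrix distances, (ii) preservation of
# per-sample ecological summaries, (iii) preservation of per-taxon
# distributional summaries. Every metric is >= 0 and 0 iff est == truth;
# smaller is better.

# Gini coefficient of a nonnegative vector (mean absolute difference form).
#' @noRd
gini_coef <- function(x) {
  n <- length(x)
  mu <- mean(x)
  if (mu == 0) return(0)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mu)
}

# Kolmogorov-Smirnov distance between two equal-length empirical samples.
#' @noRd
ks_dist <- function(a, b) {
  g <- sort(c(a, b))
  Fa <- ecdf(a)(g)
  Fb <- ecdf(b)(g)
  max(abs(Fa - Fb))
}

# Pearson/Spearman taxon correlation matrix with zero-variance columns
# mapped to zero correlation rather than NA.
#' @noRd
safe_cor <- function(X, method) {
  C <- suppressWarnings(cor(X, method = method))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  C
}

#' Compare an estimated composition matrix with the truth
#'
#' Computes fifteen distances between paired composition matrices:
#'
#' * **Matrix similarity** — `mse` (elementwise mean squared error),
#'   `sample_dist` (mean per-sample Euclidean distance), `taxon_dist`
#'   (mean per-taxon Euclidean distance).
#' * **Sample-wise ecology** — mean absolute difference of per-sample
#'   `shannon` and `simpson` diversity indices, and mean per-sample
#'   `bray_curtis`, `kl` (Kullback-Leibler of truth from estimate),
#'   `jensen_shannon`, and `hellinger` divergences between paired rows.
#' * **Taxon-wise distribution** — mean absolute difference of per-taxon
#'   `gini` coefficients and `cv` (coefficients of variation), `mean_sd`
#'   (mean Euclidean distance between per-taxon (mean, sd) pairs), mean
#'   per-taxon `ks` and 1-Wasserstein (`wasserstein`) distances between the
#'   columns viewed as empirical distributions over samples, and
#'   `correlation` (Frobenius distance between the two m x m taxon-taxon
#'   correlation matrices).
#'
#' Zeros in the estimate are floored at `1e-12` inside the logarithmic
#' divergences so they stay finite; KL is computed as `KL(truth || est)`,
#' penalizing underestimation of truly present taxa.
#'
#' @param est,truth n x m composition matrices (rows on the simplex), with
#'   matching dimensions and label order.
#' @param cor_method `"pearson"` (default) or `"spearman"` for the taxon
#'   correlation metric.
#' @return object of class `bmdd_metrics`: named list of 15 nonnegative
#'   scalars plus `meta` (n, m, definitions).
#' @export
evaluate_composition <- function(est, truth, cor_method = c("pearson",
                                                            "spearman")) {
  cor_method <- match.arg(cor_method)
  est <- validate_composition(est)
  truth <- validate_composition(truth)
  if (!all(dim(est) == dim(truth))) {
    stop("estimated and true matrices must have identical shape",
         call. = FALSE)
  }
  if (!is.null(rownames(est)) && !is.null(rownames(truth)) &&
      !identical(rownames(est), rownames(truth))) {
    stop("sample label order differs between matrices", call. = FALSE)
  }
  n <- nrow(est)
  m <- ncol(est)
  eps <- 1e-12
  D <- est - truth

  shannon <- function(X) vegan::diversity(X, index = "shannon")
  simpson <- function(X) vegan::diversity(X, index = "simpson")

  row_kl <- function(p, q) rowSums(xlogy(p, p) - xlogy(p, pmax(q, eps)))
  js <- vapply(seq_len(n), function(i) {
    p <- truth[i, ]; q <- pmax(est[i, ], eps); mid <- (p + q) / 2
    0.5 * sum(xlogy(p, p / mid)) + 0.5 * sum(xlogy(q, q / mid))
  }, numeric(1))

  col_stat <- function(f) {
    vapply(seq_len(m), function(j) f(est[, j], truth[, j]), numeric(1))
  }

  # single-sample matrices have no spread; treat sd as 0 rather than NA
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  mean_sd_pairs <- col_stat(function(a, b) {
    sqrt((mean(a) - mean(b))^2 + (sd0(a) - sd0(b))^2)
  })
  cv <- function(x) if (mean(x) > 0) sd0(x) / mean(x) else 0

  scores <- list(
    mse = mean(D^2),
    sample_dist = mean(sqrt(rowSums(D^2))),
    taxon_dist = mean(sqrt(colSums(D^2))),
    shannon = mean(abs(shannon(est) - shannon(truth))),
    simpson = mean(abs(simpson(est) - simpson(truth))),
    bray_curtis = mean(rowSums(abs(D)) / rowSums(est + truth)),
    kl = mean(row_kl(truth, est)),
    jensen_shannon = mean(js),
    hellinger = mean(sqrt(0.5 * rowSums((sqrt(est) - sqrt(truth))^2))),
    gini = mean(abs(apply(est, 2, gini_coef) - apply(truth, 2, gini_coef))),
    mean_sd = mean(mean_sd_pairs),
    cv = mean(abs(apply(est, 2, cv) - apply(truth, 2, cv))),
    ks = mean(col_stat(ks_dist)),
    wasserstein = mean(col_stat(function(a, b) mean(abs(sort(a) - sort(b))))),
    correlation = norm(safe_cor(est, cor_method) - safe_cor(truth, cor_method),
                       type = "F")
  )
  structure(c(scores, list(meta = list(n = n, m = m,
                                       cor_method = cor_method))),
            class = "bmdd_metrics")
}

#' @export
print.bmdd_metrics <- function(x, ...) {
  meta <- x$meta
  cat(sprintf("Composition metric report (%d samples x %d taxa)\n",
              meta$n, meta$m))
  keys <- setdiff(names(x), "meta")
  for (k in keys) cat(sprintf("  %-15s %.6g\n", k, x[[k]]))
  invisible(x)
}

#' @export
as.data.frame.bmdd_metrics <- function(x, ...) {
  keys <- setdiff(names(x), "meta")
  data.frame(metric = keys, value = unlist(x[keys], use.names = FALSE))
}
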