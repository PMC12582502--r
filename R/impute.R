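# Posterior-based imputation, posterior sampling, posterior predictive
# checks, naive baselines, and real-data preprocessing filters.

#' Posterior mean composition
#'
#' The imputed composition under the fitted mean-field posterior: each row is
#' the mean of its Dirichlet factor, `X_ij = beta_ij / sum_k beta_ik`. The
#' result is strictly positive — no zeros survive imputation.
#'
#' @param fit a [bmdd_fit()] object (or any list with a `beta` matrix).
#' @return n x m composition matrix.
#' @export
posterior_mean <- function(fit) {
  beta <- fit$beta
  beta / rowSums(beta)
}

#' Draw posterior composition samples
#'
#' Draws `L` independent composition matrices from the variational posterior:
#' row `i` of each draw comes from `Dirichlet(beta_i)` (under the mean-field
#' factorization the composition factor is independent of the mode
#' indicators, so this is the full variational posterior of the composition).
#'
#' Dirichlet marginals with very small concentrations (imputed zero cells)
#' place most mass within a hair of zero, below double precision; raw gamma
#' draws then underflow to exact zeros. Draws are therefore floored at
#' `floor` and renormalized, which keeps every sampled composition strictly
#' positive and log-transformable while perturbing row sums by at most
#' `m * floor`.
#'
#' @param fit a [bmdd_fit()] object.
#' @param L number of draws (>= 1).
#' @param seed integer seed; identical seeds give identical sample sets.
#' @param floor numerical floor applied to each sampled relative abundance
#'   before renormalization (default `1e-10`).
#' @return object of class `bmdd_samples`: list with `samples` (length-L list
#'   of n x m composition matrices), `L`, `seed`.
#' @export
posterior_sample <- function(fit, L, seed = 1L, floor = 1e-10) {
  stopifnot(L >= 1, floor >= 0)
  beta <- fit$beta
  with_seed(seed, {
    samples <- lapply(seq_len(L), function(l) {
      X <- rdirichlet_rows(beta)
      if (floor > 0) {
        X[X < floor] <- floor
        X <- X / rowSums(X)
      }
      dimnames(X) <- dimnames(beta)
      X
    })
    structure(list(samples = samples, L = as.integer(L),
                   seed = as.integer(seed)),
              class = "bmdd_samples")
  })
}

#' @export
print.bmdd_samples <- function(x, ...) {
  d <- dim(x$samples[[1]])
  cat(sprintf("Posterior sample set: %d draws of a %d x %d composition (seed %d)\n",
              x$L, d[1], d[2], x$seed))
  invisible(x)
}

#' Posterior predictive count replicates
#'
#' For each of `L` replicates, draws a composition matrix from the fitted
#' posterior and then counts `Multinomial(N_i, X_i)` at the observed depths.
#' Summaries compare the replicate distribution of two per-taxon statistics
#' — the proportion of zeros and the standard deviation of counts — with
#' their observed values, the classic posterior predictive check for
#' zero-inflated count models.
#'
#' @param fit a [bmdd_fit()] object.
#' @param W the observed count matrix the model was fitted to.
#' @param L number of replicates.
#' @param seed integer seed.
#' @return list with `replicates` (length-L list of count matrices),
#'   `summary` — a data.frame per taxon with observed and replicate-mean
#'   zero proportions and count standard deviations.
#' @export
posterior_predict <- function(fit, W, L = 200L, seed = 1L) {
  W <- validate_counts(W, require_positive_totals = FALSE)
  depths <- rowSums(W)
  beta <- fit$beta
  with_seed(seed, {
    reps <- vector("list", L)
    zero_prop <- matrix(0, L, ncol(W))
    count_sd <- matrix(0, L, ncol(W))
    for (l in seq_len(L)) {
      X <- rdirichlet_rows(beta)
      Wrep <- matrix(0L, nrow(W), ncol(W))
      pos <- depths > 0
      Wrep[pos, ] <- rmultinom_rows(X[pos, , drop = FALSE], depths[pos])
      reps[[l]] <- Wrep
      zero_prop[l, ] <- colMeans(Wrep == 0)
      count_sd[l, ] <- apply(Wrep, 2, sd)
    }
    summary <- data.frame(
      taxon = colnames(W),
      observed_zero_prop = colMeans(W == 0),
      replicate_zero_prop = colMeans(zero_prop),
      observed_sd = apply(W, 2, sd),
      replicate_sd = colMeans(count_sd),
      row.names = NULL
    )
    list(replicates = reps, summary = summary, L = as.integer(L),
         seed = as.integer(seed))
  })
}

#' Naive imputation baselines
#'
#' The four standard zero-handling strategies used as baselines:
#' `naive1` normalizes the raw counts (zeros retained — the only baseline
#' allowed to return zeros); `naive2` adds a pseudocount of 1 to all counts;
#' `naive3` replaces zeros with 0.5; `naive4` replaces each zero cell
#' `(i, j)` with `N_i / max{N_k : W_kj = 0}`, i.e. scales by the deepest
#' sample in which the taxon is absent (vacuous for taxa without zeros).
#' All outputs are renormalized to the simplex.
#'
#' @param W count matrix.
#' @param method one of `"naive1" ... "naive4"`.
#' @return n x m composition matrix.
#' @export
naive_impute <- function(W, method = c("naive1", "naive2", "naive3",
                                       "naive4")) {
  method <- match.arg(method)
  W <- validate_counts(W)
  N <- rowSums(W)
  V <- switch(method,
    naive1 = W,
    naive2 = W + 1,
    naive3 = {
      V <- W
      V[V == 0] <- 0.5
      V
    },
    naive4 = {
      V <- W
      for (j in seq_len(ncol(W))) {
        zero <- W[, j] == 0
        if (any(zero)) {
          V[zero, j] <- N[zero] / max(N[zero])
        }
      }
      V
    }
  )
  V / rowSums(V)
}

#' Preprocess a count table for analysis
#'
#' Applies, in this fixed order: (1) drop samples with fewer than
#' `min_depth` total reads; (2) drop taxa whose prevalence (fraction of
#' retained samples with a nonzero count) is below `min_prevalence`;
#' (3) winsorize each taxon column at its empirical `winsor_q` quantile
#' across retained samples (values above the quantile are capped at it,
#' rounded to the nearest integer to keep counts integral).
#'
#' @param W count matrix.
#' @param min_depth minimum per-sample total reads (default 1000).
#' @param min_prevalence minimum taxon prevalence (default 0.2).
#' @param winsor_q winsorization quantile per taxon (default 0.97); `NULL`
#'   or 1 disables it.
#' @return filtered (and winsorized) count matrix.
#' @export
preprocess_counts <- function(W, min_depth = 1000L, min_prevalence = 0.2,
                              winsor_q = 0.97) {
  W <- validate_counts(W, require_positive_totals = FALSE)
  keep_s <- rowSums(W) >= min_depth
  if (!any(keep_s)) {
    stop("no samples retained: all below the minimum depth of ", min_depth,
         call. = FALSE)
  }
  W <- W[keep_s, , drop = FALSE]
  prev <- colMeans(W > 0)
  keep_t <- prev >= min_prevalence
  if (!any(keep_t)) {
    stop("no taxa retained: all below the minimum prevalence of ",
         min_prevalence, call. = FALSE)
  }
  W <- W[, keep_t, drop = FALSE]
  if (!is.null(winsor_q) && winsor_q < 1) {
    for (j in seq_len(ncol(W))) {
      cap <- round(quantile(W[, j], winsor_q, names = FALSE))
      W[W[, j] > cap, j] <- cap
    }
  }
  W
}
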