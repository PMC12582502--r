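# Differential abundance analysis on imputed compositions: per-taxon
# log-linear models with mode-based compositional bias correction
# ("LinDA-style, simplified"), single- and multiple-imputation variants
# (stacked repeated-measures mixed model, or Rubin's rules), and a
# shuffled-label harness for empirical FDR assessment.

# Vectorized per-taxon simple linear regression of log-composition on a
# binary group: returns raw coefficients, standard errors, residual df.
#' @noRd
log_linear_fit <- function(X, group) {
  if (any(X <= 0)) stop("compositions must be strictly positive (impute first)",
                        call. = FALSE)
  g <- as.numeric(group)
  if (length(unique(g)) < 2) stop("group must contain both labels",
                                  call. = FALSE)
  Y <- log(X)
  n <- nrow(Y)
  gc <- g - mean(g)
  sxx <- sum(gc^2)
  coef <- as.vector(crossprod(gc, Y)) / sxx
  fitted <- outer(gc, coef)
  resid <- scale(Y, scale = FALSE) - fitted
  df <- n - 2
  sigma2 <- colSums(resid^2) / df
  # zero-variance columns: pooled residual variance keeps se and p defined
  zero <- sigma2 <= .Machine$double.eps
  if (any(zero)) sigma2[zero] <- max(mean(sigma2), .Machine$double.eps)
  list(coef = coef, se = sqrt(sigma2 / sxx), df = df)
}

# Mode of a coefficient vector via Gaussian kernel density (Silverman
# bandwidth). The compositional bias of log-linear models shifts ALL
# coefficients by a common constant; assuming most taxa are null, the mode
# of the coefficient distribution estimates that shift.
#' @noRd
coef_mode <- function(coef) {
  if (length(unique(coef)) == 1) return(coef[1])
  d <- density(coef, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' @noRd
finalize_daa <- function(taxon, coef, se, df, alpha) {
  bias <- coef_mode(coef)
  est <- coef - bias
  tstat <- est / se
  p <- 2 * pt(-abs(tstat), df = df)
  q <- p.adjust(p, method = "BH")
  data.frame(taxon = taxon, estimate = est, se = se, df = df,
             stat = tstat, p = p, q = q, reject = q <= alpha,
             row.names = NULL)
}

#' Differential abundance test on a single imputed composition
#'
#' Per taxon, regresses the log relative abundance on a binary group label,
#' then corrects the compositional bias by subtracting the kernel-density
#' mode of the taxon-wise group coefficients (valid when most taxa are not
#' differential). P-values come from the corrected coefficients'
#' t-statistics; q-values are Benjamini-Hochberg adjusted.
#'
#' @param X strictly positive n x m composition matrix (e.g.
#'   [posterior_mean()] or [naive_impute()] output).
#' @param group binary (0/1) vector of length n with both labels present.
#' @param alpha target FDR level for the `reject` flag (default 0.05).
#' @return data.frame with columns `taxon`, `estimate` (bias-corrected
#'   log-fold coefficient), `se`, `df`, `stat`, `p`, `q`, `reject`.
#' @export
daa_single <- function(X, group, alpha = 0.05) {
  fit <- log_linear_fit(X, group)
  finalize_daa(colnames(X) %||% paste0("taxon", seq_along(fit$coef)),
               fit$coef, fit$se, fit$df, alpha)
}

# Rubin's rules pooling with Barnard-Rubin small-sample degrees of freedom.
#' @noRd
rubin_pool <- function(coefs, ses, df_com, L) {
  est <- colMeans(coefs)
  Wbar <- colMeans(ses^2)
  B <- apply(coefs, 2, var)
  Tvar <- Wbar + (1 + 1 / L) * B
  lambda <- pmin(pmax(((1 + 1 / L) * B) / Tvar, 1e-12), 1 - 1e-12)
  nu_old <- (L - 1) / lambda^2
  nu_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
  nu <- 1 / (1 / nu_old + 1 / nu_obs)
  list(est = est, se = sqrt(Tvar), df = nu)
}

#' Multiple-imputation differential abundance analysis
#'
#' Runs the log-linear differential abundance analysis across `L` posterior
#' composition draws and combines them:
#'
#' * `combine = "rubin"` — fit each imputed matrix separately, pool the raw
#'   coefficients and variances by Rubin's rules (within- plus
#'   between-imputation variance, Barnard-Rubin degrees of freedom), then
#'   bias-correct by the coefficient mode and BH-adjust.
#' * `combine = "stacked_lmm"` — stack the `L` matrices as repeated
#'   measurements of each sample and fit, per taxon, a linear mixed model of
#'   log abundance with a fixed group effect and a random sample intercept
#'   ([lme4::lmer()]); t-statistics use the residual-based degrees of
#'   freedom `n - 2` (the number of independent samples, not the stacked
#'   rows, governs the information content).
#'
#' With `L = 1` the call is redirected to [daa_single()] with a warning.
#'
#' @param S a `bmdd_samples` object from [posterior_sample()] (or a plain
#'   list of composition matrices).
#' @param group binary (0/1) vector.
#' @param combine `"rubin"` (default; fast) or `"stacked_lmm"`.
#' @param alpha target FDR level for the `reject` flag.
#' @return data.frame as in [daa_single()].
#' @export
daa_multiple <- function(S, group, combine = c("rubin", "stacked_lmm"),
                         alpha = 0.05) {
  combine <- match.arg(combine)
  samples <- if (inherits(S, "bmdd_samples")) S$samples else S
  L <- length(samples)
  if (L == 1) {
    warning("only one imputation supplied; falling back to daa_single",
            call. = FALSE)
    return(daa_single(samples[[1]], group, alpha))
  }
  m <- ncol(samples[[1]])
  taxa <- colnames(samples[[1]]) %||% paste0("taxon", seq_len(m))
  n <- nrow(samples[[1]])
  if (combine == "rubin") {
    coefs <- matrix(0, L, m)
    ses <- matrix(0, L, m)
    df_com <- n - 2
    for (l in seq_len(L)) {
      f <- log_linear_fit(samples[[l]], group)
      coefs[l, ] <- f$coef
      ses[l, ] <- f$se
    }
    pool <- rubin_pool(coefs, ses, df_com, L)
    finalize_daa(taxa, pool$est, pool$se, pool$df, alpha)
  } else {
    id <- factor(rep(seq_len(n), times = L))
    g <- rep(as.numeric(group), times = L)
    coef <- numeric(m)
    se <- numeric(m)
    for (j in seq_len(m)) {
      y <- log(unlist(lapply(samples, function(X) X[, j]), use.names = FALSE))
      fm <- suppressMessages(suppressWarnings(
        lme4::lmer(y ~ g + (1 | id), REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                                                 "ignore"))))
      sm <- summary(fm)$coefficients
      coef[j] <- sm["g", "Estimate"]
      se[j] <- sm["g", "Std. Error"]
    }
    finalize_daa(taxa, coef, se, n - 2, alpha)
  }
}

#' Shuffled-label empirical FDR harness
#'
#' Disrupts any real signal by permuting the group labels and records, for a
#' grid of target FDR levels, the fraction of permutations in which the
#' supplied method made any discovery — the empirical FDR under the global
#' null (any rejection on shuffled labels is a false discovery).
#'
#' @param method a function `(group, alpha) -> data.frame` with a `q`
#'   column, typically a closure over a fixed count matrix or posterior
#'   sample set.
#' @param group the original binary label vector (permuted each repetition).
#' @param reps number of label permutations.
#' @param levels target FDR grid (default `seq(0.01, 0.25, by = 0.02)`).
#' @param seed integer seed for the permutations.
#' @return data.frame with `level` and `empirical_fdr` (fraction of reps
#'   with at least one discovery at that level).
#' @export
shuffled_fdr <- function(method, group, reps = 100L,
                         levels = seq(0.01, 0.25, by = 0.02), seed = 1L) {
  stopifnot(reps >= 1)
  hits <- matrix(FALSE, reps, length(levels))
  with_seed(seed, {
    for (r in seq_len(reps)) {
      gp <- sample(group)
      res <- method(gp, max(levels))
      qmin <- min(res$q)
      hits[r, ] <- qmin <= levels
    }
  })
  data.frame(level = levels, empirical_fdr = colMeans(hits))
}
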