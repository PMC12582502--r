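# Exact posterior by enumeration of mode configurations. Intended for
# testing and small-m validation: the number of configurations is 2^m, so
# requests beyond m = 15 taxa are refused.

#' Dirichlet-multinomial log probability mass
#'
#' Log density of a count vector under the Dirichlet-multinomial
#' distribution, i.e. a multinomial whose probability vector has been
#' integrated out against a `Dirichlet(theta)` prior:
#' `log[ N!/prod(W_j!) * Gamma(sum(theta))/Gamma(N+sum(theta)) *
#' prod(Gamma(W_j+theta_j)/Gamma(theta_j)) ]`.
#'
#' @param x nonnegative integer count vector.
#' @param theta strictly positive concentration vector, same length as `x`.
#' @param log return the log density (default `TRUE`).
#' @return scalar (log) density.
#' @export
ddirmult <- function(x, theta, log = TRUE) {
  if (length(x) != length(theta)) stop("length mismatch", call. = FALSE)
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    stop("theta must be strictly positive", call. = FALSE)
  }
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    stop("x must be nonnegative integers", call. = FALSE)
  }
  n <- sum(x)
  s <- sum(theta)
  ll <- lgamma(n + 1) - sum(lgamma(x + 1)) +
    lgamma(s) - lgamma(n + s) +
    sum(lgamma(x + theta) - lgamma(theta))
  if (log) ll else exp(ll)
}

#' Exact bimodal-Dirichlet posterior for one sample by enumeration
#'
#' Enumerates all `2^m` mode configurations `delta` of the bimodal Dirichlet
#' prior, computes each configuration's exact posterior weight
#' `p(delta | W) \propto prod_j pi_j^delta_j (1-pi_j)^(1-delta_j) *
#' DirMult(W; theta(delta))` with `theta_j(delta) = alpha_{j,delta_j}`, and
#' returns the weights, the exact posterior mean composition, and the exact
#' log marginal likelihood `log p(W | pi, alpha)`.
#'
#' This is the quantity the variational approximation targets; it is
#' tractable only for small numbers of taxa and serves as a ground-truth
#' oracle in tests and calibration studies.
#'
#' @param w nonnegative integer count vector for one sample (length m <= 15).
#' @param hp list with components `pi`, `alpha0`, `alpha1` (length-m each).
#' @return list with `delta_probs` (length `2^m`, rows of `configs` give the
#'   corresponding delta vectors), `configs` (2^m x m 0/1 matrix),
#'   `mean_composition` (length m, sums to 1), `gamma_exact` (length m,
#'   exact `P(delta_j = 1 | w)`), and `log_marginal`.
#' @export
exact_posterior <- function(w, hp) {
  m <- length(w)
  if (m > 15) {
    stop("exact enumeration refused for m > 15 taxa (2^m configurations)",
         call. = FALSE)
  }
  hp <- validate_hyperparams(hp, m)
  configs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), m)))
  dimnames(configs) <- NULL
  n_cfg <- nrow(configs)
  logw <- numeric(n_cfg)
  means <- matrix(0, n_cfg, m)
  N <- sum(w)
  for (k in seq_len(n_cfg)) {
    d <- configs[k, ]
    # prior mass of the configuration; pi_j = 0 gives -Inf for delta_j = 1
    lp <- sum(ifelse(d == 1, log(hp$pi), log1p(-hp$pi)))
    if (!is.finite(lp)) {
      logw[k] <- -Inf
      next
    }
    theta <- ifelse(d == 1, hp$alpha1, hp$alpha0)
    logw[k] <- lp + ddirmult(w, theta)
    means[k, ] <- (w + theta) / (N + sum(theta))
  }
  log_marginal <- log_sum_exp(logw)
  p <- exp(logw - log_marginal)
  p <- p / sum(p)
  list(
    delta_probs = p,
    configs = configs,
    mean_composition = as.vector(crossprod(p, means)),
    gamma_exact = as.vector(crossprod(p, configs)),
    log_marginal = log_marginal
  )
}
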