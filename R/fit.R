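# Bimodal Dirichlet-multinomial model fitted by mean-field variational EM.
#
# Model, per sample i and taxon j:
#   delta_ij ~ Bernoulli(pi_j)                       latent mode indicator
#   theta_ij = alpha1_j if delta_ij = 1 else alpha0_j
#   X_i      ~ Dirichlet(theta_i1, ..., theta_im)    true composition
#   W_i      ~ Multinomial(N_i, X_i)                 observed counts
#
# Mean-field posterior: X_i ~ Dirichlet(beta_i), delta_ij ~ Bernoulli(gamma_ij).
# Expectations of lgamma(sum_j theta_ij) are replaced throughout by the
# Jensen lower bound lgamma(sum_j abar_ij) with
# abar_ij = gamma_ij*alpha1_j + (1-gamma_ij)*alpha0_j, which makes every
# update deterministic and smooth.

#' Fit configuration for the variational EM algorithm
#'
#' @param max_iter maximum number of outer EM iterations.
#' @param rel_tol relative change of the surrogate objective declaring
#'   convergence.
#' @param max_sweeps maximum coordinate sweeps over taxa inside each E-step.
#' @param gamma_tol E-step inner fixed point: stop when the largest change of
#'   any mode responsibility falls below this.
#' @param alpha_bounds length-2 positive vector bounding `alpha` during the
#'   M-step optimization (applied on the log scale).
#' @param init_strategy `"moment"` (default; prevalence/moment-based),
#'   `"random"` (seeded random responsibilities), or `"user"` (start from
#'   `hp_init` passed to [bmdd_fit()]).
#' @param seed integer seed controlling any randomized initialization.
#' @param verbose print the objective each iteration.
#' @return a list of class `bmdd_config`.
#' @export
bmdd_config <- function(max_iter = 200L, rel_tol = 1e-6, max_sweeps = 20L,
                        gamma_tol = 1e-4, alpha_bounds = c(1e-6, 1e4),
                        init_strategy = c("moment", "random", "user"),
                        seed = 1L, verbose = FALSE) {
  init_strategy <- match.arg(init_strategy)
  stopifnot(max_iter >= 1, rel_tol >= 0, max_sweeps >= 1,
            length(alpha_bounds) == 2, alpha_bounds[1] > 0,
            alpha_bounds[2] > alpha_bounds[1])
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 max_sweeps = as.integer(max_sweeps), gamma_tol = gamma_tol,
                 alpha_bounds = alpha_bounds, init_strategy = init_strategy,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "bmdd_config")
}

# ---- E-step primitives -----------------------------------------------------

#' Dirichlet factor update
#'
#' Closed-form coordinate-ascent update of the per-sample Dirichlet
#' posterior: `beta_j = W_j + gamma_j*alpha1_j + (1-gamma_j)*alpha0_j`.
#' Vectorized over samples when matrices are supplied.
#'
#' @param W count vector (or n x m matrix).
#' @param gamma mode responsibilities in `[0,1]`, same shape as `W`.
#' @param hp hyperparameter list (`pi`, `alpha0`, `alpha1`).
#' @return updated Dirichlet parameters, same shape as `W`.
#' @export
update_beta <- function(W, gamma, hp) {
  if (length(W) != length(gamma)) stop("dimension mismatch", call. = FALSE)
  if (any(!is.finite(W)) || any(!is.finite(gamma))) {
    stop("non-finite input", call. = FALSE)
  }
  m <- if (is.matrix(W)) ncol(W) else length(W)
  hp <- validate_hyperparams(hp, m)
  if (is.matrix(W)) {
    a1 <- matrix(hp$alpha1, nrow(W), m, byrow = TRUE)
    a0 <- matrix(hp$alpha0, nrow(W), m, byrow = TRUE)
    W + gamma * a1 + (1 - gamma) * a0
  } else {
    W + gamma * hp$alpha1 + (1 - gamma) * hp$alpha0
  }
}

#' Jensen-bounded mode log-score h_j(d)
#'
#' Evaluates, for taxon `j` and mode `d` in `{0,1}`, the deterministic lower
#' bound of the expected complete-data log density that drives the
#' responsibility update:
#' `h = lgamma(alpha_{j,d} + R_j) + (alpha_{j,d}-1)*(digamma(beta_j) -
#' digamma(sum(beta))) - lgamma(alpha_{j,d})`,
#' where `R_j = sum_{k != j} [gamma_k*alpha1_k + (1-gamma_k)*alpha0_k]`.
#' The `lgamma(alpha + R)` term is the Jensen bound of the otherwise
#' intractable expectation over the other taxa's mode indicators.
#'
#' @param j taxon index.
#' @param d mode, 0 or 1.
#' @param beta_row strictly positive Dirichlet parameter vector (length m).
#' @param gamma_row responsibilities in `[0,1]` (length m).
#' @param hp hyperparameter list.
#' @return scalar.
#' @export
h_value <- function(j, d, beta_row, gamma_row, hp) {
  m <- length(beta_row)
  hp <- validate_hyperparams(hp, m)
  stopifnot(d %in% c(0, 1), j >= 1, j <= m, all(beta_row > 0),
            all(gamma_row >= 0), all(gamma_row <= 1))
  a <- if (d == 1) hp$alpha1[j] else hp$alpha0[j]
  abar <- gamma_row * hp$alpha1 + (1 - gamma_row) * hp$alpha0
  R <- sum(abar[-j])
  elog <- digamma(beta_row[j]) - digamma(sum(beta_row))
  lgamma(a + R) + (a - 1) * elog - lgamma(a)
}

#' Mode responsibility update for one taxon
#'
#' Stable logistic form of
#' `gamma_j = pi_j*exp(h_j(1)) / (pi_j*exp(h_j(1)) + (1-pi_j)*exp(h_j(0)))`,
#' computed as `plogis(h(1) - h(0) + qlogis(pi_j))`. `pi_j = 0` forces
#' `gamma_j = 0`.
#'
#' @inheritParams h_value
#' @return scalar in `[0,1]`.
#' @export
update_gamma <- function(j, beta_row, gamma_row, hp) {
  pij <- hp$pi[j]
  if (pij <= 0) return(0)
  h1 <- h_value(j, 1, beta_row, gamma_row, hp)
  h0 <- h_value(j, 0, beta_row, gamma_row, hp)
  plogis(h1 - h0 + qlogis(pij))
}

# One full coordinate sweep of gamma across taxa, vectorized over samples.
# abar and A (= rowSums(abar)) are maintained incrementally; E is the matrix
# digamma(beta) - digamma(rowSums(beta)) held fixed during the sweep.
#' @noRd
gamma_sweep <- function(gamma, abar, A, E, hp) {
  m <- ncol(gamma)
  max_delta <- 0
  lpi <- qlogis(pmin(pmax(hp$pi, 0), 1 - 1e-12))
  for (j in seq_len(m)) {
    Rj <- A - abar[, j]
    a1 <- hp$alpha1[j]
    a0 <- hp$alpha0[j]
    dh <- (lgamma(a1 + Rj) - lgamma(a0 + Rj)) +
      (a1 - a0) * E[, j] - lgamma(a1) + lgamma(a0)
    gnew <- if (hp$pi[j] <= 0) rep(0, nrow(gamma)) else plogis(dh + lpi[j])
    max_delta <- max(max_delta, max(abs(gnew - gamma[, j])))
    abar_new_j <- gnew * a1 + (1 - gnew) * a0
    A <- A + (abar_new_j - abar[, j])
    abar[, j] <- abar_new_j
    gamma[, j] <- gnew
  }
  list(gamma = gamma, abar = abar, A = A, max_delta = max_delta)
}

#' Run the variational E-step to its inner fixed point
#'
#' Alternates the closed-form Dirichlet update ([update_beta()]) with
#' coordinate sweeps of the mode responsibilities across taxa (samples are
#' updated in parallel) until the largest responsibility change drops below
#' `gamma_tol` or `max_sweeps` is reached. Hyperparameters are held fixed,
#' so this is also the way to compute the variational posterior under known
#' (e.g. simulation-truth) hyperparameters.
#'
#' @param W validated count matrix (samples x taxa).
#' @param hp hyperparameter list (`pi`, `alpha0`, `alpha1`).
#' @param gamma optional starting responsibilities; defaults to the zero
#'   pattern `1*(W > 0)`.
#' @param max_sweeps,gamma_tol inner-loop controls, see [bmdd_config()].
#' @return list with `beta`, `gamma`, `n_sweeps`, `converged`.
#' @export
bmdd_estep <- function(W, hp, gamma = NULL, max_sweeps = 20L,
                       gamma_tol = 1e-4) {
  W <- validate_counts(W, require_positive_totals = FALSE)
  m <- ncol(W)
  hp <- validate_hyperparams(hp, m)
  n <- nrow(W)
  if (is.null(gamma)) gamma <- matrix(as.numeric(W > 0), n, m)
  a1 <- matrix(hp$alpha1, n, m, byrow = TRUE)
  a0 <- matrix(hp$alpha0, n, m, byrow = TRUE)
  converged <- FALSE
  sweeps <- 0L
  repeat {
    abar <- gamma * a1 + (1 - gamma) * a0
    beta <- W + abar
    E <- digamma(beta) - digamma(rowSums(beta))
    sw <- gamma_sweep(gamma, abar, rowSums(abar), E, hp)
    gamma <- sw$gamma
    sweeps <- sweeps + 1L
    if (sw$max_delta < gamma_tol) {
      converged <- TRUE
      break
    }
    if (sweeps >= max_sweeps) break
  }
  abar <- gamma * a1 + (1 - gamma) * a0
  beta <- W + abar
  dimnames(beta) <- dimnames(W)
  dimnames(gamma) <- dimnames(W)
  list(beta = beta, gamma = gamma, n_sweeps = sweeps, converged = converged)
}

# ---- M-step primitives -----------------------------------------------------

#' Mixture weight update
#'
#' Closed-form M-step for the mode probabilities: `pi_j` is the mean
#' responsibility of taxon `j` across samples, clipped to `[0, 1 - 1e-8]` to
#' respect the `pi_j < 1` constraint of the prior.
#'
#' @param gamma n x m responsibility matrix.
#' @return length-m probability vector.
#' @export
update_pi <- function(gamma) {
  if (!is.matrix(gamma) || nrow(gamma) == 0) {
    stop("gamma must be a matrix with at least one row", call. = FALSE)
  }
  if (any(gamma < 0) || any(gamma > 1)) {
    stop("responsibilities must lie in [0,1]", call. = FALSE)
  }
  pmin(pmax(colMeans(gamma), 0), 1 - 1e-8)
}

#' M-step objective for the concentration parameters
#'
#' The portion of the surrogate objective that depends on `alpha`, with the
#' Jensen bound applied to the expected log-normalizing constant:
#' `sum_i lgamma(A_i) + sum_ij [(abar_ij - 1)*Elog_ij -
#' gamma_ij*lgamma(alpha1_j) - (1-gamma_ij)*lgamma(alpha0_j)]`,
#' where `abar_ij = gamma_ij*alpha1_j + (1-gamma_ij)*alpha0_j`,
#' `A_i = sum_j abar_ij` and `Elog_ij = digamma(beta_ij) -
#' digamma(sum_j beta_ij)`.
#'
#' @param alpha0,alpha1 strictly positive length-m vectors.
#' @param gamma,beta n x m matrices from the E-step.
#' @return scalar objective value (to be maximized).
#' @export
alpha_objective <- function(alpha0, alpha1, gamma, beta) {
  if (any(alpha0 <= 0) || any(alpha1 <= 0)) {
    stop("alpha must be strictly positive", call. = FALSE)
  }
  E <- digamma(beta) - digamma(rowSums(beta))
  n <- nrow(gamma)
  m <- ncol(gamma)
  a1 <- matrix(alpha1, n, m, byrow = TRUE)
  a0 <- matrix(alpha0, n, m, byrow = TRUE)
  abar <- gamma * a1 + (1 - gamma) * a0
  sum(lgamma(rowSums(abar))) +
    sum((abar - 1) * E) -
    sum(colSums(gamma) * lgamma(alpha1)) -
    sum(colSums(1 - gamma) * lgamma(alpha0))
}

# Analytic gradient of alpha_objective in (alpha0, alpha1); E precomputed.
#' @noRd
alpha_objective_grad <- function(alpha0, alpha1, gamma, E) {
  n <- nrow(gamma)
  m <- ncol(gamma)
  a1 <- matrix(alpha1, n, m, byrow = TRUE)
  a0 <- matrix(alpha0, n, m, byrow = TRUE)
  abar <- gamma * a1 + (1 - gamma) * a0
  psiA <- digamma(rowSums(abar))
  g1 <- colSums(gamma * (psiA + E)) - colSums(gamma) * digamma(alpha1)
  g0 <- colSums((1 - gamma) * (psiA + E)) -
    colSums(1 - gamma) * digamma(alpha0)
  c(g0, g1)
}

#' Concentration parameter update (M-step)
#'
#' Maximizes [alpha_objective()] over `(alpha0, alpha1)` jointly with
#' [stats::nlminb()] in a log parameterization (box constraints from
#' `alpha_bounds`), warm-started at the current values and with analytic
#' gradients. If the optimizer fails or worsens the objective, the warm
#' start is returned unchanged (no-worsening guarantee) with a warning.
#'
#' @param gamma,beta E-step matrices.
#' @param hp current hyperparameters (warm start).
#' @param cfg a [bmdd_config()].
#' @return list with updated `alpha0`, `alpha1` and the achieved `objective`.
#' @export
update_alpha <- function(gamma, beta, hp, cfg = bmdd_config()) {
  m <- ncol(gamma)
  lb <- log(cfg$alpha_bounds[1])
  ub <- log(cfg$alpha_bounds[2])
  E <- digamma(beta) - digamma(rowSums(beta))
  n <- nrow(gamma)
  cs_g <- colSums(gamma)
  cs_1mg <- n - cs_g
  negobj <- function(par) {
    a0 <- exp(par[seq_len(m)])
    a1 <- exp(par[m + seq_len(m)])
    abar <- gamma * matrix(a1, n, m, byrow = TRUE) +
      (1 - gamma) * matrix(a0, n, m, byrow = TRUE)
    -(sum(lgamma(rowSums(abar))) + sum((abar - 1) * E) -
        sum(cs_g * lgamma(a1)) - sum(cs_1mg * lgamma(a0)))
  }
  neggrad <- function(par) {
    a0 <- exp(par[seq_len(m)])
    a1 <- exp(par[m + seq_len(m)])
    g <- alpha_objective_grad(a0, a1, gamma, E)
    -g * c(a0, a1)   # chain rule for the log parameterization
  }
  start <- pmin(pmax(log(c(hp$alpha0, hp$alpha1)), lb), ub)
  f_start <- negobj(start)
  res <- tryCatch(
    nlminb(start, negobj, gradient = neggrad,
           lower = lb, upper = ub,
           control = list(iter.max = 200, eval.max = 400)),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$objective) ||
      res$objective > f_start + 1e-10) {
    if (is.null(res)) {
      warning("alpha optimization failed; keeping previous values",
              call. = FALSE)
    }
    return(list(alpha0 = hp$alpha0, alpha1 = hp$alpha1,
                objective = -f_start))
  }
  a0 <- exp(res$par[seq_len(m)])
  a1 <- exp(res$par[m + seq_len(m)])
  list(alpha0 = a0, alpha1 = a1, objective = -res$objective)
}

# ---- Objective -------------------------------------------------------------

#' Surrogate evidence lower bound
#'
#' The mean-field evidence lower bound with the intractable expectation
#' `E[lgamma(sum_j theta_ij)]` replaced by its Jensen lower bound
#' `lgamma(sum_j abar_ij)` (so the value is a lower bound of the exact
#' ELBO, hence of the log marginal likelihood). Used as the convergence
#' monitor of [bmdd_fit()].
#'
#' @param W count matrix.
#' @param state list with `beta` and `gamma` matrices.
#' @param hp hyperparameter list.
#' @return scalar.
#' @export
surrogate_elbo <- function(W, state, hp) {
  beta <- state$beta
  gamma <- state$gamma
  n <- nrow(W)
  m <- ncol(W)
  hp <- validate_hyperparams(hp, m)
  a1 <- matrix(hp$alpha1, n, m, byrow = TRUE)
  a0 <- matrix(hp$alpha0, n, m, byrow = TRUE)
  abar <- gamma * a1 + (1 - gamma) * a0
  B <- rowSums(beta)
  E <- digamma(beta) - digamma(B)
  # multinomial log-normalizer
  const <- sum(lgamma(rowSums(W) + 1)) - sum(lgamma(W + 1))
  ll_mult <- const + sum(W * E)
  # E[log p(X | delta, alpha)], Jensen-bounded normalizer
  ll_prior_x <- sum(lgamma(rowSums(abar))) + sum((abar - 1) * E) -
    sum(colSums(gamma) * lgamma(hp$alpha1)) -
    sum(colSums(1 - gamma) * lgamma(hp$alpha0))
  # E[log p(delta | pi)]
  lp <- matrix(log(hp$pi), n, m, byrow = TRUE)
  l1mp <- matrix(log1p(-hp$pi), n, m, byrow = TRUE)
  t1 <- gamma * lp
  t1[gamma == 0] <- 0          # 0 * log(0) convention when pi_j = 0
  t2 <- (1 - gamma) * l1mp
  t2[gamma == 1] <- 0
  ll_prior_d <- sum(t1) + sum(t2)
  # entropies of the variational factors
  ent_dir <- sum(lgamma(beta)) - sum(lgamma(B)) +
    sum((B - m) * digamma(B)) - sum((beta - 1) * digamma(beta))
  ent_bern <- sum(bern_entropy(gamma))
  ll_mult + ll_prior_x + ll_prior_d + ent_dir + ent_bern
}

# ---- Initialization --------------------------------------------------------

# Moment-based initialization: gamma from the zero pattern, pi from
# prevalence, alpha1 from a shared-precision method-of-moments fit to the
# nonzero observed proportions, alpha0 a near-zero spike.
#' @noRd
init_moment <- function(W, cfg) {
  n <- nrow(W)
  m <- ncol(W)
  P <- W / rowSums(W)
  gamma <- matrix(as.numeric(W > 0), n, m)
  pi <- pmin(colMeans(gamma), 1 - 1e-8)
  mu <- numeric(m)
  prec <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    p <- P[W[, j] > 0, j]
    mu[j] <- if (length(p)) mean(p) else 1 / (n * m)
    if (length(p) >= 3) {
      v <- var(p)
      if (is.finite(v) && v > 0) prec[j] <- mu[j] * (1 - mu[j]) / v - 1
    }
  }
  A <- median(prec[is.finite(prec) & prec > 0])
  if (!is.finite(A) || A <= 0) A <- m  # fall back to a flat-ish prior scale
  lo <- cfg$alpha_bounds[1]
  hi <- cfg$alpha_bounds[2]
  alpha1 <- pmin(pmax(mu * A, 0.05), hi)
  alpha0 <- rep(max(0.01, lo), m)
  list(pi = pi, alpha0 = alpha0, alpha1 = pmin(pmax(alpha1, lo), hi),
       gamma = gamma)
}

#' @noRd
init_random <- function(W, cfg) {
  n <- nrow(W)
  m <- ncol(W)
  with_seed(cfg$seed, {
    gamma <- matrix(runif(n * m), n, m)
    alpha1 <- exp(runif(m, log(0.5), log(20)))
    alpha0 <- exp(runif(m, log(0.005), log(0.2)))
    pi <- runif(m, 0.05, 0.95)
    list(pi = pi, alpha0 = alpha0, alpha1 = alpha1, gamma = gamma)
  })
}

# ---- Driver ----------------------------------------------------------------

#' Fit the bimodal Dirichlet-multinomial model
#'
#' Estimates the per-taxon hyperparameters (`pi`, `alpha0`, `alpha1`) and the
#' mean-field posterior (`beta`, `gamma`) by variational EM: the E-step runs
#' [bmdd_estep()] to its inner fixed point, the M-step applies the
#' closed-form [update_pi()] and the numerical [update_alpha()]. After each
#' M-step the mode labels are put in canonical order (`alpha0 <= alpha1`,
#' swapping `gamma` and `pi` accordingly); the surrogate objective is
#' recorded once per outer iteration and convergence is declared when its
#' relative change falls below `rel_tol`.
#'
#' All-zero taxon columns are retained (their posterior is driven by the
#' prior) with a warning, since the data carry no mode information for them.
#'
#' @param W count matrix, samples in rows, taxa in columns (at least 2 taxa).
#' @param config a [bmdd_config()].
#' @param hp_init optional hyperparameter list used when
#'   `config$init_strategy == "user"` (and as the starting point otherwise
#'   ignored).
#' @return object of class `bmdd_fit`: list with `pi`, `alpha0`, `alpha1`,
#'   `beta`, `gamma`, `objective_trace`, `converged`, `n_iter`, `config`,
#'   plus the input dimensions and labels.
#' @examples
#' hp <- list(pi = c(0.5, 0.5, 0.5), alpha0 = rep(0.05, 3), alpha1 = rep(5, 3))
#' sim <- simulate_bmdd(hp, n = 40, depths = rep(5000, 40), seed = 1)
#' fit <- bmdd_fit(sim$counts, bmdd_config(max_iter = 25))
#' head(posterior_mean(fit))
#' @export
bmdd_fit <- function(W, config = bmdd_config(), hp_init = NULL) {
  W <- validate_counts(W)
  n <- nrow(W)
  m <- ncol(W)
  if (m < 2) stop("at least two taxa are required", call. = FALSE)
  if (any(colSums(W) == 0)) {
    warning("all-zero taxon column(s) retained: posterior driven by the prior",
            call. = FALSE)
  }
  cfg <- config
  init <- switch(cfg$init_strategy,
    moment = init_moment(W, cfg),
    random = init_random(W, cfg),
    user = {
      if (is.null(hp_init)) {
        stop("init_strategy 'user' requires hp_init", call. = FALSE)
      }
      hp_init <- validate_hyperparams(hp_init, m)
      c(hp_init, list(gamma = matrix(as.numeric(W > 0), n, m)))
    }
  )
  hp <- validate_hyperparams(
    list(pi = init$pi, alpha0 = init$alpha0, alpha1 = init$alpha1), m)
  gamma <- init$gamma
  trace <- numeric(0)
  converged <- FALSE
  prev <- -Inf
  iter <- 0L
  for (iter in seq_len(cfg$max_iter)) {
    es <- bmdd_estep(W, hp, gamma = gamma, max_sweeps = cfg$max_sweeps,
                     gamma_tol = cfg$gamma_tol)
    gamma <- es$gamma
    beta <- es$beta
    # M-step
    hp$pi <- update_pi(gamma)
    upd <- update_alpha(gamma, beta, hp, cfg)
    hp$alpha0 <- upd$alpha0
    hp$alpha1 <- upd$alpha1
    # canonical mode ordering: alpha0 <= alpha1 per taxon
    swap <- hp$alpha0 > hp$alpha1
    if (any(swap)) {
      tmp <- hp$alpha0[swap]
      hp$alpha0[swap] <- hp$alpha1[swap]
      hp$alpha1[swap] <- tmp
      gamma[, swap] <- 1 - gamma[, swap]
      hp$pi[swap] <- pmin(pmax(1 - hp$pi[swap], 0), 1 - 1e-8)
    }
    # refresh the Dirichlet factor under the new hyperparameters before
    # recording the objective (an exact ascent move of the surrogate)
    beta <- update_beta(W, gamma, hp)
    obj <- surrogate_elbo(W, list(beta = beta, gamma = gamma), hp)
    trace <- c(trace, obj)
    if (cfg$verbose) {
      message(sprintf("iter %3d  objective %.6f", iter, obj))
    }
    if (is.finite(prev) &&
        abs(obj - prev) <= cfg$rel_tol * (abs(prev) + 1e-10)) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  dimnames(beta) <- dimnames(W)
  dimnames(gamma) <- dimnames(W)
  structure(list(
    pi = setNames(hp$pi, colnames(W)),
    alpha0 = setNames(hp$alpha0, colnames(W)),
    alpha1 = setNames(hp$alpha1, colnames(W)),
    beta = beta, gamma = gamma,
    objective_trace = trace, converged = converged, n_iter = iter,
    config = cfg, sample_ids = rownames(W), taxon_ids = colnames(W),
    n = n, m = m
  ), class = "bmdd_fit")
}

#' @export
print.bmdd_fit <- function(x, ...) {
  cat(sprintf(
    "Bimodal Dirichlet-multinomial fit: %d samples x %d taxa\n", x$n, x$m))
  cat(sprintf("  %s after %d EM iterations (surrogate objective %.4f)\n",
              if (x$converged) "converged" else "stopped", x$n_iter,
              tail(x$objective_trace, 1)))
  cat(sprintf("  pi: [%.3f, %.3f]  alpha0: [%.3g, %.3g]  alpha1: [%.3g, %.3g]\n",
              min(x$pi), max(x$pi), min(x$alpha0), max(x$alpha0),
              min(x$alpha1), max(x$alpha1)))
  invisible(x)
}

#' @importFrom utils tail
NULL
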