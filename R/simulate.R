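# Synthetic data generators: the bimodal-Dirichlet generative process, the
# misspecified parametric families with copula-induced taxon correlation, and
# two-group differential-abundance designs. All generators are deterministic
# given `seed` and return the simulation truth alongside the counts.

# Draw one Dirichlet row via normalized gammas (scale fixed at 1; the
# composition is invariant to the gamma scale). Rows that underflow to all
# zeros (possible for extremely small shapes) are redrawn.
#' @noRd
rdirichlet_rows <- function(shape) {
  y <- matrix(rgamma(length(shape), shape = shape, rate = 1),
              nrow(shape), ncol(shape))
  bad <- rowSums(y) == 0
  while (any(bad)) {
    y[bad, ] <- rgamma(sum(bad) * ncol(shape), shape = shape[bad, ], rate = 1)
    bad <- rowSums(y) == 0
  }
  y / rowSums(y)
}

#' @noRd
rmultinom_rows <- function(X, depths) {
  n <- nrow(X)
  W <- matrix(0L, n, ncol(X))
  for (i in seq_len(n)) {
    W[i, ] <- as.integer(rmultinom(1, size = depths[i], prob = X[i, ]))
  }
  W
}

#' Default sequencing depths
#'
#' Log-uniform depths in `[5e3, 5e4]`, the typical per-sample read-count
#' range of genus-level 16S tables.
#'
#' @param n number of samples.
#' @return integer vector of length `n` (drawn with the current RNG state).
#' @export
default_depths <- function(n) {
  as.integer(round(exp(runif(n, log(5e3), log(5e4)))))
}

#' Random bimodal-Dirichlet hyperparameters
#'
#' Draws a plausible genus-level hyperparameter set: mode probabilities
#' `pi_j ~ Beta(2,2)`, near-zero spikes `alpha0_j` log-uniform in
#' `[0.01, 0.5]`, and high-abundance concentrations `alpha1_j` log-uniform
#' in `[0.5, 20]` (ordered so `alpha0 <= alpha1`).
#'
#' @param m number of taxa.
#' @param seed integer seed.
#' @return hyperparameter list (`pi`, `alpha0`, `alpha1`).
#' @export
random_hyperparams <- function(m, seed = 1L) {
  with_seed(seed, {
    pi <- rbeta(m, 2, 2)
    alpha0 <- exp(runif(m, log(0.01), log(0.5)))
    alpha1 <- exp(runif(m, log(0.5), log(20)))
    swap <- alpha0 > alpha1
    tmp <- alpha0[swap]; alpha0[swap] <- alpha1[swap]; alpha1[swap] <- tmp
    list(pi = pmin(pi, 1 - 1e-8), alpha0 = alpha0, alpha1 = alpha1)
  })
}

#' @importFrom stats rbeta
NULL

#' Simulate counts from the bimodal Dirichlet-multinomial process
#'
#' Runs the generative model forward: for each sample, mode indicators
#' `delta_j ~ Bernoulli(pi_j)`, composition
#' `X ~ Dirichlet(alpha_{1,delta_1}, ..., alpha_{m,delta_m})`, counts
#' `W ~ Multinomial(N_i, X)`.
#'
#' @param hp hyperparameter list (`pi`, `alpha0`, `alpha1`).
#' @param n number of samples.
#' @param depths integer sequencing depths, length `n` (or scalar, recycled);
#'   `NULL` draws [default_depths()].
#' @param seed integer seed; identical seeds reproduce identical tables.
#' @return list with `counts` (n x m integer matrix), and `truth` — a list
#'   holding `composition`, `delta`, `hyperparams`, `depths`.
#' @export
simulate_bmdd <- function(hp, n, depths = NULL, seed = 1L) {
  m <- length(hp$pi)
  hp <- validate_hyperparams(hp, m)
  stopifnot(n >= 1)
  with_seed(seed, {
    if (is.null(depths)) depths <- default_depths(n)
    depths <- as.integer(rep(depths, length.out = n))
    if (any(depths <= 0)) stop("depths must be positive", call. = FALSE)
    delta <- matrix(rbinom(n * m, 1, rep(hp$pi, each = n)), n, m)
    shape <- matrix(hp$alpha0, n, m, byrow = TRUE)
    a1 <- matrix(hp$alpha1, n, m, byrow = TRUE)
    shape[delta == 1] <- a1[delta == 1]
    X <- rdirichlet_rows(shape)
    W <- rmultinom_rows(X, depths)
    dimnames(W) <- list(paste0("sample", seq_len(n)),
                        paste0("taxon", seq_len(m)))
    dimnames(X) <- dimnames(W)
    list(counts = W,
         truth = list(composition = X, delta = delta, hyperparams = hp,
                      depths = depths, group = NULL, differential = NULL))
  })
}

# Correlation matrix for the Gaussian copula.
#' @noRd
copula_sigma <- function(m, structure = c("none", "exchangeable", "ar1"),
                         rho = 0) {
  structure <- match.arg(structure)
  if (structure == "none" || rho == 0) return(diag(m))
  if (abs(rho) >= 1) stop("correlation coefficient must lie in (-1, 1)",
                          call. = FALSE)
  if (structure == "exchangeable") {
    S <- matrix(rho, m, m)
    diag(S) <- 1
    if (rho < -1 / (m - 1)) stop("exchangeable rho too negative", call. = FALSE)
    S
  } else {
    rho ^ abs(outer(seq_len(m), seq_len(m), "-"))
  }
}

# n x m matrix of correlated uniforms via a Gaussian copula.
#' @noRd
copula_uniforms <- function(n, m, structure, rho) {
  S <- copula_sigma(m, structure, rho)
  L <- chol(S)
  Z <- matrix(rnorm(n * m), n, m) %*% L
  pnorm(Z)
}

#' Simulate counts under misspecified parametric models
#'
#' Generates correlated absolute abundances (or counts) outside the bimodal
#' Dirichlet family, for robustness studies. Latent per-taxon marginals are
#' gamma or log-normal (abundances normalized to compositions, counts then
#' multinomial at the given depths) or Poisson / negative binomial (counts
#' drawn directly; the truth composition is the normalized mean abundance).
#' Cross-taxon correlation is induced by a Gaussian copula with an
#' exchangeable or AR(1) structure.
#'
#' @param model one of `"gamma"`, `"lognormal"`, `"poisson"`, `"negbin"`.
#' @param n,m samples and taxa.
#' @param depths sequencing depths (`NULL` for [default_depths()]); for the
#'   Poisson/negative-binomial models they scale the expected counts.
#' @param correlation list with `structure` (`"none"`, `"exchangeable"`,
#'   `"ar1"`) and `rho` in `(-1, 1)`.
#' @param params optional overrides of the marginal parameters: `shape`,
#'   `scale` (gamma), `sdlog` (log-normal), `size` (negative-binomial
#'   dispersion), `mean_sdlog` (spread of per-taxon mean abundances).
#' @param group optional 0/1 vector of length `n`; `effect_fold` multiplies
#'   the mean abundance of `differential` taxa in group 1.
#' @param differential integer taxon indices carrying the effect.
#' @param effect_fold multiplicative abundance fold change (1 = none).
#' @param seed integer seed.
#' @return list with `counts` and `truth` (as in [simulate_bmdd()], with
#'   `delta = NULL` and `latent` holding the latent abundances where defined).
#' @export
simulate_parametric <- function(model = c("gamma", "lognormal", "poisson",
                                          "negbin"),
                                n, m, depths = NULL,
                                correlation = list(structure = "none",
                                                   rho = 0),
                                params = list(), group = NULL,
                                differential = integer(0), effect_fold = 1,
                                seed = 1L) {
  model <- match.arg(model)
  p <- modifyList(list(shape = 0.5, scale = NULL, sdlog = 1, size = 0.5,
                       mean_sdlog = 1), params)
  structure <- correlation$structure %||% "none"
  rho <- correlation$rho %||% 0
  with_seed(seed, {
    if (is.null(depths)) depths <- default_depths(n)
    depths <- as.integer(rep(depths, length.out = n))
    # per-taxon mean absolute abundances on a log-normal scale across taxa
    mu <- exp(rnorm(m, 0, p$mean_sdlog))
    M <- matrix(mu, n, m, byrow = TRUE)
    if (length(differential) && effect_fold != 1) {
      if (is.null(group)) stop("differential effects require a group vector",
                               call. = FALSE)
      M[group == 1, differential] <- M[group == 1, differential] * effect_fold
    }
    U <- copula_uniforms(n, m, structure, rho)
    if (model %in% c("gamma", "lognormal")) {
      Y <- if (model == "gamma") {
        scale <- if (is.null(p$scale)) M / p$shape else p$scale
        qgamma(U, shape = p$shape, scale = scale)
      } else {
        qlnorm(U, meanlog = log(M) - p$sdlog^2 / 2, sdlog = p$sdlog)
      }
      Y[Y <= 0] <- min(Y[Y > 0]) * 1e-3  # guard against quantile underflow
      X <- Y / rowSums(Y)
      W <- rmultinom_rows(X, depths)
      latent <- Y
    } else {
      lam <- M * (depths / mean(depths))
      W <- if (model == "poisson") {
        matrix(qpois(U, lambda = lam), n, m)
      } else {
        matrix(qnbinom(U, mu = lam, size = p$size), n, m)
      }
      X <- lam / rowSums(lam)  # normalized mean abundances
      latent <- lam
    }
    storage.mode(W) <- "integer"
    dimnames(W) <- list(paste0("sample", seq_len(n)),
                        paste0("taxon", seq_len(m)))
    dimnames(X) <- dimnames(W)
    list(counts = W,
         truth = list(composition = X, delta = NULL, hyperparams = NULL,
                      depths = depths, group = group,
                      differential = if (length(differential))
                        list(taxa = differential,
                             log_fold = log(effect_fold)) else NULL,
                      latent = latent))
  })
}

#' Simulate a two-group differential abundance design
#'
#' Two equal groups of `n/2` samples; a random `ceiling(prop_differential*m)`
#' subset of taxa receives a multiplicative mean-abundance shift of
#' `effect_fold` in group 1. Marginals and correlation are delegated to
#' [simulate_parametric()].
#'
#' @param model marginal family, as in [simulate_parametric()].
#' @param n total number of samples (split evenly).
#' @param m number of taxa.
#' @param prop_differential fraction of differential taxa in `[0, 1]`.
#' @param effect_fold multiplicative fold change (1 = global null).
#' @param depths,correlation,params,seed see [simulate_parametric()].
#' @return as [simulate_parametric()]; `truth$group` is the 0/1 group label
#'   and `truth$differential$taxa` the planted taxa.
#' @export
simulate_daa <- function(model = c("gamma", "lognormal", "poisson", "negbin"),
                         n, m, prop_differential = 0.1, effect_fold = 10,
                         depths = NULL,
                         correlation = list(structure = "none", rho = 0),
                         params = list(), seed = 1L) {
  model <- match.arg(model)
  stopifnot(prop_differential >= 0, prop_differential <= 1, n >= 2)
  group <- rep(c(0L, 1L), length.out = n)
  k <- ceiling(prop_differential * m)
  differential <- if (k > 0) {
    with_seed(seed + 1000003L, sample.int(m, k))
  } else integer(0)
  simulate_parametric(model, n = n, m = m, depths = depths,
                      correlation = correlation, params = params,
                      group = group, differential = differential,
                      effect_fold = effect_fold, seed = seed)
}

#' @importFrom stats sd
NULL
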