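# Generators: forward model, misspecified families, copula correlation,
# two-group designs.

test_that("bimodal generator honors depths, seeds, and degenerate priors", {
  hp <- tiny_hp(4)
  sim <- simulate_bmdd(hp, n = 12, depths = c(100, 200, 300), seed = 5)
  expect_identical(rowSums(sim$counts), rep(c(100, 200, 300), 4),
                   ignore_attr = TRUE)
  expect_simplex(sim$truth$composition)
  sim2 <- simulate_bmdd(hp, n = 12, depths = c(100, 200, 300), seed = 5)
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$truth$composition, sim2$truth$composition)

  # zero mixture weight collapses to the low mode
  hp0 <- list(pi = rep(0, 3), alpha0 = c(2, 3, 5), alpha1 = rep(9, 3))
  s0 <- simulate_bmdd(hp0, n = 4000, depths = 100, seed = 6)
  expect_true(all(s0$truth$delta == 0))
  expect_equal(colMeans(s0$truth$composition), c(2, 3, 5) / 10,
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("marginals of the bimodal composition match the exact mixture", {
  # m = 2 lets the marginal cdf of taxon 1 be written exactly as a
  # four-configuration mixture of Beta distributions
  hp <- list(pi = c(0.5, 0.3), alpha0 = c(0.05, 0.2), alpha1 = c(5, 3))
  n <- 5000
  sim <- simulate_bmdd(hp, n = n, depths = 100, seed = 8)
  X1 <- sim$truth$composition[, 1]
  cfg <- expand.grid(d1 = 0:1, d2 = 0:1)
  wts <- with(cfg, ifelse(d1 == 1, hp$pi[1], 1 - hp$pi[1]) *
                ifelse(d2 == 1, hp$pi[2], 1 - hp$pi[2]))
  a1 <- ifelse(cfg$d1 == 1, hp$alpha1[1], hp$alpha0[1])
  a2 <- ifelse(cfg$d2 == 1, hp$alpha1[2], hp$alpha0[2])
  for (t in c(1e-4, 0.05, 0.5, 0.9)) {
    p_exact <- sum(wts * pbeta(t, a1, a2))
    se <- sqrt(p_exact * (1 - p_exact) / n)
    expect_lt(abs(mean(X1 < t) - p_exact), 3 * se + 1e-3)
  }
  # mean count proportion vs exact mixture mean
  mu_exact <- sum(wts * a1 / (a1 + a2))
  W1 <- sim$counts[, 1] / rowSums(sim$counts)
  expect_lt(abs(mean(W1) - mu_exact), 3 * sd(W1) / sqrt(n))
})

test_that("copula correlation is present when requested and absent otherwise", {
  s_ind <- simulate_parametric("gamma", n = 2000, m = 4,
                               params = list(shape = 2),
                               correlation = list(structure = "none",
                                                  rho = 0), seed = 3)
  C <- cor(log(s_ind$truth$latent))
  off <- C[upper.tri(C)]
  expect_true(all(abs(off) < 3 / sqrt(2000) + 0.02))

  s_ar <- simulate_parametric("gamma", n = 4000, m = 5,
                              params = list(shape = 2),
                              correlation = list(structure = "ar1",
                                                 rho = 0.6), seed = 4)
  # Gaussian copula implies Spearman correlation 6/pi*asin(rho/2) between
  # adjacent latent columns
  rho_s <- (6 / pi) * asin(0.6 / 2)
  for (j in 1:4) {
    est <- cor(s_ar$truth$latent[, j], s_ar$truth$latent[, j + 1],
               method = "spearman")
    expect_lt(abs(est - rho_s), 0.05)
  }
  expect_error(simulate_parametric("gamma", n = 10, m = 3,
                                   correlation = list(structure = "ar1",
                                                      rho = 1.2), seed = 1),
               "(-1, 1)")
})

test_that("parametric marginals have the stated moments", {
  s <- simulate_parametric("gamma", n = 3000, m = 3,
                           params = list(shape = 2, scale = 3), seed = 9)
  for (j in 1:3) {
    expect_lt(abs(mean(s$truth$latent[, j]) - 6),
              3 * sd(s$truth$latent[, j]) / sqrt(3000))
  }
  # Poisson / negative binomial counts: truth composition is the normalized
  # mean, constant across samples at equal depths
  sp <- simulate_parametric("poisson", n = 500, m = 4, depths = 1e4, seed = 10)
  expect_simplex(sp$truth$composition)
  expect_equal(max(apply(sp$truth$composition, 2, sd)), 0)
  expect_lt(max(abs(colMeans(sp$counts) / sum(colMeans(sp$counts)) -
                      sp$truth$composition[1, ])), 0.03)
  # negative binomial at unit mean and size 0.5 has variance 3, well above
  # the Poisson variance of 1
  snb <- simulate_parametric("negbin", n = 2000, m = 4, depths = 1e4,
                             params = list(size = 0.5, mean_sdlog = 0),
                             seed = 11)
  expect_true(all(apply(snb$counts, 2, var) > 2 * colMeans(snb$counts)))
})

test_that("two-group designs plant the requested differential structure", {
  sim <- simulate_daa("gamma", n = 40, m = 30, prop_differential = 0.1,
                      effect_fold = 10, seed = 12)
  expect_equal(sum(sim$truth$group), 20)
  expect_length(sim$truth$differential$taxa, 3)
  expect_equal(sim$truth$differential$log_fold, log(10))

  # null design: no differential set at prop 0
  sim0 <- simulate_daa("gamma", n = 40, m = 30, prop_differential = 0,
                       seed = 13)
  expect_null(sim0$truth$differential)
  # zero effect: set recorded but distributionally null
  sim1 <- simulate_daa("gamma", n = 40, m = 30, prop_differential = 0.1,
                       effect_fold = 1, seed = 13)
  simref <- simulate_parametric("gamma", n = 40, m = 30, seed = 13,
                                group = rep(c(0L, 1L), 20))
  expect_identical(sim1$counts, simref$counts)
})
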