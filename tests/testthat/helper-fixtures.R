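# Shared fixture builders; all synthetic, generated in code at test time.

tiny_hp <- function(m = 3, pi = 0.5, a0 = 0.05, a1 = 5) {
  list(pi = rep(pi, m), alpha0 = rep(a0, m), alpha1 = rep(a1, m))
}

# Small count matrix with guaranteed positive row totals.
tiny_counts <- function(n = 6, m = 4, seed = 1) {
  sim <- simulate_bmdd(tiny_hp(m), n = n, depths = rep(500, n), seed = seed)
  sim$counts
}

# A strictly positive composition matrix.
tiny_composition <- function(n = 10, m = 5, seed = 1, conc = 2) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    Y <- matrix(rgamma(n * m, shape = conc), n, m)
    X <- Y / rowSums(Y)
    dimnames(X) <- list(paste0("sample", 1:n), paste0("taxon", 1:m))
    X
  })
}

expect_simplex <- function(X, tol = 1e-8) {
  expect_true(all(X >= 0))
  expect_true(max(abs(rowSums(X) - 1)) < tol)
}
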