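test_that("gamma discretization has unit mean, increasing rates, quadrature match", {
  expect_equal(discretize_gamma(0.7, 1)$rate, 1)

  for (alpha in c(0.2, 0.4, 1, 3)) {
    for (K in c(2, 4, 10)) {
      gm <- discretize_gamma(alpha, K)
      expect_equal(sum(gm$rate * gm$weight), 1, tolerance = 1e-10)
      expect_true(all(diff(gm$rate) > 0))
    }
  }
  # quadrature oracle
  expect_equal(discretize_gamma(0.5, 4)$rate, quadrature_gamma_rates(0.5, 4),
               tolerance = 1e-6)
  # independent library cross-check
  expect_equal(discretize_gamma(0.4, 10)$rate,
               as.vector(phangorn::discrete.gamma(0.4, 10)), tolerance = 1e-6)

  expect_error(discretize_gamma(-1, 4), "alpha")
  expect_error(discretize_gamma(0.5, 0), "K")
})

test_that("transition matrices are stochastic and match closed forms", {
  m2 <- rate_model(matrix(c(0L, 1L, 1L, 0L), 2, 2), values = 0.07,
                   labels = c("0", "1"))
  expect_equal(transition_matrix(m2, 0), diag(2), ignore_attr = TRUE)
  for (t in c(0.5, 3, 20)) {
    P <- transition_matrix(m2, t)
    expect_equal(unname(P[1, 1]), (1 + exp(-2 * 0.07 * t)) / 2, tolerance = 1e-12)
  }
  for (seed in 1:10) {
    m <- random_rate_model(4, seed)
    P <- transition_matrix(m, 7.3)
    expect_true(all(P >= 0))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  }
})

test_that("transition matrices satisfy the semigroup property", {
  for (seed in 1:10) {
    k <- if (seed %% 2 == 0) 2 else 4
    m <- random_rate_model(k, seed)
    P1 <- transition_matrix(m, 3.1)
    P2 <- transition_matrix(m, 8.4)
    P12 <- transition_matrix(m, 11.5)
    expect_lt(max(abs(P1 %*% P2 - P12)), 1e-10)
  }
})

test_that("pruning equals exhaustive enumeration on small trees", {
  for (seed in 1:12) {
    n <- 3 + (seed %% 4)
    tr <- simulate_chronogram(n, root_age = 60, seed = seed)
    k <- if (seed %% 2 == 0) 2 else 4
    m <- random_rate_model(k, seed + 100)
    states <- random_states(tr, m$labels, seed + 200,
                            missing_prob = if (seed %% 3 == 0) 0.3 else 0)
    ll <- prune_loglik(tr, states, m)
    ll_oracle <- oracle_loglik(tr, states, generator(m), root_distribution(m),
                               labels = m$labels)
    expect_equal(ll, ll_oracle, tolerance = 1e-8)
  }
})

test_that("degenerate likelihoods are handled exactly", {
  tr <- as_chronogram("((A:5,B:5):5,C:10);")
  m <- rate_model(matrix(c(0L, 2L, 1L, 0L), 2, 2), values = c(0.05, 0.02),
                  labels = c("0", "1"))
  # all tips missing: likelihood 1
  expect_equal(prune_loglik(tr, c(A = "?", B = "?", C = "?"), m), 0)
  # all rates 0, all tips in one state, uniform root: log(1/k)
  m0 <- set_rates(m, c(0, 0))
  expect_equal(prune_loglik(tr, c(A = "1", B = "1", C = "1"), m0), log(1 / 2))
  # stationary root, single-tip data: likelihood = stationary frequency
  m_st <- rate_model(matrix(c(0L, 2L, 1L, 0L), 2, 2), values = c(0.05, 0.02),
                     labels = c("0", "1"), root = "stationary")
  two <- as_chronogram("(A:1,B:1);")
  pi <- stationary_dist(m_st)
  expect_equal(prune_loglik(two, c(A = "1", B = "?"), m_st), log(pi[2]),
               tolerance = 1e-12)
  # unknown tip in the matrix
  expect_error(prune_loglik(tr, c(A = "1", Z = "0"), m), "'Z'")
})

test_that("stationary distributions solve pi Q = 0", {
  for (seed in 1:6) {
    m <- random_rate_model(4, seed)
    pi <- stationary_dist(m)
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_lt(max(abs(pi %*% generator(m))), 1e-10)
  }
})

test_that("rate models validate their structure and serialize losslessly", {
  cl <- matrix(c(0L, 2L, 1L, 0L), 2, 2)
  expect_error(rate_model(cl, values = c(0.1)), "2 values|1 value")
  expect_error(rate_model(cl, values = c(-0.1, 0.2)), ">= 0")
  cl_bad <- matrix(c(0L, 3L, 1L, 0L), 2, 2)
  expect_error(rate_model(cl_bad, values = c(0.1, 0.2)), "contiguous")

  m <- preset_model("odontode_model2", root = "stationary", init = 0.02)
  path <- withr::local_tempfile(fileext = ".json")
  write_rate_model(m, path)
  m2 <- read_rate_model(path)
  expect_equal(m2$classes, m$classes)
  expect_equal(unname(m2$values), unname(m$values))
  expect_identical(m2$root, "stationary")
  # generator rows sum to zero
  expect_lt(max(abs(rowSums(generator(m)))), 1e-12)
})
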