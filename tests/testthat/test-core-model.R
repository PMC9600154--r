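# Negative-binomial and compound (log-normal mixed) transcript models

test_that("negative-binomial pmf matches hand values and the log-gamma form", {
  # r = 1, b = 1 reduces to geometric with p = 1/2
  expect_equal(negbinom_pmf(0, 1, 1), 0.5)
  expect_equal(negbinom_pmf(2, 1, 1), 0.125)

  # independent oracle: binomial-coefficient form evaluated via log-gamma
  nb_oracle <- function(n, r, b) {
    p <- b / (1 + b)
    exp(lgamma(n + r) - lgamma(r) - lgamma(n + 1) +
          r * log(1 - p) + n * log(p))
  }
  expect_equal(negbinom_pmf(5, 2.5, 4.0), nb_oracle(5, 2.5, 4.0),
               tolerance = 1e-12)
  expect_equal(negbinom_pmf(0:40, 7.3, 0.8), nb_oracle(0:40, 7.3, 0.8),
               tolerance = 1e-12)

  # sums to one over the support
  expect_equal(sum(negbinom_pmf(0:2000, 2.5, 4.0)), 1, tolerance = 1e-10)
})

test_that("negative-binomial pmf rejects invalid arguments", {
  expect_error(negbinom_pmf(-1, 1, 1), "non-negative")
  expect_error(negbinom_pmf(1.5, 1, 1), "non-negative integers")
  expect_error(negbinom_pmf(1, 0, 1), "positive")
  expect_error(negbinom_pmf(1, 1, -2), "positive")
})

test_that("compound pmf reduces exactly to the negative binomial at freq_sd = 0", {
  grid <- expand.grid(bf = c(0.1, 1, 5, 20, 50), b = c(0.5, 2, 10, 30, 50))
  for (i in seq_len(nrow(grid))) {
    p <- telegraph_params(grid$bf[i], grid$b[i], 0)
    n <- 0:500
    expect_lt(max(abs(compound_pmf(n, p) -
                        negbinom_pmf(n, grid$bf[i], grid$b[i]))), 1e-8)
  }
})

test_that("compound pmf is normalized and matches closed-form moments", {
  cases <- list(c(2, 5, 1), c(1, 10, 0.5), c(5, 2, 3), c(0.5, 20, 0.4))
  for (cs in cases) {
    p <- telegraph_params(cs[1], cs[2], cs[3])
    mo <- compound_moments(p)
    # Chebyshev-style bound well past the bulk of the distribution
    nmax <- ceiling(mo$mean + 30 * sqrt(mo$variance)) + 200
    q <- compound_pmf(0:nmax, p)
    expect_gt(sum(q), 1 - 1e-6)
    m1 <- sum((0:nmax) * q)
    m2 <- sum((0:nmax)^2 * q)
    expect_equal(m1, mo$mean, tolerance = 1e-6)
    expect_equal(m2 - m1^2, mo$variance, tolerance = 1e-6)
  }
})

test_that("closed-form compound moments follow the law of total variance", {
  expect_equal(compound_moments(telegraph_params(2, 5, 0)),
               list(mean = 10, variance = 60))
  expect_equal(compound_moments(telegraph_params(2, 5, 1)),
               list(mean = 10, variance = 85))
  expect_equal(compound_moments(telegraph_params(1, 1, 0)),
               list(mean = 1, variance = 2))
})

test_that("compound pmf agrees with a Monte-Carlo mixture oracle", {
  # average of the conditional NB pmf over many log-normal draws of the
  # per-cell burst frequency; agreement within 3 Monte-Carlo SEs
  set.seed(4821)
  cases <- list(c(3, 1, 10, 0.5), c(0, 2, 5, 1), c(25, 2, 10, 1.5),
                c(10, 5, 2, 2))
  for (cs in cases) {
    n <- cs[1]; bf <- cs[2]; b <- cs[3]; s <- cs[4]
    s2 <- log(1 + (s / bf)^2)
    r <- rlnorm(1e6, log(bf) - s2 / 2, sqrt(s2))
    draws <- dnbinom(n, size = r, prob = 1 / (1 + b))
    mc <- mean(draws)
    se <- sd(draws) / sqrt(length(draws))
    q <- compound_pmf(n, telegraph_params(bf, b, s))
    expect_lt(abs(q - mc), 3 * se)
  }
})

test_that("quadrature is converged: doubling the nodes leaves the pmf unchanged", {
  p <- telegraph_params(2, 10, 1)
  q1 <- compound_pmf(0:300, p, quad_config(n_nodes = 128))
  q2 <- compound_pmf(0:300, p, quad_config(n_nodes = 256))
  expect_lt(max(abs(q1 - q2)), 1e-8)
})

test_that("log-likelihood sums pointwise log pmf values", {
  p <- telegraph_params(1, 1, 0)
  expect_equal(log_likelihood(0L, p), log(0.5))
  expect_equal(log_likelihood(c(0L, 2L), p), log(0.5) + log(0.125))
  expect_error(log_likelihood(integer(0), p), "non-empty")
})

test_that("log-likelihood flags pmf underflow instead of returning -Inf", {
  # a count absurdly far into the tail underflows to exactly zero
  p <- telegraph_params(0.5, 0.5, 0)
  expect_error(log_likelihood(c(1L, 50000L), p), "underflow")
})

test_that("likelihood at the generating parameters beats a wrong model", {
  # likelihood-consistency: the true parameters should out-score a
  # doubled burst frequency for the clear majority of replicates
  truth <- telegraph_params(2, 5, 0.5)
  wrong <- telegraph_params(4, 5, 0.5)
  wins <- 0L
  n_rep <- 50L
  for (i in seq_len(n_rep)) {
    counts <- sample_compound(truth, 500, seed = 7000 + i)
    if (log_likelihood(counts, truth) > log_likelihood(counts, wrong))
      wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * n_rep))
})

test_that("telegraph parameters validate and round-trip through JSON", {
  p <- telegraph_params(2.5, 10, 0.75)
  expect_equal(params_from_json(params_to_json(p)), p)
  expect_error(telegraph_params(-1, 1), "positive")
  expect_error(telegraph_params(1, 0), "positive")
  expect_error(telegraph_params(1, 1, -0.1), "non-negative")
  expect_error(quad_config(1), ">= 2")
  expect_error(quad_config(128, 0.5), "0.01")
})
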