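# MCMC fitting machinery: contracts, summaries, determinism, prior

make_chain <- function(samples, lps) {
  structure(list(samples = samples, log_posterior = lps,
                 chain = rep(1L, nrow(samples)), config = fit_config(),
                 counts = c(1L, 2L), n_cells = 2L,
                 acceptance_rate = 0.3,
                 rhat = c(burst_freq = 1, burst_size = 1, freq_sd = 1)),
            class = "telegraph_fit")
}

test_that("map_estimate returns the joint argmax with earliest tie-break", {
  smp <- data.frame(burst_freq = c(1, 2, 3, 4),
                    burst_size = c(5, 6, 7, 8),
                    freq_sd = c(0.1, 0.2, 0.3, 0.4))
  fit <- make_chain(smp, c(-5, -1, -3, -4))
  expect_equal(unclass(map_estimate(fit)),
               list(burst_freq = 2, burst_size = 6, freq_sd = 0.2))
  # two equal maxima: the earlier sample wins
  fit2 <- make_chain(smp, c(-5, -1, -1, -4))
  expect_equal(map_estimate(fit2)$burst_freq, 2)
})

test_that("credible intervals use equal-tailed type-7 quantiles", {
  smp <- data.frame(burst_freq = 1:100, burst_size = 1:100,
                    freq_sd = 1:100)
  fit <- make_chain(smp, rep(0, 100))
  ci <- credible_interval(fit, 0.95)
  expect_equal(unname(ci["burst_freq", ]), c(3.475, 97.525))
  # level -> 1 limit gives the sample range
  ci99 <- credible_interval(fit, 0.999999)
  expect_equal(unname(ci99["burst_freq", ]), c(1, 100), tolerance = 1e-3)
  # symmetric samples give an interval symmetric about the median
  sym <- data.frame(burst_freq = c(1:9), burst_size = 1:9, freq_sd = 1:9)
  fit_sym <- make_chain(sym, rep(0, 9))
  ci50 <- credible_interval(fit_sym, 0.5)
  expect_equal(mean(ci50["burst_freq", ]), 5)
  expect_error(credible_interval(fit, 1.2), "between 0 and 1")
})

test_that("fit refuses degenerate inputs", {
  expect_error(fit_telegraph(integer(0)), "non-empty")
  expect_error(fit_telegraph(c(0L, 0L, 0L)), "unidentifiable")
  expect_error(fit_telegraph(c(1.5, 2)), "non-negative integers")
  expect_error(fit_config(n_steps = 100, n_burn = 100), "exceed")
  expect_error(fit_config(n_walkers = 7), "even")
  expect_error(fit_config(bounds = list(burst_freq = c(2, 1),
                                        burst_size = c(1, 2),
                                        freq_sd = c(1, 2))),
               "ordered")
})

test_that("fits are reproducible for a fixed seed", {
  counts <- sample_compound(telegraph_params(2, 8, 0.5), 300, seed = 1)
  cfg <- fit_config(n_steps = 120, n_burn = 40, n_walkers = 8, seed = 99)
  f1 <- suppressWarnings(fit_telegraph(counts, cfg))
  f2 <- suppressWarnings(fit_telegraph(counts, cfg))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$log_posterior, f2$log_posterior)
})

test_that("prior-only sampling recovers the log-uniform marginals", {
  # thin to roughly independent generations before the KS comparison:
  # ensemble samples within a generation share the walker cloud
  cfg <- fit_config(n_steps = 16000, n_burn = 500, n_walkers = 16,
                    seed = 12345, prior_only = TRUE)
  fit <- suppressWarnings(fit_telegraph(c(1L, 2L, 3L), cfg))
  gen <- rep(seq_len(cfg$n_steps - cfg$n_burn), each = cfg$n_walkers)
  keep <- gen %% 24 == 0   # ~10,000 retained samples
  expect_gte(sum(keep), 10000)
  for (nm in c("burst_freq", "burst_size", "freq_sd")) {
    b <- cfg$bounds[[nm]]
    u <- (log(fit$samples[[nm]][keep]) - log(b[1])) /
      (log(b[2]) - log(b[1]))
    ks <- suppressWarnings(ks.test(u, "punif"))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("the fitted model object supports the standard S3 interface", {
  counts <- sample_compound(telegraph_params(2, 8, 0.5), 400, seed = 2)
  fit <- suppressWarnings(
    fit_telegraph(counts, fit_config(n_steps = 200, n_burn = 80,
                                     n_walkers = 12, seed = 5)))
  expect_named(coef(fit), c("burst_freq", "burst_size", "freq_sd"))
  expect_equal(dim(confint(fit)), c(3L, 2L))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "nobs"), 400L)
  expect_lt(as.numeric(ll), 0)
  sim <- simulate(fit, nsim = 50, seed = 3)
  expect_length(sim, 50)
  d <- fitted_pmf(fit)
  expect_equal(sum(d$empirical), 1, tolerance = 1e-9)
  expect_true(all(d$fitted >= 0))
  expect_length(residuals(fit), max(counts) + 1L)
  expect_output(print(fit), "MAP")
  expect_output(print(summary(fit)), "acceptance")
})
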