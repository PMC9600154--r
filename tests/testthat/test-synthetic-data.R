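# Seeded generators: compound sampling, Gillespie telegraph, coupled
# pairs, synthetic spot tables

test_that("compound sampling matches closed-form moments", {
  p <- telegraph_params(2, 5, 0)
  x <- sample_compound(p, 1e5, seed = 1)
  mo <- compound_moments(p)
  se_mean <- sqrt(mo$variance / length(x))
  expect_lt(abs(mean(x) - mo$mean), 3 * se_mean)
  expect_lt(abs(var(x) - mo$variance) / mo$variance, 0.05)

  # with extrinsic noise the variance picks up the b^2 s^2 term
  p2 <- telegraph_params(2, 5, 1)
  y <- sample_compound(p2, 1e5, seed = 2)
  expect_lt(abs(var(y) - 85) / 85, 0.05)
})

test_that("compound sampling at freq_sd = 0 matches the NB pmf (chi-squared)", {
  p <- telegraph_params(2, 5, 0)
  x <- sample_compound(p, 1e4, seed = 3)
  ub <- max(x)
  probs <- negbinom_pmf(0:ub, 2, 5)
  obs <- tabulate(x + 1L, nbins = ub + 1L)
  # pool the sparse tail so expected cell counts stay reasonable
  keep <- which(probs * length(x) >= 5)
  cut <- max(keep)
  obs2 <- c(obs[1:cut], sum(obs[-(1:cut)]))
  probs2 <- c(probs[1:cut], 1 - sum(probs[1:cut]))
  gof <- suppressWarnings(chisq.test(obs2, p = probs2))
  expect_gt(gof$p.value, 0.01)
})

test_that("generators are deterministic under a fixed seed", {
  p <- telegraph_params(2, 5, 1)
  expect_identical(sample_compound(p, 100, seed = 9),
                   sample_compound(p, 100, seed = 9))
  rates <- kinetic_rates(1, 50, 500, 1)
  expect_identical(gillespie_telegraph(rates, 20, seed = 9),
                   gillespie_telegraph(rates, 20, seed = 9))
  expect_identical(
    simulate_coupled_pair(p, p, coupling_spec(1, 10), 50, seed = 9),
    simulate_coupled_pair(p, p, coupling_spec(1, 10), 50, seed = 9))
  expect_identical(simulate_spot_table(0:5, seed = 9),
                   simulate_spot_table(0:5, seed = 9))
  expect_error(sample_compound(p, 0), "positive integer")
})

test_that("gillespie occupancy matches lambda/(lambda+nu) times K/delta", {
  rates <- kinetic_rates(2, 6, 40, 1)
  x <- gillespie_telegraph(rates, 4000, seed = 21)
  mean_theory <- 40 * 2 / (2 + 6)   # K/delta * occupancy
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mean_theory), 3 * se)
})

test_that("constitutive promoter limit is Poisson-like", {
  # nu = 0: once active, the gene stays active; K/delta = 10
  rates <- kinetic_rates(100, 0, 10, 1)
  x <- gillespie_telegraph(rates, 5000, seed = 22)
  expect_gt(var(x) / mean(x), 0.9)
  expect_lt(var(x) / mean(x), 1.1)
  expect_equal(mean(x), 10, tolerance = 0.1)
})

test_that("bursty-regime simulation converges to the negative binomial", {
  # lambda/delta = 1, nu/delta = 50, K/delta = 500 -> NB(r = 1, b = 10)
  rates <- kinetic_rates(1, 50, 500, 1)
  x <- gillespie_telegraph(rates, 1e4, seed = 23)
  ub <- max(max(x), 200)
  emp <- tabulate(x + 1L, nbins = ub + 1L) / length(x)
  tv <- 0.5 * sum(abs(emp - negbinom_pmf(0:ub, 1, 10)))
  expect_lt(tv, 0.05)
})

test_that("kinetic rates validate and map to bursty-limit ratios", {
  expect_error(kinetic_rates(1, 50, 500, 0), "positive")
  expect_error(gillespie_telegraph(kinetic_rates(1, 50, 500, 1), 0),
               "positive integer")
  expect_warning(gillespie_telegraph(kinetic_rates(1, 50, 500, 1), 2,
                                     t_end = 1, seed = 1),
                 "steady state")
  p <- nb_approx_params(kinetic_rates(1, 50, 500, 1))
  expect_equal(unclass(p),
               list(burst_freq = 1, burst_size = 10, freq_sd = 0))
  expect_warning(nb_approx_params(kinetic_rates(10, 50, 500, 1)),
                 "bursty regime")
})

test_that("zero-exponent coupling reproduces the independent marginal", {
  p_up <- telegraph_params(2, 5, 0.5)
  p_dn <- telegraph_params(1, 8, 0)
  pc <- simulate_coupled_pair(p_up, p_dn, coupling_spec(0, 10), 1e4,
                              seed = 31)
  ub <- max(pc$y)
  probs <- compound_pmf(0:ub, p_dn)
  obs <- tabulate(pc$y + 1L, nbins = ub + 1L)
  keep <- which(probs * length(pc$y) >= 5)
  cut <- max(keep)
  obs2 <- c(obs[1:cut], sum(obs[-(1:cut)]))
  probs2 <- c(probs[1:cut], 1 - sum(probs[1:cut]))
  gof <- suppressWarnings(chisq.test(obs2, p = probs2))
  expect_gt(gof$p.value, 0.01)
})

test_that("strong coupling is detectable, zero coupling is not", {
  p_up <- telegraph_params(2, 5, 0.5)
  p_dn <- telegraph_params(1, 8, 0.3)
  pc1 <- simulate_coupled_pair(p_up, p_dn, coupling_spec(1, 10), 500,
                               seed = 41)
  r1 <- permutation_significance(pc1, n_shuffles = 500, seed = 42)
  expect_lt(r1$p_value, 0.01)
  pc0 <- simulate_coupled_pair(p_up, p_dn, coupling_spec(0, 10), 500,
                               seed = 41)
  r0 <- permutation_significance(pc0, n_shuffles = 500, seed = 42)
  expect_gt(r0$p_value, 0.01)
})

test_that("spot tables emulate controls and recover true counts", {
  truth <- rep(0:10, each = 30)
  st <- simulate_spot_table(truth, unit_intensity = 100,
                            intensity_cv = 0.1, false_positive_rate = 0.2,
                            seed = 55)
  expect_true(all(c("zero_control", "low_control", "sample") %in%
                    st$sample_class))
  calib <- calibrate_spots(st)
  expect_lt(calib$threshold, calib$unit_intensity)
  counts <- integrate_copy_numbers(st, calib, attr(st, "cells"))
  expect_gte(mean(abs(counts - truth) <= 1), 0.95)

  # no expression and no false positives leaves an empty sample block
  st0 <- simulate_spot_table(rep(0L, 5), false_positive_rate = 0,
                             seed = 56)
  expect_identical(sum(st0$sample_class == "sample"), 0L)
})
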