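#' Negative-binomial transcript distribution of the bursty telegraph model
#'
#' In the bursty limit of the two-state promoter model (deactivation much
#' faster than activation, transcription much faster than degradation)
#' the steady-state mRNA copy number is negative-binomial with shape
#' equal to the normalized burst frequency and mean equal to burst
#' frequency times burst size. The success parameter is
#' `burst_size / (1 + burst_size)`, so that the mean is
#' `burst_freq * burst_size` and the variance
#' `burst_freq * burst_size * (1 + burst_size)`.
#'
#' @param n Vector of non-negative integer copy numbers.
#' @param burst_freq Positive real; normalized burst frequency (shape).
#' @param burst_size Positive real; mean burst size.
#' @return `P(N = n)` for each element of `n`.
#' @examples
#' negbinom_pmf(0:5, burst_freq = 1, burst_size = 1)
#' @export
negbinom_pmf <- function(n, burst_freq, burst_size) {
  n <- check_counts(n, "n")
  check_scalar(burst_freq, "burst_freq", positive = TRUE)
  check_scalar(burst_size, "burst_size", positive = TRUE)
  stats::dnbinom(n, size = burst_freq, prob = 1 / (1 + burst_size))
}

# log-normal with mean m and SD s of the variate itself -> (meanlog, sdlog)
lnorm_pars <- function(m, s) {
  s2 <- log1p((s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# Gauss-Hermite nodes/weights, cached per node count
.gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(n_nodes) {
  key <- as.character(n_nodes)
  if (is.null(.gh_cache[[key]]))
    .gh_cache[[key]] <- pracma::gaussHermite(n_nodes)
  .gh_cache[[key]]
}

# quadrature grid over the per-cell burst frequency r:
# nodes r_i on the log-normal, probability weights summing to 1
freq_grid <- function(params, quad) {
  lp <- lnorm_pars(params$burst_freq, params$freq_sd)
  gh <- gh_rule(quad$n_nodes)
  list(r = exp(lp[["meanlog"]] + lp[["sdlog"]] * sqrt(2) * gh$x),
       w = gh$w / sum(gh$w))
}

#' Compound transcript distribution with log-normal extrinsic noise
#'
#' Mixes the negative-binomial copy-number distribution over a log-normal
#' distribution of the per-cell burst frequency (mean `burst_freq`, SD
#' `freq_sd`, both on the degradation-normalized scale). The mixture
#' integral is evaluated by deterministic Gauss-Hermite quadrature in
#' log-frequency space, so results are reproducible bit-for-bit for a
#' fixed quadrature configuration. With `freq_sd = 0` the mixing
#' distribution is degenerate and the pure negative binomial is returned
#' exactly.
#'
#' @param n Vector of non-negative integer copy numbers.
#' @param params A [telegraph_params()] object.
#' @param quad A [quad_config()] object.
#' @return `q(n)` for each element of `n`.
#' @examples
#' compound_pmf(0:5, telegraph_params(2, 5, 1))
#' @export
compound_pmf <- function(n, params, quad = quad_config()) {
  stopifnot(is.telegraph_params(params), inherits(quad, "quad_config"))
  if (params$freq_sd == 0)
    return(negbinom_pmf(n, params$burst_freq, params$burst_size))
  n <- check_counts(n, "n")
  g <- freq_grid(params, quad)
  pmf <- nb_mix_pmf(max(n), g$r, g$w, params$burst_size)
  pmf[n + 1L]
}

# mixture pmf over n = 0..nmax for NB(shape r_i, burst size b) with
# probability weights w_i, via the stable upward pmf recurrence
# pmf(n+1) = pmf(n) * (n + r) / (n + 1) * b/(1+b). Nodes whose pmf(0)
# (de)normalizes below double precision would lose their whole rising
# phase to underflow, so they are evaluated with the exact log-gamma
# pmf instead.
nb_mix_pmf <- function(nmax, r, w, b) {
  pp <- b / (1 + b)
  prob <- 1 / (1 + b)
  row <- exp(-r * log1p(b))
  deep <- row < 1e-280
  out <- numeric(nmax + 1L)
  if (any(!deep)) {
    rr <- r[!deep]; ww <- w[!deep]
    rw <- row[!deep]
    out[1L] <- sum(ww * rw)
    if (nmax >= 1L) for (n in 0:(nmax - 1L)) {
      rw <- rw * (n + rr) * (pp / (n + 1))
      out[n + 2L] <- sum(ww * rw)
    }
  }
  if (any(deep)) {
    for (i in which(deep))
      out <- out + w[i] * stats::dnbinom(0:nmax, size = r[i], prob = prob)
  }
  out
}

#' Closed-form moments of the compound transcript distribution
#'
#' By the law of total expectation/variance over the mixing frequency r
#' (mean rbar, variance s^2): mean = rbar * b and
#' variance = rbar * b * (1 + b) + b^2 * s^2, with b the burst size.
#'
#' @param params A [telegraph_params()] object.
#' @return A list with elements `mean` and `variance`.
#' @examples
#' compound_moments(telegraph_params(2, 5, 1)) # mean 10, variance 85
#' @export
compound_moments <- function(params) {
  stopifnot(is.telegraph_params(params))
  rbar <- params$burst_freq
  b <- params$burst_size
  s <- params$freq_sd
  list(mean = rbar * b, variance = rbar * b * (1 + b) + b^2 * s^2)
}

#' Log-likelihood of counts under the compound model
#'
#' Computes the compound pmf once over `0:max(counts)` and sums its log
#' over the observations. A pmf value that underflows to exactly zero at
#' an observed count raises an error (it signals that the quadrature
#' truncation cannot support the data), rather than silently returning
#' `-Inf`.
#'
#' @param counts Non-empty vector of non-negative integer counts.
#' @param params A [telegraph_params()] object.
#' @param quad A [quad_config()] object.
#' @return The scalar log-likelihood.
#' @export
log_likelihood <- function(counts, params, quad = quad_config()) {
  counts <- check_counts(counts, "counts")
  pmf <- compound_pmf(0:max(counts), params, quad)
  p <- pmf[counts + 1L]
  if (any(p == 0))
    stop("compound pmf underflowed to 0 at an observed count; ",
         "the quadrature cannot support these data at these parameters",
         call. = FALSE)
  sum(log(p))
}

# fast path used by the MCMC sampler: counts pre-tabulated into unique
# values and multiplicities; returns -Inf on underflow instead of erroring
loglik_tabulated <- function(values, mult, params, quad) {
  g <- freq_grid(params, quad)
  pmf <- nb_mix_pmf(max(values), g$r, g$w, params$burst_size)
  p <- pmf[values + 1L]
  if (any(p <= 0)) return(-Inf)
  sum(mult * log(p))
}
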