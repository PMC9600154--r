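#' Configuration for Bayesian fitting of the compound model
#'
#' Priors are log-uniform (flat on the log scale) within the given
#' bounds, the scale-free choice for positive rate ratios. Note that
#' the log-uniform prior on `freq_sd` is deliberately conservative
#' about extrinsic noise: every decade of indistinguishably-small SD
#' values carries equal prior mass, so the posterior reports extrinsic
#' dispersion only when the likelihood demands it. Sampling is
#' performed in log-parameter space by an affine-invariant ensemble
#' sampler (Goodman-Weare stretch moves), which mixes well on the
#' correlated, ridge-shaped posteriors this model produces.
#'
#' @param bounds Named list of length-2 numeric ranges (lower, upper) for
#'   `burst_freq`, `burst_size`, `freq_sd`.
#' @param n_steps Ensemble generations (each generation updates every
#'   walker once).
#' @param n_burn Burn-in generations discarded.
#' @param n_walkers Number of ensemble walkers (>= 8; even).
#' @param stretch Stretch-move scale parameter `a` (> 1; default 2).
#' @param seed Integer seed; the whole fit is reproducible given it.
#' @param quad A [quad_config()] for the likelihood quadrature.
#' @param prior_only If `TRUE` the likelihood is switched off and the
#'   sampler targets the prior alone (a validation hook).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(bounds = list(burst_freq = c(1e-2, 1e3),
                                     burst_size = c(1e-2, 1e3),
                                     freq_sd = c(1e-3, 1e2)),
                       n_steps = 1500L, n_burn = 500L, n_walkers = 32L,
                       stretch = 2, seed = 1L, quad = quad_config(),
                       prior_only = FALSE) {
  stopifnot(inherits(quad, "quad_config"))
  for (nm in c("burst_freq", "burst_size", "freq_sd")) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2L || any(b <= 0) || b[1] >= b[2])
      stop(sprintf("bounds for '%s' must be a positive, ordered pair", nm),
           call. = FALSE)
  }
  n_steps <- as.integer(n_steps); n_burn <- as.integer(n_burn)
  n_walkers <- as.integer(n_walkers)
  if (n_steps <= n_burn) stop("'n_steps' must exceed 'n_burn'", call. = FALSE)
  if (n_walkers < 8L || n_walkers %% 2L != 0L)
    stop("'n_walkers' must be an even integer >= 8", call. = FALSE)
  if (!is.numeric(stretch) || stretch <= 1)
    stop("'stretch' must exceed 1", call. = FALSE)
  structure(list(bounds = bounds[c("burst_freq", "burst_size", "freq_sd")],
                 n_steps = n_steps, n_burn = n_burn, n_walkers = n_walkers,
                 stretch = stretch, seed = as.integer(seed), quad = quad,
                 prior_only = isTRUE(prior_only)),
            class = "fit_config")
}

#' Fit the compound bursty-transcription model by MCMC
#'
#' Samples the posterior over (burst frequency, burst size, frequency
#' SD) given per-cell transcript counts, using an affine-invariant
#' ensemble sampler (Goodman-Weare stretch moves) with log-uniform
#' priors. Internally the sampler works in moment coordinates (log
#' mean, log of Fano factor minus one, logit-scaled extrinsic fraction)
#' where the posterior is connected and the weak identifiability of the
#' mixing SD appears as a single flat ridge; the prior is carried over
#' by the coordinate Jacobian and samples are reported in the model
#' parameters. Walkers are initialized from a short deterministic
#' ascent and spread along the extrinsic-fraction direction; walkers
#' whose mean retained log-posterior stays more than 6 units below the
#' median walker are discarded as non-equilibrated. Convergence is
#' summarized by a split R-hat per parameter computed over pooled
#' walker groups; a warning is raised if any R-hat exceeds 1.05 or the
#' post-burn-in acceptance rate falls outside [0.1, 0.6].
#'
#' @param counts Non-empty vector of non-negative integer per-cell
#'   counts. All-zero counts are refused (the mean is unidentifiable).
#' @param config A [fit_config()].
#' @return An object of class `telegraph_fit` with components `samples`
#'   (post-burn-in data frame of the three parameters), `log_posterior`,
#'   `chain` (walker id per sample), `acceptance_rate`, `rhat`,
#'   `counts`, `config`. Methods: `print`, `summary`, [coef()] (MAP
#'   triplet), [confint()] (credible intervals), `logLik`, `plot`,
#'   `simulate`, `residuals`.
#' @seealso [map_estimate()], [credible_interval()],
#'   [posterior_noise_decomposition()]
#' @examples
#' counts <- sample_compound(telegraph_params(2, 10, 1), 200, seed = 1)
#' fit <- fit_telegraph(counts, fit_config(n_steps = 150, n_burn = 50,
#'                                         n_walkers = 16, seed = 1))
#' coef(fit)
#' @export
fit_telegraph <- function(counts, config = fit_config()) {
  counts <- check_counts(counts, "counts")
  stopifnot(inherits(config, "fit_config"))
  if (!config$prior_only && all(counts == 0))
    stop("all counts are zero: the mean expression level is unidentifiable",
         call. = FALSE)

  lb <- log(vapply(config$bounds, `[`, 0, 1L))
  ub <- log(vapply(config$bounds, `[`, 0, 2L))
  tab <- table(counts)
  values <- as.integer(names(tab))
  mult <- as.numeric(tab)

  # The sampler works in the moment coordinates
  #   u = (log mean, log(Fano - 1), z),  e = plogis(z) * (1 - 1/Fano)
  # rather than in (log bf, log b, log s) directly. In the original
  # coordinates the posterior has two nearly disconnected regimes (no
  # extrinsic noise with a larger burst size vs strong mixing with a
  # smaller one) between which stretch moves cannot jump; in moment
  # coordinates the same surface is a single connected blob with a flat
  # direction along z, which the affine-invariant ensemble handles by
  # stretching. The log-uniform prior on the original parameters is
  # carried over through the log-Jacobian of th(u).
  u_to_th <- function(u) {
    mu <- exp(u[1])
    fano <- 1 + exp(u[2])
    e <- stats::plogis(u[3]) * (1 - 1 / fano)
    b <- (1 - e) * fano - 1
    if (b <= 0) return(rep(NA_real_, 3))
    bf <- mu / b
    s <- sqrt(e * mu * fano) / b
    log(c(bf, b, max(s, 1e-300)))
  }
  th_to_u <- function(th) {
    bf <- exp(th[1]); b <- exp(th[2]); s <- exp(th[3])
    mu <- bf * b
    fano <- 1 + b + b * s^2 / bf
    e <- b * s^2 / (bf * (1 + b) + b * s^2)
    c(log(mu), log(fano - 1), stats::qlogis(min(e / (1 - 1 / fano),
                                                1 - 1e-12)))
  }
  log_jac <- function(u, th) {
    h <- 1e-6
    J <- vapply(1:3, function(i) {
      up <- u; up[i] <- up[i] + h
      (u_to_th(up) - th) / h
    }, numeric(3))
    d <- det(J)
    if (!is.finite(d) || d <= 0) return(-Inf)
    log(d)
  }
  # prior-only mode samples the flat target directly in th coordinates
  # (its natural space); with data the sampler runs in u with the
  # box-prior carried over by the Jacobian
  logpost <- if (config$prior_only) {
    function(th) if (any(th < lb) || any(th > ub)) -Inf else 0
  } else {
    function(u) {
      th <- u_to_th(u)
      if (anyNA(th) || any(th < lb) || any(th > ub)) return(-Inf)
      lj <- log_jac(u, th)
      if (lj == -Inf) return(-Inf)
      p <- list(burst_freq = exp(th[1]), burst_size = exp(th[2]),
                freq_sd = exp(th[3]))
      lj + loglik_tabulated(values, mult, p, config$quad)
    }
  }

  # moment-based initialization in u, with a short deterministic ascent
  m <- mean(counts); v <- stats::var(counts)
  if (config$prior_only || m == 0) {
    u0 <- th_to_u((lb + ub) / 2)
  } else {
    fano0 <- max(v / m, 1.05)
    starts <- lapply(c(-3, 0, 1.5), function(z0)
      c(log(m), log(fano0 - 1), z0))
    opts <- lapply(starts, function(s0)
      stats::optim(s0, function(uu) -logpost(uu), method = "Nelder-Mead",
                   control = list(maxit = 200)))
    u0 <- opts[[which.min(vapply(opts, `[[`, 0, "value"))]]$par
  }

  nw <- config$n_walkers
  n_keep <- config$n_steps - config$n_burn
  samples <- matrix(NA_real_, n_keep * nw, 3L)
  lps <- numeric(n_keep * nw)
  chain_id <- integer(n_keep * nw)
  acc_post <- 0L
  a <- config$stretch

  with_seed(config$seed, {
    if (config$prior_only) {
      walkers <- matrix(stats::runif(3L * nw, rep(lb, each = nw),
                                     rep(ub, each = nw)), nrow = nw)
    } else {
      # spread walkers along the whole extrinsic-fraction direction z
      # (from the smallest representable mixing up to past the ascent
      # optimum); the posterior is connected along z, so the ensemble
      # can then balance mass between weak- and strong-mixing regions
      z_hi <- max(u0[3] + 1, 2)
      walkers <- matrix(NA_real_, nw, 3L)
      for (k in seq_len(nw)) {
        cand <- c(u0[1:2] + stats::rnorm(2, 0, 0.15),
                  stats::runif(1, z_hi - 16, z_hi))
        tries <- 0L
        while (!is.finite(logpost(cand)) && tries < 40L) {
          cand[3] <- cand[3] + 1
          tries <- tries + 1L
        }
        if (!is.finite(logpost(cand))) cand <- u0
        walkers[k, ] <- cand
      }
    }
    lp <- apply(walkers, 1L, logpost)
    half <- nw %/% 2L
    sets <- list(seq_len(half), (half + 1L):nw)
    for (step in seq_len(config$n_steps)) {
      for (h in 1:2) {
        active <- sets[[h]]; other <- sets[[3L - h]]
        z <- ((a - 1) * stats::runif(length(active)) + 1)^2 / a
        j <- other[sample.int(length(other), length(active),
                              replace = TRUE)]
        u <- stats::runif(length(active))
        for (ii in seq_along(active)) {
          k <- active[ii]
          prop <- walkers[j[ii], ] + z[ii] * (walkers[k, ] - walkers[j[ii], ])
          lp_prop <- logpost(prop)
          if (log(u[ii]) < 2 * log(z[ii]) + lp_prop - lp[k]) {
            walkers[k, ] <- prop
            lp[k] <- lp_prop
            if (step > config$n_burn) acc_post <- acc_post + 1L
          }
        }
      }
      if (step > config$n_burn) {
        i <- (step - config$n_burn - 1L) * nw + seq_len(nw)
        samples[i, ] <- walkers
        lps[i] <- lp
        chain_id[i] <- seq_len(nw)
      }
    }
  })

  # map stored u samples back to the model parameters; the reported
  # log-posterior is on the log-parameter scale (flat prior there), so
  # the sampling-space Jacobian is removed again
  if (config$prior_only) {
    th_mat <- samples
  } else {
    th_mat <- t(apply(samples, 1L, u_to_th))
    lj_vec <- vapply(seq_len(nrow(samples)), function(i)
      log_jac(samples[i, ], th_mat[i, ]), 0)
    lps <- lps - lj_vec
  }
  smp <- data.frame(burst_freq = exp(th_mat[, 1]),
                    burst_size = exp(th_mat[, 2]),
                    freq_sd = exp(th_mat[, 3]))
  acc_rate <- acc_post / (n_keep * nw)

  # drop walkers that stayed decisively below the ensemble for the
  # whole retained run (mean log-posterior more than 6 units under the
  # median walker): they failed to equilibrate out of a region the
  # posterior has rejected; walkers exploring the flat part of the
  # mixing ridge sit within a few units and are kept
  wmean <- vapply(split(lps, chain_id), mean, 0)
  stuck <- wmean < stats::median(wmean) - 6
  if (any(stuck)) {
    keep_rows <- !(chain_id %in% as.integer(names(wmean))[stuck])
    th_mat <- th_mat[keep_rows, , drop = FALSE]
    lps <- lps[keep_rows]
    chain_id <- chain_id[keep_rows]
    smp <- smp[keep_rows, , drop = FALSE]
    rownames(smp) <- NULL
  }

  # R-hat over pooled walker groups (split in generation halves inside
  # split_rhat); per-walker traces are too short and autocorrelated for
  # a meaningful walker-level diagnostic
  group_id <- (match(chain_id, sort(unique(chain_id))) - 1L) %/%
    max(length(unique(chain_id)) %/% 4L, 1L) + 1L
  rhat <- stats::setNames(split_rhat(th_mat, group_id), names(smp))
  if (any(rhat > 1.05, na.rm = TRUE))
    warning(sprintf("split R-hat above 1.05 (%s); chains may not have converged",
                    paste(sprintf("%s=%.3f", names(rhat), rhat), collapse = ", ")),
            call. = FALSE)
  if (acc_rate < 0.1 || acc_rate > 0.6)
    warning(sprintf("post-burn-in acceptance rate %.2f outside [0.1, 0.6]",
                    acc_rate), call. = FALSE)

  structure(list(samples = smp, log_posterior = lps, chain = chain_id,
                 acceptance_rate = acc_rate, rhat = rhat,
                 n_walkers_dropped = sum(stuck),
                 counts = counts, config = config,
                 n_cells = length(counts)),
            class = "telegraph_fit")
}

#' Maximum a posteriori parameter triplet of a fit
#'
#' Returns the jointly sampled triplet with the highest log-posterior
#' (the argmax over chain samples, not per-parameter marginal modes).
#' Ties resolve to the earliest sample in chain order.
#'
#' @param fit A `telegraph_fit`.
#' @return A [telegraph_params()] object.
#' @export
map_estimate <- function(fit) {
  stopifnot(inherits(fit, "telegraph_fit"))
  if (nrow(fit$samples) == 0L) stop("empty chain", call. = FALSE)
  i <- which.max(fit$log_posterior)
  telegraph_params(fit$samples$burst_freq[i], fit$samples$burst_size[i],
                   fit$samples$freq_sd[i])
}

#' Equal-tailed marginal credible intervals
#'
#' Per-parameter quantile intervals at levels `(1-level)/2` and
#' `(1+level)/2`, using linear-interpolation (type 7) quantiles.
#'
#' @param fit A `telegraph_fit`.
#' @param level Credibility level in (0, 1); default 0.95.
#' @return A matrix with one row per parameter and columns `lower`,
#'   `upper`.
#' @export
credible_interval <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "telegraph_fit"))
  if (nrow(fit$samples) == 0L) stop("empty chain", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must lie strictly between 0 and 1", call. = FALSE)
  probs <- c((1 - level) / 2, (1 + level) / 2)
  ci <- t(vapply(fit$samples, function(v)
    stats::quantile(v, probs, names = FALSE, type = 7), numeric(2)))
  colnames(ci) <- c("lower", "upper")
  ci
}

#' @export
coef.telegraph_fit <- function(object, ...) {
  unlist(unclass(map_estimate(object)))
}

#' @export
confint.telegraph_fit <- function(object, parm, level = 0.95, ...) {
  ci <- credible_interval(object, level)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
logLik.telegraph_fit <- function(object, ...) {
  ll <- log_likelihood(object$counts, map_estimate(object),
                       object$config$quad)
  structure(ll, df = 3L, nobs = object$n_cells, class = "logLik")
}

#' @export
print.telegraph_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Compound bursty-transcription model fit (%d cells, %d MCMC samples)\n",
              x$n_cells, nrow(x$samples)))
  cat("MAP estimates:\n")
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
summary.telegraph_fit <- function(object, level = 0.95, ...) {
  ci <- credible_interval(object, level)
  out <- list(map = coef(object), ci = ci, level = level,
              rhat = object$rhat, acceptance_rate = object$acceptance_rate,
              n_cells = object$n_cells, n_samples = nrow(object$samples),
              mean_count = mean(object$counts),
              var_count = stats::var(object$counts))
  class(out) <- "summary.telegraph_fit"
  out
}

#' @export
print.summary.telegraph_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Compound bursty-transcription model: %d cells, mean %.2f, variance %.2f\n",
              x$n_cells, x$mean_count, x$var_count))
  tab <- cbind(MAP = x$map, x$ci, rhat = x$rhat)
  print(round(tab, digits))
  cat(sprintf("%d posterior samples; acceptance rate %.2f; %g%% equal-tailed intervals\n",
              x$n_samples, x$acceptance_rate, 100 * x$level))
  invisible(x)
}

#' Empirical and fitted copy-number distributions
#'
#' Tabulates the observed counts and evaluates the fitted compound pmf
#' at the MAP parameters over the same support, for plotting fitted
#' versus empirical distributions.
#'
#' @param fit A `telegraph_fit`.
#' @return A data frame with columns `n`, `empirical`, `fitted`.
#' @export
fitted_pmf <- function(fit) {
  stopifnot(inherits(fit, "telegraph_fit"))
  nmax <- max(fit$counts)
  emp <- tabulate(fit$counts + 1L, nbins = nmax + 1L) / fit$n_cells
  fitv <- compound_pmf(0:nmax, map_estimate(fit), fit$config$quad)
  data.frame(n = 0:nmax, empirical = emp, fitted = fitv)
}

#' @export
plot.telegraph_fit <- function(x, ...) {
  d <- fitted_pmf(x)
  graphics::barplot(d$empirical, names.arg = d$n, col = "grey85",
                    border = NA, xlab = "mRNA copy number",
                    ylab = "probability",
                    main = "Empirical vs fitted copy-number distribution",
                    ylim = c(0, max(d$empirical, d$fitted) * 1.05), ...)
  xpos <- seq(0.7, by = 1.2, length.out = nrow(d))
  graphics::lines(xpos, d$fitted, col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c("data", "MAP fit"),
                   fill = c("grey85", NA), border = NA,
                   col = c(NA, "firebrick"), lty = c(NA, 1), lwd = c(NA, 2),
                   bty = "n")
  invisible(d)
}

#' @export
simulate.telegraph_fit <- function(object, nsim = 1, seed = NULL, ...) {
  n <- if (nsim == 1) object$n_cells else nsim
  sample_compound(map_estimate(object), n, seed = seed)
}

#' @export
residuals.telegraph_fit <- function(object, ...) {
  d <- fitted_pmf(object)
  n <- object$n_cells
  (d$empirical - d$fitted) / sqrt(pmax(d$fitted * (1 - d$fitted), 1e-12) / n)
}
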