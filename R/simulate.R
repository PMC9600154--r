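#' Sample per-cell counts from the compound bursty model
#'
#' For each cell, draws a burst frequency r from the log-normal mixing
#' distribution (with `freq_sd = 0`, r equals `burst_freq` exactly) and
#' then a negative-binomial count with shape r and success parameter
#' `burst_size / (1 + burst_size)`.
#'
#' @param params A [telegraph_params()] object.
#' @param n_cells Number of cells to draw (>= 1). Imaged samples in
#'   smFISH experiments typically span 200-1,000 cells.
#' @param seed Integer seed.
#' @return An integer vector of per-cell counts.
#' @examples
#' sample_compound(telegraph_params(2, 5, 1), 10, seed = 1)
#' @export
sample_compound <- function(params, n_cells, seed = NULL) {
  stopifnot(is.telegraph_params(params))
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L)
    stop("'n_cells' must be a positive integer", call. = FALSE)
  with_seed(seed, {
    r <- if (params$freq_sd == 0) rep(params$burst_freq, n_cells)
    else {
      lp <- lnorm_pars(params$burst_freq, params$freq_sd)
      stats::rlnorm(n_cells, lp[["meanlog"]], lp[["sdlog"]])
    }
    stats::rnbinom(n_cells, size = r, prob = 1 / (1 + params$burst_size))
  })
}

#' Exact stochastic simulation of the two-state promoter scheme
#'
#' Simulates independent cells with the Gillespie algorithm over the
#' four reactions of the telegraph scheme (promoter activation and
#' deactivation, transcription while active, first-order mRNA
#' degradation) and returns the copy number at `t_end` per cell. Each
#' cell starts inactive with zero transcripts, so `t_end` should allow
#' steady state to be reached; a warning is raised when
#' `t_end < 10 / degradation`.
#'
#' @param rates A [kinetic_rates()] object.
#' @param n_cells Number of independent cells.
#' @param t_end Simulated time per cell (default `10 / degradation`).
#' @param seed Integer seed.
#' @return An integer vector of per-cell copy numbers at `t_end`.
#' @export
gillespie_telegraph <- function(rates, n_cells, t_end = NULL, seed = NULL) {
  stopifnot(inherits(rates, "kinetic_rates"))
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 1L)
    stop("'n_cells' must be a positive integer", call. = FALSE)
  if (is.null(t_end)) t_end <- 10 / rates$degradation
  if (t_end < 10 / rates$degradation)
    warning("t_end is shorter than 10 mRNA lifetimes; ",
            "counts may not reflect steady state", call. = FALSE)
  lam <- rates$activation; nu <- rates$deactivation
  K <- rates$transcription; delta <- rates$degradation
  with_seed(seed, {
    out <- integer(n_cells)
    for (i in seq_len(n_cells)) {
      t <- 0; active <- FALSE; m <- 0L
      repeat {
        a_switch <- if (active) nu else lam
        a_txn <- if (active) K else 0
        a_deg <- delta * m
        a_tot <- a_switch + a_txn + a_deg
        if (a_tot <= 0) break
        t <- t + stats::rexp(1L, a_tot)
        if (t > t_end) break
        u <- stats::runif(1L) * a_tot
        if (u < a_switch) active <- !active
        else if (u < a_switch + a_txn) m <- m + 1L
        else m <- m - 1L
      }
      out[i] <- m
    }
    out
  })
}

#' Simulate a coupled two-gene pair
#'
#' Draws upstream counts g from the upstream compound model, then sets
#' the downstream per-cell mean burst frequency to
#' `burst_freq_down * (max(g, 1) / reference_count)^exponent` and draws
#' the downstream count from the compound model around that mean
#' (log-normal frequency jitter of SD `freq_sd_down` when non-zero).
#' With a zero exponent the two genes are exactly independent.
#'
#' @param params_up,params_down [telegraph_params()] for the upstream
#'   and downstream genes.
#' @param coupling A [coupling_spec()].
#' @param n_cells Number of cells (>= 2).
#' @param seed Integer seed.
#' @param gene_a,gene_b Labels for the pair (upstream first).
#' @return A [paired_counts()] object (`x` upstream, `y` downstream).
#' @export
simulate_coupled_pair <- function(params_up, params_down,
                                  coupling = coupling_spec(),
                                  n_cells, seed = NULL,
                                  gene_a = "upstream", gene_b = "downstream") {
  stopifnot(is.telegraph_params(params_up), is.telegraph_params(params_down),
            inherits(coupling, "coupling_spec"))
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 2L)
    stop("'n_cells' must be at least 2", call. = FALSE)
  with_seed(seed, {
    g <- sample_compound(params_up, n_cells)
    bf <- params_down$burst_freq *
      (pmax(g, 1) / coupling$reference_count)^coupling$exponent
    r <- if (params_down$freq_sd == 0) bf
    else {
      s2 <- log1p((params_down$freq_sd / params_down$burst_freq)^2)
      stats::rlnorm(n_cells, log(bf) - s2 / 2, sqrt(s2))
    }
    yy <- stats::rnbinom(n_cells, size = r,
                         prob = 1 / (1 + params_down$burst_size))
    paired_counts(g, yy, gene_a = gene_a, gene_b = gene_b)
  })
}

#' Simulate a spot table from known per-cell copy numbers
#'
#' Emits, for each cell, `true_count` genuine spots with intensities
#' `Normal(unit_intensity, intensity_cv * unit_intensity)` plus a
#' Poisson number of dim false-positive spots, alongside zero-control
#' and low-control blocks sized like typical imaging controls. False
#' positives draw from a truncated normal centred at
#' `fp_intensity_scale * unit_intensity` with SD half that centre, so
#' the zero-control 99.9th percentile lands between the false-positive
#' and single-mRNA intensity scales. The false-positive intensity model
#' and control sizes are simulation conveniences, not measured
#' properties.
#'
#' @param true_counts Integer vector of true per-cell copy numbers.
#' @param unit_intensity True single-mRNA intensity (arbitrary units).
#' @param intensity_cv Coefficient of variation of genuine spot
#'   intensities (>= 0).
#' @param false_positive_rate Mean number of false-positive spots per
#'   cell (Poisson).
#' @param fp_intensity_scale Centre of the false-positive intensity
#'   distribution, relative to `unit_intensity`.
#' @param seed Integer seed.
#' @param n_zero_cells,n_low_cells Sizes of the control blocks.
#' @return A spot-table data frame with columns `cell_id`,
#'   `spot_intensity`, `sample_class`.
#' @export
simulate_spot_table <- function(true_counts, unit_intensity = 100,
                                intensity_cv = 0.1,
                                false_positive_rate = 0.2,
                                fp_intensity_scale = 0.2,
                                seed = NULL,
                                n_zero_cells = 1000L, n_low_cells = 500L) {
  true_counts <- check_counts(true_counts, "true_counts")
  check_scalar(unit_intensity, "unit_intensity", positive = TRUE)
  if (!is.numeric(intensity_cv) || length(intensity_cv) != 1L ||
      intensity_cv < 0)
    stop("'intensity_cv' must be a non-negative number", call. = FALSE)
  check_scalar(false_positive_rate, "false_positive_rate", positive = FALSE)
  if (false_positive_rate < 0)
    stop("'false_positive_rate' must be >= 0", call. = FALSE)

  rspot <- function(k) abs(stats::rnorm(k, unit_intensity,
                                        intensity_cv * unit_intensity))
  rfp <- function(k) {
    centre <- fp_intensity_scale * unit_intensity
    abs(stats::rnorm(k, centre, centre / 2)) + 1e-9
  }
  with_seed(seed, {
    blocks <- list()
    # zero control: pure false positives
    nz <- stats::rpois(n_zero_cells, max(false_positive_rate, 0.2))
    blocks$zero <- data.frame(
      cell_id = rep(paste0("zero_", seq_len(n_zero_cells)), nz),
      spot_intensity = rfp(sum(nz)),
      sample_class = rep("zero_control", sum(nz)))
    # low control: ~1 genuine spot per cell plus false positives
    nlow <- 1L + stats::rpois(n_low_cells, 0.2)
    nfp_low <- stats::rpois(n_low_cells, false_positive_rate)
    blocks$low <- data.frame(
      cell_id = c(rep(paste0("low_", seq_len(n_low_cells)), nlow),
                  rep(paste0("low_", seq_len(n_low_cells)), nfp_low)),
      spot_intensity = c(rspot(sum(nlow)), rfp(sum(nfp_low))),
      sample_class = rep("low_control", sum(nlow) + sum(nfp_low)))
    # sample block
    ids <- paste0("cell_", seq_along(true_counts))
    nfp <- stats::rpois(length(true_counts), false_positive_rate)
    blocks$sample <- data.frame(
      cell_id = c(rep(ids, true_counts), rep(ids, nfp)),
      spot_intensity = c(rspot(sum(true_counts)), rfp(sum(nfp))),
      sample_class = rep("sample", sum(true_counts) + sum(nfp)))
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    attr(out, "cells") <- ids
    out
  })
}
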