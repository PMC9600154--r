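#' Telegraph-model parameter ratios
#'
#' Container for the three dimensionless parameter ratios of the bursty
#' transcription model: the mean normalized burst frequency (promoter
#' activation rate over mRNA degradation rate), the mean burst size
#' (transcription rate over promoter deactivation rate), and the
#' normalized standard deviation of the per-cell burst frequency. A
#' `freq_sd` of zero identifies the pure negative-binomial model with no
#' extrinsic noise.
#'
#' @param burst_freq Positive real; mean normalized burst frequency.
#' @param burst_size Positive real; mean burst size.
#' @param freq_sd Non-negative real; SD of the per-cell burst frequency
#'   on the same normalized scale as `burst_freq`. Default 0.
#' @return An object of class `telegraph_params`.
#' @examples
#' telegraph_params(burst_freq = 2, burst_size = 10, freq_sd = 1)
#' @export
telegraph_params <- function(burst_freq, burst_size, freq_sd = 0) {
  check_scalar(burst_freq, "burst_freq", positive = TRUE)
  check_scalar(burst_size, "burst_size", positive = TRUE)
  check_scalar(freq_sd, "freq_sd", positive = FALSE)
  if (freq_sd < 0) stop("'freq_sd' must be non-negative", call. = FALSE)
  structure(
    list(burst_freq = as.numeric(burst_freq),
         burst_size = as.numeric(burst_size),
         freq_sd = as.numeric(freq_sd)),
    class = "telegraph_params"
  )
}

#' @export
print.telegraph_params <- function(x, digits = 4, ...) {
  cat("Telegraph model parameters (bursty limit):\n")
  cat(sprintf("  burst frequency (lambda/delta): %.*g\n", digits, x$burst_freq))
  cat(sprintf("  burst size      (K/nu):         %.*g\n", digits, x$burst_size))
  cat(sprintf("  frequency SD    (sigma/delta):  %.*g\n", digits, x$freq_sd))
  invisible(x)
}

#' @export
format.telegraph_params <- function(x, ...) {
  sprintf("(burst_freq=%g, burst_size=%g, freq_sd=%g)",
          x$burst_freq, x$burst_size, x$freq_sd)
}

#' @rdname telegraph_params
#' @param x Object to test or convert.
#' @export
is.telegraph_params <- function(x) inherits(x, "telegraph_params")

#' Serialize and deserialize telegraph parameters as JSON
#'
#' @param params A [telegraph_params()] object.
#' @return `params_to_json()` returns a JSON string with keys
#'   `burst_freq`, `burst_size`, `freq_sd`; `params_from_json()` the
#'   corresponding `telegraph_params` object.
#' @export
params_to_json <- function(params) {
  stopifnot(is.telegraph_params(params))
  jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
}

#' @rdname params_to_json
#' @param json A JSON string as produced by `params_to_json()`.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  telegraph_params(x$burst_freq, x$burst_size, x$freq_sd)
}

#' Quadrature configuration for the compound distribution
#'
#' The compound transcript distribution mixes a negative binomial over a
#' log-normal burst frequency. The mixture integral is evaluated by
#' Gauss-Hermite quadrature in log-frequency space, where the log-normal
#' density is Gaussian, with weights normalized to sum to one.
#'
#' @param n_nodes Number of quadrature nodes (default 128).
#' @param tail_mass Probability mass per log-normal tail excluded when
#'   bounding the pmf support for likelihood evaluation; must lie in
#'   (0, 0.01).
#' @return An object of class `quad_config`.
#' @export
quad_config <- function(n_nodes = 128L, tail_mass = 1e-6) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L)
    stop("'n_nodes' must be an integer >= 2", call. = FALSE)
  check_scalar(tail_mass, "tail_mass", positive = TRUE)
  if (tail_mass >= 0.01)
    stop("'tail_mass' must be in (0, 0.01)", call. = FALSE)
  structure(list(n_nodes = n_nodes, tail_mass = tail_mass),
            class = "quad_config")
}

#' Kinetic rates of the two-state promoter scheme
#'
#' The telegraph scheme: the promoter switches from inactive to active at
#' the activation rate and back at the deactivation rate; transcription
#' occurs at the transcription rate while active, and each mRNA decays at
#' the degradation rate. All rates are per unit time. The bursty regime
#' (deactivation much faster than activation, transcription much faster
#' than degradation) is where the copy-number distribution approaches a
#' negative binomial.
#'
#' @param activation Promoter activation rate (> 0).
#' @param deactivation Promoter deactivation rate (>= 0; zero gives a
#'   constitutively active promoter once switched on).
#' @param transcription Transcription rate while active (> 0).
#' @param degradation mRNA degradation rate (> 0).
#' @return An object of class `kinetic_rates`.
#' @export
kinetic_rates <- function(activation, deactivation, transcription, degradation) {
  check_scalar(activation, "activation", positive = TRUE)
  check_scalar(deactivation, "deactivation", positive = FALSE)
  if (deactivation < 0) stop("'deactivation' must be >= 0", call. = FALSE)
  check_scalar(transcription, "transcription", positive = TRUE)
  check_scalar(degradation, "degradation", positive = TRUE)
  structure(list(activation = activation, deactivation = deactivation,
                 transcription = transcription, degradation = degradation),
            class = "kinetic_rates")
}

#' Map kinetic rates to the bursty-limit parameter ratios
#'
#' Returns the negative-binomial parameter ratios implied by a set of
#' kinetic rates: burst frequency activation/degradation and burst size
#' transcription/deactivation. Warns when the rates are outside the
#' bursty regime (deactivation/activation < 10 or
#' transcription/degradation < 10), where the negative-binomial
#' approximation degrades.
#'
#' @param rates A [kinetic_rates()] object.
#' @return A [telegraph_params()] object with `freq_sd = 0`.
#' @export
nb_approx_params <- function(rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  if (rates$deactivation <= 0)
    stop("bursty-limit mapping requires a positive deactivation rate",
         call. = FALSE)
  if (rates$deactivation / rates$activation < 10 ||
      rates$transcription / rates$degradation < 10)
    warning("rates are outside the bursty regime (nu/lambda < 10 or ",
            "K/delta < 10); the negative-binomial approximation may be poor",
            call. = FALSE)
  telegraph_params(rates$activation / rates$degradation,
                   rates$transcription / rates$deactivation, 0)
}

#' Power-law coupling between an upstream and a downstream gene
#'
#' Test-harness coupling used by [simulate_coupled_pair()]: the
#' downstream per-cell burst frequency is the downstream mean frequency
#' scaled by `(max(g, 1) / reference_count)^exponent`, where `g` is the
#' upstream copy number in the same cell. An exponent of zero gives
#' exact independence. The power-law form is a modelling convenience for
#' generating pairs with tunable dependence, not an inferred mechanism.
#'
#' @param exponent Real; coupling strength (0 = independent).
#' @param reference_count Positive real; upstream count at which the
#'   downstream frequency equals its nominal mean.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(exponent = 0, reference_count = 10) {
  check_scalar(exponent, "exponent", positive = FALSE)
  check_scalar(reference_count, "reference_count", positive = TRUE)
  structure(list(exponent = exponent, reference_count = reference_count),
            class = "coupling_spec")
}

#' Paired per-cell counts for two genes measured in the same cells
#'
#' @param x,y Non-negative integer vectors of equal length (>= 2):
#'   per-cell transcript counts of gene A and gene B, aligned by cell.
#' @param gene_a,gene_b,strain,replicate Optional labels carried through
#'   to reports.
#' @return An object of class `paired_counts`.
#' @export
paired_counts <- function(x, y, gene_a = "gene_a", gene_b = "gene_b",
                          strain = NA_character_, replicate = NA) {
  x <- check_counts(x, "x")
  y <- check_counts(y, "y")
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length (same cells, same order)",
         call. = FALSE)
  if (length(x) < 2L)
    stop("paired counts require at least 2 cells", call. = FALSE)
  structure(list(x = x, y = y,
                 labels = list(gene_a = gene_a, gene_b = gene_b,
                               strain = strain, replicate = replicate)),
            class = "paired_counts")
}

#' @export
print.paired_counts <- function(x, ...) {
  cat(sprintf("Paired per-cell counts: %s vs %s, %d cells\n",
              x$labels$gene_a, x$labels$gene_b, length(x$x)))
  invisible(x)
}
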