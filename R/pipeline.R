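#' Read a per-cell count table from delimited text
#'
#' Expects a headered table with columns `cell_id` and `count`
#' (optionally `gene`, `strain`, `replicate`). Errors name the first
#' offending row or missing column.
#'
#' @param path Path to the file.
#' @param sep Field separator; guessed from the extension by default
#'   (`.csv` comma, otherwise tab).
#' @return A data frame with at least `cell_id` and integer `count`.
#' @export
read_counts <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_id", "count"), names(d))
  if (length(miss))
    stop("count table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(d$count) | d$count < 0 | d$count != floor(d$count))
  if (length(bad))
    stop("count table ", path, ": non-integer or negative count at row ",
         bad[1L], call. = FALSE)
  d$count <- as.integer(d$count)
  d
}

#' Read a paired two-gene count table from delimited text
#'
#' Expects columns `cell_id`, `count_a`, `count_b` (optionally labels).
#'
#' @inheritParams read_counts
#' @param gene_a,gene_b,strain,replicate Labels attached to the pair.
#' @return A [paired_counts()] object.
#' @export
read_paired_counts <- function(path, sep = NULL, gene_a = "gene_a",
                               gene_b = "gene_b", strain = NA_character_,
                               replicate = NA) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_id", "count_a", "count_b"), names(d))
  if (length(miss))
    stop("paired count table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(is.na(d$count_a) | is.na(d$count_b))
  if (length(bad))
    stop("paired count table ", path, ": unpaired row ", bad[1L],
         call. = FALSE)
  paired_counts(d$count_a, d$count_b, gene_a = gene_a, gene_b = gene_b,
                strain = strain, replicate = replicate)
}

#' Write a per-cell count table as delimited text
#'
#' @param counts Integer vector of per-cell counts (names become cell
#'   ids when present).
#' @param path Output path (tab-separated).
#' @export
write_counts <- function(counts, path) {
  ids <- if (is.null(names(counts))) paste0("cell_", seq_along(counts))
  else names(counts)
  utils::write.table(data.frame(cell_id = ids, count = as.integer(counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration for the end-to-end analysis
#'
#' Bundles inputs and settings for [run_single_gene()] and
#' [run_pair()]. A dataset is one strain-by-replicate count table; each
#' dataset is analysed separately.
#'
#' @param count_files Named character vector of count-table paths
#'   (single-gene analysis), names being dataset labels.
#' @param pair_files Named character vector of paired-count-table paths
#'   (MI analysis).
#' @param spot_files Named character vector of spot-table paths to
#'   quantify into counts before fitting (optional alternative to
#'   `count_files`).
#' @param fit A [fit_config()].
#' @param n_shuffles Permutation-null shuffles for MI significance
#'   (default 100,000, the scale used for final reports).
#' @param n_triplets Posterior triplets for the noise decomposition
#'   (default 4,000).
#' @param seed Integer seed governing decomposition subsampling and
#'   shuffles.
#' @param out_dir Output directory for reports.
#' @return An object of class `run_config`.
#' @export
run_config <- function(count_files = character(), pair_files = character(),
                       spot_files = character(), fit = fit_config(),
                       n_shuffles = 100000L, n_triplets = 4000L,
                       seed = 1L, out_dir = ".") {
  stopifnot(inherits(fit, "fit_config"))
  for (f in c(count_files, pair_files, spot_files))
    if (!file.exists(f)) stop("input file does not exist: ", f, call. = FALSE)
  structure(list(count_files = count_files, pair_files = pair_files,
                 spot_files = spot_files, fit = fit,
                 n_shuffles = as.integer(n_shuffles),
                 n_triplets = as.integer(n_triplets),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `fit` holds
#' the arguments of [fit_config()] (with `quad` holding those of
#' [quad_config()]).
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  fit_args <- y$fit %||% list()
  if (!is.null(fit_args$quad)) fit_args$quad <- do.call(quad_config, fit_args$quad)
  if (!is.null(fit_args$bounds))
    fit_args$bounds <- lapply(fit_args$bounds, as.numeric)
  fit <- do.call(fit_config, fit_args)
  run_config(count_files = unlist(y$count_files) %||% character(),
             pair_files = unlist(y$pair_files) %||% character(),
             spot_files = unlist(y$spot_files) %||% character(),
             fit = fit,
             n_shuffles = y$n_shuffles %||% 100000L,
             n_triplets = y$n_triplets %||% 4000L,
             seed = y$seed %||% 1L,
             out_dir = y$out_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fingerprint of the scientific settings; the output location is not
# part of a run's identity
config_fingerprint <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  fnv1a(paste(deparse(x), collapse = ""))
}

report_meta <- function(config) {
  list(package_version = as.character(utils::packageVersion("burstfit")),
       config_hash = config_fingerprint(config),
       seed = config$seed)
}

#' Single-gene analysis: quantify, fit, decompose
#'
#' For each dataset, reads counts (or quantifies a spot table into
#' counts first), fits the compound bursty-transcription model, and
#' decomposes the variance into intrinsic and extrinsic contributions.
#' Writes per-dataset JSON reports
#' (`<label>_fit.json`: MAP, 95% credible intervals, R-hat, seed;
#' `<label>_noise.json`: variance split, posterior extrinsic fraction
#' with 68% interval), a fitted-versus-empirical pmf table
#' (`<label>_pmf.tsv`), the posterior chain (`<label>_chain.tsv`), and
#' a combined delimited summary (`summary_single_gene.tsv`). Reports
#' embed the package version, a config fingerprint and all seeds;
#' reruns with identical config and seeds are byte-identical.
#'
#' @param config A [run_config()] with `count_files` and/or
#'   `spot_files` set.
#' @return (Invisibly) a data frame with one row per dataset: MAP
#'   parameters, interval bounds, extrinsic fraction summaries.
#' @export
run_single_gene <- function(config) {
  stopifnot(inherits(config, "run_config"))
  datasets <- list()
  for (lbl in names(config$count_files))
    datasets[[lbl]] <- read_counts(config$count_files[[lbl]])$count
  for (lbl in names(config$spot_files)) {
    spots <- read_spot_table(config$spot_files[[lbl]])
    calib <- calibrate_spots(spots)
    datasets[[lbl]] <- unname(integrate_copy_numbers(spots, calib))
  }
  if (!length(datasets))
    stop("run_single_gene: no count or spot tables in config", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- report_meta(config)

  rows <- lapply(names(datasets), function(lbl) {
    counts <- datasets[[lbl]]
    fit <- fit_telegraph(counts, config$fit)
    map <- map_estimate(fit)
    ci <- credible_interval(fit, 0.95)
    dec <- posterior_noise_decomposition(fit, config$n_triplets,
                                         seed = config$seed,
                                         quad = config$fit$quad)
    fit_report <- c(meta, list(
      dataset = lbl, n_cells = fit$n_cells,
      map = unclass(map),
      ci95 = list(burst_freq = unname(ci["burst_freq", ]),
                  burst_size = unname(ci["burst_size", ]),
                  freq_sd = unname(ci["freq_sd", ])),
      rhat = as.list(fit$rhat),
      acceptance_rate = fit$acceptance_rate,
      fit_seed = config$fit$seed))
    jsonlite::write_json(fit_report,
                         file.path(config$out_dir, paste0(lbl, "_fit.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    noise_report <- c(meta, list(
      dataset = lbl,
      intrinsic_var = dec$intrinsic_var, extrinsic_var = dec$extrinsic_var,
      total_var = dec$total_var, e = dec$e, e_map = dec$e_map,
      e_ci68 = as.list(dec$e_ci68), n_triplets = dec$n_triplets))
    jsonlite::write_json(noise_report,
                         file.path(config$out_dir, paste0(lbl, "_noise.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(fitted_pmf(fit),
                       file.path(config$out_dir, paste0(lbl, "_pmf.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    chain <- cbind(fit$samples, log_posterior = fit$log_posterior,
                   chain = fit$chain)
    utils::write.table(chain,
                       file.path(config$out_dir, paste0(lbl, "_chain.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    data.frame(dataset = lbl, n_cells = fit$n_cells,
               burst_freq = map$burst_freq, burst_size = map$burst_size,
               freq_sd = map$freq_sd,
               e_map = dec$e_map, e_lo68 = dec$e_ci68[["lower"]],
               e_hi68 = dec$e_ci68[["upper"]])
  })
  summary <- do.call(rbind, rows)
  utils::write.table(summary,
                     file.path(config$out_dir, "summary_single_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}

#' Paired-gene analysis: mutual information with permutation null
#'
#' For each paired dataset, computes the mutual information between the
#' two genes and its permutation-null significance, and writes one
#' report row per dataset (`summary_pairs.tsv` plus per-dataset JSON)
#' shaped like a mutual-information results table: labels, MI in bits,
#' entropy of each gene in bits, p-value, shuffle count and seed. Runs
#' with fewer than 1,000 shuffles are flagged `approximate`.
#'
#' @param config A [run_config()] with `pair_files` set.
#' @return (Invisibly) the summary data frame.
#' @export
run_pair <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!length(config$pair_files))
    stop("run_pair: no pair tables in config", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- report_meta(config)

  rows <- lapply(names(config$pair_files), function(lbl) {
    paired <- read_paired_counts(config$pair_files[[lbl]])
    res <- permutation_significance(paired, config$n_shuffles,
                                    seed = config$seed)
    report <- c(meta, list(
      dataset = lbl, n_cells = res$n_cells,
      mi_bits = res$mi_bits,
      entropy_a_bits = res$entropy_x_bits,
      entropy_b_bits = res$entropy_y_bits,
      p_value = res$p_value, p_value_corrected = res$p_value_corrected,
      n_shuffles = res$n_shuffles,
      null_mean = res$null_mean, null_sd = res$null_sd,
      approximate = res$n_shuffles < 1000L))
    jsonlite::write_json(report,
                         file.path(config$out_dir, paste0(lbl, "_mi.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    data.frame(dataset = lbl, n_cells = res$n_cells, mi_bits = res$mi_bits,
               entropy_a_bits = res$entropy_x_bits,
               entropy_b_bits = res$entropy_y_bits,
               p_value = res$p_value, n_shuffles = res$n_shuffles,
               approximate = res$n_shuffles < 1000L)
  })
  summary <- do.call(rbind, rows)
  utils::write.table(summary, file.path(config$out_dir, "summary_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}
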