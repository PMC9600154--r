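#' False-positive spot-intensity threshold from a zero control
#'
#' The zero control is a non-expressing sample, so every detected spot
#' in it is a false positive. The threshold is the 99.9th percentile of
#' the zero-control spot intensities (linear-interpolation quantile
#' convention); sample spots below it are discarded.
#'
#' @param zero_intensities Positive spot intensities from the zero
#'   control; at least 100 values are required for a stable extreme
#'   percentile.
#' @return The threshold intensity.
#' @export
false_positive_threshold <- function(zero_intensities) {
  if (length(zero_intensities) < 100L)
    stop("at least 100 zero-control spot intensities are required (got ",
         length(zero_intensities), ")", call. = FALSE)
  if (!is.numeric(zero_intensities) || anyNA(zero_intensities) ||
      any(zero_intensities <= 0))
    stop("zero-control intensities must be positive numbers", call. = FALSE)
  stats::quantile(zero_intensities, 0.999, names = FALSE, type = 7)
}

#' Single-mRNA intensity calibration from a low control
#'
#' The low control is a weakly expressing sample in which most spots are
#' single transcripts. A Gaussian curve is fitted by least squares to
#' the Freedman-Diaconis-binned spot-intensity histogram; the fitted
#' mean is the characteristic single-mRNA intensity. Fitting the
#' histogram (rather than maximum likelihood on raw values) keeps the
#' estimate robust to a small high-intensity tail of multi-mRNA spots.
#'
#' @param low_intensities Positive spot intensities from the low
#'   control; at least 200 values are required.
#' @return A list with `unit_intensity` (fitted Gaussian mean) and
#'   `fit_sd` (fitted Gaussian SD).
#' @export
unit_intensity <- function(low_intensities) {
  if (length(low_intensities) < 200L)
    stop("at least 200 low-control spot intensities are required (got ",
         length(low_intensities), ")", call. = FALSE)
  if (!is.numeric(low_intensities) || anyNA(low_intensities) ||
      any(low_intensities <= 0))
    stop("low-control intensities must be positive numbers", call. = FALSE)
  if (diff(range(low_intensities)) == 0)
    return(list(unit_intensity = low_intensities[1L], fit_sd = 0))

  h <- graphics::hist(low_intensities, breaks = "FD", plot = FALSE)
  d <- data.frame(x = h$mids, y = h$counts)
  i0 <- which.max(d$y)
  start <- list(a = max(d$y), m = d$x[i0],
                s = max(stats::mad(low_intensities), diff(h$mids[1:2])))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - m)^2 / (2 * s^2)), data = d,
                      start = start,
                      lower = c(a = 0, m = min(d$x), s = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Gaussian fit to the spot-intensity histogram failed to ",
           "converge: ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  list(unit_intensity = unname(cf[["m"]]), fit_sd = abs(unname(cf[["s"]])))
}

#' Calibrate spot quantification from the control blocks of a spot table
#'
#' Combines [false_positive_threshold()] on the `zero_control` rows and
#' [unit_intensity()] on the `low_control` rows. A warning is raised if
#' the threshold is not below the unit intensity (the calibration would
#' then discard genuine single-mRNA spots).
#'
#' @param spots A spot table: data frame with columns `cell_id`,
#'   `spot_intensity` (positive) and `sample_class` (one of
#'   `"zero_control"`, `"low_control"`, `"sample"`).
#' @return An object of class `spot_calibration` with fields
#'   `threshold`, `unit_intensity`, `fit_sd`.
#' @export
calibrate_spots <- function(spots) {
  spots <- check_spot_table(spots)
  thr <- false_positive_threshold(
    spots$spot_intensity[spots$sample_class == "zero_control"])
  ui <- unit_intensity(
    spots$spot_intensity[spots$sample_class == "low_control"])
  if (thr >= ui$unit_intensity)
    warning(sprintf(paste0("false-positive threshold (%.3g) is not below ",
                           "the single-mRNA intensity (%.3g); genuine ",
                           "spots may be discarded"),
                    thr, ui$unit_intensity), call. = FALSE)
  structure(list(threshold = thr, unit_intensity = ui$unit_intensity,
                 fit_sd = ui$fit_sd),
            class = "spot_calibration")
}

#' @export
print.spot_calibration <- function(x, digits = 4, ...) {
  cat("Spot-intensity calibration:\n")
  cat(sprintf("  false-positive threshold: %.*g\n", digits, x$threshold))
  cat(sprintf("  single-mRNA intensity:    %.*g (fit SD %.*g)\n",
              digits, x$unit_intensity, digits, x$fit_sd))
  invisible(x)
}

#' Integrate spot intensities into per-cell mRNA copy numbers
#'
#' For every cell in the sample block, sums the intensities of spots
#' strictly above the false-positive threshold, divides by the
#' single-mRNA unit intensity and rounds to the nearest integer (ties
#' half-up). Cells present in the table whose spots are all filtered
#' out get a count of 0; such cells still carry information for the
#' model fit.
#'
#' @param spots A spot table (see [calibrate_spots()]); only `sample`
#'   rows are integrated.
#' @param calib A `spot_calibration`.
#' @param cells Optional character vector of all imaged cell ids
#'   (including cells with no detected spots, which receive count 0).
#'   Sample rows referencing a cell id absent from `cells` are an
#'   error.
#' @return A named integer vector of per-cell copy numbers.
#' @export
integrate_copy_numbers <- function(spots, calib, cells = NULL) {
  spots <- check_spot_table(spots)
  stopifnot(inherits(calib, "spot_calibration"))
  smp <- spots[spots$sample_class == "sample", , drop = FALSE]
  ids <- as.character(smp$cell_id)
  if (is.null(cells)) {
    cells <- unique(ids)
  } else {
    cells <- as.character(cells)
    unknown <- setdiff(ids, cells)
    if (length(unknown))
      stop("sample rows reference unknown cell ids: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  keep <- smp$spot_intensity > calib$threshold
  sums <- stats::setNames(numeric(length(cells)), cells)
  if (any(keep)) {
    agg <- tapply(smp$spot_intensity[keep], ids[keep], sum)
    sums[names(agg)] <- agg
  }
  counts <- as.integer(floor(sums / calib$unit_intensity + 0.5))
  stats::setNames(counts, cells)
}

check_spot_table <- function(spots) {
  if (!is.data.frame(spots))
    stop("a spot table must be a data frame", call. = FALSE)
  need <- c("cell_id", "spot_intensity", "sample_class")
  miss <- setdiff(need, names(spots))
  if (length(miss))
    stop("spot table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(spots$spot_intensity) | spots$spot_intensity <= 0)
  if (length(bad))
    stop("spot table has non-positive intensity at row ", bad[1L],
         call. = FALSE)
  ok <- spots$sample_class %in% c("zero_control", "low_control", "sample")
  if (!all(ok))
    stop("spot table has unknown sample_class at row ", which(!ok)[1L],
         call. = FALSE)
  no_id <- which(spots$sample_class == "sample" &
                   (is.na(spots$cell_id) | spots$cell_id == ""))
  if (length(no_id))
    stop("sample spot without a cell_id at row ", no_id[1L], call. = FALSE)
  spots
}

#' Read a spot table from delimited text
#'
#' @param path Path to a delimited file with columns `cell_id`,
#'   `spot_intensity`, `sample_class`.
#' @param sep Field separator; guessed from the extension by default
#'   (`.csv` comma, otherwise tab).
#' @return A validated spot-table data frame.
#' @export
read_spot_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  check_spot_table(utils::read.table(path, header = TRUE, sep = sep,
                                     stringsAsFactors = FALSE))
}
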