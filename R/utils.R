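# internal helpers shared across modules

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

# validate a vector of non-negative integer copy numbers; returns integer
check_counts <- function(n, name = "counts", allow_empty = FALSE) {
  if (!allow_empty && length(n) == 0L)
    stop(sprintf("'%s' must be non-empty", name), call. = FALSE)
  if (!is.numeric(n) || anyNA(n))
    stop(sprintf("'%s' must be numeric with no missing values", name),
         call. = FALSE)
  if (any(n < 0) || any(n != floor(n)))
    stop(sprintf("'%s' must contain non-negative integers", name),
         call. = FALSE)
  as.integer(n)
}

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# histogram mode with Freedman-Diaconis bins: midpoint of the modal bin
# (first modal bin on ties); degenerate samples return their common value
fd_mode <- function(x) {
  if (diff(range(x)) == 0) return(x[1L])
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  i <- which.max(h$counts)
  h$mids[i]
}

# tiny polynomial rolling hash of a string, for config fingerprints
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# split-R-hat (Gelman-Rubin) per column of a samples matrix, given a
# chain id per row; each chain is split in half
split_rhat <- function(mat, chain_id) {
  vapply(seq_len(ncol(mat)), function(j) {
    halves <- lapply(split(mat[, j], chain_id), function(v) {
      m <- length(v) %/% 2L
      list(v[seq_len(m)], v[(length(v) - m + 1L):length(v)])
    })
    chains <- unlist(halves, recursive = FALSE)
    m <- length(chains)
    n <- min(lengths(chains))
    chains <- lapply(chains, function(v) v[seq_len(n)])
    means <- vapply(chains, mean, 0)
    vars <- vapply(chains, stats::var, 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}
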