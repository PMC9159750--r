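# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded entry points do not
#' perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # ensure a stream exists so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# sample() without the length-1 surprise
sample_int <- function(n, size, replace = FALSE, prob = NULL) {
  sample.int(n, size = size, replace = replace, prob = prob)
}

# column-wise SD of a matrix, n-1 denominator
col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows to compute an SD")
  mu <- colMeans(m)
  sqrt(colSums(sweep(m, 2L, mu)^2) / (n - 1L))
}

# row-wise SD
row_sds <- function(m) col_sds(t(m))

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

# centered moving-average (boxcar) smoothing of the rows of a matrix;
# edges use the available samples only (shrinking window)
boxcar_rows <- function(m, k) {
  stopifnot(k >= 1L)
  if (k == 1L) return(m)
  nb <- ncol(m)
  half <- (k - 1L) / 2
  lo <- pmax(1L, ceiling(seq_len(nb) - half))
  hi <- pmin(nb, floor(seq_len(nb) + half))
  cs <- cbind(0, t(apply(m, 1L, cumsum)))
  out <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(m))
  dimnames(out) <- dimnames(m)
  out
}
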