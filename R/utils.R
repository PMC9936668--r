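# internal helpers

#' @useDynLib vnsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# evaluate expr under a local, seeded RNG without disturbing the caller's
# stream; seed may be NULL to keep the current stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  expr
}

# derive a reproducible sub-seed (< 2^31) from a base seed and a stage tag
.sub_seed <- function(seed, tag, k = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + k * 7919) %% 2147483629)
}

# rolling mean over exactly-w-sample centered windows via cumulative sums;
# NA outside the valid range
.centered_rolling_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  cs[hi + 1] - cs[lo]
}
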