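#' @keywords internal
"_PACKAGE"

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic derived seed for a named substream (kept below 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 104729 * k) %% 2147483646) + 1L
}

# Deterministic per-stage seeds derived from one root seed.
stage_seeds <- function(seed, stages) {
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(stages))
    names(s) <- stages
    s
  })
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

days_num <- function(d) as.numeric(d)

# All unordered index pairs (i, j), i < j, with |date_i - date_j| < t (strict).
# Dates are numeric days. O(n log n + P) via a sorted sliding window.
temporal_pairs <- function(dates, t_days) {
  n <- length(dates)
  if (n < 2L) {
    return(list(i = integer(0), j = integer(0), dt = numeric(0)))
  }
  ord <- order(dates)
  d <- dates[ord]
  # hi[k] = number of sorted dates strictly below d[k] + t
  hi <- findInterval(d + t_days, d, left.open = TRUE)
  lens <- pmax(hi - seq_len(n), 0L)
  if (sum(lens) == 0) {
    return(list(i = integer(0), j = integer(0), dt = numeric(0)))
  }
  ii <- rep.int(seq_len(n), lens)
  jj <- ii + sequence(lens)
  list(i = ord[ii], j = ord[jj], dt = d[jj] - d[ii])
}
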