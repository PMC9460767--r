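# Independent brute-force oracles, deliberately written from the formulas
# rather than reusing package internals.

# linear interpolation between order statistics at position 1 + (n-1)p
brute_quantile <- function(v, p) {
  vs <- sort(v)
  n <- length(vs)
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  vs[lo] + (h - lo) * (vs[hi] - vs[lo])
}

brute_fence <- function(v) {
  v <- v[!is.na(v)]
  q1 <- brute_quantile(v, 0.25)
  q3 <- brute_quantile(v, 0.75)
  iqr <- q3 - q1
  c(lower = q1 - 1.5 * iqr, upper = q3 + 1.5 * iqr)
}

# strictly outside the closed fence interval
brute_flags <- function(v) {
  f <- brute_fence(v)
  out <- v < f[["lower"]] | v > f[["upper"]]
  out[is.na(v)] <- FALSE
  out
}

brute_weighted_mean <- function(y, w) sum(w * y) / sum(w)
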