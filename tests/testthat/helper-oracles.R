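# Independent oracles used across the suite. These deliberately use naive,
# brute-force formulations so they share no code path with the package.

# Otsu by exhaustive search: for every candidate threshold t compute the
# between-class variance directly from the pixel values; first maximum wins.
brute_otsu <- function(v) {
  v <- as.integer(round(v))
  best_t <- NA_integer_
  best <- -Inf
  for (t in 0:255) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) {
      best <- sb
      best_t <- t
    }
  }
  best_t
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign vectors.
wilcoxon_enum <- function(m1, m2) {
  d <- m1 - m2
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  stats <- apply(signs, 1, function(s) sum(rk[s]))
  p_le <- mean(stats <= v_obs + 1e-9)
  p_ge <- mean(stats >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Longest cyclically contiguous run of TRUE, by walking from every start.
cyclic_run_brute <- function(x) {
  n <- length(x)
  if (all(x)) return(n)
  best <- 0L
  for (s in seq_len(n)) {
    len <- 0L
    for (k in seq_len(n)) {
      if (x[((s + k - 2L) %% n) + 1L]) len <- len + 1L else break
    }
    best <- max(best, len)
  }
  best
}

jaccard_brute <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# A small deterministic chemogram painted from a probability matrix.
chem_from_prob <- function(p, mm_per_column = 0.5) {
  rgb <- colormap_forward(as.vector(p))
  h <- nrow(p); w <- ncol(p)
  chemogram(red = matrix(rgb[, 1], h, w), green = matrix(rgb[, 2], h, w),
            blue = matrix(rgb[, 3], h, w), mm_per_column = mm_per_column)
}
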