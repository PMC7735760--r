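# independent brute-force oracles used across test files

# O(n * w) windowed mean, NA-aware
rolling_mean_oracle <- function(x, window, min_count = 1L) {
  h <- (window - 1L) %/% 2L
  vapply(seq_along(x), function(i) {
    w <- x[max(1L, i - h):min(length(x), i + h)]
    w <- w[!is.na(w)]
    if (length(w) >= min_count && length(w) > 0) mean(w) else NA_real_
  }, numeric(1))
}

# O(L^2) lagged pairwise-complete Pearson correlation
acf_oracle <- function(x, min_n = 10L) {
  L <- length(x)
  nlag <- L %/% 2L
  vapply(seq_len(nlag) - 1L, function(k) {
    a <- x[seq_len(L - k)]
    b <- x[seq_len(L - k) + k]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < min_n) return(NA_real_)
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    stats::cor(a[ok], b[ok])
  }, numeric(1))
}

# two-sided Fisher p by direct enumeration with binomial coefficients
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0L, c1 - (n - r1)):min(r1, c1)
  pr <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
  pobs <- choose(r1, a) * choose(n - r1, c1 - a) / choose(n, c1)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# all-pairs interval overlap with closed max_dist expansion (half-open coords)
overlap_oracle <- function(molecules, features, max_dist) {
  hits <- list()
  for (i in seq_len(nrow(molecules))) {
    for (j in seq_len(nrow(features))) {
      if (molecules$ref_name[i] != features$chrom[j]) next
      gap <- max(0L,
                 features$start[j] - molecules$ref_end[i],
                 molecules$ref_start[i] - features$end[j])
      if (gap <= max_dist) {
        hits[[length(hits) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

# reference position of every molecule position, by explicit construction
ref_map_oracle <- function(ref_start, length, strand) {
  if (strand == "+") ref_start + seq_len(length) - 1L
  else rev(ref_start + seq_len(length) - 1L)
}

# adjusted Rand index (needs mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
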