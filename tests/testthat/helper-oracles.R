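# Independent, definition-level oracles used to cross-check the package's
# implementations. They are deliberately written from first principles
# (sorting, explicit loops) rather than reusing package code paths.

# percentile with linear interpolation from the sorted sample
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_soft_minmax <- function(x) {
  p5 <- oracle_percentile(x, 0.05)
  p95 <- oracle_percentile(x, 0.95)
  (x - p5) / (p95 - p5)
}

# run-length merge of a binary vector into half-open intervals
oracle_merge <- function(bin, t0 = 0) {
  starts <- ends <- numeric(0)
  inside <- FALSE
  for (i in seq_along(bin)) {
    if (bin[i] == 1 && !inside) {
      starts <- c(starts, t0 + i - 1)
      inside <- TRUE
    }
    if (bin[i] == 0 && inside) {
      ends <- c(ends, t0 + i - 1)
      inside <- FALSE
    }
  }
  if (inside) ends <- c(ends, t0 + length(bin))
  data.frame(start_s = starts, end_s = ends)
}

# greedy one-to-one matching with explicit overlap computation
oracle_match <- function(det, ref, min_overlap = 1) {
  used <- rep(FALSE, nrow(ref))
  tp <- 0
  for (i in seq_len(nrow(det))) {
    for (j in seq_len(nrow(ref))) {
      if (used[j]) next
      ov <- min(det$end_s[i], ref$end_s[j]) -
        max(det$start_s[i], ref$start_s[j])
      if (ov >= min_overlap) {
        used[j] <- TRUE
        tp <- tp + 1
        break
      }
    }
  }
  list(TP = tp, FP = nrow(det) - tp, FN = nrow(ref) - tp)
}

# random sorted non-overlapping interval list on [0, span)
random_intervals <- function(n, span = 300) {
  if (n == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  starts <- sort(runif(n, 0, span - 2))
  ends <- starts + runif(n, 0.5, 15)
  for (i in seq_len(n - 1))
    ends[i] <- min(ends[i], starts[i + 1])
  keep <- ends > starts
  data.frame(start_s = starts[keep], end_s = ends[keep])
}

oracle_mean_ranks <- function(x) {
  # average ranks for ties, built from sorting alone
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  xs <- x[o]
  while (i <= length(xs)) {
    j <- i
    while (j < length(xs) && xs[j + 1] == xs[i]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

oracle_spearman <- function(a, b) {
  ra <- oracle_mean_ranks(a)
  rb <- oracle_mean_ranks(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

oracle_bland_altman <- function(ref, est) {
  d <- est - ref
  m <- sum(d) / length(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  list(bias = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

# pointwise linear interpolation of (t, v) samples onto a grid
oracle_interp <- function(t, v, grid) {
  vapply(grid, function(g) {
    if (g <= t[1]) return(v[1])
    if (g >= t[length(t)]) return(v[length(v)])
    i <- max(which(t <= g))
    if (t[i] == g) return(v[i])
    v[i] + (v[i + 1] - v[i]) * (g - t[i]) / (t[i + 1] - t[i])
  }, numeric(1))
}
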