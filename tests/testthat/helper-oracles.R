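# Independent oracles used to freeze expected values; these deliberately do
# not share code with the implementation paths they check.

# Brute-force consensus oracle: O(n^2) pairwise midpoint-in-span matching
# followed by naive transitive closure over a membership vector.
oracle_consensus <- function(df) {
  # df: chrom, start, end (1-based closed)
  n <- nrow(df)
  if (n == 0) return(df[0, ])
  mid <- floor((df$start + df$end) / 2)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (df$chrom[i] != df$chrom[j]) next
        match_ij <- (mid[i] >= df$start[j] && mid[i] <= df$end[j]) ||
                    (mid[j] >= df$start[i] && mid[j] <= df$end[i])
        if (match_ij && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(k) {
    sel <- comp == k
    data.frame(chrom = df$chrom[sel][1], start = min(df$start[sel]),
               end = max(df$end[sel]))
  }))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# Exhaustive hypergeometric enumeration for the one-sided (greater) Fisher
# exact p of the 2x2 table [a, b; c, d].
oracle_fisher_greater <- function(a, b, c, d) {
  n1 <- a + b
  k <- a + c
  N <- a + b + c + d
  xs <- max(0, k - (c + d)):min(n1, k)
  probs <- choose(k, xs) * choose(N - k, n1 - xs) / choose(N, n1)
  sum(probs[xs >= a])
}

# Closed-form ordinary least squares for y ~ x.
oracle_ols <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# random peak set generator for consensus property tests
random_peaks <- function(n, n_chrom = 2, span = 5000, width_range = c(50, 400)) {
  chrom <- sample(sprintf("chr%d", seq_len(n_chrom)), n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE)
  width <- sample(seq(width_range[1], width_range[2]), n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width - 1)
}
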