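# Independent brute-force oracles, kept separate from the implementation
# paths they check.

# Friedman chi-square statistic from first principles: rank within blocks,
# sum squared column rank sums (valid for tie-free data).
friedman_stat_brute <- function(m) {
  R <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
}

# AUROC as explicit pairwise concordance over all positive-negative pairs.
auc_brute <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Trapezoidal deviation areas recomputed interval by interval.
areas_brute <- function(series, base) {
  d <- series - base
  above <- 0; below <- 0
  for (i in seq_len(length(d) - 1)) {
    above <- above + (max(d[i], 0) + max(d[i + 1], 0)) / 2
    below <- below + (max(-d[i], 0) + max(-d[i + 1], 0)) / 2
  }
  list(area_above = above, area_below = below, mean_dev = mean(d),
       dev_at_t = d[length(d)])
}

# Window completion from first principles: for each gap position find the
# nearest present neighbors and apply the two-point line (or nearest-value
# extension at the edges).
interp_brute <- function(values) {
  n <- length(values)
  present <- which(!is.na(values))
  out <- values
  for (i in which(is.na(values))) {
    left <- present[present < i]
    right <- present[present > i]
    if (!length(left)) {
      out[i] <- values[min(right)]
    } else if (!length(right)) {
      out[i] <- values[max(left)]
    } else {
      l <- max(left); r <- min(right)
      out[i] <- values[l] + (values[r] - values[l]) * (i - l) / (r - l)
    }
  }
  out
}
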