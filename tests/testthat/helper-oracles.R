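# Brute-force oracles, written independently of the package internals.

# per-base membership set of an interval data.frame (single chromosome)
bf_bases <- function(iv) {
  if (nrow(iv) == 0) return(integer(0))
  unique(unlist(lapply(seq_len(nrow(iv)), function(i)
    seq(iv$start[i], iv$end[i] - 1))))
}

# merge via per-base occupancy -> runs
bf_merge_one_chrom <- function(iv) {
  b <- sort(bf_bases(iv))
  if (length(b) == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  brk <- c(0, which(diff(b) > 1), length(b))
  data.frame(start = b[brk[-length(brk)] + 1],
             end = b[brk[-1]] + 1)
}

bf_overlap <- function(a, b) {
  a$chrom == b$chrom && length(intersect(bf_bases(a), bf_bases(b))) > 0
}

bf_snp_in <- function(snp, iv) {
  snp$chrom == iv$chrom && (snp$pos - 1) %in% bf_bases(iv)
}

# random interval fixture on one chromosome
rand_ivs <- function(n, max_coord = 300, chrom = "chrZ") {
  s <- sample.int(max_coord, n, replace = TRUE) - 1
  w <- sample.int(30, n, replace = TRUE)
  data.frame(chrom = chrom, start = s, end = s + w)
}

# exhaustive PWM enumeration: all 4^w words scored on a given score matrix,
# tail probability under per-base background weights
bf_enum_pvalues <- function(score_mat, background, thresholds) {
  w <- ncol(score_mat)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words))
  pr <- rep(1, nrow(words))
  for (j in seq_len(w)) {
    sc <- sc + score_mat[cbind(words[, j], j)]
    pr <- pr * background[words[, j]]
  }
  vapply(thresholds, function(t) sum(pr[sc >= t]), 0)
}

# exact two-sided Mann-Whitney by direct assignment enumeration, using the
# U statistic (pairwise wins + half-ties) rather than rank sums
bf_mw_twosided <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  u_of <- function(xi, yi) {
    sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  }
  u_obs <- u_of(x, y)
  mu <- m * (n - m) / 2
  combos <- utils::combn(n, m)
  u_all <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# average-rank Spearman from first principles
bf_spearman <- function(x, y) {
  avg_rank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# pooled-variance two-sample t from the closed form
bf_pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  df <- length(x) + length(y) - 2
  list(t = t, p = 2 * pt(-abs(t), df))
}

# random PFM in JASPAR text, round-tripped through the parser
rand_pwm <- function(w, peaked = 2) {
  counts <- matrix(rpois(4 * w, 10) + 1, 4, w)
  j <- sample(w, 1)
  counts[sample(4, 1), j] <- counts[sample(4, 1), j] * peaked
  txt <- c(sprintf(">RAND%d test_w%d", w, w),
           sprintf("%s [ %s ]", c("A", "C", "G", "T"),
                   apply(counts, 1, paste, collapse = " ")))
  parse_jaspar(text = txt)[[1]]
}
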