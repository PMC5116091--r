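test_that("digest_sequence places cuts before each site and conserves bp", {
  d <- digest_sequence("TTGATCCGATCAA")
  expect_equal(d$start, c(0, 2, 7))
  expect_equal(d$end, c(2, 7, 13))
  expect_equal(digest_sequence("AAAA")$end, 4)          # no site
  expect_equal(nrow(digest_sequence("AAAA")), 1)
  d0 <- digest_sequence("GATCAA")                        # site at position 0
  expect_equal(d0$start[1], 0)
  expect_true(all(interval_width(d0) > 0))
  # bp conservation on random sequences
  set.seed(4)
  for (rep in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    dd <- digest_sequence(s)
    expect_equal(dd$start[-1], dd$end[-nrow(dd)])
    expect_equal(sum(interval_width(dd)), 500)
  }
})

test_that("filter_and_trim removes baitless reads and the bait prefix", {
  bait <- "ACGTACGT"
  reads <- c(paste0(bait, "TTTT"), "GGGGCCCC", bait)
  ft <- filter_and_trim(reads, bait)
  expect_equal(ft$trimmed, "TTTT")
  expect_equal(ft$n_no_bait, 1)
  expect_equal(ft$n_empty_after_trim, 1)
  expect_equal(ft$retained_fraction, 1 / 3)
})

test_that("count_fragments assigns by 5' position with half-open boundaries", {
  frags <- digest_sequence("TTGATCCGATCAA")  # [0,2) [2,7) [7,13)
  reads <- data.frame(chrom = "region", start = c(0, 2, 7, 6, 50),
                      strand = "+", length = 4)
  cf <- count_fragments(reads, frags)
  expect_equal(cf$counts, c(1, 2, 1))  # boundary base 2 -> downstream frag
  expect_equal(cf$n_assigned + cf$n_dropped, nrow(reads))
  # minus-strand read assigned by its rightmost base
  rminus <- data.frame(chrom = "region", start = 0, strand = "-", length = 4)
  expect_equal(count_fragments(rminus, frags)$counts, c(0, 1, 0))
})

test_that("trend_profile averages normalized counts by fragment midpoint", {
  region <- genomic_interval("r", 0, 100)
  frags <- data.frame(chrom = "r", start = c(0, 30, 60), end = c(30, 60, 100),
                      fragment = 1:3)
  prof <- trend_profile(c(5, 5, 5), frags, region, resolution = 50)
  # uniform normalized counts -> flat profile
  expect_equal(prof$stat, rep(5 / 15 * 1e6, 2))
  single <- trend_profile(c(0, 0, 9), frags, region, resolution = 50)
  expect_equal(single$stat[1], 0)
  expect_gt(single$stat[2], 0)
  # empty window flagged
  frags2 <- data.frame(chrom = "r", start = 0, end = 10, fragment = 1)
  prof2 <- trend_profile(3, frags2, region, resolution = 50)
  expect_true(prof2$empty[2])
  expect_equal(prof2$stat[2], 0)
})

test_that("low_count_filter keeps rows strictly above the threshold", {
  m <- rbind(c(25, 25), c(26, 25), c(0, 0))
  expect_equal(low_count_filter(m), c(FALSE, TRUE, FALSE))
  expect_false(any(low_count_filter(matrix(0, 3, 4))))
})

test_that("call_differential enforces support and count rules", {
  windows <- data.frame(chrom = "r", start = seq(0, 45, 5), end = seq(5, 50, 5))
  n_win <- nrow(windows)
  groups <- rep(c("risk", "nonrisk"), each = 4)
  base <- matrix(rep(c(10, 11, 9, 10, 10, 11, 9, 10), each = n_win),
                 n_win, 8)
  raw_ok <- matrix(20, n_win, 8)  # row sums 160 > 50
  # identical groups -> no calls
  expect_equal(nrow(call_differential(base, raw_ok, groups, windows)), 0)
  # plant in all 4 risk donors over windows 4-6 -> one merged call
  m <- base
  m[4:6, 1:4] <- m[4:6, 1:4] * 3
  calls <- call_differential(m, raw_ok, groups, windows)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "up-in-risk")
  expect_equal(c(calls$start, calls$end), c(15, 30))
  expect_equal(calls$n_supporting_donors, 4)
  expect_equal(calls$p_value, bf_mw_twosided(colMeans(m[4:6, 1:4]),
                                             colMeans(m[4:6, 5:8])))
  # effect in only 2 of 4 risk donors -> no call at min_support = 3
  m2 <- base
  m2[4:6, 1:2] <- m2[4:6, 1:2] * 3
  expect_equal(nrow(call_differential(m2, raw_ok, groups, windows)), 0)
  # failing the >50 raw-sum rule suppresses the call
  raw_low <- raw_ok
  raw_low[4:6, ] <- 50 / 8  # row sums exactly 50 -> dropped (strict >)
  expect_equal(nrow(call_differential(m, raw_low, groups, windows)), 0)
  raw_low[4:6, ] <- 51 / 8
  expect_equal(nrow(call_differential(m, raw_low, groups, windows)), 1)
  expect_error(call_differential(m, raw_ok, rep(c("risk", "nonrisk"), c(2, 6)),
                                 windows), "min_support")
})

test_that("sequence-level 4C pipeline recovers the planted counts", {
  spec <- fourc_spec(region_length = 40000, reads_per_donor = c(8000, 9000),
                     loops = list(list(start = 5000, end = 10000, fold = 4,
                                       group = "risk")))
  sim <- gen_4c_reads(spec, groups = c("risk", "nonrisk"), seed = 17)
  region <- genomic_interval(spec$chrom, 0, spec$region_length)
  for (d in names(sim$reads)) {
    ft <- filter_and_trim(sim$reads[[d]], sim$bait_seq)
    expect_gt(ft$retained_fraction, 0.9)
    mapped <- map_reads_exact(ft$trimmed, sim$region_seq, chrom = spec$chrom)
    cf <- count_fragments(mapped, sim$frags)
    expect_equal(cf$n_assigned + cf$n_dropped, nrow(mapped))
    # recovered per-fragment counts match the sampled truth
    expect_equal(cf$counts, unname(sim$truth$counts[, d]))
  }
})

test_that("read conservation holds through the fragment counter", {
  spec <- fourc_spec(region_length = 20000, reads_per_donor = c(2000, 2500))
  sim <- gen_4c_reads(spec, groups = c("risk", "nonrisk"), seed = 3)
  ft <- filter_and_trim(sim$reads[[1]], sim$bait_seq)
  mapped <- map_reads_exact(ft$trimmed, sim$region_seq, chrom = spec$chrom)
  cf <- count_fragments(mapped, sim$frags)
  expect_equal(sum(cf$counts), cf$n_assigned)
  expect_equal(cf$n_assigned + cf$n_dropped, nrow(mapped))
})
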