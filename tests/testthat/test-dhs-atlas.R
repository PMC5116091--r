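mk_peaks <- function(starts, ends, scores, chrom = "chr17") {
  data.frame(chrom = chrom, start = starts, end = ends, score = scores,
             stringsAsFactors = FALSE)
}

test_that("merge_cell_type applies the max-score master-peak rule", {
  t1 <- mk_peaks(10, 30, 5)
  t2 <- mk_peaks(20, 40, 9)
  m <- merge_cell_type(list(t1, t2), "T_cell")
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end, m$score), c(10, 40, 9))
  # idempotence over identical replicates
  m3 <- merge_cell_type(list(t1, t1, t1))
  expect_equal(m3[, c("start", "end", "score")],
               merge_cell_type(t1)[, c("start", "end", "score")])
  # disjoint peaks keep their own scores
  m4 <- merge_cell_type(mk_peaks(c(0, 100), c(50, 150), c(2, 7)))
  expect_equal(m4$score, c(2, 7))
})

test_that("count_dhs and unique_locus_dhs count overlaps and deduplicate", {
  locus <- list(interval = genomic_interval("chr17", 1000, 2000))
  merged <- mk_peaks(c(900, 1500, 2500), c(1100, 1600, 2600), c(1, 1, 1))
  expect_equal(count_dhs(locus, merged), 2)  # straddling peak counts once
  expect_equal(count_dhs(locus, mk_peaks(5000, 5100, 1)), 0)
  expect_equal(unique_locus_dhs(list(merged, merged), locus), 2)
  other <- mk_peaks(1800, 1900, 3)
  expect_equal(unique_locus_dhs(list(merged, other), locus), 3)
  expect_equal(unique_locus_dhs(list(mk_peaks(1, 2, 1)[0, ]), locus), 0)
})

test_that("snp_overlap counts distinct DHS containing SNPs", {
  merged <- mk_peaks(c(100, 300), c(200, 400), c(1, 1))
  snps <- data.frame(id = c("s1", "s2", "s3"), chrom = "chr17",
                     pos = c(150, 160, 999))
  ov <- snp_overlap(snps, merged)
  expect_equal(unname(ov$snp_flags), c(TRUE, TRUE, FALSE))
  expect_equal(ov$n_snps_in_dhs, 2)
  expect_equal(ov$n_dhs_with_snp, 1)  # two SNPs share one DHS
  empty <- snp_overlap(snps, merged[0, ])
  expect_false(any(empty$snp_flags))
})

test_that("snp_overlap agrees with a brute-force all-pairs scan", {
  set.seed(3)
  for (rep in 1:25) {
    merged <- merge_intervals(rand_ivs(6))
    merged$score <- 1
    snps <- data.frame(id = paste0("s", 1:10), chrom = "chrZ",
                       pos = sample.int(300, 10))
    ov <- snp_overlap(snps, merged)
    bf_flags <- vapply(seq_len(nrow(snps)), function(i)
      any(vapply(seq_len(nrow(merged)), function(j)
        bf_snp_in(snps[i, ], merged[j, ]), TRUE)), TRUE)
    expect_equal(unname(ov$snp_flags), bf_flags)
    bf_dhs <- sum(vapply(seq_len(nrow(merged)), function(j)
      any(vapply(seq_len(nrow(snps)), function(i)
        bf_snp_in(snps[i, ], merged[j, ]), TRUE)), TRUE))
    expect_equal(ov$n_dhs_with_snp, bf_dhs)
  }
})

test_that("rank_cell_types orders by count with lexicographic ties", {
  expect_equal(rank_cell_types(c(A = 5, B = 9)), c("B", "A"))
  expect_equal(rank_cell_types(c(C = 5, A = 5)), c("A", "C"))
  expect_equal(rank_cell_types(c(only = 3)), "only")
})

test_that("immune_enrichment matches the pooled t-test closed form", {
  counts <- c(i1 = 8, i2 = 9, i3 = 10, n1 = 1, n2 = 2, n3 = 3)
  cats <- c(i1 = "immune", i2 = "immune", i3 = "immune",
            n1 = "non-immune", n2 = "non-immune", n3 = "non-immune")
  res <- immune_enrichment(counts, cats, n_tests = 5)
  oracle <- bf_pooled_t(c(8, 9, 10), c(1, 2, 3))
  expect_equal(res$t_statistic, oracle$t, tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(res$p_bonferroni, min(1, oracle$p * 5))
  expect_equal(res$immune_ratio, 9 / 2)
  # identical groups -> t = 0, p = 1, ratio 1
  same <- immune_enrichment(c(i1 = 4, i2 = 4, n1 = 4, n2 = 4), cats[c(1, 2, 4, 5)])
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$immune_ratio, 1)
  expect_error(immune_enrichment(c(i1 = 1, n1 = 2, n2 = 3), cats[c(1, 4, 5)]),
               ">= 2")
})

test_that("bonferroni multiplies and caps at 1", {
  counts <- c(i1 = 9, i2 = 11, n1 = 2, n2 = 3)
  cats <- c(i1 = "immune", i2 = "immune", n1 = "non-immune", n2 = "non-immune")
  r1 <- immune_enrichment(counts, cats, n_tests = 5)
  expect_equal(r1$p_bonferroni, min(1, r1$p_value * 5))
  r2 <- immune_enrichment(counts, cats, n_tests = 1e6)
  expect_equal(r2$p_bonferroni, 1)
})

test_that("immune enrichment has power on rate-separated synthetic tracks", {
  cts <- data.frame(name = c(paste0("imm", 1:4), paste0("non", 1:4)),
                    category = rep(c("immune", "non-immune"), each = 4))
  locus <- define_locus(data.frame(id = "s", chrom = "chr17", pos = 120000,
                                   ref = "A", alt = "G", is_lead = TRUE),
                        flank = 100000)
  sim <- gen_dhs_tracks(cts, locus, rate_immune = 60, rate_nonimmune = 15,
                        seed = 21)
  merged <- lapply(sim$tracks, merge_cell_type)
  counts <- vapply(merged, function(m) count_dhs(locus, m), 0L)
  cats <- setNames(cts$category, cts$name)
  res <- immune_enrichment(counts, cats)
  expect_gt(res$immune_ratio, 2)
  expect_lt(res$p_value, 0.01)
})
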