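test_that("fold_enrichment follows the percent-of-input arithmetic", {
  cts <- data.frame(site = rep(c("target", "control"), each = 2),
                    fraction = rep(c("input", "IP"), 2),
                    ct = c(20, 20, 20, 20))
  expect_equal(unname(fold_enrichment(cts)["target"]), 1)
  cts$ct <- c(20, 15, 20, 18)  # target IP 3 cycles below control IP
  expect_equal(unname(fold_enrichment(cts)["target"]), 8)
  set.seed(2)
  cts$ct <- runif(4, 10, 35)
  expect_gt(unname(fold_enrichment(cts)["target"]), 0)
  expect_error(fold_enrichment(cts[-2, ]), "exactly one")
})

test_that("allele_ratio renormalizes over the two alleles", {
  r <- allele_ratio(c(A = 100, C = 5, G = 300, T = 2), "G", "A")
  expect_equal(r$pct_risk, 75)
  expect_equal(r$pct_nonrisk, 25)
  expect_equal(allele_ratio(c(A = 50, G = 50), "G", "A")$pct_risk, 50)
  # scale invariance
  r2 <- allele_ratio(c(A = 100, C = 5, G = 300, T = 2) * 17, "G", "A")
  expect_equal(r2$pct_risk, r$pct_risk)
  expect_error(allele_ratio(c(A = 0, G = 0), "G", "A"), "zero")
  expect_error(allele_ratio(c(A = 1), "G", "A"), "present")
})

test_that("synthetic traces recover the mixing fraction (input vs IP)", {
  input <- gen_trace(0.5, "G", "A", seed = 31)
  ip <- gen_trace(0.95, "G", "A", seed = 32)
  expect_equal(allele_ratio(input, "G", "A")$pct_risk, 50, tolerance = 0.05)
  expect_equal(allele_ratio(ip, "G", "A")$pct_risk, 95, tolerance = 0.05)
})

test_that("extend_reads extends along the sequencing direction", {
  plus <- data.frame(chrom = "c", start = 1000, strand = "+", length = 50)
  expect_equal(extend_reads(plus)[, c("start", "end")],
               data.frame(start = 1000, end = 1250))
  minus <- data.frame(chrom = "c", start = 1200, strand = "-", length = 50)
  expect_equal(extend_reads(minus)[, c("start", "end")],
               data.frame(start = 1000, end = 1250))
  near0 <- data.frame(chrom = "c", start = 10, strand = "-", length = 50)
  expect_equal(extend_reads(near0)$start, 0)  # clipped
  # duplicates retained
  dup <- rbind(plus, plus)
  expect_equal(nrow(extend_reads(dup)), 2)
})

test_that("window_coverage matches the rpkm formula and a brute-force count", {
  region <- genomic_interval("c", 0, 500)
  one <- data.frame(chrom = "c", start = 10, strand = "+", length = 50)
  prof <- window_coverage(extend_reads(one), region, 50, library_size = 1e6)
  expect_equal(prof$rpkm[1], 20)  # 1 / 1 / 0.05
  expect_equal(sum(prof$count), sum(prof$start < 260))  # spans windows 1..6
  zero <- window_coverage(extend_reads(one[0, ]), region, 50, 1e6)
  expect_true(all(zero$rpkm == 0))
  # brute-force per-window overlap count on random reads
  set.seed(8)
  reads <- data.frame(chrom = "c", start = sample(0:450, 40, TRUE),
                      strand = sample(c("+", "-"), 40, TRUE), length = 30)
  ext <- extend_reads(reads, ext = 40)
  prof2 <- window_coverage(ext, region, 50, 40)
  bf <- vapply(seq_len(nrow(prof2)), function(w)
    sum(vapply(seq_len(nrow(ext)), function(r)
      bf_overlap(ext[r, ], prof2[w, c("chrom", "start", "end")]), TRUE)), 0)
  expect_equal(prof2$count, bf)
  # truncated last window flagged
  prof3 <- window_coverage(ext, genomic_interval("c", 0, 120), 50, 40)
  expect_true(attr(prof3, "truncated_last"))
  expect_equal(prof3$end[3] - prof3$start[3], 20)
})

test_that("snp_region_value equals direct formula evaluation", {
  snp <- data.frame(id = "s", chrom = "c", pos = 1001)
  # 4-read fixture: two overlap the 400bp window [800,1200) after extension
  reads <- data.frame(chrom = "c",
                      start = c(500, 790, 1150, 5000),
                      strand = c("+", "+", "-", "+"), length = 50)
  v <- snp_region_value(reads, snp, span = 400, library_size = 1e6)
  # extended: [500,750) out, [790,1040) in, [950,1200) in, [5000,5250) out
  expect_equal(as.numeric(v), 2 / 1 / 0.4)
  expect_equal(attr(v, "span"), 400)
  expect_equal(as.numeric(
    snp_region_value(reads[0, ], snp, 200, library_size = 10)), 0)
  expect_error(snp_region_value(reads, snp, span = 201, library_size = 10),
               "even")
  # uniform coverage at c rpkm per 50-bp window -> region value c
  dense <- data.frame(chrom = "c", start = 0:1999, strand = "+", length = 1)
  win <- window_coverage(extend_reads(dense, ext = 1),
                         genomic_interval("c", 800, 1200), 50,
                         library_size = 2000)
  vr <- snp_region_value(dense, snp, 400, library_size = 2000, ext = 1)
  expect_equal(as.numeric(vr), unique(win$rpkm))
})

test_that("genotype_fold_change: fold arithmetic and exact MW p-value", {
  same <- genotype_fold_change(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$fold_change, 1)
  expect_equal(same$p_value, 1)
  res <- genotype_fold_change(c(2, 3, 4), c(1, 1, 2))
  expect_equal(res$fold_change, 2.25)
  expect_equal(res$p_value, bf_mw_twosided(c(2, 3, 4), c(1, 1, 2)))
  expect_match(res$method, "exact")
  expect_error(genotype_fold_change(c(1, 2), c(0, 0)), "zero")
})

test_that("exact permutation MW agrees with the U-statistic oracle", {
  set.seed(13)
  for (rep in 1:20) {
    x <- sample(1:5, 4, replace = TRUE)
    y <- sample(1:5, 4, replace = TRUE)
    expect_equal(mann_whitney_exact(x, y), bf_mw_twosided(x, y),
                 info = paste(c(x, "|", y), collapse = " "))
  }
})

test_that("planted 1.44-fold H3K27ac effect is recovered from reads", {
  region <- genomic_interval("chr17", 0, 10000)
  enhancer <- genomic_interval("chr17", 4850, 5150)
  snp <- data.frame(id = "rs8076131", chrom = "chr17", pos = 5001)
  sim <- gen_chip_reads(n_risk = 36, n_nonrisk = 7, enhancer, region,
                        fold = 1.44, seed = 99)
  vals <- vapply(names(sim$reads), function(d)
    as.numeric(snp_region_value(sim$reads[[d]], snp, span = 400,
                                library_size = sim$library_sizes[[d]])), 0)
  cmp <- genotype_fold_change(vals[sim$groups == "risk"],
                              vals[sim$groups == "nonrisk"])
  expect_equal(cmp$fold_change, 1.44, tolerance = 0.15)
  expect_lt(cmp$p_value, 0.05)
})
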