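toy_jaspar <- c(">MA0001.1 TOY",
                "A [ 4 19 ]",
                "C [ 16 0 ]",
                "G [ 0 1 ]",
                "T [ 0 0 ]")

test_that("parse_jaspar reads the text dialect and normalizes row order", {
  p <- parse_jaspar(text = toy_jaspar)[[1]]
  expect_s3_class(p, "pwm")
  expect_equal(ncol(p$matrix), 2)
  expect_equal(p$matrix["A", ], c(4, 19))
  expect_equal(p$tf_name, "TOY")
  # rows out of order are reassembled by label
  shuffled <- toy_jaspar[c(1, 3, 2, 5, 4)]
  p2 <- parse_jaspar(text = shuffled)[[1]]
  expect_identical(p2$matrix, p$matrix)
  expect_error(parse_jaspar(text = toy_jaspar[1:4]), "4 base rows")
  expect_error(parse_jaspar(text = c(">X", "A [ 1 2 ]", "C [ 1 ]",
                                     "G [ 1 2 ]", "T [ 1 2 ]")), "ragged")
})

test_that("jaspar round-trips through write_jaspar", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  orig <- parse_jaspar(text = toy_jaspar)[[1]]
  write_jaspar(orig, path)
  back <- parse_jaspar(path)[[1]]
  expect_identical(back$matrix, orig$matrix)
})

test_that("log_odds follows the background-pseudocount formula", {
  # uniform column with uniform background scores 0 everywhere
  p <- pwm(matrix(5, 4, 2))
  expect_true(all(abs(log_odds(p)) < 1e-12))
  # hand-evaluated 4x1 case: counts 6,2,1,1, pc 0.1 uniform bg
  p2 <- pwm(matrix(c(6, 2, 1, 1), 4, 1))
  adj <- c(6, 2, 1, 1) + 0.1 * 0.25
  expect_equal(log_odds(p2)[, 1], log2(adj / sum(adj) / 0.25),
               ignore_attr = TRUE)
  # a near-pure column approaches log2(4) for the dominant base
  p3 <- pwm(matrix(c(1e6, 0, 0, 0), 4, 1), pseudocount = 1e-9)
  expect_equal(log_odds(p3)["A", 1], 2, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("score_pvalue boundary cases", {
  p <- parse_jaspar(text = toy_jaspar)[[1]]
  sc <- pwm_scoring(p)
  lo_min <- sum(apply(sc$lo, 2, min))
  lo_max <- sum(apply(sc$lo, 2, max))
  expect_equal(score_pvalue(p, lo_min - 1), 1.0)
  expect_equal(score_pvalue(p, lo_min), 1.0)
  # max achievable with uniform bg: single best word per column
  expect_equal(score_pvalue(p, lo_max), 0.25^2, tolerance = 1e-12)
})

test_that("score_pvalue DP equals exhaustive enumeration (w <= 8)", {
  set.seed(101)
  for (w in 1:8) {
    p <- rand_pwm(w)
    sc <- pwm_scoring(p)
    # thresholds: distinct achievable integer scores, checked on the same
    # discretized matrix the DP uses -- isolates the DP aggregation
    words_mat <- sc$ints
    qs <- quantile(colSums(matrix(words_mat[cbind(
      sample(1:4, 200 * w, replace = TRUE), rep(1:w, each = 200))],
      nrow = w)), c(0.1, 0.5, 0.9))
    thresholds <- sort(unique(round(c(qs, sc$base, sc$max_total))))
    enum <- bf_enum_pvalues(words_mat, p$background, thresholds)
    dp <- vapply(thresholds, function(t)
      haploregulome:::int_pvalue(sc, t), 0)
    expect_equal(dp, enum, tolerance = 1e-9)
  }
})

test_that("discretization preserves continuous-score p-values (w = 3)", {
  set.seed(5)
  p <- rand_pwm(3)
  sc <- pwm_scoring(p)
  words <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  exact_scores <- sc$lo[cbind(words[, 1], 1)] +
    sc$lo[cbind(words[, 2], 2)] + sc$lo[cbind(words[, 3], 3)]
  # evaluate at midpoints between well-separated achievable scores
  u <- sort(unique(round(exact_scores, 6)))
  gaps <- which(diff(u) > 10 * sc$g)
  mids <- (u[gaps] + u[gaps + 1]) / 2
  enum <- bf_enum_pvalues(sc$lo, p$background, mids)
  dp <- vapply(mids, function(s) score_pvalue(p, s), 0)
  expect_equal(dp, enum, tolerance = 1e-3)
})

test_that("p is non-increasing in score", {
  p <- ctcf_like_pwm()
  sc <- pwm_scoring(p)
  ps <- haploregulome:::int_pvalue(sc, seq(sc$base, sc$max_total, by = 7))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("scan_sequence finds planted sites on both strands", {
  p <- ctcf_like_pwm()
  lo <- log_odds(p)
  consensus <- paste(c("A", "C", "G", "T")[apply(lo, 2, which.max)],
                     collapse = "")
  set.seed(9)
  bg <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  seq_fwd <- paste0(bg(40), consensus, bg(40))
  hits <- scan_sequence(seq_fwd, p)
  expect_true(any(hits$start == 40 & hits$strand == "+"))
  seq_rev <- paste0(bg(40), revcomp(consensus), bg(40))
  hits_rev <- scan_sequence(seq_rev, p)
  expect_true(any(hits_rev$start == 40 & hits_rev$strand == "-"))
  # mirrored hits on the reverse complement of the whole sequence
  rc_hits <- scan_sequence(revcomp(seq_fwd), p)
  n <- nchar(seq_fwd)
  expect_setequal(n - rc_hits$end, hits$start)
  expect_equal(sort(rc_hits$score), sort(hits$score))
  # edge cases
  expect_equal(nrow(scan_sequence("ACGT", p)), 0)     # shorter than w
  expect_equal(nrow(scan_sequence(strrep("N", 60), p)), 0)
})

test_that("allele_scan classifies gain/loss and respects preconditions", {
  p <- ctcf_like_pwm()
  fx <- gen_motif_fixture(p, flank_len = 25, snp_effect = "loss", seed = 77)
  expect_equal(fx$expected, "loss")
  res <- allele_scan(fx$seq_ref, fx$snp, 1, p)
  expect_equal(res$classification, "loss")
  expect_gt(res$best_ref$score, 0)
  expect_null(res$best_alt)

  fx2 <- gen_motif_fixture(p, flank_len = 25, snp_effect = "gain", seed = 78)
  res2 <- allele_scan(fx2$seq_ref, fx2$snp, 1, p)
  expect_equal(res2$classification, "gain")
  # ref == alt can never produce gain/loss
  res3 <- allele_scan(fx$seq_ref, transform(fx$snp, alt = ref), 1, p)
  expect_true(res3$classification %in% c("retained", "absent"))
  # insufficient flank -> error
  short <- substr(fx$seq_ref, fx$snp$pos - 3, fx$snp$pos + 3)
  snp_short <- transform(fx$snp, pos = 4)
  expect_error(allele_scan(short, snp_short, 1, p), "w - 1")
  expect_error(allele_scan(fx$seq_ref, transform(fx$snp, pos = 9999), 1, p),
               "outside")
})

test_that("width-1 PWMs classify consistently (degenerate edge)", {
  p1 <- pwm(matrix(c(97, 1, 1, 1), 4, 1))
  snp <- data.frame(id = "s", chrom = "c", pos = 3, ref = "A", alt = "G",
                    is_lead = FALSE)
  res <- allele_scan("CCACC", snp, 1, p1)
  expect_equal(res$classification, "absent")  # best p = 0.25 >> 1e-4
})
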