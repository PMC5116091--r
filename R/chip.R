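#' qPCR fold enrichment over a control region
#'
#' Percent-of-input per site is `2^(Ct_input - Ct_IP)`; the fold enrichment
#' of a target site is its percent-of-input divided by that of the control
#' site, which cancels any constant dilution factor.
#'
#' @param cts data.frame for one sample with columns `site`, `fraction`
#'   ("input" or "IP") and `ct`.
#' @param control_site label of the background control site.
#' @return named numeric vector of fold enrichment per non-control site.
#' @export
fold_enrichment <- function(cts, control_site = "control") {
  stopifnot(all(c("site", "fraction", "ct") %in% names(cts)))
  if (any(cts$ct <= 0)) stop("Ct values must be positive")
  pct <- function(site) {
    ip <- cts$ct[cts$site == site & cts$fraction == "IP"]
    input <- cts$ct[cts$site == site & cts$fraction == "input"]
    if (length(ip) != 1 || length(input) != 1)
      stop("site '", site, "': need exactly one IP and one input Ct")
    2^(input - ip)
  }
  if (!control_site %in% cts$site) stop("control site not found")
  ctrl <- pct(control_site)
  targets <- setdiff(unique(cts$site), control_site)
  vapply(stats::setNames(targets, targets), function(s) pct(s) / ctrl, 0)
}

#' Allele ratio from Sanger chromatogram intensities
#'
#' The percentage of each allele is read from the trace signal intensities
#' at the SNP position; channels other than the two relevant alleles are
#' ignored and the two percentages renormalize to 100.
#'
#' @param intensities named numeric vector of channel intensities
#'   (names among A, C, G, T).
#' @param risk_base,nonrisk_base the two alleles.
#' @return list with `pct_risk` and `pct_nonrisk`.
#' @export
allele_ratio <- function(intensities, risk_base, nonrisk_base) {
  if (!all(c(risk_base, nonrisk_base) %in% names(intensities)))
    stop("both alleles must be present in the intensity mapping")
  r <- intensities[[risk_base]]
  n <- intensities[[nonrisk_base]]
  if (r < 0 || n < 0) stop("intensities must be non-negative")
  if (r + n == 0) stop("zero total intensity over the two alleles")
  list(pct_risk = 100 * r / (r + n), pct_nonrisk = 100 * n / (r + n))
}

#' Extend reads along the sequencing direction
#'
#' A plus-strand read starting at `s` becomes `[s, s + ext)`; a minus-strand
#' read whose (exclusive) right end is `e = start + length` becomes
#' `[e - ext, e)`. Extension past coordinate 0 is clipped. Duplicates are
#' retained (uniq = FALSE).
#'
#' @param reads data.frame with `chrom`, `start` (0-based leftmost base),
#'   `strand`, `length`.
#' @param ext extension length in bp (default 250).
#' @return interval data.frame.
#' @export
extend_reads <- function(reads, ext = 250) {
  e5 <- ifelse(reads$strand == "+", reads$start, reads$start + reads$length)
  start <- ifelse(reads$strand == "+", e5, pmax(0, e5 - ext))
  end <- ifelse(reads$strand == "+", e5 + ext, e5)
  keep <- end > start
  data.frame(chrom = reads$chrom[keep], start = start[keep], end = end[keep],
             stringsAsFactors = FALSE)
}

#' Windowed coverage profile (RPKM)
#'
#' The region is tiled with consecutive windows; the count per window is the
#' number of extended reads overlapping it (a read spanning two windows is
#' counted in both), normalized as
#' `rpkm = count / (library_size / 1e6) / (window_bp / 1000)`.
#'
#' @param extended interval data.frame of extended reads.
#' @param region one-row interval data.frame.
#' @param window window size in bp (default 50).
#' @param library_size total mapped reads (> 0).
#' @return data.frame `chrom`, `start`, `end`, `count`, `rpkm`, with
#'   attribute `truncated_last` flagging a final window shorter than
#'   `window`.
#' @export
window_coverage <- function(extended, region, window = 50, library_size) {
  stopifnot(nrow(region) == 1, library_size > 0, window > 0)
  starts <- seq(region$start, region$end - 1, by = window)
  ends <- pmin(starts + window, region$end)
  wins <- IRanges::IRanges(start = starts + 1L, end = ends)
  ext <- extended[extended$chrom == region$chrom, , drop = FALSE]
  count <- IRanges::countOverlaps(wins, as_iranges(ext))
  wbp <- ends - starts
  out <- data.frame(chrom = region$chrom, start = starts, end = ends,
                    count = as.numeric(count),
                    rpkm = count / (library_size / 1e6) / (wbp / 1000),
                    stringsAsFactors = FALSE)
  attr(out, "truncated_last") <- wbp[length(wbp)] < window
  attr(out, "window") <- window
  out
}

#' Normalized read count around a SNP
#'
#' RPKM over the span centered on the SNP's 0-based index: the window
#' `[pos - 1 - span/2, pos - 1 + span/2)`. The default span is 400 bp
#' (200 bp on either side); set `span = 200` for a 200 bp total window.
#'
#' @param reads read data.frame (`chrom`, `start`, `strand`, `length`).
#' @param snp one-row SNP data.frame.
#' @param span total window width in bp (even).
#' @param library_size total mapped reads.
#' @param ext read extension (bp) applied before counting.
#' @return RPKM value with attribute `span`.
#' @export
snp_region_value <- function(reads, snp, span = 400, library_size, ext = 250) {
  if (span %% 2 != 0) stop("span must be even")
  c0 <- snp$pos - 1
  region <- genomic_interval(snp$chrom, max(0, c0 - span / 2), c0 + span / 2)
  extended <- extend_reads(reads, ext)
  n <- count_overlapping(extended, region)
  v <- n / (library_size / 1e6) / (interval_width(region) / 1000)
  attr(v, "span") <- span
  v
}

#' Exact two-sided Mann-Whitney p-value by permutation
#'
#' Enumerates all assignments of the pooled values into groups of the
#' observed sizes and compares the rank-sum statistic (midranks for ties)
#' two-sidedly around its permutation mean. Used for small groups where an
#' exact test with ties is needed.
#'
#' @param x,y numeric vectors.
#' @return two-sided p-value.
#' @export
mann_whitney_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  mu <- length(x) * (n + 1) / 2
  combos <- utils::combn(n, length(x))
  w_all <- colSums(matrix(r[combos], nrow = length(x)))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

#' Genotype-stratified fold change with Mann-Whitney test
#'
#' Fold change is the ratio of group means (risk over non-risk); the
#' two-sided Mann-Whitney p-value uses exact permutation enumeration for
#' small groups (both n <= 20 and a feasible enumeration) and the normal
#' approximation with tie correction otherwise.
#'
#' @param risk,nonrisk numeric vectors of per-donor values.
#' @return list with `fold_change`, `p_value`, `group_means`, `n`,
#'   `method`.
#' @export
genotype_fold_change <- function(risk, nonrisk) {
  if (length(risk) < 1 || length(nonrisk) < 1)
    stop("need >= 1 donor per group")
  if (mean(nonrisk) == 0) stop("non-risk group mean is zero")
  n1 <- length(risk); n2 <- length(nonrisk)
  exact_ok <- max(n1, n2) <= 20 && choose(n1 + n2, n1) <= 2e5
  if (n1 >= 2 && n2 >= 2) {
    if (exact_ok) {
      p <- mann_whitney_exact(risk, nonrisk)
      method <- "exact permutation"
    } else {
      p <- suppressWarnings(stats::wilcox.test(risk, nonrisk, exact = FALSE,
                                               correct = TRUE)$p.value)
      method <- "normal approximation with tie correction"
    }
  } else {
    p <- NA_real_
    method <- "not tested (singleton group)"
  }
  list(fold_change = mean(risk) / mean(nonrisk),
       p_value = p,
       group_means = c(risk = mean(risk), nonrisk = mean(nonrisk)),
       n = c(risk = n1, nonrisk = n2),
       method = method)
}
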