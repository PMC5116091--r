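#' In-silico restriction digest
#'
#' A cut is placed immediately before each occurrence of the recognition
#' site (blunt simplification; the 4-bp overhang geometry does not affect
#' fragment counting at this resolution). Fragments tile the sequence
#' exactly; a site at position 0 does not create an empty fragment.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param site recognition sequence (default GATC, DpnII).
#' @param chrom,offset0 coordinates of the first base of `seq`.
#' @return fragment data.frame `chrom`, `start`, `end` (0-based half-open)
#'   with a `fragment` index column.
#' @export
digest_sequence <- function(seq, site = "GATC", chrom = "region", offset0 = 0) {
  n <- nchar(seq)
  hits <- gregexpr(paste0("(?=", site, ")"), seq, perl = TRUE)[[1]]
  cuts <- if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
  bounds <- sort(unique(c(0L, cuts, n)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  data.frame(chrom = chrom, start = offset0 + starts, end = offset0 + ends,
             fragment = seq_along(starts), stringsAsFactors = FALSE)
}

#' Filter reads for the bait sequence and trim it
#'
#' Reads lacking an exact bait match at the 5' end are discarded; survivors
#' have the bait prefix removed. Reads that are exactly the bait (empty
#' remainder) are discarded too.
#'
#' @param reads character vector of read sequences.
#' @param bait_seq bait (reading primer) sequence.
#' @return list with `trimmed` (character vector), `retained_fraction`,
#'   `n_input`, `n_no_bait`, `n_empty_after_trim`.
#' @export
filter_and_trim <- function(reads, bait_seq) {
  if (nchar(bait_seq) == 0) stop("bait sequence must be non-empty")
  has_bait <- startsWith(reads, bait_seq)
  trimmed <- substring(reads[has_bait], nchar(bait_seq) + 1)
  empty <- !nzchar(trimmed)
  n_kept <- sum(has_bait) - sum(empty)
  list(trimmed = trimmed[!empty],
       retained_fraction = if (length(reads)) n_kept / length(reads) else NA_real_,
       n_input = length(reads),
       n_no_bait = sum(!has_bait),
       n_empty_after_trim = sum(empty))
}

#' Place trimmed reads by unique exact match
#'
#' Stand-in for read alignment on synthetic data: each trimmed read is
#' located by exact string match against the region sequence; reads with
#' zero or multiple matches are dropped.
#'
#' @param trimmed character vector of trimmed read sequences.
#' @param region_seq region DNA string.
#' @param chrom,offset0 region coordinates.
#' @return read data.frame (`chrom`, `start`, `strand`, `length`) with
#'   attributes `n_unmapped` and `n_ambiguous`.
#' @export
map_reads_exact <- function(trimmed, region_seq, chrom = "region", offset0 = 0) {
  subject <- Biostrings::DNAString(region_seq)
  uniq <- unique(trimmed)
  pos <- vapply(uniq, function(s) {
    m <- Biostrings::matchPattern(s, subject)
    if (length(m) == 1) Biostrings::start(m) else NA_integer_
  }, 0L)
  n_match <- vapply(uniq, function(s)
    length(Biostrings::matchPattern(s, subject)), 0L)
  lookup <- stats::setNames(pos, uniq)
  amb <- stats::setNames(n_match > 1, uniq)
  p <- lookup[trimmed]
  is_amb <- amb[trimmed]
  keep <- !is.na(p) & !is_amb
  out <- data.frame(chrom = chrom, start = offset0 + p[keep] - 1,
                    strand = "+", length = nchar(trimmed[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- sum(is.na(p))
  attr(out, "n_ambiguous") <- sum(is_amb, na.rm = TRUE)
  out
}

#' Count reads per restriction fragment
#'
#' Each read is assigned to the fragment containing its 5' position (the
#' leftmost base for plus-strand reads, the rightmost for minus-strand); a
#' read starting exactly on a fragment boundary belongs to the downstream
#' fragment (half-open convention). Reads outside the fragment map are
#' dropped and counted.
#'
#' @param reads read data.frame.
#' @param frags fragment map from [digest_sequence()].
#' @return list with `counts` (per fragment), `n_assigned`, `n_dropped`.
#' @export
count_fragments <- function(reads, frags) {
  n_input <- nrow(reads)
  reads <- reads[reads$chrom == frags$chrom[1], , drop = FALSE]
  p5 <- ifelse(reads$strand == "+", reads$start,
               reads$start + reads$length - 1)
  idx <- findInterval(p5, frags$start)
  inside <- idx >= 1 & p5 < frags$end[pmax(idx, 1)]
  counts <- tabulate(idx[inside], nbins = nrow(frags))
  list(counts = counts, n_assigned = sum(inside),
       n_dropped = n_input - sum(inside))
}

fragment_windows <- function(frags, region, resolution) {
  starts <- seq(region$start, region$end - 1, by = resolution)
  ends <- pmin(starts + resolution, region$end)
  mid <- (frags$start + frags$end) / 2
  win_of_frag <- findInterval(mid, starts)
  win_of_frag[mid < region$start | mid >= region$end] <- NA
  list(starts = starts, ends = ends, win_of_frag = win_of_frag)
}

#' Near-cis trend profile
#'
#' Fragment counts are normalized to reads per million of in-region reads;
#' the window statistic is the mean normalized count over fragments whose
#' midpoint lies in the window (trend resolution 5,000 bp by default).
#' Windows without any fragment midpoint carry 0 and are flagged.
#'
#' @param counts per-fragment read counts.
#' @param frags fragment map.
#' @param region one-row interval data.frame.
#' @param resolution window width in bp.
#' @return data.frame `chrom`, `start`, `end`, `stat`, `n_fragments`,
#'   `empty`.
#' @export
trend_profile <- function(counts, frags, region, resolution = 5000) {
  stopifnot(resolution > 0, nrow(region) == 1)
  fw <- fragment_windows(frags, region, resolution)
  total <- sum(counts)
  norm <- if (total > 0) counts / total * 1e6 else counts
  nwin <- length(fw$starts)
  stat <- numeric(nwin)
  nfrag <- integer(nwin)
  ok <- !is.na(fw$win_of_frag)
  if (any(ok)) {
    agg_sum <- tapply(norm[ok], fw$win_of_frag[ok], sum)
    agg_n <- tapply(norm[ok], fw$win_of_frag[ok], length)
    wi <- as.integer(names(agg_sum))
    stat[wi] <- agg_sum / agg_n
    nfrag[wi] <- agg_n
  }
  data.frame(chrom = region$chrom, start = fw$starts, end = fw$ends,
             stat = stat, n_fragments = nfrag, empty = nfrag == 0,
             stringsAsFactors = FALSE)
}

#' Aggregate raw fragment counts to trend windows
#'
#' @inheritParams trend_profile
#' @return numeric vector of per-window raw-count sums.
#' @export
window_raw_counts <- function(counts, frags, region, resolution = 5000) {
  fw <- fragment_windows(frags, region, resolution)
  out <- numeric(length(fw$starts))
  ok <- !is.na(fw$win_of_frag)
  if (any(ok)) {
    agg <- tapply(counts[ok], fw$win_of_frag[ok], sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' Low-count filter
#'
#' Keeps rows (fragments or windows) whose raw-count sum across all donors
#' is strictly greater than `min_sum` (default 50).
#'
#' @param mat numeric matrix, rows = fragments/windows, columns = donors.
#' @param min_sum strict lower bound on the cross-donor sum.
#' @return logical vector of kept rows.
#' @export
low_count_filter <- function(mat, min_sum = 50) {
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  rowSums(mat) > min_sum
}

#' Call genotype-differential near-cis regions
#'
#' A window is donor-enriched for a group when that donor's normalized
#' value strictly exceeds the other group's per-window median. A window is
#' called for a direction when at least `min_support` donors of that group
#' are enriched and the window passed the low-count filter; adjacent called
#' windows with the same direction are merged into regions. Each region
#' gets a two-sided Mann-Whitney p-value across groups on per-donor region
#' means, Benjamini-Hochberg adjusted across regions; calls are annotated
#' significant at adjusted p < `alpha` (default 0.1).
#'
#' @param norm_mat windows x donors matrix of normalized trend statistics.
#' @param raw_mat windows x donors matrix of raw window counts (for the
#'   low-count filter).
#' @param groups character vector per donor, "risk" or "nonrisk".
#' @param windows window data.frame (`chrom`, `start`, `end`) matching the
#'   matrix rows.
#' @param min_support minimum enriched donors per group (default 3).
#' @param min_sum low-count filter threshold (default 50).
#' @param alpha BH-adjusted significance level (default 0.1).
#' @return data.frame of calls (`chrom`, `start`, `end`, `direction`,
#'   `n_supporting_donors`, `n_windows`, `p_value`, `p_adjusted`,
#'   `significant`, `passed_count_filter`), with an `enrichment_rule`
#'   attribute describing the donor-enrichment formalization.
#' @export
call_differential <- function(norm_mat, raw_mat, groups, windows,
                              min_support = 3, min_sum = 50, alpha = 0.1) {
  stopifnot(nrow(norm_mat) == nrow(windows), ncol(norm_mat) == length(groups))
  risk_i <- which(groups == "risk")
  non_i <- which(groups == "nonrisk")
  if (length(risk_i) < min_support || length(non_i) < min_support)
    stop("need >= min_support donors in each group")
  passed <- low_count_filter(raw_mat, min_sum)
  med_non <- apply(norm_mat[, non_i, drop = FALSE], 1, stats::median)
  med_risk <- apply(norm_mat[, risk_i, drop = FALSE], 1, stats::median)
  sup_risk <- rowSums(norm_mat[, risk_i, drop = FALSE] > med_non)
  sup_non <- rowSums(norm_mat[, non_i, drop = FALSE] > med_risk)
  up_risk <- passed & sup_risk >= min_support
  up_non <- passed & sup_non >= min_support
  both <- up_risk & up_non
  if (any(both)) {
    # tie-break by larger group-mean difference
    d <- rowMeans(norm_mat[, risk_i, drop = FALSE]) -
      rowMeans(norm_mat[, non_i, drop = FALSE])
    up_risk[both] <- d[both] > 0
    up_non[both] <- d[both] <= 0
  }
  direction <- ifelse(up_risk, "up-in-risk", ifelse(up_non, "up-in-nonrisk", NA))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), n_supporting_donors = integer(),
                      n_windows = integer(), p_value = numeric(),
                      p_adjusted = numeric(), significant = logical(),
                      passed_count_filter = logical(), stringsAsFactors = FALSE)
  called <- which(!is.na(direction))
  if (!length(called)) return(empty)
  # merge runs of adjacent called windows with the same direction
  run_id <- cumsum(c(1, diff(called) != 1 |
                       direction[called][-1] != direction[called][-length(called)]))
  calls <- lapply(split(called, run_id), function(wi) {
    donor_vals <- colMeans(norm_mat[wi, , drop = FALSE])
    p <- mann_whitney_exact(donor_vals[risk_i], donor_vals[non_i])
    dirn <- direction[wi[1]]
    sup <- if (dirn == "up-in-risk")
      sum(donor_vals[risk_i] > stats::median(donor_vals[non_i]))
    else
      sum(donor_vals[non_i] > stats::median(donor_vals[risk_i]))
    data.frame(chrom = windows$chrom[wi[1]], start = windows$start[wi[1]],
               end = windows$end[wi[length(wi)]], direction = dirn,
               n_supporting_donors = sup, n_windows = length(wi),
               p_value = p, passed_count_filter = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out <- out[, c("chrom", "start", "end", "direction", "n_supporting_donors",
                 "n_windows", "p_value", "p_adjusted", "significant",
                 "passed_count_filter")]
  rownames(out) <- NULL
  attr(out, "enrichment_rule") <-
    "donor-enriched: normalized window value > other group's per-window median"
  out
}

#' Region from printed 1-based coordinates
#'
#' Convenience for analysis view regions quoted as 1-based inclusive
#' spans; reports width in bp and rounded kb.
#'
#' @param chrom chromosome.
#' @param first,last printed 1-based inclusive bounds.
#' @param name label.
#' @export
printed_region <- function(chrom, first, last, name = "region") {
  iv <- iv_from_printed(chrom, first, last)
  list(name = name, interval = iv, first = first, last = last,
       width_bp = last - first + 1,
       width_kb = round((last - first + 1) / 1000))
}

#' Full near-cis differential analysis from fragment counts
#'
#' Convenience wrapper: builds per-donor trend profiles (reads-per-million
#' normalization), aggregates raw counts to windows, and calls
#' genotype-differential regions.
#'
#' @param counts fragment x donor count matrix.
#' @param frags fragment map.
#' @param region one-row interval data.frame.
#' @param groups per-donor group labels ("risk"/"nonrisk").
#' @param resolution trend window width (default 5000).
#' @inheritParams call_differential
#' @return list with `windows`, `norm_mat`, `raw_mat`, `calls`.
#' @export
fourc_differential <- function(counts, frags, region, groups,
                               resolution = 5000, min_support = 3,
                               min_sum = 50, alpha = 0.1) {
  profiles <- lapply(seq_len(ncol(counts)), function(i)
    trend_profile(counts[, i], frags, region, resolution))
  windows <- profiles[[1]][, c("chrom", "start", "end")]
  norm_mat <- vapply(profiles, `[[`, numeric(nrow(windows)), "stat")
  norm_mat <- matrix(norm_mat, nrow = nrow(windows),
                     dimnames = list(NULL, colnames(counts)))
  raw_mat <- vapply(seq_len(ncol(counts)), function(i)
    window_raw_counts(counts[, i], frags, region, resolution),
    numeric(nrow(windows)))
  raw_mat <- matrix(raw_mat, nrow = nrow(windows),
                    dimnames = list(NULL, colnames(counts)))
  calls <- call_differential(norm_mat, raw_mat, groups, windows,
                             min_support = min_support, min_sum = min_sum,
                             alpha = alpha)
  list(windows = windows, norm_mat = norm_mat, raw_mat = raw_mat,
       calls = calls)
}
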