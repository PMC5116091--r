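#' Genomic intervals
#'
#' All internal coordinates are 0-based half-open (BED convention):
#' an interval covers bases `start`, ..., `end - 1`. Printed genome
#' coordinates and SNP positions are 1-based inclusive and are converted at
#' the I/O boundary (see [iv_from_printed()]). Chromosome names are compared
#' as exact strings; use [normalize_chrom()] to reconcile "chr17" vs "17".
#'
#' @param chrom character chromosome name(s).
#' @param start 0-based inclusive start(s), `>= 0`.
#' @param end 0-based exclusive end(s), `> start`.
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @export
genomic_interval <- function(chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  iv <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv) {
  stopifnot(is.data.frame(iv), all(c("chrom", "start", "end") %in% names(iv)))
  if (nrow(iv) == 0) return(invisible(iv))
  if (any(!is.finite(iv$start)) || any(!is.finite(iv$end)))
    stop("interval coordinates must be finite")
  if (any(iv$start < 0)) stop("interval start must be >= 0")
  if (any(iv$end <= iv$start)) stop("interval end must be > start")
  invisible(iv)
}

#' Convert printed 1-based inclusive coordinates to an internal interval
#'
#' @param chrom chromosome name.
#' @param first,last 1-based inclusive first and last base.
#' @export
iv_from_printed <- function(chrom, first, last) {
  genomic_interval(chrom, first - 1, last)
}

#' Interval width in bp
#' @param iv interval data.frame.
#' @export
interval_width <- function(iv) iv$end - iv$start

#' Do two intervals overlap?
#'
#' Half-open semantics: `[100,200)` and `[200,300)` abut but do not overlap.
#' Vectorized elementwise (arguments recycled).
#'
#' @param a,b interval data.frames.
#' @return logical vector.
#' @export
overlaps <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(logical(0))
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ai] == b$chrom[bi] &
    a$start[ai] < b$end[bi] &
    b$start[bi] < a$end[ai]
}

#' Is a SNP position inside an interval?
#'
#' SNP positions are 1-based; the 0-based index `pos - 1` must satisfy
#' `start <= pos - 1 < end`.
#'
#' @param snp one-row data.frame (or list) with `chrom` and `pos`.
#' @param iv interval data.frame (any number of rows).
#' @return logical vector, one element per interval row.
#' @export
snp_in_interval <- function(snp, iv) {
  idx0 <- snp$pos - 1
  snp$chrom == iv$chrom & iv$start <= idx0 & idx0 < iv$end
}

as_iranges <- function(iv) {
  # internal: 0-based half-open -> IRanges 1-based closed
  IRanges::IRanges(start = iv$start + 1L, end = iv$end)
}

from_iranges <- function(ir, chrom) {
  data.frame(chrom = chrom,
             start = IRanges::start(ir) - 1,
             end = IRanges::end(ir),
             stringsAsFactors = FALSE)
}

#' Merge intervals into a sorted, disjoint set
#'
#' Overlapping and abutting intervals are unioned (consistent with a
#' "non-overlapping DHS" master set). Output is sorted by chromosome then
#' start, covers exactly the same bases as the input, and is idempotent.
#'
#' @param ivs interval data.frame.
#' @return interval data.frame of disjoint intervals.
#' @export
merge_intervals <- function(ivs) {
  validate_intervals(ivs)
  if (nrow(ivs) == 0) return(ivs[, c("chrom", "start", "end")])
  out <- lapply(split(ivs, ivs$chrom), function(part) {
    red <- IRanges::reduce(as_iranges(part))
    from_iranges(red, part$chrom[1])
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

#' Count query intervals overlapping a single region
#'
#' @param ivs interval data.frame (queries).
#' @param region one-row interval data.frame.
#' @return integer count of rows of `ivs` overlapping `region`.
#' @export
count_overlapping <- function(ivs, region) {
  stopifnot(nrow(region) == 1)
  sum(overlaps(ivs, region))
}

#' Normalize chromosome naming
#'
#' @param x character vector of chromosome names.
#' @param style `"keep"` (default), `"chr"` (add prefix), or `"plain"`
#'   (strip prefix).
#' @export
normalize_chrom <- function(x, style = c("keep", "chr", "plain")) {
  style <- match.arg(style)
  switch(style,
         keep = x,
         chr = ifelse(grepl("^chr", x), x, paste0("chr", x)),
         plain = sub("^chr", "", x))
}
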