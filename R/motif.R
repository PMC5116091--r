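BASES <- c("A", "C", "G", "T")

#' Construct a position frequency matrix object
#'
#' @param matrix 4 x w numeric matrix of counts or frequencies, rows
#'   A, C, G, T.
#' @param tf_name transcription factor name.
#' @param id motif identifier.
#' @param pseudocount total pseudocount distributed by background (FIMO
#'   default 0.1).
#' @param background base frequencies (A, C, G, T), must sum to 1; uniform
#'   by default.
#' @return an object of class `pwm`.
#' @export
pwm <- function(matrix, tf_name = "TF", id = tf_name,
                pseudocount = 0.1, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PWM needs 4 rows (A, C, G, T)")
  if (ncol(matrix) < 1) stop("PWM needs width >= 1")
  if (any(matrix < 0)) stop("PWM entries must be non-negative")
  if (any(colSums(matrix) <= 0)) stop("PWM column sums must be positive")
  if (abs(sum(background) - 1) > 1e-8) stop("background must sum to 1")
  rownames(matrix) <- BASES
  structure(list(tf_name = tf_name, id = id, matrix = matrix,
                 pseudocount = pseudocount, background = background),
            class = "pwm")
}

#' Parse JASPAR-format motif files
#'
#' Text dialect: a `>ID NAME` header followed by four rows labelled
#' A/C/G/T with bracketed counts, e.g. `A [ 4 19 0 ]`. Rows may appear in
#' any order; they are normalized to A, C, G, T. Several motifs per file
#' are supported.
#'
#' @param path file path (or a character vector of lines via `text`).
#' @param text optional character vector of lines instead of a file.
#' @inheritParams pwm
#' @return list of [pwm()] objects.
#' @export
parse_jaspar <- function(path = NULL, text = NULL,
                         pseudocount = 0.1, background = rep(0.25, 4)) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("JASPAR parse error: no '>' header found")
  bounds <- c(starts, length(lines) + 1)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    header <- sub("^>", "", lines[starts[k]])
    toks <- strsplit(header, "[ \t]+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else id
    body <- lines[seq(starts[k] + 1, bounds[k + 1] - 1)]
    body <- body[grepl("^[ACGTacgt][ \t]*\\[?", body)]
    if (length(body) != 4)
      stop("JASPAR parse error in motif ", id, ": expected 4 base rows, got ",
           length(body))
    rows <- list()
    for (b in body) {
      base <- toupper(substr(b, 1, 1))
      nums <- gsub("[][]", " ", substr(b, 2, nchar(b)))
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "[ \t]+")[[1]]))
      if (anyNA(vals))
        stop("JASPAR parse error in motif ", id, ": non-numeric counts")
      rows[[base]] <- vals
    }
    if (!setequal(names(rows), BASES))
      stop("JASPAR parse error in motif ", id, ": need rows A, C, G, T")
    widths <- lengths(rows)
    if (length(unique(widths)) != 1)
      stop("JASPAR parse error in motif ", id, ": ragged row widths")
    mat <- do.call(rbind, rows[BASES])
    out[[k]] <- pwm(mat, tf_name = name, id = id,
                    pseudocount = pseudocount, background = background)
  }
  out
}

#' Write motifs in JASPAR text format
#' @param pwms list of [pwm()] objects (or a single one).
#' @param path output path.
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$id, " ", p$tf_name),
      vapply(BASES, function(b)
        paste0(b, " [ ", paste(p$matrix[b, ], collapse = " "), " ]"), ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Log-odds score matrix of a PWM
#'
#' `entry(b, j) = log2( freq(b, j) / bg(b) )` where
#' `freq(b, j) = (count(b, j) + pc * bg(b)) / sum_b'(count(b', j) + pc * bg(b'))`
#' (pseudocount distributed by background, the FIMO model). Scores are in
#' bits.
#'
#' @param pwm a [pwm()] object.
#' @return 4 x w numeric matrix.
#' @export
log_odds <- function(pwm) {
  m <- pwm$matrix
  adj <- m + pwm$pseudocount * pwm$background
  freq <- sweep(adj, 2, colSums(adj), "/")
  log2(freq / pwm$background)
}

#' Discretized scoring model for a PWM
#'
#' The log-odds matrix is rounded to integer multiples of a granularity
#' `g = score range / bins` (FIMO-style discretization; `bins = 1000` by
#' default, so g is 1/1000 of the total score range). The exact null score
#' distribution under the background model is obtained by dynamic
#' programming (column-wise convolution over the integer score support) and
#' stored as an upper-tail table.
#'
#' @param pwm a [pwm()] object.
#' @param bins number of discretization bins across the score range.
#' @return list with `lo` (exact log-odds), `ints` (integer score matrix),
#'   `g` (granularity, bits), `base` (minimum achievable integer total),
#'   `p_ge` (p_ge\[k\] = P(integer total >= base + k - 1)), `max_total`.
#' @export
pwm_scoring <- function(pwm, bins = 1000) {
  lo <- log_odds(pwm)
  col_min <- apply(lo, 2, min)
  col_max <- apply(lo, 2, max)
  range <- sum(col_max - col_min)
  g <- if (range > 0) range / bins else 1
  ints <- round(lo / g)
  base <- sum(apply(ints, 2, min))
  span <- sum(apply(ints, 2, max)) - base
  # DP over shifted integer scores 0..span
  p <- c(1, numeric(span))
  bg <- pwm$background
  for (j in seq_len(ncol(ints))) {
    off <- ints[, j] - min(ints[, j])
    newp <- numeric(span + 1)
    for (b in 1:4) {
      if (off[b] == 0) {
        newp <- newp + bg[b] * p
      } else {
        idx <- seq_len(span + 1 - off[b])
        newp[idx + off[b]] <- newp[idx + off[b]] + bg[b] * p[idx]
      }
    }
    p <- newp
  }
  p_ge <- rev(cumsum(rev(p)))
  list(lo = lo, ints = ints, g = g, base = base, p_ge = p_ge,
       max_total = base + span, bins = bins)
}

#' Exact PWM score p-value
#'
#' Tail probability that a random background window scores at least
#' `score`, computed on the integer-discretized score distribution. Scores
#' at or below the minimum achievable score give p = 1.
#'
#' @param pwm a [pwm()] object.
#' @param score log-odds score in bits.
#' @param scoring optional precomputed [pwm_scoring()] object.
#' @param bins discretization bins (used if `scoring` is NULL).
#' @return p-value.
#' @export
score_pvalue <- function(pwm, score, scoring = NULL, bins = 1000) {
  if (is.null(scoring)) scoring <- pwm_scoring(pwm, bins)
  si <- as.integer(floor(score / scoring$g + 0.5 + 1e-9))
  int_pvalue(scoring, si)
}

int_pvalue <- function(scoring, si) {
  k <- si - scoring$base + 1L
  k <- pmin(pmax(k, 1L), length(scoring$p_ge) + 1L)
  ifelse(k > length(scoring$p_ge), 0, scoring$p_ge[k])
}

seq_codes <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  match(chars, BASES)  # N and anything else -> NA
}

window_int_scores <- function(codes, ints) {
  w <- ncol(ints)
  n_win <- length(codes) - w + 1
  if (n_win < 1) return(integer(0))
  sc <- numeric(n_win)
  i <- seq_len(n_win)
  for (j in seq_len(w)) sc <- sc + ints[cbind(codes[i + j - 1], j)]
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Every width-w window is scored on the plus strand and as its reverse
#' complement (minus strand); windows containing N are skipped. Hits with
#' p strictly below the threshold are returned sorted by position. Reported
#' scores are on the discretized scale (integer score times granularity, in
#' bits), as in FIMO.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param pwm a [pwm()] object.
#' @param p_threshold strict upper bound on p (default 1e-4).
#' @param chrom,offset0 coordinates of the first base of `seq` (0-based),
#'   used to report hit intervals.
#' @param scoring optional precomputed [pwm_scoring()].
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `score`, `p_value`.
#' @export
scan_sequence <- function(seq, pwm, p_threshold = 1e-4,
                          chrom = "seq", offset0 = 0, scoring = NULL) {
  if (is.null(scoring)) scoring <- pwm_scoring(pwm)
  w <- ncol(scoring$ints)
  codes <- seq_codes(seq)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (length(codes) < w) return(empty)
  rc_ints <- scoring$ints[4:1, rev(seq_len(w)), drop = FALSE]
  res <- list()
  for (strand in c("+", "-")) {
    m <- if (strand == "+") scoring$ints else rc_ints
    sc <- window_int_scores(codes, m)
    ok <- which(!is.na(sc))
    if (!length(ok)) next
    p <- int_pvalue(scoring, sc[ok])
    keep <- p < p_threshold
    if (!any(keep)) next
    i <- ok[keep]
    res[[strand]] <- data.frame(
      chrom = chrom, start = offset0 + i - 1, end = offset0 + i - 1 + w,
      strand = strand, score = sc[i] * scoring$g, p_value = p[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allele-aware motif scan at a SNP
#'
#' Both alleles of the SNP are substituted into the reference flanking
#' sequence and scanned; only windows overlapping the SNP position are
#' compared, so flanking hits unaffected by the SNP cannot masquerade as
#' gain or loss. Classification at the p-threshold: `gain` = hit on alt
#' only, `loss` = hit on ref only, `retained` = both, `absent` = neither.
#'
#' @param seq_ref reference DNA around the SNP; must extend >= w - 1 bp on
#'   each side of the SNP.
#' @param snp one-row SNP data.frame (`id`, `chrom`, `pos`, `ref`, `alt`).
#' @param seq_start1 1-based genomic position of the first base of
#'   `seq_ref`.
#' @param pwm a [pwm()] object.
#' @param p_threshold strict hit threshold (default 1e-4).
#' @return list with `snp_id`, `tf_name`, `classification`, `best_ref`,
#'   `best_alt` (one-row hit data.frames or NULL), `hits_ref`, `hits_alt`.
#' @export
allele_scan <- function(seq_ref, snp, seq_start1 = 1, pwm, p_threshold = 1e-4) {
  scoring <- pwm_scoring(pwm)
  w <- ncol(scoring$ints)
  n <- nchar(seq_ref)
  idx <- snp$pos - seq_start1 + 1
  if (idx < 1 || idx > n) stop("SNP position falls outside the sequence")
  if (idx - 1 < w - 1 || n - idx < w - 1)
    stop("sequence must extend >= w - 1 bp on each side of the SNP")
  have <- toupper(substr(seq_ref, idx, idx))
  if (have != snp$ref)
    stop("reference sequence has ", have, " at the SNP, expected ", snp$ref)
  seq_alt <- seq_ref
  substr(seq_alt, idx, idx) <- snp$alt
  snp_windows <- function(hits) {
    # window [start+1, end] (1-based, seq coords) must cover idx
    hits[hits$start + 1 <= idx & idx <= hits$end, , drop = FALSE]
  }
  hits_ref <- snp_windows(scan_sequence(seq_ref, pwm, p_threshold,
                                        scoring = scoring))
  hits_alt <- snp_windows(scan_sequence(seq_alt, pwm, p_threshold,
                                        scoring = scoring))
  best <- function(h) if (nrow(h) == 0) NULL else h[which.max(h$score), ]
  cls <- if (nrow(hits_ref) > 0 && nrow(hits_alt) > 0) "retained"
         else if (nrow(hits_ref) > 0) "loss"
         else if (nrow(hits_alt) > 0) "gain"
         else "absent"
  list(snp_id = snp$id, tf_name = pwm$tf_name, classification = cls,
       best_ref = best(hits_ref), best_alt = best(hits_alt),
       hits_ref = hits_ref, hits_alt = hits_alt,
       p_threshold = p_threshold, granularity = scoring$g)
}

#' Reverse complement of a DNA string
#' @param seq DNA string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
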