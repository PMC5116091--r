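#' Read a BED3/BED5 peak track
#'
#' Tab-delimited, no header; columns beyond 5 are ignored. BED coordinates
#' are already 0-based half-open so no conversion is applied. The score
#' (column 5) defaults to 0 when absent.
#'
#' @param path file path.
#' @param source_track label recorded on every record (defaults to the file
#'   base name).
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `source_track`, preserving input order.
#' @export
read_bed <- function(path, source_track = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      source_track = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  bad <- which(n_col < 3)
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": fewer than 3 columns")
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": non-numeric coordinates")
  bad <- which(ends <= starts | starts < 0)
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": requires 0 <= start < end")
  name <- ifelse(n_col >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), ".")
  score <- rep(0, length(lines))
  has5 <- n_col >= 5
  if (any(has5)) {
    sc <- suppressWarnings(as.numeric(vapply(fields[has5], `[`, "", 5L)))
    if (anyNA(sc))
      stop("BED parse error at line ", which(has5)[which(is.na(sc))[1]],
           ": non-numeric score")
    score[has5] <- sc
  }
  data.frame(chrom = vapply(fields, `[`, "", 1L), start = starts, end = ends,
             name = name, score = score, source_track = source_track,
             stringsAsFactors = FALSE)
}

#' Write peaks as BED5
#' @param peaks data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`.
#' @param path output path.
#' @export
write_bed <- function(peaks, path) {
  name <- if ("name" %in% names(peaks)) peaks$name else rep(".", nrow(peaks))
  score <- if ("score" %in% names(peaks)) peaks$score else rep(0, nrow(peaks))
  df <- data.frame(peaks$chrom, format_coord(peaks$start), format_coord(peaks$end),
                   name, score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a SNP table
#'
#' TSV with header columns `id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `is_lead`, and optionally `locus` (lead-SNP locus label) and `lead_id`.
#'
#' @param path file path.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt", "is_lead")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SNP table missing columns: ", paste(miss, collapse = ", "))
  df$is_lead <- as.logical(df$is_lead)
  validate_snps(df)
  df
}

validate_snps <- function(snps) {
  bases <- c("A", "C", "G", "T")
  if (any(!snps$ref %in% bases) || any(!snps$alt %in% bases))
    stop("SNP alleles must be single bases A/C/G/T")
  if (any(snps$ref == snps$alt)) stop("ref and alt alleles must differ")
  if (any(snps$pos < 1)) stop("SNP positions are 1-based and must be >= 1")
  invisible(snps)
}

#' @rdname read_snp_table
#' @param snps SNP data.frame.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read single-end read records from a BED6-like TSV
#'
#' Columns chrom, start (0-based), end, name, score, strand; `length` is
#' derived as `end - start`.
#'
#' @param path file path.
#' @export
read_reads_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("read table needs 6 columns (BED6-like)")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be + or -")
  out <- data.frame(chrom = df$chrom, start = df$start, strand = df$strand,
                    length = df$end - df$start, stringsAsFactors = FALSE)
  if (any(out$length <= 0)) stop("read length must be > 0")
  out
}

#' @rdname read_reads_tsv
#' @param reads data.frame with `chrom`, `start`, `strand`, `length`.
#' @export
write_reads_tsv <- function(reads, path) {
  df <- data.frame(reads$chrom, format_coord(reads$start),
                   format_coord(reads$start + reads$length),
                   ".", 0, reads$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' FASTA / FASTQ sequence IO
#'
#' Thin wrappers over Biostrings returning plain named character vectors.
#'
#' @param path file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fastq <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  invisible(path)
}

#' Write an R object as JSON
#' @param x object (lists/vectors).
#' @param path output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
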