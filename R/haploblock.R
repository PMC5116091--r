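#' Linkage disequilibrium r-squared between two dosage vectors
#'
#' r^2 is the squared Pearson correlation of unphased 0/1/2 dosages, the
#' standard surrogate when phase is unavailable. Missing entries are removed
#' by pairwise-complete deletion; at least two complete pairs are required.
#'
#' @param x,y numeric dosage vectors in \{0, 1, 2, NA\}.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("dosage vectors must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need >= 2 complete dosage pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined LD: a dosage vector is constant after deletion")
  stats::cor(x, y)^2
}

#' All lead-vs-candidate LD pairs from a genotype matrix
#'
#' @param geno numeric matrix, SNPs in rows (rownames = SNP ids),
#'   individuals in columns; entries 0/1/2 or NA.
#' @param lead_ids SNP ids to use as the `snp_a` side; defaults to all SNPs
#'   (upper triangle of all pairs).
#' @return data.frame `snp_a`, `snp_b`, `r2`. Pairs where LD is undefined
#'   (constant dosages) are omitted.
#' @export
compute_ld_table <- function(geno, lead_ids = NULL) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)))
  ids <- rownames(geno)
  if (is.null(lead_ids)) {
    pairs <- utils::combn(ids, 2)
    a <- pairs[1, ]; b <- pairs[2, ]
  } else {
    stopifnot(all(lead_ids %in% ids))
    grid <- expand.grid(a = lead_ids, b = ids, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, ]
    a <- grid$a; b <- grid$b
  }
  r2 <- mapply(function(i, j) {
    tryCatch(ld_r2(geno[i, ], geno[j, ]), error = function(e) NA_real_)
  }, a, b)
  out <- data.frame(snp_a = a, snp_b = b, r2 = r2, stringsAsFactors = FALSE)
  out[!is.na(out$r2), , drop = FALSE]
}

ld_lookup <- function(ld, a, b) {
  # symmetric lookup; a missing pair is treated as r2 = 0
  hit <- (ld$snp_a == a & ld$snp_b == b) | (ld$snp_a == b & ld$snp_b == a)
  if (!any(hit)) return(0)
  max(ld$r2[hit])
}

#' Expand a lead SNP into its haploblock by LD
#'
#' Members are the lead plus every candidate with r^2 strictly above the
#' threshold (tight linkage, r^2 > 0.8 by default). Candidate order does not
#' affect the result.
#'
#' @param lead one-row SNP data.frame (the lead SNP).
#' @param candidates SNP data.frame of candidates.
#' @param ld LD table (`snp_a`, `snp_b`, `r2`); missing pairs count as 0.
#' @param threshold strict lower bound on r^2 (default 0.8).
#' @return list with `lead`, `members` (SNP data.frame including the lead,
#'   ordered by position), `r2_threshold`.
#' @export
expand_haploblock <- function(lead, candidates, ld, threshold = 0.8) {
  stopifnot(nrow(lead) == 1)
  candidates <- candidates[candidates$id != lead$id, , drop = FALSE]
  # vectorized symmetric lookup; missing pairs count as r2 = 0
  fwd <- paste(ld$snp_a, ld$snp_b, sep = "\r")
  rev <- paste(ld$snp_b, ld$snp_a, sep = "\r")
  want <- paste(lead$id, candidates$id, sep = "\r")
  r2 <- pmax(ld$r2[match(want, fwd)], ld$r2[match(want, rev)], 0,
             na.rm = TRUE)
  members <- rbind(lead, candidates[r2 > threshold, , drop = FALSE])
  members <- members[order(members$pos), , drop = FALSE]
  rownames(members) <- NULL
  list(lead = lead, members = members, r2_threshold = threshold)
}

#' Define an analysis locus from SNP extremes
#'
#' The locus interval spans the outermost member SNPs extended by `flank` bp
#' at each end (10 kb by default), i.e. 1-based inclusive
#' `[min(pos) - flank, max(pos) + flank]`, clipped at base 1. Width is
#' reported in bp (inclusive reckoning) and rounded kb.
#'
#' @param snps SNP data.frame (single chromosome, >= 1 row).
#' @param flank extension in bp at each end.
#' @param name locus label.
#' @return list with `name`, `interval` (internal 0-based half-open),
#'   `first`, `last` (printed 1-based inclusive bounds), `width_bp`,
#'   `width_kb`, `member_snps`, `flank`.
#' @export
define_locus <- function(snps, flank = 10000, name = "locus") {
  if (nrow(snps) == 0) stop("cannot define a locus from zero SNPs")
  chroms <- unique(snps$chrom)
  if (length(chroms) > 1)
    stop("SNPs span multiple chromosomes: ", paste(chroms, collapse = ", "))
  first <- max(1, min(snps$pos) - flank)
  last <- max(snps$pos) + flank
  iv <- iv_from_printed(chroms, first, last)
  list(name = name, interval = iv, first = first, last = last,
       width_bp = last - first + 1, width_kb = round((last - first + 1) / 1000),
       member_snps = snps, flank = flank)
}

#' Summarise a compiled GWAS SNP table
#'
#' Reproduces the headline counts of a lead+linked SNP compilation: total
#' SNPs, number of lead SNPs, number of loci (distinct locus labels of lead
#' SNPs -- the locus assignment is read from the table, not re-derived),
#' lead SNPs falling in a target region, and the size of the target-region
#' haploblock obtained by expanding every lead in the region through the LD
#' table and taking the union.
#'
#' @param snps SNP data.frame with `is_lead` and `locus` columns.
#' @param ld LD table.
#' @param region one-row interval data.frame (target region), or NULL to
#'   skip region-specific counts.
#' @param threshold r^2 threshold for haploblock expansion.
#' @return list of counts.
#' @export
summarise_snp_compilation <- function(snps, ld, region = NULL, threshold = 0.8) {
  leads <- snps[snps$is_lead, , drop = FALSE]
  out <- list(n_snps = nrow(snps), n_lead = nrow(leads),
              n_loci = length(unique(leads$locus)))
  if (!is.null(region)) {
    stopifnot(nrow(region) == 1)
    lead_in <- leads$chrom == region$chrom &
      region$start <= leads$pos - 1 & leads$pos - 1 < region$end
    region_leads <- leads[lead_in, , drop = FALSE]
    member_ids <- character()
    for (i in seq_len(nrow(region_leads))) {
      hb <- expand_haploblock(region_leads[i, ], snps, ld, threshold)
      member_ids <- union(member_ids, hb$members$id)
    }
    out$n_lead_in_region <- nrow(region_leads)
    out$n_block_members <- length(member_ids)
    out$block_member_ids <- member_ids
  }
  out
}
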