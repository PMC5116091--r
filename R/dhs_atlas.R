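#' Merge replicate DHS tracks for one cell type
#'
#' The union of peak intervals across replicate tracks is reduced to
#' non-overlapping regions; each merged region carries the score of its
#' "master" peak, the highest peak height/z-score among the contributing
#' peaks.
#'
#' @param tracks a single peak data.frame or a list of them (columns
#'   `chrom`, `start`, `end`, `score`).
#' @param cell_type label stored on the output.
#' @return data.frame of disjoint peaks (`chrom`, `start`, `end`, `score`,
#'   `cell_type`), sorted.
#' @export
merge_cell_type <- function(tracks, cell_type = "cell_type") {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  if (length(tracks) < 1) stop("need at least one track")
  all_peaks <- do.call(rbind, lapply(tracks, function(t)
    t[, c("chrom", "start", "end", "score")]))
  merged <- merge_intervals(all_peaks)
  if (nrow(merged) == 0) {
    merged$score <- numeric()
    merged$cell_type <- character()
    return(merged)
  }
  score <- vapply(seq_len(nrow(merged)), function(i) {
    hit <- overlaps(all_peaks, merged[i, ])
    max(all_peaks$score[hit])
  }, 0)
  merged$score <- score
  merged$cell_type <- cell_type
  merged
}

#' Number of merged DHS overlapping a locus
#'
#' A peak straddling the locus boundary counts once (overlap suffices).
#'
#' @param locus locus list from [define_locus()] (or a one-row interval
#'   data.frame).
#' @param merged merged peak data.frame.
#' @export
count_dhs <- function(locus, merged) {
  region <- locus_interval(locus)
  count_overlapping(merged, region)
}

locus_interval <- function(locus) {
  if (is.data.frame(locus)) locus else locus$interval
}

#' Unique DHS in a locus across all cell types
#'
#' The merged union, across cell types, of peaks overlapping the locus;
#' identical peaks in several cell types are counted once.
#'
#' @param all_merged list of merged peak data.frames.
#' @param locus locus (as in [count_dhs()]).
#' @export
unique_locus_dhs <- function(all_merged, locus) {
  region <- locus_interval(locus)
  in_locus <- lapply(all_merged, function(m)
    m[overlaps(m, region), c("chrom", "start", "end"), drop = FALSE])
  pooled <- do.call(rbind, in_locus)
  if (is.null(pooled) || nrow(pooled) == 0) return(0L)
  nrow(merge_intervals(pooled))
}

#' SNP / DHS overlap for one cell type
#'
#' @param snps SNP data.frame (haploblock members).
#' @param merged merged peak data.frame for one cell type.
#' @return list: `snp_flags` (logical per SNP: inside >= 1 merged DHS),
#'   `n_snps_in_dhs`, and `n_dhs_with_snp` (number of distinct merged DHS
#'   containing >= 1 SNP -- two SNPs in one peak contribute one DHS).
#' @export
snp_overlap <- function(snps, merged) {
  if (nrow(merged) == 0 || nrow(snps) == 0) {
    return(list(snp_flags = stats::setNames(rep(FALSE, nrow(snps)), snps$id),
                n_snps_in_dhs = 0L, n_dhs_with_snp = 0L))
  }
  hit_mat <- vapply(seq_len(nrow(snps)), function(i)
    snp_in_interval(snps[i, ], merged), logical(nrow(merged)))
  hit_mat <- matrix(hit_mat, nrow = nrow(merged))
  flags <- stats::setNames(colSums(hit_mat) > 0, snps$id)
  list(snp_flags = flags,
       n_snps_in_dhs = sum(flags),
       n_dhs_with_snp = sum(rowSums(hit_mat) > 0))
}

#' DHS count table: cell types x loci
#'
#' @param merged_by_celltype named list of merged peak data.frames.
#' @param loci named list of loci.
#' @return integer matrix, rows = cell types, columns = loci.
#' @export
dhs_count_table <- function(merged_by_celltype, loci) {
  if (is.null(names(loci))) names(loci) <- vapply(loci, `[[`, "", "name")
  out <- vapply(loci, function(loc)
    vapply(merged_by_celltype, function(m) count_dhs(loc, m), 0L),
    integer(length(merged_by_celltype)))
  out <- matrix(out, nrow = length(merged_by_celltype),
                dimnames = list(names(merged_by_celltype), names(loci)))
  out
}

#' Rank cell types by DHS count in a locus
#'
#' Descending by count; ties broken lexicographically by cell-type name for
#' determinism.
#'
#' @param counts named integer vector (per cell type), or a count matrix
#'   plus `locus` column name.
#' @param locus column to rank when `counts` is a matrix.
#' @return character vector of cell-type names, best first.
#' @export
rank_cell_types <- function(counts, locus = NULL) {
  if (is.matrix(counts)) {
    stopifnot(!is.null(locus))
    counts <- counts[, locus]
  }
  names(counts)[order(-counts, names(counts))]
}

#' Immune vs non-immune DHS enrichment
#'
#' Equal-variance two-sample Student t-test (two-tailed) on per-cell-type
#' DHS counts, immune vs non-immune, with Bonferroni correction across the
#' loci tested.
#'
#' @param counts named numeric vector of per-cell-type DHS counts in one
#'   locus.
#' @param categories named character vector mapping cell type ->
#'   "immune"/"non-immune" (other categories ignored).
#' @param n_tests number of loci tested (Bonferroni multiplier), default 1.
#' @return list with `t_statistic`, `p_value`, `p_bonferroni`,
#'   `group_means`, `immune_ratio` (Inf flag when the non-immune mean is 0),
#'   `n` per group.
#' @export
immune_enrichment <- function(counts, categories, n_tests = 1) {
  imm <- counts[names(counts) %in% names(categories)[categories == "immune"]]
  non <- counts[names(counts) %in% names(categories)[categories == "non-immune"]]
  if (length(imm) < 2 || length(non) < 2)
    stop("need >= 2 cell types in each of immune and non-immune")
  if (stats::sd(imm) == 0 && stats::sd(non) == 0 && mean(imm) == mean(non)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(imm, non, var.equal = TRUE)
  }
  ratio <- if (mean(non) == 0) Inf else mean(imm) / mean(non)
  list(t_statistic = unname(tt$statistic),
       p_value = tt$p.value,
       p_bonferroni = min(1, tt$p.value * n_tests),
       group_means = c(immune = mean(imm), non_immune = mean(non)),
       immune_ratio = ratio,
       n = c(immune = length(imm), non_immune = length(non)))
}
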