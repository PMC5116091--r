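#' Seeded execution helper
#'
#' Runs an expression under a temporary RNG seed, restoring the caller's
#' RNG state afterwards; with `seed = NULL` the current RNG stream is used.
#' All generators route their randomness through this, so a fixed seed
#' gives bit-identical output.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Cohort specification
#'
#' Defaults mirror the expression cohort: 34 donors split 9 TT (risk
#' homozygote), 16 TC, 9 CC (non-risk homozygote) at the index SNP.
#'
#' @param n_tt,n_tc,n_cc genotype group sizes.
#' @param index_snp index SNP id.
#' @export
cohort_spec <- function(n_tt = 9, n_tc = 16, n_cc = 9,
                        index_snp = "rs7216389") {
  list(n_donors = n_tt + n_tc + n_cc, n_tt = n_tt, n_tc = n_tc, n_cc = n_cc,
       index_snp = index_snp)
}

#' Deterministic donor genotype labels for a cohort
#' @param spec a [cohort_spec()].
#' @return named character vector donor id -> "TT"/"TC"/"CC".
#' @export
cohort_genotypes <- function(spec) {
  g <- c(rep("TT", spec$n_tt), rep("TC", spec$n_tc), rep("CC", spec$n_cc))
  stats::setNames(g, sprintf("donor%02d", seq_along(g)))
}

#' Effect-size specification for the synthetic cohort
#'
#' Defaults are the stated observations: ~3-fold expression increase
#' (TT vs CC), ~1.44-fold H3K27ac increase, cross-cell-type Spearman target
#' 0.74 and gene-gene Spearman target 0.63. The second gene's genotype fold
#' (not printed) is set to 2.0. Noise is lognormal with per-assay sigma on
#' the natural-log scale.
#'
#' @param expression_fold TT/CC fold for the primary gene.
#' @param gene2_fold TT/CC fold for the second gene.
#' @param h3k27ac_fold risk/non-risk fold for the enhancer mark.
#' @param spearman_celltype target rank correlation of one gene across two
#'   cell types.
#' @param spearman_gene target rank correlation of the two genes within a
#'   cell type.
#' @param sigma_expression,sigma_chip lognormal noise sd per assay.
#' @export
effect_spec <- function(expression_fold = 3.0, gene2_fold = 2.0,
                        h3k27ac_fold = 1.44,
                        spearman_celltype = 0.74, spearman_gene = 0.63,
                        sigma_expression = 0.4, sigma_chip = 0.3) {
  stopifnot(expression_fold > 0, gene2_fold > 0, h3k27ac_fold > 0,
            abs(spearman_celltype) <= 1, abs(spearman_gene) <= 1)
  list(expression_fold = expression_fold, gene2_fold = gene2_fold,
       h3k27ac_fold = h3k27ac_fold, spearman_celltype = spearman_celltype,
       spearman_gene = spearman_gene, sigma_expression = sigma_expression,
       sigma_chip = sigma_chip)
}

#' Synthetic genotype matrix with haploblock structure
#'
#' Individuals are drawn as pairs of haplotypes from a two-haplotype pool:
#' block SNPs carry the alternate allele on the risk haplotype (so SNPs on
#' the same background have population r^2 = 1, attenuated to (1-2e)^2 by a
#' per-SNP copying-error probability e), while off-block SNPs assort
#' independently at their minor-allele frequency.
#'
#' @param n_ind number of individuals.
#' @param n_block number of haploblock SNPs (the first is the index SNP).
#' @param n_offblock number of independent SNPs.
#' @param risk_hap_freq frequency of the risk haplotype.
#' @param flip_prob per-haplotype copying-error probability for block SNPs
#'   (scalar or vector of length `n_block`).
#' @param maf minor-allele frequency of off-block SNPs.
#' @param seed RNG seed.
#' @return list: `geno` (SNP x individual dosage matrix), `truth`
#'   (data.frame id, in_block, expected_r2 vs the index SNP), `risk_dosage`
#'   (per individual).
#' @export
gen_genotypes <- function(n_ind = 34, n_block = 10, n_offblock = 10,
                          risk_hap_freq = 0.5, flip_prob = 0, maf = 0.3,
                          seed = NULL) {
  with_seed(seed, {
    flip <- rep_len(flip_prob, n_block)
    hap1 <- stats::rbinom(n_ind, 1, risk_hap_freq)
    hap2 <- stats::rbinom(n_ind, 1, risk_hap_freq)
    block <- matrix(0L, n_block, n_ind)
    for (s in seq_len(n_block)) {
      a1 <- ifelse(stats::runif(n_ind) < flip[s], 1L - hap1, hap1)
      a2 <- ifelse(stats::runif(n_ind) < flip[s], 1L - hap2, hap2)
      block[s, ] <- a1 + a2
    }
    off <- matrix(stats::rbinom(n_offblock * n_ind, 2, maf), n_offblock, n_ind)
    geno <- rbind(block, off)
    ids <- c(sprintf("blk%03d", seq_len(n_block)),
             sprintf("off%03d", seq_len(n_offblock)))
    rownames(geno) <- ids
    colnames(geno) <- sprintf("ind%03d", seq_len(n_ind))
    truth <- data.frame(
      id = ids,
      in_block = rep(c(TRUE, FALSE), c(n_block, n_offblock)),
      expected_r2 = c((1 - 2 * flip)^2 * (1 - 2 * flip[1])^2,
                      rep(0, n_offblock)),
      stringsAsFactors = FALSE)
    list(geno = geno, truth = truth, risk_dosage = hap1 + hap2)
  })
}

#' Synthetic compiled GWAS SNP table (stand-in for an unpublished table)
#'
#' Builds a lead+linked SNP compilation with stated marginals: `n_total`
#' SNPs, `n_lead` leads over `n_loci` locus labels, of which
#' `n_lead_target` leads and `n_block_target` total members sit in a target
#' haploblock whose SNP extremes are `target_first` / `target_last`.
#' An accompanying LD table links every non-lead member to a lead of its
#' locus with r^2 above the threshold. This is a synthetic stand-in with
#' the published marginal counts, used to exercise parsing, LD expansion
#' and counting; it is not the real compilation.
#'
#' @param n_total,n_lead,n_loci,n_lead_target,n_block_target marginals.
#' @param target_chrom,target_first,target_last the target block's
#'   chromosome and outermost SNP positions.
#' @param seed RNG seed.
#' @return list: `snps` (SNP table with `locus` and `lead_id`), `ld`
#'   (LD table), `target_locus_label`.
#' @export
gen_snp_table <- function(n_total = 3502, n_lead = 96, n_loci = 75,
                          n_lead_target = 6, n_block_target = 136,
                          target_chrom = "chr17",
                          target_first = 37909254, target_last = 38129253,
                          seed = NULL) {
  stopifnot(n_lead_target <= n_lead, n_block_target <= n_total,
            n_loci <= n_lead - n_lead_target + 1)
  with_seed(seed, {
    rand_alleles <- function(n) {
      ref <- sample(BASES, n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")
      list(ref = ref, alt = unname(alt))
    }
    # target block: n_lead_target leads + linked members on target_chrom
    n_members <- n_block_target
    pos <- sort(c(target_first, target_last,
                  sample(seq(target_first + 1, target_last - 1),
                         n_members - 2)))
    is_lead_t <- rep(FALSE, n_members)
    is_lead_t[sample(n_members, n_lead_target)] <- TRUE
    al <- rand_alleles(n_members)
    target <- data.frame(
      id = sprintf("rs17q%04d", seq_len(n_members)),
      chrom = target_chrom, pos = pos, ref = al$ref, alt = al$alt,
      is_lead = is_lead_t, locus = "17q21",
      stringsAsFactors = FALSE)
    # remaining leads over the remaining loci
    n_lead_rest <- n_lead - n_lead_target
    n_loci_rest <- n_loci - 1
    locus_of_lead <- sort(c(seq_len(n_loci_rest),
                            sample(n_loci_rest, n_lead_rest - n_loci_rest,
                                   replace = TRUE)))
    n_rest <- n_total - n_members
    n_linked_rest <- n_rest - n_lead_rest
    # spread linked SNPs over the rest leads
    owner <- sort(sample(n_lead_rest, n_linked_rest, replace = TRUE))
    lead_chrom <- paste0("chr", sample(c(1:16, 18:22), n_lead_rest,
                                       replace = TRUE))
    lead_pos <- sample(1e6:2e8, n_lead_rest)
    al_l <- rand_alleles(n_lead_rest)
    leads_rest <- data.frame(
      id = sprintf("rsL%04d", seq_len(n_lead_rest)),
      chrom = lead_chrom, pos = lead_pos, ref = al_l$ref, alt = al_l$alt,
      is_lead = TRUE, locus = sprintf("locus%02d", locus_of_lead),
      stringsAsFactors = FALSE)
    al_k <- rand_alleles(n_linked_rest)
    linked_rest <- data.frame(
      id = sprintf("rsK%05d", seq_len(n_linked_rest)),
      chrom = lead_chrom[owner],
      pos = lead_pos[owner] + sample(1:50000, n_linked_rest, replace = TRUE),
      ref = al_k$ref, alt = al_k$alt,
      is_lead = FALSE, locus = leads_rest$locus[owner],
      stringsAsFactors = FALSE)
    snps <- rbind(target, leads_rest, linked_rest)
    rownames(snps) <- NULL
    # LD table: every non-lead member linked to one lead of its block
    t_leads <- target$id[target$is_lead]
    t_nonlead <- target$id[!target$is_lead]
    ld_target <- data.frame(
      snp_a = sample(t_leads, length(t_nonlead), replace = TRUE),
      snp_b = t_nonlead,
      r2 = stats::runif(length(t_nonlead), 0.85, 0.999),
      stringsAsFactors = FALSE)
    lead_pairs <- utils::combn(t_leads, 2)
    ld_leads <- data.frame(snp_a = lead_pairs[1, ], snp_b = lead_pairs[2, ],
                           r2 = stats::runif(ncol(lead_pairs), 0.85, 0.999),
                           stringsAsFactors = FALSE)
    ld_rest <- data.frame(
      snp_a = leads_rest$id[owner], snp_b = linked_rest$id,
      r2 = stats::runif(n_linked_rest, 0.805, 0.999),
      stringsAsFactors = FALSE)
    ld <- rbind(ld_target, ld_leads, ld_rest)
    list(snps = snps, ld = ld, target_locus_label = "17q21")
  })
}

#' Synthetic DHS tracks per cell type
#'
#' Per cell type, a Poisson number of peaks at its category rate is placed
#' uniformly in the locus (widths 150-400 bp, positive scores); replicate
#' tracks are jittered copies of the cell type's peak set. Designated SNPs
#' are guaranteed a containing peak in the listed cell types.
#'
#' @param cell_types data.frame with `name` and `category` ("immune" /
#'   "non-immune" / "fetal" / "cell-line").
#' @param locus locus list from [define_locus()] (or one-row interval df).
#' @param rate_immune,rate_nonimmune Poisson peak rates per category
#'   (non-immune rate also used for other categories).
#' @param n_replicates replicate tracks per cell type.
#' @param snp_targets optional data.frame `cell_type`, `snp_id`, `pos`
#'   listing SNPs that must be covered by a peak in that cell type.
#' @param seed RNG seed.
#' @return list: `tracks` (named list of lists of replicate peak
#'   data.frames), `truth` (per cell type peak count; snp placements).
#' @export
gen_dhs_tracks <- function(cell_types, locus, rate_immune = 60,
                           rate_nonimmune = 15, n_replicates = 2,
                           snp_targets = NULL, seed = NULL) {
  stopifnot(rate_immune >= 0, rate_nonimmune >= 0)
  region <- locus_interval(locus)
  with_seed(seed, {
    tracks <- list()
    n_peaks <- integer(nrow(cell_types))
    for (i in seq_len(nrow(cell_types))) {
      ct <- cell_types$name[i]
      rate <- if (cell_types$category[i] == "immune") rate_immune
              else rate_nonimmune
      n <- stats::rpois(1, rate)
      width <- if (n > 0) round(stats::runif(n, 150, 400)) else numeric(0)
      start <- if (n > 0)
        round(stats::runif(n, region$start, region$end - width)) else numeric(0)
      peaks <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), score = numeric(0))
      if (n > 0)
        peaks <- data.frame(chrom = region$chrom, start = start,
                            end = start + width,
                            score = round(abs(stats::rnorm(n, 5, 2)), 2) + 0.1,
                            stringsAsFactors = FALSE)
      if (!is.null(snp_targets)) {
        tgt <- snp_targets[snp_targets$cell_type == ct, , drop = FALSE]
        for (k in seq_len(nrow(tgt))) {
          c0 <- tgt$pos[k] - 1
          w <- round(stats::runif(1, 150, 400))
          off <- sample.int(w, 1) - 1
          peaks <- rbind(peaks, data.frame(
            chrom = region$chrom, start = c0 - off, end = c0 - off + w,
            score = round(abs(stats::rnorm(1, 5, 2)), 2) + 0.1,
            stringsAsFactors = FALSE))
        }
      }
      n_peaks[i] <- nrow(peaks)
      reps <- lapply(seq_len(n_replicates), function(r) {
        if (nrow(peaks) == 0) return(peaks)
        jit <- round(stats::rnorm(nrow(peaks), 0, 10))
        out <- peaks
        out$start <- pmax(region$start, peaks$start + jit)
        out$end <- pmax(out$start + 1, peaks$end + jit)
        out
      })
      tracks[[ct]] <- reps
    }
    list(tracks = tracks,
         truth = list(n_peaks = stats::setNames(n_peaks, cell_types$name),
                      snp_targets = snp_targets))
  })
}

spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' Calibrate the latent-variable loadings of the expression generator
#' @noRd
calibrate_expression <- function(effects, genotype_x) {
  vx <- stats::var(genotype_x) * (length(genotype_x) - 1) / length(genotype_x)
  f1 <- log(effects$expression_fold)
  f2 <- log(effects$gene2_fold)
  s2 <- effects$sigma_expression^2
  r_same <- spearman_to_pearson(effects$spearman_celltype)
  r_cross <- spearman_to_pearson(effects$spearman_gene)
  total_var <- s2 / (1 - r_same)
  a2 <- max(0, r_cross * total_var - f1 * f2 * vx)
  h2 <- pmax(0, total_var - c(f1, f2)^2 * vx - a2 - s2)
  list(a = sqrt(a2), h = sqrt(h2), f = c(f1, f2), total_var = total_var)
}

#' Synthetic expression Ct tables with genotype effect and donor structure
#'
#' Each donor carries a latent log-expression shared across cell types
#' (producing the cross-cell-type rank correlation), a gene-specific donor
#' latent (setting the gene-gene correlation), a genotype effect
#' (TT multiplied by the full fold, TC by its square root) and lognormal
#' assay noise. Loadings are calibrated in closed form from the Spearman
#' targets (via the bivariate-normal rank-correlation identity). Ct values
#' are back-computed against a housekeeping Ct.
#'
#' @param cohort a [cohort_spec()].
#' @param effects an [effect_spec()].
#' @param cell_types cell-type labels (default 4; the structure is
#'   identical across them).
#' @param genes two gene labels.
#' @param housekeeping_ct housekeeping-gene Ct.
#' @param seed RNG seed.
#' @return list: `cts` (long data.frame donor, cell_type, gene, ct_gene,
#'   ct_housekeeping), `values` (same rows with linear `value`),
#'   `genotypes`, `truth` (folds and calibrated loadings).
#' @export
gen_expression <- function(cohort = cohort_spec(), effects = effect_spec(),
                           cell_types = c("CD4_naive", "CD8", "B_cell", "NK"),
                           genes = c("geneA", "geneB"),
                           housekeeping_ct = 20, seed = NULL) {
  genotypes <- cohort_genotypes(cohort)
  x <- c(TT = 1, TC = 0.5, CC = 0)[genotypes]
  cal <- calibrate_expression(effects, x)
  with_seed(seed, {
    nd <- length(genotypes)
    z <- stats::rnorm(nd)
    w <- matrix(stats::rnorm(nd * 2), nd, 2)
    rows <- expand.grid(donor = names(genotypes), cell_type = cell_types,
                        gene = genes, stringsAsFactors = FALSE)
    di <- match(rows$donor, names(genotypes))
    gi <- match(rows$gene, genes)
    mu <- cal$f[gi] * x[di] + cal$a * z[di] +
      cal$h[gi] * w[cbind(di, gi)]
    value <- exp(mu + effects$sigma_expression * stats::rnorm(nrow(rows)))
    cts <- data.frame(rows,
                      ct_gene = housekeeping_ct - log2(value),
                      ct_housekeeping = housekeeping_ct,
                      stringsAsFactors = FALSE)
    values <- data.frame(rows, value = value, stringsAsFactors = FALSE)
    list(cts = cts, values = values, genotypes = genotypes,
         truth = list(expression_fold = effects$expression_fold,
                      gene2_fold = effects$gene2_fold,
                      spearman_celltype = effects$spearman_celltype,
                      spearman_gene = effects$spearman_gene,
                      loadings = cal))
  })
}

#' Linear expression values from a Ct table
#' @param cts Ct data.frame from [gen_expression()] (or same columns).
#' @export
expression_from_cts <- function(cts) {
  data.frame(cts[, c("donor", "cell_type", "gene")],
             value = relative_expression(cts$ct_gene, cts$ct_housekeeping),
             stringsAsFactors = FALSE)
}

#' Synthetic ChIP reads with a planted genotype effect at an enhancer
#'
#' Background reads fall uniformly over the region; enhancer reads arrive
#' at an elevated rate multiplied by `fold` for risk donors. Per-donor
#' lognormal variability (sigma on the natural-log scale) models
#' donor-to-donor efficiency. Cohort defaults are 36 risk vs 7 non-risk.
#'
#' @param n_risk,n_nonrisk donor counts.
#' @param enhancer one-row interval data.frame (the marked element).
#' @param region one-row interval data.frame (profiled span).
#' @param fold planted risk/non-risk fold.
#' @param bg_reads expected background reads per donor over the region.
#' @param enh_reads expected enhancer reads per non-risk donor.
#' @param genome_reads expected genome-wide mapped reads per donor; the
#'   recorded library size (RPKM denominator) is genome-wide, of which only
#'   the profiled region's reads are emitted.
#' @param sigma lognormal donor noise sd.
#' @param read_length read length (bp).
#' @param seed RNG seed.
#' @return list: `reads` (named list of read data.frames), `library_sizes`,
#'   `groups`, `truth`.
#' @export
gen_chip_reads <- function(n_risk = 36, n_nonrisk = 7, enhancer, region,
                           fold = 1.44, bg_reads = 1000, enh_reads = 400,
                           genome_reads = 1e6, sigma = 0.3,
                           read_length = 50, seed = NULL) {
  groups <- c(rep("risk", n_risk), rep("nonrisk", n_nonrisk))
  donors <- sprintf("chip%02d", seq_along(groups))
  with_seed(seed, {
    reads <- list()
    lib <- numeric(length(donors))
    for (i in seq_along(donors)) {
      # donor IP efficiency acts on the specific (enhancer) signal;
      # background and genome-wide library vary only by sampling
      u <- exp(sigma * stats::rnorm(1))
      f <- if (groups[i] == "risk") fold else 1
      n_bg <- stats::rpois(1, bg_reads)
      n_enh <- stats::rpois(1, enh_reads * u * f)
      bg_start <- round(stats::runif(n_bg, region$start,
                                     region$end - read_length))
      enh_start <- round(stats::runif(n_enh, enhancer$start,
                                      pmax(enhancer$start + 1,
                                           enhancer$end - read_length)))
      start <- c(bg_start, enh_start)
      strand <- sample(c("+", "-"), length(start), replace = TRUE)
      reads[[donors[i]]] <- data.frame(
        chrom = region$chrom, start = start, strand = strand,
        length = read_length, stringsAsFactors = FALSE)
      lib[i] <- stats::rpois(1, genome_reads)
    }
    list(reads = reads, library_sizes = stats::setNames(lib, donors),
         groups = stats::setNames(groups, donors),
         truth = list(fold = fold, enhancer = enhancer, sigma = sigma))
  })
}

#' Counts-level ChIP enrichment values (fast path)
#'
#' Distributional core of [gen_chip_reads()] for large replicate studies:
#' per-donor enrichment values are lognormal around a base level, with risk
#' donors multiplied by `fold`. Used for null-calibration and recovery
#' simulations where the read-level pipeline would dominate runtime.
#'
#' @inheritParams gen_chip_reads
#' @param base_value non-risk mean level.
#' @return list with `risk` and `nonrisk` value vectors.
#' @export
gen_chip_region_values <- function(n_risk = 36, n_nonrisk = 7, fold = 1.44,
                                   sigma = 0.3, base_value = 10, seed = NULL) {
  with_seed(seed, {
    list(risk = base_value * fold * exp(sigma * stats::rnorm(n_risk)),
         nonrisk = base_value * exp(sigma * stats::rnorm(n_nonrisk)))
  })
}

#' Synthetic Sanger trace intensities at a heterozygous SNP
#'
#' Channel intensities proportional to the allele mixing fraction with
#' multiplicative noise; the two irrelevant channels carry small baseline
#' noise.
#'
#' @param risk_frac fraction of molecules carrying the risk allele.
#' @param risk_base,nonrisk_base the two alleles.
#' @param scale total signal scale.
#' @param noise_sd multiplicative noise sd.
#' @param seed RNG seed.
#' @return named intensity vector over A, C, G, T.
#' @export
gen_trace <- function(risk_frac, risk_base, nonrisk_base, scale = 1000,
                      noise_sd = 0.02, seed = NULL) {
  with_seed(seed, {
    out <- stats::setNames(abs(stats::rnorm(4, 0, scale * 0.005)), BASES)
    out[risk_base] <- scale * risk_frac * exp(stats::rnorm(1, 0, noise_sd))
    out[nonrisk_base] <- scale * (1 - risk_frac) *
      exp(stats::rnorm(1, 0, noise_sd))
    out
  })
}

#' Synthetic allele-motif fixture
#'
#' Plants the PWM consensus across a SNP in random background sequence: one
#' allele carries the consensus base at the most discriminating motif
#' column, the other a score-minimizing base. The background is
#' rejection-sampled so the planted window is the only motif occurrence
#' overlapping the SNP (quality control against accidental hits). The truth
#' records the classification the construction implies at the p-threshold.
#'
#' @param pwm a [pwm()] object.
#' @param flank_len background flank length on each side (>= motif width).
#' @param snp_effect "loss" (reference carries the motif) or "gain".
#' @param p_threshold hit threshold used to derive the expected class.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling cap.
#' @return list: `seq_ref`, `snp` (one-row SNP data.frame), `seq_start1`,
#'   `expected` classification, `planted_window` (1-based seq coords).
#' @export
gen_motif_fixture <- function(pwm, flank_len, snp_effect = c("loss", "gain"),
                              p_threshold = 1e-4, seed = NULL,
                              max_tries = 100) {
  snp_effect <- match.arg(snp_effect)
  scoring <- pwm_scoring(pwm)
  w <- ncol(scoring$ints)
  if (flank_len < w) stop("flank_len must be >= motif width")
  lo <- scoring$lo
  consensus <- apply(lo, 2, which.max)
  jstar <- which.max(apply(lo, 2, function(col) max(col) - min(col)))
  worst <- which.min(lo[, jstar])
  if (worst == consensus[jstar]) worst <- which.min(replace(lo[, jstar],
                                                           consensus[jstar],
                                                           Inf))
  motif_best <- sum(scoring$ints[cbind(consensus, seq_len(w))])
  motif_broken <- motif_best - scoring$ints[consensus[jstar], jstar] +
    scoring$ints[worst, jstar]
  p_best <- int_pvalue(scoring, motif_best)
  p_broken <- int_pvalue(scoring, motif_broken)
  has <- c(p_best < p_threshold, p_broken < p_threshold)
  expected <- if (snp_effect == "loss") {
    if (has[1] && !has[2]) "loss" else if (has[1] && has[2]) "retained"
    else "absent"
  } else {
    if (has[1] && !has[2]) "gain" else if (has[1] && has[2]) "retained"
    else "absent"
  }
  # integer score threshold for a hit
  th_idx <- which(scoring$p_ge < p_threshold)
  int_th <- if (length(th_idx)) scoring$base + th_idx[1] - 1 else Inf
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      flank5 <- sample(BASES, flank_len, replace = TRUE)
      flank3 <- sample(BASES, flank_len, replace = TRUE)
      core_ref <- BASES[consensus]
      core_alt <- core_ref
      if (snp_effect == "loss") {
        core_alt[jstar] <- BASES[worst]
      } else {
        core_ref[jstar] <- BASES[worst]
      }
      seq_ref <- paste(c(flank5, core_ref, flank3), collapse = "")
      seq_alt <- paste(c(flank5, core_alt, flank3), collapse = "")
      snp_idx <- flank_len + jstar
      if (!spurious_hit(seq_ref, scoring, int_th, snp_idx, flank_len + 1) &&
          !spurious_hit(seq_alt, scoring, int_th, snp_idx, flank_len + 1)) {
        snp <- data.frame(id = "synthSNP", chrom = "synth", pos = snp_idx,
                          ref = substr(seq_ref, snp_idx, snp_idx),
                          alt = substr(seq_alt, snp_idx, snp_idx),
                          is_lead = FALSE, stringsAsFactors = FALSE)
        return(list(seq_ref = seq_ref, snp = snp, seq_start1 = 1,
                    expected = expected,
                    planted_window = c(flank_len + 1, flank_len + w)))
      }
    }
    stop("could not build a clean motif fixture in ", max_tries, " tries")
  })
}

# any non-planted SNP-overlapping window reaching the hit threshold?
spurious_hit <- function(seq, scoring, int_th, snp_idx, planted_start) {
  w <- ncol(scoring$ints)
  codes <- seq_codes(seq)
  rc <- scoring$ints[4:1, rev(seq_len(w)), drop = FALSE]
  for (strand in c("+", "-")) {
    m <- if (strand == "+") scoring$ints else rc
    sc <- window_int_scores(codes, m)
    i <- seq_along(sc)
    over <- i <= snp_idx & snp_idx <= i + w - 1
    planted <- strand == "+" & i == planted_start
    if (any(over & !planted & !is.na(sc) & sc >= int_th)) return(TRUE)
  }
  FALSE
}

#' A CTCF-like toy motif with one critical column
#'
#' 12-column PFM built in code for tests and examples (synthetic; not the
#' JASPAR CTCF matrix): eleven moderately informative columns plus one
#' near-invariant column, tuned so the full consensus scores far below
#' p = 1e-4 while breaking the critical base lifts the best achievable
#' p above it -- i.e. a single SNP at that column switches the site, the
#' regime a motif gain/loss analysis probes.
#' @export
ctcf_like_pwm <- function() {
  consensus <- c("C", "C", "G", "C", "G", "A", "G", "G", "T", "G", "G", "C")
  m <- matrix(15, 4, length(consensus), dimnames = list(BASES, NULL))
  m[cbind(match(consensus, BASES), seq_along(consensus))] <- 55
  m[, 6] <- 1
  m[match(consensus[6], BASES), 6] <- 97  # the critical (SNP) column
  pwm(m, tf_name = "CTCF-like", id = "SYNTH.CTCF")
}

#' 4C experiment specification
#'
#' Read depth defaults to 1-2 x 10^5 per donor, a 10x scale-down of the
#' assay's 1-2 million reads, for desk-scale runtime (`depth_scale` knob).
#'
#' @param region_length analysed span (bp).
#' @param chrom,offset0 region coordinates.
#' @param bait_pos bait (viewpoint) position; defaults to the region
#'   midpoint.
#' @param reads_per_donor length-2 range of reads per donor.
#' @param depth_scale multiplier applied to `reads_per_donor`.
#' @param decay_exponent power-law distance-decay exponent alpha.
#' @param read_length sequenced read length.
#' @param bait_len bait (primer) sequence length.
#' @param loops list of planted interactions, each
#'   `list(start=, end=, fold=, group=)` in region coordinates.
#' @export
fourc_spec <- function(region_length = 340000, chrom = "chr17", offset0 = 0,
                       bait_pos = NULL, reads_per_donor = c(1e5, 2e5),
                       depth_scale = 1, decay_exponent = 1,
                       read_length = 150, bait_len = 20, loops = list()) {
  if (is.null(bait_pos)) bait_pos <- offset0 + round(region_length / 2)
  for (lp in loops) {
    if (lp$start < offset0 || lp$end > offset0 + region_length)
      stop("planted loop outside the region")
  }
  list(region_length = region_length, chrom = chrom, offset0 = offset0,
       bait_pos = bait_pos, reads_per_donor = reads_per_donor * depth_scale,
       decay_exponent = decay_exponent, read_length = read_length,
       bait_len = bait_len, loops = loops)
}

fragment_weights <- function(spec, frags, group) {
  mid <- (frags$start + frags$end) / 2
  wts <- (1 + abs(mid - spec$bait_pos))^(-spec$decay_exponent)
  for (lp in spec$loops) {
    if (lp$group == group || lp$group == "both") {
      hit <- mid >= lp$start & mid < lp$end
      wts[hit] <- wts[hit] * lp$fold
    }
  }
  wts
}

#' Counts-level 4C generator (fast path)
#'
#' Samples per-donor fragment counts from a multinomial whose weights
#' follow power-law distance decay from the bait times planted loop folds
#' for the designated group. Used directly for simulation studies;
#' [gen_4c_reads()] wraps the same sampling at the sequence level.
#'
#' @param spec a [fourc_spec()].
#' @param frags fragment map (from [digest_sequence()]).
#' @param groups character vector per donor ("risk"/"nonrisk").
#' @param seed RNG seed.
#' @return list: `counts` (fragment x donor matrix), `library_sizes`,
#'   `groups`.
#' @export
gen_4c_counts <- function(spec, frags, groups = rep(c("risk", "nonrisk"),
                                                    each = 4),
                          seed = NULL) {
  donors <- sprintf("fc%02d", seq_along(groups))
  with_seed(seed, {
    counts <- matrix(0, nrow(frags), length(groups),
                     dimnames = list(NULL, donors))
    lib <- numeric(length(groups))
    for (i in seq_along(groups)) {
      wts <- fragment_weights(spec, frags, groups[i])
      n <- round(stats::runif(1, spec$reads_per_donor[1],
                              spec$reads_per_donor[2]))
      counts[, i] <- stats::rmultinom(1, n, wts)
      lib[i] <- n
    }
    list(counts = counts, library_sizes = stats::setNames(lib, donors),
         groups = stats::setNames(groups, donors))
  })
}

#' Sequence-level 4C read generator
#'
#' Builds a random region sequence, digests it with the primary cutter,
#' samples fragment counts as in [gen_4c_counts()], and emits reads of the
#' form bait sequence + fragment 5' sequence, plus a fraction of baitless
#' noise reads (to exercise the bait filter).
#'
#' @inheritParams gen_4c_counts
#' @param site primary restriction site.
#' @param noise_frac fraction of additional baitless reads.
#' @return list: `reads` (named list of character vectors per donor),
#'   `region_seq`, `frags`, `bait_seq`, `truth` (counts matrix, loops,
#'   groups, library sizes).
#' @export
gen_4c_reads <- function(spec, groups = rep(c("risk", "nonrisk"), each = 4),
                         site = "GATC", noise_frac = 0.05, seed = NULL) {
  with_seed(seed, {
    region_seq <- paste(sample(BASES, spec$region_length, replace = TRUE),
                        collapse = "")
    frags <- digest_sequence(region_seq, site, chrom = spec$chrom,
                             offset0 = spec$offset0)
    bait_seq <- paste(sample(BASES, spec$bait_len, replace = TRUE),
                      collapse = "")
    cl <- gen_4c_counts(spec, frags, groups, seed = NULL)
    insert_len <- spec$read_length - spec$bait_len
    frag_rel_start <- frags$start - spec$offset0
    frag_seq <- substring(region_seq, frag_rel_start + 1,
                          pmin(frag_rel_start + insert_len,
                               spec$region_length))
    reads <- list()
    for (i in seq_along(cl$groups)) {
      idx <- rep(seq_len(nrow(frags)), cl$counts[, i])
      rs <- paste0(bait_seq, frag_seq[idx])
      n_noise <- round(length(rs) * noise_frac)
      if (n_noise > 0) {
        noise <- vapply(seq_len(n_noise), function(k)
          paste(sample(BASES, spec$read_length, replace = TRUE),
                collapse = ""), "")
        rs <- c(rs, noise)
      }
      reads[[names(cl$groups)[i]]] <- rs[sample.int(length(rs))]
    }
    list(reads = reads, region_seq = region_seq, frags = frags,
         bait_seq = bait_seq,
         truth = list(counts = cl$counts, loops = spec$loops,
                      groups = cl$groups,
                      library_sizes = cl$library_sizes))
  })
}
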