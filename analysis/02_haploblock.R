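#!/usr/bin/env Rscript
# Stage 1: expand lead SNPs into the risk haploblock by LD (r2 > 0.8) and
# define the analysis locus by extending the SNP extremes 10 kb each way.

suppressPackageStartupMessages(library(haploregulome))
outdir <- "results"
snps <- read_snp_table("results/sim/snp_table.tsv")
ld <- utils::read.delim("results/sim/ld_table.tsv")

region17 <- iv_from_printed("chr17", 37899254, 38139253)
summ <- summarise_snp_compilation(snps, ld, region17)
block <- snps[snps$id %in% summ$block_member_ids, ]
locus <- define_locus(block, flank = 10000, name = "17q21")

utils::write.table(block, file.path(outdir, "haploblock_members.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_bed(data.frame(chrom = locus$interval$chrom,
                     start = locus$interval$start,
                     end = locus$interval$end,
                     name = locus$name, score = 0),
          file.path(outdir, "locus.bed"))
write_json_report(list(n_snps = summ$n_snps, n_lead = summ$n_lead,
                       n_loci = summ$n_loci,
                       n_lead_in_block = summ$n_lead_in_region,
                       n_block_members = summ$n_block_members,
                       locus_first = locus$first, locus_last = locus$last,
                       locus_kb = locus$width_kb),
                  file.path(outdir, "haploblock_summary.json"))

cat("haploblock:", summ$n_block_members, "members from",
    summ$n_lead_in_region, "leads; locus", locus$interval$chrom, ":",
    locus$first, "-", locus$last, "(", locus$width_kb, "kb )\n")
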