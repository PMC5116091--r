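# haploregulome

Tools for localizing the regulatory effects of a disease-associated
haploblock — written for computational genomicists who need the full chain
from GWAS SNP lists to allele-specific chromatin readouts as tested,
reusable R functions rather than one-off scripts.

The motivating setting is the 17q21 asthma-risk block: 136 SNPs in tight
LD spanning six genes, where the question is *which* cell types and *which*
cis-regulatory elements carry the effect, and how linked variants switch a
CTCF binding site from one position to another, rewiring promoter–enhancer
contacts and raising *ORMDL3* expression.

## What it computes

| Stage | Core quantity |
|---|---|
| Haploblock | r² = cor(dosage_a, dosage_b)²; members where r² > 0.8; locus = SNP extremes ± 10 kb |
| DHS atlas | merged master peaks (max score); DHS counts per locus; immune vs non-immune unpaired two-tailed *t* with Bonferroni; immune ratio |
| Motif switch | FIMO-style log₂(freq/bg) scores with pseudocount 0.1; exact p-value P(score ≥ s) by DP over the discretized score distribution; gain/loss at p < 10⁻⁴ across SNP alleles |
| Allelic ChIP | % input = 2^(Ct_in − Ct_IP); allele % from trace intensities; reads extended 250 bp, 50-bp windows, RPKM; 400-bp SNP region; Mann–Whitney (exact by permutation for small n) |
| Expression | 2^−ΔCt vs housekeeping; TT/CC fold and t-test on linear values; log₂ FC vs CC mean; Spearman ρ via average ranks |
| 4C (simplified) | DpnII fragment counts from a bait viewpoint; reads-per-million; 5-kb trend windows (mean); sum > 50 filter; ≥3-of-4-donor consistency; BH-adjusted Mann–Whitney at 0.1 |

A first-class `gen_*` generator family produces seeded synthetic data with
the study's statistical structure (34 donors 9/16/9 at the index SNP,
36 vs 7 for H3K27ac, planted 3-fold expression and 1.44-fold H3K27ac
effects, Spearman targets 0.74/0.63, 4C distance decay with planted
loops), so every stage is testable offline. See the methods vignette
(`vignettes/haploblock-regulatory-analysis.Rmd`) for the models,
calibration math, and the choices made where the source analyses were
underspecified.

## Worked example

```r
library(haploregulome)

# compiled SNP table -> LD expansion -> analysis locus
tbl <- gen_snp_table(seed = 11)                       # synthetic stand-in
region17 <- iv_from_printed("chr17", 37899254, 38139253)
s <- summarise_snp_compilation(tbl$snps, tbl$ld, region17)
block <- tbl$snps[tbl$snps$id %in% s$block_member_ids, ]
locus <- define_locus(block, flank = 10000, name = "17q21")

# allele-aware motif scan at a planted SNP
ctcf <- ctcf_like_pwm()
fx <- gen_motif_fixture(ctcf, flank_len = 30, snp_effect = "gain", seed = 4)
res <- allele_scan(fx$seq_ref, fx$snp, fx$seq_start1, ctcf)

# genotype-stratified H3K27ac at an intronic enhancer (36 risk vs 7 non-risk)
region <- genomic_interval("chr17", 0, 10000)
enh <- genomic_interval("chr17", 4850, 5150)
snp <- data.frame(id = "rs8076131", chrom = "chr17", pos = 5001)
sim <- gen_chip_reads(enhancer = enh, region = region, fold = 1.44, seed = 8)
vals <- vapply(names(sim$reads), function(d)
  as.numeric(snp_region_value(sim$reads[[d]], snp, 400,
                              library_size = sim$library_sizes[[d]])), 0)
cmp <- genotype_fold_change(vals[sim$groups == "risk"],
                            vals[sim$groups == "nonrisk"])
```

prints, via the `cat()` calls in `analysis/`-style drivers:

```
3502 SNPs, 96 leads, 75 loci; 17q21 block: 136 members
locus chr17:37899254-38139253 (240 kb)
rs: C>A  classification: gain  (p_alt = 6e-08)
H3K27ac fold (risk/non-risk): 1.42, Mann-Whitney p = 0.00234
```

Reading: the LD expansion recovers the 136-member block and the 10-kb
flank reproduces the 240-kb locus; the alternate allele creates a
CTCF-like site that is absent on the reference allele (a motif gain); and
the windowed-coverage pipeline recovers a planted 1.44-fold enhancer
effect from raw reads with a significant rank test at the real cohort's
group sizes.

## Analysis workflow

`analysis/01_simulate_cohort.R` … `analysis/07_fourc.R` are thin numbered
drivers that run the stages in order on the synthetic world and write
their tables under `results/` (haploblock summary, DHS counts and
enrichment, motif-switch table, expression folds and correlations, ChIP
quantifications, 4C profiles and differential calls). Each is runnable as
`Rscript analysis/NN_name.R` from the repository root, in order.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package — haploblock counts and locus geometry, DHS enrichment,
motif-switch classification, allele ratios and the H3K27ac genotype
comparison, expression folds and correlations, and the 4C
sequence-to-calls path — under a supplied seed, and writes the JSON report
to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
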