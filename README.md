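# rumherit

Heritability screening and phylogenetic characterization of rumen
microbiome OTUs from host SNP genotypes.

Ruminants digest feed only through their rumen microbiome, which makes the
interplay between host genetics and microbiome composition a central
question for feed efficiency and methane research. `rumherit` implements,
as a tested R package, the complete screening procedure for detecting
*heritable* rumen bacterial OTUs in a genotyped cow cohort and
characterizing what they have in common:

1. **Genotype QC** — PLINK-dialect PED/MAP text (recode12 coding), the
   standard `mind` / `geno` / `maf` filters with per-stage removal counts.
2. **Genomic relatedness** — the allele-frequency-weighted genetic
   relationship matrix
   `A_jk = (1/n) Σ_i (x_ij − 2p_i)(x_ik − 2p_i) / (2 p_i (1 − p_i))`,
   pairwise-complete over missing calls, with GCTA-style text
   serialization.
3. **GREML heritability** — REML variance components of
   `y = Xβ + u + ε`, `u ~ N(0, σ_u² A)`, `h² = σ_u²/(σ_u² + σ_ε²)`, via a
   profiled one-dimensional likelihood and a shared eigendecomposition
   cache that makes thousands of per-OTU fits cheap; significance by the
   boundary LRT (50:50 mixture of a point mass and χ²₁).
4. **Consensus screen** — presence filter (≥ 12 genotyped animals), the
   `h² > 0.7` and `p < 0.05` rule on **all three** sampling days, and a
   100-iteration genotype-shuffling permutation null for the discovery
   count.
5. **16S clade test** — mean pairwise percent identity (global alignment,
   affine gaps, C++ core) of the heritable set against 100 random
   same-size subsets, plus per-order Fisher enrichment.
6. **Trait association** — Spearman profiles of heritable OTUs against
   metabolite/physiology indices across the full cohort, a 1000-iteration
   profile-shuffling null for mean correlations, Welch comparison of
   |r| against the rest of the microbiome, and the per-index correlation
   odds ratio `(hc/hn)/(nc/nn)` with Fisher p and Bonferroni flag.

A synthetic-data module (`herd_design()`, `simulate_genotypes()`,
`planted_microbiome()`, `simulate_abundances()`, `simulate_sequences()`,
`simulate_traits()`) generates half-sib cohorts with planted heritable
OTUs, a planted 16S clade and linked traits, so the whole pipeline is
testable end to end without animal data. `run_pipeline()` orchestrates all
stages from one config with a master seed and writes a manifest;
identically-seeded runs are byte-identical.

## Worked example

```r
library(rumherit)

design <- herd_design(n_animals = 200, n_genotyped = 200,
                      families = rep(5L, 40), n_snps = 2000,
                      missing_rate = 0.01, seed = 7)
sim <- simulate_genotypes(design)
qc  <- apply_qc(sim$genotypes, mind = 0.05, geno = 0.05, maf = 0.05)
print(qc$report)
#> QC (mind 0.05, geno 0.05, maf 0.05):
#>   individuals removed (low call rate): 0
#>   SNPs removed (missingness):          0
#>   SNPs removed (MAF):                  30
#>   SNPs passing:                        1970

grm <- compute_grm(qc$genotypes)

spec <- planted_microbiome(n_otus = 250, n_heritable = 10, true_h2 = 0.9,
                           seed = 8)
spec$presence_profile[spec$heritable_ids] <- 1  # planted h2 on the observed scale
abund <- simulate_abundances(embed_relatedness(grm, sim$pedigree$ids$iid),
                             spec)

filt   <- presence_filter(abund, grm$ids$iid, min_present = 12)
screen <- screen_heritable(filt, grm, h2_min = 0.7, alpha = 0.05)
print(screen)
#> screen_result: 6 consensus heritable OTUs of 250 screened (h2 > 0.7 , p < 0.05 on all days)
sum(screen$consensus %in% spec$heritable_ids)
#> [1] 6          # all six calls are planted OTUs; no false positives

fdr <- permutation_fdr(filt, grm, n_perm = 20, seed = 9)
print(fdr)
#> permutation_fdr: observed 6 heritable OTUs; 100% of 20 permutations below observed

seqs  <- simulate_sequences(spec)
clade <- similarity_null_test(seqs, screen$consensus, filt$otus$otu_id,
                              n_draws = 100, seed = 10)
print(clade)
#> similarity_null: observed mean identity 90.2% vs 100 random size-6 subsets (null mean 74.1%), p = 0.009901
```

Reading the output: the screen called 6 of the 10 planted OTUs heritable
and no background OTU — at 200 animals a REML heritability estimate
carries a standard error near 0.15, so planted OTUs whose estimate drew
low miss the 0.7 consensus bar; that is the expected behaviour, and the
permutation null (every shuffled cohort yields fewer calls than the
observed 6) is what certifies the count. The consensus set's 16S identity
(90.2%) exceeds all 100 random subsets, recovering the planted clade with
the smallest p the 100-draw null can produce.

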