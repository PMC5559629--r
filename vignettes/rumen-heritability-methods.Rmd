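---
title: "Screening rumen microbiome OTUs for host-genetic heritability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening rumen microbiome OTUs for host-genetic heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumherit)
```

## The scientific problem

A cow cannot digest forage without its rumen microbiome, and herds carry
both genotype and microbiota variation, so a natural question is whether the
abundance of specific rumen bacteria is *heritable* — whether animals with
more similar genomes carry more similar amounts of particular taxa. The
package implements the full screening procedure for that question: estimate
genomic relatedness between animals from SNP genotypes, fit a mixed model to
every OTU's relative abundance to estimate heritability, demand consistency
across repeated sampling days, calibrate the number of discoveries against a
genotype-shuffling null, characterise the 16S sequence relatedness of the
discovered set, and associate the discovered OTUs with rumen metabolites and
host traits.

No animal data ships with the package. A synthetic-data module generates
cohorts with the statistical structure the analysis assumes — paternal
half-sib families, biallelic SNPs, OTUs with a planted additive genetic
component, 16S sequences with a planted clade, trait columns linked to
specific OTUs — so every stage is exercised, end to end, by code alone.

## Relatedness from SNPs

For animals $j,k$ and biallelic SNPs $i = 1 \dots n$ with reference-allele
counts $x_{ij} \in \{0,1,2\}$ and population reference-allele frequency
$p_i$, the genomic relationship estimate is

$$A_{jk} = \frac{1}{n}\sum_i
  \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2p_i(1 - p_i)},$$

allele sharing weighted by allele rareness. With complete genotypes this is
$WW'/n$ for the column-standardised genotype matrix $W$; with missing calls
each pair's sum runs over the SNPs observed in both animals and $n$ becomes
that pair's count (`compute_grm()` stores those counts). Two diagonal
conventions are provided: the default applies the same formula with $j = k$;
`diagonal_mode = "gcta"` uses the alternative diagonal of the GCTA toolkit.
Which one the original toolchain used is not documented for this procedure,
so both are exposed and recorded.

Quality control mirrors the standard single-pass PLINK filters, in its
documented order: individuals with more than `mind` missing calls, then SNPs
with more than `geno` missing among retained individuals, then SNPs with
minor allele frequency strictly below `maf` (equality kept), all statistics
recomputed between stages. A reference-panel hook (`freqs` in
`compute_grm()`) allows allele frequencies from a larger population, since
cohort-only frequencies shrink relatedness slightly in small, family-heavy
cohorts.

Pairwise-complete estimation has one practical consequence worth knowing: a
GRM computed from data with even 1% missing calls is *not* exactly positive
semidefinite — smallest eigenvalues around $-0.01$ are routine.
`eigen_prepare()` floors the spectrum at $10^{-8}\,\mathrm{tr}(A)/N$ and
treats only violations beyond 5% of the mean diagonal as malformed input.

## Heritability by REML

Each phenotype (one OTU, one sampling day, relative abundance across
genotyped animals) is modelled as

$$y = X\beta + u + \varepsilon, \qquad
  u \sim N(0, \sigma_u^2 A), \quad
  \varepsilon \sim N(0, \sigma_\varepsilon^2 I),$$

with $X$ an intercept by default (no covariates are used). Heritability is
$h^2 = \sigma_u^2 / (\sigma_u^2 + \sigma_\varepsilon^2)$. `reml_fit()`
maximises the restricted likelihood profiled to one dimension: writing
$V = \sigma_P^2\,(h^2 A + (1 - h^2) I)$, the total variance $\sigma_P^2$ has
a closed-form optimum, and the scalar problem in $h^2$ is solved on $[0,1]$
by a deterministic 101-point bracket followed by golden-section refinement
(tolerance $10^{-8}$), so boundary solutions at $\sigma_u^2 = 0$ are returned
exactly and no fit depends on a random start.

Because $A$ is shared across thousands of OTU fits, `eigen_prepare()`
decomposes it once ($A = Q\Lambda Q'$); every fit then rotates its phenotype
by $Q'$ and evaluates the likelihood against a diagonal covariance in
$O(\text{animals})$ per candidate $h^2$. `reml_fit_batch()` vectorises the
grid across phenotype columns and is what the screen and the permutation
null use; it is algorithmically identical to the scalar path and the suite
asserts agreement to $10^{-6}$.

Significance uses the boundary likelihood-ratio test: under
$H_0\!:\sigma_u^2 = 0$ the parameter sits on the boundary, so the LR
statistic is referred to a 50:50 mixture of a point mass at zero and
$\chi^2_1$, $p = \tfrac12 \Pr(\chi^2_1 \ge LR)$. The original analysis does
not state its p-value construction; the mixture is the convention of the
cited variance-component software and is asymptotically exact-to-conservative,
which the suite checks by simulation (type-I rate at $\alpha = 0.05$ stays
at or below about 0.05).

## The consensus screen and its permutation null

OTUs enter the screen only if present in at least 12 genotyped animals
(`presence_filter()`); presence is an animal-level notion by default — the
OTU is nonzero in at least one of the animal's three day samples — because
the animal is the unit of genotyping (a stricter day-level switch is
provided). An OTU is called heritable only if $\hat h^2 > 0.7$ **and**
$p < 0.05$ on *all three* sampling days (`screen_heritable()`). The day
consensus trades power for robustness: with ~50 genotyped animals a single
day's estimate is extremely noisy, and day-to-day agreement is the
procedure's replication argument.

`permutation_fdr()` calibrates the *count* of consensus calls: each of 100
iterations shuffles the genotyped-animal identities once — one permutation
applied to the GRM rows and columns, shared across all OTUs and days, which
preserves the cross-OTU dependence of the null — reruns the full consensus
screen, and records the heritable count. The report is the fraction of
permutations whose count falls strictly below the observed count, the
comparison the original analysis reports (94% there). Per-OTU q-values are
deliberately not produced; the procedure's own calibration is count-based.

## Phylogenetic relatedness of the heritable set

`pairwise_identity()` computes percent identity from an end-to-end global
alignment (Needleman–Wunsch with affine gaps, implemented in C++ with
deterministic tie-breaking): matched columns divided by all alignment
columns, gaps included. The default scoring is match $+2$, mismatch $-1$,
gap open $-5$, gap extend $-2$ (a gap run of length $L$ costs
$5 + 2L$); `N` never matches anything. The original similarity came from a
progressive aligner whose pairwise scores are version- and
parameter-dependent, so the scoring here is explicit, configurable and
recorded in outputs; the suite pins the implementation against an
independent dynamic-programming oracle (exactly) and against the Biostrings
global aligner (score equality).

`similarity_null_test()` compares the heritable set's mean pairwise identity
with 100 random same-size subsets of the presence-filtered pool, reporting
the add-one empirical p-value $(1 + \#\{\text{null} \ge \text{obs}\}) /
(n_{\text{draws}} + 1)$, which can never be zero. `taxon_enrichment()` asks
whether any order (or other rank) contributes more OTUs to the heritable set
than its share of the pool predicts, by two-sided Fisher exact tests.

## Association with metabolites and host traits

For correlation analyses each animal's abundance is the mean over its
available day samples (`animal_abundance()`); heritability stays per-day.
`spearman_profile()` computes Spearman rank correlations (average ranks for
ties; two-sided p from the large-sample $t$ approximation) over
pairwise-complete animals — the full trait cohort, not only genotyped
animals. `mean_correlation_null()` shuffles every heritable OTU's abundance
profile independently in each of 1000 iterations and recomputes the
per-index mean signed $r$ and mean $|r|$; both observed statistics are
reported with add-one empirical p-values, because the signed mean and the
magnitude mean answer different questions (directional coherence vs overall
coupling). `mean_abs_corr_compare()` contrasts $|r|$ of heritable OTUs
against all other eligible OTUs per index (Welch $t$).
`correlation_odds_ratio()` counts, per index, heritable and non-heritable
OTUs with nominal Spearman $p < 0.05$ and reports
$(hc/hn)/(nc/nn)$ with a two-sided Fisher exact p and a Bonferroni flag
whose divisor is the number of indices actually tested.

## What the synthetic data emulates — and what it does not

`herd_design()` defaults to the study's shape: 78 animals, 47 genotyped, 11
paternal half-sib families (one of four, one of three, nine pairs),
independent biallelic SNPs with allele frequencies drawn from
$[0.05, 0.5]$, 1% missing calls. Offspring inherit one randomly chosen sire
haplotype allele per SNP plus a fresh maternal allele, which yields the
0.25 half-sib expectation without pedigree machinery. There is no linkage
disequilibrium and no genotyping-error model: the realized GRM converges to
the pedigree expectation as SNPs grow, which the suite asserts at
10,000 SNPs within 0.05.

`simulate_abundances()` plants the genetic signal *through the relationship
matrix the caller supplies*. Use the realized (post-QC) GRM — embedded in
the cohort with `embed_relatedness()` when non-genotyped animals are needed
— so that the generating covariance is exactly the matrix the downstream
fits use; planting through the pedigree expectation instead leaves a
generating-model mismatch that attenuates recovered heritability by roughly
a third at these cohort sizes. Each OTU's latent value per animal and day is
$g + e_{\text{animal}} + e_{\text{day}}$ with $\mathrm{var}(g) = h^2$,
day noise at 20% of the total latent standard deviation (so three daily
replicates cohere, as the day-consensus requires), and the animal-level
environment filling the remainder; the per-day latent heritability is
exactly the planted value. Latents map to abundances through the
exponential — strictly monotone, nonnegative, right-skewed — then the
animals with the lowest day-invariant latent are zeroed until the OTU's
presence fraction is met, and every sample is renormalised to sum to one.

Three numerical choices deserve explanation:

* **Latent scale** (`latent_sd = 0.2`). The planted $h^2$ is a statement
  about the *observed* relative-abundance scale only insofar as the
  monotone map is near-affine. At latent standard deviation $s$ the
  exponential attenuates covariances by roughly $s^2 / (e^{s^2} - 1)$ —
  2% at $s = 0.2$, but 42% at $s = 1$. The default keeps the planted value
  meaningful; real OTU tables are far more dispersed, which is precisely
  why heritability estimated on raw abundances of wild data should be
  interpreted qualitatively.
* **Baseline spread** (`baseline_log_sd = 0.5`). Per-sample renormalisation
  divides by the sample total, whose fluctuations act as shared noise on
  every OTU. With 500 OTUs and modest baseline spread this costs under 3%
  of the latent variance; with the orders-of-magnitude spread of real
  tables it would cost more.
* **Presence zeroing** deterministically censors the lowest-latent animals.
  Censoring attenuates recovered heritability (the zeroed animals carry no
  covariance information), so where a protocol's purpose is parameter
  recovery the planted OTUs are given full presence and the presence
  machinery is tested separately. Background OTUs default to presence
  drawn in $[0.1, 1]$ and heritable OTUs in $[0.7, 1]$, matching the
  observation that heritable taxa are highly prevalent.

Passing tests on these data therefore show that the *procedure* — QC, GRM,
REML, consensus, permutation calibration, clade test, associations — is
implemented correctly and recovers planted truth under its own model
assumptions. They cannot show that real rumen abundances satisfy those
assumptions (Gaussian latents, log-normal shape, independent SNPs, no
common-environment confounding between half-sibs).

## Problem sizes and statistical power of the checks

The acceptance checks (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) run at desk scale: cohorts of 300 animals,
5,000 SNPs, 500 OTUs, three days. Two design choices matter for
reproducibility of the checks themselves:

* A REML heritability estimate from a half-sib cohort of 300 animals
  carries a standard error around 0.15 (eleven 27-head families or sixty
  5-head families — family count helps only mildly). A planted
  $h^2 = 0.85$ OTU therefore passes the $\hat h^2 > 0.7$-on-all-days rule
  with probability only ~0.7, and any check phrased as "$k$ of 10 planted
  OTUs recovered" is a coin flip. The recovery checks consequently pool
  replicate cohorts — 60 fits for the mean-recovery band, 100 planted OTUs
  across ten cohorts for the consensus-recovery fraction — leaving every
  threshold untouched while shrinking the Monte-Carlo noise of the check
  itself. Single-cohort counts fluctuate between roughly 4 and 8 of 10.
* For the end-to-end screen the acceptance herd uses sixty five-offspring
  sire families: small paternal half-sib groups are the realistic
  AI-breeding structure (the study herd's own families had two to four
  offspring) and carried the most information per animal among the family
  sizes examined when the protocol was fixed.

On one CPU the full suite runs in about ten minutes and
`scripts/acceptance.R` in about two.

## Known limitations

* Heritability estimates at $n \approx 47$ (the study scale) are nearly
  unidentified per-OTU; the package reproduces the *screening logic*, whose
  robustness argument is the day consensus plus the permutation null, not
  the point estimates.
* The reference panel the original QC leaned on (2,691 additional animals)
  is emulated only as a frequency hook; cohort-only QC necessarily differs.
* Sequences are simulated on a star topology with independent sites — no
  indels, rate heterogeneity, or realistic 16S secondary structure; the
  clade test consumes only mean pairwise identity, which this suffices for.
* The permutation null shuffles whole genetic identities; it does not model
  shared-environment (pen, diet) confounding, which real designs must
  address in the fixed effects.
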