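---
title: "Candidate-gene SNP screening: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene SNP screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsnp)
```

# The problem

A handful of *candidate genes* — genes previously associated with disease risk
or outcome — rarely act alone: their protein products sit in pathways and
interaction networks, and variants anywhere in that neighbourhood can modulate
the same phenotype. `netsnp` implements a local, fully testable version of the
candidate-gene data-integration strategy:

1. **Network expansion.** Candidate genes are expanded to *focal genes*: every
   gene that shares at least one pathway with a candidate, or whose protein has
   a direct interaction edge to a candidate's protein. Pathway membership comes
   from GMT snapshots, interactions from SIF/TSV edge lists — flat files, never
   live services.
2. **Central-SNP filtering.** SNP annotations for the focal genes are reduced
   to *central SNPs*: variants with at least one consequence outside the
   exclusion set `{UPSTREAM, DOWNSTREAM, INTRONIC, WITHIN_NON_CODING_GENE,
   HGMD_MUTATION}` — i.e. variants in coding or regulatory regions (coding
   changes, splice sites, UTRs) that can plausibly alter protein function or
   expression.
3. **LD tagging.** Central SNPs are usually absent from genotyping arrays, so
   they are linked to *tag-SNPs* through pairwise linkage disequilibrium
   computed from genotype data: a candidate tags a central SNP when
   r² ≥ threshold (default 0.8).
4. **Effect prediction.** For non-synonymous SNPs, four protein-effect
   predictors (PolyPhen-style categories, PolyPhen-2-style categories, a
   structure-based score, a conservation probability) are reconciled into one
   record and a consensus call.
5. **Survival screening.** Array SNPs in the central-or-tag universe are tested
   for association with patient survival: genotype QC, Kaplan–Meier curves per
   genotype group, a log-rank test, and logistic-regression odds ratios;
   significant tags are mapped back to the central SNPs they proxy.

A synthetic-data module generates every input format with controllable
statistical structure, so the entire workflow runs and is tested with no
database access.

# Models and estimators

## Two-locus haplotype EM and r²

For two biallelic loci, let $p_A$, $p_B$ be allele frequencies and
$p_{AB}$ the frequency of the haplotype carrying both alleles. Linkage
disequilibrium is $D = p_{AB} - p_A p_B$ and

$$ r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}. $$

Unphased genotypes identify the haplotype pair of every sample except the
double heterozygote, which is compatible with either the cis
($AB/ab$) or trans ($Ab/aB$) configuration. `pairwise_r2(method = "em")` runs
the classical two-locus EM: starting from linkage-equilibrium frequencies, the
E-step splits the double-heterozygote count between the two configurations in
proportion to $\hat p_{AB}\hat p_{ab}$ versus $\hat p_{Ab}\hat p_{aB}$, and the
M-step renormalises. Convergence is declared when no haplotype frequency moves
by more than `1e-10`, capped at 1000 iterations. Because the genotype margins
fix the allele frequencies, the only free parameter is $p_{AB}$; the tests
exploit this by maximising the multinomial likelihood directly over a fine
$p_{AB}$ grid as an independent oracle.

Numerical choices: samples missing at either locus are excluded per pair
(pairwise-complete deletion, reported as `n_used`); a monomorphic locus makes
r² undefined and is an error, not a zero; the pair is evaluated in
lexicographic SNP order internally, so `pairwise_r2(a, b)` and
`pairwise_r2(b, a)` are bit-identical; the likelihood is symmetric in the sign
of $D$ for r² purposes, so no tie-break is needed. `method = "allelic_corr"`
(squared Pearson correlation of dosage vectors) is kept as a cross-check; the
two agree asymptotically under Hardy–Weinberg equilibrium.

## Kaplan–Meier, Greenwood, log-rank

The survival screen is deliberately elementary — the goal is a transparent,
per-SNP test. `km_estimate()` computes the product-limit estimator per
genotype group with Greenwood's variance
$\widehat{\mathrm{Var}}(\hat S) = \hat S^2 \sum d_i / (n_i(n_i-d_i))$ and 0.95
confidence bands on the log-survival scale, clipped to $[0,1]$.
`logrank_test()` compares groups by summing, over distinct event times, the
observed minus hypergeometric-expected deaths per group; the statistic is the
quadratic form of the first $k-1$ components in their covariance, chi-square
with $k-1$ degrees of freedom. With no events the test reports
$\chi^2 = 0, p = 1$ and a flag rather than failing. Odds ratios come from a
single-predictor logistic regression with indicator coding against the
major-homozygote reference (`stats::glm`); a zero cell makes the contrast
non-estimable and is flagged, not an error. The outcome modelled is the bare
observed-death indicator over follow-up — a documented assumption, since
nothing in the screen conditions the odds ratio on time.

## Rare-homozygote merging

Kaplan–Meier estimates are unstable in small groups, so when the rarer
homozygote class has frequency below `merge_homo_freq` (default 0.10) among
called samples it is merged with the heterozygotes — e.g. an 11-of-209
homozygote group merges, a 21-of-209 group does not. When the two homozygote
classes are equally frequent the minor(alternate)-allele homozygote is the
merge candidate, a deterministic tie-break. Merging is optional and the
threshold is a parameter.

# Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `confidence_min` | 0.95 | call confidence in [0,1] | calls below it become missing |
| `max_missing_rate` | 0.05 | fraction per SNP | standard array QC |
| `min_maf` | 0.05 | allele frequency | screen needs testable groups |
| `min_sample_snr` | 5 | signal-to-noise | drops failed samples |
| `merge_homo_freq` | 0.10 | fraction of called samples | small-group KM stability |
| `alpha` | 0.05 | significance level | nominal, uncorrected |
| `r2_threshold` | 0.8 | r² in (0,1] | conventional tagging cutoff |
| `filter_mode` | `any_transcript` | — | see below |

The QC thresholds and `alpha` are parameters rather than constants; the QC
report always echoes the values used, so no run hides its thresholds. The
screen uses nominal p-values by design — it is a hypothesis-generating
filter, not a confirmatory analysis — but a Benjamini–Hochberg column
(`logrank_p_bh`) is emitted alongside every result sheet so users can apply a
multiplicity-aware cut.

`filter_mode` exists because annotation interfaces disagree about transcripts:
`any_transcript` (default) keeps a SNP if *any* transcript gives it a
non-excluded consequence; `first_transcript` evaluates only the first-listed
transcript, reproducing single-transcript interfaces. The first always
contains the second, which the property tests assert.

# The synthetic-data generator

`sim_config()` fixes the emulated study conditions: a 200-gene universe with
20 pathways (5–25 members) and an Erdős–Rényi PPI graph of mean degree 2;
209 patients (a typical clinical-cohort size); 60 annotated SNPs with a
realistic consequence mix (≈58% in the excluded classes) plus 8 tag partners
drawn from two-locus haplotype pools; 2% missing calls and 2% low-confidence
calls; exponential survival with baseline hazard $\log 2$ per year — median
survival one year, as in glioblastoma — and 30% independent exponential
censoring. One master seed derives independent sub-streams per component, so
regenerating genotypes does not perturb the network snapshot.

`gen_haplotype_pool(maf_a, maf_b, target_r2)` solves the pool exactly:
$D = \sqrt{r^2\,p_Aq_Ap_Bq_B}$ with positive sign, which is feasible only when
the target does not exceed $r^2_{\max}$ for the MAF pair (equal MAFs make any
target feasible); infeasible targets are rejected with the bound named.
Genotypes are two independent haplotype draws per sample — the same
Hardy–Weinberg assumption the EM estimator makes, keeping simulator and
estimator coherent.

What the generator does **not** emulate: real allele-frequency spectra,
genomic coordinates and gene structure, LD beyond isolated two-locus pools,
population stratification, informative censoring, or genotype-calling error
structure beyond a uniform confidence mix. Passing tests therefore show the
machinery is correct under its stated model, not that real cohorts will
behave this way.

# Problem sizes in the tests

The test suite and acceptance script scale the simulations to desk size:
LD oracles on 20-sample fixtures (where phase ambiguity actually bites),
round-trip r² recovery at n = 1000, screen power from 200 replicates at
n = 300 and HR = 3 per minor allele, null calibration from 2000 replicates at
n = 200, and the end-to-end pipeline on the default 209 × 68 panel. The
published-scale counts that motivated the workflow (tens of thousands of
central SNPs) only exercise set arithmetic, which is checked at full size.

# Design choices that were genuinely open

- **Query genes in the output.** Whether the focal set includes the queries
  themselves is convention; they are included and flagged `is_query`, so both
  conventions are recoverable.
- **Counting a gene found via pathway *and* PPI.** Counted once, under a
  `both` category, in `source_distribution()`.
- **Consensus with absent predictors.** Predictors cover different SNP sets.
  Default (`require_all = TRUE`): a SNP absent from any table cannot reach
  consensus. The lenient alternative (absence is non-dissent) is a flag.
- **Boundary scores.** A structure score of exactly 0 and a conservation
  probability of exactly 0.05 are *not* damaging (strict inequalities).
- **Confidence-gated calls.** Low-confidence genotype handling is implemented
  as call acceptance: calls below `confidence_min` become missing before the
  missing-rate filter. The alternative reading (imputing missing calls from
  high-confidence neighbours) needs raw array intensities that flat files do
  not carry.
- **Self-links.** A SNP may be both central and candidate tag, but never tags
  itself, and self-loops in the PPI never create focal genes.

# Known limitations

- LD is pairwise only; no multi-marker tagging or haplotype blocks.
- No Cox regression; the screen is KM/log-rank/logistic by construction.
- Genotype files carry allele pairs, so a locus observed only as one
  homozygote class is indistinguishable from a monomorphic locus on re-read.
- The EM can in principle sit on a local likelihood optimum for extreme
  20-sample tables; across the tested fixtures it agrees with the exhaustive
  grid MLE to ~1e-9, but pathological tables are not provably excluded.

# A minimal run

```{r example, eval = FALSE}
dir <- tempfile()
files <- gen_dataset(sim_config(seed = 11,
                                effect_snp = list(rsid = "rs000005",
                                                  hazard_ratio = 3)), dir)
manifest <- run_pipeline(list(
  queries = files[["queries"]], pathway_db = files[["pathways"]],
  ppi = files[["ppi"]], aliases = files[["aliases"]], snps = files[["snps"]],
  genotypes = files[["genotypes"]], confidence = files[["confidence"]],
  clinical = files[["clinical"]], outdir = file.path(dir, "out")))
manifest$central_hits
```

With this seed the causal central SNP `rs000005` is itself lost to genotype QC
but its tag `rsT00002` (target r² = 0.9) is flagged by the log-rank screen and
mapped back — the exact situation tag-SNP integration exists to handle.
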