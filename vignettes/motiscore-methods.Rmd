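---
title: "Methods: a transparent multi-omics tumor immunogenicity score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a transparent multi-omics tumor immunogenicity score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Tumor immunogenicity — the capacity of a tumor to be recognized and attacked
by the immune system — is what immune checkpoint inhibitor (ICI) therapy
exploits, and no single molecular biomarker captures it well. This package
implements a deliberately transparent composite: a set of candidate
biomarkers derived from paired tumor/normal whole-exome sequencing and bulk
tumor RNA-Seq is screened statistically on an ICI-treated discovery cohort
with RECIST-labeled outcomes, and the score of a sample is

$$\mathrm{score}(x) \;=\; \sum_{b \in \mathcal{S}} w_b \,
\frac{x_b - \mu_b}{\sigma_b},
\qquad
w_b \;=\; \frac{-\log_{10} p_b}{\sum_{c \in \mathcal{S}} -\log_{10} p_c},$$

where $\mathcal{S}$ is the selected biomarker set, $p_b$ the selection
p-value of biomarker $b$, and $\mu_b, \sigma_b$ the discovery-cohort mean
and sample standard deviation. Every term is inspectable: the weight of a
biomarker is exactly the (normalized) strength of its univariate outcome
association, and a sample's score decomposes into per-biomarker z-score
contributions. Weights are magnitudes; directionality is carried by the
biomarker coding itself (the ICI-resistance flag is $-1$ when present, so a
defective antigen-presentation pathway *lowers* the score).

### Candidate biomarkers

Eight candidates enter selection, spanning DNA- and RNA-derived biology:

| biomarker | type | units | derivation |
|---|---|---|---|
| `tmb` | continuous | mutations/Mb | nonsynonymous somatic variants (VEP impact above "protein altering", i.e. the `moderate`/`high` levels of the packaged vocabulary) inside the common target region, per megabase |
| `neoantigen_burden` | continuous | count | predicted MHC-I binders with median affinity < 500 nM, ≥ 1 supporting RNA read, restricted to retained HLA alleles |
| `tcr_entropy` | continuous | nats | Shannon entropy of TCR α-chain clonotype frequencies, clones seen ≥ 2× |
| `resistance_flag` | categorical | −1/0 | deleterious main-clone alteration in *B2M* or the antigen-processing machinery (*TAP1, TAP2, TAPBP, CIITA, CALR, CANX*) |
| `response_flag` | categorical | 0/1 | *LRP1B* high-impact + CMC-annotated variant or homozygous deletion, any clonality |
| `hed` | continuous | Grantham units | HLA evolutionary divergence: mean per-site Grantham distance between binding-groove sequences, averaged over loci A/B/C |
| `pdl1_cpm`, `b2m_cpm` | continuous | CPM | *CD274* and *B2M* expression, counts per million |

A combined C-X-C chemokine marker (mean log2 fold change of *CXCL9/10/11*
against per-gene cohort median CPM, pseudocount 1) is computed alongside the
panel but is not a fit candidate by default; it exists for exploratory
evaluation and can be added to `panel_biomarkers()` by the user.

### Selection, pruning, weighting

Continuous candidates are tested by two-sided Mann–Whitney U
(`stats::wilcox.test`: exact when both groups have < 50 observations and no
ties, otherwise the normal approximation with tie and continuity
corrections), categorical ones by two-sided Fisher's exact test on the 2×2
presence × outcome table. Candidates with $p \ge \alpha$ (default 0.05) are
excluded. Among the survivors, pairs with absolute Spearman correlation
above 0.5 are resolved iteratively — strongest correlation first — by
rejecting the member with the smaller effect size. Effect sizes are the
absolute rank-biserial correlation $|2\,\mathrm{AUC}-1|$ for continuous
biomarkers and the absolute Yule's Q (a monotone map of the Haldane-corrected
odds ratio onto $[0,1]$) for categorical ones; the two scales are comparable
by construction, which is what the pruning rule needs. P-values are floored
at $10^{-300}$ before taking logs.

The binary flags are z-scored like every other selected biomarker — the
weighted-sum formula is applied literally; a switch to pass flags through raw
was considered and rejected because it would silently change the meaning of
the stored standardization constants.

### Cutoff and evaluation

The continuous score is dichotomized at the threshold maximizing Youden's
$J = \mathrm{sensitivity} + \mathrm{specificity} - 1$ on the discovery ROC
curve. Operating points use the rule *positive iff score > threshold*; tied
maxima resolve to the smallest threshold (the more sensitive classifier —
the package prefers not to miss potential responders), and a score exactly
at the cutoff classifies *low* (conservative toward not recommending
therapy). The AUC is the tie-corrected concordance probability, identical to
the trapezoidal area and to the normalized Mann–Whitney U statistic; the
test suite verifies this equivalence against brute-force pair counting and
an independent ROC implementation.

Survival is compared between score groups with Kaplan–Meier curves
(`survival::survfit`) and a univariate Cox model with **Breslow** tie
handling (`survival::coxph`), reporting the hazard ratio of the *high*
group versus *low* with a Wald 95% CI and p-value. Breslow was chosen
because it is the simplest well-defined tie rule and is directly checkable
against a hand-written partial-likelihood grid search, which the tests do. A
group without events, or a monotone partial likelihood, raises a diagnostic
error rather than returning a silent estimate.

## Quality control

Sample level (all five metrics mandatory; every failed rule is reported,
not just the first): mean tumor coverage ≥ 60×, mean normal coverage ≥ 20×,
tumor/normal SNP genotype correlation ≥ 0.80, at most 70% of somatic
variants present in gnomAD, tumor content ≥ 0.30. Variant level: depth ≥
20× in tumor *and* normal, VAF strictly > 5%, ≥ 3 supporting reads. CNV
calls require log-likelihood strictly > 100. Coverages and the SNP
correlation are consumed as upstream pipeline metrics — this package
operates downstream of alignment and variant calling.

When no CNV-based purity estimate exists, tumor content is estimated as
$\min(1,\, 2 \times \mathrm{median}(\text{top-15 VAFs}))$ (all VAFs if
fewer than 15): a clonal heterozygous variant in a diploid tumor has VAF of
about half the purity, hence the doubling; the multiplier is exposed as an
argument. Zero somatic variants leave the content undefined — the function
returns `NA` with a `motiscore_review` warning so the sample is flagged for
manual review rather than auto-failed.

The common target region is built per study — bases covered ≥ 20× in at
least half of the normal samples (integer counts, so the quorum is
$\lceil n/2 \rceil$: 2 of 4 passes, 1 of 3 fails), intersected with exons
padded by ±2 bp — and then intersected across studies. Intervals are BED
0-based half-open throughout; book-ended intervals merge so that region
sizes are unambiguous; variant positions are 1-based (VCF convention), with
the conversion centralized in one pair of helpers.

## Biomarker details and open choices

**Main-clone rule.** A resistance alteration must affect the main tumor
clone: SNVs/indels need VAF ≥ 0.8 × tumor clonality; homozygous deletions
(copy number 0) apply the same 0.8 factor to the CNV call's own clonality.
"Tumor clonality" is interpreted on the same scale as the CNV clonality
field. Both choices are configurable (`clonal_fraction`).

**HLA allele loss.** A class-I allele counts as lost if an overlapping CNV
deletes it with clonality ≥ 25%, or if the tumor/normal assigned-read-count
ratios of the two alleles deviate by more than 40%, formalized as
$|r_1 - r_2| / \max(r_1, r_2) > 0.40$ with the smaller-ratio allele lost.
The deviation formula is one of several defensible readings of a
"ratio deviation" rule and is exposed as `deviation_max`. Phasing a deletion
to a specific allele is upstream annotation, so HLA CNV input carries the
deleted allele explicitly.

**HED.** The divergence at a locus is the *mean per-aligned-site* Grantham
distance over the binding groove, zero for homozygosity or allele loss, and
the sample value averages loci A, B, C (per-locus values are always
reported). Per-site normalization follows the HED literature; without it the
statistic would scale with groove length. The Grantham matrix is computed at
load from the published physicochemical formula (composition, polarity,
molecular volume; mean pairwise distance scaled to 100, rounded) rather than
shipped as a typed-in table; a handful of entries differ from the printed
1974 matrix by exactly one unit due to rounding in the original publication,
which is negligible at the scale of the statistic. The packaged
allele→groove-sequence table is **synthetic** (random 24-residue stand-ins,
labelled as such); supply a real IMGT-derived alignment for production use.

**Gene naming.** The resistance set's "CALX" is read as *CANX* (calnexin);
"CALX" is accepted as an alias, as is "PDL1" for *CD274*. Gene-level CNV
annotation is carried as a `genes` column on the CNV table.

**Entropy log base.** Natural log (nats). The defining formula's
unqualified "log" is conventionally natural in the diversity literature;
the choice only rescales the biomarker and is absorbed by z-scoring.

**Missingness.** `build_panel()` marks biomarkers whose inputs are absent
as `NA`, never zero, and `score_samples()` refuses to score a sample with a
missing selected biomarker unless mean-imputation is explicitly requested
(`impute_mean = TRUE`, which scores the missing term at z = 0). Silence must
not create scores.

## The synthetic cohort generator

`simulate_panels()` draws panel-level cohorts from a Gaussian copula:
latent standard normals with a target correlation structure (Spearman
targets converted to latent Pearson via $2\sin(\pi\rho/6)$; non-PSD
specifications are rejected), per-group location shifts in latent SD units,
then marginal maps — log-normal for TMB, neoantigen burden and expression
(skewed, positive), normal for entropy and HED, per-group prevalences for
the binary flags. The default configuration emulates an ICI melanoma
discovery cohort: n = 225 with responder fraction 98/225; moderate shifts
(0.45–0.7 SD) for TMB, neoantigen burden, TCR entropy and PDL1; a
response-flag prevalence difference (0.25 vs 0.08); rare outcome-neutral
resistance alterations (1%); null HED and B2M; and a planted TMB–neoantigen
Spearman correlation of 0.9. Under these defaults the fitting pipeline
typically selects four biomarkers with the neoantigen burden pruned as the
weaker member of the TMB pair — the qualitative selection structure the
score was designed around.

`simulate_raw_sample()` plants exact biomarker values into parseable raw
tables (variant, CNV, clonotype, neoantigen, counts, HLA) so every
derivation formula can be tested against known truth; realism targets the
parsers and formulas, not biology — no mutational signatures, no real
sequences, no batch effects. Passing tests on these data therefore
demonstrate correctness of the arithmetic and plumbing, not performance on
real cohorts. `simulate_survival()` draws exponential event times with a
group hazard ratio and independent uniform censoring on $(0, \tau)$, with
$\tau$ solved numerically so the expected censoring fraction matches the
configured rate.

Reproducibility: one root seed is expanded into per-purpose streams through
a fixed linear mixing scheme, so panels, survival and raw samples each have
their own stream and results do not depend on call order. Identical seed
and configuration give identical output.

## Problem sizes in the test suite

The stochastic checks run at sizes chosen to give stable Monte-Carlo
estimates while keeping the suite quick on a laptop: null calibration of
the selection step uses 1000 replicate cohorts of n = 100 (the
Mann–Whitney selection rate per continuous biomarker must land in
[3%, 7%] at α = 0.05; the Fisher-tested flags are asserted conservative,
≤ 7%, since Fisher's exact test sits below its nominal level at moderate
prevalence — a property of the test, not a defect); planted-effect
recovery and hazard-ratio consistency each use 200 replicates (n = 100
cohorts with +2.0/+1.0 SD planted shifts; n = 400 survival draws with
hazard ratio 0.5 and 20% censoring).

## Known limitations

* The score is only as good as its inputs: variant calling, CNV calling,
  HLA genotyping, neoantigen prediction and clonotype assembly all happen
  upstream and are consumed as tables.
* Expression inputs are assumed batch-homogeneous or pre-corrected; no
  batch correction is performed here.
* The packaged groove-sequence table is synthetic; HED values computed from
  it are structurally correct but not biologically meaningful.
* Fisher's exact selection is conservative for rare flags: genuinely
  informative but rare alterations (like resistance-pathway hits) need
  larger cohorts to be selected.
* No multivariable survival modeling, cross-validation machinery, or
  machine-learning comparison model is included.
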