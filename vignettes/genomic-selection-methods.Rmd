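---
title: "Methods: simulating and evaluating single-step genomic selection in a family-based salmon program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating single-step genomic selection in a family-based salmon program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`salmogs` re-creates, end to end, the machinery of a family-based Atlantic
salmon breeding program that transitions from pedigree BLUP to single-step
genomic BLUP (ssGBLUP): a breeding-program simulator, genotype QC and
parentage assignment, relationship matrices (A, G, G*, H), multi-trait
mixed-model evaluation, two-tier SNP panel design, family + population
imputation, and the selection-index/validation layer. This vignette is the
package's account of the models, the tunable parameters, and the design
choices made where the design was genuinely open. No empirical claim is made
here that the test suite or `scripts/acceptance.R` does not itself compute.

## The breeding program being emulated

The simulated program mirrors a sib-testing aquaculture design. Each year
class, parents are crossed in a partial factorial in which **every sire and
every dam is used in exactly two crosses** (so `families_per_year` crosses
need `families_per_year / 2` parents of each sex), families contribute
`pool_per_family` eyed-eggs to a communal pool, and a random sample
(`progeny_genotyped_per_year`, default 8000 of 50,000) is tagged and
genotyped. Of the sampled fish, 3/8 stay in fresh water as broodstock
candidates; the rest are marine-tested and never return. Marine traits
(harvest weight, disease scores, marine maturation, flesh quality) are
therefore measured only on sibs of the selection candidates; freshwater
weight and maturation are measured on the candidates themselves. Males spawn
from age 2, females from age 3, and ~15% of each year's parents are repeat
spawners, which together with overlapping sib relationships links year
classes genetically.

Phenotype timing is compressed into one rule: every record becomes available
two years after its cohort's spawning (`availability_year = birth_year + 2`),
matching the production lag that drives the validation design below. One
simplification follows from it: in the first simulated year no evaluation
data exist, so the first parents are taken in id order — identically in both
schemes, which keeps scheme comparisons paired.

## Trait model

Traits are multivariate Gaussian with phenotype
`y = cohort + u_g + u_n + e`, where `u_g` is the additive value realized by
QTL dosages, `u_n` a full-sib family (common-environment plus non-additive)
deviation with covariance `G_n`, and `e` residual with covariance `R`.
Defaults (`saltas_trait_model()`) use the program's published heritabilities
— acquired AGD resistance 0.36, harvest weight 0.44, innate AGD resistance
0.16, maturation 0.20, flesh colour 0.65, flesh fat 0.28 — a common
environment fraction `c2 = 0.1` per trait (a typical full-sib tank value;
the source program does not publish its family variances), phenotypic
variance 1 per trait, genetic correlations of 0.63 between freshwater and
marine weight and 0.76 between the two maturation expressions, and zero for
pairs the program does not report. Heritability here is
`var(u_g) / (var(u_g) + var(u_n) + var(e))`. Binary traits such as
maturation are simulated and analyzed on a continuous scale, consistent with
the linear mixed models used operationally.

QTL effects are drawn multivariate normal across traits and rescaled so the
*sample* covariance of founder true breeding values equals `G_p` exactly —
an infinitesimal-like architecture justified by the GWAS screen finding no
large-effect QTL (`gwas_scan()` reproduces that screen: single-marker
regression with fixed covariates, Bonferroni-reported, no kinship correction
by default because it is a screen, with pedigree-BLUP pre-adjustment
available when structure matters).

## Founder LD by Markov copying

The only LD statement available for calibration is mean r² ≈ 0.2 persisting
to 500 kbp, so founders are not produced by a coalescent but by a cheaper
first-order copying walk whose single parameter is solved from that
statistic. Each haplotype carries a latent uniform retained between adjacent
markers with probability `exp(-lambda * gap)`; the allele is the indicator
that the uniform falls below the marker's frequency (drawn from a U-shaped
Beta(0.5, 0.5) truncated at MAF 0.02). Two loci are correlated exactly when
the latent value survives the walk between them, giving
`E[r²](d) = exp(-2 lambda d) * kappa`, with `kappa` the mean squared
frequency-mismatch factor over the spectrum; `lambda` is solved so the mean
r² at `ld_target_dist_bp` equals `ld_target_r2`. Consequences to keep in
mind: the decay is exponential with a ceiling of `kappa` (≈ 0.3) at zero
distance, so short-range LD is *lower* than in real dense data, and there is
no population-history structure (no bottleneck signatures, no variable
recombination). Meiosis is Haldane (Poisson crossovers, no interference) at
0.01 Morgans/Mbp — the conventional 1 Morgan ≈ 100 Mbp, unstated in the
source program.

What passing the fidelity checks shows is that the generator realizes the
configured h², genetic correlations and LD level; it does not show that the
imputation or prediction accuracies transfer quantitatively to real salmon
data, where LD structure, allele-frequency spectra and genotyping artifacts
differ.

## Relationship matrices and the mixed model

`numerator_relationship()` is the tabular method; `a_inverse()` uses
Henderson's rules with inbreeding. `genomic_relationship()` is VanRaden
method 1 with observed allele frequencies — the convention of the standard
single-step software stack; founder frequencies are not used because a real
program does not know them. `scale_blend_G()` first fits `a + bG` so the
mean diagonal and mean off-diagonal match `A22` (a two-statistic
compatibility fit; the underlying literature offers several variants and the
source program does not say which it used), then blends
`G* = (1 - tau) G_s + tau A22` with `tau = 0.05` — the polygenic weight is
likewise unpublished, and 0.05 is the common default. `h_matrix()` builds
`H^-1 = A^-1 + [0, 0; 0, G*^-1 - A22^-1]` and, for verification, the
equivalent joint-distribution form.

`build_mme()` assembles R⁻¹-weighted Henderson equations for the multi-trait
animal model with trait-by-cohort cell-mean fixed effects, trait-by-family
random effects (`G_n ⊗ I`) and trait-by-animal effects (`G_p ⊗ K`,
`K ∈ {A, H}`). Variance components are *inputs* (REML is out of scope);
tests and analyses use the simulation's true values. Residual covariance
between traits an individual cannot co-express (fresh vs marine) is
irrelevant by construction and fixed at zero in the default trait model.
Dense Cholesky is the default solver with a Jacobi-preconditioned conjugate
gradient as the cross-check; prediction error variances are the animal-block
diagonals of the inverse coefficient matrix, so an individual carrying no
information reports its prior additive variance. Repeated AGD scores are
modeled as distinct correlated traits, not a repeatability model, matching
how the program lists them; the derived acquired-resistance value is a
weighted combination of the score breeding values (`acquired_agd_bv()`),
with equal weights by default because the combination weights are not
published.

## Panels and imputation

The high-density design (`design_hd_panel()`) follows the segment-tagging
recipe: keep everything that survives LD pruning at r² < 0.2 (greedy
left-to-right, first-kept tie-break — the pruning algorithm itself is not
specified in the source, so the simplest deterministic one is used) plus all
trait-associated markers, then fill 100 kbp bins by a deterministic
rank-sum score (MAF rank minus local-LD rank), covering every feasible bin
once before any bin gets a second filler. Bins follow the 1-based convention
`[k*100000 + 1, (k+1)*100000]`. The low-density design picks one HD marker
per even physical window with the same score, force-including trait markers.
"Optimize" steps in the source are realized as these reproducible rank rules
on purpose: a documented deterministic rule can be replaced, a heuristic
cannot be re-run.

Imputation is a two-stage scheme of this package's own design (the
operational program used an external imputer whose algorithm is not restated
in the source): (1) `mendelian_impute()` iterates to a fixed point filling
only *forced* genotypes (parents 0×0, 0×2, 2×2; a missing parent becomes
heterozygous when its offspring include opposing homozygotes), never
overwriting observations and flagging — not repairing — inconsistent trios;
(2) `population_impute()` slides non-overlapping windows of
`window_markers = 20` markers and fills each gap by the majority vote of the
`n_neighbors = 5` reference *genotype* templates with the lowest dosage
mismatch against the target's observed markers in the window (chromosome-wide
mismatch as tie-break and fallback; voting ties resolve to the reference-wide
modal dosage, then the lower dosage). Dosage templates rather than phased
haplotype pairs keep the matcher deterministic and O(targets × references)
per window; the cost is some accuracy at low panel densities, which the
masking validation quantifies rather than hides. `mask_and_validate()`
implements the masking design — newest year class masked to a panel,
imputed from all older data, accuracy = proportion of masked,
originally-called genotypes imputed to the identical dosage (genotype-wise,
not allele-wise; the source does not say which it used) — and optionally the
Spearman concordance between GEBV from imputed and original genotypes.

## Selection, gain, and validation

Breeding values are standardized to genetic-SD units; the index applies the
published selection pressures (38/25/13/13/13, fat monitored at 0) after
normalization. `select_parents()` truncates within sex with an optional
full-sib family cap and id tie-breaks. `genetic_gain()` reports year-class
means, cumulative gain against a baseline, and the least-squares slope;
simulation output defaults to genetic-SD units because the founder
phenotypic baseline of a simulated program is arbitrary (percent-of-baseline
is available for real data). `validate_accuracy()` reproduces the
spawning-vs-updated design: the truth proxy is the updated run (two or more
years later) with the lowest mean standard error, preferring the genomic run
on ties as the operational program did; the index column is recomputed from
the updated breeding values rather than carried over. `compare_schemes()`
runs paired replicates (same founders and stage seeds) under GEBV- and
EBV-based selection and summarizes the ratio of mean index gains with a
paired bootstrap CI; the ratio of means rather than mean of ratios is used
because per-replicate ratios are unstable when the null (selection-off) gain
is near zero.

## Problem sizes and numerical choices

Desk-scale runs stand in for the production scale throughout the tests,
analysis scripts and acceptance script: 2 chromosomes × 50 Mbp with 600–5000
markers represent the genome and the ~45K standard set; 8–40 families and
80–400 sampled progeny per year class represent the 200/8000 program; the
1K/3K assays are represented by 100/300-marker panels against the 5000-marker
standard set. Directional conclusions (denser panels impute better, GEBV
discriminate within family, genomic selection accelerates index gain) are
insensitive to this scaling; absolute accuracies are not and should not be
read as predictions for the full-scale program. Other fixed choices:
simulation RNG is one master seed with named stage substreams
(`stage_seed()`), so every stage is independently reproducible;
`solve_mme()` tolerance is 1e-10 relative; G is built only over polymorphic
markers and errors on monomorphic input rather than silently repairing it;
QC keeps markers at exactly MAF 0.02 (the keep-condition is "> 0.02" read as
the removal rule "< 0.02" so boundary markers are not discarded); QC removes
markers first (on all individuals) and then individuals in full mode, so a
rerun at the same thresholds is a no-op on realistic data; parentage
assignment adds a margin rule (best pair must beat the runner-up by 0.02
mismatch rate) that the operational description lacks, to avoid false
assignments among close relatives and duplicated samples.

## Known limitations

REML variance estimation, threshold models for binary traits, dominance and
epistasis, probabilistic (dosage) imputation output, optimal-contribution
selection and economic weighting are all out of scope. The LD generator
trades realism at short range for a one-parameter calibration; the
population imputer is a deliberately simple template matcher, not an HMM.
Validation truth in simulation is the true breeding value or the
lowest-SE updated run — both proxies, and the second inherits the models'
assumptions.
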