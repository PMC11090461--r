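---
title: "Microbiome-enabled genomic selection: models, simulation design and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbiome-enabled genomic selection: models, simulation design and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic selection (GS) predicts a plant's phenotype from genome-wide markers
so that promising individuals can be selected before (or without)
phenotyping. Root-associated microbial communities — the rhizobiome — are
partly heritable and influence nutrient acquisition, which suggests that the
microbes a genotype recruits carry predictive information beyond the
genotype's own markers, particularly under nutrient stress. This package
implements microbiome-enabled genomic selection (MEGS): linear mixed models
that treat both SNPs and amplicon sequence variants (ASVs, the columns of a
16S-derived log relative-abundance table) as random effects, a
cross-validation protocol that guards against trivial explanations of any
accuracy gain, and a genome-wide mediation scan that asks which individual
microbes sit on the causal path from host genotype to phenotype.

## The prediction model

For plot-level observations in a two-nitrogen split-plot field trial, the
joint model is

$$
y_{ijkuv} = \mu + f_i + b_j + sp_u + spb_v
  + \sum_{l} \alpha_l g_{kl} + \sum_{t} \gamma_t m_{ijkt} + \epsilon,
$$

with nitrogen treatment $f$, block $b$, split plot $sp$ and split-plot block
$spb$ as fixed factors (reference-coded, intercept always present), SNP
dosages $g$ (centered) with i.i.d. random coefficients
$\alpha_l \sim N(0, \sigma^2_\alpha)$, ASV log relative abundances $m$
(centered) with $\gamma_t \sim N(0, \sigma^2_\gamma)$, and residual
$\epsilon \sim N(0, \sigma^2_\epsilon)$.

**Variance plug-ins.** The two variance components are deliberately *not*
estimated jointly. $\sigma^2_\alpha$ (and the residual carried into the
joint solve) comes from a SNP-only single-component REML fit with the design
factors fixed; $\sigma^2_\gamma$ comes from an ASV-only REML fit whose fixed
part additionally contains the first three genotype principal components, so
broad genomic background does not masquerade as microbial signal. The joint
system is then solved by Henderson's mixed-model equations at those fixed
variances, which is equivalent to generalized ridge regression with
per-block penalties $\sigma^2_\epsilon/\sigma^2_\alpha$ and
$\sigma^2_\epsilon/\sigma^2_\gamma$. The residual for the joint solve is
taken from the SNP-only fit; this is a stated convention (`fit_megs` logs
all three plug-ins in `meta$plugin`).

**REML.** Each single-component fit uses the spectral trick: rotate onto an
orthonormal basis of the fixed-effects complement, eigendecompose the
covariance kernel once, and optimize the restricted likelihood over the log
variance ratio on $[-10, 10]$ with `stats::optimize` (a bracketed
golden-section/parabolic search, tolerance $10^{-8}$). The kernel is
normalized to unit mean diagonal first, so the bracket covers ratios from
$e^{-10}$ to $e^{10}$ on the heritability-like scale; a solution at the
lower bracket end is a boundary maximum and is reported as exactly zero
variance (flagged in `meta$boundary`), so an inert random component
collapses the fit to the baseline exactly rather than leaving a numerically
tiny residue of it. The test suite verifies the estimates
against `lme4` on grouped data and the profile's local-maximum property by
bracketing.

**Solvers.** When columns outnumber rows the $n \times n$ kernel system
$V = \sigma^2_\alpha ZZ' + \sigma^2_\gamma MM' + \sigma^2_\epsilon I$ is
solved by Cholesky; otherwise the explicit column system. Both routes are
asserted to agree to $10^{-8}$, and against a dense closed-form generalized
ridge oracle, on randomized instances up to 200 rows by 500 columns.

The conventional baseline (`fit_gblup_genotype`) is genotype-level BLUP with
covariance $A\sigma^2_g$, where $A$ is the VanRaden method-1 additive
relationship matrix ($WW' / 2\sum p_k(1-p_k)$ on mean-imputed centered
dosages); taxonomic-group abundances can enter as a second,
identity-covariance random component to treat microbes as
microenvironmental covariates.

## Evaluation protocol

Accuracy is the Pearson correlation between predicted and observed phenotype
over held-out plots in randomized five-fold cross-validation. Three design
choices matter:

* **Genotype-disjoint folds.** Genotypes are partitioned, and every plot of
  a genotype inherits its fold, so a genotype never appears on both sides
  of a split.
* **Variance components are re-estimated inside each training fold** — the
  default guards against leakage; whole-data plug-ins would mix test
  information into the penalties.
* **The shuffled-microbiome control.** The microbiome matrix's rows are
  permuted within nitrogen treatment (or treatment × quadrant, the
  block × split-plot cell), exactly preserving each stratum's row multiset.
  This arm has the same dimensionality and marginal distribution as the
  real microbiome but no plot-level linkage, so "more covariates" alone
  cannot explain a gain. Fold seeds are shared across arms, making
  comparisons paired.

Arms are compared by a two-sided paired t-test on fold-level accuracy pairs
(a Wilcoxon signed-rank option exists); the star convention is
ns / * / ** / *** / **** at 0.05 / 0.01 / 0.001 / 0.0001. Accuracies are
summarized both per fold and per repeat. Relative improvement is
$(r_{\text{full}} - r_{\text{base}})/r_{\text{base}}$, undefined at a zero
baseline.

## Mediation scan

The scan implements the two model equations above transparently. For ASV
$j$, the mediator model is $M_j = Q A_j + Z B_j + e_j$ and the outcome model
is $y = Qv + Za + Mc + e$, where $Q$ column-binds an intercept, the first
three genotype PCs, and the design-factor dummies (11 columns at the default
cardinalities). Estimation is two-stage ridge: $A_j$ by GLS with $B_j$ as
REML-shrunk random SNP coefficients; the outcome model reuses the plug-in
two-component solver with $Q$ fixed.

Significance is permutation-based, with two constructions chosen for exact
symmetry and speed:

* **Genetic path.** A kernel score statistic $r' K r / r'r$, where $r$ is
  $M_j$ residualized on $Q$ and $K = ZZ'$ (normalized). Genotype labels are
  permuted; because the kernel depends on plots only through their genotype,
  the quadratic form collapses to genotype-level sums (an exact identity),
  and because the PC columns of $Q$ are themselves functions of the
  genotypes, they are permuted together with the kernel before
  residualization. Without that second step the test is severely
  conservative (the observed statistic has its top kernel directions
  projected out; permuted ones do not).
* **Phenotype path.** The score-form ridge coefficient evaluated at the
  null (no-mediator) variance structure,
  $|M_j' V_0^{-1}(y - Qv_0)|$ with $V_0$ from the SNP-only fit — the
  standard score-test construction. The microbiome rows are permuted
  *jointly* within treatment (the same scheme as the shuffled CV control),
  preserving inter-ASV correlation under the null, with the weight vector
  frozen; each permutation is then an $O(np)$ cross product. Evaluating the
  score under the null model rather than the full ridge matters for power:
  the full-model weights absorb precisely the mediator signal being tested.

Both tests' null calibration (uniform p-values) is verified by simulation in
the test suite. An ASV is called a mediator only when *both* paths are
individually significant (joint-significance / MaxP: the joint p-value is
the larger of the two), with Benjamini–Hochberg FDR across the scan.

**Resolution of permutation p-values.** With $B$ permutations the smallest
attainable p-value is $1/(B+1)$. A BH threshold of $0.05\,k/p$ at $p = 500$
ASVs requires p-values near $10^{-3}$ or smaller, so scans meant to call
mediators genome-wide need $B \ge 2000$; the `n_perm = 200` default is a
floor suitable for single-ASV follow-up, and the package's own power
studies use $B = 2999$–$4999$.

## The synthetic hologenome generator

The generator emulates the study conditions end to end, with defaults fixed
to the emulated trial: 230 genotypes in 2 nitrogen treatments × 2 blocks,
4 split plots and 3 split-plot blocks assigned by spatial nesting, i.i.d.
plot dropout at rate $1 - 795/920 \approx 0.136$ (the observed plot count;
the true missingness mechanism is unknown, so Bernoulli dropout is the
simplest stated rule), 3,626 ASVs in 154 groups nested in 19 classes, and
50,000 markers. "Quadrant" is defined as the block × split-plot cell.

* **Genotypes.** Per-marker minor allele frequencies are uniform on the
  configured range; LD comes from a block copula (exchangeable latent
  Gaussian correlation 0.9 within blocks of `ld_block_size` adjacent
  markers, thresholded to two gametes) — cheap, controllable LD for pruning
  tests. Markers sit on a synthetic grid: 100 bp within blocks, 20 kb
  between blocks, ten chromosomes.
* **Microbiome.** Log relative abundances are generated directly on the log
  scale (the modeling scale; no compositional renormalization): intercept +
  treatment/block/split-plot microenvironment effects + a sparse genetic
  component $Z B_j$ for heritable ASVs + noise. The genetic part is scaled
  so the genotype-attributable fraction equals `asv_h2`. Microenvironment
  effect SDs (0.2 treatment; 0.1 block/split-plot/split-plot-block, against
  plot noise 0.5) are deliberately modest so that the genotype-attributable
  fraction is nearly the same whether or not the design factors are
  conditioned out — this keeps the ANOVA repeatability estimate and the
  mediator model's conditional variance share mutually consistent.
* **Phenotype.** $y = \mu + \text{design FE} + Z\alpha + M\gamma +
  \epsilon$ with dense Gaussian $\alpha$ and sparse $\gamma$ on the causal
  set; each component is rescaled so the realized sample-variance shares
  equal `h2_snp` and `var_share_asv` exactly. Mediators are the
  intersection of the heritable and causal sets *by construction*; the
  remaining causal ASVs are drawn from the non-heritable pool, so only
  planted mediators carry both paths. With `treatment_specific = TRUE` the
  microbial term acts only on low-nitrogen plots (the LN-dominant
  scenario). `gamma_magnitude` switches the causal effects from N(0,1)
  draws to fixed-magnitude, random-sign effects scaled by each ASV's
  abundance SD — the "equal phenotypic contribution" design used by the
  mediation power study, where every planted mediator must clear a
  genome-wide FDR threshold, not just the average one.

Unstated-by-the-field defaults were chosen once as realistic for a
heritable vegetation-index trait: `h2_snp = 0.5`, `var_share_asv = 0.1`,
50 causal ASVs, 10 mediators, `asv_h2 = 0.3`.

**What the generator does not emulate:** sequencing counts and
compositionality (abundances are Gaussian on the log scale), library-size
effects, spatial autocorrelation beyond the split-plot factors, and
genotype × microbiome interaction. Passing tests therefore show that the
estimators recover the linear-mixed-model structure they assume — not that
real rhizobiome data satisfies that structure.

## Genotype preparation

Filters (missingness > 0.3, MAF < 0.05) precede LD pruning, which precedes
random subsampling — the pipeline order is fixed and logged. Pruning slides
a 10 kb window in 10 bp steps (half-open, 1-based physical coordinates) and
removes the later marker of any surviving pair with $r^2 > 0.1$; with the
default step this is effectively an exhaustive check of all pairs closer
than the window, which is what the brute-force oracle in the tests
enumerates. Monomorphic markers never trigger removal ($r^2$ treated as 0).
Missing dosages are mean-imputed for the GRM, PCA and model fitting (the
stated rule for general inputs; the emulated panel was already imputed).
PC scores fix their sign by making each component's largest-magnitude
loading positive.

## Microbiome preparation

Counts are converted to relative abundance per observation, zeros replaced
by half the smallest nonzero relative abundance (finite, strictly below
every observed value), and natural-logged (the log base is a package
convention; the choice only shifts effect scales). Taxonomic aggregation
sums relative abundances *before* re-logging, so a group's value remains a
composite relative abundance; summing on the exponentiated scale conserves
total abundance per observation exactly. Repeatability is the one-way
genotype-random ANOVA ratio per treatment, clipped to [0, 1]; "selection
score"-style annotations are accepted as inputs, not computed.

## Problem sizes used by the tests and acceptance script

The test suite and `scripts/acceptance.R` run the full pipeline at reduced
scale, chosen once as the smallest sizes at which each check is
well-powered: CV comparisons use 120 genotypes × 250 SNPs × 120 ASVs with 2
repeats of 5 folds over 20 simulated datasets per scenario (more repeats
would add *dependent* fold pairs and inflate the paired test's type-I rate,
so sample size, not repeat count, is the power lever); REML recovery
uses n = 300 with 500 markers over 100 seeds; the mediation power study
uses 200 genotypes × 200 SNPs × 500 ASVs with 10 equal-contribution
mediators and 2,999 permutations over 20 datasets, and the null
false-discovery study 50 datasets at 60 genotypes × 150 ASVs. The analysis
drivers under `analysis/` narrate one LN-dominant scenario at 100 genotypes
× 2,000 SNPs × 200 ASVs.

One subtlety in the type-I scenario: a "null" microbiome must be fully
decoupled from the phenotype. With `var_share_asv = 0` but heritable ASVs
present, the ASV table still correlates with the genetic component of $y$,
so the augmented arm genuinely differs from the baseline and a two-sided
comparison can correctly reach significance; the type-I study therefore
also sets `asv_h2 = 0`.

## Known limitations

* The plug-in variance scheme is faithful to the prediction protocol but is
  not a joint REML; standard errors of the BLUPs are not reported.
* The mediation estimator is a transparent two-stage ridge with
  permutation-calibrated MaxP — a deliberate, fully specified choice; other
  high-dimensional mediation estimators (penalized joint models, debiased
  tests) may differ in power and are out of scope.
* MaxP is conservative when only one path is null; the FDR guarantee is on
  the joint rule, and single-path ASVs are never called.
* Accuracy under real field data depends on microbiome stability over time
  and across environments, which a single-environment simulation cannot
  address.
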