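---
title: "Recessive-model association in admixed cohorts: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recessive-model association in admixed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

Genome-wide association studies of type 2 diabetes have overwhelmingly
used an additive genetic model, in which disease risk scales linearly
with the 0/1/2 dosage of an effect allele. For a variant whose effect is
truly recessive — only homozygous carriers are at elevated risk — the
additive test dilutes the homozygote signal across the (much larger)
heterozygote group and loses most of its power unless the allele is
common and the effect very large. In small, historically isolated
populations such as the Greenlandic population, common alleles with
large recessive effects are a realistic part of the genetic
architecture, and the correct coding of the test matters.

This package implements, end to end, the statistical machinery of a
recessive-model case-control discovery analysis in an admixed,
family-structured cohort:

1. a synthetic-cohort generator with the structure such analyses must
   cope with (two-way admixture, divergent ancestral allele
   frequencies, relatedness, a recessive-effect causal variant, OGTT
   phenotypes);
2. phenotype derivation from OGTT measurements (diagnostic
   classification, HOMA-IR, Gutt's ISI(0,120), rank-based inverse
   normal transformation);
3. additive-vs-recessive power simulation over an (EAF, OR) grid;
4. association testing: a linear mixed model for relatedness-aware
   discovery p values plus covariate-adjusted logistic regression for
   odds ratios, with GRM/PCA construction and genomic-inflation
   diagnostics;
5. a two-step bootstrap maximum-likelihood estimator of
   ancestry-component allele frequencies.

The numbered scripts under `analysis/` run these stages as a workflow
over one simulated cohort; everything they do is a call into the
package functions documented here.

# The disease model and its penetrance convention

Disease status at a causal SNP with dosage $g$ is Bernoulli with

$$
\Pr(D = 1 \mid g) =
\begin{cases}
b & g \in \{0, 1\} \\
\dfrac{\mathrm{OR}\cdot b/(1-b)}{1 + \mathrm{OR}\cdot b/(1-b)} & g = 2,
\end{cases}
$$

i.e. the homozygote probability is obtained by multiplying the baseline
*odds* by the odds ratio. With baseline risk $b = 0.1$ and
$\mathrm{OR} = 3$ the homozygote risk is exactly $0.25$. We deliberately
do **not** use a relative-risk convention ($\pi = \mathrm{OR}\cdot b$):
the odds ratio is the effect measure reported by the logistic analyses
this model feeds, and the two conventions diverge for large effects
(at $\mathrm{OR} = 10$, odds-multiplication gives $\pi = 0.526$ while a
risk-ratio reading would give an impossible $\pi = 1$ beyond
$\mathrm{OR} = 10$).

# The synthetic cohort

`simulate_cohort()` draws, in order:

* **Ancestry proportions** $Q$ ($n \times K$, rows on the simplex) from
  a Dirichlet distribution. The default concentration $(3, 1)$ gives a
  mean ancestry split of 75/25 with substantial per-individual spread,
  emulating a predominantly Inuit-ancestry cohort with European
  admixture. A zero concentration entry pins a component out, which is
  how unadmixed reference individuals are generated.
* **Ancestral allele frequencies** $F$ ($m \times K$)
  Balding–Nichols-style: for base frequency $p$ and divergence $d$,
  each component draws from
  $\mathrm{Beta}\!\big(p(1-d)/d,\ (1-p)(1-d)/d\big)$, which has mean
  $p$ and variance $d\,p(1-p)$. The default $d = 0.15$ produces
  frequency gaps on the scale observed between the Inuit and European
  components of real Arctic cohorts (e.g. 0.31 vs 0.03 at a strongly
  differentiated SNP). Draws are clamped to $[10^{-6}, 1-10^{-6}]$.
* **Genotypes**: dosage of individual $i$ at SNP $j$ is
  $\mathrm{Binomial}(2, p_{ij})$ with
  $p_{ij} = \sum_k Q_{ik} F_{jk}$ — the genotype model of the binomial
  admixture likelihood, and the Hardy–Weinberg assumption within
  ancestry strata. SNPs are independent: no linkage disequilibrium is
  simulated, so nothing downstream may rely on LD (regional plots and
  fine-mapping are out of scope by construction).
* **Disease status** from the penetrance model above, on a causal SNP
  always simulated without missingness.
* **OGTT phenotypes** conditional on status. Controls draw fasting
  glucose around 5.35 mmol/l (SD 0.4) and 2 h glucose around 5.9
  mmol/l (SD 0.95); cases around 8.2 and 12.6 mmol/l, with 45%
  additionally flagged as self-reported diabetes. Insulin is
  log-normal (fasting median 40 pmol/l, 2 h median 230 pmol/l, shifted
  upward for cases), weight normal (72 kg, SD 14). These values were
  chosen once so that the diagnostic thresholds (7 / 11.1 / 6.1 /
  7.8 mmol/l) re-identify most simulated cases and controls while
  leaving a realistic indeterminate fringe; they are plausibility
  dressing for the phenotype pipeline, not a calibrated model of any
  real cohort.

What the generator does **not** emulate: LD and haplotype structure,
X-chromosome inheritance, informative missingness (missing genotypes
are MCAR), assay error in the biochemistry, or ancestry-correlated
environment. Tests passing on this generator therefore demonstrate the
statistical machinery under its stated assumptions, not robustness to
those real-data complications.

All sampling flows from one explicit integer seed per operation; no
function consumes global random state without setting it.

# Phenotype derivation

**Classification.** T2D if self-reported diabetes, fasting plasma
glucose $> 7$ mmol/l, or 2 h glucose $> 11.1$ mmol/l; NGT (the control
class) if fasting $< 6.1$ and 2 h $< 7.8$ and no self-report; otherwise
INDETERMINATE (excluded from case-control contrasts). Boundary
equalities follow the strict inequalities, so 7.0 mmol/l fasting is not
a case and 6.1 is not a control. Self-report overrides measured values
— a treated diabetic with normalised glycaemia remains a case; the
alternative precedence is defensible but would misclassify treated
patients, and the choice is surfaced here because diagnostic criteria
in the source literature do not state it.

**HOMA-IR** is `fpg * (fins / 6.945) / 22.5` with glucose in mmol/l and
insulin in pmol/l (6.945 pmol/l per μU/ml).

**ISI(0,120)** is Gutt's index. Published renderings of the formula are
frequently garbled typographically; this package resolves it
dimensionally as
$$
m = \frac{75{,}000 + (G_0 - G_{120}) \times 18 \times 0.19 \times
\text{weight}}{120}, \qquad
\mathrm{ISI} = \frac{m}{\bar G \cdot \ln \bar I},
$$
with $G$ in mmol/l ($\times 18$ converts the disposal term to mg/dl;
75,000 mg is the oral load), $\bar G$ the mean of the two glucose
values and $\bar I$ the mean of the two insulins converted to μU/ml.
The natural logarithm is used. Records whose mean insulin is $\le 1$
μU/ml (non-positive log) are flagged and returned missing rather than
failing a batch. Worked value used in the tests:
$(G_0, G_{120}, I_0, I_{120}, w) = (5, 6, 60, 300, 70)$ gives
$m = 623.005$, $\bar G = 5.5$, $\bar I = 25.92$, ISI $= 34.80$.

**Rank-based inverse normal transformation.** Within each sex-by-cohort
stratum, non-missing values are ranked (average ranks on ties) and
mapped to $\Phi^{-1}\!\big((r - 0.5)/n\big)$. The $(r-0.5)/n$ plotting
position is symmetric and maps an odd stratum's median to exactly 0;
other conventions (Blom, $r/(n+1)$) differ negligibly at GWAS sample
sizes but are not interchangeable in exactness tests, so the convention
is fixed and documented. Strata with fewer than two non-missing values
raise an error naming the stratum.

# Power simulation

The design grid crosses EAF $\in \{0.05, 0.10, \dots, 0.30\}$ with OR
$\in \{1.1, 1.2, \dots, 10.0\}$ — 540 cells, the OR axis built by
integer indexing ($1.1 + 0.1k$) so the 10.0 endpoint is exact. Each
replicate simulates $n = 2948$ genotypes $\mathrm{Binomial}(2,
\mathrm{EAF})$, disease status from the penetrance model, and fits two
logistic regressions: dosage coding (additive) and homozygote-indicator
coding (recessive). Power is the fraction of replicates whose two-sided
Wald p value falls below the study-wide threshold $4.3\times 10^{-7}$
(the Bonferroni level for 115,182 tests at family level 0.05). Choices
worth surfacing:

* **Wald rather than likelihood-ratio** p values: at $n = 2948$ the two
  are practically indistinguishable and Wald needs no second fit per
  replicate.
* **Degenerate replicates** (no homozygotes, non-convergence, or
  separation, detected as $|\hat\beta| > 15$) contribute $p = 1$, so
  power is estimated conservatively instead of silently conditioning on
  estimability. Their count is reported per cell.
* **No covariates** in the simulation: the data-generating model has
  none.
* **Per-cell seeds** derive deterministically from the master seed and
  the cell's position, so any cell is reproducible in isolation and
  cells can be distributed.

At the headline configuration (EAF 0.25, OR 3 — the scale of a real
Arctic-cohort recessive T2D variant) the recessive test has power
$\approx 0.80$ and the additive test $< 0.20$; the default replicate
depth is 20,000 per cell, and the bundled analysis script runs the
headline cell at 2,000 replicates (Monte-Carlo SE $\approx$ 0.9
percentage points), which is the depth the test suite also uses.

# Association testing

The engine mirrors the two-track design of mixed-model GWAS of binary
traits: **discovery p values** come from a linear mixed model applied
to the 0/1 status (the standard practice of GWAS LMM software, with the
documented caveat that a linear model on a binary outcome estimates
risk-difference-scale effects), while **odds ratios** come from
covariate-adjusted logistic regression with principal components.

**GRM.** Centered construction: missing dosages mean-imputed, columns
mean-centered, $K = X_c X_c^\top / m$, monomorphic SNPs dropped. A
standardized flavour (columns divided by $\sqrt{2p(1-p)}$) is
available; centered is the default of the mixed-model software this
re-implements. Note one exact consequence of centering used in the
tests: columns of $X_c$ sum to zero, so the off-diagonal mean is
exactly $-\overline{\mathrm{diag}}/(n-1)$.

**LMM.** $y = X\beta + g + e$ with $g \sim N(0, \sigma_g^2 K)$,
$e \sim N(0, \sigma_e^2 I)$. One eigendecomposition $K = UDU^\top$
rotates the model so the covariance is diagonal in
$\lambda = \sigma_g^2/\sigma_e^2$; the restricted likelihood is then a
one-dimensional function of $\lambda$, optimized on $\log_{10}$ scale
over $[10^{-5}, 10^5]$ with `optimize()` (tolerance $10^{-6}$), with
both interval endpoints checked so boundary solutions (no genetic
variance) are honoured. Per-SNP tests re-profile $\lambda$ exactly
(`ratio = "profile"`); a plug-in mode (`ratio = "null"`) reuses the
null-model estimate for speed — on the null-calibration experiment
below the two agree to the third decimal of the inflation factor. The
Wald test uses a $t$ reference with $n - p$ degrees of freedom. In the
batch scan missing dosages are mean-imputed (matching the GRM's
handling and keeping one rotation for all SNPs); the single-SNP
`lmm_assoc()` instead drops incomplete cases and subsets the GRM, which
is the exact treatment.

**Why the mixed model:** on a simulated null cohort of 100 six-sib
families ($n = 600$) with a fully polygenic trait drawn from the
realized GRM ($h^2 = 0.5$, $m = 20{,}000$ SNPs), plain regression shows
genomic inflation $\lambda_{GC} \approx 1.8$ while the LMM's p values
are calibrated ($\lambda_{GC} \in [0.95, 1.05]$). The acceptance suite
re-runs exactly this experiment.

**Genomic inflation** is
$\mathrm{median}\{\chi^2_1\text{-quantiles of } 1 - p\}/0.4549364$.

# Ancestry-component allele frequencies

The two-step estimator for a SNP of interest:

1. **Admixture proportions** $\hat Q$ by EM on the binomial admixture
   likelihood $\prod_{ij}\mathrm{Binom}(g_{ij} \mid 2, \sum_k Q_{ik}
   F_{jk})$ over all SNPs. Component labels are arbitrary; they are
   fixed either by supervised anchoring (clamping the $Q$ rows of
   reference individuals with known ancestry, the analogue of adding
   unadmixed European samples to the estimation) or post hoc with
   `align_components()`.
2. **Per-SNP frequencies** $\hat f$ by maximizing the same likelihood
   in $f \in [0,1]^K$ with $Q$ fixed (EM on $f$, log-likelihood
   tolerance $10^{-8}$), and **bootstrap CIs** from $B = 1000$
   resamples of individuals (dosage and $Q$ row jointly — the sampling
   unit is the individual, never alleles or SNPs), taking empirical
   quantiles (R type-7, level 0.95 by default; neither the level nor
   the quantile type is canonical in the source literature, so both are
   explicit arguments).

Numerical and degeneracy choices:

* Both EM loops use SQUAREM-style extrapolation with a plain-EM
  fallback whenever the extrapolated step does not improve the
  likelihood, preserving EM's monotone convergence while cutting
  iteration counts by one to two orders of magnitude near boundary
  optima (a recessive-relevant regime: interesting components often
  have frequencies near 0).
* Bootstrap replicates warm-start at the full-sample estimate.
* A component whose total ancestry mass $\sum_i Q_{ik}$ among
  non-missing individuals is below one individual-equivalent is
  **non-identifiable**: it is reported `NA` and flagged, never returned
  as an arbitrary interior number. Bootstrap replicates in which a
  component loses identifiability are excluded from that component's
  quantiles, with the valid count reported.
* $K = 1$ degenerates exactly to per-SNP sample frequencies.

**Problem sizing in the tests.** Per-individual ancestry error of the
EM scales roughly as $1/\sqrt{m}$ for fixed divergence. The recovery
check asserting every individual's $\hat Q$ within 0.05 of truth runs
at $m = 8000$ SNPs, where the cohort-wide maximum error is
$\approx 0.02$–$0.03$ and the check measures estimator correctness; at
$m = 2000$ the converged MLE's maximum error sits almost exactly on
0.05, i.e. the bound would be a coin flip over data seeds rather than a
test of the algorithm. Real MetaboChip-scale inputs
($m \approx 10^5$) are finer still. The bootstrap-coverage check (95%
CIs covering generating frequencies $(0.31, 0.03)$ in $\ge 90\%$ of 50
cohorts of $n = 3000$) uses $B = 500$ replicates per interval; $B$
affects only the Monte-Carlo noise of the interval endpoints, and the
package default stays at $B = 1000$.

# Reproducibility and problem sizes

Every stochastic function takes an explicit seed and derives any
internal per-cell or per-SNP seeds from it below $2^{31}$. The analysis
scripts use seed 1 throughout and write their tables under `results/`.
Problem sizes in the bundled scripts and tests (cohort $n = 2948$,
$m = 2000$ SNPs; power cells at 2,000 replicates; null-calibration scan
at $n = 600$, $m = 20{,}000$) were chosen as the smallest sizes at
which each quantity's Monte-Carlo error is well inside the scientific
claim being checked; the full 540-cell grid at 20,000 replicates per
cell is exposed through `run_power_grid()` for users who want the
complete surface.

# Known limitations

* The LMM treats case-control status as a 0/1 quantitative outcome for
  discovery p values; effect sizes on that scale are risk differences,
  which is why odds ratios are taken from the logistic track.
* No LD, imputation dosages, X chromosome, or ancestry-specific
  effect-size decomposition (the latter is acknowledged as a distinct
  model and deliberately not reproduced here).
* The admixture EM is the classic multiplicative EM (accelerated);
  block-relaxation tricks of dedicated admixture software are not
  re-implemented, so very large $n \times m$ step-1 problems are slow
  relative to such tools.
* Bootstrap CIs are percentile intervals; near-boundary frequencies
  make them asymmetric and occasionally degenerate ($[0, 0]$ when no
  copies of the allele are resampled), which is reported rather than
  corrected.
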