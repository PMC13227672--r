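---
title: "Multi-kernel BLUP for multi-omics phenotype prediction: methods and design"
author: "omicBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kernel BLUP for multi-omics phenotype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicBLUP)
```

## The problem

Blood drawn from clinically healthy piglets before they enter a high
disease-pressure environment carries molecular state — transcript
abundances, plasma proteins, metabolite concentrations — that may predict
how the animal will later grow, stay healthy, or die under challenge.
omicBLUP asks the quantitative-genetics question: how much phenotypic
variance does each molecular layer capture, alone and together with
genomics, and how well does each combination predict phenotypes of a
*future batch* from the same breeding company?

The machinery is the linear mixed model familiar from genomic prediction,
with the genomic relationship matrix generalized to one similarity kernel
per omics layer.

## The model

For a trait vector $y$ over $n$ animals,

$$ y = 1\mu + Xb + Z_p p + Z_l l + \sum_k u_k + e $$

with fixed covariates $b$ (entry age, batch), random pen effects
$p \sim N(0, I\sigma^2_p)$, random litter effects
$l \sim N(0, I\sigma^2_l)$, residuals $e \sim N(0, I\sigma^2_e)$, and one
random animal effect per included kernel,

$$ u_k \sim N(0, K_k \sigma^2_k), $$

where $K_k$ is the relationship matrix of layer $k \in \{G, T, P, M\}$
(genomic, transcriptomic, proteomic, metabolomic).  Effects of different
kernels are assumed uncorrelated.  As a parsimonious alternative, the
selected kernels can be collapsed into their unweighted elementwise mean
$C = \frac{1}{n_K}\sum_k K_k$ carrying a single component $\sigma^2_c$
(`combined = TRUE` in a `ModelSpec`).  No cross-layer rescaling is applied
before averaging: comparability is provided by the feature standardization
below, and the equal-weight mean is understood as a pragmatic baseline, not
an optimal weighting.

The share of phenotypic variance attributed to the kernels is

$$ \hat h^2_{\text{omics,total}} =
   \frac{\sum_k \hat\sigma^2_k}
        {\hat\sigma^2_p + \hat\sigma^2_l + \sum_k \hat\sigma^2_k +
         \hat\sigma^2_e}, $$

with the per-kernel share defined analogously (`varianceReport()`).

## Kernels

**Genomic.** `buildGenomicKernel()` computes VanRaden method 1,
$G = W_c W_c' / 2\sum_j p_j(1-p_j)$ with dosages centered at $2p_j$,
separately per source company using within-company allele frequencies, and
assembles the blocks on the diagonal; cross-company entries are exactly
zero.  This restricts relationships to within-company comparisons — the
structure under which pooled within-company variance components are
meaningful.  SNPs monomorphic within a company are excluded from that
block's centering and denominator.  Method 1 with observed within-company
frequencies is a documented assumption; the centering/scaling variant of
the original software pipeline is not printed anywhere we could follow.

**Omics.** Each layer is reduced to a residual-standardized matrix
$M$ (animals $\times$ features; see preprocessing), and
$K = M M' / p$ over its $p$ features (`buildOmicsKernel()`).  With
unit-variance columns the mean diagonal is $(n-1)/n \approx 1$.

**Stabilization.** Mixed-model solving needs factorizable covariance
matrices.  `stabilizeKernel()` raises the minimum eigenvalue to
$\varepsilon = 10^{-8}$ by adding $\varepsilon - \lambda_{\min}$ to the
diagonal when needed, recording the ridge in the object.  $10^{-8}$ is the
smallest target that reliably permits Cholesky factorization around
$n \approx 1000$ in double precision.

## Preprocessing

Each layer follows the field-standard route from raw values to $M$:

* **Transcriptome** — TMM scaling factors (edgeR; log-ratio trim 0.30,
  absolute-intensity trim 0.05, upper-quartile reference — the canonical
  published defaults, since only "TMM" is specified by the protocols we
  follow), CPM on effective library sizes, $\log_2(\mathrm{CPM}+1)$.
* **Metabolome** — features below the detection limit in >20% of samples
  or missing in ≥20% are excluded (note the two different comparators,
  applied independently); remaining missing cells are replaced by
  metabolite-specific medians; then $\log_2$.  The filter+imputation stage
  is idempotent; the log transform is applied once.
* **Proteome** — $\log_2$ abundances; missing-at-random cells filled by
  feature-wise K-nearest-neighbor imputation (`knnImpute()`): a missing
  cell of feature $j$ is the unweighted mean of the $k = 10$ features
  nearest to $j$ (root-mean-square distance on standardized, co-observed
  values, at least 3 co-observed animals), each neighbor value
  standardized on its own scale and mapped through feature $j$'s observed
  mean and SD.  $k = 10$ is a default, not a published value.
* **Genotypes** — call-rate filters (SNP > 0.90, individual > 0.90, both
  strict, evaluated on the input matrix in one pass) then MAF > 0.05 on
  the survivors; remaining missing dosages mean-imputed per SNP.  One
  subtlety forced the one-pass choice: with strict thresholds and
  sequential re-filtering, a surviving SNP could never retain a missing
  call in small cohorts, making the individual-rate rule vacuous.

**Imputation validation** (`validateImputation()`) mirrors the standard
masking experiment: per repeat, randomly selected features each have half
of their observed cells held out, one feature at a time, re-imputed, and
correlated with the originals; features whose mean correlation over
repeats exceeds 0.4 are retained.  Masking a feature's *entire* observed
vector — the literal description of the experiment we follow — is undefined
for feature-wise KNN (no co-observed animals to compute distances, no
observed mean/SD to map back), so the 50% holdout is the package's design
choice.  Two consequences are documented behavior: features never sampled
across repeats are *not* dropped (no evidence against them), and with pure
noise the per-feature mean accuracy is not centered exactly at zero — KNN
neighbor selection picks the most chance-correlated features, so spurious
accuracy of order $1/\sqrt{n}$ (amplified by neighbor averaging) survives
repetition.  Retention at the 0.4 rule is unaffected at realistic $n$.

**Residualization** (`residualizeFeatures()`).  Every feature is adjusted
by the mixed model

$$ y_f = 1\mu + Xb + Z_p p + e, \qquad p \sim N(0, I\sigma^2_p),\;
   e \sim N(0, I\sigma^2_e) $$

with layer-specific fixed effects (transcriptome: batch, enrichment-toy
status, entry age, RNA integrity number; proteome and metabolome: batch
and entry age) and pen-within-batch random.  All features of a layer share
the design, so the pen cross-product is eigendecomposed once and each
feature reduces to a one-dimensional profiled REML search over
$\lambda = \sigma^2_p/\sigma^2_e$, bounded on $[0, 10^6]$ — fast enough
for tens of thousands of features and robust by construction.  A failed
search falls back to the $\lambda = 0$ limit (OLS residuals), flagged in
the provenance.  *Conditional* residuals
$\hat e = \hat\sigma^2_e V^{-1}(y - X\hat b)$ are used (the pen BLUP is
removed), a deliberate choice where marginal residuals would also have
been defensible.  Each feature is then divided by the empirical SD of its
residuals, which makes the column exactly mean-zero and unit-variance —
the property the kernel scaling relies on.  Features with numerically zero
residual variance are dropped as degenerate.

## REML

`fitREML()` maximizes the restricted likelihood of
$V(\theta) = \sum_k \theta_k V_k + \theta_e I$ by average-information (AI)
steps with three safeguards:

* **Step halving** — an AI proposal is accepted only if the restricted
  log-likelihood does not decrease; otherwise the step is halved (up to 12
  times).
* **EM-type fallback** — if no AI step improves, the multiplicative update
  $\theta_k \leftarrow \theta_k \cdot (y'PV_kPy)/\mathrm{tr}(PV_k)$ is
  tried (positive by construction, fixed point where the gradient
  vanishes), again with halving.
* **Active set** — components driven below $10^{-8}\times$ the
  fixed-effects residual variance with a non-positive gradient are pinned
  at zero and released only if the gradient turns positive.

Only improving iterates are recorded, so the likelihood trace is
non-decreasing by construction (a validity condition of `VarCompFit`).
Convergence requires both a log-likelihood change below $10^{-6}$ and a
maximum relative component change below $10^{-4}$, within 200 iterations;
a fit that does not get there returns `converged = FALSE` rather than an
error, because non-convergence of over-parameterized multi-kernel models
is an expected outcome that downstream tables must display (and
cross-validation must skip), not hide.  Components are initialized at an
equal split of the fixed-effects residual variance — a neutral,
reproducible start.

Per-iteration cost is one Cholesky and one inverse of $V$: the traces
$\mathrm{tr}(PV_k)$ are elementwise sums $\sum P \circ V_k$ and the AI
matrix needs only matrix–vector products, so $n \approx 800$ fits take
about a second on one core.  Binary traits are fitted with the same linear
model (linear BLUP on 0/1 outcomes); no threshold-model likelihood is
implemented.

Two identities anchor correctness and are asserted in the tests: the
single-kernel fit agrees with a one-dimensional grid/profile search of the
restricted likelihood, and kernel-based BLUPs equal ridge SNP-effect
predictions mapped through centered dosages (GBLUP ↔ SNP-BLUP).

## Leave-one-batch-out validation

`planFolds()` builds one fold per batch within every company holding at
least three batches; the batch is validation, the company's other batches
are training.  Per fold, `runCV()`:

1. drops fixed factors whose validation levels are unseen in training
   (always the batch factor — it is confounded with the split; its
   adjustment falls to the intercept, and the event is logged);
2. fits the kernel-free baseline (fixed + pen + litter) on the training
   batches and corrects phenotypes; validation animals are corrected with
   the training-fold fixed-effect estimates (their pen/litter BLUPs are
   zero — new levels).  Whether the original analyses adjusted globally or
   per fold is ambiguous; per-fold is the default because it cannot leak
   validation information, and `adjustMode = "global"` provides the other
   reading;
3. fits the full model on the raw training phenotypes;
4. projects each kernel effect onto the validation animals,
   $\hat u_{val} = K_{vt}(K_{tt} + 10^{-8}I)^{-1}\hat u_{tr}$ — the
   conditional mean, identical to solving the mixed-model equations with
   validation phenotypes absent (asserted against a Henderson-system
   oracle) — and sums them into the prediction score;
5. correlates scores with corrected phenotypes.

The trait-level accuracy is the sample-size-weighted mean of fold
correlations over folds whose REML fit converged; zero-variance-score
folds (typical when a component pins at zero under a null trait)
contribute to neither numerator nor denominator and are logged.  For
binary traits, out-of-sample scores are pooled across folds — each animal
exactly once — and summarized as a midrank AUC (ties count one half),
which stays defined when single batches contain only cases or only
controls.

## The synthetic cohort generator

No animal data ship with the package; `simulateCohort()` produces cohorts
whose generative model *is* the analysis model, with known variance
components, so every stage is testable end to end.

Defaults emulate the study design the package targets: 7 companies
contributing 15 batches (2, 4, 1, 3, 3, 1, 1 — exactly three companies
reach the 3-batch threshold for fold planning), 56 animals per batch
($n = 840$), 4 pens and up to 12 litters nested per batch, a 1000-SNP
panel with MAF uniform on (0.05, 0.5) and per-company logit-normal
allele-frequency jitter (sd 0.3) so the block-diagonal genomic kernel is
exercised non-trivially, and three omics layers.  Each feature is a
genetically anchored mixture: a standardized random-weight combination of
a 20-SNP subset (weight `geneticAnchor`, defaults 0.3/0.25/0.2 across
layers) plus batch (10% of the non-genetic share), pen (5%) and
independent noise (85%).  Transcript counts arise by pushing the latent
signal through a log-link into negative-binomial sampling (size 20,
lognormal library-size factors), proteome abundances are $2^{16+1.2z}$
with 10% missing-at-random cells, metabolome concentrations are
$e^{\log 80 + 0.8 z}$ with the lowest 5% per feature masked as below the
detection limit.  Phenotypes are drawn from the mixed model with kernel
effects sampled as $u_k \sim N(0, K_k\sigma^2_k)$ from the realized truth
kernels; binary traits threshold a liability composed of the random terms
only, so expected prevalence is exactly
$1-\Phi(\tau/\sigma_{\text{liab}})$.  One master seed drives per-stage
substreams; identical configs give bitwise-identical cohorts.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: linkage disequilibrium and pedigree
relatedness (genotypes are unlinked and animals unrelated, a stated
non-goal), so within-company kernel off-diagonals are much smaller than in
real half-sib populations and absolute LOBO accuracies on synthetic
defaults are modest; trait-specific fixed-effect lists (the published
lists live in a prior study and are replaced by a minimal entry age +
batch stand-in); pathogen exposure dynamics; and raw-signal artifacts
(alignment, spectral deconvolution, isobaric-label interference).

## Reporting and orchestration

`runPipeline()` chains simulate → preprocess → kernels → variance fits →
cross-validation from a single YAML config and writes delimited tables
(one row per trait × model, mirroring the supplementary-table layout of
variance-partition studies), per-fold detail, barplots, and a JSON
manifest with config hash, seed, package version and per-file digests;
reruns of the same config are byte-identical.  The model grid over four
layers comprises 15 subset models plus 11 combined-mean variants (subsets
of size ≥ 2) = 26 specifications (`enumerateModelSpecs()`).  A thin
Rscript wrapper lives in `inst/scripts/omicblup-pipeline.R`; the package
functions are the primary interface.  Per-stage digest caching was
considered and dropped: at the problem sizes the package targets, a full
rerun is cheaper than cache invalidation is risky.

## Numerical choices, at a glance

| Quantity | Value | Why |
|---|---|---|
| Kernel ridge target $\varepsilon$ | $10^{-8}$ | smallest reliable Cholesky margin at $n \approx 1000$ |
| REML tolerances | $\Delta\ell < 10^{-6}$, rel. $\Delta\theta < 10^{-4}$ | conventional AI-REML stopping, both required |
| REML iteration cap | 200 | non-convergence is reported, not raised |
| Component floor | $10^{-8} \times$ residual variance | active-set pinning threshold |
| Eq.-ratio search bound | $\lambda \in [0, 10^6]$ | profiled residualization solver |
| KNN | $k = 10$, ≥3 co-observed, unweighted | defaults; distance ties broken by column order |
| Validation projection ridge | $10^{-8}$ | keeps $K_{tt}$ solvable; error ≪ the $10^{-6}$ oracle bound |

Test and acceptance runs use deliberately scaled problem sizes — cohorts
of 90–840 animals, 100–2500 features, 20-replicate calibration loops at
$n \approx 800$ — chosen so the whole suite exercises every code path at
full fidelity while completing in minutes on one core.

## Limitations

Variance shares from kernels built on features measured once in early life
mix genetic signal, early environment and transient physiology; nothing in
the machinery separates these.  Identity-kernel sets are unidentified
beyond their sum (the REML solver correctly returns an arbitrary split
with the right total).  The equal-weight combined kernel presumes equally
informative layers after standardization — a stated approximation, not a
finding.  And all calibration statements in the tests are statements about
the generator's world; transfer to real cohorts rides on how well the
mixed-model assumptions hold there.
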