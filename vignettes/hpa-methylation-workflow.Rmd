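---
title: "Targeted methylation analysis of HPA-axis genes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted methylation analysis of HPA-axis genes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

hpamethyl implements a targeted epigenome-wide association workflow for
comparing buccal-mucosa DNA methylation between former paediatric-intensive-care
(PICU) patients and healthy children across a panel of
hypothalamus–pituitary–adrenal (HPA) axis genes. This vignette is the
package's own account of the statistical machinery: the models, the tunable
parameters and their defaults, the synthetic cohort the tests run on, and the
design decisions taken where the methodology left room.

## Data model

Methylation at a CpG site is a *beta value* — the proportion methylated, in
$[0,1]$. The pipeline's central object is a probes × samples beta matrix
(`meth_set`), optionally paired with a detection p-value matrix of the same
shape. Modelling happens on the *M-value* scale,

$$M = \log_2\!\frac{\beta}{1-\beta},$$

which is unbounded and closer to homoscedastic. Betas are clipped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ before the logit,
bounding $|M|$ at about 19.9 and avoiding infinities; the inverse transform is
exact for unclipped values. Effect sizes are reported on both scales: the
adjusted log fold change in M values, and the unadjusted absolute difference
in group mean beta values (which is what a clinician can read as "percent
methylation difference").

Genomic coordinates are 1-based, closed intervals internally; BED input
(0-based, half-open) is converted on read (`pos = start + 1`). Missing
measurements are explicit `NA`s, never sentinel zeros, and each operation
documents whether it accepts them.

## Quality control

**Samples.** A clean buccal-swab methylation profile is bimodal, with modes
near 0.1 and 0.9. Rather than counting density modes — which would need a
bandwidth choice of its own and is sensitive to sample order and estimator
details — `sample_qc()` uses a mid-band-fraction rule: a sample fails when
more than `midband_threshold` (default 0.4) of its beta values fall strictly
inside (0.3, 0.7). A genuinely bimodal sample puts only a few percent of its
mass there; a degraded, mid-heavy sample puts most of it there, so the rule
separates the two regimes with a wide margin and is deterministic and
order-free. Samples known to have failed upstream for insufficient DNA yield
are merged into the report with their own failure reason.

**Probes.** A probe is removed when its detection p-value exceeds 0.01 in at
least 50% of samples, or when it is annotated as spanning a single-nucleotide
polymorphism. The 50% rule is applied *inclusively* (`>=`), the conservative
reading of the boundary case; both the threshold and the fraction are
arguments. Control probes are exempt from the SNP rule (a flagged control
probe is a likely annotation error; the flag is dropped with a warning).

**Normalization.** `quantile_normalize()` forces every sample's beta
distribution onto the across-sample mean quantile curve (ties share the mean
of their quantile span), preserving within-sample ranks; it delegates to
`limma::normalizeQuantiles()`. Quantile normalization is the default with a
switch to none — the upstream processing this workflow models does not pin
down a specific normalization, and the group contrast is robust to the
choice because it acts within probes.

**Age at exposure.** Patients carry their age at PICU admission. Controls
were never admitted, so their age at exposure is imputed as the follow-up
age minus two years (the follow-up happens two years after the patients'
exposure); a negative imputed age is an error naming the sample.

## Technical-variation adjustment

Batch and other technical variation is adjusted with principal components of
the technical control probes, in the tradition of control-probe-PC
adjustment for Illumina arrays: PCA is run on the probe-wise centred beta
submatrix of non-negative control probes, and the leading `n_pcs` (default
30) score vectors enter every downstream model as covariates. Two deliberate
choices:

* **Beta values, not intensities.** The original control-probe-PC method
  operates on raw channel intensities, which exist only inside IDAT files.
  This package's data model starts at beta values, so the PCA runs on
  control-probe betas. The latent structure that batch imprints on control
  probes is preserved either way, and the simulator's recovery tests confirm
  the PCs capture it.
* **Deterministic signs.** Each PC is flipped so its loading vector has a
  non-negative sum, making outputs reproducible across linear-algebra
  backends.

Requested components beyond the rank bound
$\min(\#\text{control probes}, n-1)$ are reduced with a warning;
zero-variance control probes are dropped. Centring is probe-wise with no
scaling by default (scaling is an option): control probes share a scale, and
scaling would inflate near-constant probes into noise directions.

## Per-CpG models

At each CpG the M values follow an ordinary least-squares model with a shared
design: the group contrast (patient vs control), baseline risk factors (age
at exposure, sex, centre, race, origins, malignancy, syndrome — whatever the
caller supplies), and the technical PCs. Categorical covariates are one-hot
encoded against a first-level reference so aliasing is detectable; a
rank-deficient design is an error listing the aliased columns.

**Empirical-Bayes moderation.** With modest group sizes the per-probe
variance estimates are noisy; the ensemble of probes is used to stabilise
them. The residual variances $s_j^2$ (df $d$) are modelled as draws from a
scaled inverse-chi-square prior with parameters $(d_0, s_0^2)$, estimated by
matching the first two moments of $\log s_j^2$ (digamma/trigamma equations;
the trigamma inverse is solved by Newton iteration). The posterior variance

$$\tilde s_j^2 = \frac{d_0 s_0^2 + d\, s_j^2}{d_0 + d}$$

yields a moderated $t = \hat\beta_j / (\tilde s_j \cdot \mathrm{se}_1)$
referred to a t distribution with $d_0 + d$ degrees of freedom, and 95%
confidence intervals on that same distribution. Degenerate branches are
explicit: a prior df of zero reproduces the ordinary t exactly, and when the
moment equations imply an infinite prior df (variance spread no wider than
sampling noise) every posterior variance equals $s_0^2$. The test suite
cross-checks the whole path against `limma::eBayes()` to near machine
precision and recovers known $(d_0, s_0^2)$ from simulated variances.

**Multiplicity.** Group-contrast p-values are Benjamini–Hochberg adjusted
(via `stats::p.adjust`; the test suite keeps an exhaustive step-up oracle),
and a CpG is a differentially methylated position (DMP) at FDR
$q \le 0.05$. Interaction and glucocorticoid p-values are reported
*unadjusted*: they are follow-up analyses evaluated only on the
already-identified DMP set, and adjusting them is left to the caller (an
argument, not a hard-coded policy).

**Interactions and the glucocorticoid contrast.** Sex and age-at-exposure
interactions add a group × covariate term to the same model and report the
moderated p-value of that term, on the DMP set only. The glucocorticoid
contrast refits within patients only — treated vs untreated — with the
extended covariate list (length of stay, admission diagnosis, severity
scores, randomisation arm, malnutrition risk) plus the technical PCs. Both
reuse the moderation machinery; with very small probe sets the data-driven
prior is unstable, so a forced prior df is accepted.

**Hypo/Hyper status** is assigned from the sign of the adjusted log fold
change (negative = hypomethylated in patients), which in the packaged
reference table agrees with the published status on all 26 rows.

## Region detection

Differentially methylated regions (DMRs) are found by kernel smoothing of
squared per-CpG statistics, the approach of the DMRcate family:

$$S_i = \frac{\sum_j w_{ij} t_j^2}{\sum_j w_{ij}}, \qquad
  w_{ij} = \exp\!\left(-\frac{(x_i-x_j)^2}{2\sigma^2}\right),
  \quad \sigma = \lambda / C,$$

with weights never crossing chromosome boundaries. Treating the inputs as
unit-df chi-squares, the Satterthwaite effective df of the weighted mean is
$\nu_i = (\sum_j w_{ij})^2 / \sum_j w_{ij}^2$ and the tail probability is
$P(\chi^2_{\nu_i} \ge \nu_i S_i)$; these are BH-adjusted and CpGs with
$q \le 0.05$ are agglomerated into maximal runs whose consecutive genomic
gaps never exceed $\lambda$. Defaults $\lambda = 1000$ bp and $C = 2$ are
the published defaults of that methodology; `min_cpgs = 2` so a lone
significant CpG never forms a "region". Width is `end - start + 1` under
the 1-based closed convention. Region direction is Hypo/Hyper when all
member effects agree and Mixed otherwise; region significance is summarised
as the minimum member q (a Stouffer-style summary would be a
straightforward extension, but minimum q is what the region tables report).
Input tables are canonically sorted by chromosome and position before
grouping, which makes the output invariant to input row order.

## Cross-validated robustness of outcome associations

For each (DMP, developmental outcome) pair, the association model is
`outcome ~ methylation + covariates` within patients on the non-missing
subset, with linguistic origin added to the baseline covariates because it
confounds the functional assessments. Robustness is assessed by repeated
k-fold cross-validation: per iteration the patients are partitioned into
`k_folds = 10` random disjoint folds, each fold yields one p-value for the
methylation term, the k p-values are combined by Fisher's method
($-2\sum\ln p \sim \chi^2_{2k}$), and the iteration is significant when the
combined p is at or below $\alpha = 0.05$. Over `n_iterations = 100`
iterations the percentage of significant iterations is the heatmap cell; a
pair is *significant* when its full-data p is at or below $\alpha$ and
*robust* when 100% of iterations are significant.

"The p-value of a test fold" admits two readings, and both ship behind
`fold_p_mode`:

* `per_fold_refit` (default): the full model is refit inside each fold and
  the methylation coefficient's p recorded. The k p-values come from
  disjoint subsamples, so Fisher's independence assumption holds by
  construction — which is why this is the default.
* `train_test_predict`: the model is trained on the other k−1 folds and the
  held-out fold contributes the p-value of the correlation between predicted
  and observed outcome.

Per-fold refitting needs every fold to support the model, so the covariate
set for cross-validation is deliberately small at desk scale (a couple of
technical PCs rather than 30); an explicit estimability check refuses folds
smaller than the parameter count. Randomness derives from one root seed via
a per-(probe, outcome) hash, so results are independent of evaluation order
and bit-reproducible.

**Benefit/harm labels.** A significant pair is labelled by pushing
methylation in the direction of the patients' abnormality: hypomethylation
means the abnormal direction is a decrease, so the predicted outcome shift
is $-\bar\beta_{\text{meth}}$ (and $+\bar\beta$ for hypermethylation). If
that shift improves the outcome under its higher-is-better polarity the
label is B, otherwise H; non-significant pairs are unlabelled. The eight
sign combinations are enumerated in a truth-table test.

## The synthetic cohort

No individual-level data from the motivating study are distributable, so the
package carries a simulator whose defaults *are* the study conditions the
analysis assumes, plus a packaged reference table of 26 differentially
methylated positions as a regression fixture.

The generator draws per-probe baseline M values from a three-component
mixture (modes near beta 0.1 and 0.9, a minority of intermediate probes),
per-probe residual SDs from a scaled inverse-chi-square chosen to give
confidence-interval widths like those seen in cohorts of this size
(prior df 20, prior variance 0.25, i.e. residual SDs near 0.5 M units), and
sample values as baseline + group effect + batch effect + noise, mapped back
through the inverse logit — so betas are always strictly inside (0, 1).
Batch effects load through `batch_rank = 2` latent factors shared between
biological and control probes (control probes load twice as strongly and
carry no group effect), which is exactly the structure control-probe PCA can
recover; an optional `batch_confounding` parameter skews batch membership by
group for bias studies. Spiked group effects are specified as target
differences in group mean beta; because the inverse logit is nonlinear, the
M-scale shift is calibrated numerically (Gaussian quadrature over the noise)
so the *expected* realised beta difference equals the target. The default
spike panel mirrors the packaged reference table's 26 magnitudes and signs
(0.2–5.5 percentage points); three clustered spikes of 4/8/12 CpGs spanning
665/438/146 bp form true regions. Outcome scores are generated as linear
functions of M values plus a small age term and Gaussian noise, with
higher-is-better polarity carried as metadata. Covariates are sampled to
resemble the study population (about 58% male patients, a quarter of
patients glucocorticoid-treated, Table-1-like proportions for centre, race,
origin, malignancy, syndrome, severity scores) but are colour, not an
acceptance surface.

The desk-scale default — 120 patients (30 treated), 60 controls, 3,000
biological plus 300 control probes, 4 batches, probes spaced 600 bp — is
the size at which the whole test suite and pipeline run comfortably on one
core while keeping every statistical property measurable; `full_scale =
TRUE` mirrors the real cohort sizes (818/210/392). The QC fixture is
821 bimodal patient samples of which one is flagged for insufficient DNA
yield and two are given mid-heavy distributions, so the sample-QC stage
passes exactly 818 — the count the acceptance script recomputes.

What the simulator does *not* emulate, and what passing tests therefore do
not establish about real data: probe-type chemistry differences and dye
bias, cell-type composition of buccal swabs, spatially correlated residuals
along the genome, genotype effects at SNP-adjacent probes, and any
non-additive or non-Gaussian structure in the outcome models. Tests on this
cohort validate the *statistical machinery* — calibration, recovery,
invariances — not array chemistry.

## Numerical choices, degenerate inputs, known limitations

* Logit clipping at $\varepsilon = 10^{-6}$; detection rule inclusive at the
  50% boundary; BH q capped at 1 with original order restored.
* The trigamma inverse uses Newton iteration with closed-form guards at both
  extremes; identical residual variances take the infinite-prior branch
  explicitly.
* Zero p-values entering Fisher's method are clipped to the smallest
  positive double, with a message; a zero methylation coefficient with a
  significant p is labelled `none` with a warning rather than guessing a
  direction.
* Single-sample quantile normalization is the identity (warning); empty
  matrices, all-missing samples, all-GC patient sets, constant outcomes and
  folds smaller than the parameter count are errors with actionable
  messages.
* The moderated-model and region machinery assume a shared design across
  probes and complete model covariates; probes × samples with missing cells
  must be imputed or dropped before normalization and fitting.
* Region p-values rest on the scaled-chi-square approximation to a weighted
  mean of correlated squared t statistics; the test suite checks the
  approximation's null uniformity in the equal-weight case, where it is
  exact, and the null region count empirically elsewhere.

## Running the pipeline

`run_pipeline(pipeline_config(...))` composes every stage on a simulated
cohort, writes each stage's table as headered TSV plus a run log (package
version, seed, configuration hash), aborts with the failing stage named
while retaining earlier outputs, and is byte-reproducible for a fixed
configuration and seed. The configuration round-trips through YAML and
rejects unknown keys. There is no shell entry point: this is an analysis
package, and its interface is these functions.

```{r example}
library(hpamethyl)
cohort <- simulate_cohort(sim_config(seed = 1))
pcs <- control_probe_pcs(cohort$ms, cohort$annotation, n_pcs = 10)
samples <- attach_technical_covariates(cohort$samples, pcs)
bio <- cohort$ms[!grepl("^ctrl", probe_ids(cohort$ms)), ]
filtered <- probe_filter(bio, cohort$annotation)
dmps <- dmp_table(filtered$matrix, samples, cohort$annotation, n_pcs_use = 10)
dmrs <- dmr_table(attr(dmps, "fit"), cohort$annotation)
summarize_dmps(dmps, gene_totals = table(cohort$annotation$gene))
```
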