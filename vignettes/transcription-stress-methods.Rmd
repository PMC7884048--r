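---
title: "Methods: transcription stress, survival and stereology in txstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcription stress, survival and stereology in txstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txstress)
```

This vignette documents the statistical model behind `txstress`, the
conventions used by each estimator, the default parameter choices and the
reasoning behind them, and the package's known limitations. It is the
reference for *why* the code does what it does; the function reference
documents *what* each function does.

## 1. The lesion model of transcription stress

The core assumption is that transcription-blocking DNA lesions accumulate as
a homogeneous Poisson process along gene bodies, at a rate of $\lambda$
lesions per kilobase. A polymerase completes a transcript of a gene of length
$L$ kb only if the gene body carries no lesion, which happens with
probability $e^{-\lambda L}$. The expected expression of a gene is therefore
its lesion-free baseline multiplied by $e^{-\lambda L}$; on the log2 scale
used throughout,

$$\log_2 \mu(L) \;=\; \beta \;-\; \frac{\lambda L}{\ln 2},$$

with $\beta$ the baseline log2 mean. `simulate_expression()` implements
exactly this: per-gene baselines, a group lesion rate acting through the
closed form above, an optional *programmed* differential-expression
component that is independent of gene length (modelling genuine regulatory
responses such as those induced by dietary restriction), and i.i.d. Gaussian
noise on the log2 scale. The returned `truth` element records the group
lesion rates and which genes carried programmed effects, so every downstream
estimator can be tested against ground truth.

Two consequences of the model shape the whole package:

* **Length bias.** Under a lesion-rate difference, down-regulation is an
  increasing function of length, so genes called "down" are longer than
  genes called "up". `length_bias()` quantifies this.
* **Log-linearity in $L$.** The per-gene log ratio of group means is
  $-\Delta\lambda \cdot L$ plus noise, so a linear regression of
  $\ln(\bar{x}_B/\bar{x}_A)$ on $L$ recovers $\Delta\lambda$ with a standard
  error. `estimate_lesion_rate()` is that regression; no fold-change cutoff
  or significance filter is applied, because every gene is informative about
  the slope.

### Default parameters

`lesion_params()` defaults: baseline log2 mean 6, log2 noise SD 0.25, 5
samples per group — sizes and noise typical of a small rodent expression
study. `default_study_groups()` encodes the package's reference five-group
design: wild-type control and wild-type dietary restriction (lesion rate 0),
repair-deficient control and rapamycin (0.004/kb), and repair-deficient
dietary restriction at half that rate (0.002/kb), reflecting the premise
that restriction lowers lesion load while rapamycin acts mostly through
programmed expression. Programmed-DE fractions are 10% for dietary
restriction groups and 5% for repair-deficient groups, with effect size
1 log2 unit and random sign. Gene lengths are log-normal:
$\log_{10} L_{bp} \sim N(4.2, 0.6)$, floored at 200 bp — a reasonable match
to mammalian gene-length distributions (median ≈ 16 kb, long right tail).

## 2. Differential expression: a transparent moderated t

`call_degs()` uses an empirical-Bayes moderated two-sample t test. Per gene
and group, sample variances $s^2_g$ with $d_g$ degrees of freedom are shrunk
toward the cross-gene mean variance $\bar{s}^2$ with prior weight $d_0$
(default 4):

$$s^{*2}_g = \frac{d_0\,\bar{s}^2 + d_g\,s^2_g}{d_0 + d_g}.$$

The t statistic is the Welch statistic with shrunken variances; its degrees
of freedom are Satterthwaite's formula evaluated with the shrunken variances
and the *original* per-group degrees of freedom, plus $d_0$. Setting
$d_0 = 0$ recovers plain Welch exactly (and this identity is unit-tested).
The shrinkage target being the plain mean of variances (rather than a fitted
inverse-gamma prior) keeps the estimator fully transparent and closed-form;
for $n = 5$ per group the difference from a fitted prior is minor. P values
receive Benjamini–Hochberg correction; a gene is a DEG iff $q < 0.05$ **and**
its linear fold change is at least 1.5. Direction is the sign of log2 fold
change.

## 3. The length-bias statistic

`length_bias()` compares $\log_{10}$ gene length between up- and
down-regulated DEGs.

* **Density view.** Each direction gets a Gaussian kernel density estimate
  with Silverman's rule-of-thumb bandwidth, evaluated on a 512-point grid
  spanning the data range extended by three bandwidths on each side. Because
  the grid truncates the Gaussian tails slightly, each curve is renormalised
  so its trapezoid integral on the grid equals 1; the test never uses these
  densities, they are descriptive.
* **Test.** A two-sided Wilcoxon–Mann–Whitney test on the lengths. The exact
  null distribution is used when the smaller group has at most 25
  observations and there are no ties; otherwise the tie-corrected normal
  approximation with continuity correction. The switch point keeps exact
  computation cheap while the approximation error is negligible (checked to
  be within 0.02 of exact in tests).
* **Classification.** By default only DEGs are classified
  (`significant_only = TRUE`). With `significant_only = FALSE` every gene is
  classified by the sign of its fold change — useful for null calibration,
  where no DEGs exist but the test should still reject at its nominal rate,
  since lengths are exchangeable between sign classes under the null.

Calibration and power at the package's reference settings (recomputed by
`scripts/acceptance.R`): the null rejection rate at $\alpha = 0.05$ is
within sampling error of 5% over 500 replicates, and at a lesion rate of
0.004/kb with 10,000 genes the correct-direction detection rate at
$p < 0.01$ is 100/100.

A known regime effect: the *median* length gap between down and up classes
grows with the lesion-rate difference only while power is limiting
(roughly $\Delta\lambda \le 0.002$/kb at 3,000 genes). At higher rates the
1.5-fold-change cutoff starts admitting progressively shorter genes into the
down class and the gap saturates and then shrinks — the bias is still
overwhelmingly significant, but the median gap is not a monotone effect-size
measure across the whole range.

## 4. Survival analysis

Cohorts are simulated from a Gompertz law with hazard $a e^{bt}$ via the
inverse CDF, $t = \frac{1}{b}\log\!\left(1 - \frac{b}{a}\log U\right)$,
reducing to the exponential $-\log(U)/a$ at $b = 0$. Optional administrative
censoring truncates follow-up at a fixed time.

Kaplan–Meier curves and log-rank tests are computed with the `survival`
package; the package's tests verify them against independent hand
implementations (product-limit recomputation; full $2\times2$ hypergeometric
enumeration of the log-rank O, E and V). Stratified log-rank sums O−E and V
across strata; strata containing only one group carry no information and are
dropped with a warning.

Two log hazard-ratio estimators are provided, both built from the log-rank
quantities:

* **Mantel–Haenszel:** $\log\mathrm{HR} = \log\frac{O_A/E_A}{O_B/E_B}$ with
  $\mathrm{se} = \sqrt{1/E_A + 1/E_B}$.
* **Score:** $\log\mathrm{HR} = (O_A - E_A)/V$ with $\mathrm{se} = 1/\sqrt{V}$.

Both are first-order approximations around $\mathrm{HR} = 1$ and both
compress toward the null as the event fraction approaches 1: with complete
follow-up at a true HR of 2 the measured systematic bias is 6–9%, while
with administrative censoring leaving roughly half the animals event-free it
is below 1%. The package's recovery checks therefore simulate partial
follow-up, which is also the regime of the onset analyses these estimators
serve. For strongly non-proportional hazards or near-complete follow-up, a
parametric fit is the better tool.

`onset_analysis()` reuses the same machinery for phenotype-onset data, where
death before onset is a censoring event, and `forest_assemble()` collects
hazard-ratio fits into a tibble for forest plotting.

## 5. The body-weight AUC ledger

`bodyweight_auc()` implements a survival-aware area-under-the-curve
comparison:

1. **Interval.** The analysis window ends at the largest week at which
   *every* group's Kaplan–Meier survival is at least 0.80 (inclusive; a
   $10^{-9}$ tolerance absorbs floating-point representation of the 0.80
   boundary). This avoids survivor bias from comparing weights on windows
   where groups have been differentially depleted. Animals dying inside the
   window are excluded from the AUC.
2. **Normalisation.** Weights are $\log_{10}$-transformed and expressed
   relative to the study-wide minimum baseline, making AUC differences
   approximately relative-growth differences.
3. **AUC.** Per-animal trapezoidal integration (`pracma::trapz`) over the
   window.
4. **Outlier screen.** A single-pass two-sided Grubbs test at
   $\alpha = 0.01$ on the pooled AUCs, with
   $G_{crit} = \frac{N-1}{\sqrt{N}} \sqrt{\frac{t^2}{N-2+t^2}}$,
   $t = t_{1-\alpha/(2N),\,N-2}$. One pass only — iterated Grubbs inflates
   the false-positive rate.
5. **Comparison.** Welch's t test per requested group pair.

Each component is tested against closed forms (triangle/constant AUCs,
$G_{crit}(4, 0.01) = 1.49625$, the Welch toy example
$t = -3/\sqrt{2/3}$, df = 4, $p = 0.0213$).

## 6. Optical fractionator stereology

`simulate_tissue()` generates a homogeneous Poisson point cloud in a slab of
given x–y extent and `n_sections × cut_thickness` depth, with the true count
retained. `counting_design()` fixes the sampling fractions: section sampling
fraction `ssf`, counting-frame size within a systematic grid (area sampling
fraction `asf` = frame area / grid tile area), and disector height `h`
within mounted thickness `t`, with guard zones defaulting to
$(t - h)/2$ on each face. `sample_frames()` tiles the volume with a single
uniform random offset (systematic uniform random sampling) and applies the
standard unbiased counting rules: inclusion edges
$x \in [x_0, x_0 + f_x)$, exclusion edges $y \in (y_0, y_0 + f_y]$, and
$z \in [\text{guard}, \text{guard} + h)$. Zero-count frames are enumerated
explicitly — they carry information and dropping them would bias the
estimate. The estimator is

$$\hat{N} = \sum Q^- \cdot \frac{t}{h} \cdot \frac{1}{asf} \cdot \frac{1}{ssf}.$$

Mounted thickness is taken equal to cut thickness (no shrinkage model). Two
properties are verified: with all fractions equal to 1 and no guard the
estimator is an exact census (absolute error 0), and under genuine
subsampling the mean over 500 random grid offsets is within ~1% of the true
count — the design-based unbiasedness that justifies the method.

## 7. Reproducibility conventions

All simulators take a `seed` and restore the caller's RNG state afterwards.
Internally, independent substreams are derived as
`derive_seed(seed, tag)` — a Lehmer-style mix of the user seed with a string
hash — so adding a new simulation stage does not perturb existing streams.
`scripts/acceptance.R` re-derives every reported quantity from a single
`--seed` argument; the same seed reproduces the same JSON exactly.

## 8. Known limitations

* The lesion model treats $e^{-\lambda L}$ as acting on the *mean* with
  log-normal measurement noise; it does not model count noise
  (negative-binomial) and is therefore a microarray-flavoured rather than
  RNA-seq-flavoured generator.
* The moderated t uses a fixed prior df rather than estimating it from the
  data; for very small prior df misspecification the q values are
  conservative rather than wrong.
* Hazard-ratio estimators are log-rank-based approximations; see §4 for the
  complete-follow-up caveat.
* The median length gap is not monotone in $\Delta\lambda$ across all
  regimes (§3).
* Stereology assumes no tissue shrinkage and full section sampling within
  `ssf`; lost caps or differential z-shrinkage are out of scope.
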