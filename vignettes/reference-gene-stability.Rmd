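---
title: "Reference-gene stability and relative quantification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability and relative quantification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcrstab)
```

## The problem

RT-qPCR quantifies a transcript through its threshold cycle (Ct): the PCR
cycle at which amplification fluorescence crosses a detection threshold.
One cycle corresponds to one doubling, so Ct is a negated log2 abundance.
Absolute Ct values are not comparable between samples — RNA input,
reverse-transcription efficiency and loading all shift every Ct of a
sample up or down — so target genes are expressed *relative to* reference
("housekeeping") genes assumed constitutively expressed. That assumption
fails often enough, particularly across developmental stages, that
candidate references must themselves be validated on the study's own
samples. This package implements that validation for grouped designs
(e.g. gestational-week time courses of fetal tissue), the downstream
multi-reference ΔΔCt quantification, and the group-comparison statistics
such studies report.

## The data model

All estimators operate on a `ct_table`: a genes × samples Ct matrix with
one ordered group label per sample. The generative model the package
assumes (and that the synthetic-data module implements exactly) is

$$Ct_{igj} = a_i + d_{ig} + h_j + \varepsilon_{igj},$$

where $a_i$ is the gene's baseline Ct, $d_{ig}$ a fixed intergroup effect
in log2 units (zero for an ideal reference gene), $h_j \sim N(0,\tau^2)$
a per-sample loading shift shared by every gene of sample $j$, and
$\varepsilon_{igj} \sim N(0,\sigma^2_{ig})$ heteroscedastic noise.
Normal noise on the Ct (log) scale is the standard assumption for qPCR
and is what makes the CV analysis below have a closed-form large-sample
limit. What this model does **not** emulate: amplification-efficiency
differences between assays (the package fixes efficiency at exact
doubling), technical-replicate structure, heavy-tailed outliers from
pipetting failures, and undetermined wells that correlate with low
expression. Passing recovery tests on synthetic data therefore shows the
estimators are implemented correctly and behave as designed under the
stated model — not that any particular real data set satisfies the model.

## The four stability estimators

**Mean ± SD** (`mean_sd_stability`) ranks genes by the sample standard
deviation of raw Ct, pooling all groups. It is the bluntest screen: the
SD confounds $\tau$, $\sigma$ and intergroup drift, but it is what a
bench scientist reads directly off the instrument export.

**CV analysis** (`cv_stability`) linearizes each Ct as $e = 2^{-Ct}$ and
reports $100\cdot\mathrm{sd}(e)/\mathrm{mean}(e)$. Because a per-gene
constant cancels, the CV is independent of expression level. Under the
model, for $Ct \sim N(\mu, \sigma^2)$ the CV converges to
$100\sqrt{e^{\sigma^2 (\ln 2)^2} - 1}$ — the log-normal limit the test
suite checks by Monte Carlo (averaging ten replicate estimates of
$n = 10^5$ each; a single draw of that size still carries 1–2% sampling
spread at $\sigma = 1.5$, so the check averages replicates rather than
pretending one draw is exact).

**Pairwise ΔCt** (`pairwise_dct_stability`) scores gene $i$ by the mean
over partners $j$ of $\mathrm{sd}_k(Ct_{ik} - Ct_{jk})$. Differences
cancel $h_j$ exactly, making this the only pooled estimator immune to
loading variation; the price is that one bad partner inflates every
gene's score a little.

**Model-based score** (`normfinder_stability`), in the NormFinder
family, estimates the variance components of the model above. Within
each group the genes × samples submatrix is double-centered; because the
residuals then mix gene variances, the intragroup estimate uses the
unbiased correction
$\hat\sigma^2_{ig} = \tfrac{G}{G-2}(v_{ig} - \bar v_g/(G-1))$, truncated
at zero. Intergroup deviations $\hat d_{ig}$ (gene-centered group means,
so $\sum_i \hat d_{ig} = 0$ within each group) are shrunk towards zero
by the empirical-Bayes factor $\gamma^2/(\gamma^2 + c_{ig})$, with
$c_{ig}$ the sampling variance of $\hat d_{ig}$ and $\gamma^2$ the
estimated variance of true intergroup deviations across all genes and
groups. The stability value is

$$S_i = \frac{1}{n_{\mathrm{grp}}}\sum_g\left(|\tilde d_{ig}| + \sqrt{c_{ig}}\right),$$

the shrunken systematic deviation plus the random uncertainty of its
estimate, in cycles. We deliberately use the *sampling* SE rather than
the posterior SD in the second term: the posterior SD saturates at
$\gamma$ for very noisy genes, which would let a gene with wild
intragroup noise hide behind a panel whose intergroup variation is
small. With the sampling SE, both failure modes — a gene that *moves*
between groups and a gene that is merely *noisy* — raise $S$. Without
groups the score reduces to $\hat\sigma_i$. The numeric scale of $S$
therefore follows cycles and is not comparable across published
NormFinder variants, whose scales differ by software and settings;
rankings, not raw values, are the supported output.

**Aggregation** (`rank_aggregate`): the per-method ranks are combined by
geometric mean. Exact ties in any statistic get average ranks; residual
display ordering is alphabetical, so output is deterministic. This
formalizes the common informal practice of eyeballing the four rank
columns; it is a documented convention, not a claim of optimality.

Missing wells are never imputed. Mean/SD and CV skip them per gene,
pairwise ΔCt uses complete pairs only (a pair needs ≥ 2 complete
samples), and the model-based score requires a complete matrix and names
the blocking cells — two-way centering has no unique solution with
holes.

## Normalization and fold changes

`reference_index` averages the reference Cts per sample, which equals
the negated log2 of the geometric mean of the linearized quantities —
the standard multi-reference normalizer. `delta_delta_ct` then computes
$\Delta Ct$, the relative quantity $2^{-\Delta Ct}$, and log2 fold
change against the *arithmetic mean* $\Delta Ct$ of the calibrator group
(the geometric mean on the linear scale; a median alternative sits
behind `calibrator_agg = "median"`). The calibrator group's mean log2FC
is zero by construction. Per-group summaries of relative quantity are
emitted both as geometric and arithmetic means, clearly labelled,
because the two differ for skewed linear-scale quantities and published
figures do not always say which they use. Amplification efficiency is
fixed at 2.0 throughout; there is no standard-curve correction module.

`profile_concordance` compares per-group log2FC profiles (e.g. qPCR vs
an externally computed RNA-seq table ingested by `read_fc_profile`) by
Pearson and Spearman correlation over ≥ 3 common groups; constant
profiles are flagged "not assessable" rather than returning silent NaN.

## Group statistics

"Brown–Forsythe one-way ANOVA" here means the modified-F test for
equality of **means** under unequal variances —
$F^* = \sum_g n_g(\bar y_g - \bar y)^2 \big/ \sum_g (1 - n_g/N) s_g^2$
with fractional Satterthwaite df — the meaning the term has in common
statistics software, *not* the Levene-type test for equality of
variances. The df2 is kept fractional; p-values come from the continuous
F distribution. Simulation shows the test is slightly conservative in
small balanced designs (empirical size ≈ 0.041 at five groups of six),
which is a known property of Satterthwaite-type approximations, while
classic ANOVA's size degrades badly (≈ 0.13) when a small group has the
largest variance — the package's test suite checks both directions.
Classic one-way ANOVA and Tukey HSD are delegated to `stats`; the
calibrator-referenced contrasts (`posthoc_vs_calibrator`) use Welch
tests with Holm adjustment — a documented choice for star annotations
against a baseline group, not a claim that any published figure used
exactly this procedure. Stars map to 0.05/0.01/0.001, two-sided.

## The synthetic scenario and its defaults

`scenario_paperlike` emulates a 12-candidate panel over five ordered
developmental groups. Defaults, chosen once as realistic qPCR values:
baselines 18–26 cycles with one very high expressor at 9 cycles (an
18S-rRNA-like candidate); stable-gene noise SD 0.2–0.5 cycles; loading
shift τ = 0.4 cycles; two deliberately unstable genes — one with
intergroup effects of ±1 log2 and one with inflated noise (SD 1.2
cycles); and two monotonically rising synthetic target genes (+3 and
+2.8 log2 over the course, marked `_syn`). Six samples per group is a
power choice: it is the smallest size at which the model-based score
reliably separates *both* designed instability modes from the stable
background; at four per group the sampling error of per-group variance
estimates drowns the inflated-noise signature. The declared ground-truth
stability functional is $\mathrm{mean}_g |d_{ig}| + \mathrm{mean}_g
\sigma_{ig}$, computed from the generating parameters so recovery tests
are unambiguous.

Generation is fully deterministic under a mandatory seed (one
Mersenne-Twister stream; draw order: sample shifts, then reference noise
gene-major, then targets in declared order), and the generator restores
the caller's RNG state.

## Numerical and formatting conventions

Sample SDs use the n−1 denominator throughout. Negative variance
estimates truncate to zero. Degenerate inputs (zero within-group
variance) yield flagged results with p forced to 1 or the machine floor
rather than NaN. Tables are written as UTF-8 TSV with floats at 4
decimals and fixed column order, so identical runs are byte-identical;
every pipeline output directory carries a JSON manifest (config echo,
seed, versions) sufficient to re-run the command.

Problem sizes used by the test suite and the acceptance script — e.g.
10,000 null replicates for the size check, ten replicates of $10^5$
draws for the CV limit, 200 simulated studies for the worst-gene rate,
30 replicates at $n_g = 20$ for trajectory recovery — were chosen so
each check resolves its stated tolerance with comfortable Monte-Carlo
margin.

## Known limitations

- No PCR-efficiency estimation or correction; all log-linear algebra
  assumes exact doubling.
- No geNorm-style iterative exclusion or BestKeeper variant; the four
  implemented estimators cover the variance-decomposition,
  raw-dispersion, relative-dispersion and pairwise-difference families.
- The model-based score needs a complete matrix; with sparse missingness
  the other three estimators still apply.
- Concordance with external RNA-seq profiles is ingest-only: this
  package never recomputes differential expression from counts.

## A minimal worked run

```{r example, eval = FALSE}
spec <- scenario_paperlike(seed = 1)
sim <- generate_ct_data(spec)
fit <- gene_stability(ct_subset(sim$ct, genes = names(spec$baselines)))
summary(fit)

rq <- delta_delta_ct(sim$ct, "OTOF_syn", c("B2M", "GAPDH", "GUSB", "HPRT1"))
fold_change_profile(rq)
brown_forsythe_anova(rq$log2fc, rq$group)
```
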