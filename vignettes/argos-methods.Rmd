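---
title: "Modeling dosage compensation and overexpression toxicity with argos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dosage compensation and overexpression toxicity with argos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argos)
```

## The problem

Somatic copy-number gains usually drag a gene's expression up roughly in
proportion to DNA dosage. Genes that resist this — whose expression stays
flat despite extra copies — are *compensated*, and compensation is
interesting precisely when the cell appears to be actively defending
itself against the extra product. If the same gene is also *toxic* when
overexpressed in an ORF screen, the amplified tumor is plausibly relying
on its compensation machinery, and that reliance is a candidate
therapeutic vulnerability. We call such genes ARGOS genes
(amplification-related gain of sensitivity). `argos` implements the full
discovery pipeline: copy-number encoding, a per-gene Bayesian negative
binomial regression in cell-line and tumor variants, score shrinkage and
classification, an ORF-screen depletion statistic, ARGOS integration, and
protein-complex prioritization, together with a synthetic-cohort
generator that makes every stage testable by parameter recovery.

## The compensation model

Copy number enters the model on the linear scale, parameterized as
*euploid equivalents* $c = 2^{\log_2 \text{ratio}}$ and *euploid
deviation* $d = c - 1$. A copy-neutral sample has $c = 1, d = 0$; one
extra copy on a diploid background gives $c = 2, d = 1$; total loss gives
$c = 0, d = -1$. By construction $c - d = 1$ everywhere, so the pair
splits an observed dosage into "what scales" and "what deviates from
scaling".

For each gene in a cell-line cohort, raw counts $r$ across samples are
modeled as

$$\mu = \sum_t \beta_1^{t}\,c + \beta_2\,d, \qquad
  r \sim \mathrm{NB}(s\,m\,\mu,\ \sigma),$$

with a tissue-specific scaling coefficient $\beta_1^t$, a shared
deviation coefficient $\beta_2$, per-sample size factor $s$
(median-of-ratios, geometric mean 1), gene mean $m$ (mean of
size-normalized counts over retained samples), and NB shape $\sigma$
(variance $\mu + \mu^2/\sigma$). Dividing by $m$ makes coefficients
comparable across genes regardless of expression level. For bulk tumors
the cancer signal is diluted by purity $p$ and a non-cancer compartment
contributes the remainder:

$$\mu = \sum_t \beta_1^{t}\,c\,p + \beta_2\,d\,p +
        \sum_t \beta_3^{t}\,(1 - p).$$

At $p = 1$ the tumor model reduces exactly to the cell-line model — this
identity is checked numerically in the test suite on random parameter
draws.

Priors are $\beta_1, \beta_3 \sim \mathrm{logNormal}(0, 1)$ (positive
scaling and non-cancer expression), $\beta_2 \sim N(0, 0.5)$ for cell
lines and $N(0, 0.2)$ for tumors (the tumor deviation is noisier per
sample and the tighter prior guards against purity-driven inflation), and
a weakly informative $\mathrm{Gamma}(0.01, 0.01)$ prior on $\sigma$. The
link is the identity, which is what makes $\beta_2/\beta_1$
interpretable as a fraction of the per-copy increment — but the identity
link does not keep the NB mean positive, so parameter draws implying
$\mu \le 0$ for any retained sample are given zero posterior mass.

### Sample inclusion and eligibility

Only samples that are cleanly copy-neutral ($|c - 1| \le 0.15$) or carry
a one-copy gain ($c \ge 1.85$) enter a gene's fit; intermediate and
deleted samples are excluded, because the contrast of interest is "one
extra copy vs baseline". The 15% tolerance is absolute on the linear copy
scale (and exposed as configuration; the alternative relative reading is
not materially different at these values). A gene is fit only if it has
at least 3 amplified samples in a cell-line cohort or 5 in a tumor
cohort. A tiny numeric epsilon (1e-9) absorbs floating-point error at the
tolerance boundaries.

### Inference

Each gene is fit independently by MCMC: a component-wise adaptive
random-walk Metropolis warmup (Robbins–Monro tuning toward 0.44
acceptance), whose second half also estimates the posterior covariance;
sampling then uses a joint multivariate proposal built from that
covariance (Haario-style, global scale tuned toward 0.23 acceptance and
then frozen). The joint phase matters: compensated genes induce a strong
$\beta_1$–$\beta_2$ posterior correlation that single-coordinate updates
traverse slowly. Defaults are 4 chains × 1000 post-warmup draws (500
warmup); convergence is judged by split-$\hat R < 1.1$ and a crude
initial-positive-sequence effective sample size is reported.
Non-converged fits are flagged and excluded from classification. All
randomness flows from explicit seeds; per-gene seeds are derived from the
run seed and the gene identifier so results do not depend on gene order.

Smaller chain budgets (2 chains × 500–1000 draws) are adequate for the
simulation studies shipped in the test suite and are what those tests
use; the package default is deliberately more conservative for real
cohorts. The tumor posterior (extra $\beta_3$ terms) mixes more slowly
and benefits from roughly doubled draws at equal chain count.

### Scores, shrinkage, classification

The deviation coefficient is normalized by mean euploid expression,
$\beta_2^* = \beta_2 / \bar\beta_1$, where $\bar\beta_1$ is the
unweighted mean over fitted tissues of the $\beta_1^t$ posterior means
(a sample-size-weighted mean is available as an option; with tissue
counts roughly balanced the two agree, and the unweighted form keeps a
rare tissue from being ignored). On this scale $-1$ is full compensation
(no expression change under gain), $0$ pure dosage scaling, $+1$ full
hyperactivation. The final score shrinks $\beta_2^*$ by its
pseudo-p-value: $z = \mathrm{mean}(\beta_2)/\mathrm{sd}(\beta_2)$ over
the posterior, $p = 2\Phi(-|z|)$ (two-sided — the conservative choice
where one-sided would halve the p), and $s = (1 - p)\,\beta_2^*$. Hence
$|s| \le |\beta_2^*|$ always, and $s$ is monotone in $|z|$: uncertain
deviations are pulled to zero rather than thresholded away.

A gene is called **compensated** when $s < -0.3$ in *both* cohorts
(typically one cell-line-like and one tumor-like), **hyperactivated**
when $s > 0.3$ in both; inequalities are strict. **Toxic** means the
pooled ORF-screen estimate corresponds to at least a 30% growth decrease
(mean barcode $\mathrm{lfc} \le \log_2 0.7 \approx -0.515$, inclusive at
the boundary) with two-sided $p < 10^{-5}$; **commonly amplified** means
gained in strictly more than 15% of samples. **ARGOS** = compensated AND
toxic; frequent amplification is annotated alongside but not required,
so downstream users can slice either way.

## The toxicity model

ORF-screen barcodes measure fitness under overexpression: the log2 fold
change of barcode abundance between the early and late time points,
$\mathrm{lfc} = \log_2\frac{(late + 0.5)/N_{late}}{(early + 0.5)/N_{early}}$,
with a 0.5 pseudocount (configurable; precomputed lfc input bypasses it).
Every barcode measurement for a gene, in any screen of the chosen scope,
is one independent observation of an intercept-only linear model; the
estimate is the pooled mean and significance is the Wald t-test
(identical to the one-sample t-test, which a test verifies in closed
form). Per-screen median centering is available but off by default — no
recentering is applied unless asked for. Tissue-specific scope restricts
to screens sharing a cancer type; on a single-tissue table it equals the
pan-cancer fit exactly.

## Complex prioritization

Compensation concentrated in a protein complex is stronger evidence than
scattered single-gene calls. For each complex, a one-sided Fisher's exact
test asks whether compensated genes are over-represented among its
members within the tested universe; q-values are Benjamini–Hochberg
(the FDR method is not dictated by the science; BH is the standard
step-up and is cross-checked against a hand implementation in the
tests). The complex's member toxicity is contrasted against the
background by the same indicator-variable linear model used for gene-set
score differences, reported as a signed Wald statistic (negative =
members drop out more). Complexes are ranked by ascending q, ties broken
by more negative toxicity.

## The synthetic-cohort generator

The generator emulates the statistical structure the analysis assumes,
with known ground truth per gene: per-tissue baseline expression,
NB-distributed counts (variance $\mu + \mu^2/\mathrm{shape}$, matching
the model's shape convention), log-normal library factors (geometric mean
1), a fixed fraction of gained samples per tissue (first
$\lfloor \mathrm{frac} \cdot n \rfloor$ after a seeded shuffle, so
fixtures are stable), Beta-distributed purity with a per-gene constant
non-cancer expression for tumor cohorts, and Gaussian barcode lfc noise
for screens. The noiseless mean is exactly
$L\,(p \cdot \mathrm{base}(c + \mathrm{score}\cdot d) + (1-p)\,\mathrm{normal})$ —
no noise enters before the NB draw, which is what makes the purity-mixing
and dosage identities testable exactly.

Default study conditions: one tissue of 200 samples per cohort, baseline
500 normalized counts, NB shape 20 (a typical bulk RNA-seq dispersion of
0.05), 25% gained samples, one extra copy (`amp_copies = 2`),
purity $\sim$ Beta(6, 3) (mean ≈ 0.67, a plausible bulk-tumor spread),
non-cancer expression equal to the cancer baseline, 3 screens × 2
barcodes per gene, and barcode noise sd 0.1 (the scale at which a
6-observation pooled t-test can resolve a 30% growth effect at
$p < 10^{-5}$ — real screens achieve the equivalent by carrying many
more barcode observations per gene). These are the conditions under
which the shipped recovery tests run: scores of $-1$/$0$/$+1$ are
recovered within ±0.15 (cell-line model) and ±0.2 (tumor model), and a
490-gene cohort with 10 planted ARGOS genes, 40 compensated-only and 40
toxic-only decoys and 400 nulls yields at least 8/10 planted genes with
at most 2 false positives.

What the generator does *not* emulate: batch and GC effects, focal vs
arm-level CNA geometry, deletions, WGD, allele-specific copy number, or
read-level data. Passing recovery tests therefore demonstrates that the
estimator inverts its own generative assumptions — not that those
assumptions capture every failure mode of real cohorts, where gain calls
and purity estimates are themselves noisy inputs.

## Numerical choices and degenerate inputs

* Copy-number entries that are `NA` are flagged missing and excluded per
  gene; `-Inf` log2 is accepted as the zero-copy sentinel ($c=0, d=-1$).
* A gene whose mean normalized expression is zero over retained samples
  is skipped (the $m$-rescaled model is undefined), with a reason
  recorded in the output table.
* Fits with all purities zero are refused (the cancer component is
  unidentifiable); at near-zero purity the $\beta_2$ posterior returns
  its prior, which a test confirms.
* Gene-set contrasts with zero residual variance report an undefined p
  rather than a fabricated one; toxicity fits with fewer than two
  observations are never classified toxic.
* Ties in complex ranking are broken by more negative toxicity; gene
  identifiers are matched as opaque strings with attrition counts
  recorded, and no symbol/alias resolution is attempted.

## Reproducibility

Every stochastic step — cohort simulation, screen simulation, chain
initialization and sampling — is a deterministic function of explicit
seeds, and the file pipeline writes the seed, thresholds, inference
settings and gene attrition into `run_manifest.json`. Running
`run_pipeline()` twice with the same configuration produces byte-identical
outputs, which the test suite asserts.
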