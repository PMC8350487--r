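---
title: "Stepwise connectomics and imaging transcriptomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise connectomics and imaging transcriptomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectogene)
```

This vignette is the package's own account of the methods it implements:
the models, their assumptions, the tunable parameters and their defaults,
the numerical choices made where the mathematics alone does not force one,
and what the synthetic-data experiments do and do not demonstrate.

## From time series to a normalized association matrix

A subject's input is a timepoints × nodes matrix of BOLD-like signals.
Preprocessing is a fixed chain:

1. **Pearson correlation** between all node pairs (diagonal set to 0 —
   self-connectivity carries no information for walk-based graph measures);
2. **Fisher z** (`atanh`), with correlations clipped to ±(1 − 1e−7) so
   duplicated series cannot produce infinities;
3. **negative removal** — negative functional couplings have a contested
   interpretation in graph-integration analyses and are zeroed;
4. **FDR thresholding** at q = 0.005: each edge's two-sided p-value comes
   from the t transform `t = r sqrt((n−2)/(1−r²))` with `n` timepoints,
   Benjamini–Hochberg is applied to the upper triangle only and mirrored.
   A parametric p-value is assumed; a permutation alternative would change
   only this step's internals, not its contract;
5. **min–max normalization** of the off-diagonal onto [0, 1].

`q` is deliberately strict (0.005): the chains below accumulate weighted
walks, and weak spurious edges inflate every power of the matrix.

## Stepwise, local and distributed chains

With the normalized matrix `NSFC_1 = a`, step `s > 1` is
`SFC_s = NSFC_{s−1} · NSFC_1` with the diagonal zeroed, re-symmetrized,
and normalized to give `NSFC_s`. Entry (i, j) of step s accumulates the
weight of all s-step walks between i and j.

Two numerical choices deserve explanation:

* **Re-symmetrization.** The product of two *different* symmetric matrices
  is not symmetric, so from step 3 on `(M + M')/2` is applied before
  normalization. The asymmetry is an artifact of the diagonal zeroing and
  per-step affine normalization, not a directed-graph feature; symmetric
  storage is what makes the weighted-degree map a per-node row sum.
* **Zero-baseline step normalization.** A step matrix is a nonnegative
  walk measure in which 0 means "no walk of this length exists". The
  per-step normalization therefore divides by the maximum and keeps 0 as
  the floor rather than subtracting a positive minimum: subtracting the
  minimum would zero the *weakest existing* walk, and on graphs where
  every pair is s-step reachable that silently deletes exactly the pairs
  the distributed mask needs. The exported `minmax_normalize()` keeps the
  full affine map for general matrices; only the chain's internal step
  normalization uses the zero baseline. Consequence: the off-diagonal
  minimum of a step matrix is exactly 0 whenever some pair lacks a walk
  (always the case for realistic sparse FDR-thresholded graphs), and
  slightly positive otherwise.

The **local** chain restricts step 1 to direct links that also have a
two-step alternative (`NSFC_2 ≠ 0`): links inside modules. It propagates
along the masked matrix `NLC_1`. The **distributed** chain seeds from
pairs with *neither* a direct nor a two-step connection but a four-step
one (`NDC_1 = NSFC_4 [NSFC_1 = NSFC_2 = 0]`): links bridging modules. It
propagates along the full `NSFC_1` — the two recursions are deliberately
asymmetric, and the masked step-1 matrices are not re-normalized (only
products at s > 1 are). Mask comparisons use a 1e−12 tolerance because
products accumulate rounding even though post-normalization zeros are
exact.

**Weighted degree** sums the *normalized* step matrices of steps 2–7 as
per-node row sums. Two open choices were resolved as: normalized matrices
(they are the only per-step quantities the chain defines) and plain row
sums of the symmetric matrices (not halved node strength); any consistent
alternative is a monotone rescaling that the downstream regression absorbs.

## Association with divergent thinking

Per node, WD is regressed on `[intercept, DT, age, sex]` by OLS; the DT
coefficient, its t statistic and two-sided p are reported. Sex enters as a
single 0/1 indicator; WD maps are used raw (not standardized across
subjects), so the slope keeps WD units per DT unit. The design matrix is
shared across nodes, which reduces the whole map fit to two matrix
products — the same code path evaluates the Monte-Carlo null cheaply.

Cluster-extent correction replaces an external cluster-simulation binary
with an in-package Monte Carlo: `n_iter` Gaussian-noise response maps are
regressed on the *observed* design, each iteration records the maximum
supra-threshold cluster size (|t| above the two-sided `voxel_p` quantile,
components under the supplied node adjacency, positive and negative tails
pooled into one maximum), and an observed cluster is kept when its
Monte-Carlo p-value `(1 + #{null ≥ size})/(n_iter + 1)` is at most
`alpha`. The p-value rule rather than a raw quantile cut avoids the
liberal bias that heavy ties in a discrete size distribution give the
quantile; the price is conservatism — on 60-node lattices the empirical
family-wise error at nominal 0.05 sits near 0.01–0.02 because null
maximum sizes take only a few integer values. Defaults: `voxel_p = 0.05`,
`alpha = 0.05`, `n_iter = 10000` (1,000 is adequate for calibration
experiments). The null model assumes exchangeable Gaussian node noise; it
does not model spatial smoothness of real fMRI residual fields, which is
out of scope here.

## Parcellation and the transcriptome screen

A node-level statistic map is summarized per region by the unweighted
arithmetic mean of member nodes (label 0 = unassigned, empty regions are
omitted with a notice). The default parcellation size, 68, mirrors the
Desikan–Killiany cortical atlas that regional expression summaries are
conventionally projected onto.

Each gene's expression profile across the shared regions is correlated
(Pearson by default; Spearman behind a flag) with the regional map. The
**empirical null is the whole-transcriptome score distribution itself**:
its mean and SD define the ±`k_sd` (default 2) selection. This follows
the screen's original logic; it does not build a spatial-autocorrelation-
preserving null, so smooth maps make the null wider but also genuinely
harder to stand out of — a known limitation, reproduced deliberately.
Selection is invariant to positive affine transforms of the map since
Pearson r is. At least 100 scored genes are required for stable moments;
zero-variance genes are scored missing and excluded.

Overrepresentation of a candidate list uses the one-sided hypergeometric
upper tail per term, fold enrichment `FE = (k/n)/(K/N)`, and Bonferroni
`q = min(1, p × #terms)`; a term is reported when `FE > 2` and
`q < 0.05`. The background defaults to the genes actually scored by the
screen — the screen defines the testable universe, not the annotation
file. Interactome validation computes closeness centrality with hop-count
distances (interaction weights are confidences, not metric lengths; an
inverse-weight option exists) and Wasserman–Faust scaling
`(m−1)/Σd · (m−1)/(n−1)` so components of a disconnected network are
comparable.

## Semantic-distance scoring

Per embedding space, a prompt–response pair scores
`1 − cosine(prompt, response)` in [0, 2]; multi-word texts are composed by
the element-wise mean of resolvable word vectors (the additive-composition
convention; stop-word handling is the caller's responsibility). Item-level
distances are averaged per subject and space, and the latent DT score is
the first principal component of the column-standardized subject × space
matrix, sign-aligned so loadings are predominantly positive; a one-factor
maximum-likelihood extraction is available behind a flag and agrees with
the PC on well-behaved data. Aggregation by means and PC extraction are
the two places the underlying assessment literature leaves open; both
choices are the simplest members of their families.

## What the synthetic data emulates

`synthetic_spec()` fixes the study conditions: 60 subjects, 120 nodes in 4
equal modules, 150 timepoints (a 5-minute scan at TR = 2 s), planted
standardized WD–DT slope −0.5 on the module-1 nodes, 2,000 genes with 50
planted at expression noise SD 0.5, a 68-region parcellation, age ∼
N(22.7, 6.4) and P(female) = 127/175 matching a young, mostly female
cohort. The module graph is a weighted planted partition (within-module
edge probability 0.35, weights U(0.5, 0.9); between 0.02, U(0.2, 0.4)),
regenerated up to 50 times until connected (per-module connectivity when
the between probability is 0). Subject covariance sets off-diagonal
entries to 0.6 × the (effect-scaled) edge weights with unit diagonal;
when that matrix is not positive definite it is repaired by eigenvalue
flooring and rescaling to unit diagonal, with a notice. The DT effect
scales covariances incident to effect nodes by `1 + effect_size · z(DT)`,
clamped to [0.05, 1.9] so extreme subjects cannot produce negative
couplings.

Every generator is a pure function of the spec (the master seed plus a
fixed per-generator offset), restores the caller's RNG state, and is
byte-reproducible. The generators emulate modular connectivity, planted
anti-correlated expression, a concentrated annotation term, a dense
interactome core, and novelty-controlled word responses; they do **not**
emulate hemodynamics, head motion, scanner noise spectra, spatial
autocorrelation of expression maps, or heavy-tailed noise. Passing tests
therefore demonstrate that the pipeline recovers effects of the planted
kind at realistic sizes — not that it is robust to every artifact of real
acquisitions.

## Problem sizes and test design

The test suite checks each operation against an independent brute-force
oracle (triple-loop walk accumulation, hand-run Benjamini–Hochberg,
factorial hypergeometric sums, breadth-first closeness) on instances of
12–200 elements, and the end-to-end properties at the reference
conditions above: 20 cohorts for cluster recovery, 200 null datasets with
1,000-iteration nulls for family-wise-error calibration, 10 screens of
2,000 genes for transcriptome recovery. These sizes keep the full suite
within a few minutes on one CPU while leaving Monte-Carlo error well
inside the asserted bands; `analysis/03_association.R` uses the full
10,000-iteration null that per-study inference warrants.

## Known limitations

* The chains store dense matrices; node counts beyond a few thousand need
  blocked or sparse products.
* The cluster null assumes exchangeable Gaussian node noise (no residual
  smoothness model) and is conservative on small discrete lattices.
* The similarity null ignores spatial autocorrelation of both map and
  expression.
* Fold-enrichment values depend on the chosen background universe;
  comparisons across tools require matching reference lists.
* Hop-count closeness ignores interaction confidences by default.
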