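---
title: "Methods: the redundancy index and its cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the redundancy index and its cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The redundancy index

A functional brain network is *redundant* when information can travel
between any two regions along more than one route, so a single failing
node does not sever communication. `redconn` operationalizes this for the
dynamic functional connectome through two classical graph predicates:

* **connectedness** — a path exists between every pair of nodes and no
  node is isolated;
* **two-connectedness (biconnectivity)** — the graph is connected, has at
  least three nodes, and no articulation point: removing any single node
  leaves it connected, equivalently every pair of nodes is joined by at
  least two internally node-disjoint paths.

Both predicates depend strongly on edge density, and as density grows a
thresholded network passes from disconnected to connected and eventually
to two-connected. Rather than locating both transition points, the index
asks a single question per sliding window: *when the network first becomes
connected, is it already two-connected?* The per-window state is 1 if the
minimally connected thresholded graph is two-connected and 0 otherwise,
and the redundancy index (RI) is the mean state over windows, reported as
a percentage. A window whose graphs never connect anywhere on the density
grid receives state 0 — a network that cannot even connect cannot be
redundant; this case is not otherwise specified by the state rule and is a
documented choice (`minimal_connected_density()` returns `NA` there, so
the situation is visible in the per-window output).

Two-connectedness is evaluated *only* at the minimal connected density: a
denser graph in the same window being biconnected does not rescue the
state. A two-node graph is defined not two-connected, since a single edge
provides one path only. One- and two-node graphs therefore always score 0.

## Pipeline parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| window length | 30 | volumes | 60 s at TR = 2 s — long enough for a stable correlation estimate, short enough to track dynamics; 40 and 50 are offered as robustness settings (`ri_sweep()`) |
| window step | 1 | volumes | maximal temporal resolution; consecutive 30-volume windows overlap by 58 s |
| TR | 2 | s | typical fMRI repetition time; supplied with the series, not read from file |
| density grid | 5–50% in 5% steps | fraction of possible edges | 10 graphs per window; the 50% cap avoids the saturated regime where every graph is trivially biconnected |
| edge ranking | signed | — | strongest positive correlations first, the common proportional-thresholding convention; `ranking = "absolute"` ranks by magnitude instead |
| k(d) rounding | half-up | edges | see below |
| correlation cap | 1 − 1e−7 | — | perfect correlations (degenerate windows) are capped, not rejected: thresholding uses only ranks, so the cap value is inconsequential |

### Numerical choices

* **k(d) = round(d·N(N−1)/2)** with *half-up* rounding (`floor(x + 0.5)`),
  because IEEE round-half-to-even would make k ambiguous-looking at exact
  .5 boundaries (e.g. d = 0.05 with 10 possible edges). `floor` and
  `ceiling` are available via the `rounding` argument.
* **Ties in edge weights** are broken by lexicographic node-pair order
  after the weight sort. A single ranking serves all densities, which
  makes the graph stack *nested* by construction — the edge set at any
  density is a subset of the edge set at any higher density — and makes
  connectedness monotone in density. Because atanh is strictly
  increasing, binarization from raw correlations and from Fisher-z
  matrices is identical.
* **Zero-variance regions** within a window are an error naming the region
  and window, not a silent NaN.
* Graph predicates are computed with `igraph` (components and articulation
  points via depth-first search); the test suite verifies both predicates
  against independent brute-force oracles — matrix-power reachability and
  exhaustive single-node removal — on hundreds of random graphs, so
  correctness does not rest on the particular algorithm.

## Cohort statistics

All regressions are ordinary least squares on z-scored variables
(sample SD), so reported coefficients are standardized betas; binary
predictors are standardized like continuous ones to keep betas comparable
(raw coding available via `standardize = FALSE`). In a simple regression
the standardized beta equals the Pearson correlation, which the tests
assert as a numeric identity.

* **FDR control** is Benjamini–Hochberg, applied *within each cognitive
  domain* across the predictor family tested for that domain.
* **Stepwise selection** is forward–backward with entry p < 0.05 and
  removal p > 0.10 (the convention of the SPSS software family), with
  covariates forced into every model and never eligible for removal. A
  rank-deficient candidate set (e.g. a duplicated column) is rejected up
  front; an iteration cap guards against entry/removal cycling.
* **Cross-validation** re-runs the selection inside every training fold —
  reporting only the full-data selection would understate selection
  variability — and evaluates out-of-fold MSE on the raw outcome scale.
  The adjusted R² is reported from a full-data refit of the full-data
  selection; both quantities are returned side by side since either may
  be quoted as "the" model fit.
* **Collinearity** is screened with variance inflation factors
  (`car::vif`); VIF is exactly 1 for orthogonal predictors.

## Mediation

Simple mediation X → M → Y with a shared covariate set: a from M ~ X +
covariates, b and c′ from Y ~ X + M + covariates, total effect c from
Y ~ X + covariates. With identical covariates in all three models the
decomposition c = c′ + a·b is an algebraic identity of nested OLS, which
the tests check to 1e−10.

The indirect effect a·b gets a **percentile bootstrap** 95% CI (default
5000 resamples; bias-corrected bounds via `ci_type = "bias_corrected"`).
Percentile intervals are the default because they are the more common
report in PROCESS-style analyses and their null coverage is verified by
simulation in the test suite. Standardization is performed once on the
full sample before resampling, so path coefficients remain on a common
scale across resamples; per-resample re-standardization would conflate
scale noise with sampling noise. A resample with a degenerate design —
e.g. an all-zero draw of a rare binary exposure — is redrawn and counted.
Classification: *full* mediation when the CI excludes zero and c′ is not
significant at α = 0.05; *partial* when the CI excludes zero and c′ is
significant; *none* otherwise. Default covariates are age, sex and
education.

## Synthetic data: what it does and does not emulate

The time-series generator draws zero-mean multivariate normal samples
under a block-constant correlation structure (communities with correlation
`within_block_corr`, `between_block_corr` across, unit-variance signal)
plus independent Gaussian noise. This is the simplest family in which the
density sweep produces minimally connected graphs on both sides of the
two-connectedness boundary. Observed correlations attenuate by the closed
form r/(1 + noise_sd²), which the tests use as an independent check. The
generator does **not** model hemodynamics, temporal autocorrelation, head
motion, or scanner drift — so passing tests demonstrate correctness of the
graph pipeline, not realism of BOLD dynamics, and RI values obtained on
synthetic series are not comparable to values from real cohorts.

The cohort generator emulates a community-dwelling older-adult table:
age ~ N(58, 6), 57% female, ~9 years of education, log-normal mean
framewise displacement around 0.11 mm, vascular risk prevalences near
27/40/9/17/32%, small-vessel markers with ~10% lacune and microbleed
prevalence, and cognitive-reserve scores. The exposure X (binary at 10%
prevalence by default, emulating an unbalanced marker such as microbleeds,
or standard normal), mediator M and outcome Y follow the linear system

  M = a·X + γ′_M Z + e_M,  Y = c′·X + b·M + γ′_Y Z + e_Y

with Z the z-scored age/sex/education covariates. The mediator is kept on
its generative z-like scale (the column is named `ri_percent` for schema
compatibility; no cosmetic rescaling is applied, since rescaling would
change the recoverable coefficients). Cognitive-domain columns other than
the designated outcome are covariate-driven noise; the memory composite in
a real table would be the re-standardized mean of several recall and
recognition scores, a mapping the generator abstracts into a single
z-column.

**Identifiability of the noise-free case.** With `noise_m_sd = 0` the
mediator is an exact linear function of X and the covariates, so M cannot
itself appear as a regressor alongside them — the design is rank-deficient
by construction. Exact recovery is therefore verified equation-wise: a is
exact when the M-equation is noise-free; b and c′ are exact when the
Y-equation is noise-free (with a noisy M). This is a property of linear
systems, not of the implementation.

## Problem sizes

The test suite and analysis scripts run at sizes chosen to exercise every
transition while keeping a laptop run comfortable: graphs of 4–20 nodes
for the oracle comparisons (200+ random graphs), 14–16-region series for
the RI invariance checks, a 100-region × 240-volume series per subject in
the analysis workflow, cohorts of 121–2000 subjects for the regression and
mediation recovery checks, and 500 simulations × 1000 bootstrap resamples
for the null-coverage study of the indirect-effect CI.

## Known limitations

* RI is a global scalar; no per-node, per-module, or k > 2 connectivity
  variants are provided.
* Whether proportional thresholding should rank signed or absolute
  correlations is a genuinely open convention; signed is the default and
  the alternative is one argument away, but results can differ when
  strong negative edges are present.
* Ordinal imaging grades (perivascular-space and white-matter scores)
  enter the linear models as numeric scores; no ordinal regression is
  offered.
* The stepwise procedure inherits the known inferential caveats of
  stepwise selection; the cross-validation output (per-fold selections and
  out-of-fold MSE) is the intended guard against over-reading the
  full-data fit.
* Mediation is single-mediator and linear; no moderated, serial, or
  SEM-based estimation.
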