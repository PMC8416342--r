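---
title: "Methods: network analysis of survey cohorts with surveynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network analysis of survey cohorts with surveynet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surveynet)
```

## Overview

`surveynet` analyses wide-format mental-health survey cohorts of the kind
collected from university students during the COVID-19 pandemic: one row
per respondent carrying grade (year of study), sex, and 43 coded analysis
variables — 7 pandemic-attitude items on a 5-point agreement scale coded
−2..+2, one binary school-dropout-intention item, the 10 PSS items
(0..4), the 7 GAD-7 items (0..3), the 9 PHQ-9 items (0..3), 6 binary
spare-time-activity flags, and 3 binary online-class-difficulty flags.

Four analysis stages are provided, each usable on its own and chained by
`run_pipeline()`:

1. **Scale scoring** (`score_cohort()`): instrument totals with reverse
   coding and moderate-severity cut-offs.
2. **Group comparisons** (`compare_cohort()`, `compare_table1()`):
   chi-square homogeneity, Kruskal–Wallis, and one-way ANOVA across the
   four grade strata with Bonferroni-adjusted thresholds.
3. **Psychometric diagnostics** (`pca_varimax()`, `kmo()`,
   `bartlett_sphericity()`, `cronbach_alpha()`): principal components of
   the attitude items with varimax rotation and the usual adequacy
   checks.
4. **Network analyses**: a group-wise Bayesian network learned by
   BIC-scored hill climbing with bootstrap model averaging
   (`bootstrap_average()`), and per-respondent intra-individual
   covariance networks with graph-theoretic hub detection
   (`icn_study()`).

Because raw cohorts of this kind are typically not publicly deposited, a
synthetic-cohort generator (`generate_cohort()`) reproduces the
statistical structure the analyses assume, so every stage is exercised by
tests without access to real data.

## Scale scoring

Totals are plain sums with each reverse-scored item $i$ contributing
$(\max - x_i)$. The PSS-10 follows the instrument's published convention
of reverse-scoring its four positively stated items (items 4, 5, 7, 8);
GAD-7 and PHQ-9 have no reverse items. Moderate anxiety and moderate
depressive mood are flagged at GAD-7 $\ge 10$ and PHQ-9 $\ge 10$, the
cut-offs validated for the population the package targets. The PSS
carries no conventional moderate cut-off, and asking for one is an
error rather than a silent default.

Records with any missing analysis variable are dropped before analysis
(with a message and a count attribute); item-level imputation is out of
scope.

## Group comparisons

Binary items are compared across the four grades with the Pearson
chi-square test of homogeneity *without* continuity correction — on a
4×2 table (df = 3) the correction is neither customary nor compatible
with the published statistics the package reproduces. Ordinal attitude
items use the tie-corrected Kruskal–Wallis test; scale totals use the
classic equal-variance one-way ANOVA. Significance thresholds follow the
source analysis: $0.05/3 = 0.017$ for main analyses (three outcome
domains) and $0.05/6 = 0.008$ for the six pairwise grade contrasts. The
source does not name its post-hoc procedure; as a documented convention
the same family of test is applied to each grade pair.

`anova_from_summary()` computes $F$ from per-group means, SDs and sizes,
algebraically identical to the raw-data $F$ (the identity is tested to
$10^{-10}$ relative error). When checking an $F$ printed alongside
moments rounded to one decimal, exactness is impossible: for the PSS row
the recomputed $F$ lies within 0.15 of the printed value, and 0.15 is
the documented tolerance. The same computation applied to the anxiety
scale's printed row differs from its printed $F$ by about 0.19 — a
rounding artefact of the same kind, which is why only loose consistency
is asserted there.

One published contingency row (sleep) is internally inconsistent — its
grade-3 cells sum to 131 where the stratum holds 121 respondents — and
is flagged by `table1_counts()$consistent` and excluded from
exact-reproduction checks.

## Psychometric diagnostics

PCA operates on the correlation matrix (items share a response scale but
not a variance), retaining components with eigenvalue strictly greater
than 1 (Kaiser). Retained loadings are varimax-rotated with Kaiser
normalization at tolerance $10^{-6}$, then each column's sign is flipped
so its largest-magnitude loading is positive, giving a reproducible
orientation. Rotation preserves per-item communalities and the retained
variance (tested at $10^{-8}$). Ordinal items are treated as numeric —
Pearson correlations — matching the source analysis; polychoric
correlations and parallel analysis are out of scope.

KMO is computed from the anti-image: with $A = R^{-1}$, partial
correlations $q_{ij} = -a_{ij}/\sqrt{a_{ii}a_{jj}}$, and
$\mathrm{KMO} = \sum r^2 / (\sum r^2 + \sum q^2)$. Bartlett's test uses
$\chi^2 = -(n - 1 - (2p+5)/6)\ln\det R$ on $p(p-1)/2$ df. Cronbach's
$\alpha$ is the variance-ratio form. All three have brute-force oracles
in the test suite.

## Bayesian-network structure learning

All 43 items are treated as discrete multinomial variables with level
sets fixed by the schema *before* any resampling, so bootstrap resamples
are scored against identical state spaces. The network score is the
decomposable BIC

$$\mathrm{score}(G) = \sum_v \left[ \ell_v(\mathrm{pa}_v) -
  \tfrac{\ln n}{2}\,(L_v - 1)\prod_{u \in \mathrm{pa}_v} L_u \right],$$

with $\ell_v$ the multinomial log-likelihood of $v$ given each parent
configuration. A configurable cap on the family parameter count guards
against parent-configuration explosion: scoring past the cap is an
error, and hill climbing simply never proposes such a move.

`hill_climb()` starts from the empty graph and greedily applies the
single-edge add/delete/reverse move with the largest strictly positive
gain, skipping cycle-creating moves. Among equal-gain moves the
lexicographically smallest (operation, source, target) is chosen — with
operations ordered add < delete < reverse — so the search is fully
deterministic and needs no randomness. Family scores are cached, so each
iteration costs one cache lookup per candidate move in the common case.

`bootstrap_average()` draws $B$ nonparametric resamples, learns a
structure on each, and tabulates for every unordered pair the presence
strength (fraction of resamples connecting the pair either way) and
direction strength (fraction of those oriented each way). Edges with
presence at or above the threshold (default 0.5, configurable — the
source describes only "most consistent" edges) are kept and oriented by
majority, ties toward the lower-indexed source. Majority orientations
can in principle combine into a cycle; if so, the lowest-presence edge
of each cycle is dropped, deterministically and with a message, until
the graph is acyclic. The reference analysis used $B = 10{,}000$; the
package default is 200, adequate for testing, and fidelity runs simply
pass a larger `B`. Local conditional-probability tables are not
estimated — the deliverable is the averaged structure.

## Intra-individual covariance networks

Each respondent's profile is the vector of z-deviations
$z_i = (x_i - M_i)/SD_i$ against cohort means and SDs. The similarity
between items $a$ and $b$ within a respondent is

$$w_{ab} = \exp\!\left(-(z_a - z_b)^2\right),$$

which lies in $(0, 1]$, equals 1 exactly when the two items deviate
identically, and decays monotonically as the deviations diverge. (The
source renders this formula garbled by typesetting; this is the unique
reading consistent with its stated range and interpretation.)

Proportional thresholding at sparsity $K$ keeps exactly
$\mathrm{round}(K \cdot 903)$ of the 903 off-diagonal weights as binary
edges ($K = 0.14$ keeps 126), ties at the cut broken by lexicographic
pair order. The working $K$ is the smallest grid value (grid 0.05–0.20
in steps of 0.01; the source's stated interval width is impossible to
reconcile with its grid bounds, and 0.01 makes its chosen 0.14 a grid
point) at which more than 95% of respondents satisfy three criteria:
connectedness (> 80% of items in the largest component), small-worldness
$\sigma = (C/\bar C_{null})/(L/\bar L_{null}) > 1$ against 20
degree-preserving rewired null graphs (10×|E| swap attempts each; C is
the mean local clustering coefficient with degree-<2 nodes counted 0, L
the characteristic path length of the largest component), and modularity
$Q > 0.3$ from the best of 5 seeded Louvain restarts. Rewiring was
chosen over density-matched random graphs for the null because it
preserves the degree sequence, the stricter and more common convention;
the restart count and null-ensemble size are configurable. Metrics are
computed on the binarized graph; weights are discarded after
thresholding.

Betweenness centrality is unweighted shortest-path betweenness,
rank-transformed within each respondent in descending order with ties
taking the minimum shared rank — so "rank ≤ 4" keeps its top-10%-of-43
meaning under ties. A hub is an item whose rank is at or above the rank
threshold in more than the prevalence threshold of respondents; two
published presets ship (`"results"`: rank ≤ 4 in > 40%; `"figure"`:
rank ≤ 5 in ≥ 25% — the source states both in different places), with
the stricter one as default. Spearman correlations between an item's
rank profile and the scale totals are flagged at $|\rho| > 0.3$ and
$p < 0.001$.

## The synthetic cohort generator

`generate_cohort()` draws, per respondent, a general distress factor and
four block factors (stress, anxiety, depression, attitude), all standard
normal. Each ordinal item is a linear combination of factors (its row of
the loading matrix) plus an item difficulty offset plus Gaussian noise,
cut into coded levels by fixed per-block thresholds. Grade effects enter
as a mean offset of the *general factor*, reaching each item through its
signed general loading — so reverse-keyed PSS items shift coherently
with the construct rather than cancelling. Binary items threshold their
own latent score at the per-grade prevalence quantile, reducing to
independent Bernoulli draws at the configured prevalence when (as by
default) they carry no factor loadings.

Defaults are chosen once to emulate the study conditions: grade strata
of 123/110/121/100 respondents; per-grade binary prevalences equal to
the observed frequencies of the printed contingency rows; a grade shift
of (0.4, 0.15, −0.15, −0.4) giving junior students roughly half a
standard deviation more latent distress than seniors, consistent with
the printed scale means; loadings of 0.7 (general) and 0.5 (block) on
symptom items with noise SD 0.5, i.e. inter-item correlations in the
0.4–0.75 range typical of these instruments; and skewed GAD-7/PHQ-9
thresholds that put mean totals and moderate-severity rates in the low
single digits and low tens of percent respectively, as screening
instruments show in student populations.

**Item difficulty matters more than it looks.** Real survey items differ
widely in endorsement rates, and the generator spreads difficulties
evenly within each block (±0.7 latent SD) by default. Although
z-scoring cancels difficulty in an item's *mean* deviation, it does not
cancel it in the *grid* of attainable z-values of a coded item: item
difficulties stagger the quantized z-grids across items. Without that
spread, all items of a block share one grid, same-code pairs sit at
near-zero z-gaps, and the thresholded ICN's fixed edge budget is
exhausted by co-located pairs — networks fragment and the screening
criteria become unsatisfiable at any grid sparsity. With it, respondent
profiles spread quasi-continuously and the screen behaves as in real
data, with connectedness the binding criterion as $K$ decreases.

What the generator does **not** emulate: the real cohort's full joint
distribution (fitting the generator to the printed moments is explicitly
out of scope), item-specific wording effects, non-Gaussian latent
structure, and missingness patterns. Tests passing on synthetic cohorts
show the pipeline's operations are correct and calibrated under the
stated latent-factor model; they do not certify conclusions about any
real cohort.

## Planted hubs and what recovery can mean

`plant_hub_item()` exists so hub detection can be tested against a known
ground truth. Its design follows from a geometric fact about this ICN:
since $w_{ab}$ depends only on $|z_a - z_b|$, each respondent's
thresholded network is a one-dimensional proximity graph on the z-line.
A bridge item midway between two item blocks sits $|D|/2$ from each
shore, where $D$ is the shore separation, while the direct shore-shore
gap is $|D|$; bridging edges are retained *and* direct edges excluded
only when $|D|$ falls inside the window between the retention cut and
twice the cut. For any Gaussian-distributed separation that window
captures a minority of respondents, which caps the per-respondent
probability that a designated item is the bridge — empirically, no item
(planted or natural) attains a top-10% betweenness prevalence much above
a third under realistic 4/5-level quantization, short of the stricter
hub preset's 40%.

The planting construction therefore concentrates $|D|$ inside the
window: the two bridge blocks are placed on a shared latent factor with
opposite difficulty offsets (0.45 latent SD apart by default), so their
deviation bands sit a controlled distance apart in every respondent, and
the hub item is given the shared factor at zero offset, landing midway.
All planted quantities blend with the original configuration, so
strength → 0 recovers it. Recovery is asserted at the level this
geometry supports: pooled across cohorts, the planted item's top-10%
prevalence is enriched well above the exchangeable-null expectation of
4/43 and the item ranks among the very top items cohort-over-cohort,
while under the exchangeable null (i.i.d. z-profiles) essentially no
cohort yields any hub at the default criteria. Those are the properties
the test suite and the acceptance script measure.

## Numerical choices and degenerate inputs

* Chi-square requires positive row and column marginals; a zero marginal
  is a degenerate-table error. All-identical values give H = 0, p = 1
  from Kruskal–Wallis (not an error); zero within-group variance with
  equal means makes F undefined and is an error, with unequal means it
  yields F = ∞.
* A constant item makes z-scoring impossible and the item is named in
  the error. K values retaining zero edges are errors.
* σ is undefined (and flagged) when the null ensemble has no triangles.
* Hill-climb gains must exceed $10^{-8}$ to count as improvements,
  protecting termination against floating-point noise.
* Bootstrap direction ties (exactly 0.5/0.5) orient toward the
  lower-indexed node; threshold ties at the proportional cut resolve in
  lexicographic pair order. Both are logged conventions, not data-driven
  choices.

## Problem sizes used by the test suite

The suite runs the full pipeline at reduced scale, chosen so the whole
battery completes comfortably on a laptop: bootstrap averaging with
B = 200 on 3-variable chains and B = 5 for the 43-variable smoke test;
hill-climb-versus-enumeration on 100 three-node datasets; chain-skeleton
recovery on 50 datasets of n = 5000; planted-hub pooling over 8–10
cohorts of n = 200; null-hub calibration on 500 cohorts of n = 454;
type-I-error calibration on 1000 replicate cohorts. Fidelity-scale runs
(B = 10,000, dense K grids, 20-null screens for every respondent) use
the same code paths through configuration alone.

## Known limitations

* The averaged-DAG edge set of the original analysis is not an exact
  reproduction target: the presence/direction threshold behind its
  published figure is unstated, and the raw data are unavailable.
* Printed psychometric diagnostics (KMO, Bartlett, explained variance,
  α) depend on the unavailable raw data and serve as documentation
  anchors only; the package asserts the formulas against oracles
  instead.
* The ICN hub criteria interact with item marginals through the
  quantized z-grids; hub prevalences from cohorts with strongly
  different marginal structure are not directly comparable.
* Discrete BIC is the only structure score implemented; ordinal-aware
  scores and local-parameter estimation are out of scope.
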