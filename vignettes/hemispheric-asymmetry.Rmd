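---
title: "Quantifying hemispheric asymmetry of weighted structural brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hemispheric asymmetry of weighted structural brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(hemiasym)
```

## The problem

Structural connectomes built from diffusion tensor imaging (DTI)
tractography describe the white-matter wiring of a brain as a weighted
graph: parcellation regions are nodes, and a pair of regions is linked
when streamlines connect them, with the mean fractional anisotropy (FA)
of the connection as the edge weight. Many psychiatric conditions —
bipolar disorder among them — are hypothesized to disturb not just the
topology of this network but its *lateralization*: the normal left/right
differences in network efficiency and small-world organization.

`hemiasym` implements the full analysis chain for this question:

1. **Network construction.** From a whole-brain fiber-number (FN) matrix
   and FA matrix, keep an edge only when its fiber count is strictly
   greater than a threshold (default 3 — low-count connections are likely
   tractography noise), discard all inter-hemispheric connections, and
   form one weighted network per hemisphere (45 nodes each under the
   packaged AAL-90 parcellation).
2. **Graph metrics.** Weighted clustering coefficient $C_p$,
   characteristic path length $L_p$, global efficiency $E_g$, local
   efficiency $E_{loc}$, and per-region nodal efficiency
   $E_{nodal}(i)$, with topological distance defined as the reciprocal
   of the FA weight.
3. **Null normalization.** Small-world quantities
   $\gamma = C_p/C_{rand}$, $\lambda = L_p/L_{rand}$,
   $\sigma = \gamma/\lambda$ against an ensemble of (by default 100)
   degree- and weight-matched rewired random networks.
4. **Asymmetry scores.** For every metric $X$,
   $AS(X) = 100\,[X(R)-X(L)]/[X(R)+X(L)]$; positive values mean
   rightward, negative leftward lateralization.
5. **Statistics.** A repeated-measures GLM (hemisphere within subject,
   group between subjects, group-by-hemisphere interaction; age, gender
   and age-by-gender as covariates), one-sample t-tests and a univariate
   ANCOVA on the asymmetry scores, Bonferroni correction across regional
   families, and partial Pearson/Spearman correlations between regional
   asymmetry and clinical severity scores in the patient group.

Because raw DTI data cannot ship with a package, a first-class synthetic
cohort generator emulates the statistical structure such a study
analyzes, with known injectable effects, so that every stage is testable
against ground truth.

## Metric definitions and conventions

Edge weights are FA values in $(0,1]$. The distance between adjacent
nodes is $1/w$, the standard convention for FA-weighted connectomes
(stronger tracts are functionally "closer"). Since $w \le 1$, all
finite shortest-path distances are $\ge 1$ and every efficiency lies in
$[0,1]$.

* $L_p$ is the mean shortest-path distance over *connected* ordered
  pairs; the number of excluded (unreachable) pairs is reported
  alongside. This keeps $L_p$ finite on fragmented hemispheric graphs —
  disconnection is already captured by $E_g$, which uses
  $1/d = 0$ for unreachable pairs. The alternative (declare $L_p$
  infinite) would make group statistics on sparse networks degenerate.
* $E_g$ is the mean of $1/d_{ij}$ over all ordered pairs; identically
  the mean of the nodal efficiencies. ($E_g$ is often described loosely
  as the "inverse" of $L_p$; with these definitions it is the mean of
  inverses, not the inverse of the mean, and we implement the standard
  efficiency form.)
* Weighted clustering follows the Onnela geometric-mean form with
  weights normalized by the network-wide maximum,
  $C_i = \frac{1}{k_i(k_i-1)}\sum_{j,h}
  (\tilde w_{ij}\tilde w_{ih}\tilde w_{jh})^{1/3}$.
  This is the convention of the common connectome toolboxes; the Barrat
  form (arithmetic weights over binary triangles) was considered and
  rejected to stay aligned with that practice. Nodes with degree < 2
  score 0 and are *included* in the average.
* $E_{loc}$ averages, over nodes, the global efficiency of each node's
  neighborhood subgraph with its original weights (not renormalized),
  the central node excluded; degree < 2 nodes contribute 0.
* Null networks randomize topology by Maslov–Sneppen double-edge swaps
  (10 attempted swaps per edge by default), which preserve each node's
  degree exactly, and then permute the original weight multiset onto the
  rewired edges. Weight–degree correlations are deliberately *not*
  preserved; "matched" here means degree sequence plus weight
  distribution, the common toolbox behavior. Nulls are not forced to be
  connected; the connected-pairs $L_p$ convention absorbs occasional
  fragmentation. $\sigma$ is defined as $\gamma/\lambda$. The ensemble
  statistic is the arithmetic mean of the per-null $C_p$ and $L_p$.

All-pairs shortest paths are computed by Dijkstra's algorithm (via
`igraph`); the test suite checks them against an independent exhaustive
path-enumeration oracle on small graphs, and checks the clustering and
local-efficiency implementations against literal-formula evaluations.

## The statistical model

The two-level within-subject factor is solved by the exact
sum/difference decomposition, which for two levels is algebraically
identical to the classical mixed-model ANOVA and easy to audit:

* group main effect — OLS regression of the subject mean $(L+R)/2$ on
  group and covariates;
* hemisphere main effect — intercept of the regression of the
  difference $R-L$ on group and covariates;
* group-by-hemisphere interaction — the group coefficient of that same
  difference regression.

Each reported $F$ with $(1, n - p)$ degrees of freedom is the square
of the corresponding regression $t$; the equality is verified
numerically in the tests, as is the exact agreement with `aov`'s
repeated-measures strata in the covariate-free case.

Covariates are coded so the decomposition stays interpretable: age is
mean-centered, gender effect-coded ($\pm 1/2$), and the age-by-gender
product formed after centering — the difference-model intercept is then
the covariate-adjusted hemisphere effect at the sample-average age,
averaged over genders. Group is also effect-coded. Two-sample t-tests
use the pooled-variance Student form ($df = n_1 + n_2 - 2$, e.g. 108
for 49 + 61 subjects), not Welch, matching the convention of the
classical repeated-measures framework around them.

Regional (nodal-efficiency) families are Bonferroni-corrected over the
45 regions (significance at $p < \alpha/45$, adjusted
$p = \min(1, 45p)$ reported). Clinical correlations are computed in the
patient group only and left uncorrected — they are exploratory — using
partial correlation: residualize both variables on age, gender and
age-by-gender, then correlate residuals, with $df = n - 2 - 3$. The
Spearman variant rank-transforms variables *and* covariates first and
then residualizes, treating both sides symmetrically; residualize-then-
rank was considered and rejected for that symmetry.

Asymmetry scores with a zero denominator (a region isolated in both
hemispheres) are returned as `NA` with a warning and propagate through
all statistics by pairwise deletion, with per-test `n` reported.

## What the synthetic generator emulates

`synthetic_spec()` defaults describe the cohort the pipeline is designed
for: 49 patients and 61 controls on 45 regions per hemisphere, ages on
the group ranges 22–50 / 21–49 years, education 11–19 / 12–19 years, and
gender frequencies of roughly 57%/52% male — the demographic structure
of a mid-sized two-group DTI study.

* **Template.** One intra-hemisphere topology is drawn as a
  Watts–Strogatz ring lattice at edge density 0.30 with rewiring
  probability 0.1, so the generated networks are small-world by
  construction ($\gamma > 1$); FA weights are Beta(6, 6) (mean 0.5,
  typical of white-matter FA). The template is copied *identically*
  into both hemispheres — so with no injected effects the generator is
  exactly mirror-symmetric in distribution — and every homotopic pair is
  bridged by an inter-hemispheric edge so that the elimination step is
  always exercised.
* **Subjects.** Per-subject FA is the template times hemisphere/group/
  nodal multipliers plus Gaussian edge noise (SD 0.03, a few percent of
  a typical FA value), clipped to $[0.01, 1]$. Asymmetry is injected
  multiplicatively on weights (the networks are FA-weighted and
  efficiency responds monotonically to weights); topology is never
  changed by the injection. Fiber counts on true edges are
  $4 + \mathrm{Poisson}(\max(0, 50\,\mathrm{FA} - 4))$ — mean
  $50 \times \mathrm{FA}$, and true edges always survive the default
  FN > 3 filter — while 2% of absent node pairs receive spurious edges
  with counts 1–3 that the filter must remove.
* **Clinical link.** Patient YMRS scores are generated as
  $12 + 3 \times AS(E_{nodal}(\mathrm{ROL})) + \mathcal N(0, 8^2)$,
  truncated at 0 and rounded. The slope was set so the implied partial
  correlation is about 0.3 at the default noise level — the moderate
  magnitude this clinical literature reports for regional-asymmetry /
  severity associations — giving the correlation-recovery tests a
  realistic target. HAMD is drawn independently (mean 12, SD 8.4,
  truncated to 0–32); controls carry `NA` clinical scores.
* **Reproducibility.** One master seed; the template, the metadata, each
  subject, and the clinical draw use streams derived from it by a fixed
  key-hashing scheme, so cohorts are bitwise reproducible and subjects
  independent.

What the generator does **not** emulate: spatial structure of real
parcellations (hub architecture, modules, distance-dependent
connectivity), FA correlations between neighboring edges,
weight–degree correlations, scanner/site effects, and any relationship
between medication or illness duration and the network (recorded as
placeholders only, as they enter no analysis). Passing tests therefore
demonstrate the *statistical machinery* — calibration, power, sign
recovery — not fidelity to any particular empirical connectome.

## Numerical and design choices

* Strict fiber filter: FN must be *larger than* the threshold; FN = 3
  edges are removed at the default.
* Hemisphere membership comes from the parcellation file, never from
  index parity; the packaged `aal90.tsv` encodes the AAL convention
  (alternating L/R), and the k-th left and k-th right region in scheme
  order are homotopic partners.
* Input symmetry tolerance is $10^{-8}$; larger asymmetry is an error,
  not a silent symmetrization.
* Metric comparisons in the test suite use absolute tolerance
  $10^{-9}$ or tighter ($10^{-12}$ against the oracles).
* The ring-lattice neighbor count is the rounded density target; the
  requested density 1 is special-cased to the complete graph. A
  disconnected template triggers a warning, not an error.
* Degenerate statistical inputs (zero variance, fewer than two
  observations, rank-deficient designs) raise errors naming the
  problem; a zero-residual fit with a zero coefficient is reported as
  $t = 0$, $p = 1$ rather than `NaN`.

## Problem sizes used in the shipped tests

The packaged validation uses sizes chosen to make the full suite run in
minutes while keeping every check at the study's relevant scale: oracle
comparisons on 200 random graphs of up to 7 nodes; small-world checks on
the full 45-node default template with 100-null ensembles over 20 seeds;
type-I calibration with 1000 replicate cohorts at the design sample
sizes (49/61) using global efficiency; and effect-recovery checks with
200 replicates each for the hemispheric delta (0.15) and the clinical
link. The miniature fixture cohort (6 subjects, 10 regions per
hemisphere) exercises every code path, including an FN = 3 edge that the
filter must remove and a region isolated in both hemispheres that
produces a zero-denominator asymmetry score.

One property deserves a caveat: for a genuinely small-world topology the
normalized path length $\lambda$ exceeds 1 by construction (clustering
is bought with slightly longer paths). Under the default template
$\lambda \approx 1.06$, which is "close to 1" in the conventional
small-world sense ($\sigma > 1$ comfortably) but is many *ensemble*
standard deviations away from 1, because the 100-null ensemble spread of
$L_p$ is only a few tenths of a percent. Checks that compare
$\lambda - 1$ against the null-ensemble spread will therefore flag any
small-world network; $\gamma$ and $\sigma$ are the meaningful
small-world indicators.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(delta_right_control = 0.15, seed = 7)
cohort <- generate_cohort(spec)
metrics <- cohort_metrics(cohort$connectomes, cohort$parcellation,
                          threshold = 3, n_nulls = 100, seed = 7)
asym <- cohort_asymmetry(metrics)
stats <- run_statistics(metrics, asym, cohort$metadata, alpha = 0.05)
stats$glm_global[stats$glm_global$effect == "group_x_hemisphere", ]
```

Or, as one reproducible run with all tables written to disk:

```{r pipeline, eval = FALSE}
res <- run_pipeline(run_config(out_dir = "run1",
                               spec = spec, n_nulls = 100, seed = 7))
```

## Known limitations

* The pipeline consumes whatever FA matrix it is given; whether FA was
  averaged per streamline or per voxel upstream is outside its scope.
* Only FA-weighted analysis is implemented — no binarized networks, no
  inter-hemispheric network, no betweenness/modularity/rich-club
  metrics, and no lattice-normalized small-world variants.
* The repeated-measures decomposition is exact only for a two-level
  within-subject factor (which is all a hemisphere contrast needs).
* Bonferroni is the only regional multiple-testing correction offered.
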