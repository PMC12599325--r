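---
title: "Methods: classifying and quantifying pairwise co-culture interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and quantifying pairwise co-culture interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocultr)
```

This vignette documents the statistical model behind `cocultr`, the
conventions and tunable parameters of each stage, the design of the
synthetic-data module, and the numerical choices that complete
definitions left open by the underlying formulas.

## The measurement model

The unit observation is an endpoint fluorescent cell density
(cells/ml) of one species after 72 h, in mono-culture or in
co-culture with one partner, in a defined environment, in biological
triplicate. Environments are sets of carbon sources at a fixed total
concentration (default 1.0 mg/ml) contributed equally by mass; zero
sources encodes the no-carbon control.

Flow-cytometric density estimates have a lower reporting limit.
Every density below the **detection floor** (default
4.57 × 10⁵ cells/ml, the constant published with the assay, derived
there from the 90th percentile of densities observed without carbon
sources) is set to the floor *per replicate measurement, before any
summary*. Flooring first matters: means, variances and ratios are all
computed from floored replicates, so a species that never grew has a
well-defined (floor-valued) yield rather than a zero that would make
log ratios diverge. Flooring is idempotent and flagged, so the
sensitivity variant that drops floor-bound records can be applied
downstream.

## Unidirectional effects and the six classes

For focal species $i$ with partner $j$ in environment $m$, the three
replicate ratios $Y_m^{i,j}(r)/\bar{Y}_m^i$ are tested against 1 with
a two-sided one-sample Student $t$-test on the raw ratios
($\mathrm{df} = n - 1$). Testing raw ratios (not log ratios) follows
the assay's published procedure exactly. Two conventions complete the
definition:

* **Zero-variance triplicates** happen whenever all three replicates
  were floored. The $t$-statistic is then undefined; we set $p = 1$
  when the constant ratio equals 1 and $p = 0$ otherwise, which is the
  limit of the test as the variance shrinks around a fixed mean.
* **The multiple-testing family** is *every* unidirectional test of a
  run — both directions, all pairs, all environments — adjusted
  together by Benjamini–Hochberg at the configured FDR (default
  0.05). The source procedure states one correction over the
  comparisons; a single global family is the straightforward reading
  and only borderline calls depend on it.

Calls are `+` (significant, mean ratio > 1), `-` (significant,
mean ratio < 1), else `0`; the unordered pair of calls maps to
mutualism, commensalism, exploitation, neutralism, amensalism or
competition. For summaries, mutualism + commensalism are aggregated
as *synergistic* and competition + amensalism as *competitive*;
exploitation and neutralism are reported on their own.

## Effect size and the interaction-type angle

The quantitative effect is $E_m^{i,j} = \log_2
(\bar{Y}_m^{i,j}/\bar{Y}_m^i)$ on means of floored replicates.
Because $E$ uses means while the sign calls use a test on replicate
ratios, the two can disagree in noisy data; both are reported and no
reconciliation is forced.

The interaction type is the angle between the plotted point
$(\min(E_{ij}, E_{ji}), \max(E_{ij}, E_{ji}))$ and the anti-diagonal
$\max = -\min$:

$$\theta = \arctan\!\left(\frac{E_{ij} + E_{ji}}{\lvert E_{ij} -
E_{ji}\rvert}\right)\frac{180}{\pi} \in [-90^\circ, 90^\circ].$$

Conventions:

* If all four mean densities of the record sit at the detection
  floor, $\theta = 0^\circ$ (nothing grew; no interaction is
  measurable).
* If $E_{ij} = E_{ji} = 0$, $\theta = 0^\circ$.
* If $E_{ij} = E_{ji} \neq 0$ the formula's denominator vanishes.
  We define $\theta = \operatorname{sign}(E_{ij} + E_{ji}) \cdot
  90^\circ$, the continuity limit along any path with fixed nonzero
  sum, and flag such records (`equal_effects`).

The implementation is verified against an independent geometric
oracle: rotating the plane by 45° maps the anti-diagonal onto an
axis, and the two-argument arctangent of the rotated coordinates must
reproduce $\theta$ (it does, to well below $10^{-9}$ degrees over
$10^4$ random effect pairs).

Two averages summarise $\theta$: per environment over all pairs
present ($\bar\theta_m$), and per pair over the single-carbon-source
environments only ($\bar\theta^{i,j}$), matching how each average is
defined for the 16-source design.

## Growth on mixtures versus the component average

For species $i$ on an $n$-source mixture, Group 1 is the triple of
observed $\log_{10}$ yields. Group 2 is the constructed pseudo-sample
$\{\bar m + s, \bar m, \bar m - s\}$ where $\bar m$ averages the
component-wise mean $\log_{10}$ yields and $s^2$ averages the
component-wise unbiased variances; the triple's sample mean and
unbiased standard deviation equal $\bar m$ and $s$ *exactly*, which
is the point of using it literally rather than an analytic
two-moment test. Group 1 and Group 2 are compared with a two-sided
two-sample $t$-test; the Welch (unequal-variance) form is the
default — the source analysis environment's default $t$-test — with
the pooled-variance Student form available (`welch = FALSE`) and the
choice recorded in the run manifest. All (species, mixture)
comparisons form one BH family; `higher`/`lower` verdicts require
significance, otherwise `not_different`. The headline summary is the
fraction *matched or exceeded* = higher + not_different, reported per
mixture size.

## Grower stratification

Mono-culture mean $\log_{10}$ yields separate into species that grew
substantially and species that did not. Labels come from the exact
two-cluster solution of **Ward's criterion** (minimal total
within-cluster sum of squares). In one dimension the optimum is a
contiguous split of the sorted values, which we find exactly by
scanning all $n-1$ split points; greedy agglomerative Ward linkage
can return a suboptimal two-cluster cut on exactly this kind of 1-D
data, so the exact solution is preferred and is validated in the
tests against brute-force enumeration over *all* two-partitions. Two
guards handle degenerate inputs: all values at the floor gives all
`non_grower`; cluster means closer than `gap` (default 0.5 log10
units, i.e. about 3-fold — below genuine grower/non-grower contrast)
indicate no real bimodality, and all points take the label decided by
the grand mean against floor + gap.

Clustering runs per species across its environments by default
(`axis = "species"`); the per-environment variant
(`axis = "source"`) is provided because summaries are sometimes
presented per carbon source. Each interaction is then assigned to the
`both_growers` or `any_non_grower` stratum in its environment, and
each class is tested for over-representation in each stratum against
the pooled table with a one-sided hypergeometric test, BH-adjusted
across (stratum, class). The enrichment defaults to the 1-, 2- and
4-source bins, where both strata are populated in the reference
design; bins are configurable. Since inhibition of a species that
never grew is undetectable, `stratify_interactions()` offers the
sensitivity variant that first drops records whose mono-culture
means sit at the floor.

## Community-level statistics

**Monte-Carlo chi-square.** Heterogeneity of class counts across
carbon sources (or pairs) uses the Pearson statistic with a null of
random tables with both margins fixed — equivalent to permuting class
labels across records — sampled with `stats::r2dtable`, and the
add-one estimator $p = (1 + \#\{\chi^2_{sim} \ge \chi^2_{obs}\})/(1 +
N)$, so $p$ is never zero and is bounded below by $1/(1+N)$. Default
$N = 10^5$.

**Pairwise PERMANOVA.** Environments are points in the space of
per-pair $\theta$ values; distances are Euclidean (the
distance/feature choice of the source analysis is not published, so
it is configurable in principle and recorded). For each pair of
biochemical categories (sugars, sugar alcohols, carboxylate ions,
amino acids, nucleic acids — the shipped partition of the 16
catalogued sources) the two-group pseudo-F is computed from the
squared-distance matrix; $p$ comes from permuting category labels,
with exhaustive enumeration of all label assignments whenever that
count is below `exhaustive_limit`, and BH across category pairs. On
1-D data the pseudo-F provably equals the one-way ANOVA F, which the
tests exploit as an oracle; the multivariate statistic is
cross-checked against `vegan::adonis2`.

**Species rank enrichment.** To ask whether a species is biased
toward synergistic or competitive interactions, pairs are ranked by
$\theta$ (mid-ranks for ties) and each species' statistic is the mean
rank of its pairs. The null is the permutation distribution of the
mean rank over equally sized random subsets of pairs — enumerated
exactly when feasible — with a two-sided $p$ (twice the smaller tail,
capped at 1) and BH across species. This is a deliberately plain
rank-permutation analogue of gene-set enrichment, used because the
exact weighting of the original enrichment procedure is not
published; it is exact, symmetric and assumption-free at these sizes.

**Trend test.** The association between carbon-source number and
$\theta$ is Spearman's rank correlation with mid-ranks and the
two-sided $t$-approximation $p$; the no-carbon control is excluded.

**Seeding.** One master seed governs a run. Every randomised
procedure derives a stable sub-seed by hashing the master seed with
the procedure's identity string, so results do not depend on stage
order and any stage can be reproduced in isolation. MC $p$-values use
the add-one estimator throughout.

## Counting FBA by-products

Given a stoichiometric model with carbon counts per metabolite, flux
balance analysis maximises the biomass flux subject to steady state
and flux bounds. Because the optimal flux vector is generally
non-unique, by-products are restricted to reactions *essential for
near-optimal growth*: a reaction is essential when forcing its flux
to zero drops the optimum by more than the threshold (default 1%).
Essentiality depends only on optimal values, never on which optimal
vector the solver returned. Possible carbon-containing by-products
are then the metabolites with ≥ 1 carbon atom participating in
reactions that both carry nonzero flux (relative tolerance $10^{-9}$
against solver noise) and are essential. The supplied carbon source
and any biomass pseudo-metabolite are excluded — counting the input
as its own by-product would be meaningless — and both exclusions are
flags. The biomass reaction and the exchange of the supplied source
are always in the essential set by definition.

The linear programs are solved by a compact dense two-phase simplex
with Bland's smallest-index anti-cycling rule, written for the
box-constrained, highly degenerate equality systems these models
produce and validated against hand optima; it is sized for toy models
(tens of reactions), which is also the scale of every shipped
fixture. Genome-scale models can be supplied as SBML level 3 / fbc
(a minimal importer resolves species formulas, bounds and the active
objective) or in the package's plain JSON format, but solving them is
outside the intended scale. Per-species by-product counts across
single sources are correlated (Spearman, BH across species) with the
rank of the environment-average angle, restricted to sources with
experimentally verified growth and at least three usable points.

## The synthetic-data module

No generative model is published for these assays; both generators
are engineered stand-ins with known ground truth, and that is their
purpose — they calibrate the inference, they do not imitate any real
dataset.

**Planted-effect tables** draw mono-culture means log-uniformly in
$[10^{6.5}, 10^8]$ cells/ml (well above the floor, the range of
clearly growing cultures), plant per-direction true effects
$E_{\text{true}}$, and generate replicates with multiplicative noise
— Gaussian on $\log_{10}$ density, default $\sigma = 0.05$ (a
realistic 10–15% coefficient of variation for triplicate
flow-cytometric yields), $n = 3$ replicates. With $\sigma = 0$ the
tables are deterministic and the inferred $E$ equals the planted
value exactly, which anchors the recovery tests. The default design
plants 100 pair-environments with $|E_{\text{true}}| \in \{0, 1,
1.5\}$: a 2-fold yield change is the scale of effect the three-
replicate design should reliably sign, and 0 probes the null.

**The consumer-resource simulator** is a discrete-time batch culture:
species $s$ demands $u_{sk} X_s \,\mathrm{d}t$ of resource $k$ per
step; over-demanded resources are shared pro rata to demand; a
fraction $\beta_{sk}$ of consumed carbon is secreted into the
species' by-product pool (an additional resource column consumable
only by species with nonzero uptake for it, in the same step) and the
rest becomes biomass at yield $\gamma$. Carbon mass balance holds to
machine precision by construction and is asserted to $10^{-9}$
relative in the tests. The step (default 0.05 h over 72 h) with
availability-capped, demand-proportional sharing avoids ODE stiffness
while keeping closed forms checkable: no carbon leaves densities at
the inoculum; one species on one source with $\beta = 0$ ends at
inoculum + $\gamma \cdot$ 1.0 mg/ml exactly; two identical
competitors split a source exactly in half. Inocula follow the
assay's dilution scheme: $10^5$ cells/ml in mono-culture and
$5 \times 10^4$ per species in co-culture.

The default 8-species community encodes the mechanism under study —
resource-niche overlap that grows with carbon-source diversity. Four
staple sources (Glucose, Glycerol, Succinate, Proline, the compounds
used to select culturable strains) are usable by all species at
species-specific rates ($0.4$–$1.0 \times u_0$, $u_0 = 5 \times
10^{-10}$ mg cell⁻¹ h⁻¹, giving a realistic ~0.5 h⁻¹ maximal growth
rate at $\gamma = 10^9$ cells/mg); eight sources are private to one
species each ($1.2\,u_0$); four are shared by two species
($0.8\,u_0$); and each species secretes $\beta = 0.25$ of its primary
consumption into a pool the cyclically next species can eat, so
sparse environments can show commensal cross-feeding. Environments
follow the reference design: 16 singles, nested mixtures of 2, 4, 8
and 16 (8 + 4 + 2 + 1), and a no-carbon control, total fixed at
1.0 mg/ml. The nesting makes the grower fraction provably
non-decreasing in source number (an environment union supports a
species iff some component does), and shared staples make co-growers
compete harder as diversity rises; at seed 1 the pipeline on the
default simulator yields a Spearman correlation of about $-0.43$
between source number and $\theta$. Replicate noise defaults to
$\sigma = 0.05$ as in the planted tables.

What the simulator does **not** emulate: inhibitory secretions,
quorum sensing, spatial structure, lags and temporal dynamics,
density-dependent yields, or parameters fitted to any real dataset.
Passing tests therefore show that the *inference machinery* is
correct and that the resource-competition mechanism suffices to
produce the diversity–competition trend — not that real communities
follow this generative model.

## Numerical conventions and problem sizes

* Degenerate tests resolve deterministically: zero-variance
  one-sample ratios give $p \in \{0, 1\}$ by the mean; two constant
  samples in the mixing test likewise; empty hypergeometric margins
  give $p = 1$.
* Monte-Carlo $p$-values always use the add-one estimator; exhaustive
  enumeration replaces sampling whenever the arrangement count is at
  most `exhaustive_limit` (default $2 \times 10^5$).
* Comparisons against permutation statistics use a $10^{-12}$-scale
  slack so ties are counted as "at least as extreme".
* Floor comparisons use a $10^{-9}$ relative tolerance.
* The test suite sizes its simulations for a laptop-scale run:
  $10^4$ random pairs for the angle oracle, 500 instances ($n \le
  12$) for the Ward oracle, 100 planted pair-environments, 1000
  all-null tests, $2 \times 10^4$ chi-square iterations; the full
  896-interaction simulator run appears once. These sizes are the
  package's chosen trade-off between resolution and run time.

## Known limitations

* The t-test on raw ratios treats the mono-culture mean as fixed;
  its sampling error is ignored, exactly as in the published
  procedure.
* With one global BH family, borderline calls depend on the whole
  dataset analysed together; analysing a subset can flip
  near-threshold calls.
* The equal-effects $\pm 90^\circ$ extension of $\theta$ is a
  continuity convention for a case the defining formula leaves
  undefined; such records are flagged.
* PERMANOVA's distance/feature choice and the exact original
  enrichment procedures are not published; the implementations here
  are documented, configurable stand-ins.
* The simplex solver and the toy-model format target small models;
  genome-scale FBA should use a dedicated solver stack.
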