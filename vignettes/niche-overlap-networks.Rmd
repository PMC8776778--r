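---
title: "Methods: niche-overlap networks, null models, and the synthetic study"
author: "overlapnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche-overlap networks, null models, and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapnet)
```

## The model

An isolate's resource niche is its growth vector over a 95-substrate carbon
panel, read as optical density. Competition between two isolates is scored
by the directed, asymmetric mean niche overlap

$$\bar\omega_{i\to j} \;=\; \frac{1}{N}\sum_{n=1}^{N}
  \min\!\left(\frac{g_{i,n}}{g_{j,n}},\, 1\right),$$

where the capped ratio is defined only on substrates where both isolates
grow and contributes 0 elsewhere, and $N$ (default 95) is the full panel
size. Three consequences shape everything downstream:

* $\bar\omega_{i\to j} \le |\text{shared niche}|/N$ — an isolate can only
  overlap a partner on substrates both use, so high overlap requires broad
  niches;
* on every shared substrate at least one of the two directions equals 1, so
  asymmetry between kingdoms must come from growth *magnitudes*, not niche
  membership;
* the statistic is invariant to rescaling both isolates' growth on a
  substrate by a common factor, so plate-level multiplicative calibration
  drops out.

An edge $i \to j$ is drawn when $\bar\omega_{i\to j} \ge \theta$ with
$\theta = 0.75$ by default. The inclusive rule ($\ge$, not $>$) only
matters for exact ties; it is fixed here once so the tie behavior is
defined. Isolated nodes are retained in all computations, and edge sets
across a $\theta$ sweep are nested by construction.

## Structural metrics

* **Degree records** count in- and out-edges, optionally restricted to
  same- or cross-kingdom partners; `prop_in` is the inbound share of total
  degree, undefined for isolated nodes.
* **Closeness** is the harmonic variant, $\frac{1}{n-1}\sum_{u}1/d(v,u)$,
  with unreachable pairs contributing 0. Classical closeness is undefined
  on disconnected graphs, and these networks can be disconnected (the
  design allows isolated nodes), so the harmonic form is used throughout;
  it preserves the "short paths, high value" reading.
* **Clustering** is Watts–Strogatz local clustering on the underlying
  undirected simple graph (directions collapsed, duplicates dropped);
  directed-clustering generalizations are deliberately out of scope.
* **Intransitivity** is $1 - (\text{closed 2-paths} / \text{2-paths})$,
  where a 2-path $i\to j\to k$ ($i \ne k$) is closed by an edge $i\to k$.
  It is 0 on any transitively closed relation, 1 on disjoint 3-cycles, and
  undefined when no 2-paths exist. This closed-2-path definition matches
  the transitivity concept of the competition literature the metric serves.
* **Triad census** counts the 16 isomorphism classes of directed 3-node
  graphs over all $\binom{n}{3}$ triples, in the standard census order
  003, 012, 102, 021D, 021U, 021C, 111D, 111U, 030T, 030C, 201, 120D,
  120U, 120C, 210, 300 (referred to as Triads 1–16 in that order).

Census, closeness, clustering and degrees are computed through igraph; the
test suite validates each against an independent brute-force implementation
(exhaustive triple classification from first-principles representatives,
hand-rolled BFS, triangle and 2-path enumeration) exactly on hundreds of
random graphs with $n \le 8$.

## The configuration-model null and the HOI test

Higher-order interactions are inferred when network structure deviates from
what the pairwise interaction counts alone dictate. The null model holds
every node's in- and outdegree fixed and randomizes who connects to whom:
a Markov chain of directed double-edge swaps, where two edges $a\to b$ and
$c\to d$ become $a\to d$ and $c\to b$ provided all four endpoints are
distinct in the required pattern and neither replacement edge exists. The
swap chain (compiled, using R's RNG for reproducibility) guarantees a
simple graph at every step; reciprocity is *not* preserved, only degrees.

Choices the test depends on:

* **Burn-in**: each ensemble member is a fresh chain of $10\times E$
  successful swaps from the observed network ($E$ = edge count), a standard
  mixing heuristic; configurable.
* **Empirical p**: mid-p rank, $p = (\#\{x < \hat x\} + \tfrac12\#\{x =
  \hat x\})/N$. Nested networks can admit only a handful of labelled
  configurations, making exact ties routine; pure "<" counting would bias
  p toward 0. With mid-p, a metric conserved by the null (e.g. edge count)
  lands exactly at $p = 0.5$.
* **Flags**: $p < 0.05$ "lower than expected", $p > 0.95$ "higher",
  accompanied by $z = (\hat x - \bar x_{null})/s_{null}$ with $|z|>2$ as
  the magnitude convention; $z$ is undefined for constant nulls.
* **Degeneracy**: ensembles visiting fewer than 5 unique labelled
  configurations (counted by canonical serialization of the sampled edge
  sets, not exhaustive enumeration) are flagged `degenerate`; the test is
  then uninformative because the degree sequence essentially dictates the
  network. The simulated control communities routinely hit this regime —
  highly nested fungal-dominance networks have tiny configuration spaces —
  which is itself a finding the package surfaces rather than hides.

Calibration: a network drawn from its own null ensemble and re-tested must
yield approximately uniform empirical p. Because every rewire shares the
original degree sequence, all replicates share one null distribution, and
replicates and reference draws are generated by identical chains; the
acceptance suite exploits this to check uniformity (Kolmogorov–Smirnov)
and the two-sided flag rate (nominal 10%) exactly, at modest cost.

## Cross-group statistics

Welch's unequal-variance t-test is used for all group contrasts (kingdoms
within a network; treatments across networks), with Satterthwaite degrees
of freedom. Identical constant groups return $t = 0$, $p = 1$ rather than
erroring. p-values are corrected by Benjamini–Hochberg within each table
family (global metrics; triad counts; per-leaf kingdom tests); the
correction method is recorded in the output and can be swapped (e.g. Holm)
by argument, since the underlying reference for the correction is a
configurable choice rather than a fixed fact. Triad classes absent from
every network in both groups are reported as not-applicable rather than
tested. Treatment comparisons exclude networks below 20 nodes by default,
matching a design with one undersized community.

Indegree-by-outdegree slopes are ordinary least squares with indegree as
response, per focal kingdom, partner filter and treatment; a constant
predictor is flagged degenerate instead of fitted.

Community structure uses igraph's spin-glass (Potts) optimizer on the
undirected collapse, run per connected component (the optimizer requires
connected input); isolated nodes become singletons, the stochastic search
is seeded, and the method tag travels with the result. Kingdom association
is a Pearson χ² without continuity correction; when any expected cell count
falls below 5 the p-value comes from a seeded Monte-Carlo resampling of the
table (10,000 draws) instead of the asymptotic distribution.

## The synthetic-data generator

No growth data are distributed with the package, so a generator produces
studies with the statistical structure the analysis expects: 12 communities
(6 control, 6 NPK), each 10 bacteria + 10 fungi on 95 substrates, with an
optional undersized control leaf (5 bacteria) to exercise unequal network
sizes.

Per isolate: a niche width drawn from a binomial on the 95 substrates
(truncated to at least 1), usable substrates chosen uniformly, and growth
on them lognormal around a kingdom-specific scale — multiplicative OD noise
is the standard plate-reader error model, and lognormal keeps values
positive and right-skewed.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `niche_width_mean_bacteria` | 85 / 95 | overlap is bounded by shared-niche size ÷ 95, so the empirically observed regime — most overlaps high, many above 0.75 — forces broad niches; narrow widths would make every network empty at the default threshold |
| `niche_width_mean_fungi` | 90 / 95 | fungi are the broader resource users; widths stay distinguishable (Welch p < 0.001 over replicate communities) |
| `growth_scale` | 0.5 OD | typical plate OD scale |
| `fungal_growth_advantage` | 2.0 | fungi must out-*grow*, not just out-*cover*, bacteria: with iid magnitudes the overlap statistic is symmetric in expectation, so the observed asymmetry (fungi overlap bacteria, rarely vice versa) requires a magnitude gap |
| `growth_dispersion` | 0.45 (sdlog) | enough pair-to-pair noise that equal-scale pairs (fungus–fungus, bacterium–bacterium) fall mostly below the 0.75 threshold while the fungal advantage keeps fungus→bacterium above it |
| `treatment_effect` | 0.6 | NPK pulls fungal growth back toward bacterial levels, eroding fungal outdegree and raising bacterial overlap on fungi |
| `npk_heterogeneity` | 0.3 (sdlog) | a *uniform* fungal multiplier cannot change fungus–fungus overlap (scale invariance); a per-isolate factor adds fungal-fungal growth heterogeneity, reducing within-kingdom overlap too, as the treatment is expected to |

Under these defaults, control communities show fungi with high outdegree
and low indegree, bacteria the reverse, and NPK communities show both
contrasts attenuated — the qualitative degree structure the analysis is
designed to detect, verified over 100 replicate studies in the acceptance
suite.

What the generator does **not** emulate: substrate identities or chemistry
(substrates are exchangeable indices), growth kinetics (only the 72-h
endpoint is modelled), taxonomic structure below kingdom, spatial or
co-occurrence correlation between isolates of a leaf, and plate-level
artifacts (blanks, edge effects). Passing tests therefore demonstrate that
the pipeline recovers planted structure of this kind — not that real
endophyte communities have that structure.

## Numerical and degenerate-input choices

* Growth strictly greater than a tolerance (default 0) counts as "non-zero"
  for niche membership; the tolerance is exposed for noisy OD data since
  whether small ODs should be blanked is a data-cleaning decision upstream
  of the statistic.
* Skewness uses the $1/n$ moment coefficient $g_1 = m_3/m_2^{3/2}$, no
  small-sample correction, `NA` for constant samples.
* Empty networks, isolated nodes, all-zero profiles, single-edge networks,
  and constant null distributions all return defined values or explicit
  `NA`/flags rather than errors; parameter violations error early with
  informative messages.
* Problem sizes: the test suite validates metrics on graphs of up to 20
  nodes, oracle checks on 200 graphs of 3–8 nodes, null-model integrity on
  1000-member ensembles, HOI calibration on 500 replicates against a
  2000-draw null, and parameter recovery on 100 simulated twelve-community
  studies — sizes chosen to estimate each property's rate with comfortable
  statistical margin.

## Limitations

* The niche-overlap statistic inherits the panel: substrates off the plate
  are invisible, and the fixed $1/N$ denominator means panel composition
  shifts all overlaps.
* The swap-chain null samples configurations approximately uniformly only
  insofar as the chain mixes; burn-in is a heuristic, and no
  importance-sampling correction is applied. For near-degenerate networks
  the unique-configuration count is the honest diagnostic.
* Weighted-network generalizations of the structural metrics are out of
  scope; the weighted overlap matrix is retained and feeds only community
  detection.
* The spin-glass optimizer is stochastic; partitions are seeded and
  reproducible, but different seeds can find different near-optimal
  partitions on weakly modular networks.
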