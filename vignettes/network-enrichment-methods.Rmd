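---
title: "Functional link enrichment in typed molecular networks: methods and design"
author: "netenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional link enrichment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netenrich)
```

## The question the method answers

An experimental gene or protein list — differential expression hits, a
proteomics panel, a GWAS candidate set — is biologically coherent to the
extent that its members interact. `netenrich` quantifies that coherence on a
global molecular-interaction network: it reconstructs the induced subnetwork
of the set (all typed links with both endpoints in the set), counts its
links, and asks whether that count exceeds what degree-matched random sets
of the same size achieve.

The statistic is deliberately simple — an intra-set link count — because the
null model carries the scientific weight. Interaction databases are shaped
by study bias: heavily studied proteins (hubs) accumulate links, including
false-positive ones, so a list of famous proteins looks "connected" under
any naive null. The null model here replaces each query node with a node of
*identical* generalized degree in the global network, drawn uniformly from
its degree class, without replacement across the replacement set, and then
takes the induced subgraph of the replacements. Degrees are matched exactly,
so hub-heavy query sets are compared against equally hub-heavy random sets.
Labels are permuted only for nodes relevant to the analysed set; the global
network is never rewired.

## Typed links

Edges carry a fine interaction-type label (e.g. `"activity upregulation"`,
`"catalyze"`, `"coexpression"`). Six coarse groups aggregate them:
activity and transport regulation; catalysis; coexpression; expression
regulation; interaction; and a residual `other` (holding `"expression"`,
`"association"`, and anything unrecognized) that participates only in the
generalized `all_types` view. Filtering happens *after* subnetwork
reconstruction, so the degree classes of the null model are always built
from the unfiltered (all-types, post-score-threshold) network — the filter
changes what is counted, not who is exchangeable with whom.

A node pair connected by *k* fine types contributes *k* to the all-types
link count. This multigraph convention matters for densely annotated
processes, whose networks carry many parallel links of different types.

Edges are treated as undirected throughout: the statistic is a link count,
and direction never enters the null model.

## The two p-values

Let $x$ be the observed link count and $c_1,\dots,c_n$ the counts of $n$
random networks.

* **Normal approximation** (`mode = "t"`, default $n = 100$): fit
  $\mathcal N(\hat\mu, \hat\sigma^2)$ by the sample mean and sample
  standard deviation ($n-1$ denominator; the two-moment fit does not
  dictate a denominator, and $n-1$ is the unbiased-variance convention)
  and report the upper tail $P(X \ge x)$. This is cheap and smooth but can
  misbehave in the extreme tail — it may underflow to exactly 0 for very
  dense subnetworks, which the result flags as `underflow`.
* **Permutation** (`mode = "permutation"`, default $n = 1000$): the
  add-one estimator $(\#\{c_i \ge x\} + 1)/(n+1)$, never exactly zero,
  standard for Monte-Carlo tests.

**The edgeless convention.** When the analysed subnetwork has zero links
*and* every random network is also edgeless, both p-values are fixed at
0.5: the null sample carries no information, and a small non-zero number
of edges in the null would place an edgeless network near the middle of
the distribution, not at either extreme. The override takes precedence
over the add-one formula, which would otherwise report $\approx 1$.

A degenerate null sample with $\hat\sigma = 0$ but a non-zero level
resolves by position: 0 above the constant, 1 below it, 0.5 on it.

Because the normal-approximation p can be biased, an **empirical ROC
p-value** can be attached when a panel of known-non-functional sets is
available: the proportion of the panel's p-values less than or equal to
the analysed set's p-value (inclusive).

Families of tests (e.g. one set tested under all six filters across
several experiments) are adjusted by Benjamini–Hochberg step-up over
exactly the p-values passed in; `bhAdjust()` delegates to base R's
`p.adjust(method = "BH")`.

## Sampling details and tie-breaks

* Degree classes are exact: one bucket per integer degree, bucket members
  sorted, so all operations are deterministic given the seed.
* Replacement sets are drawn per degree class; classes are disjoint, so
  without-replacement sampling never collides across classes. A query node
  is always a member of its own class, hence a class can never be smaller
  than the number of query nodes it must supply; the nearest-degree
  fallback (smaller degree preferred on ties, every substitution counted
  on the sample's policy record) exists for robustness but cannot trigger
  for query sets that live in the indexed network.
* Nodes with zero links after score thresholding are outside the sampling
  universe; `enrich()` drops them from the query with a message. They
  cannot contribute links, so the statistic is unchanged; only the
  effective set size shrinks.
* Node rankings break value ties lexicographically by node ID.

## ROC benchmarking

The classifier score is $1 - p$. Tied scores are grouped into single
threshold steps, so a large shared atom (typically edgeless sets at
$p = 0.5$ in both panels) produces one diagonal segment. The AUC is the
trapezoidal area, which under this construction equals the tie-corrected
Mann–Whitney statistic (half-credit per tie) — the test suite asserts the
equality to machine precision. `sensitivityAtSpecificity()` interpolates
the curve linearly at a target false-positive rate, returning the highest
sensitivity achievable at an exact curve point.

## The synthetic worlds

Real global networks cannot ship with a package, so benchmarking runs on
generated worlds designed to reproduce the features the method is
sensitive to:

* **Power-law background.** Degrees are drawn from a truncated discrete
  power law with exponent $\gamma = 1.39$ by default — the shape of real
  curated interactomes' degree histograms — between `minDegree` and a
  structural cutoff of $\lfloor\sqrt{n}\rfloor$, then realized by
  configuration-model stub pairing. Colliding stubs (self-loops,
  duplicate pairs) are re-paired for up to 25 rounds and irreparable
  leftovers dropped (counted in the config echo); realized degrees are
  re-derived from the network, so degree classes are always exact.
* **Typed edges** from a configurable fine-type mixture whose default
  spans all six coarse groups, including `other`-group labels so that
  partition accounting is non-trivial.
* **Planted modules**: node-disjoint sets whose pairs receive an extra
  edge with probability `extraEdgeProb`, the ground-truth positives.
* **Annotations**: every module is a process; additional random background
  processes (one per ~20 nodes) give the process-disjoint negative model
  a realistic universe.
* **Publication counts** are heavy-tailed and positively associated with
  degree (log-normal multiplier on degree), emulating study bias so the
  well-studied negative model differs meaningfully from simple random
  draws.

What the generator does *not* emulate: real type frequencies, ontology
structure (annotations are flat, no ancestor propagation), gene/protein
node duality (a single node namespace is used), degree–degree
correlations, and the correlated noise of literature-derived links.
Passing benchmarks on these worlds therefore demonstrates the statistical
machinery — calibration, power, degree matching — not database-specific
accuracy.

## Study conditions used by the heavier checks

The test suite's end-to-end checks fix these problem sizes (chosen to be
large enough for the asserted properties to be stable across seeds while
keeping a full run on one CPU in minutes):

* *Calibration*: a module-free world of 2,000 nodes (`minDegree = 3`,
  ~11,500 links); 500 simply-random sets of 80 nodes each, permutation
  p-values with $n = 1000$. Sets of 80 sit in the larger of the two size
  regimes used for real gene-set panels and give the link-count statistic
  wide support, so near-uniformity of p is a meaningful check: with much
  smaller or sparser sets the count distribution collapses onto a few
  atoms and any uniformity test measures discreteness, not miscalibration.
* *Power*: 100 planted modules of sizes 11–50 with `extraEdgeProb = 0.2`
  in an 8,000-node world versus 100 size-matched simply-random sets,
  normal-approximation mode with $n = 100$.
* *Completeness*: modules with constant expected intra-module degree
  $\lambda = 2.5$ (edge probability $\lambda/(\text{size}-1)$) of sizes
  10, 20, 100 and 400; ten members drawn per module, so the bins
  correspond to 100%, 50%, 10% and 2.5% completeness; five seeds,
  AUC averaged per bin. The $\lambda/(\text{size}-1)$ scaling is what
  makes completeness bite: a fixed-size subsample of a larger module
  carries proportionally fewer intra-module links, as in real processes
  whose interaction density does not grow with annotation size. (With a
  constant edge probability a subsample would be as dense as the whole
  module and completeness would have no effect — that regime is used only
  for the power benchmark above.)
* *Tiny-world oracle*: an 8-node network whose degree-matched assignments
  can be enumerated exhaustively; the Monte-Carlo permutation p at
  $n = 10{,}000$ is compared against the exact tail probability.

## Known limitations

* The normal approximation is a two-moment fit; its extreme-tail values
  are indicative only (hence the underflow flag and the empirical ROC
  calibration hook).
* The add-one permutation p is conservative in the presence of count
  ties; with $n = 1000$ and non-degenerate counts the effect is at the
  third decimal.
* The process-disjoint negative model uses direct annotations only; under
  ontologies with ancestor propagation the disjointness constraint would
  be stricter.
* `specificityRate()` counts typed multi-edges once per type under the
  active filter; sources that collapse parallel links will report
  slightly different ratios for multiply-linked hubs.
* Isolated nodes survive score thresholding as nodes but cannot be
  written to an edge list; world round-trips preserve them only via the
  JSON config echo.

## A worked example

```{r example, eval = FALSE}
cfg <- syntheticWorldConfig(2000, minDegree = 2,
                            modules = list(list(size = 20,
                                                extraEdgeProb = 0.3)),
                            seed = 42)
world <- generateWorld(cfg)
res <- enrich(world@net, world@modules[[1]], mode = "permutation",
              seed = 1)
res
```

The observed count sits far above the null mean and both p-values are
small; a size-matched random draw (`sampleNegative(world@net,
"simply_random", 20, seed = 2)`) lands near p = 0.5. The README shows the
printed output.
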