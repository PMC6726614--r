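---
title: "Spatial enrichment of labelled genomic bins: models, algorithms and design choices"
author: "smhg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial enrichment of labelled genomic bins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smhg)
```

## The problem

Hi-C experiments produce genome-wide read counts that correlate with the
3D spatial proximity of genomic loci.  Given a 3D embedding of the binned
genome and a binary annotation over the bins (targets of a transcription
factor, members of a GO category, copy-number outliers, ...), we ask: do
the positively labelled bins co-localize somewhere in space?  Classical
approaches restrict candidate neighbourhood centers to the bins
themselves ("bead" pivots).  That misses co-localization centred between
chromosomes or away from the chain entirely — the two-row construct in
`tests/testthat/helper-clouds.R` is the canonical counterexample, where the
optimal center lies midway between two genomic clusters and no bead comes
close.

## The statistic

Let the data be $\mathcal{D} = \{x_i, y_i\}_{i=1}^N$ with $x_i \in
\mathbb{R}^d$ ($d \in \{2,3\}$), $y_i \in \{0,1\}$ and $B = \sum_i y_i$.
For an arbitrary pivot $p$, rank all bins by Euclidean distance from $p$
to obtain the binary vector $\lambda_p$.  The minimum hypergeometric (mHG)
score of $\lambda_p$ is

$$\mathrm{mHG}(\lambda_p) \;=\; \min_{1 \le n \le N}
  \sum_{i=b_n}^{\min(n,B)}
  \frac{\binom{n}{i}\binom{N-n}{B-i}}{\binom{N}{B}},$$

where $b_n$ is the number of ones in the length-$n$ prefix: the most
surprising prefix of the ranking under a uniform-placement null.  Because
prefixes are dependent, the score is not a p-value; the exact corrected
p-value $P(\mathrm{mHG} \le s)$ is computed by a lattice dynamic program
over the (prefix length, prefix one-count) grid (`mhg_exact_pvalue()`).
Our implementation propagates path *probabilities* rather than counts, so
it cannot overflow; the test suite validates it to $10^{-12}$ against
exhaustive enumeration of all $\binom{N}{B}$ arrangements for every
$N \le 12$.  Degenerate inputs ($B = 0$ or $B = N$) return score 1 and
p-value 1 by convention; the annotation pipeline filters sets with
$B < 4$ before they reach the statistic.

The spatial objective is $\min_p \mathrm{mHG}(\lambda_p)$ over all of
$\mathbb{R}^d$.  The search space is effectively finite: the perpendicular
bisector between every ('1','0') point pair is the locus where their
ranking order flips, and the arrangement of all $m = B(N-B)$ bisectors
partitions space into convex cells of constant $\lambda_p$.

## Search strategies

**Sampling** (`smhg_sample()`).  Every $d$-tuple of bisectors in general
position meets in an arrangement vertex.  Stepping one coordinate by
$+\varepsilon$, re-solving each bisector for its dependent coordinate and
averaging yields a point strictly inside the cell just above the vertex —
the cell's "bottom-most" representative.  Enumerating all
$\binom{m}{d}$ tuples (plus all bead pivots, which also cover clouds with
too few bisectors to form a tuple) visits every such cell representative
exactly once.  The default $\varepsilon$ is $10^{-6}$ times the
bounding-box diagonal — far below the minimal bisector separation for the
instance sizes where the exhaustive enumeration is feasible, and tested to
leave the induced ranking invariant over two decades of $\varepsilon$.
When a bisector has a zero coefficient on the canonical dependent axis the
axes are permuted to any axis with usable coefficients; tuples that are
orthogonal to every axis pairing fall back to an averaged-normal step off
the vertex.  Since $\binom{m}{3} = \Theta(N^6)$, full enumeration is only
feasible for small instances; beyond the `max_tuples` budget (default
$2 \times 10^4$) the sampler draws a seeded uniform subsample of tuples.
All small-instance guarantees in the tests run the exact enumeration.

**Octree branch and bound** (`smhg_grid()`).  Space is recursively split
into $2^d$ sub-cubes starting from the data bounding box expanded by a
`slack` margin (default 10% of the diagonal), so pivots outside the convex
hull are reachable.  Each cube's center is scored as a pivot.  For each
cube we keep the *active* bisectors — those intersecting the cube, a
subset of the parent's active set, decided by an exact interval test on
the linear form over the cube.  Let $k$ count active bisectors whose
preferred side the center fails to satisfy.  Any pivot inside the cube can
differ from the center's ranking only across active bisectors, and at most
$k$ swaps can promote a '1' earlier; optimistically inserting up to $k$
ones after every prefix (never exceeding $B$) therefore bounds the best
achievable score in the cube from below.  Cubes are traversed best-first
by this bound (ties: shallower first, then insertion order), and a cube
whose bound exceeds the current optimum is pruned.  A cube with no active
bisectors has constant $\lambda$ and is never split.  `k` is recomputed
from each cube's own active set — slightly conservative, always sound.
The tests verify that the bound never exceeds a Monte-Carlo minimum inside
random cubes, and that disabling pruning never changes the optimum.

Two implementation parameters have no counterpart in the underlying
method.  `max_depth` (default 30) caps the refinement depth: a cube
straddling a bisector plane keeps that plane active at every depth, so
without a cap the tree is infinite; the budget normally binds first.
`budget` (default $10^5$) caps the number of scored pivots.  Both
heuristics return upper bounds on the true spatial optimum: they can miss
the optimum but never overstate significance relative to the pivots they
did visit.  `exhaustive_oracle()` (sampled pivots + beads + a dense
lattice) provides the small-instance ground truth used by the tests.

## Controls

* **Bead control** — the search restricted to the data points, i.e. the
  pre-existing approach; comparing it with the spatial optimum is what
  demonstrates an off-bead event.
* **1D genomic control** (`genomic_1d_control()`) — ranks by
  $|i - j|$ in genomic bin units, per chromosome (inter-chromosomal
  genomic distance is undefined), with per-chromosome $N$ and $B$;
  equidistant up/downstream ties rank the upstream bin first.  Filters
  events explained by linear genome order alone.
* **Shuffle control** (`simulation_control()`) — permutes the labels
  (default 100 times), recomputes the full search (both heuristics by
  default, identical budgets for observed and shuffled data) and reports
  the empirical survival probability with the add-one convention
  $P_{sim} = (r+1)/(n+1)$, so it is never exactly 0; $r = 0$ is also
  displayed as "< 1/n".  This is the correction for the many dependent
  cells the spatial search inspects, which the per-ranking exact p-value
  does not cover.
* **BH q-values** (`fdr_qvalues()`) — computed across the annotation sets
  tested on one embedding with one method.  The family choice is a
  genuinely open design point; we adopt per-method families and expose the
  raw p-values so any other family can be formed.

Two permutation tests cover focused follow-up questions:
`assignment_permutation_test()` (are the observed positives mutually
closer than a random assignment over candidate sites — median or mean
pairwise distance) and `cross_set_proximity_test()` (is an observed second
set unusually close to a fixed set — mean cross-pair distance).  The spec
of the latter requires the observed second set as an explicit argument;
both use the add-one convention and are calibration-tested.

## sNMDS: smoothed nonmetric MDS

Contact counts are mapped to dissimilarities by a monotone-decreasing
transform — default $(1+c)^{-1}$ rescaled to $[0,1]$; a rank and a power
transform are available, and nonmetric MDS depends only on ranks so
inverse and rank are equivalent.  Zero-count pairs are treated as missing
and excluded from the stress, not imputed: sparse Hi-C zeros are censored
observations, not maximal distances.  The 3D configuration is fitted with
`vegan::monoMDS` (global nonmetric stress), deterministically initialised
from classical scaling with missing entries imputed at the maximum
dissimilarity.

Plain NMDS of Hi-C data produces occasional teleported bins —
genomically consecutive bins placed unreasonably far apart.  sNMDS
(`snmds()`) iterates: compute consecutive-bin distances per chromosome
(the discrete derivative), Z-score them against the pooled distribution
across chromosomes, flag the bins flanking any derivative with
$Z > 3$ (default), replace flagged runs by linear interpolation between
the nearest valid neighbours (terminal runs are extrapolated), and refit
the NMDS initialised at the corrected configuration.  The refit restores
stress optimality but can re-create the same discontinuities — the
corrupted dissimilarities genuinely support them — so the loop stops when
the flagged set stops changing or after `smooth_max_iter` (default 10)
rounds, and finishes with interpolation-only passes iterated to a fixed
point (interpolation tightens the derivative distribution, which can
expose previously marginal derivatives).  The returned configuration has
no flagged derivative at the working threshold; round-trip tests confirm
this and that the Spearman correlation between true and embedded
distances on synthetic data exceeds 0.8 (in practice ~0.99) and improves
on plain NMDS.

`procrustes_align()` aligns time-course embeddings by the optimal
similarity transform; reflections are allowed by default (an NMDS
configuration is defined only up to isometry) and can be forbidden.  The
optimum is cross-checked against `vegan::procrustes` in the tests.

## Annotation mapping

Bins are 0-based half-open, BED-native.  An annotation labels a bin iff
any interval overlaps it by at least 1 bp (midpoint assignment was
considered and rejected: a 2-bin gene should label both bins).  Sets with
fewer than 4 positive bins are rejected as a typed result, not an error,
so batch pipelines can record the rejection.  CGH profiles are aggregated
per bin as $\sum v / \sqrt{n_{probes}}$ — the stated aggregation is
ambiguous between a scaled sum and a mean; we read it as the
Stouffer-style scaled sum, which up-weights well-covered bins, and expose
the plain mean as a switch.  Bins with fewer than 20 probes are masked;
kept bins are labelled when exceeding $\mu + 2\sigma$ (one-sided high; a
two-sided variant would also flag deletions and is trivially obtained by
lowering `z_cut` on the negated values).  Differential contact labelling
Z-scores each per-chromosome sub-matrix against its own entries (zeros
included by default — they are part of the measured matrix; a
nonzero-only switch exists), masks entries with $|i-j| > 5$, summarises
each locus by the Euclidean distance between its masked rows in the two
maps, Z-scores those distances per chromosome, and labels $|Z| > 1.96$.
Any zero-variance Z step yields all-zero scores.

## Synthetic data

The generators define the study conditions under which every guarantee is
tested.  `generate_polymer()`: per chromosome the bin-to-bin *directions*
follow a Gaussian random walk smoothed by a 5-bin moving average, while
the bond lengths are redrawn as $\mathrm{step} \times U(0.9, 1.1)$; each
chromosome is centred at a territory center drawn uniformly from a ball
of radius $\mathrm{step} \times \sqrt{\mathrm{bins}}$.  The bounded bonds
matter: with raw Gaussian steps the consecutive-distance distribution has
enough spread that, over a couple of hundred derivatives, a few exceed
$Z = 3$ on their own, so a "clean" generated polymer would carry
spurious discontinuities.  With bounded bonds the baseline spread stays
below the threshold by construction and every detected discontinuity is
an injected one.  A related saturation effect shapes the smoothing
procedure itself: teleporting $k$ bins creates $2k$ outlier derivatives
whose magnitude inflates the pooled standard deviation, capping
attainable Z-scores near $\sqrt{n/2k}$ — which is why discontinuity
correction must iterate rather than detect everything in one pass.
`generate_contact_map()`: $c_{ij} \sim \mathrm{Poisson}(k\, d_{ij}^{-\alpha})$
with $\alpha = 1$ by default (mild decay preserves long-range ordinal
signal; steep decay starves the embedding of it) and $k$ calibrated to an
expected depth of $10^6$ read pairs for the default 200 bins.
`plant_hotspot()` labels 12 bins drawn from a ball around a random bin;
the default radius reaches the $2 \times 12$-th nearest bin so the planted
bins occupy about half the ball — a strong but not degenerate signal.
`inject_discontinuities()` teleports non-adjacent interior bins (adjacent
teleports would make interpolation ill-posed).

What the generators do *not* emulate: polymer physics (loop extrusion,
confinement forces), mappability and coverage biases, copy-number-driven
count inflation, or ensemble heterogeneity across cells.  Passing tests
demonstrate the statistical machinery under its stated model, not
robustness to those real-data artefacts.

## Problem sizes used by the test suite

Chosen so the full validation runs comfortably on a laptop-class single
core: exact p-value enumeration to $N = 12$; sampler-vs-oracle on 20
planar clouds with $N \le 10$; pruning equivalence on 20 spatial clouds
with $N \le 30$ at `max_depth = 4` with an exhaustion budget; bound
soundness on 100 random cloud/cube pairs with 1000 Monte-Carlo pivots
each; hotspot recovery on 20 polymers of 200 bins with `budget = 2e4`
for the reported search and 1000-pivot budgets inside the 100-shuffle
control; calibration over 200 null labelings of a 60-bin polymer;
sNMDS round trips on 120-bin maps; permutation-test calibration over 200
repeats of 500 permutations.

## Known limitations

* Both search heuristics are upper bounds: a significant result is
  trustworthy (given the controls), a negative one is not exhaustive
  evidence of absence.
* The exact corrected p-value corrects for prefixes within one ranking,
  not for the multiplicity of cells inspected by the spatial search;
  $P_{sim}$ and the q-values carry that burden.
* The sampler's tuple subsampling beyond `max_tuples` makes large-instance
  `smhg_sample()` stochastic (seeded); the grid search is deterministic at
  any size.
* sNMDS coordinates live in an abstract latent space; distances support
  ordinal reasoning, not physical interpretation in nanometres.
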