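# smhg — spatial enrichment of labelled genomic bins in 3D genome embeddings

`smhg` asks a simple question about 3D genome organisation: given a 3D
embedding of a binned Hi-C contact map and a binary annotation over the
bins (targets of a transcription factor, a GO category, copy-number or
differential-structure outliers), **do the positively labelled bins
co-localize in space?** It answers it with the minimum-hypergeometric
(mHG) statistic evaluated at *arbitrary* pivot points — not just at the
bins themselves — which detects co-localization centred between
chromosomes that bead-restricted methods miss.

It is aimed at computational biologists analysing unicellular (or any
small-genome) Hi-C datasets, and at methodologists who need an exact,
controlled spatial enrichment statistic for labelled point clouds.

## The statistic

For data `{x_i, y_i}` (points in R^3, binary labels, `B = Σ y_i`) and a
pivot `p`, rank the points by distance from `p` to get the binary vector
`λ_p`, and score

    mHG(λ_p) = min over prefixes n of  Σ_{i=b_n}^{min(n,B)}  C(n,i) C(N−n,B−i) / C(N,B)

with `b_n` the one-count of the length-`n` prefix.  The exact corrected
p-value `P(mHG ≤ s)` is computed by a lattice dynamic program (no
resampling, no approximation).  The spatial objective `min_p mHG(λ_p)` is
minimised two ways:

* **`smhg_sample()`** — exhaustive enumeration of the perpendicular
  bisector arrangement between oppositely labelled points: every
  non-degenerate triple of bisectors contributes one in-cell pivot
  (ε-step construction), plus all bead pivots;
* **`smhg_grid()`** — best-first octree branch and bound with a sound
  per-cube lower bound built by optimistically promoting the `k`
  unsatisfied active bisectors of the cube.

Guard rails: bead-pivot control, per-chromosome genomic-order (1D)
control, label-shuffle `P_sim` (add-one empirical survival over full
re-searches), BH q-values across annotation sets, plus two focused
permutation tests (assignment over candidate sites; cross-set proximity).

Embeddings are produced by **sNMDS** (`snmds()`): nonmetric MDS of
inverse-count dissimilarities (zero-count pairs treated as missing) with
iterative Z-score detection and linear interpolation of
genomic-neighbour discontinuities.  `procrustes_align()` aligns
time-course embeddings.  Synthetic generators (polymer, distance-decay
Poisson contact maps, planted hotspots, injected discontinuities) make
the whole pipeline testable end to end without external data.

## Worked example

```r
library(smhg)
spec  <- synthetic_spec(seed = 42)          # 4 chromosomes x 50 bins
truth <- generate_polymer(spec)             # ground-truth 3D polymer
map   <- generate_contact_map(truth, seed = 42)
emb   <- snmds(map)                         # smoothed NMDS embedding
emb
#> sNMDS embedding: 200 bins, stress 0.1317, 2 smoothing round(s) [2, 2]

hot   <- plant_hotspot(truth, n_inside = 12, seed = 42)
cloud <- as_labeled_cloud(emb, hot$labels)
fit   <- smhg(cloud, method = "grid", seed = 42, n_shuffles = 100, budget = 2e4)
fit
#> Spatial mHG enrichment (method: grid)
#>   N = 200 bins (3D), B = 12 positive
#>   best score 2.98e-16, exact corrected p = 3.281e-16
#>   pivot (0.0445, -0.6732, -0.255), ball radius 0.597 covering n = 16 bins (b = 12)
#>   bead control:    p = 1.157e-12
#>   1D control:      min p = 5.107e-05 over 4 chromosome(s)
#>   shuffle control: P_sim < 0.01
```

Reading the output: the best pivot's ball of radius 0.597 contains 16
bins including all 12 positives (`b = 12` of `n = 16`), with exact
corrected p ≈ 3.3e-16; no label shuffle in 100 reached the observed
score (`P_sim < 0.01`).  Here the planted hotspot sits on contiguous
polymer stretches, so the bead and 1D controls fire as well; a
significant spatial result with *non*-significant controls is the
signature of enrichment invisible to bead- or genomic-order-based
methods (see the two-row construct in the test suite).  `plot(fit)`
draws the cloud, pivot and enrichment ball; `smhg_run()` processes many
annotation sets and attaches q-values; `smhg_cli()` (or the installed
`inst/cli/smhg` script) exposes `synth`, `embed`, `label`, `search`,
`controls` and `run` subcommands over TSV/BED files.

See `vignettes/spatial-enrichment-methods.Rmd` for the model, algorithm
and design-decision details.

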