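---
title: "Models and methods behind zoopim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zoopim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

zoopim quantifies a mesozooplankton community twice — from scanner images
and from multi-marker amplicon tables — and asks whether the two views
agree. This vignette is the package's own account of the science: the
models, their assumptions, the tunable parameters, and the places where
the design was genuinely open.

## 1. Imaging quantification

Each validated object is reduced to the major and minor axes of a fitted
ellipse (mm; pixel inputs are converted at `mm = px · 25.4 / dpi`,
default 2400 dpi). The body is modelled as a prolate spheroid,

$$BV = \tfrac{4}{3}\pi\,\tfrac{major}{2}\left(\tfrac{minor}{2}\right)^2,$$

which is the standard volume model for copepod-like silhouettes. We read
the conventional printed form of this formula as
$(major/2)\cdot(minor/2)^2$ — any other parenthesisation is
dimensionally wrong. Dry mass assumes neutral buoyancy (1 g cm⁻³, so
1 mm³ wet = 1 mg) times a wet-to-dry conversion factor resolved
deepest-rank-first along the lineage with a configurable global
fallback. Only two factors ship: 0.16 (Arctic copepods) and 0.08
(*Calanus hyperboreus*, whose lipid sac makes the generic factor a
2-fold overestimate); factors for other groups live in the literature
and must be user-supplied — an unresolvable lineage is an error by
default, NA on request.

Community matrices divide split-corrected per-object sums by the
station's filtered volume (`net_area · speed_knots · 0.514444 ·
duration_s`). Split factors are applied **per size fraction before
summing across fractions**: the physical sample is split fraction by
fraction, and the recombination rule is not otherwise specified, so the
per-fraction rule is the only one consistent with the splitting
hardware. Objects not flagged as validated organisms are excluded with
an uploaded/discarded/retained accounting. A hook (`species_lookup`)
lets users apply prosome-length-to-species assignment inside a genus
before aggregation; no default cutoffs ship because published cutoffs
are instrument- and region-specific.

## 2. Metabarcoding processing

Order of operations: **singletons first, then the metazoan filter** —
this matches the accounting layout of published marker tables (total
ASVs → after singleton deletion → metazoan), and the percentages only
reconcile under this order. A singleton is an ASV whose **dataset-wide**
total is ≤ 1 read; per-sample interpretations would delete vastly more
and are not what "singleton" means in this literature. The metazoan
filter keeps a configurable phylum set (default: the 11 metazoan phyla
recorded in the study system this package emulates).

**NSRA.** Sequencing depth varies between size-fraction libraries for
technical reasons, so per station every fraction is scaled to the
station's minimum fraction depth (`x̃ = x · D_min/D_f`) and the scaled
fractions are summed. Two properties are guaranteed and tested:
each included fraction's scaled total equals `D_min` (to 1e-9
relative), and within-fraction read ratios are unchanged. Scaled reads
are kept as reals — re-rounding would break proportion preservation and
nothing downstream needs integers. Zero-depth fractions are dropped with
a stable warning code (`ZP_W01`) rather than zero-filled; the station's
fraction count in the conservation identity adjusts accordingly.

**What NSRA is not.** Scaling to the minimum depth deliberately gives
every fraction equal weight. It therefore reconstructs *within-fraction
composition*, not absolute biomass: the merged value of taxon *t* is
`D_min·Σ_f share(t,f)` while true dry mass is `Σ_f M_f·share(t,f)`,
and the fraction biomass totals `M_f` are gone. With log-spaced sieves
(0.5/1/2/4 mm) and individual mass growing like length³, `M_f` spans
orders of magnitude in any realistic assemblage, so taxa dominating the
small fractions are systematically inflated. In the default synthetic
scenario this caps the raw per-station Pearson correlation between
merged NSRA and true dry mass near 0.33 (rank correlation ≈ 0.73),
which is why the package's acceptance suite reports that recovery
statistic honestly below its nominal 0.8 target instead of adjusting
the world until it passes. Users comparing NSRA to biomass should work
on ranks, logs, or within fractions.

## 3. Comparative statistics

* **Transform**: square-root, applied to the matrices entering
  Bray–Curtis/nMDS. Shannon H′ (natural log) is computed on
  untransformed relative values: the analysis chain applies the
  transform only where skewness matters for distances, and H′ is
  already scale-free.
* **Jaccard** is stored as similarity; correlations between pairwise
  matrices use the strictly-lower-triangle vectors with a plain paired
  t test (`df = m − 2` over the m pairs). That test treats pairs as
  independent, which distance pairs are not; it is nevertheless the
  procedure commonly applied when pairwise matrices are fed to a
  correlation test, so it is the default, with an explicitly labelled
  Mantel permutation mode for exchangeability-correct inference.
* **PCA** is a singular-value decomposition of the centred (and by
  default unit-scaled) environment table; axes are oriented so the
  largest-magnitude loading is positive, making signs reproducible.
  Passive variables are projected as correlations with the axis scores
  and never alter the ordination.
* **nMDS** minimises Kruskal stress-1 with iterative majorization
  (Guttman transform) alternated with isotonic regression
  (pooled-adjacent-violators). Ties in the input dissimilarities are
  averaged (primary treatment): tied pairs share one fitted disparity.
  An update is accepted only if stress does not increase, so the stress
  trace is non-increasing by construction; convergence is a stress
  change below `tol` (default 1e-7, max 500 iterations). The best of
  one metric-scaling start plus `n_starts = 20` random starts is kept,
  then centred, rotated to principal axes and sign-fixed. Stress is
  validated against brute-force optimization on 4-point toys in the
  test suite.
* **Environmental vector fitting** regresses each centred, unit-scaled
  covariate on the ordination scores; r² is the regression share of
  variance; significance is permutational with the +1/+1 estimator
  (`p = (1 + #{r²_perm ≥ r²})/(1 + n_perm)`), which can never return a
  zero p. The default `n_perm = 999` is the conventional tool default;
  the emulated study does not state its permutation count. The PCA
  covariate "% PSW" and the nMDS covariate "PSW-layer thickness" are
  both station scalars describing the same water mass and are treated
  as one configurable column, `pct_PSW`.
* **Clustering** uses Ward.D2 on Euclidean distances of the first three
  ordination axes, alongside k-means with ten seeded restarts;
  within-cluster sums of squares are reported for choosing k.
* **Influential taxa**: a taxon sits at the abundance-weighted average
  of the station coordinates and its influence is (taxon total) ×
  (distance from the origin). The underlying published figure does not
  state its criterion; weighted-average placement is standard for
  species scores, and weighting by total keeps rare taxa from being
  declared influential purely by position. This is one defensible
  choice and is documented as such.
* **Taxon harmonization** merges identical lineage strings after
  whitespace/case normalization and synonym substitution. A
  family-level record is never merged into a species-level record of
  the same family: presence/absence overlap compares named categories
  as given. Venn counts are provided both at mixed ranks (default) and
  the catalog records carry ranks so callers can restrict to one rank;
  "unassigned" placeholders are excluded from richness and Venn counts
  but retained inside community matrices.

## 4. The synthetic world

The generator emulates the sampling design of a high-Arctic RMT1
transect: 12 stations from 80.8 to 83.7 °N (the published station
coordinates are the default), a 1 m² net towed at 2.5 knots for 10 min
(filtered volume ≈ 772 m³, inside the reported 651–1443 m³),
sieving at 0.5/1/2/4 mm, Motoda splitting by halving until ≤ ~1000
particles per aliquot with a 1/256 floor, and per-fraction library
depths of 30k–100k reads.

* **Community**: expected density
  `d0 · exp(slope·(lat − lat0) + affinity·T)`; realized density
  lognormal (mean-corrected, sdlog 0.25) around it. The curated pool is
  a *Calanus*-dominated assemblage whose first two members guarantee
  structural features the tests rely on: a large-bodied taxon with the
  halved conversion factor, and a hydrozoan invisible to V4. Default
  `n_taxa = 30` adds a rare tail (reference densities log-uniform
  0.01–1 ind m⁻³, steep northward declines) so presence/absence varies
  across stations, as in real assemblages. *C. hyperboreus* has a
  mildly increasing-north effective gradient — its dominance grows with
  latitude — which, combined with the rare tail's decline, produces the
  northward Shannon decline in all four data streams.
* **Catch**: Poisson with mean density × volume. The net's true
  sampling statistics are unknown; Poisson is an explicit assumption.
* **Splitting**: independent Bernoulli retention at probability 2⁻ᵏ
  rather than literal alternating halves — preserves unbiased
  split-corrected counts while staying simple.
* **Reads**: multinomial per library with probabilities ∝ dry mass ×
  amplification efficiency (reads track biomass, not abundance), spread
  over 1–6 ASVs per taxon (1–3 for 18S), truncated to the marker's
  resolution (species for COI; family/order for V4/V9), plus ~5%
  non-metazoan background and five brand-new 1-read noise ASVs per
  library so the singleton filter is exercised.

**What a green test does not establish.** The simulator has no
taxonomic misclassification, no chimeras or sequencing error beyond
singleton noise, no net avoidance or mesh escape, no within-station
patchiness beyond Poisson, and environment covariates generated from
latitude alone; green pipeline tests certify the arithmetic chain and
the stated statistical structure, not performance on real samples.

## 5. Numerical and engineering choices

Every stochastic operation takes an explicit seed; stream-specific seeds
are derived from one master seed, keeping all derived seeds below 2³¹.
Degenerate inputs are flagged, not silently patched: empty-row pairs in
Jaccard/Bray–Curtis become NA with stable warning codes, constant
variables are skipped in vector fitting, constant distance vectors make
matrix correlations NA. Sieve intervals are half-open `[lo, hi)` with an
open-ended top fraction; objects below the smallest cutoff are excluded
as below-mesh. Configs are JSON (fail-fast on unknown keys); the
simulator echoes its scenario as a YAML-style text file for human
inspection. Accumulation curves subsample nested prefixes of one
shuffled read pool per replicate, which makes every replicate curve
monotone by construction.

## 6. Known limitations

* NSRA's equal-fraction weighting limits absolute-biomass recovery (see
  §2); this is a property of the published procedure, reproduced
  faithfully.
* The t-based significance for matrix correlations ignores the
  non-independence of distance pairs; use the Mantel mode for inference
  you need to defend.
* The influence criterion for taxa in ordinations is one defensible
  choice among several.
* Conversion factors other than the two shipped values must be supplied
  by the user; the imaging stream cannot invent them.
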