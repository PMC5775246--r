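---
title: "Phylogenetic and functional community structure along a temperature gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic and functional community structure along a temperature gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commstruct)
```

## The question this package addresses

Communities assembled under harsh, fluctuating environments are expected to
be *phylogenetically clustered*: an environmental filter admits only the
subset of lineages whose tolerances fit, and because tolerances and the
traits behind them are heritable, the admitted species are closer relatives
than a random draw from the regional pool. Under benign conditions the
opposite force — competition among close relatives with similar niches —
can push communities toward *overdispersion*. `commstruct` implements the
statistical machinery for detecting this structure in site-by-species
abundance data distributed along an environmental gradient, in both
phylogenetic space (distances on a dated tree) and functional space (Gower
distances on morphometric traits), and for relating compositional turnover
between sites to candidate temperature predictors.

## Alpha structure: MPD, MNTD and their standardized effect sizes

Within a community, two distance summaries are computed from a
species-by-species distance matrix $\delta$:

* **MPD**, mean pairwise distance — sensitive to tree-wide structure;
* **MNTD**, mean nearest taxon distance — sensitive to structure near the
  tips.

Both come abundance-weighted by default. For weighted MPD the self-pairs
$i = j$ are excluded ($\delta_{ii} = 0$ terms would only dilute the mean;
the metric is defined among distinct species):

$$\mathrm{MPD} = \frac{\sum_{i \ne j} \delta_{ij} f_i f_j}{\sum_{i \ne j} f_i f_j},
\qquad
\mathrm{MNTD} = \sum_i f_i \, \min_{j \ne i} \delta_{ij},$$

with $f$ the within-community relative abundances. Each observed value is
compared against a richness-preserving null: species identities are redrawn
uniformly (without replacement) from the whole species pool — every species
with nonzero total abundance in the matrix, the only pool observable from
survey data — while the observed abundance vector is reassigned to the
drawn species in random order. Keeping the abundance distribution and
randomizing only identity isolates the question "are these *particular*
species unusually related?". The standardized effect size is

$$\mathrm{SES} = \frac{X_\mathrm{obs} - \overline{X}_\mathrm{null}}{\mathrm{SD}_\mathrm{null}},$$

so $\mathrm{SES}(\mathrm{MPD}) = -\mathrm{NRI}$ and
$\mathrm{SES}(\mathrm{MNTD}) = -\mathrm{NTI}$; negative values mean
clustering, positive overdispersion. The rank p-value is
$(\#\{X_\mathrm{null} \le X_\mathrm{obs}\} + 1)/(n_\mathrm{null} + 1)$.
The default is 999 nulls — one convention across alpha and beta keeps
p-value resolution uniform. A site whose community exhausts the pool has a
degenerate (constant) null; it is flagged and skipped rather than failing
the run.

## Beta structure: abundance-weighted Dpw and Dnn

Between two communities $k_1$ and $k_2$, basal turnover is the full
abundance-weighted double sum

$$D'_\mathrm{pw} = \sum_i^{n_{k_1}} \sum_j^{n_{k_2}} \delta_{ij} f_i f_j,$$

with shared species contributing their zero self-distances (the sum is
deliberately unrestricted), and terminal turnover is the nearest-neighbour
form

$$D'_\mathrm{nn} = \frac{\sum_i \min_j \delta_{ij} f_i + \sum_j \min_i \delta_{ij} f_j}
{\sum_i f_i \times \sum_j f_j}.$$

As printed, the nearest-neighbour formula *adds* the two directional terms;
many implementations (e.g. `picante::comdistnt`) report their *mean*. Both
conventions are provided (`convention = "literal"`, the default, and
`"halved"`); they differ by an exact factor of two, so the choice cannot
change any standardized or comparative result. The tip-shuffle null
standardization permutes the labels of the distance matrix — exactly
equivalent to shuffling species across the tips of the tree or the rows of
the trait table, and much cheaper — and recomputes every pairwise value;
per-pair SES uses the same standardization formula as the alpha metrics.
Null means and SDs are computed from the stored replicate values rather
than running sums: with exchangeable distances every replicate equals the
observed value and the SD must come out exactly zero so the pair is flagged
as degenerate, which running-sum accumulation cannot guarantee in floating
point.

Region contrasts group site pairs by region pair (within-west,
between-west-east, ...) and delegate the omnibus test and pairwise
comparisons to one-way ANOVA with Tukey HSD, the standard tooling for that
step.

## Phylogenetic signal

Two complementary tests per trait:

* **Randomization of contrast variance.** The variance of the standardized
  independent contrasts (Felsenstein's algorithm; polytomies resolved
  deterministically with zero-length branches first) is compared with its
  distribution over shuffles of trait values among tips (default 1000). A
  low observed variance indicates signal, a high one antisignal; the test
  is two-tailed at the extreme 2.5% ranks per side (25 ranks per tail at
  1000 shuffles). All shuffles are pushed through one matrix-valued
  traversal of the tree, so the test costs a single pruning pass.
* **Blomberg's K**, the ratio of observed to Brownian-expected
  mean-squared-error structure computed from the phylogenetic
  variance-covariance matrix: K near 1 is Brownian-like, K > 1 conserved,
  K < 1 labile. Its own permutation p-value (upper tail of K under trait
  shuffles) is reported alongside, since either flavour appears in
  published signal tables.

## Temperature predictors, ordination, vector fitting

Eight predictors are derived from site-by-month mean temperatures: seasonal
means (MAT annual, MAuT autumn Sep–Nov, MWT winter Dec–Feb, MST spring
Mar–May) and fluctuations (ATF, AWTF Sep–Feb, WTF Dec–Feb, WSTF Dec–May).
"Fluctuation" is not a standardized term; here it defaults to the sample
standard deviation of the window's monthly means, with the max − min range
as an option. The windows suit a Northern-Hemisphere wintering system and
are configurable.

Each beta matrix is ordinated by two-dimensional NMDS (Kruskal stress,
multiple random starts, delegated to `vegan::metaMDS` with no community
transformation since the input is already a dissimilarity). Environmental
vectors are then fitted by regressing each (centered) predictor on the
ordination coordinates: the direction cosines are the unit coefficient
vector, $r^2$ the squared multiple correlation, the p-value a permutation
test of $r^2$ over site shuffles, and the plotted arrow is the direction
scaled by $\sqrt{r^2}$ — weak predictors get short arrows. Correlations
between whole dissimilarity matrices (e.g. phylogenetic vs functional
turnover, with taxonomic Bray-Curtis dissimilarity partialled out) use
Mantel and partial Mantel tests with label permutations of the first
matrix; when the control matrix explains a matrix completely the partial
correlation is reported as 0 rather than an undefined ratio.

## The synthetic-data generator

No census data accompany the analysis, so the generator produces datasets
with the statistical structure the methods assume, making every stage
testable end to end:

* **Tree**: Yule pure-birth, rescaled to unit depth.
* **Traits**: Brownian motion (root 0, increment variance
  $\sigma^2 \times$ branch length), mapped onto positive morphometrics
  (wing, beak, tarsus in mm; body mass in g) by log-scale displacement
  around field-realistic waterbird baselines (150 mm, 35 mm, 45 mm, 500 g;
  log-scale spread 0.35 for the linear measures and 1.0 for mass, which
  scales roughly with the cube of linear size).
* **Communities**: per site, one of three assembly rules. *Filtering*
  admits species with probability proportional to a Gaussian kernel of
  width $\sigma_f$ (default 0.5 trait SD) around a site optimum tracking
  the gradient. *Neutral* admits uniformly. *Competition* (limiting
  similarity) adds species in random order, rejecting candidates whose
  nearest cophenetic distance to the residents falls below the 25th
  percentile of all pairwise distances. Abundances are log-normal counts
  (meanlog 1, sdlog 1, rounded up to 1) — heavy-tailed, as waterbird
  censuses are.
* **Temperature**: a seasonal sinusoid (coldest in January) plus monthly
  noise; amplitude (8 → 2 °C) and noise (3 → 0.5 °C) decline from the west
  to the east end of the gradient while site mean offsets are drawn
  independently of the gradient, so fluctuation — not mean temperature —
  carries the gradient signal.

The `"paperlike"` scenario combines west = filtering, center = neutral,
east = competition over 42 sites (the study's census size) and an
80-species pool (the species count is not published; 80 is a realistic
regional waterbird pool, fixed once). This is the construction under which
the pipeline should, and in testing does, recover the full qualitative
geography: negative western SES, positive eastern SES, lower western
within-region basal turnover, and fluctuation predictors beating mean
temperature in the ordination fits.

What the generator deliberately does *not* emulate: spatial
autocorrelation and dispersal limitation beyond the gradient itself,
detection error in counts, intraspecific trait variation, and
phylogenetic uncertainty (a single known tree rather than a
pseudo-posterior sample). Passing tests therefore demonstrate that the
estimators recover known structure from idealized gradient data, not that
any particular field system behaves this way.

## Numerical and design choices

* Longitude bins for regions are half-open in decimal degrees — west
  [111, 113), center [113, 115), east [115, 117) — since minute-based
  bounds leave the exact boundary ambiguous.
* Gower distances use the observed trait range and equal weights; a trait
  with zero range is an error, and missing trait values are rejected
  rather than pairwise-deleted (with only four traits, silent deletion
  would distort distances). Traits enter raw; log10 body mass is opt-in.
* The maximum clade credibility tree scores each candidate by the product
  of its clades' frequencies across the set (ties return the first tree in
  input order) and annotates mean node heights, with height defined as the
  distance from a node to its furthest descendant tip; tips sit at height
  zero, so non-ultrametric inputs are flattened with a warning, and any
  negative edge implied by inconsistent mean heights is clamped to zero.
* Every stochastic function takes a `seed` and is bit-reproducible under
  it; seeds are applied via `withr::with_seed` so the caller's RNG stream
  is never disturbed.
* Test problem sizes (tens of species, tens of sites, hundreds of nulls)
  were chosen so the whole suite exercises every calibration property —
  type-I error of the permutation tests, SES self-calibration, Brownian
  consistency of K — in well under a minute per property.

## Known limitations

Polytomies are resolved in order of appearance rather than alphabetically;
contrasts at zero-length resolved nodes depend on that (documented,
deterministic) order. The Dnn tip-shuffle null can be degenerate for
exchangeable distance matrices, which is flagged rather than worked
around. NMDS inherits `vegan::metaMDS`'s local-optimum caveats; stress
should always be inspected. The ANOVA/Tukey region contrast treats site
pairs as independent observations, which pseudo-replicates shared sites —
the same caveat applies to any published use of this design, and the
Mantel machinery is the distribution-free alternative provided.
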