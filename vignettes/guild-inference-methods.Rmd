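---
title: "Guild-based analysis of microbiome resilience: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guild-based analysis of microbiome resilience: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildflow)
```

## The problem

Ex vivo batch fermentation of fecal communities under crossed oxygen and
dietary-fiber treatments produces a repeated-measures 16S data set: amplicon
sequence variants (ASVs) counted in every sample of a
donors × treatments × time × replicates design, plus per-sample chemistry
(pH and the short-chain fatty acids acetate, propionate and butyrate).
Individual ASVs are noisy and heavily inter-correlated, so the analysis
groups them into *co-abundance groups* (CAGs, "guilds"): sets of ASVs whose
abundances covary across samples and that can be treated as single
ecological units when testing how the community responds to oxygen stress
and fiber fermentation. `guildflow` implements that pipeline end to end and
ships a synthetic-community generator with planted guild structure so every
stage can be validated against known ground truth.

## Pipeline and models

### Preprocessing

Counts are rarefied to a common depth (default 28,000 reads) by subsampling
without replacement (hypergeometric semantics); samples below the depth are
dropped with a logged message rather than an error, because batch designs
tolerate occasional shallow libraries. Guild inference then uses only ASVs
present in strictly more than 30% of samples, evaluated globally (the
design is balanced across donors, so global and per-donor prevalence are
nearly equivalent; global is simpler and is the convention we adopt).
Abundances are closed to relative abundance and, for correlation and
regression, log-transformed with a half-minimum pseudocount (half the
smallest nonzero value in the table).

### Repeated-measures correlation

Because every donor contributes many samples, ordinary Pearson correlation
confounds within-donor covariation with between-donor composition
differences. The Bland–Altman repeated-measures correlation removes the
donor level: both variables are centered within subject, and

\[ r_{rm} = \mathrm{cor}(x - \bar{x}_{subject},\; y - \bar{y}_{subject}),
\qquad t = r\sqrt{\frac{df}{1-r^2}},\; df = N - k - 1 \]

with \(N\) observations and \(k\) subjects. The subject is the **donor**
(not donor × treatment), matching the donor adjustment used throughout the
pipeline; this is configurable. Correlations are computed on
log-transformed relative abundance by default (raw relative abundance is
available), since the downstream regression models are also log-scale. The
equivalence with the ANCOVA formulation (signed
\(\sqrt{SS_x/(SS_x+SS_{err})}\) from `y ~ subject + x`) is enforced by an
oracle test at \(10^{-10}\). A pair in which either variable has no
within-subject variance has an undefined correlation; such pairs are
flagged, form no network edge, and enter clustering at distance 1
(\(r\) treated as 0).

### Guild delimitation

The correlation matrix is transformed to a distance \(d = 1 - r \in [0,2]\)
and clustered with Ward's minimum-variance linkage (`ward.D2`), features
sorted lexicographically first so the tree does not depend on input column
order. Guilds are delimited by a *sequential top-down PERMANOVA*: starting
at the root, each split is tested with features as observations, the
node-restricted distance matrix, and child membership as the grouping; the
split is accepted if \(p < \alpha\) (default \(\alpha = 0.001\), 9,999
permutations) and the descent continues into both children, otherwise the
clade becomes one guild.

Two decisions here were genuinely open:

* **Observation unit.** The procedure operates in feature space (ASVs as
  observations, sibling clade vs sibling clade), the natural reading of
  "defining significant clades" on a feature dendrogram.
* **Undersized children.** PERMANOVA is undefined for a group of one, so a
  split whose smaller child has fewer than `min_clade = 2` leaves is
  *untestable*. We treat untestable splits as unaccepted: the node
  terminates as one guild. The alternative — splitting off small children
  untested — lets caterpillar-shaped subtrees of perfectly homogeneous
  clades shatter into singletons with no test ever run (in development this
  fragmented a planted 7-member guild into 7 singleton guilds), so every
  guild boundary in our output is supported by a significant test.

The permutation p-value is the bias-avoiding estimator
\((1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})\), so at 9,999
permutations the smallest attainable p is \(10^{-4} < \alpha\). For
two-group tests without strata where the complete label enumeration is no
larger than `n_perm`, the permutation distribution is enumerated exactly
instead. Per-node permutation streams are seeded deterministically from the
user seed, which makes the partition reproducible and guarantees that guild
counts are monotone in \(\alpha\).

Guilds are named `CAG1..CAGn` by descending overall abundance, and guild
abundance is the per-sample sum over member ASVs. The co-abundance network
retains edges with \(|r| > 0.5\) and \(p < 0.05\) (both strict), with node
weight the mean relative abundance; it is exported as an edge-list TSV and
GraphML.

### Ordination and community-level tests

Bray–Curtis dissimilarity \(\sum|x_i-y_i| / \sum(x_i+y_i)\) feeds classical
PCoA (Gower double-centering, eigendecomposition; negative eigenvalues are
dropped without Lingoes/Cailliez correction, matching the plain PCoA
reported for such data). Donor-adjusted PCoA (aPCoA) projects the
Gower-centered matrix through the residual-maker \(H\) of the donor
indicator design, \(H G H\), before eigendecomposition; the resulting axes
are exactly orthogonal to donor membership, so donor \(R^2\) on the
adjusted axes is zero to machine precision while treatment separation in a
balanced design is essentially untouched.

PERMANOVA uses the standard pseudo-F from squared distances with
\(p\) as above. "Subject-stratified" pairwise PERMANOVA permutes treatment
labels only within donor blocks (labels never cross a block; asserted on
the permutation stream in the tests) and adjusts p-values across the
\(\binom{4}{2}\) treatment pairs by Benjamini–Hochberg. Pairwise tests
default to 999 permutations, the tree cut to 9,999; the two defaults are
deliberately distinct.

Concordance between the ASV-level and guild-level adjusted ordinations is
measured by symmetric Procrustes superimposition on the first two axes
(matching what is plotted; configurable), with significance from PROTEST
row permutations. \(m^2\) near zero with a small PROTEST p indicates the
guild summary preserves the community structure.

### Association models

Per guild, log-transformed guild abundance is modelled as

\[ \log(\text{abundance} + \varepsilon) \sim \text{treatment} + (1\,|\,\text{donor}) \]

by REML (the MaAsLin2-style configuration: log transform, subject as random
effect, Control as reference), with Satterthwaite p-values and BH q-values
over the whole family of guild × non-reference-level tests. Guild–SCFA
models use the z-scored SCFA as predictor and z-scored log abundance as
response, so the slope is a standardized coefficient invariant to units.
If a mixed fit fails it is refit with donor as a fixed effect and the rows
are labelled accordingly; zero-variance guilds are flagged and excluded
from the FDR family. By default all post-0 h samples enter these models
(0 h is the pre-treatment inoculum; treatment effects are undefined there),
configurable via `times`.

The chemistry model is the same mixed model with pH or an SCFA as the
response; all pairwise treatment contrasts use Tukey's studentized-range
adjustment on the estimated marginal means with the model's degrees of
freedom (via `emmeans`). With a single donor the model falls back to fixed
effects with a warning.

## The synthetic community

The generator emulates the study design: 4 treatments × 4 time points
(0, 12, 24, 48 h) × 5 replicates × 3 donors = 240 samples, library size
28,000. For feature \(f\) in guild \(g\) and sample \(s\),

\[ \lambda_{fs} = \text{baseline}_g + \text{effect}_g(\text{trt}_s)\,
   \mathrm{ramp}(t_s) + \text{donor}_g(d_s) + w_g Z_{gs} +
   \varepsilon_{fs} \]

with \(Z_{gs} \sim N(0,1)\) a guild-level shared factor (loading \(w_g\),
default 0.85), donor intercepts drawn once per (guild, donor) (SD 0.4) —
donors differ in community composition, which is the motivation for
subject adjustment — feature noise SD 0.3, and
\(\mathrm{ramp}(t) = \min(t/24, 1)\) so effects are absent in the 0 h
inoculum and full from 24 h. Counts are
\(\text{multinomial}(28{,}000, \mathrm{softmax}(\lambda_{\cdot s}))\):
compositional sampling is deliberate, because the analysis consumes
relative structure and closure induces the realistic negative coupling
between a blooming guild and everything else. All randomness flows from a
single seed; identical seeds give bit-identical output.

The default scenario plants nine guilds encoding the qualitative response
structure of the experiment: two pathobiont guilds (oxygen log-fold effects
+2.5/+2.0, suppressed at −2.5/−2.0 whenever fiber is present — the
facultative-anaerobe bloom that fiber excludes), three oxygen-sensitive
fiber-rescued fermenter guilds (oxygen ≈ −2, fiber +3.8 to +4.2 from a low
baseline, carrying the SCFA yields), a transitional guild promoted (+2.0)
only under oxygen + fiber, a fiber responder indifferent to oxygen, and two
neutral background guilds. No quantitative effect sizes are available for
guild responses of this kind, so these were fixed once at values a
fermentation experiment of this size could plausibly detect and are not
tuned thereafter. Chemistry is
\(\text{SCFA}_a = \sum_g \text{yield}_{ga} \cdot \text{relabund}_{gs} +
N(0, 200\,\mu M)\) truncated at zero, and
\(\text{pH} = 6.7 - 0.75 \log(1 + \text{total SCFA in mM})\) clipped to
\([3.8, 7.2]\), yielding fiber-arm pH ≈ 4.4–4.7 versus ≈ 5.8–6.4 without
fiber at ≥ 24 h.

What the generator does *not* emulate: absolute biomass growth (relative
abundance caps the chemistry's dynamic range, compressing the pH contrast
relative to a real fermentation), taxonomy, phylogeny, sequencing error,
overdispersion beyond multinomial sampling, and time-autocorrelated
replicate trajectories. Passing tests therefore demonstrate correctness of
the statistical machinery and recoverability of planted structure — not
that real communities satisfy the model.

## Numerical choices

* Softmax is computed after subtracting the per-sample maximum; an all
  `-Inf` row is a hard error.
* Ties in clustering are resolved by lexicographic feature order;
  permutation streams are seeded per tree node (`seed + node index`).
* Exact PERMANOVA enumeration engages automatically for two groups without
  strata when \(\binom{N}{n_1} \le n_{perm}\).
* Degenerate rmcorr pairs: \(r = 0\), \(p = 1\), flagged; distance 1.
* Half-minimum pseudocounts are computed per table, not per feature.
* Validation fails fast and names the offending sample/feature/cell.

## Problem sizes used in the test suite

Module tests run on a reduced design (4 treatments × 2 time points × 2
replicates × 3 donors, 3,000 reads, 16 features in 3 guilds). The
full-design checks use the default 240-sample scenario: guild recovery is
scored over 10 simulation seeds at 9,999 tree-cut permutations, PERMANOVA
calibration over 500 null data sets of 20 samples at 199 permutations, and
PROTEST calibration over 200 null configuration pairs at 199 permutations.

## Known limitations

* **Post-selection anti-conservatism of the tree cut.** Each node test
  evaluates the split that Ward clustering chose *on the same distances*,
  so on large perfectly homogeneous feature blocks the selected split is
  extreme among random relabelings and the cut over-splits (observed:
  i.i.d.-distance blocks of 20–24 features split into 2–3 guilds even at
  \(\alpha = 0.001\)). Small clades are provably protected by the exact
  enumeration floor (for 12 features, min attainable \(p = 1/924 >
  0.001\)). This is a property of the sequential testing procedure itself,
  not of this implementation; guild counts on real data should be read as
  upper bounds.
* **Compositional closure.** Because abundances are relative, a strong
  bloom (the oxygen pathobiont reaches >50%) depresses every other guild's
  relative abundance, and those spillover shifts are statistically
  significant at this design's sample size. Marginal treatment
  coefficients of non-responding guilds are therefore biased away from
  zero in arms containing a bloom; signs and relative magnitudes of the
  planted responders are recovered correctly, but "no true effect" does
  not imply "no significant coefficient". A compositionally aware model
  (e.g. CLR-based) is out of scope.
* **Three donors.** Variance components from 3 donor levels are fragile;
  the fixed-effect fallback exists for exactly this reason.
* **Bray–Curtis negative eigenvalues** are dropped, so PCoA "proportion
  explained" is relative to the positive part of the spectrum only.
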