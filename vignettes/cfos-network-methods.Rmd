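---
title: "Methods: c-Fos coactivity networks, module detection and node metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: c-Fos coactivity networks, module detection and node metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosnet)
```

## The measurement model

c-Fos protein expression marks recently active neurons; the density of
stained cells (cells/mm³) in a brain region is treated as that region's
activity level for the subject's recent behavioral episode. The pipeline
starts from a long-format table of one density per (subject, condition,
region) — everything upstream (staining, imaging, counting) is outside its
scope. Two inferential readings are layered on this table:

- **Regional activation**: does a region's mean density differ across
  behavioral conditions? (the region screen)
- **Functional connectivity**: within one condition, do two regions'
  densities covary across subjects? (the coactivity network)

The connectivity reading rests on a strong assumption worth keeping in
view: with 7–9 subjects per condition, each Pearson correlation is
estimated from very few points, so single networks are descriptive. The
package's statistical guarantees are therefore phrased as properties over
replicated synthetic studies, not as standard errors on one network.

## Region screen

Each region is tested with a classical fixed-effects one-way ANOVA
(between-subjects factor: condition), `F = MS_between / MS_within` on
`(k − 1, N − k)` degrees of freedom. Variance homogeneity is assumed, not
tested. When the ANOVA rejects at `alpha` (default 0.05), pairwise
differences are resolved with the step-down Student–Newman–Keuls
procedure: group means are ordered; the pair spanning `r` ordered means is
tested with the Studentized range statistic

```
q = |mean_a − mean_b| / sqrt(MS_within / n_h),   n_h = 2 / (1/n_a + 1/n_b)
```

against the upper-`alpha` quantile of the Studentized range distribution
at `(r, df_within)`. The harmonic mean `n_h` handles the unequal group
sizes (7 vs 9) that arise when subjects are excluded between behavior and
histology. The step-down blocking rule is strict: once a span fails to
reject, every pair nested inside it is declared non-significant without
regard to its own statistic. SNK thresholds for spans shorter than `k` are
smaller than Tukey's single threshold, which is why SNK is never less
powerful pair-for-pair than Tukey HSD (a property the test suite checks by
simulation).

The resulting relation is rendered as a compact letter display by
insert-and-absorb: start with one class holding all groups; each
significant pair splits every class containing both; classes absorbed into
supersets are dropped; letters are assigned in ascending mean order. Two
groups share a letter iff they do not differ — the screen's output encodes
exactly the post-step-down relation (round-tripped in tests).

Two degenerate cases are defined rather than rejected: all values
identical everywhere gives `F = 0, p = 1`; zero within-group variance with
separated means gives `F = Inf, p = 0`, and the SNK result flags the
convention (all unequal pairs significant) via its `zero_variance`
attribute.

No correction is applied across the 13 regional ANOVAs, and the screen
object carries an `uncorrected` flag to keep the caveat visible: at
`alpha = 0.05` roughly one null region in twenty will be flagged, a rate
the acceptance suite verifies directly.

## Coactivity and module detection

Per condition, the interregional matrix holds Pearson correlations across
subjects, computed pairwise-complete so that missing subject–region values
(possible in real bilateral quantification) degrade gracefully; pairs with
fewer than `min_pairs` (default 5) complete observations become an `NA`
sentinel that can never form an edge. Zero-variance regions are dropped
with a warning. No correlation p-values are computed anywhere: edge
inclusion downstream is purely threshold-based.

Each region's *coactivity profile* is its full row of the correlation
matrix — all columns, diagonal included. The diagonal contributes the same
constant to both profiles of any pair and the own-columns contribute
symmetric terms, so including them is the simplest faithful definition; it
is fixed, not configurable. One consequence worth noting: negating every
off-diagonal correlation does **not** preserve the distance between two
perfectly correlated regions, because their profiles now disagree exactly
at their own two positions (the distance becomes `sqrt(8)` for a pair with
`R = 1`); the test suite pins this behavior down.

Regions are clustered agglomeratively on the Euclidean distances between
profiles. Complete linkage is the default: its merge heights are monotone,
which makes a height-fraction cut well defined; `single`, `average` and
`ward` (ward.D2) are available. Labels are sorted lexicographically before
clustering so that tie-breaking never depends on input order (an
invariance the tests check by permutation).

Modules come from cutting the dendrogram at `cut_fraction × max_height`
with the default `cut_fraction = 0.5` — half the height of each tree, a
per-tree normalization (a tree whose heights were rescaled to max 1 would
equivalently be cut at absolute 0.5). The cut is strict: a merge exactly
at the cut height does not join, so ties at the boundary resolve
identically every run. `cut_fraction = 1` is read as "cut at the root" and
yields a single module. Leaves not merged below the cut are singleton
modules — isolates — and are counted as modules, matching how fragmented
coactivity patterns are described in IEG network studies.

## The signed network and its node metrics

Edges are thresholded strictly: a pair with `|R| = 0.5` exactly carries no
edge; `R = 0.51` a positive edge, `R = −0.51` a negative one, the
correlation kept as the signed weight. The default 0.5 sits inside the
range used across IEG network studies (≈0.3–0.87) and is chosen so that
typical 13-region networks leave no node isolated; synthetic data can
still produce isolated nodes, so the metrics are total functions rather
than erroring.

Two per-node metrics are computed, deliberately asymmetric in how they
treat weights:

- the **modified within-module degree score** sums the *absolute weights*
  of the node's within-module edges and divides by `(s_i − 1)`, the
  maximum possible number of module mates. It is a saturation measure for
  small modules: 0 for a node with no within-module edges (and, by
  definition, for a singleton module), 1 when the node touches every mate
  with `|r| = 1`. It is not a z score — no mean or variance enters — and
  the classical standardized within-module degree is intentionally not
  implemented.
- the **participation coefficient** counts edges *by number*, both signs
  alike, into each module: `1 − Σ_s (K_is / k_i)²`. An isolated node
  returns 0 with a warning. Flipping any edge's sign changes neither
  metric, a property asserted directly in the tests.

Module identity always comes from the dendrogram partition of the same
condition; the metrics never re-derive communities from the graph itself.
Both metrics are verified against independent brute-force edge-list
oracles, exhaustively over all edge subsets on 4 and 5 nodes and on seeded
6-node graphs.

Exports: GraphML (via igraph) and a hand-rolled minimal GEXF 1.2 (no
installed package writes GEXF), both carrying module, mWMDz and PC node
attributes and signed-weight/sign edge attributes, plus plain edge-list
text.

## The synthetic study generator

Real subject-level c-Fos tables of this kind are rarely deposited, so the
generator is a first-class module: it draws each condition from a
multivariate normal whose correlation matrix is block-structured by a
planted module partition (`rho_within` on same-module pairs,
`rho_between` across), scaled to per-region standard deviations and
shifted to per-region means, then clipped at zero. Clipping is made
negligible by choosing means at least 4 sd above zero (the default design
uses 500 ± 100 and 900 ± 150 cells/mm³, plausible magnitudes for dense
nuclear c-Fos staining); generation is on the raw scale, not log-scale, so
the planted Pearson correlations are exactly the targets the tests check
against.

Positive semi-definiteness of the implied correlation matrix is validated
at construction. A minimum eigenvalue in `[−1e-10, 0)` is treated as
floating-point noise and repaired by adding `1e-10` to the diagonal;
anything worse is rejected with the offending eigenvalue — silent repair
of a genuinely infeasible specification would hide the error.

One master seed spawns per-condition substreams through a polynomial hash
of the condition name, so adding or renaming a condition never perturbs
its siblings' draws — studies stay bit-reproducible as they grow.

The default study (`simulate_sdmn_study()`) is a four-condition design
over the 13 social-decision-making-network regions with 7/9/9/9 subjects:
socially evoked mean elevations in eight regions (VP, LS, BNST, mPOA, AH,
MeA, VMH, VTA) distributed stimulus-specifically, and condition-specific
planted coactivity — 3 broadly coupled modules at rest; a strongly coupled
affiliation block among 5 modules (one isolate) under partner exposure; 8
modules with 4 isolates and mild negative cross-coupling (−0.1) under
opposite-sex exposure; 5 modules (one isolate) with the strongest negative
cross-coupling (−0.2) under same-sex exposure. The negative magnitudes are
the strongest values that keep each block design positive semi-definite
with margin.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: non-normal and heteroscedastic densities,
hemispheric asymmetry (one value per subject-region is assumed, averaged
upstream), missingness mechanisms, litter or cohort effects, and any
dependence between conditions (subjects are distinct by design). Recovery
guarantees are statements about the planted model only.

## Numerical and design choices

- **Determinism over timestamps.** Every artifact of `run_pipeline()` is a
  pure function of (input bytes, config, seed); the provenance manifest
  records config, seed, package version and the input's MD5 — not wall
  clock time — so that two runs are byte-identical, which the tests check
  file by file.
- **Strict inequalities** at both thresholds (edge inclusion, dendrogram
  cut) so boundary ties behave identically every run.
- **ANOVA by direct sums of squares** inside `one_way_anova()` (the SNK
  step reuses `MS_within` and the screen runs thousands of replicates in
  the calibration tests); it is cross-checked in the suite against
  `stats::oneway.test(var.equal = TRUE)` and `stats::aov`.
- **Letter count** is capped at 26 (single alphabet), far beyond any
  realistic condition count here.
- **Problem sizes in the test suite**, chosen as the package's own
  validation design: planted-partition recovery uses two blocks (6 + 7
  regions), `rho_within = 0.85`, `rho_between ∈ {0, −0.6}`, 200 subjects
  and 100 seeded replicates per setting, requiring exact recovery
  (adjusted Rand index 1) in at least 95; type-I calibration uses 1000
  replicates of a null 4 × 13 study at 7/9/9/9, requiring a flag rate in
  [0.03, 0.07] at `alpha = 0.05`; metric oracles run exhaustively at 4–5
  nodes and sampled at 6.

## Known limitations

- Networks are descriptive at realistic sample sizes; the package
  deliberately offers no significance filter on edges and no
  between-condition network comparison statistics.
- Only one-way between-subjects designs are supported in the screen; no
  repeated measures, no non-parametric alternatives.
- Module detection is dendrogram-cut only; no modularity-optimization
  community detection is provided, by design, so that module definitions
  stay directly interpretable in terms of coactivity distance.
- The region set is user-defined; nothing is hard-coded to 13 regions
  beyond the default study fixture (hippocampal subfields, for instance,
  can be entered as separate regions if quantified separately).
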