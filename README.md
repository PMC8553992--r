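# fosnet

Functional connectivity networks from regional c-Fos density.

Immediate-early-gene (IEG) mapping experiments measure neuronal activation
by counting c-Fos–positive cells per brain region, per subject, under
different behavioral conditions — for example, a pair-bonded rodent exposed
to its partner, to a stranger, or to no social stimulus. `fosnet` turns a
table of such densities (cells/mm³) into per-condition functional
connectivity networks and the statistics used to interpret them:

1. **Region screen** — per region, a one-way between-subjects ANOVA across
   conditions with a step-down Student–Newman–Keuls (SNK) post hoc test and
   a compact letter display ("a" differs from "b"; "ab" differs from
   neither).
2. **Coactivity** — per condition, the interregional Pearson correlation
   matrix of densities across subjects (pairwise-complete, with a
   minimum-pairs floor).
3. **Module detection** — hierarchical clustering (complete linkage by
   default) of the Euclidean distances between correlation profiles, cut at
   half the dendrogram's height; unmerged leaves become singleton modules
   ("isolates").
4. **Signed network** — an edge joins two regions iff |R| > 0.5 (strict),
   keeping the correlation's sign; node metrics suited to small signed
   networks; export to Gephi-readable GraphML/GEXF.

The two node metrics are, for node *i* in module *s* with module size
*s_i*:

- **Modified within-module degree score** (mWMDz):
  `mWMDz_i = Σ_e |r_e| / (s_i − 1)`, summing the absolute correlation
  weights of the node's within-module edges. Ranges 0–1; a node alone in
  its module scores 0 by definition. Despite the inherited "z" in its
  name it involves no standardization — it is a weight-based saturation
  measure for small modules.
- **Participation coefficient**:
  `PC_i = 1 − Σ_s (K_is / k_i)²`, where `K_is` counts the node's edges
  (by number, both signs) into module *s* and `k_i` its total degree.
  0 when all edges stay in one module, approaching 1 as edges spread
  evenly across modules.

Because subject-level c-Fos datasets of this kind are typically not
deposited, the package includes a seeded synthetic-study generator with
planted block-correlation structure (`simulate_sdmn_study()`, a
four-condition study over the 13-region social decision-making network
with 7/9/9/9 subjects), so the whole pipeline is testable end to end with
known ground truth.

## Worked example

```r
library(fosnet)

study <- simulate_sdmn_study(seed = 42)   # 4 conditions, 13 regions, 7/9/9/9
scr <- screen_regions(study)              # ANOVA + SNK + letters per region

cm   <- correlation_matrix(study$tables$partner)
part <- cut_dendrogram(hierarchical_cluster(correlation_distance(cm)))
g    <- threshold_edges(cm)               # |R| > 0.5, signed
part
g
head(node_metrics_table(g, part)[order(-node_metrics_table(g, part)$mwmdz), ], 3)
```

```
Module partition: 13 regions in 5 modules (0 isolates)
  module 1: AH, LS
  module 2: BLA, NAcc, CP, VTA
  module 3: BNST, VMH
  module 4: HIP, mPOA, VP
  module 5: MeA, PAG
Signed graph 'partner': 13 nodes, 19 edges (14 positive, 5 negative), |R| > 0.5
   region module k_within k_total mwmdz   pc
2     BLA      2        3       3  0.84 0.00
13    VTA      2        3       3  0.83 0.00
6     MeA      5        1       3  0.82 0.44
```

The partition groups regions whose coactivity profiles cluster below half
the tree height; the graph keeps the 19 region pairs whose densities
correlate beyond ±0.5 in the partner condition. BLA's mWMDz of 0.84 says
its three edges, all inside its module, carry strong weights relative to
its three module mates; its PC of 0 says no edge leaves the module. In the
screen table, `F(3, 30)` tests each region's condition effect (34 subjects,
4 groups), e.g. `VP: F = 43.3, p = 5.1e-11` with letters
`control = "a", partner = "b"` — partner exposure elevates VP above
baseline.

A full run — validation, screen, per-condition matrices, trees, partitions,
graphs, metrics, manifest — is one call:

```r
input <- tempfile(fileext = ".tsv")
write_density_long(study, input)
report <- run_pipeline(pipeline_config(input, "out/"))
```

or from a shell via the bundled CLI
(`inst/cli/fosnet simulate | validate | screen | network | run`).

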