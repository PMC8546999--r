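# phyloscape

Scalable phylogenetic tree layouts linked to community data.

Microbiome, metabolomic and genomic-surveillance studies pair a reference
phylogeny with a samples × features count table, per-sample and
per-feature metadata, and often a sample ordination. Inspecting a tree of
10⁵–10⁶ tips in that context needs machinery that general-purpose tree
plotters lack: a tree representation that navigates in constant time,
shearing to the features actually observed, layouts that stay exact at
scale, tip-aligned metadata summaries, and queries that connect samples to
clades and back. phyloscape provides that machinery as plain R functions
with deterministic, testable outputs.

## What is inside

* **Succinct trees.** A rooted, multifurcating tree is a length-2n
  balanced-parenthesis bit vector plus per-node names and branch lengths.
  Navigation — `bp_parent()`, `bp_first_child()`, `bp_next_sibling()`,
  `bp_is_leaf()`, `bp_open()`/`bp_close()`, pre/postorder select,
  `bp_subtree_tip_count()` — is O(1) after an O(n) index build, and is
  tested node-for-node against a pointer-tree oracle.
* **I/O.** A Newick reader/writer (quoted labels, comments,
  multifurcations, exact round-trip, offset-bearing parse errors), dense
  TSV and JSON-BIOM feature tables stored sparsely, typed TSV metadata,
  and the sectioned plain-text ordination format (eigenvalues, proportion
  explained, site and optional biplot coordinates).
* **Shearing and leaf sorting.** `shear(tree, keep)` restricts the tree
  to the tips of a feature table (the default in the pipeline, as in
  `community_plot()`); `sort_siblings()` reorders clades by tip count,
  stably.
* **Layouts.** `rectangular_layout()`, `circular_layout()` and
  `unrooted_equal_angle_layout()`, each in actual or unit branch mode.
  Tip k of n gets circular angle 2πk/n exactly; equal-angle sectors are
  proportional to subtree tip counts and conserved exactly at every node.
* **Community layers.** Per-tip stacked category proportions
  (`tip_category_proportions()`), per-feature numeric aggregates —
  mean/median of a sample field over containing samples, or log10
  occurrence counts (`feature_numeric_aggregate()`), quantile-based
  middle-fraction sample subsetting, uniform-metadata propagation up the
  tree and maximal-clade collapsing.
* **Linked views.** `samples_to_nodes()` / `node_to_samples()` (adjoint
  selection queries), categorical selection summaries, biplot-arrow
  resolution, per-frame unique-feature computation for animations
  (`build_frames()`), and `sliding_window_communities()`, which turns
  dated, located records into community samples (7-day windows, one-day
  stride, ≥ 5 records per emitted window by default).
* **Rendering.** `render_svg()` writes byte-deterministic SVG with node
  colouring, collapsed-clade wedges, stacked/numeric barplot layers
  (columns or rings) and per-layer legends. `community_plot()` /
  `tree_plot()` and the `exec/community-plot`, `exec/tree-plot` scripts
  wire everything together and emit an output directory with the SVG, a
  `summary.json` and a log.

## Worked example

```r
library(phyloscape)

fx <- generate_fixture(n_tips = 8, n_samples = 4, density = 0.5, seed = 1)
fx$tree
#> <bptree> 15 nodes, 8 tips, root 'n7'

tree <- shear(fx$tree, rownames(fx$table))
tree
#> <bptree> 13 nodes, 6 tips, root 'n7'

presence <- build_presence(fx$table)
presence
#> <presence_index> 6 features, 4 samples, 14 present pairs

layer <- tip_category_proportions(tree, presence, fx$sample_metadata, "group")
layer$payload$t1
#>      Host      Soil     Water
#> 0.3333333 0.3333333 0.3333333

feature_numeric_aggregate(presence, fx$sample_metadata, "ph", "mean")[1:3]
#>       t1       t2       t3
#> 7.513333 6.955000 7.800000

render_svg(circular_layout(tree), barplot_layers = list(layer),
           out_path = "tree.svg")
```

The fixture's tip `t1` occurs in three of the four samples, one from each
`group` level, so its stacked bar splits into thirds; its containing
samples have pH 9.96, 7.80 and 4.78, whose mean 7.51 is what the numeric
aggregate reports. The SVG contains one radial bar group per occupied
tip, drawn identically on every run with the same inputs.

From a shell, the same pipeline is:

```sh
exec/community-plot --tree tree.nwk --table table.tsv \
  --sample-metadata samples.tsv --barplot-category group \
  --layout circular --out-dir out/
```

which writes `out/plot.svg`, `out/summary.json` (node/tip/sample counts
after shearing) and `out/log.txt`; `--no-shear` keeps the full tree.

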