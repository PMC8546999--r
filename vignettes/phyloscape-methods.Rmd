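---
title: "phyloscape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phyloscape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloscape)
```

phyloscape draws large phylogenies in the context of community data — the
kind of samples-by-features count tables produced by amplicon, metagenomic,
metabolomic or genomic-surveillance studies — and keeps the tree, the
table, the metadata and a sample ordination connected by explicit,
testable queries. This vignette explains the underlying representations
and algorithms, the tunable parameters, and the design decisions that
were genuinely open.

## The succinct tree and its navigation algebra

A rooted, possibly multifurcating tree with $n$ nodes is stored as a
balanced parenthesis (BP) bit vector of length $2n$: each node is one
open/close pair and subtrees are nested intervals. Names and branch
lengths are carried per node in preorder. A missing branch length is `NA`
and is never conflated with a zero-length branch — substituting zero (or
one) is a *layout-time* decision, because the substitution chosen can
visibly distort depth.

Navigation (`bp_parent()`, `bp_first_child()`, `bp_next_sibling()`,
`bp_is_leaf()`, `bp_open()`/`bp_close()`, pre/postorder select,
`bp_subtree_tip_count()`) is answered in O(1) from plain prefix-sum and
match indices built once at construction. We deliberately do not chase
$o(n)$-space succinct rank/select structures: the contract here is the
*correctness of the navigation algebra*, which the test suite verifies
exhaustively against a naive pointer-tree oracle on hundreds of seeded
random trees, not space optimality. Node identity is positional
(opening-parenthesis position) and is recomputed after every structural
change; stable cross-operation references should use names.

The Newick dialect accepted is the permissive one taxonomy-bearing trees
need: multifurcations, quoted labels with `''` escaping, `[]` comments,
underscores kept verbatim, and internal labels treated as *names* rather
than support values (a support-value reinterpretation flag would be a
backward-compatible addition). Malformed input fails with the 1-based
character offset. The writer emits lengths with the shortest decimal
representation that the parser's own `strtod` maps back to the identical
double, so read–write–read is an exact identity.

## Shearing

When a feature table accompanies a tree, the tree is sheared by default to
the tips named in the table. Shearing keeps exactly the requested tips,
removes internal nodes left with no kept descendant, and **retains**
internal nodes reduced to a single child. Retention was an open choice:
suppressing unifurcations gives tidier drawings, but it silently discards
named internal nodes — and their metadata — that colouring and collapsing
may still need. `collapse_unifurcations = TRUE` opts into splicing, with
branch lengths summed (two absent lengths stay absent). Sibling order is
always preserved, and shearing twice with the same set is a no-op.

## Layouts

Three standard layouts are provided; all are pure functions of the tree
and a branch mode.

* **Rectangular.** Tips take integer y-positions $0..n_{tips}-1$ in the
  order tips appear in a traversal; each internal node sits at the
  arithmetic mean of its children's y; x accumulates branch lengths from
  the root. Internal nodes carry the vertical connector spanning their
  children.
* **Circular.** The same recurrence on an angular coordinate: tip $k$ of
  $n$ gets $\theta_k = \theta_0 + 2\pi k / n$ — so consecutive tips are
  separated by exactly $2\pi/n$ — internal angles are means of children,
  and radius accumulates branch length. The internal-node angle rule was
  open (mean-of-children vs midpoint of the angular extremes); we chose
  mean-of-children for consistency with the rectangular layout, and
  document it rather than hide it.
* **Unrooted equal-angle.** Every node subdivides its angular sector
  among its children proportionally to their tip counts, counterclockwise
  in tree order; a child sits at branch-length distance from its parent
  along its sector's bisector. The root is treated as an interior vertex
  at the origin with the full circle, which is the natural reading of an
  "unrooted" drawing of a rooted data structure. Sector widths are
  conserved exactly at every node (tested to $10^{-9}$).

Branch modes: `actual` uses stored lengths, substituting 0 with a warning
where a length is absent; `unit` assigns every branch length 1. Negative
lengths are rejected outright rather than clamped — they indicate an
upstream problem the user should see. Layouts are abstract Cartesian;
"y grows downward" happens only at render time.

## Community statistics

Presence is strictly `count > 0`; there is deliberately no minimum-count
threshold in this version, because thresholding interacts with library
size in ways that belong upstream (rarefaction or prevalence filtering).

* `tip_category_proportions()` gives, per tip, the proportion of its
  containing samples in each level of a categorical field — the payload
  of a stacked barplot. Proportions sum to exactly 1 for every occupied
  tip; missing field values pool into the reserved `"__missing__"`
  category (a collision with a real category of that name is an error,
  not a silent merge). Tips absent from the table get an empty payload
  and simply draw no bar.
* `feature_numeric_aggregate()` computes the per-feature mean or median
  of a numeric sample field over containing samples (missing values
  excluded), or `count_log10`, the log10 occurrence count used to
  summarize very uneven feature prevalence in large surveys.
* `subset_samples_middle_fraction()` keeps samples in the central
  `keep_fraction` of a numeric field. "Middle 90%" is implemented as the
  2.5th..97.5th-style *empirical quantiles* (linear interpolation,
  inclusive cutoffs) rather than fractions of the min–max span: the
  purpose of such a subset is outlier removal, which the quantile reading
  serves and the span reading does not when the field is skewed. The span
  reading remains available as `mode = "range"`.
* `propagate_uniform_metadata()` labels an internal node with value $v$
  exactly when at least one descendant tip has a non-missing value and
  all such tips agree on $v$; missing-valued tips are tolerated rather
  than poisoning the clade. `collapse_uniform_clades()` then reports the
  *maximal* uniform internal nodes (no uniform ancestor), whose tip sets
  are therefore disjoint; an exclusion list keeps named clades expanded
  while still reporting maximal uniform clades strictly inside them.

## Linked selections and animation frames

`samples_to_nodes()` maps a sample selection to the tips present in at
least one selected sample *plus* every internal node whose descendant
tips are all covered — whole clades light up only when fully covered.
This follows the "highlight nodes, not just tips" reading; a `tips_only`
flag restricts it. `node_to_samples()` is the reverse union query, and
the two are adjoint: a tip is always recovered by mapping its own sample
set back to the tree. Biplot arrows resolve to tree nodes by exact name
match only; fuzzy matching would be a correctness hazard with large
feature namespaces.

`build_frames()` orders samples along a gradient field (numeric columns
sort numerically, otherwise lexicographically) and groups them by a
trajectory field; within each frame a trajectory's "unique features" are
those present in none of the other trajectories of the same frame, which
makes the per-frame unique sets pairwise disjoint by construction.

`sliding_window_communities()` turns per-record (e.g. per-genome)
metadata with dates and locations into community samples: per location, a
window of `window_days` days (default 7) advances one day at a time over
the observed date range, and any window containing at least `min_records`
records (default 5) is emitted as a sample whose feature vector marks
each record once. Two choices here were open and are documented rather
than guessed silently: the stride is one day (the maximal-overlap reading
of a "sliding" window), and window contents are per-record presence, not
abundance. Merging of sub-locations (boroughs into a city) is the
caller's job via `location_rename`, keeping the windowing itself free of
geographic policy.

## Rendering

`render_svg()` writes plain SVG 1.1 deterministically — the same inputs
produce byte-identical files, which makes golden-file testing and diffing
practical, and is why a static vector format was chosen over an
interactive viewer (explicitly out of scope here). Barplot layers are
supported on rectangular (columns) and circular (rings) layouts and
refused on the unrooted layout, whose tips are not aligned on any common
axis. Discrete palettes cap at 12 categories with least-frequent pooling
into "Other"; continuous values map through Lab-interpolated sequential
or diverging ramps, so colour is perceptually monotone in the data; an
all-equal numeric layer degenerates to the ramp midpoint rather than
dividing by zero. Collapsed clades draw as labelled wedges and their
subtree edges are suppressed.

## Synthetic data: what it emulates, and what it does not

`generate_fixture()` produces the study conditions used throughout the
tests: a random tree from sequential random coalescence (pairs, with a
15% chance of a triple merge, so multifurcations occur), exponential
branch lengths with rate 1, a sparse count table over a random 80% subset
of tips with independent Bernoulli occupancy and 1 + Poisson(2) counts,
and metadata with a three-level categorical column and a numeric pH-like
column spanning 4–10, each with ~5% missing values. A second generator,
`generate_record_fixture()`, emulates dated, located surveillance records
over a 30-day default range. Both are byte-deterministic per seed.

These fixtures exercise the *combinatorics* the package must get right —
topology, sparsity, missingness, ties — but not the statistical structure
of real communities: no phylogenetic signal in occupancy, no
sample-depth variation, no compositionality, no temporal autocorrelation
in the record dates. Passing tests therefore certify the algorithms'
contracts, not any biological inference.

Test problem sizes were chosen to probe each property at the smallest
scale that can falsify it: hundreds of trees of ≤ 64 tips for the oracle
and round-trip properties, a 1,000-tip × 200-sample fixture for
conservation laws, and a single 100,000-tip tree as a scalability smoke
test of parsing, all three layouts and a barplot layer.

## Numerical choices and degenerate inputs

* Quantiles use R's default linear-interpolation definition (type 7),
  with inclusive cutoffs.
* Sibling sorting is stable (ties keep input order), so a star tree is a
  fixed point of leaf sorting in either direction.
* Equal-angle conservation and stacked-proportion conservation are
  asserted to $10^{-9}$; coordinates themselves are exact arithmetic on
  doubles.
* A single-tip tree is legal everywhere: it lays out at the origin,
  shears to itself, and renders.
* Branch-length formatting uses the shortest decimal that the parser's
  `strtod` inverts exactly, falling back to 17 significant digits.
* Empty selections, empty frames and an empty sliding-window result are
  all valid empty objects, never errors.

## Known limitations

* BIOM support is JSON BIOM only; HDF5 BIOM files must be converted
  upstream.
* The ordination reader accepts the sectioned plain-text format with
  `Eigvals`, `Proportion explained`, `Site` and optional `Species`
  blocks; constrained-ordination blocks are tolerated only when empty.
* No equal-daylight refinement of the equal-angle layout, no radial
  layout, and no curved aesthetics.
* Taxonomy strings are treated as opaque labels; rank-aware parsing is
  left to upstream tools.
* The SVG output is presentation-quality but intentionally minimal; it is
  a rendering of the layout contract, not a figure-design system.
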