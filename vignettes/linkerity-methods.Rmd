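---
title: "Detecting linker proteins: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting linker proteins: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(linkerity)
```

## The problem

Cellular processes — cell-cycle regulation, cytokinesis, polarized growth —
are usually studied as separate regulatory modules, yet cells coordinate
them tightly. In a protein–protein interaction (PPI) network annotated with
functional categories, the proteins doing that coordination have a
characteristic topological signature: they sit at the *fringe* of their own
functional sub-network but become *central* once the sub-network is merged
with the others. This package quantifies that signature and supplies the
supporting machinery (network construction from snapshot files, annotation
handling, null models, robustness protocols, community composition) needed
to use it responsibly on noisy interaction data.

## The linkerity statistic

For a functional category $c$, let the *sub-network* be the induced graph on
all proteins annotated with $c$ (we analyse its largest connected
component), and the *core network* be the merged graph over all studied
categories. Every member $v$ of the sub-network gets two descending
betweenness-centrality (BC) ranks:

* $\mathrm{Rank}_{sub}(v)$ — BC computed inside the sub-network, members
  ranked among themselves;
* $\mathrm{Rank}_{core}(v)$ — BC computed on the full core network, but with
  *only the sub-network members* sorted and ranked among themselves (all
  other proteins are skipped, so both ranks live on the same scale).

Then

$$\mathrm{linkerity}(v) \;=\; \frac{\mathrm{Rank}_{sub}(v)}{\mathrm{Rank}_{core}(v)}.$$

A protein whose position does not shift has linkerity 1 by definition;
values well above 1 mark proteins peripheral locally but central globally.
Note the asymmetry of the ratio: large *numerators* (a deep rank in the
sub-network) combined with small *denominators* (a top rank in the core)
produce large scores, so the statistic specifically rewards the
fringe-to-centre shift rather than centrality per se — a hub that is central
in both graphs scores near (or below) 1.

### Ranking with ties

PPI sub-networks contain many proteins with BC exactly 0, so the tie rule
matters. We use average-tie ranking: scores sorted descending, and every
member of a tie group receives the arithmetic mean of the integer positions
the group occupies (`average_rank()`; scores `[10, 10, 7, 5, 5, 5]` rank as
`[1.5, 1.5, 3, 5, 5, 5]`). Ranks over $n$ proteins always sum to
$n(n+1)/2$, which the test suite asserts for every table the pipeline
produces. Because ranking is invariant under any positive monotone
transform of the scores, the choice of unnormalised BC is immaterial to
every downstream linkerity value — normalising BC could not change any
result, so we keep raw path counts.

### Assumptions

* The interaction graph is treated as **undirected and unweighted**;
  confidence scores are used only as a pre-filter (records with
  `confidence >= cutoff` are kept — the boundary score is included) and kept
  as provenance.
* BC is computed on the **largest connected component**; proteins outside
  it (or outside the sub-network's largest component) receive no rank and
  no record, and are counted in diagnostics instead.
* Annotations arrive **pre-resolved**: category files list (protein,
  category) pairs, with umbrella merges (e.g. two polarity-related child
  terms folded into one "polarity" label) applied at load time. No GO-DAG
  traversal is performed; partial overlaps between categories caused by
  shared child terms can be handled by an explicit exclusion list of
  affected proteins (`classify_edges(exclude = ...)`).

## Functional modularity and its nulls

To ask whether proteins preferentially interact within their functional
group, we use the pair-normalised likelihood ratio

$$L \;=\; \frac{E_{same}/P_{same}}{E_{diff}/P_{diff}},$$

where $E_{same}$/$E_{diff}$ count edges between annotated proteins that do /
do not share a category, and $P_{same}$/$P_{diff}$ count annotated protein
*pairs* that do / do not share one. The pair normalisation matters: without
it, the raw edge ratio $E_{same}/E_{diff}$ (also reported, via
`modularity_counts()`) conflates wiring preference with category sizes — a
fully random graph over unbalanced categories already has a large raw
ratio. $L$ has a clean null of 1 under random wiring.

Two resampling nulls are provided (`null_distribution()`):

* **Fully random rewiring** — all edges removed, the same number redrawn
  uniformly over node pairs (simple graph), annotations untouched.
* **Degree-preserving rewiring** — repeated double edge swaps: edges
  $(u,v), (x,y)$ replaced by $(u,x), (v,y)$, rejecting self-loops and
  duplicates; every protein keeps its exact degree. Default 10·m attempted
  swaps per replicate, enough to decorrelate the wiring; configurable.

Empirical p-values use the add-one correction
$p = (1 + \#\{L_{null} \ge L_{obs}\})/(1 + n_{null})$, so $p$ can never be
reported as 0. Both nulls are worth inspecting: a high observed $L$ against
the degree-preserving null shows the modularity is not a degree artefact.

## Robustness to imperfect interaction data

Interaction snapshots certainly miss true edges and contain false ones, so
exact ranks should not be over-interpreted. `robustness_summary()`
implements the perturbation protocol: repeatedly apply one of

* `add_random` — add `round(fraction * m)` edges uniformly over
  non-adjacent pairs (missing-link noise; the reference fraction is 10%),
* `add_preferential` — endpoints drawn proportional to degree
  (study-bias noise that concentrates on hubs),
* `remove_random` — delete edges uniformly (false-positive noise),

recompute the category ranking (by linkerity, or by sub-network BC), and
accumulate per-protein mean rank, rank SD, and the frequency of remaining
in the top 10% / top 20% of the ranking. The informative readout is
*retention*: proteins with genuinely high scores stay inside the top
quintile essentially always, while mid-table order shuffles freely. On the
default planted fixture, the planted bridges that occupy top-decile
positions retain top-20% membership in ≥ 90% of 100 replicates (asserted in
the acceptance suite); ordinary nodes that happen to occupy the tail of the
top decile with noise-level linkerity do not have — and cannot have — that
kind of stability, which is itself a useful caution when reading real
ranking tails.

Top-fraction sets use a `ceiling(fraction * n)` quota; a tie group
straddling the boundary is included whole only when it fits, otherwise
members fill the quota in identifier order (the quota rule is documented
rather than meaningful — real BC ties at the boundary are rare).

## Communities and neighbour heterogeneity

`k_clique_communities()` implements clique percolation: communities are
unions of k-cliques chained through (k−1)-node overlaps, computed by
percolating over maximal cliques of size ≥ k (equivalent, and far cheaper
than enumerating all k-subsets — the test suite proves the equivalence
against an exhaustive-enumeration oracle on small random graphs). Default
k = 4; k = 2 degenerates to connected components. Communities may overlap,
which is the point: multifunctional proteins belong to several. Per
community, `community_composition()` counts members by exact annotation
subset, the numbers behind functional pie charts.

`neighbor_profiles()` counts, for each protein under a focal category, its
annotated interactors sharing the category versus carrying only other
categories; the heterogeneity ratio `n_other / n_same` correlates with
linkerity (`linkerity_heterogeneity_association()`). Spearman rank
correlation is the default — linkerity is rank-derived, so only orderings
are meaningful — with Pearson exposed as an option; proteins with
`n_same = 0` (infinite ratio) are excluded and counted. The exact statistic
behind the published association is not printed in the available text, so
this choice is our documented stand-in.

## The synthetic test surface

`generate_modular_network()` is the package's no-download benchmark. It
emulates exactly the features the method needs: blocks of
`module_size = 40` nodes per category (3 categories) wired within at
`p_in = 0.3` and across at `p_out = 0.01` (strong planted functional
modularity), an optional fraction of multi-annotated nodes, essentiality
labels planted with probability proportional to degree rank (so hubs are
enriched, as in real essentiality data), and — per module pair — 2 planted
linker nodes.

A planted linker carries exactly one category but attaches with 4 edges
inside its home module (well below the expected within-module degree of
~12, keeping its sub-network BC near the bottom) and 20 edges into the
paired module. The between-module attachment must be this strong for the
construction to realise its definition: with only a handful of cross edges
the linker carries almost no inter-module shortest paths — the random
`p_out` background provides competing routes — and it is then simply a
low-degree node, not a bridge. At 4/20 the planted linkers occupy the top
linkerity positions of their category in ≥ 95% of seeded replicates, which
the acceptance suite asserts over 100 seeds.

What the generator does **not** emulate: scale-free degree structure inside
modules (modules are Erdős–Rényi blocks; `generate_scale_free()` covers the
heavy-tailed case separately for the degree-distribution fit), realistic
annotation incompleteness, and any quantitative match to a real organism's
network statistics. Passing tests on these fixtures therefore demonstrates
correctness of the algorithms and recoverability of planted structure under
the stated noise, not performance guarantees on real snapshots.

`toy_linker_fixture()` is an 11-node worked example of the same idea whose
full rank/linkerity table was computed once with an independent
shortest-path oracle and frozen; it doubles as a readable illustration of
the statistic and as a bit-exact regression anchor.

## Numerical and engineering choices

* **Formula orientation.** The ratio is sub-network rank over core rank;
  the published worked examples (e.g. 73.5/8 = 9.19) fix the orientation
  unambiguously even though prose descriptions can be read both ways.
* **Display rounding.** Linkerity is kept at full precision internally;
  `round_display()` rounds half away from zero to 2 decimals for
  presentation only. One published table cell (32/9 shown as 3.55) is
  inconsistent with its own neighbours under any fixed rounding rule
  (32/9 = 3.5556 → 3.56); we do not reproduce that cell.
* **Edge counts from fractions** use base R's `round()`
  (half-to-even); `fraction = 0` is allowed as a degenerate spec so
  protocols can be smoke-tested deterministically.
* **Seeds.** Every stochastic operation takes an explicit integer seed and
  is a pure function of (input, seed); replicated protocols give replicate
  *i* the seed `base + i`, so any single replicate is reproducible in
  isolation. Identical config + seed reproduces byte-identical pipeline
  artifacts.
* **Tie-breaks.** Largest-component ties resolve to the component holding
  the lexicographically smallest identifier; community ordering is by
  smallest member. Both are determinism devices, not scientific claims.
* **Degenerate inputs.** Graphs below 3 nodes have all-zero BC; a category
  inducing fewer than 3 connected nodes is an error for linkerity; a graph
  with no cross-category edges yields a flagged infinite modularity ratio;
  degree histograms need ≥ 3 positive-frequency bins to fit (zero bins are
  dropped before taking logs, since log 0 is undefined).
* **Problem sizes.** The replicated protocols in the test and acceptance
  suites run on the default 126-node fixture with 100–200 replicates and
  20–100 seeds per property — sizes at which every property is decisive yet
  the whole suite runs in minutes on a laptop. The user-facing defaults
  (1000 replicates, with 500 supported for the linkerity robustness run)
  match the reference protocol.

## Known limitations

* Linkerity is not normalised for sub-network size: larger sub-networks
  allow larger rank jumps, so scores are comparable within a category list,
  not across categories. A size normalisation is deliberately left as
  future work.
* The modularity ratio treats "shares ≥ 1 category" as binary; graded
  annotation similarity is out of scope.
* k-clique percolation on very dense graphs can be expensive (maximal
  clique enumeration is exponential in the worst case); for the sparse PPI
  networks this package targets it is fast.
* No live database access: all inputs are local snapshot files, and
  database-version-dependent quantities (absolute node/edge counts of a
  particular snapshot) are outside what the package can or should
  reproduce.
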