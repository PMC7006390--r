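---
title: "Multi-level pathway crosstalk networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level pathway crosstalk networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathlevels)
```

## The model

`pathlevels` treats a pathway resource as an undirected graph: nodes are
pathways, and an edge joins two pathways whenever one references the other
(in KGML, a `map`-type entry). Edges are undirected on purpose. Crosstalk
annotations in pathway databases mix regulatory direction, shared
metabolites and curation conventions; rather than pretend to recover
causality, the method reads a link as "these two processes talk", so each
expansion step collects both upstream and downstream neighbors of the
previous level.

Given a set $S$ of user-chosen first-level (1L) pathways — pathways known
from the literature to be involved in the trait — and a depth $n$, the
level of a pathway $p$ is

$$\mathrm{level}(p) = 1 + d(p, S),$$

where $d$ is the minimal graph distance from $p$ to the nearest member of
$S$; pathways with $d(p,S) \le n-1$ form the network. Implementation-wise
this is a breadth-first expansion with first-assignment-wins, so a
multiply-reachable pathway carries its minimal level and appears exactly
once. That choice is not forced by the biology — one could argue for
listing a pathway at every level that reaches it — but minimal distance
makes the output unique, matches the "how far from the seed set" reading,
and keeps assignments nested as $n$ grows (the $n$-level assignment is
always a sub-mapping of the $(n{+}1)$-level one, a property the tests
check). `n_levels` is capped at 10 (with a warning) because pathway link
graphs are dense enough that breadth-first expansion saturates the
universe within a handful of steps; in practice 2–3 levels is where the
biological signal lives, and the packaged analyses use 3.

Candidate genes are then attached to every network pathway they are
annotated to — a gene annotated to two level-2 pathways yields two rows in
the level-2 table, while summary counts (`glance()`) count unique genes.
Genes that fail to attach are not discarded silently; they partition into
three informative classes: annotated only to pathways outside the
investigated levels (plausible false positives, or genes acting through
unrelated processes), known to the resource but not yet assigned to any
pathway, and absent from the resource entirely. The last two classes
measure the incompleteness of the annotation, not properties of the gene
list, which is why the partition is reported rather than folded into a
single "excluded" count. Distinguishing them requires a universe-wide
known-gene registry beyond the gene–pathway map, which the snapshot format
carries as an optional `known_genes.tsv`.

## Expression networks and fold-change bins

For transcriptomic inputs the package connects a DEG table (gene, signed
fold change, p-value) to a user-supplied list of pathways of interest, each
carrying an externally computed signed expression score (a flux estimate,
a gene-set statistic — the package consumes these, it does not compute
them). No level expansion happens here: the pathway side is exactly the
scored list, and an edge joins gene to pathway when the annotation says so.

DEGs pass a p-value filter first (`p <= cutoff`, inclusive, since that is
what "cut-off" conventionally means; the cutoff must lie in $(0,1]$).
Nodes are then binned for coloring. For a value $v$ (gene fold change or
pathway score), let $T$ be the maximum magnitude among same-direction
values of the same node class after filtering, and $r = |v|/T$. The bin is
*low* for $r < 0.25$, *moderate* for $0.25 \le r < 0.50$, *high* for
$0.50 \le r < 0.75$, and *strong* for $r \ge 0.75$ — lower bounds
inclusive, upper bounds exclusive. Two consequences worth knowing: the top
value of each direction is always *strong* ($r = 1$), and a direction with
a single value puts that value at $r = 1$ regardless of its absolute size.
"Fraction of the top value" could alternatively be read as a rank
percentile of the value distribution; the value-relative reading is
implemented because that is the natural parse of "% of the top value", and
the two coincide at the extremes where the coloring matters most. A value
of exactly zero has no direction and is rejected during validation rather
than silently assigned a side.

Fold changes are signed (log-fold-change style). Ratio-style input (all
positive, $<1$ meaning downregulation) is common enough that
`prepare_expression_list(log_transform = TRUE)` converts it with $\log_2$;
the package never guesses which convention an input uses.

## Over-representation

Each pathway is tested with the upper-tail hypergeometric probability
$P(X \ge k)$ — the one-sided Fisher exact test — where $N$ is the
background size, $K$ the pathway's background genes, $n$ the candidates in
the background and $k$ the overlap. The tail is computed through the
distribution's survival function (`phyper(k-1, ..., lower.tail = FALSE)`),
which is stable in log-space for large counts; the test suite checks it to
$10^{-12}$ against exhaustive enumeration of every draw for all urns with
$N \le 12$, and checks monotonicity in $k$ and complementarity with the
lower tail.

The background is the set of genes with at least one pathway annotation —
not every gene in the annotation table — because genes the resource cannot
place are not eligible to be "drawn into" any pathway, and counting them
deflates p-values. Candidates outside the background are excluded from $n$
and surfaced as a side count. Two scopes are provided: the global universe,
and the network-restricted background (genes of the network's pathways,
testing only those pathways), which asks a sharper question — "within the
neighborhood I chose to investigate, which pathways concentrate my
genes?". Only network pathways are tested in the restricted mode, the
literal reading of using the network as background. Pathways with $K = 0$
are omitted rather than reported at $p = 1$, and raw p-values are always
reported, with Benjamini–Hochberg adjustment optional — over-representation
screens of this kind are conventionally read on raw p-values, and the
discrete test is conservative (the null-calibration test shows per-pathway
type-I rates well under nominal).

## The synthetic universe generator

All tests and the acceptance script run on seeded synthetic universes
(`fixture_spec()` / `generate_universe()`), because the live resource is
versioned, licensed, and unavailable offline. The generator emulates the
structural features the method actually exercises:

- the link graph is Erdős–Rényi (default edge probability 0.08) over a
  random spanning-tree backbone, so it is always connected and multi-level
  expansion cannot silently degenerate — with 30 pathways (the default)
  this gives sparse graphs whose 3-level neighborhoods cover part, not
  all, of the universe, the regime where level assignment is informative;
- genes (4–12 per pathway by default) are drawn from a shared pool sized
  at 70% of the total slots, so pathways overlap the way functional
  annotations do;
- 15% extra known-but-unassigned genes and a reserve of absent ids mirror
  the annotation gaps behind the `no_pathway` and `not_in_db` classes;
- DEG tables are 85% null (fold change $\sim N(0, 0.5)$, p-value uniform)
  and 15% signal ($|FC| \ge 2$, $p < 0.01$), so planted signal survives a
  0.05 filter by construction and null p-values are checkably uniform;
  pathway scores always include both signs so both color scales appear.

What the generator does *not* emulate: the heavy-tailed degree
distribution of real pathway graphs, realistic pathway sizes (real
pathways span two orders of magnitude), hierarchical overview maps, or
correlated annotation errors. Passing tests therefore demonstrate the
algorithms' correctness on well-specified inputs, not robustness to the
idiosyncrasies of a particular database release. Ground truth is computed
with an independent shortest-path routine (igraph's distance matrix), not
the package's own breadth-first code, so the level tests are a genuine
dual-route check.

All generator randomness flows from the single seed in the spec through
`withr::with_seed`; no global RNG state leaks, and equal seeds give
byte-identical snapshots.

## Numerical and interface choices

- Pathway ids are normalized to the organism prefix; reference
  (`map`-prefixed) ids are accepted and rewritten, since analyses mix the
  two styles freely. Self-links in KGML are dropped — a pathway citing
  itself carries no crosstalk information and would distort levels.
- Snapshot tables are sorted lexicographically with LF endings, so saves
  are byte-deterministic and `save -> load -> save` is the identity; this
  is what makes the end-to-end determinism test meaningful.
- Annotation mapping is case-sensitive and first-occurrence-wins for
  duplicated input ids (with a warning); silently keeping the last
  occurrence would hide input errors. Two external ids mapping to one
  entrez id are kept and deduplicated downstream with a note.
- HTML exports embed the full node/edge payload as JSON with layout
  positions from a seeded force-directed layout (default seed 42), so
  repeated renders are byte-identical and the payload parses back to the
  document; the viewer is a small inline SVG script, keeping the file
  self-contained and renderable offline.
- Node colors follow the legend conventions of pathway network drawings:
  violet/yellow/blue diamonds for levels 1–3, orange for network pathways
  no candidate gene reaches, green circles for candidate genes; deeper
  levels cycle a fixed 8-color palette. Exact hex values are not dictated
  by any convention, so named CSS colors matching the legend words are
  used.
- Problem sizes in the packaged checks — universes of up to 50 pathways,
  100 replicate graphs for the level oracle, 1000 null draws for
  calibration, exhaustive urns to $N = 12$ — were chosen as the smallest
  sizes at which each property is a meaningful stress of the code rather
  than a formality.

## Limitations

The method inherits the limits of its resource: genes missing from the
annotation or unassigned to pathways can never be highlighted, and the
level structure is only as good as the curated link set. Direction of
crosstalk is deliberately not modeled. Expression scores are consumed, not
computed. The enrichment test treats genes as exchangeable draws — no
gene-length or expression-level bias correction — which is the standard
hypergeometric assumption and the standard objection to it.
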