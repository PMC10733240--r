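---
title: "Generating orchard and tree-child networks by minimum cherry-picking sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating orchard and tree-child networks by minimum cherry-picking sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchardgen)
```

## The model

A rooted binary phylogenetic network on taxa $X \subseteq \{1,\dots,n\}$ is a
directed acyclic graph without parallel arcs whose nodes are a unique root
(indegree 0, outdegree 1), leaves (1, 0) bijectively labeled by $X$, tree
nodes (1, 2) and reticulations (2, 1). Reticulations represent reticulate
evolutionary events — hybridization, recombination, lateral transfer. With
$r$ reticulations, the degree sums force $|X| + r - 1$ tree nodes,
$2|X| + 2r$ nodes and $2|X| + 3r - 1$ arcs; the package asserts these
identities for every network it builds.

Two leaves $i \neq j$ form a *cherry* $(i,j)$ (character `C`) when they share
a parent, and a *reticulated cherry* $(i,j)$ (character `R`) when the parent
$p_i$ is a reticulation, $p_j$ is a tree node, and $p_j p_i$ is an arc.
Reducing a cherry deletes leaf $i$; reducing a reticulated cherry deletes the
arc $p_j p_i$; elementary nodes are suppressed. A network that some sequence
of reductions takes to a single-leaf (trivial) network is an *orchard*
network, and the recorded pair sequence, applied right-to-left as
*augmentations* (the exact inverses of the reductions), rebuilds the network.
*Tree-child* networks (every non-leaf node has a child that is not a
reticulation — leaves qualify) and *stack-free* networks (no reticulation
whose child is a reticulation) are nested subclasses of orchard networks;
tree-child networks satisfy $r \le n - 1$.

## Canonical sequences

A network has many complete reducible-pairs sequences. Ordering pairs by
$(i,j) < (i',j')$ iff $i < i'$, or $i = i'$ and $j < j'$, and sequences of
equal length lexicographically, the minimum complete sequence `mcrs()` is
unique and injective: isomorphic networks and only those share it. All
complete sequences of one network have length $|X| + r - 1$, so the order is
always defined where it is needed; `seq_less()` deliberately refuses
unequal lengths rather than prefix-comparing.

`mcrs()` is computed greedily — reduce the minimum reducible pair, repeat —
which is correct because the first pair of the minimum complete sequence is
always the minimum reducible pair, and reducing an orchard network leaves an
orchard network. On non-orchard input the recursion stalls on a non-trivial
network with no reducible pair; `mcrs()` then returns a typed diagnostic
carrying the partial sequence and the stuck network rather than raising.
The diagnostic is an extension of ours: the canonical sequence itself is
only defined for orchard networks, and non-orchardness is decided solely by
that stall, with no structural shortcuts.

## Generation without networks

`generate_sequences(n, r, mode)` enumerates minimum sequences directly. Three
facts shape the search:

* every minimum sequence over $[n]$ ends in a pair $(m, n)$ with $m < n$, and
  each such pair is itself minimum — these seed the search, and the $m$
  branches partition the output;
* $(i,j)S$ is a minimum augmentation sequence iff $S$ is and $(i,j)$ is the
  minimum reducible pair of the extended network;
* the annotated reducible pairs (ARP) after a prepend follow from the ARP
  before it by constant-size local rules (pairs disjoint from $\{i,j\}$
  survive unchanged, a cherry $(i,y)$ becomes the reticulated cherry
  $(i,y)$, everything else touching $\{i,j\}$ dies, $(i,j)$ enters as `C`
  or `R` according to whether $i$ is new), so the minimality test costs a
  scan of a set of at most $\tfrac{2}{3}|X|$ stored pairs and the network
  is never materialized.

Candidate prepends are pruned before the ARP test: a pair with $i$ already
in the support spends one unit of the reticulation budget, a new $i$ spends
one leaf and must have $i < j$ (otherwise the mirrored cherry $(j,i)$ is
smaller and minimality is impossible). In exact mode a sequence is emitted
when the support reaches $[n]$ with exactly $r$ reticulations, a state with
no legal extensions since both budgets are spent; in at-most mode emission
happens whenever the support is full and the search continues through the
remaining reticulation budget.

For tree-child and stack-free generation the search also maintains the state
$\sigma(i) \in \{\mathsf{N},\mathsf{P},\mathsf{S},\mathsf{T}\}$ of every
taxon (absent; parent a reticulation; sibling a reticulation; otherwise).
An augmentation $(i,j)$ preserves tree-child iff $\sigma(i) \in
\{\mathsf{N},\mathsf{T}\}$ and stack-free iff $\sigma(i) \neq \mathsf{P}$,
and $\sigma$ itself updates by local rules that read the cherries of $i$
from the ARP. A leaf hanging directly from the root has no sibling; the
state definition falls through to $\mathsf{T}$, which only arises for the
trivial network and is implemented as such.

The DFS stores the ARP (and $\sigma$) per depth and restores them by
backtracking — never by inverting updates, which would be error-prone for no
measurable gain at these sizes. Cherries are stored once, smaller taxon
first, which keeps the stored minimum equal to the true minimum reducible
pair; the full both-orientations ARP exists at the semantic layer
(`annotated_reducible_pairs()`, `arp_after_prepend(..., orientation =
"full")`), and the generator's reduced variant is tested against it. The
output order — final pair $(m,n)$ with $m$ ascending, candidates ascending
in the pair order — is a package choice made for reproducible diffs; no
particular order is canonical.

## Random sampling

`random_sequence()` runs the same search with the candidate order shuffled
at each depth and returns the first complete sequence, backtracking over
dead ends (minimum sequences do run into states with no minimum extension,
so backtracking is required for correctness, not only for speed). Identical
seeds give identical draws; the RNG state is restored afterwards. The
sampler is **not uniform** over networks — already the final pair $(m,n)$
is drawn uniformly over $m$ while the class sizes per $m$ differ — and is
offered as a cheap source of valid class members, not as a null model.
When no network matches (tree-child with $r \ge n$), exhaustive failure
raises a typed error.

## What the tests establish, and on what

All fixtures are generated in code; there are no data files. The brute-force
oracle re-derives everything from built networks and greedy reduction —
exhaustively enumerating *all* augmentation sequences under the budget rules
only, building each network, filtering with the direct class predicates, and
counting isomorphism classes two independent ways (canonical-sequence keys
and backtracking isomorphism). It shares no logic with the incremental
ARP/state bookkeeping, so an error there cannot hide; it is guarded to
$n \le 3, r \le 2$ and $n = 4, r \le 1$, where exhaustion is affordable.

Problem sizes used by the test suite, chosen to exercise every code path at
desk scale: census cells up to $(n,r) = (6,1), (5,2), (4,3)$ are counted
exactly; incremental-vs-direct agreement of ARP and $\sigma$ is checked on
every suffix of every generated sequence for $n \le 4, r \le 2$ in all three
modes; pairwise non-isomorphism is certified exhaustively on cells with at
most 250 networks and via canonical-sequence distinctness on the rest; the
ARP-size bound and count identities are asserted per network up to
$n \le 4, r \le 2$ plus $n = 5, r \le 1$, and the length identity
$k = |X| + r - 1$ on all outputs up to $n = 5, r \le 2$.

Passing these tests shows the combinatorics is right; it says nothing about
how well any generated ensemble resembles empirical reticulate evolution.
The generator enumerates topologies uniformly *as a census* (each class
member exactly once), has no branch lengths, no non-binary nodes, and its
random mode is explicitly non-uniform.

## Numerical and design choices

* Taxa are 1-based positive integers; intermediate networks live on subsets
  of $[n]$. Internal node identifiers are arbitrary, excluded from equality,
  and never reused meaningfully; every structural function is invariant
  under relabeling them.
* The tree-child predicate reads "has a child that is a tree node" as "has a
  child that is not a reticulation", so leaves qualify — the variant under
  which the state-machine characterization is internally consistent.
* Counts are returned as doubles (they exceed integer range quickly);
  exactness is preserved far beyond the sizes the package targets.
* eNewick output is canonical: children are ordered by a structural sort key
  and hybrid numbers assigned in first-encounter order of that traversal,
  so isomorphic inputs serialize identically. Parsing is delegated to ape
  (`read.evonet` / `read.tree`), with the trivial network handled directly
  since a one-leaf tree has no ape representation.
* Backtracking isomorphism (`is_isomorphic()`) branches only at
  reticulations ($\le 2^r$ assignments) and is intended as a desk-scale test
  oracle; the canonical sequence is the production identity test.

## Limitations

Semi-binary and non-binary networks, normal networks, and uniform sampling
over classes are out of scope. The generator is correct, not tuned, beyond
desk scale: census cells far past those in the test suite are better served
by the same algorithm in a compiled language. The at-most-$r$ tree-child
run with $r = n - 1$ generates the entire tree-child class for $n$ taxa,
which grows super-exponentially; callers should budget accordingly.
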