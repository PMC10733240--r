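# orchardgen

Exhaustive, injective generation and counting of **orchard**, **tree-child**
and **stack-free** binary phylogenetic networks with a prescribed number of
leaves and reticulations, in R.

## The problem

Rooted binary phylogenetic networks extend phylogenetic trees with
*reticulations* (indegree-2 nodes) that model hybridization, recombination
and lateral gene transfer. Orchard networks are the networks that can be
dismantled leaf by leaf: repeatedly pick a *cherry* (i, j) (two leaves with a
common parent) or a *reticulated cherry* (i, j) (leaf i under a reticulation
whose other parent is the parent of leaf j) and reduce it, until a single
leaf remains. Tree-child networks (every non-leaf node has a non-reticulate
child) and stack-free networks (no reticulation feeds another reticulation)
are well-studied subclasses. Generating all such networks with given `n`
leaves and `r` reticulations — each network exactly once — is the basic
infrastructure for simulation studies, method benchmarking and census
counting in reticulate phylogenetics.

## The method

Recording the reduced pairs gives a *complete reducible-pairs sequence* of
the network; read right-to-left it rebuilds the network by augmentations, so
orchard networks are exactly the networks encoded by such cherry-picking
sequences. Among all complete sequences of a network there is a unique
lexicographic minimum, the **MCRS** (minimum complete reducible-pairs
sequence), of length `n + r − 1`; it is a canonical form, in bijection with
the isomorphism classes of orchard networks on `{1, …, n}` with `r`
reticulations. The generator performs a depth-first search over minimum
sequences directly: every minimum sequence ends in a pair `(m, n)`, and a
prepend `(i, j)S` of a minimum sequence `S` is minimum iff `(i, j)` is the
minimum reducible pair of the extended network — a test carried out on an
incrementally updated set of annotated reducible pairs (ARP), so the
networks themselves are never constructed. Tree-child and stack-free
generation add a per-taxon state vector (`N`/`P`/`S`/`T`: absent, parent
reticulate, sibling reticulate, otherwise) that is maintained by the same
constant-size local rules and gates the allowed prepends (`σ(i) ∈ {N, T}`
for tree-child, `σ(i) ≠ P` for stack-free).

## Worked example

```r
library(orchardgen)

S <- parse_sequence("(3,1)(3,2)(1,2)(3,4)(2,4)")
N <- build_network(S)
N
#> Rooted binary phylogenetic network: 4 leaves, 2 reticulations, 12 nodes, 13 arcs
#> Taxa: 1 2 3 4

format_sequence(mcrs(N))          # canonical form recovered by reduction
#> [1] "(3,1)(3,2)(1,2)(3,4)(2,4)"
annotated_reducible_pairs(N)      # the only reducible pair is (3,1), a reticulated cherry
#>   i j chi
#> 1 3 1   R
is_tree_child(N); is_stack_free(N)
#> [1] FALSE
#> [1] FALSE
write_enewick(N)
#> [1] "((((3)#H2)#H1,4),((#H1,2),(#H2,1)));"

count_networks(3, 1)              # orchard networks with 3 leaves, 1 reticulation
#> [1] 21
count_table(4, 2)                 # rows r = 0..2, columns n = 2..4
#>    n
#> r   2   3    4
#>   0 1   3   15
#>   1 2  21  228
#>   2 4 132 2832
#> attr(,"mode")
#> [1] "orchard"
format_sequence(random_sequence(4, 2, "tree_child", seed = 7))
#> [1] "(1,2)(1,3)(3,2)(3,4)(2,4)"
```

The sequence strings are canonical: two networks are isomorphic exactly when
their `mcrs()` strings coincide, so `generate_sequences(n, r, mode)` yields
every network of the class exactly once.

A command-line interface with the same functionality (`gen`, `count`,
`table`, `build`, `mcrs`, `classify`, `random`, `selfcheck`) is installed as
`exec/orchardgen`; run it with `--help` for usage.

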