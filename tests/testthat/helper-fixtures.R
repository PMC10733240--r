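# Shared fixtures, built in code.

# the worked reticulated example: orchard, 4 leaves, 2 reticulations,
# canonical sequence equal to fig1_text, not tree-child, not stack-free
fig1_text <- "(3,1)(3,2)(1,2)(3,4)(2,4)"
fig1_alt_text <- "(3,1)(3,4)(2,3)(1,3)(3,4)"  # a second complete sequence
fig1_network <- function() build_network(parse_sequence(fig1_text))

cherry_net <- function(i, j) build_network(pair_sequence(c(i, j)))

# Smallest-style non-orchard network: two tree nodes jointly feeding two
# reticulations (a "crown"), no cherry and no reticulated cherry anywhere.
# 2 leaves, 2 reticulations; stack-free but not orchard.
non_orchard_network <- function() {
  #       root -> v;  v -> t1, t2;  t1 -> r1, r2;  t2 -> r1, r2
  #       r1 -> leaf 1;  r2 -> leaf 2
  phylo_network(
    nodes = 1:8,
    arcs = rbind(c(1, 2), c(2, 3), c(2, 4),
                 c(3, 5), c(3, 6), c(4, 5), c(4, 6),
                 c(5, 7), c(6, 8)),
    leaf_nodes = c(7, 8), leaf_taxa = c(1, 2)
  )
}

# permute internal node identifiers, keeping structure and leaf labels
relabel_nodes <- function(N, seed = 1) {
  set.seed(seed)
  new_ids <- sample(1000L + seq_along(N$nodes))
  f <- function(v) new_ids[match(v, N$nodes)]
  phylo_network(f(N$nodes), cbind(f(N$arcs[, 1]), f(N$arcs[, 2])),
                f(N$leaf_nodes), N$leaf_taxa)
}

empty_arp <- function() {
  data.frame(i = integer(0), j = integer(0), chi = character(0),
             stringsAsFactors = FALSE)
}

seq_strings <- function(seqs) vapply(seqs, format_sequence, character(1))
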