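# Augmentation: the constructive inverse of reduction.
#
# Prepending a pair (i, j) to a sequence corresponds to augmenting the
# network the sequence generates: if i is a new taxon, a cherry (i, j) is
# created by subdividing the arc into j; if i is already a leaf, the arcs
# into i and j are subdivided and joined, turning i's new parent into a
# reticulation (a reticulated cherry (i, j)).  The key point for
# generation is that the set of annotated reducible pairs (ARP) and the
# tree-child state vector of the augmented network are computable from
# those of the original network by constant-size local rules, so the
# generator never materializes networks.

#' Augment a network by a pair
#'
#' @param N A valid `orchard_network`.
#' @param p Length-2 integer vector `(i, j)`; `j` must be a leaf of `N`
#'   and `i != j`.
#' @return The augmented `orchard_network`; reducing it by `p` recovers a
#'   network isomorphic to `N`.
#' @examples
#' augment_pair(make_trivial(4), c(2, 4))  # cherry on {2, 4}
#' @export
augment_pair <- function(N, p) {
  stop_if_invalid(N)
  augment_pair_unchecked(N, p)
}

augment_pair_unchecked <- function(N, p) {
  i <- as.integer(p[1L]); j <- as.integer(p[2L])
  if (i == j) stop("a pair (i, j) must have i != j")
  vj <- leaf_node_of(N, j)
  if (is.na(vj)) stop("taxon ", j, " is not a leaf of the network")
  vi <- leaf_node_of(N, i)
  arcs <- N$arcs
  aj <- which(arcs[, 2L] == vj)  # the arc into j
  if (is.na(vi)) {
    # new cherry (i, j): subdivide the arc into j, hang the new leaf i
    ids <- new_node_id(N, 2L)
    pj <- ids[1L]; leaf_i <- ids[2L]
    tail_j <- arcs[aj, 1L]
    arcs <- rbind(arcs[-aj, , drop = FALSE],
                  c(tail_j, pj), c(pj, vj), c(pj, leaf_i))
    phylo_network(c(N$nodes, ids), arcs,
                  c(N$leaf_nodes, leaf_i), c(N$leaf_taxa, i))
  } else {
    # new reticulated cherry (i, j): subdivide both pendant arcs, join them
    ids <- new_node_id(N, 2L)
    pi_ <- ids[1L]; pj <- ids[2L]
    ai <- which(arcs[, 2L] == vi)
    tail_i <- arcs[ai, 1L]; tail_j <- arcs[aj, 1L]
    arcs <- rbind(arcs[-c(ai, aj), , drop = FALSE],
                  c(tail_i, pi_), c(pi_, vi),
                  c(tail_j, pj), c(pj, vj),
                  c(pj, pi_))
    phylo_network(c(N$nodes, ids), arcs, N$leaf_nodes, N$leaf_taxa)
  }
}

#' Build the network generated by an augmentation sequence
#'
#' Starts from the trivial network on the second coordinate of the last
#' pair and applies [augment_pair()] right-to-left.  The result has leaf
#' set `support(S)` and `seq_reticulations(S)` reticulations, and `S` is a
#' complete reducible-pairs sequence for it.
#'
#' @param S A `pair_sequence` that is an augmentation sequence.  The empty
#'   sequence is not accepted (it leaves the base taxon undetermined); use
#'   [make_trivial()] for trivial networks.
#' @return A valid `orchard_network`.
#' @examples
#' build_network(parse_sequence("(3,1)(3,2)(1,2)(3,4)(2,4)"))
#' @export
build_network <- function(S) {
  m <- as_pair_matrix(S)
  if (nrow(m) == 0L) {
    stop("the empty sequence does not determine its base taxon; use make_trivial()")
  }
  if (!is_augmentation_sequence(S)) {
    stop("not an augmentation sequence: some j_t is absent from the following suffix")
  }
  N <- make_trivial(m[nrow(m), 2L])
  for (t in rev(seq_len(nrow(m)))) {
    N <- augment_pair_unchecked(N, m[t, ])
  }
  N
}

arp_df <- function(i, j, chi) {
  o <- order(i, j)
  data.frame(i = as.integer(i)[o], j = as.integer(j)[o], chi = chi[o],
             stringsAsFactors = FALSE)
}

#' Incremental ARP update under augmentation
#'
#' Computes the annotated reducible pairs of the augmented network from
#' those of the original network, without touching the network.  The local
#' rules are: pairs disjoint from `{i, j}` survive unchanged; a cherry
#' `(i, y)` with `y != j` becomes the reticulated cherry `(i, y)`; every
#' other pair meeting `{i, j}` disappears; the new pair `(i, j)` appears
#' with character `"C"` if `i` is new (plus the mirrored cherry `(j, i)`)
#' and `"R"` otherwise.
#'
#' With `orientation = "full"` the input and output carry both
#' orientations of each cherry (the semantic ARP); with `"reduced"`
#' cherries are stored once with `i < j` (the generator's working
#' representation, in which the first row is still always the minimum
#' reducible pair of the full set).
#'
#' @param arp Data frame with columns `i`, `j`, `chi`, sorted, as returned
#'   by [annotated_reducible_pairs()] (or a previous call).
#' @param X Integer vector: the taxa of the network `arp` belongs to.
#' @param p Length-2 vector `(i, j)` with `j` in `X`, `i != j`.
#' @param orientation `"full"` or `"reduced"`.
#' @return The updated ARP data frame, sorted ascending.
#' @export
arp_after_prepend <- function(arp, X, p, orientation = c("full", "reduced")) {
  orientation <- match.arg(orientation)
  i <- as.integer(p[1L]); j <- as.integer(p[2L])
  if (i == j) stop("a pair (i, j) must have i != j")
  if (!(j %in% X)) stop("j must be a taxon of the network")
  in_X <- i %in% X
  ri <- integer(0); rj <- integer(0); rc <- character(0)
  add <- function(a, b, ch) {
    ri <<- c(ri, a); rj <<- c(rj, b); rc <<- c(rc, ch)
  }
  for (t in seq_len(nrow(arp))) {
    x <- arp$i[t]; y <- arp$j[t]; ch <- arp$chi[t]
    touches_i <- (x == i || y == i)
    touches_j <- (x == j || y == j)
    if (!touches_i && !touches_j) {
      add(x, y, ch)                      # disjoint: unchanged
    } else if (touches_i && !touches_j && ch == "C") {
      if (orientation == "full") {
        # only the (i, y) orientation survives, as a reticulated cherry
        if (x == i) add(i, y, "R")
      } else {
        add(i, x + y - i, "R")           # stored once; reorient onto i
      }
    }
    # every other pair meeting {i, j} disappears
  }
  add(i, j, if (in_X) "R" else "C")
  if (!in_X && orientation == "full") add(j, i, "C")
  if (!in_X && orientation == "reduced" && i > j) {
    # reduced storage keeps cherries with smaller taxon first
    ri[length(ri)] <- j; rj[length(rj)] <- i
  }
  arp_df(ri, rj, rc)
}

#' Incremental tree-child state update under augmentation
#'
#' Computes the state vector of the augmented network from the state
#' vector and ARP of the original network.  If the state of `i` is `"N"`
#' (new taxon), the augmentation creates a cherry and both `i` and `j` get
#' state `"T"`.  Otherwise (`"T"`, or `"S"` in stack-free generation) a
#' reticulated cherry is created: `i` gets `"P"`, `j` gets `"S"`, and
#' every leaf that formed a cherry with `i` gets `"S"` (its sibling became
#' a reticulation).  A state of `"P"` for `i` is rejected: the
#' augmentation would stack two reticulations, leaving both the tree-child
#' and the stack-free class.
#'
#' @param sigma Character vector of states over `[n]` (see
#'   [sigma_states()]).
#' @param arp ARP data frame of the network (either orientation).
#' @param p Length-2 vector `(i, j)`.
#' @return The updated state vector.
#' @export
state_after_prepend <- function(sigma, arp, p) {
  i <- as.integer(p[1L]); j <- as.integer(p[2L])
  if (i == j) stop("a pair (i, j) must have i != j")
  if (sigma[j] == "N") stop("j must be a taxon of the network")
  if (sigma[i] == "P") {
    stop("state of i is P: the augmentation stacks reticulations and leaves the class")
  }
  out <- sigma
  if (sigma[i] == "N") {
    out[i] <- "T"; out[j] <- "T"
  } else {
    cherry_mates <- unique(c(arp$j[arp$chi == "C" & arp$i == i],
                             arp$i[arp$chi == "C" & arp$j == i]))
    out[cherry_mates] <- "S"
    out[i] <- "P"; out[j] <- "S"
  }
  out
}

#' Minimality test for a prepended pair
#'
#' A prepend `(i, j)` extends a minimum augmentation sequence to a
#' minimum augmentation sequence exactly when `(i, j)` is the minimum
#' reducible pair of the extended network, i.e. the minimum of the ARP
#' after the prepend.
#'
#' @param arp_after ARP data frame after the prepend, sorted (reduced
#'   orientation suffices: the stored first row is the global minimum).
#' @param p Length-2 vector `(i, j)`.
#' @return `TRUE` iff `p` is the minimum of `arp_after`.
#' @export
is_minimum_prepend <- function(arp_after, p) {
  if (nrow(arp_after) == 0L) stop("arp_after cannot be empty: it contains p itself")
  arp_after$i[1L] == as.integer(p[1L]) && arp_after$j[1L] == as.integer(p[2L])
}
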