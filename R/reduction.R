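# Reducible pairs, reductions, recognition and the canonical sequence.
#
# A pair of distinct leaves (i, j) is reducible when it is a cherry
# (shared parent; character C) or a reticulated cherry (the parent of i is
# a reticulation one of whose parents is the tree-node parent of j;
# character R).  Reducing a cherry removes leaf i; reducing a reticulated
# cherry removes the arc between the two parents.  Orchard networks are
# exactly those reduced to a trivial network by some sequence of such
# reductions, and the lexicographically minimum complete sequence (MCRS)
# is a canonical form: it determines the network up to isomorphism.

children_list <- function(N) {
  lapply(seq_along(N$nodes),
         function(v) N$arcs[N$arcs[, 1L] == N$nodes[v], 2L])
}

#' Annotated reducible pairs of a network
#'
#' All reducible pairs of distinct leaves, annotated with their character:
#' `"C"` for a cherry, `"R"` for a reticulated cherry.  Both orientations
#' of a cherry are reported, since both are reducible; the generator's
#' reduced (i < j) storage is a separate optimization.
#'
#' @param N A valid `orchard_network`.
#' @return A data frame with integer columns `i`, `j` and character column
#'   `chi`, sorted ascending in the pair order.
#' @export
annotated_reducible_pairs <- function(N) {
  stop_if_invalid(N)
  arp_of_network(N)
}

# same, without re-validating (internal hot path)
arp_of_network <- function(N) {
  nt <- length(N$leaf_nodes)
  d <- net_degrees(N)
  parent_of <- function(v) N$arcs[N$arcs[, 2L] == v, 1L]
  res_i <- integer(0); res_j <- integer(0); res_chi <- character(0)
  if (nt >= 2L) {
    par <- vapply(N$leaf_nodes, parent_of, integer(1L))
    kind <- vapply(match(par, N$nodes), function(p)
      kind_from_degrees(d$indeg[p], d$outdeg[p]), character(1L))
    arc_key <- paste(N$arcs[, 1L], N$arcs[, 2L])
    for (a in seq_len(nt)) {
      for (b in seq_len(nt)) {
        if (a == b) next
        i <- N$leaf_taxa[a]; j <- N$leaf_taxa[b]
        if (par[a] == par[b]) {
          res_i <- c(res_i, i); res_j <- c(res_j, j); res_chi <- c(res_chi, "C")
        } else if (kind[a] == "reticulation" && kind[b] == "tree" &&
                   (paste(par[b], par[a]) %in% arc_key)) {
          res_i <- c(res_i, i); res_j <- c(res_j, j); res_chi <- c(res_chi, "R")
        }
      }
    }
  }
  o <- order(res_i, res_j)
  data.frame(i = res_i[o], j = res_j[o], chi = res_chi[o],
             stringsAsFactors = FALSE)
}

# remove an elementary node (indeg 1, outdeg 1), reconnecting parent to child
suppress_node <- function(N, v) {
  pa <- N$arcs[N$arcs[, 2L] == v, 1L]
  ch <- N$arcs[N$arcs[, 1L] == v, 2L]
  stopifnot(length(pa) == 1L, length(ch) == 1L)
  keep <- N$arcs[, 1L] != v & N$arcs[, 2L] != v
  arcs <- rbind(N$arcs[keep, , drop = FALSE], c(pa, ch))
  phylo_network(setdiff(N$nodes, v), arcs, N$leaf_nodes, N$leaf_taxa)
}

#' Reduce a reducible pair
#'
#' Applies the cherry or reticulated-cherry reduction of `(i, j)`.  For a
#' cherry, leaf `i` and its arc are removed and the now-elementary common
#' parent is suppressed (the leaf set shrinks by `i`).  For a reticulated
#' cherry, the arc from `j`'s parent to `i`'s parent is removed and both
#' now-elementary parents are suppressed (the leaf set is unchanged).
#'
#' @param N A valid `orchard_network`.
#' @param p Length-2 integer vector `(i, j)` of taxa.
#' @return The reduced `orchard_network`.
#' @export
reduce_pair <- function(N, p) {
  stop_if_invalid(N)
  reduce_pair_unchecked(N, p)
}

reduce_pair_unchecked <- function(N, p) {
  i <- as.integer(p[1L]); j <- as.integer(p[2L])
  vi <- leaf_node_of(N, i); vj <- leaf_node_of(N, j)
  if (is.na(vi) || is.na(vj) || i == j) {
    stop(sprintf("(%d, %d) is not a pair of distinct leaves of the network", i, j))
  }
  pi_ <- N$arcs[N$arcs[, 2L] == vi, 1L]
  pj_ <- N$arcs[N$arcs[, 2L] == vj, 1L]
  if (pi_ == pj_) {
    # cherry: drop leaf i and its arc, suppress the common parent
    keep <- !(N$arcs[, 1L] == pi_ & N$arcs[, 2L] == vi)
    M <- phylo_network(setdiff(N$nodes, vi), N$arcs[keep, , drop = FALSE],
                       N$leaf_nodes[N$leaf_taxa != i],
                       N$leaf_taxa[N$leaf_taxa != i])
    suppress_node(M, pi_)
  } else {
    d <- net_degrees(N)
    ki <- kind_from_degrees(d$indeg[match(pi_, N$nodes)], d$outdeg[match(pi_, N$nodes)])
    kj <- kind_from_degrees(d$indeg[match(pj_, N$nodes)], d$outdeg[match(pj_, N$nodes)])
    has_arc <- any(N$arcs[, 1L] == pj_ & N$arcs[, 2L] == pi_)
    if (!(identical(ki, "reticulation") && identical(kj, "tree") && has_arc)) {
      stop(sprintf("(%d, %d) is neither a cherry nor a reticulated cherry", i, j))
    }
    keep <- !(N$arcs[, 1L] == pj_ & N$arcs[, 2L] == pi_)
    M <- phylo_network(N$nodes, N$arcs[keep, , drop = FALSE],
                       N$leaf_nodes, N$leaf_taxa)
    M <- suppress_node(M, pi_)
    suppress_node(M, pj_)
  }
}

not_orchard <- function(partial, stuck) {
  structure(list(partial = partial, stuck = stuck),
            class = "orchardgen_not_orchard")
}

#' @export
print.orchardgen_not_orchard <- function(x, ...) {
  cat("Not an orchard network: no reducible pair after partial sequence",
      if (length(x$partial) == 0L) "<empty>" else format_sequence(x$partial), "\n")
  invisible(x)
}

#' Is an object the not-orchard diagnostic?
#' @param x Any object.
#' @return `TRUE` for the typed failure returned by [mcrs()] on
#'   non-orchard input.
#' @export
is_not_orchard <- function(x) inherits(x, "orchardgen_not_orchard")

#' Minimum complete reducible-pairs sequence (canonical form)
#'
#' Greedy canonicalization: while the network is non-trivial, reduce by
#' the minimum reducible pair and record it.  For orchard networks this
#' yields the unique lexicographically minimum complete sequence (the
#' first pair of the minimum complete sequence is always the minimum
#' reducible pair, and reducing an orchard network leaves an orchard
#' network, so the greedy choice is globally optimal).  The sequence is a
#' canonical form: two networks are isomorphic iff their MCRS coincide.
#'
#' @param N A valid `orchard_network`.
#' @return A `pair_sequence` (empty for a trivial network), or a typed
#'   diagnostic of class `orchardgen_not_orchard` carrying the partial
#'   sequence and the stuck network when `N` is not orchard.
#' @examples
#' mcrs(build_network(parse_sequence("(3,1)(3,2)(1,2)(3,4)(2,4)")))
#' @export
mcrs <- function(N) {
  stop_if_invalid(N)
  out <- matrix(integer(0), 0L, 2L)
  M <- N
  while (length(M$leaf_nodes) > 1L || nrow(M$arcs) > 1L) {
    arp <- arp_of_network(M)
    if (nrow(arp) == 0L) {
      return(not_orchard(pair_sequence(out), M))
    }
    p <- c(arp$i[1L], arp$j[1L])  # minimum reducible pair (sorted output)
    out <- rbind(out, p)
    M <- reduce_pair_unchecked(M, p)
  }
  pair_sequence(out)
}

#' Orchard recognition
#'
#' @param N A valid `orchard_network`.
#' @return `TRUE` iff some (equivalently, the greedy minimum) sequence of
#'   reductions takes `N` to a trivial network.  Trivial networks are
#'   orchard.
#' @export
is_orchard <- function(N) {
  !is_not_orchard(mcrs(N))
}

#' Tree-child recognition
#'
#' A network is tree-child when every non-leaf node has at least one child
#' that is not a reticulation (leaves qualify as such children).
#' Tree-child networks are orchard and have at most `n - 1` reticulations.
#'
#' @param N A valid `orchard_network`.
#' @return `TRUE` or `FALSE`.
#' @export
is_tree_child <- function(N) {
  stop_if_invalid(N)
  d <- net_degrees(N)
  retic <- N$nodes[d$indeg == 2L & d$outdeg == 1L]
  ch <- children_list(N)
  for (v in seq_along(N$nodes)) {
    if (d$outdeg[v] == 0L) next  # leaf
    if (all(ch[[v]] %in% retic)) return(FALSE)
  }
  TRUE
}

#' Stack-free recognition
#'
#' A network is stack-free when no reticulation has a reticulation as its
#' (unique) child.  Tree-child implies stack-free.
#'
#' @param N A valid `orchard_network`.
#' @return `TRUE` or `FALSE`.
#' @export
is_stack_free <- function(N) {
  stop_if_invalid(N)
  d <- net_degrees(N)
  retic <- N$nodes[d$indeg == 2L & d$outdeg == 1L]
  for (v in retic) {
    child <- N$arcs[N$arcs[, 1L] == v, 2L]
    if (child %in% retic) return(FALSE)
  }
  TRUE
}

#' Tree-child state of each taxon
#'
#' For a network over a subset of `[n]`, the state of taxon `i` is
#' `"N"` if `i` is absent from the network, `"P"` if the parent of leaf
#' `i` is a reticulation, `"S"` if its sibling is a reticulation, and
#' `"T"` otherwise.  A leaf hanging from the root has no sibling and gets
#' state `"T"` (this only arises for the trivial network).  The state
#' gates which augmentations preserve the tree-child (state of `i` in
#' `{N, T}`) and stack-free (state of `i` not `P`) properties.
#'
#' @param N A valid `orchard_network` over a subset of `[n]`.
#' @param n Upper bound of the taxon range.
#' @return Character vector of length `n`, entry `i` being the state of
#'   taxon `i`.
#' @export
sigma_states <- function(N, n) {
  stop_if_invalid(N)
  n <- as.integer(n)
  d <- net_degrees(N)
  retic <- N$nodes[d$indeg == 2L & d$outdeg == 1L]
  out <- rep("N", n)
  for (t in seq_along(N$leaf_taxa)) {
    taxon <- N$leaf_taxa[t]
    if (taxon > n) stop("taxon ", taxon, " outside [n]")
    v <- N$leaf_nodes[t]
    p <- N$arcs[N$arcs[, 2L] == v, 1L]
    if (p %in% retic) {
      out[taxon] <- "P"
    } else {
      sib <- setdiff(N$arcs[N$arcs[, 1L] == p, 2L], v)
      out[taxon] <- if (length(sib) == 1L && sib %in% retic) "S" else "T"
    }
  }
  out
}
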