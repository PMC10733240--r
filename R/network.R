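# Data model for rooted binary phylogenetic networks.
#
# A network is a rooted, binary, leaf-labeled DAG without parallel arcs in
# which every node is one of: the root (indeg 0, outdeg 1), a leaf (1, 0),
# a tree node (1, 2) or a reticulation (2, 1).  Leaves carry pairwise
# distinct positive integer taxa; internal node identifiers are arbitrary
# and carry no meaning (two networks are equal when they are isomorphic by
# a bijection that is the identity on taxa).

#' Construct a phylogenetic network object
#'
#' Low-level constructor.  No validity checks are performed so that invalid
#' graphs can be built and inspected with [validate_network()]; all
#' higher-level operations assume a valid network.
#'
#' @param nodes Integer vector of node identifiers (arbitrary, distinct).
#' @param arcs Two-column integer matrix of arcs, one row per arc
#'   `(tail, head)`.
#' @param leaf_nodes Integer vector of node identifiers that are leaves.
#' @param leaf_taxa Integer vector of taxa (positive integers), parallel to
#'   `leaf_nodes`.
#' @return An object of class `orchard_network`.
#' @seealso [make_trivial()], [build_network()], [validate_network()]
#' @export
phylo_network <- function(nodes, arcs, leaf_nodes, leaf_taxa) {
  arcs <- matrix(as.integer(arcs), ncol = 2L)
  structure(
    list(
      nodes = as.integer(nodes),
      arcs = arcs,
      leaf_nodes = as.integer(leaf_nodes),
      leaf_taxa = as.integer(leaf_taxa)
    ),
    class = "orchard_network"
  )
}

#' Trivial network on a single taxon
#'
#' The two-node network root -> leaf, with the leaf labeled `l`.  Trivial
#' networks are the terminal objects of the reduction process: a network is
#' orchard exactly when some sequence of cherry / reticulated-cherry
#' reductions takes it to a trivial network.
#'
#' @param l Positive integer taxon.
#' @return An `orchard_network` with two nodes and one arc.
#' @examples
#' make_trivial(4)
#' @export
make_trivial <- function(l) {
  l <- as.integer(l)
  if (length(l) != 1L || is.na(l) || l < 1L) {
    stop("taxon must be a single positive integer")
  }
  phylo_network(nodes = c(1L, 2L), arcs = c(1L, 2L),
                leaf_nodes = 2L, leaf_taxa = l)
}

# in/out degree of every node, in the order of N$nodes
net_degrees <- function(N) {
  tails <- match(N$arcs[, 1L], N$nodes)
  heads <- match(N$arcs[, 2L], N$nodes)
  list(
    indeg = tabulate(heads, nbins = length(N$nodes)),
    outdeg = tabulate(tails, nbins = length(N$nodes))
  )
}

kind_from_degrees <- function(indeg, outdeg) {
  if (indeg == 0L && outdeg == 1L) return("root")
  if (indeg == 1L && outdeg == 0L) return("leaf")
  if (indeg == 1L && outdeg == 2L) return("tree")
  if (indeg == 2L && outdeg == 1L) return("reticulation")
  NA_character_
}

#' Kind of a node
#'
#' Classifies a node of a network as `"root"`, `"leaf"`, `"tree"` or
#' `"reticulation"` purely from its in/out degrees.  The kind is always
#' recomputed, never cached, since reductions and augmentations change
#' degrees.
#'
#' @param N An `orchard_network`.
#' @param v A node identifier of `N`.
#' @return One of `"root"`, `"leaf"`, `"tree"`, `"reticulation"`.
#' @export
node_kind <- function(N, v) {
  pos <- match(as.integer(v), N$nodes)
  if (is.na(pos)) stop("node ", v, " is not a node of the network")
  d <- net_degrees(N)
  k <- kind_from_degrees(d$indeg[pos], d$outdeg[pos])
  if (is.na(k)) {
    stop("node ", v, " has degrees (", d$indeg[pos], ", ", d$outdeg[pos],
         ") matching no node kind; the network is not valid")
  }
  k
}

#' Validate a network
#'
#' Checks every structural invariant of a rooted binary phylogenetic
#' network and returns the violations as a character vector (empty iff the
#' network is valid).  Violations are returned, not raised, so that
#' counterexamples can be inspected.
#'
#' @param N An `orchard_network`.
#' @return Character vector of human-readable violations; `character(0)`
#'   for a valid network.
#' @examples
#' validate_network(make_trivial(2))
#' @export
validate_network <- function(N) {
  bad <- character(0)
  if (!inherits(N, "orchard_network")) {
    return("not an orchard_network object")
  }
  if (anyDuplicated(N$nodes)) bad <- c(bad, "duplicated node identifiers")
  if (nrow(N$arcs) > 0 && !all(c(N$arcs) %in% N$nodes)) {
    bad <- c(bad, "arc endpoint is not a declared node")
    return(bad)
  }
  if (anyDuplicated(N$arcs)) bad <- c(bad, "parallel arcs present")
  if (any(N$arcs[, 1L] == N$arcs[, 2L])) bad <- c(bad, "self-loop present")

  # acyclicity by Kahn's algorithm
  d <- net_degrees(N)
  indeg <- d$indeg
  heads <- match(N$arcs[, 2L], N$nodes)
  tails <- match(N$arcs[, 1L], N$nodes)
  active <- rep(TRUE, length(N$nodes))
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    active[v] <- FALSE
    seen <- seen + 1L
    for (a in which(tails == v)) {
      h <- heads[a]
      indeg[h] <- indeg[h] - 1L
      if (indeg[h] == 0L) queue <- c(queue, h)
    }
  }
  if (seen < length(N$nodes)) bad <- c(bad, "graph contains a directed cycle")

  roots <- N$nodes[d$indeg == 0L]
  if (length(roots) != 1L) {
    bad <- c(bad, sprintf("network must have exactly one root (found %d)",
                          length(roots)))
  } else if (d$outdeg[match(roots, N$nodes)] != 1L) {
    bad <- c(bad, "root must have outdegree 1")
  }

  for (pos in seq_along(N$nodes)) {
    if (is.na(kind_from_degrees(d$indeg[pos], d$outdeg[pos]))) {
      bad <- c(bad, sprintf(
        "node %d has degrees (%d, %d): not a root, leaf, tree node or reticulation",
        N$nodes[pos], d$indeg[pos], d$outdeg[pos]))
    }
  }

  leaves <- N$nodes[d$indeg == 1L & d$outdeg == 0L]
  if (!setequal(leaves, N$leaf_nodes)) {
    bad <- c(bad, "labeled leaf set differs from the set of (indeg 1, outdeg 0) nodes")
  }
  if (length(N$leaf_nodes) != length(N$leaf_taxa)) {
    bad <- c(bad, "leaf_nodes and leaf_taxa lengths differ")
  }
  if (anyDuplicated(N$leaf_taxa)) bad <- c(bad, "taxa are not pairwise distinct")
  if (any(is.na(N$leaf_taxa)) || any(N$leaf_taxa < 1L)) {
    bad <- c(bad, "taxa must be positive integers")
  }
  bad
}

stop_if_invalid <- function(N) {
  bad <- validate_network(N)
  if (length(bad)) {
    stop("invalid network: ", paste(bad, collapse = "; "))
  }
  invisible(N)
}

#' Number of reticulations of a network
#'
#' @param N A valid `orchard_network`.
#' @return Integer count of nodes with indegree 2 and outdegree 1.
#' @export
reticulation_count <- function(N) {
  stop_if_invalid(N)
  d <- net_degrees(N)
  sum(d$indeg == 2L & d$outdeg == 1L)
}

#' Taxa of a network
#'
#' @param N An `orchard_network`.
#' @return Sorted integer vector of the taxa labeling the leaves.
#' @export
network_taxa <- function(N) {
  sort(N$leaf_taxa)
}

# node id of the leaf labeled by taxon, or NA
leaf_node_of <- function(N, taxon) {
  pos <- match(as.integer(taxon), N$leaf_taxa)
  if (is.na(pos)) NA_integer_ else N$leaf_nodes[pos]
}

# fresh node identifier
new_node_id <- function(N, k = 1L) {
  max(N$nodes) + seq_len(k)
}

#' @export
print.orchard_network <- function(x, ...) {
  d <- net_degrees(x)
  r <- sum(d$indeg == 2L & d$outdeg == 1L)
  cat(sprintf(
    "Rooted binary phylogenetic network: %d leaves, %d reticulations, %d nodes, %d arcs\n",
    length(x$leaf_nodes), r, length(x$nodes), nrow(x$arcs)))
  cat("Taxa:", paste(sort(x$leaf_taxa), collapse = " "), "\n")
  invisible(x)
}
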