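# Extended Newick (eNewick) serialization.
#
# Dialect: the text is the Newick serialization of the root's unique
# child, terminated by ";".  Each reticulation appears in two tree
# positions sharing a "#Hk" label: expanded (with its child subtree) at
# its first encounter in the canonical traversal and as a bare "#Hk"
# stub afterwards.  Topology only; no branch lengths or support values.
#
# Writing is package-own so that the output is canonical: children are
# ordered by a structural sort key that is invariant under internal node
# relabeling, and hybrid numbers are assigned in first-encounter order of
# that traversal, so isomorphic networks with identically labeled leaves
# serialize identically.  Reading is delegated to ape (read.evonet for
# reticulate inputs, read.tree otherwise), with the trivial one-leaf
# network "l;" handled directly.

#' Write a network as canonical extended Newick
#'
#' @param N A valid `orchard_network`.
#' @return A single character string, e.g. `"3;"` for `make_trivial(3)`
#'   and `"(1,2);"` for the cherry on `{1, 2}`.
#' @export
write_enewick <- function(N) {
  stop_if_invalid(N)
  d <- net_degrees(N)
  ch <- children_list(N)
  idx <- function(v) match(v, N$nodes)
  taxon_of <- function(v) N$leaf_taxa[match(v, N$leaf_nodes)]
  is_retic <- d$indeg == 2L & d$outdeg == 1L

  # structural sort key, independent of node ids and of hybrid numbering
  key_memo <- rep(NA_character_, length(N$nodes))
  key <- function(v) {
    p <- idx(v)
    if (!is.na(key_memo[p])) return(key_memo[p])
    k <- if (d$outdeg[p] == 0L) {
      as.character(taxon_of(v))
    } else if (is_retic[p]) {
      paste0("#(", key(ch[[p]]), ")")
    } else {
      kids <- vapply(ch[[p]], key, character(1L))
      paste0("(", paste(sort(kids, method = "radix"), collapse = ","), ")")
    }
    key_memo[p] <<- k
    k
  }

  hybrid_no <- rep(0L, length(N$nodes))
  next_h <- 0L
  render <- function(v) {
    p <- idx(v)
    if (d$outdeg[p] == 0L) return(as.character(taxon_of(v)))
    if (is_retic[p]) {
      if (hybrid_no[p] == 0L) {
        next_h <<- next_h + 1L
        hybrid_no[p] <<- next_h
        return(paste0("(", render(ch[[p]]), ")#H", hybrid_no[p]))
      }
      return(paste0("#H", hybrid_no[p]))
    }
    kids <- ch[[p]]
    kids <- kids[order(vapply(kids, key, character(1L)), method = "radix")]
    paste0("(", paste(vapply(kids, render, character(1L)), collapse = ","), ")")
  }

  root <- N$nodes[d$indeg == 0L]
  top <- ch[[idx(root)]]
  paste0(render(top), ";")
}

#' Read a network from extended Newick text
#'
#' Inverse of [write_enewick()] up to isomorphism: hybrid nodes are
#' recognized by shared `#Hk` labels.  The parsed top-level subtree is
#' hung under a fresh outdegree-1 root.  The result is not required to be
#' valid (use [validate_network()]); malformed text raises an error.
#'
#' @param text A single eNewick string.
#' @return An `orchard_network`.
#' @export
read_enewick <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop("expected a single character string")
  }
  s <- trimws(text)
  triv <- regmatches(s, regexec("^([0-9]+)[[:space:]]*;$", s))[[1L]]
  if (length(triv)) return(make_trivial(as.integer(triv[2L])))
  tr <- tryCatch(
    if (grepl("#", s, fixed = TRUE)) ape::read.evonet(text = s)
    else ape::read.tree(text = s),
    error = function(e) stop("malformed eNewick text: ", conditionMessage(e)))
  if (is.null(tr) || is.null(tr$edge)) stop("malformed eNewick text")
  arcs <- tr$edge
  if (!is.null(tr$reticulation)) arcs <- rbind(arcs, tr$reticulation)
  ntip <- length(tr$tip.label)
  taxa <- suppressWarnings(as.integer(tr$tip.label))
  if (any(is.na(taxa)) || any(taxa < 1L)) {
    stop("leaf labels must be positive integer taxa")
  }
  nodes <- sort(unique(c(arcs)))
  top <- setdiff(arcs[, 1L], arcs[, 2L])
  if (length(top) != 1L) stop("malformed eNewick text: no unique top node")
  root <- max(nodes) + 1L
  phylo_network(c(nodes, root), rbind(arcs, c(root, top)),
                seq_len(ntip), taxa)
}
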