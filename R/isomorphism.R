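# Isomorphism of leaf-labeled networks by backtracking.
#
# Two networks are isomorphic when an arc-preserving, arc-reflecting node
# bijection exists that is the identity on leaf labels.  Because leaves are
# labeled, the leaf matching is forced; the search propagates the mapping
# upward (child to parent).  Nodes of indegree 1 propagate deterministically;
# each reticulation contributes a binary choice between its two parents, so
# the search branches at most 2^r times.  This is intended as a test oracle
# at desk scale; the production canonical form is the minimum complete
# reducible-pairs sequence (see [mcrs()]).

#' Test whether two networks are isomorphic
#'
#' @param N,M Valid `orchard_network` objects.
#' @return `TRUE` iff there is a node bijection preserving and reflecting
#'   arcs that is the identity on leaf labels.
#' @examples
#' is_isomorphic(make_trivial(1), make_trivial(1))
#' @export
is_isomorphic <- function(N, M) {
  stop_if_invalid(N)
  stop_if_invalid(M)
  if (!setequal(N$leaf_taxa, M$leaf_taxa)) return(FALSE)
  if (length(N$nodes) != length(M$nodes)) return(FALSE)
  if (nrow(N$arcs) != nrow(M$arcs)) return(FALSE)

  vn <- length(N$nodes)
  # reindex both networks to 1..V
  an <- cbind(match(N$arcs[, 1L], N$nodes), match(N$arcs[, 2L], N$nodes))
  am <- cbind(match(M$arcs[, 1L], M$nodes), match(M$arcs[, 2L], M$nodes))
  parN <- lapply(seq_len(vn), function(v) an[an[, 2L] == v, 1L])
  parM <- lapply(seq_len(vn), function(v) am[am[, 2L] == v, 1L])

  map <- integer(vn)        # N index -> M index, 0 = unmapped
  used <- logical(vn)
  queue <- integer(0)
  # forced leaf matching
  for (t in seq_along(N$leaf_taxa)) {
    i <- match(N$leaf_nodes[t], N$nodes)
    j <- match(M$leaf_nodes[match(N$leaf_taxa[t], M$leaf_taxa)], M$nodes)
    map[i] <- j; used[j] <- TRUE; queue <- c(queue, i)
  }

  arcs_match <- function(map) {
    mapped <- cbind(map[an[, 1L]], map[an[, 2L]])
    identical(
      mapped[order(mapped[, 1L], mapped[, 2L]), , drop = FALSE],
      am[order(am[, 1L], am[, 2L]), , drop = FALSE]
    )
  }

  # try to extend map with u -> u2; returns list(map, used, queue) or NULL
  extend <- function(u, u2, st) {
    if (st$map[u] != 0L) {
      if (st$map[u] == u2) st else NULL
    } else if (st$used[u2]) {
      NULL
    } else if (length(parN[[u]]) != length(parM[[u2]])) {
      NULL
    } else {
      st$map[u] <- u2; st$used[u2] <- TRUE; st$queue <- c(st$queue, u)
      st
    }
  }

  search <- function(st) {
    while (length(st$queue)) {
      v <- st$queue[[1L]]; st$queue <- st$queue[-1L]
      p <- parN[[v]]
      q <- parM[[st$map[v]]]
      if (length(p) != length(q)) return(FALSE)
      if (length(p) == 1L) {
        st <- extend(p, q, st)
        if (is.null(st)) return(FALSE)
      } else if (length(p) == 2L) {
        for (perm in list(c(1L, 2L), c(2L, 1L))) {
          st2 <- extend(p[1L], q[perm[1L]], st)
          if (!is.null(st2)) st2 <- extend(p[2L], q[perm[2L]], st2)
          if (!is.null(st2) && search(st2)) return(TRUE)
        }
        return(FALSE)
      }
    }
    all(st$map != 0L) && arcs_match(st$map)
  }

  search(list(map = map, used = used, queue = queue))
}
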