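# Independent brute-force cross-check for the generator.
#
# Enumerates ALL augmentation sequences (no minimality filtering) with a
# given support and reticulation count, builds every network, and counts
# isomorphism classes by two routes that share no logic with the
# incremental ARP/state bookkeeping of the generator: canonical-sequence
# deduplication (build + greedy reduce) and direct backtracking
# isomorphism.  Guarded to tiny instances.

oracle_guard <- function(n, r) {
  if (!((n <= 3L && r <= 2L) || (n == 4L && r <= 1L))) {
    stop("instance too large for the brute-force oracle ",
         "(allowed: n <= 3 with r <= 2, or n = 4 with r <= 1)")
  }
}

#' Enumerate all augmentation sequences (brute force)
#'
#' All augmentation sequences with support exactly `[n]` and exactly `r`
#' reticulations, with no minimality filtering: the same prepend
#' recursion as the generator but keeping every pair `(i, j)` with `j` in
#' the support, under the leaf/reticulation budgets only.  Distinct
#' sequences may generate isomorphic networks.
#'
#' @param n Leaf count (tiny instances only; guarded).
#' @param r Reticulation count.
#' @return List of `pair_sequence` objects.  `n = 1` returns an empty
#'   list (the trivial network needs no pair).
#' @export
enumerate_all_sequences <- function(n, r) {
  n <- as.integer(n); r <- as.integer(r)
  oracle_guard(n, r)
  if (n == 1L) return(list())
  kmax <- n + r - 1L
  seqmat <- matrix(0L, kmax, 2L)
  acc <- list()
  recurse <- function(pos, X, nX, rc) {
    if (nX == n && rc == r) {
      acc[[length(acc) + 1L]] <<- pair_sequence(seqmat[pos:kmax, , drop = FALSE])
      return(invisible(NULL))
    }
    if (pos == 1L) return(invisible(NULL))
    for (i in 1:n) {
      in_X <- X[i]
      if (in_X) { if (rc >= r) next } else if (nX >= n) next
      for (j in 1:n) {
        if (j == i || !X[j]) next
        seqmat[pos - 1L, ] <<- c(i, j)
        if (in_X) recurse(pos - 1L, X, nX, rc + 1L)
        else { X2 <- X; X2[i] <- TRUE; recurse(pos - 1L, X2, nX + 1L, rc) }
      }
    }
    invisible(NULL)
  }
  for (a in 1:n) for (b in 1:n) {
    if (a == b) next
    seqmat[kmax, ] <- c(a, b)
    X <- rep(FALSE, n); X[c(a, b)] <- TRUE
    recurse(kmax, X, 2L, 0L)
  }
  acc
}

#' Count distinct networks by brute force
#'
#' Builds the network of every sequence from [enumerate_all_sequences()],
#' filters by the class predicate, and counts isomorphism classes.  With
#' `method = "mcrs"` classes are keyed by the serialized canonical
#' sequence recomputed by greedy reduction of the built network; with
#' `method = "isomorphism"` classes are formed greedily with
#' [is_isomorphic()].  The two methods must agree, and both must agree
#' with [count_networks()] — that is the headline cross-validation of the
#' generator.
#'
#' @inheritParams enumerate_all_sequences
#' @param mode `"orchard"`, `"tree_child"` or `"stack_free"`.
#' @param method `"mcrs"` (default) or `"isomorphism"`.
#' @return Integer count of isomorphism classes.
#' @export
distinct_network_count <- function(n, r,
                                   mode = c("orchard", "tree_child", "stack_free"),
                                   method = c("mcrs", "isomorphism")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  seqs <- enumerate_all_sequences(n, r)
  if (n == 1L) return(if (r == 0L) 1L else 0L)
  nets <- lapply(seqs, build_network)
  keep <- switch(mode,
    orchard = rep(TRUE, length(nets)),
    tree_child = vapply(nets, is_tree_child, logical(1L)),
    stack_free = vapply(nets, is_stack_free, logical(1L)))
  nets <- nets[keep]
  if (method == "mcrs") {
    keys <- vapply(nets, function(N) format_sequence(mcrs(N)), character(1L))
    length(unique(keys))
  } else {
    reps <- list()
    for (N in nets) {
      hit <- FALSE
      for (Rp in reps) {
        if (is_isomorphic(N, Rp)) { hit <- TRUE; break }
      }
      if (!hit) reps[[length(reps) + 1L]] <- N
    }
    length(reps)
  }
}
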