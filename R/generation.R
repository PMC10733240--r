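# Depth-first injective generation of minimum augmentation sequences.
#
# Every orchard network over [n] with r reticulations corresponds to
# exactly one minimum augmentation sequence of length n + r - 1, and such
# sequences end in a pair (m, n) with m < n.  The generator therefore
# seeds one DFS per m, and at each step tries to prepend a pair (i, j):
# the prepend is kept iff (i, j) is the minimum of the incrementally
# updated ARP.  Candidate pruning: i already present costs a reticulation
# (needs budget), i new costs a leaf (needs budget) and must satisfy
# i < j (otherwise the mirrored cherry is smaller and minimality is
# impossible).  Tree-child and stack-free generation additionally gate on
# the incrementally maintained state vector.  Networks are never
# materialized: the state is (sequence, support, r, ARP, sigma).
#
# Internal encodings in this file: the ARP is an integer matrix with
# columns (i, j, chi), chi = 1 for C and 2 for R, sorted, cherries stored
# once with i < j; states are integers 0 = N, 1 = P, 2 = S, 3 = T.

STATE_N <- 0L; STATE_P <- 1L; STATE_S <- 2L; STATE_T <- 3L

# Try to prepend (i, j) to a suffix with reduced-orientation ARP `arp`.
# Returns the updated (sorted) ARP matrix, or NULL when (i, j) is not the
# minimum reducible pair of the extended sequence.
arp_try_prepend <- function(arp, i, j, in_X) {
  m <- nrow(arp)
  cnt <- 0L
  keep <- matrix(0L, m, 3L)
  for (t in seq_len(m)) {
    a <- arp[t, 1L]; b <- arp[t, 2L]; ch <- arp[t, 3L]
    ti <- (a == i || b == i); tj <- (a == j || b == j)
    if (!ti && !tj) {
      na <- a; nb <- b; nc <- ch
    } else if (ti && !tj && ch == 1L) {
      na <- i; nb <- a + b - i; nc <- 2L   # cherry with i survives as (i, y)^R
    } else {
      next                                 # pair meeting {i, j} disappears
    }
    if (na < i || (na == i && nb < j)) return(NULL)  # a smaller pair survives
    cnt <- cnt + 1L
    keep[cnt, 1L] <- na; keep[cnt, 2L] <- nb; keep[cnt, 3L] <- nc
  }
  res <- rbind(c(i, j, if (in_X) 2L else 1L), keep[seq_len(cnt), , drop = FALSE])
  res[order(res[, 1L], res[, 2L]), , drop = FALSE]
}

# Core DFS.  `emit` is called with the k x 2 pair matrix of each yielded
# sequence.  mode: 1 orchard, 2 tree-child, 3 stack-free.
gen_dfs <- function(n, r, mode, at_most, emit) {
  n <- as.integer(n); r <- as.integer(r)
  if (n < 1L || r < 0L) stop("need n >= 1 and r >= 0")
  if (n == 1L) {
    if (r == 0L || at_most) emit(matrix(integer(0), 0L, 2L))
    return(invisible(NULL))
  }
  track <- mode != 1L
  kmax <- n + r - 1L
  seqmat <- matrix(0L, kmax, 2L)

  recurse <- function(pos, X, nX, rc, arp, sigma) {
    if (nX == n) {
      if (at_most) {
        emit(seqmat[pos:kmax, , drop = FALSE])
        if (rc == r) return(invisible(NULL))
      } else if (rc == r) {
        emit(seqmat[pos:kmax, , drop = FALSE])
        return(invisible(NULL))
      }
    }
    if (pos == 1L) return(invisible(NULL))
    for (i in 1:n) {
      in_X <- X[i]
      if (in_X) {
        if (rc >= r) next
        if (track) {
          si <- sigma[i]
          if (si == STATE_P) next
          if (mode == 2L && si == STATE_S) next
        }
      } else {
        if (nX >= n) next
      }
      for (j in 1:n) {
        if (j == i || !X[j]) next
        if (!in_X && i > j) next   # mirrored cherry would be smaller
        arp2 <- arp_try_prepend(arp, i, j, in_X)
        if (is.null(arp2)) next
        seqmat[pos - 1L, 1L] <<- i
        seqmat[pos - 1L, 2L] <<- j
        if (track) {
          sigma2 <- sigma
          if (!in_X) {
            sigma2[i] <- STATE_T; sigma2[j] <- STATE_T
          } else {
            # cherries {i, l} of the old ARP: l's sibling becomes a reticulation
            for (t in seq_len(nrow(arp))) {
              if (arp[t, 3L] == 1L) {
                if (arp[t, 1L] == i) sigma2[arp[t, 2L]] <- STATE_S
                else if (arp[t, 2L] == i) sigma2[arp[t, 1L]] <- STATE_S
              }
            }
            sigma2[i] <- STATE_P; sigma2[j] <- STATE_S
          }
        } else sigma2 <- sigma
        if (in_X) recurse(pos - 1L, X, nX, rc + 1L, arp2, sigma2)
        else {
          X2 <- X; X2[i] <- TRUE
          recurse(pos - 1L, X2, nX + 1L, rc, arp2, sigma2)
        }
      }
    }
    invisible(NULL)
  }

  for (m in 1:(n - 1L)) {
    seqmat[kmax, 1L] <- m; seqmat[kmax, 2L] <- n
    X <- rep(FALSE, n); X[c(m, n)] <- TRUE
    sigma <- rep(STATE_N, n); sigma[c(m, n)] <- STATE_T
    recurse(kmax, X, 2L, 0L, matrix(c(m, n, 1L), 1L, 3L), sigma)
  }
  invisible(NULL)
}

mode_code <- function(mode) {
  match(match.arg(mode, c("orchard", "tree_child", "stack_free")),
        c("orchard", "tree_child", "stack_free"))
}

#' Generate all orchard / tree-child / stack-free networks as sequences
#'
#' Enumerates, without repetition, the minimum augmentation sequences of
#' all networks of the requested class over taxa `[n]` with exactly `r`
#' reticulations (or at most `r` with `at_most = TRUE`).  Each returned
#' sequence is the canonical [mcrs()] of a distinct network, and every
#' network of the class appears exactly once; [build_network()] converts
#' them to networks.  Output order is deterministic: depth-first over the
#' final pair `(m, n)` with `m` ascending, candidate prepends ascending
#' in the pair order.
#'
#' @param n Number of leaves (taxa are `1..n`), `n >= 1`.
#' @param r Number of reticulations (budget when `at_most = TRUE`).
#' @param mode `"orchard"`, `"tree_child"` or `"stack_free"`.
#' @param at_most If `TRUE`, all classes with `0..r` reticulations.
#' @return List of `pair_sequence` objects.
#' @examples
#' generate_sequences(3, 0)                 # the 3 binary trees on 3 leaves
#' length(generate_sequences(3, 1))         # 21 orchard networks
#' @export
generate_sequences <- function(n, r,
                               mode = c("orchard", "tree_child", "stack_free"),
                               at_most = FALSE) {
  acc <- vector("list", 64L)
  cnt <- 0L
  gen_dfs(n, r, mode_code(mode), isTRUE(at_most), function(m) {
    cnt <<- cnt + 1L
    if (cnt > length(acc)) length(acc) <<- 2L * length(acc)
    acc[[cnt]] <<- pair_sequence(m)
  })
  acc[seq_len(cnt)]
}

#' Count networks without storing them
#'
#' Same depth-first search as [generate_sequences()] with a counter in
#' place of the accumulator.
#'
#' @inheritParams generate_sequences
#' @return Numeric count (counts can exceed integer range).
#' @examples
#' count_networks(3, 1)  # 21
#' @export
count_networks <- function(n, r,
                           mode = c("orchard", "tree_child", "stack_free"),
                           at_most = FALSE) {
  cnt <- 0
  gen_dfs(n, r, mode_code(mode), isTRUE(at_most), function(m) cnt <<- cnt + 1)
  cnt
}

#' Table of network counts by leaves and reticulations
#'
#' @param max_n Largest leaf count; columns are `n = 2..max_n`.
#' @param max_r Largest reticulation count; rows are `r = 0..max_r`.
#' @param mode `"orchard"`, `"tree_child"` or `"stack_free"`.
#' @return Numeric matrix with dimnames `r` (rows) and `n` (columns) and
#'   attribute `mode`.
#' @export
count_table <- function(max_n, max_r,
                        mode = c("orchard", "tree_child", "stack_free")) {
  mode <- match.arg(mode)
  ns <- 2:max_n
  rs <- 0:max_r
  tab <- matrix(0, length(rs), length(ns),
                dimnames = list(r = rs, n = ns))
  for (ri in seq_along(rs)) {
    for (ni in seq_along(ns)) {
      tab[ri, ni] <- count_networks(ns[ni], rs[ri], mode)
    }
  }
  attr(tab, "mode") <- mode
  tab
}

#' Random network sequence (seeded, non-uniform)
#'
#' Runs the same depth-first search but visits the candidate prepends of
#' each step in random order and returns the first complete sequence
#' found, backtracking over dead ends.  Identical seeds give identical
#' output.  The sampler is *not* uniform over networks: already the final
#' pair `(m, n)` is chosen uniformly over `m` although the number of
#' networks per `m` varies.
#'
#' @inheritParams generate_sequences
#' @param seed Optional integer seed; when given, the RNG state is set
#'   from it and restored on exit.
#' @return A `pair_sequence`.  If no network with the requested
#'   parameters exists (e.g. tree-child with `r >= n`), an error of class
#'   `orchardgen_no_network` is raised after exhaustive search.
#' @export
random_sequence <- function(n, r,
                            mode = c("orchard", "tree_child", "stack_free"),
                            seed = NULL) {
  md <- mode_code(mode)
  n <- as.integer(n); r <- as.integer(r)
  if (n < 1L || r < 0L) stop("need n >= 1 and r >= 0")
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  if (n == 1L) {
    if (r == 0L) return(pair_sequence())
    stop(errorCondition("no network with these parameters exists",
                        class = c("orchardgen_no_network", "error", "condition")))
  }
  track <- md != 1L
  kmax <- n + r - 1L
  seqmat <- matrix(0L, kmax, 2L)

  recurse <- function(pos, X, nX, rc, arp, sigma) {
    if (nX == n && rc == r) return(seqmat[pos:kmax, , drop = FALSE])
    if (pos == 1L) return(NULL)
    cand <- list()
    for (i in 1:n) {
      in_X <- X[i]
      if (in_X) {
        if (rc >= r) next
        if (track) {
          si <- sigma[i]
          if (si == STATE_P || (md == 2L && si == STATE_S)) next
        }
      } else if (nX >= n) next
      for (j in 1:n) {
        if (j == i || !X[j]) next
        if (!in_X && i > j) next
        cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
    for (t in sample.int(length(cand))) {
      p <- cand[[t]]
      in_X <- X[p[1L]]
      arp2 <- arp_try_prepend(arp, p[1L], p[2L], in_X)
      if (is.null(arp2)) next
      seqmat[pos - 1L, ] <<- p
      if (track) {
        sigma2 <- state_int_update(sigma, arp, p[1L], p[2L], in_X)
      } else sigma2 <- sigma
      if (in_X) res <- recurse(pos - 1L, X, nX, rc + 1L, arp2, sigma2)
      else {
        X2 <- X; X2[p[1L]] <- TRUE
        res <- recurse(pos - 1L, X2, nX + 1L, rc, arp2, sigma2)
      }
      if (!is.null(res)) return(res)
    }
    NULL
  }

  for (m in sample.int(n - 1L)) {
    seqmat[kmax, ] <- c(m, n)
    X <- rep(FALSE, n); X[c(m, n)] <- TRUE
    sigma <- rep(STATE_N, n); sigma[c(m, n)] <- STATE_T
    res <- recurse(kmax, X, 2L, 0L, matrix(c(m, n, 1L), 1L, 3L), sigma)
    if (!is.null(res)) return(pair_sequence(res))
  }
  stop(errorCondition("no network with these parameters exists",
                      class = c("orchardgen_no_network", "error", "condition")))
}

# integer-coded sigma update shared by the samplers
state_int_update <- function(sigma, arp, i, j, in_X) {
  sigma2 <- sigma
  if (!in_X) {
    sigma2[i] <- STATE_T; sigma2[j] <- STATE_T
  } else {
    for (t in seq_len(nrow(arp))) {
      if (arp[t, 3L] == 1L) {
        if (arp[t, 1L] == i) sigma2[arp[t, 2L]] <- STATE_S
        else if (arp[t, 2L] == i) sigma2[arp[t, 1L]] <- STATE_S
      }
    }
    sigma2[i] <- STATE_P; sigma2[j] <- STATE_S
  }
  sigma2
}
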