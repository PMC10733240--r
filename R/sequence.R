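# Pair and sequence algebra for cherry-picking (augmentation) sequences.
#
# A pair sequence S = s_1 ... s_k is stored as a k x 2 integer matrix of
# (i, j) rows.  The empty sequence (k = 0) denotes a trivial network.

#' Construct a pair sequence
#'
#' @param pairs A k x 2 integer matrix (or a length-2 vector for a single
#'   pair, or `NULL`/empty for the empty sequence), rows `(i, j)`.
#' @return An object of class `pair_sequence`.
#' @export
pair_sequence <- function(pairs = NULL) {
  if (is.null(pairs) || length(pairs) == 0L) {
    m <- matrix(integer(0), 0L, 2L)
  } else if (is.matrix(pairs)) {
    m <- matrix(as.integer(pairs), ncol = 2L)
  } else {
    m <- matrix(as.integer(pairs), ncol = 2L, byrow = TRUE)
  }
  if (nrow(m) > 0L) {
    if (any(is.na(m)) || any(m < 1L)) {
      stop("pair entries must be positive integers")
    }
    if (any(m[, 1L] == m[, 2L])) {
      stop("a pair (i, j) must have i != j")
    }
  }
  colnames(m) <- c("i", "j")
  structure(m, class = "pair_sequence")
}

as_pair_matrix <- function(S) {
  if (inherits(S, "pair_sequence")) unclass(S)
  else unclass(pair_sequence(S))
}

#' Strict total order on pairs
#'
#' `(i, j) < (i', j')` iff `i < i'`, or `i = i'` and `j < j'`.
#'
#' @param p,q Length-2 integer vectors `(i, j)`.
#' @return `TRUE` iff `p` is strictly smaller than `q`.
#' @examples
#' pair_less(c(3, 2), c(3, 4))
#' @export
pair_less <- function(p, q) {
  p[1L] < q[1L] || (p[1L] == q[1L] && p[2L] < q[2L])
}

#' Strict lexicographic order on equal-length pair sequences
#'
#' Only sequences of the same length are comparable (all complete
#' reducible-pairs sequences of one network share the length
#' `|X| + r - 1`); unequal lengths raise an error rather than silently
#' prefix-comparing.
#'
#' @param S,T `pair_sequence` objects of equal length.
#' @return `TRUE` iff `S` precedes `T` strictly.
#' @export
seq_less <- function(S, T) {
  a <- as_pair_matrix(S); b <- as_pair_matrix(T)
  if (nrow(a) != nrow(b)) {
    stop("sequences of unequal length are not comparable")
  }
  for (t in seq_len(nrow(a))) {
    if (a[t, 1L] != b[t, 1L]) return(a[t, 1L] < b[t, 1L])
    if (a[t, 2L] != b[t, 2L]) return(a[t, 2L] < b[t, 2L])
  }
  FALSE
}

#' Support of a pair sequence
#'
#' The set of taxa appearing in the sequence; equals the leaf set of the
#' network the sequence generates.
#'
#' @param S A `pair_sequence`.
#' @return Sorted integer vector of taxa (empty for the empty sequence).
#' @export
seq_support <- function(S) {
  m <- as_pair_matrix(S)
  sort(unique(as.vector(m)))
}

#' Augmentation-sequence predicate
#'
#' A sequence s_1 ... s_k of pairs (i_t, j_t) is an augmentation sequence
#' (a cherry-picking sequence) when, for every t < k, j_t belongs to the
#' support of the suffix s_(t+1) ... s_k.  Exactly these sequences build a
#' network when applied right-to-left starting from a trivial network.
#'
#' @param S A `pair_sequence`.
#' @return `TRUE` or `FALSE`.
#' @export
is_augmentation_sequence <- function(S) {
  m <- as_pair_matrix(S)
  k <- nrow(m)
  if (k <= 1L) return(TRUE)
  # scan right to left, growing the suffix support
  supp <- unique(c(m[k, ]))
  for (t in (k - 1L):1L) {
    if (!(m[t, 2L] %in% supp)) return(FALSE)
    supp <- unique(c(supp, m[t, ]))
  }
  TRUE
}

#' Reticulation count of an augmentation sequence
#'
#' The number of reticulations of the network the sequence generates: the
#' number of indices t < k with i_t in the support of the following suffix
#' (prepending such a pair turns the leaf i_t into a reticulated cherry).
#' Satisfies `length(S) = |support(S)| + r - 1` for non-empty sequences.
#'
#' @param S A `pair_sequence` that is an augmentation sequence.
#' @return Integer >= 0.
#' @export
seq_reticulations <- function(S) {
  m <- as_pair_matrix(S)
  k <- nrow(m)
  if (k == 0L) return(0L)
  if (!is_augmentation_sequence(S)) {
    stop("not an augmentation sequence")
  }
  if (k == 1L) return(0L)
  r <- 0L
  supp <- unique(c(m[k, ]))
  for (t in (k - 1L):1L) {
    if (m[t, 1L] %in% supp) r <- r + 1L
    supp <- unique(c(supp, m[t, ]))
  }
  r
}

#' Parse the textual pair-sequence dialect
#'
#' The dialect is `"(i,j)(i,j)..."`, optionally with whitespace between
#' tokens; an empty string denotes the empty sequence.
#'
#' @param text A single character string.
#' @return A `pair_sequence`.
#' @examples
#' parse_sequence("(3,1)(3,2)(1,2)(3,4)(2,4)")
#' @export
parse_sequence <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop("expected a single character string")
  }
  s <- gsub("[[:space:]]", "", text)
  if (nchar(s) == 0L) return(pair_sequence())
  out <- matrix(integer(0), 0L, 2L)
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    rest <- substr(s, pos, n)
    m <- regmatches(rest, regexec("^\\(([0-9]+),([0-9]+)\\)", rest))[[1L]]
    if (length(m) == 0L) {
      stop(sprintf("malformed pair sequence at position %d: '%s'",
                   pos, substr(s, pos, min(n, pos + 9L))))
    }
    out <- rbind(out, c(as.integer(m[2L]), as.integer(m[3L])))
    pos <- pos + nchar(m[1L])
  }
  pair_sequence(out)
}

#' Serialize a pair sequence
#'
#' Inverse of [parse_sequence()]: no spaces inside pairs, no separator
#' between pairs, e.g. `"(3,1)(3,2)(1,2)(3,4)(2,4)"`.
#'
#' @param S A `pair_sequence`.
#' @return A character string (empty string for the empty sequence).
#' @export
format_sequence <- function(S) {
  m <- as_pair_matrix(S)
  if (nrow(m) == 0L) return("")
  paste0("(", m[, 1L], ",", m[, 2L], ")", collapse = "")
}

#' @export
print.pair_sequence <- function(x, ...) {
  m <- as_pair_matrix(x)
  if (nrow(m) == 0L) {
    cat("<empty pair sequence>\n")
  } else {
    cat(format_sequence(x), "\n")
  }
  invisible(x)
}

#' @export
length.pair_sequence <- function(x) nrow(unclass(x))

#' @export
`==.pair_sequence` <- function(e1, e2) {
  identical(as_pair_matrix(e1), as_pair_matrix(e2))
}
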