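# Augmentation, sequence->network construction, incremental updates.

test_that("augmenting creates a cherry for new taxa, a reticulated cherry otherwise", {
  M <- augment_pair(make_trivial(4), c(2, 4))
  expect_true(is_isomorphic(M, cherry_net(2, 4)))

  # same pair again: i now present, so a reticulation appears
  M2 <- augment_pair(M, c(2, 4))
  expect_identical(validate_network(M2), character(0))
  expect_equal(reticulation_count(M2), 1L)

  expect_error(augment_pair(M, c(1, 3)), "not a leaf")
  expect_error(augment_pair(M, c(2, 2)), "i != j")
})

test_that("the worked example is rebuilt by right-to-left augmentation", {
  N <- make_trivial(4)
  for (p in list(c(2, 4), c(3, 4), c(1, 2), c(3, 2), c(3, 1))) {
    N <- augment_pair(N, p)
  }
  expect_true(is_isomorphic(N, fig1_network()))
})

test_that("build_network validates its input sequence", {
  expect_true(is_isomorphic(build_network(parse_sequence("(2,4)")), cherry_net(2, 4)))
  expect_error(build_network(pair_sequence()), "base taxon")
  expect_error(build_network(parse_sequence("(1,2)(3,4)")), "not an augmentation sequence")
})

test_that("reduction inverts augmentation up to isomorphism", {
  set.seed(5)
  for (t in 1:25) {
    n <- sample(2:4, 1); r <- sample(0:2, 1)
    N <- build_network(random_sequence(n, r))
    j <- sample(network_taxa(N), 1)
    i <- sample(setdiff(1:5, j), 1)
    M <- augment_pair(N, c(i, j))
    expect_true(is_isomorphic(reduce_pair(M, c(i, j)), N))
  }
})

test_that("the incremental ARP update matches the published local rules", {
  # seeding a cherry from nothing
  a <- arp_after_prepend(empty_arp(), X = 4L, p = c(2, 4))
  expect_equal(a, data.frame(i = c(2L, 4L), j = c(4L, 2L), chi = c("C", "C"),
                             stringsAsFactors = FALSE))
  # two cherries (1,2), (3,4); prepend the reticulated cherry (3,2)
  a1 <- data.frame(i = c(1L, 2L, 3L, 4L), j = c(2L, 1L, 4L, 3L),
                   chi = c("C", "C", "C", "C"), stringsAsFactors = FALSE)
  expect_equal(arp_after_prepend(a1, X = 1:4, p = c(3, 2)),
               data.frame(i = c(3L, 3L), j = c(2L, 4L), chi = c("R", "R"),
                          stringsAsFactors = FALSE))
  # both (3,.)^R pairs die when (3,1) is prepended
  a2 <- data.frame(i = c(3L, 3L), j = c(2L, 4L), chi = c("R", "R"),
                   stringsAsFactors = FALSE)
  expect_equal(arp_after_prepend(a2, X = 1:4, p = c(3, 1)),
               data.frame(i = 3L, j = 1L, chi = "R", stringsAsFactors = FALSE))
  expect_error(arp_after_prepend(a2, X = 1:4, p = c(5, 6)), "taxon")
})

test_that("incremental ARP chains equal the directly computed ARP", {
  for (spec in list(c(3, 2), c(4, 1))) {
    for (S in generate_sequences(spec[1], spec[2])) {
      m <- unclass(S); k <- nrow(m)
      if (k == 1) next
      X <- m[k, ]
      arp <- arp_after_prepend(empty_arp(), X = m[k, 2], p = m[k, ])
      for (t in seq(k - 1, 1)) {
        arp <- arp_after_prepend(arp, X, m[t, ])
        X <- sort(unique(c(X, m[t, ])))
        direct <- annotated_reducible_pairs(
          build_network(pair_sequence(m[t:k, , drop = FALSE])))
        expect_equal(arp, direct, ignore_attr = TRUE)
      }
    }
  }
})

test_that("the reduced-orientation update stores cherries once, minimum first", {
  a1 <- data.frame(i = c(1L, 3L), j = c(2L, 4L), chi = c("C", "C"),
                   stringsAsFactors = FALSE)
  red <- arp_after_prepend(a1, X = 1:4, p = c(3, 2), orientation = "reduced")
  expect_equal(red, data.frame(i = c(3L, 3L), j = c(2L, 4L), chi = c("R", "R"),
                               stringsAsFactors = FALSE))
  # new cherry with i > j is stored reoriented, so it cannot be minimum
  red2 <- arp_after_prepend(empty_arp(), X = 2L, p = c(4, 2),
                            orientation = "reduced")
  expect_equal(red2, data.frame(i = 2L, j = 4L, chi = "C",
                                stringsAsFactors = FALSE))
  expect_false(is_minimum_prepend(red2, c(4, 2)))
})

test_that("the incremental state update matches its local rules", {
  # cherry branch: new taxon joins with both states T
  s <- c("N", "N", "N", "T")
  s2 <- state_after_prepend(s, empty_arp(), c(2, 4))
  expect_equal(s2, c("N", "T", "N", "T"))
  # reticulated-cherry branch, with a cherry partner of i picking up S
  sAllT <- c("T", "T", "T", "T")
  arp <- data.frame(i = c(1L, 2L, 3L, 4L), j = c(2L, 1L, 4L, 3L),
                    chi = rep("C", 4), stringsAsFactors = FALSE)
  s3 <- state_after_prepend(sAllT, arp, c(3, 2))
  expect_equal(s3, c("T", "S", "P", "S"))
  # prepending onto a P-state taxon stacks reticulations: rejected
  expect_error(state_after_prepend(s3, empty_arp(), c(3, 1)), "state of i is P")
  expect_error(state_after_prepend(s, empty_arp(), c(2, 1)), "taxon")
})

test_that("incremental state chains equal the directly computed states", {
  for (mode in c("tree_child", "stack_free")) {
    for (S in generate_sequences(3, 2, mode)) {
      m <- unclass(S); k <- nrow(m)
      if (k == 1) next
      X <- m[k, ]
      arp <- arp_after_prepend(empty_arp(), X = m[k, 2], p = m[k, ])
      sig <- rep("N", 3); sig[m[k, ]] <- "T"
      for (t in seq(k - 1, 1)) {
        sig <- state_after_prepend(sig, arp, m[t, ])
        arp <- arp_after_prepend(arp, X, m[t, ])
        X <- sort(unique(c(X, m[t, ])))
        N <- build_network(pair_sequence(m[t:k, , drop = FALSE]))
        expect_equal(sig, sigma_states(N, 3))
      }
    }
  }
})

test_that("augmentation preserves tree-child exactly when the state allows it", {
  # brute force over all legal (N, p) for tree-child networks, n <= 3, r <= 1
  for (n in 2:3) for (r in 0:1) {
    for (S in generate_sequences(n, r, "tree_child")) {
      N <- build_network(S)
      sig <- sigma_states(N, n + 1L)
      for (j in network_taxa(N)) for (i in setdiff(seq_len(n + 1L), j)) {
        M <- augment_pair(N, c(i, j))
        expect_equal(is_tree_child(M), sig[i] %in% c("N", "T"),
                     info = sprintf("%s + (%d,%d)", format_sequence(S), i, j))
      }
    }
  }
})

test_that("minimality of a prepend is minimality in the updated ARP", {
  expect_true(is_minimum_prepend(
    data.frame(i = 2L, j = 4L, chi = "C", stringsAsFactors = FALSE), c(2, 4)))
  expect_true(is_minimum_prepend(
    data.frame(i = c(3L, 3L), j = c(2L, 4L), chi = c("R", "R"),
               stringsAsFactors = FALSE), c(3, 2)))
  # cherry prepend with i > j: the mirrored cherry is smaller
  full <- arp_after_prepend(
    arp_after_prepend(empty_arp(), X = 4L, p = c(2, 4)), X = c(2L, 4L), p = c(3, 2))
  expect_equal(full$i[1], 2L)  # (2,3)^C sorts first
  expect_false(is_minimum_prepend(full, c(3, 2)))
})
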