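# Reducible pairs, reductions, recognition, canonical sequence.

test_that("annotated reducible pairs report cherries in both orientations", {
  arp <- annotated_reducible_pairs(cherry_net(1, 2))
  expect_equal(arp$i, c(1L, 2L))
  expect_equal(arp$j, c(2L, 1L))
  expect_equal(arp$chi, c("C", "C"))
  expect_equal(nrow(annotated_reducible_pairs(make_trivial(5))), 0L)
})

test_that("the worked example network has the single reducible pair (3,1)^R", {
  arp <- annotated_reducible_pairs(fig1_network())
  expect_equal(arp$i, 3L)
  expect_equal(arp$j, 1L)
  expect_equal(arp$chi, "R")
})

test_that("reduction removes a cherry leaf or a reticulated-cherry arc", {
  N <- fig1_network()
  N31 <- reduce_pair(N, c(3, 1))
  expect_identical(validate_network(N31), character(0))
  expect_equal(reticulation_count(N31), 1L)
  expect_equal(network_taxa(N31), 1:4)  # leaf set unchanged for R pairs
  # reducing the first pair leaves the network of the remaining sequence
  expect_true(is_isomorphic(N31, build_network(parse_sequence("(3,2)(1,2)(3,4)(2,4)"))))

  M <- reduce_pair(cherry_net(1, 2), c(1, 2))
  expect_true(is_isomorphic(M, make_trivial(2)))

  expect_error(reduce_pair(N, c(1, 2)), "neither a cherry nor a reticulated cherry")
  expect_error(reduce_pair(N, c(7, 1)), "not a pair of distinct leaves")
})

test_that("reducing along a complete sequence reaches the trivial network", {
  for (txt in c(fig1_text, fig1_alt_text)) {
    M <- fig1_network()
    S <- parse_sequence(txt)
    for (t in seq_len(length(S))) M <- reduce_pair(M, unclass(S)[t, ])
    expect_true(is_isomorphic(M, make_trivial(4)))
  }
})

test_that("mcrs is the canonical minimum complete sequence", {
  expect_equal(format_sequence(mcrs(fig1_network())), fig1_text)
  expect_equal(length(mcrs(make_trivial(3))), 0L)
  expect_equal(format_sequence(mcrs(cherry_net(2, 4))), "(2,4)")
  # both complete sequences canonicalize to the same (minimum) one
  expect_equal(format_sequence(mcrs(build_network(parse_sequence(fig1_alt_text)))),
               fig1_text)
})

test_that("mcrs is invariant under internal node relabeling", {
  for (s in c(fig1_text, "(1,2)(1,2)", "(2,3)(1,3)(3,4)(2,4)")) {
    N <- build_network(parse_sequence(s))
    expect_equal(format_sequence(mcrs(relabel_nodes(N, seed = 3))),
                 format_sequence(mcrs(N)))
  }
})

test_that("orchard recognition accepts trees and rejects the crown network", {
  expect_true(is_orchard(fig1_network()))
  expect_true(is_orchard(make_trivial(1)))
  for (S in generate_sequences(4, 0)) expect_true(is_orchard(build_network(S)))

  bad <- non_orchard_network()
  expect_identical(validate_network(bad), character(0))
  expect_false(is_orchard(bad))
  diag <- mcrs(bad)
  expect_true(is_not_orchard(diag))
  expect_equal(length(diag$partial), 0L)      # stuck immediately
  expect_equal(network_taxa(diag$stuck), 1:2)
})

test_that("tree-child and stack-free predicates follow their definitions", {
  for (S in generate_sequences(3, 0)) expect_true(is_tree_child(build_network(S)))
  expect_false(is_tree_child(fig1_network()))
  expect_false(is_stack_free(fig1_network()))
  stacked <- build_network(parse_sequence("(1,2)(1,2)(1,2)"))
  expect_false(is_stack_free(stacked))
  expect_false(is_tree_child(stacked))
  expect_true(is_stack_free(build_network(parse_sequence("(1,2)"))))
  # the crown is stack-free but not orchard: the class inclusions proved
  # for orchard inputs do not extend to arbitrary networks
  expect_true(is_stack_free(non_orchard_network()))
  expect_false(is_tree_child(non_orchard_network()))
})

test_that("tree-child state is computed correctly from the network", {
  expect_equal(sigma_states(make_trivial(4), 4), c("N", "N", "N", "T"))
  expect_equal(sigma_states(cherry_net(2, 4), 4), c("N", "T", "N", "T"))
  # reticulated cherry (1,2): parent of 1 is a reticulation, sibling of 2 is
  expect_equal(sigma_states(build_network(parse_sequence("(1,2)(1,2)")), 2),
               c("P", "S"))
})

test_that("reduced-orientation ARP size is bounded by 2|X|/3", {
  for (n in 2:4) for (r in 0:2) {
    for (S in generate_sequences(n, r)) {
      N <- build_network(S)
      arp <- annotated_reducible_pairs(N)
      reduced <- arp[arp$chi == "R" | arp$i < arp$j, ]
      expect_lte(nrow(reduced), 2 * length(N$leaf_nodes) / 3)
    }
  }
})
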