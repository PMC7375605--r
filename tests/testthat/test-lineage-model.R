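# Core tree model: ambiguity resolution, collapsing, clustering, validation.

test_that("branch-point ambiguity codes are resolved by descendant majority", {
  tr <- make_tree(
    list(list("u", "UCA", "UCA", "AAA"),
         list("b", "BP1", "BP", "RAA"),
         list("x", "IgA", "OBSERVED", "AAA"),
         list("y", "IgB", "OBSERVED", "AAA"),
         list("z", "IgC", "OBSERVED", "GAA")),
    list(c("u", "b"), c("b", "x"), c("b", "y"), c("b", "z")))
  out <- resolve_ambiguities(tr)
  expect_equal(substr(out$nodes[["b"]]$sequence, 1, 1), "A")  # {A,A,G} -> A
  # unambiguous positions and non-BP nodes untouched
  expect_equal(out$nodes[["b"]]$sequence, "AAA")
  expect_equal(out$nodes[["z"]]$sequence, "GAA")
})

test_that("ambiguity ties break toward the first base in A<C<G<T order", {
  tr <- make_tree(
    list(list("u", "UCA", "UCA", "CCC"),
         list("b", "BP1", "BP", "YCC"),
         list("x", "IgA", "OBSERVED", "CCC"),
         list("y", "IgB", "OBSERVED", "TCC")),
    list(c("u", "b"), c("b", "x"), c("b", "y")))
  out <- resolve_ambiguities(tr)
  expect_equal(substr(out$nodes[["b"]]$sequence, 1, 1), "C")  # C/T tie -> C
})

test_that("a vote with no allowed descendant base falls back to N with a warning", {
  tr <- make_tree(
    list(list("u", "UCA", "UCA", "AAA"),
         list("b", "BP1", "BP", "RAA"),
         list("x", "IgA", "OBSERVED", "CAA"),
         list("y", "IgB", "OBSERVED", "TAA")),
    list(c("u", "b"), c("b", "x"), c("b", "y")))
  expect_warning(out <- resolve_ambiguities(tr), "writing N")
  expect_equal(substr(out$nodes[["b"]]$sequence, 1, 1), "N")
})

test_that("resolution is idempotent and only emits bases the code denotes", {
  for (seed in 1:10) {
    sim <- simulate_lineage(seed = seed, n_leaves = 6, uca_length = 60,
                            ambiguity_rate = 0.1)
    r1 <- suppressWarnings(resolve_ambiguities(sim$tree))
    r2 <- suppressWarnings(resolve_ambiguities(r1))
    expect_identical(r1$nodes, r2$nodes)
    for (n in r1$nodes)
      expect_false(grepl("[RYSWKMBDHV]", n$sequence))
    # every perturbed position was replaced by a base its code denotes
    amb <- sim$truth$ambiguities
    for (k in seq_len(nrow(amb))) {
      id <- names(which(vapply(sim$tree$nodes, function(n)
        n$label == amb$node[[k]], logical(1))))
      got <- substr(r1$nodes[[id]]$sequence, amb$nt_position[[k]],
                    amb$nt_position[[k]])
      expect_true(got %in% iglineage:::IUPAC_AMBIGUITY[[amb$code[[k]]]])
    }
  }
})

test_that("a branch point identical to a child collapses into it", {
  tr <- make_tree(
    list(list("u", "UCA", "UCA", "AAA"),
         list("b", "BP1", "BP", "AAG"),
         list("x", "IgX", "OBSERVED", "AAG"),
         list("y", "IgY", "OBSERVED", "AGG")),
    list(c("u", "b"), c("b", "x"), c("b", "y")))
  out <- collapse_redundant_bps(tr)
  expect_equal(sort(names(out$nodes)), c("u", "x", "y"))
  expect_equal(out$nodes[["x"]]$members, c("IgX", "BP1"))
  expect_equal(out$nodes[["x"]]$kind, "OBSERVED")
  expect_equal(parent_of <- out$edges$parent[out$edges$child == "y"], "x")
  expect_length(validate_tree(out), 0)
})

test_that("gap characters '.' and '-' and case are equal for collapsing", {
  tr <- make_tree(
    list(list("u", "UCA", "UCA", "AA-"),
         list("b", "BP1", "BP", "Ag."),
         list("x", "IgX", "OBSERVED", "AG-"),
         list("y", "IgY", "OBSERVED", "CG-")),
    list(c("u", "b"), c("b", "x"), c("b", "y")))
  out <- collapse_redundant_bps(tr)
  expect_false("b" %in% names(out$nodes))
})

test_that("all-distinct sequences collapse to a fixed point immediately", {
  tr <- make_tree(
    list(list("u", "UCA", "UCA", "AAA"),
         list("b", "BP1", "BP", "AAG"),
         list("x", "IgX", "OBSERVED", "AGG"),
         list("y", "IgY", "OBSERVED", "GGG")),
    list(c("u", "b"), c("b", "x"), c("b", "y")))
  out <- collapse_redundant_bps(tr)
  expect_equal(length(out$nodes), length(tr$nodes))
})

test_that("a branch point identical to two children merges with the first", {
  tr <- make_tree(
    list(list("u", "UCA", "UCA", "AAA"),
         list("b", "BP1", "BP", "AAG"),
         list("x", "IgX", "OBSERVED", "AAG"),
         list("y", "IgY", "OBSERVED", "AAG"),
         list("z", "IgZ", "OBSERVED", "ACG")),
    list(c("u", "b"), c("b", "x"), c("b", "y"), c("b", "z")))
  out <- collapse_redundant_bps(tr)
  expect_equal(out$nodes[["x"]]$members, c("IgX", "BP1"))
  expect_true(all(c("y", "z") %in% out$edges$child[out$edges$parent == "x"]))
})

test_that("identical observed siblings cluster into one node", {
  tr <- make_tree(
    list(list("u", "UCA", "UCA", "AAA"),
         list("a", "IgA", "OBSERVED", "AAG"),
         list("b", "IgB", "OBSERVED", "AAG")),
    list(c("u", "a"), c("u", "b")))
  out <- cluster_identical_observed(tr)
  expect_equal(length(out$nodes), 2L)
  expect_equal(out$nodes[["a"]]$members, c("IgA", "IgB"))
})

test_that("identical sequences that are not siblings are not merged", {
  tr <- make_tree(
    list(list("u", "UCA", "UCA", "AAA"),
         list("b", "BP1", "BP", "ACA"),
         list("a", "IgA", "OBSERVED", "AAG"),
         list("c", "IgC", "OBSERVED", "AAG")),
    list(c("u", "b"), c("u", "a"), c("b", "c")))
  out <- cluster_identical_observed(tr)
  expect_equal(length(out$nodes), 4L)
})

test_that("collapse and cluster preserve observed sequences and member labels", {
  for (seed in 1:20) {
    sim <- simulate_lineage(seed = seed, n_leaves = sample(2:8, 1),
                            uca_length = 30, mutations_per_edge = c(0, 2),
                            duplicate_leaf_rate = 0.3)
    tr <- sim$tree
    out <- cluster_identical_observed(collapse_redundant_bps(tr))
    expect_equal(observed_seq_multiset(out), observed_seq_multiset(tr))
    expect_equal(all_member_labels(out), all_member_labels(tr))
    expect_length(validate_tree(out), 0)
    # idempotence
    again <- cluster_identical_observed(collapse_redundant_bps(out))
    expect_equal(canonical_form(again), canonical_form(out))
    # no remaining BP identical to any child
    for (k in seq_len(nrow(out$edges))) {
      p <- out$nodes[[out$edges$parent[[k]]]]
      ch <- out$nodes[[out$edges$child[[k]]]]
      if (p$kind == "BP")
        expect_false(toupper(chartr(".", "-", p$sequence)) ==
                     toupper(chartr(".", "-", ch$sequence)))
    }
  }
})

test_that("processing matches a naive pairwise oracle on small trees", {
  for (seed in 1:25) {
    sim <- simulate_lineage(seed = seed, n_leaves = sample(2:6, 1),
                            uca_length = 30, mutations_per_edge = c(0, 2),
                            duplicate_leaf_rate = 0.4)
    mine <- cluster_identical_observed(collapse_redundant_bps(sim$tree))
    oracle <- oracle_collapse_cluster(sim$tree)
    expect_equal(canonical_form(mine), canonical_form(oracle))
  }
})

test_that("branch points are relabelled BP1.. in pre-order", {
  sim <- simulate_lineage(seed = 11, n_leaves = 6, uca_length = 30)
  tr <- process_lineage(sim$tree)
  ord <- iglineage:::preorder_ids(tr)
  bps <- ord[vapply(tr$nodes[ord], function(n) n$kind == "BP", logical(1))]
  expect_equal(vapply(tr$nodes[bps], `[[`, character(1), "label"),
               paste0("BP", seq_along(bps)), ignore_attr = TRUE)
  # re-runs are bit-stable
  tr2 <- process_lineage(simulate_lineage(seed = 11, n_leaves = 6,
                                          uca_length = 30)$tree)
  expect_identical(tr$nodes, tr2$nodes)
  expect_identical(tr$edges, tr2$edges)
})

test_that("validate_tree reports specific violations", {
  tr <- make_tree(
    list(list("u", "UCA", "UCA", "AAA"),
         list("a", "IgA", "OBSERVED", "AAG")),
    list(c("u", "a")))
  expect_length(validate_tree(tr), 0)

  bad_len <- tr
  bad_len$nodes[["a"]]$sequence <- "AAGG"
  expect_match(validate_tree(bad_len), "length", all = FALSE)

  two_roots <- make_tree(
    list(list("u", "UCA", "UCA", "AAA"),
         list("v", "UCA2", "UCA", "AAA"),
         list("a", "IgA", "OBSERVED", "AAG")),
    list(c("u", "a")))
  expect_match(validate_tree(two_roots), "multiple parentless nodes",
               all = FALSE)
})
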