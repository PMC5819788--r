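test_that("newick parsing round-trips and rejects malformed input", {
  tr <- read_newick("(A,(B,C));")
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  expect_identical(write_newick(read_newick(write_newick(tr))), write_newick(tr))
  expect_error(read_newick("(A,(B,C);"), "parse")
  tree <- phalaris_tree()
  expect_identical(length(tree$tip.label), 8L)
  expect_setequal(tree$tip.label, species_tree_label(species_names()))
})

test_that("Fitch counts match trivial hand cases", {
  tr <- read_newick("((a,b),(c,d));")
  expect_identical(fitch(tr, c(a = "x", b = "x", c = "x", d = "x"))$min_changes, 0L)
  expect_identical(fitch(tr, c(a = "x", b = "x", c = "y", d = "x"))$min_changes, 1L)
  two <- read_newick("(a,b);")
  expect_identical(fitch(two, c(a = "x", b = "y"))$min_changes, 1L)
  expect_error(fitch(tr, c(a = "x", b = "x", c = "y")), "missing")
})

test_that("Fitch equals the exhaustive minimum on random trees and characters", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = NULL)
    states <- stats::setNames(sample(letters[1:3], n, replace = TRUE), tr$tip.label)
    got <- fitch(tr, states)$min_changes
    expect_identical(got, as.integer(brute_force_parsimony(tr, states)))
  }
})

test_that("Fitch agrees with the library parsimony score as a second route", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n, br = NULL)
    states <- stats::setNames(sample(c("0", "1", "2"), n, replace = TRUE), tr$tip.label)
    pd <- phangorn::phyDat(matrix(states, ncol = 1,
                                  dimnames = list(names(states), NULL)),
                           type = "USER", levels = c("0", "1", "2"))
    expect_identical(fitch(tr, states)$min_changes,
                     as.integer(phangorn::parsimony(tr, pd, method = "fitch")))
  }
})

test_that("the parsimony count is invariant under leaf rotation and re-rooting", {
  tree <- phalaris_tree()
  states <- stats::setNames(
    c("6", "6", "7", "7", "7", "7", "7", "7"),
    species_tree_label(species_names())
  )[tree$tip.label]
  base <- fitch(tree, states)$min_changes
  rot <- ape::rotateConstr(tree, rev(tree$tip.label))
  expect_identical(fitch(rot, states)$min_changes, base)
  for (out in c("P_minor", "P_caroliniana", "P_brachystachys")) {
    rerooted <- ape::root(ape::unroot(tree), outgroup = out, resolve.root = TRUE)
    expect_identical(fitch(rerooted, states)$min_changes, base)
  }
})

test_that("character mapping recovers the single early dysploidy event", {
  mc <- map_characters()
  expect_identical(mc$parsimony$basic_number$min_changes, 1L)
  # a single change separates the x=6 lineage from the x=7 taxa (the
  # direction at the root is ambiguous to unordered parsimony)
  ce <- mc$parsimony$basic_number$change_edges
  expect_identical(nrow(ce), 1L)
  expect_setequal(c(ce$from, ce$to), c("6", "7"))
  # ploidy changes only on edges subtending tetraploids
  pe <- mc$parsimony$ploidy$change_edges
  expect_true(all(pe$to == "4"))
  expect_identical(mc$parsimony$ploidy$min_changes, 2L)
  expect_true(all(mc$checks))
})

test_that("fixture characters match the exhaustive minimum on the packaged tree", {
  mc <- map_characters()
  tree <- phalaris_tree()
  for (chname in names(mc$parsimony)) {
    states <- stats::setNames(as.character(mc$matrix[[chname]]), mc$matrix$tip)
    expect_identical(mc$parsimony[[chname]]$min_changes,
                     as.integer(brute_force_parsimony(tree, states)),
                     label = chname)
  }
})

test_that("character mapping propagates input errors", {
  expect_error(map_characters(read_newick("(A,B);")), "no karyotype")
})
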