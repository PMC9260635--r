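test_that("rooted and unrooted Newick are recognized and validated", {
  tr <- read_tree(text = "((A:1,B:1):1,C:2);", rooted = TRUE)
  expect_true(tree_is_rooted(tr))
  expect_equal(ape::Ntip(tr), 3L)
  expect_error(read_tree(text = "(A:1,B:1,C:1);", rooted = TRUE),
               "basal multifurcation")
  expect_error(read_tree(text = "((A:1,B:1):1,C:2);", rooted = FALSE),
               "unrooted")
  expect_error(read_tree(text = "((A:1,A:1):1,C:2);"), "duplicate")
  expect_warning(read_tree(text = "((A,B),C);", rooted = TRUE),
                 "branch lengths")
})

test_that("parse -> write -> parse round-trips topology and lengths", {
  set.seed(11)
  for (i in 1:100) {
    tr <- random_rooted_tree(sample(4:20, 1))
    tr2 <- read_tree(text = write_tree(tr), rooted = TRUE)
    b1 <- branch_bipartitions(tr)
    b2 <- branch_bipartitions(tr2)
    expect_setequal(names(b1), names(b2))
    expect_equal(sapply(b1, `[[`, "length")[names(b1)],
                 sapply(b2, `[[`, "length")[names(b1)], tolerance = 1e-12)
  }
})

test_that("bipartitions are canonical and symmetric in sides", {
  u <- c("A", "B", "C", "D")
  b1 <- bipartition(c("A", "B"), u)
  b2 <- bipartition(c("D", "C"), u)
  expect_identical(b1$key, b2$key)
  expect_true(b1 == b2)
  expect_identical(parse_bipartition(b1$key)$key, b1$key)
  expect_error(bipartition(u, u), "nonempty")
  expect_error(bipartition(c("A", "Z"), u), "not in the universe")
})

test_that("branch indexing matches hand enumeration and counts", {
  ## rooted 3-leaf tree: the root branch collapses with the external C branch
  tr <- read_tree(text = "((A:1,B:1):1,C:2);", rooted = TRUE)
  bb <- branch_bipartitions(tr)
  expect_setequal(names(bb), c("A|B,C", "A,C|B", "A,B|C"))
  expect_length(bb[["A,B|C"]]$edges, 2L)
  expect_true(bb[["A,B|C"]]$is_root_branch)

  ## star tree: external bipartitions only
  star <- validate_tree(ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);"))
  expect_length(branch_bipartitions(star), 5L)

  ## unrooted binary quartet: 4 external + 1 internal
  q <- read_tree(text = "((A:1,B:1):1,C:1,D:1);")
  expect_length(branch_bipartitions(q), 5L)

  ## rooted binary n-leaf tree indexes 2n-3 distinct branches
  set.seed(5)
  for (n in c(4, 7, 12)) {
    tr <- random_rooted_tree(n)
    expect_length(branch_bipartitions(tr), 2 * n - 3)
  }
})

test_that("exhaustive per-edge leaf collection agrees with branch indexing", {
  set.seed(21)
  tr <- random_rooted_tree(8)
  bb <- branch_bipartitions(tr)
  ## oracle: collect the leaf set below each edge by walking tip paths
  for (e in seq_len(nrow(tr$edge))) {
    below <- tr$tip.label[sapply(seq_len(ape::Ntip(tr)), function(tip) {
      node <- tip
      repeat {
        if (node == tr$edge[e, 2]) return(TRUE)
        up <- tr$edge[tr$edge[, 2] == node, 1]
        if (length(up) == 0) return(FALSE)
        node <- up
      }
    })]
    key <- bipartition(below, tr$tip.label)$key
    expect_true(key %in% names(bb))
    expect_true(e %in% bb[[key]]$edges)
  }
})

test_that("root bipartition is invariant under child rotation", {
  tr <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);", rooted = TRUE)
  expect_identical(root_bipartition(tr)$key, "A,B|C,D")
  rot <- read_tree(text = "((C:1,D:1):1,(A:1,B:1):1);", rooted = TRUE)
  expect_identical(root_bipartition(rot)$key, root_bipartition(tr)$key)
  tr3 <- read_tree(text = "((A:1,B:1):1,C:2);", rooted = TRUE)
  expect_identical(root_bipartition(tr3)$key, "A,B|C")
  expect_error(root_bipartition(read_tree(text = "(A:1,B:1,C:1);")),
               "not rooted")
})

test_that("rerooting preserves patristic distances and is invertible", {
  set.seed(31)
  for (i in 1:20) {
    tr <- random_rooted_tree(sample(4:12, 1))
    d0 <- patristic_distances(tr)
    orig <- current_root_placement(tr)
    keys <- names(branch_bipartitions(tr))
    for (j in 1:5) {
      pl <- root_placement(parse_bipartition(sample(keys, 1)), runif(1))
      rt <- reroot_at(tr, pl)
      expect_true(tree_is_rooted(rt))
      expect_equal(patristic_distances(rt), d0, tolerance = 1e-12)
      ## invert: back to the original placement
      back <- reroot_at(rt, orig)
      expect_identical(root_bipartition(back)$key, orig$branch$key)
      expect_equal(patristic_distances(back), d0, tolerance = 1e-12)
    }
  }
})

test_that("rerooting at the current placement reproduces the tree", {
  tr <- tree4()
  pl <- current_root_placement(tr)
  rt <- reroot_at(tr, pl)
  expect_identical(root_bipartition(rt)$key, root_bipartition(tr)$key)
  expect_setequal(names(branch_bipartitions(rt)), names(branch_bipartitions(tr)))
  expect_equal(patristic_distances(rt), patristic_distances(tr),
               tolerance = 1e-12)
  expect_equal(current_root_placement(rt)$fraction, pl$fraction,
               tolerance = 1e-9)
})

test_that("fraction endpoints give zero-length root half-branches", {
  tr <- tree4()
  keys <- names(branch_bipartitions(tr))
  for (f in c(0, 1)) {
    rt <- reroot_at(tr, root_placement(parse_bipartition(keys[2]), f))
    expect_true(tree_is_rooted(rt))
    root <- ape::Ntip(rt) + 1L
    half <- rt$edge.length[rt$edge[, 1] == root]
    expect_equal(min(half), 0)
    expect_equal(patristic_distances(rt), patristic_distances(tr),
                 tolerance = 1e-12)
  }
})

test_that("two-taxon trees reroot on their single branch", {
  tr <- read_tree(text = "(A:0.4,B:0.6);", rooted = TRUE)
  pl <- root_placement(bipartition("A", c("A", "B")), 0.25)
  rt <- reroot_at(tr, pl)
  expect_equal(sum(rt$edge.length), 1.0)
  expect_equal(current_root_placement(rt)$fraction, 0.25)
})

test_that("operations over mismatched taxon sets are refused", {
  tr <- tree4()
  other <- read_tree(text = "((A:1,B:1):1,(C:1,E:1):1);", rooted = TRUE)
  expect_error(reroot_at(tr, root_placement(root_bipartition(other), 0.5)),
               "taxon set")
  expect_error(rootstrap_support(tr, list(other)), "taxon set")
})
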