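test_that("rootstrap supports count replicate root branches exactly", {
  ml <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);", rooted = TRUE)

  ## all replicates rooted on the ML root branch
  rs <- rootstrap_support(ml, replicate(100, ml, simplify = FALSE))
  expect_equal(unname(rs$support["A,B|C,D"]), 1)
  expect_equal(sum(rs$support), 1)
  expect_equal(rs$unplaced_mass, 0)

  ## replicates rooted elsewhere are tallied per branch
  alt <- reroot_at(ml, root_placement("A|B,C,D", 0.5))
  rs2 <- rootstrap_support(ml, c(replicate(60, ml, simplify = FALSE),
                                 replicate(40, alt, simplify = FALSE)))
  expect_equal(unname(rs2$support["A,B|C,D"]), 0.6)
  expect_equal(unname(rs2$support["A|B,C,D"]), 0.4)

  ## a replicate whose root branch does not exist in the ML tree adds
  ## unplaced mass, so supports sum below one
  other_topo <- read_tree(text = "((A:1,C:1):1,(B:1,D:1):1);", rooted = TRUE)
  rs3 <- rootstrap_support(ml, c(replicate(75, ml, simplify = FALSE),
                                 replicate(25, other_topo, simplify = FALSE)))
  expect_lt(sum(rs3$support), 1)
  expect_equal(rs3$unplaced_mass, 0.25)
  expect_equal(sum(rs3$support) + rs3$unplaced_mass, 1)
  expect_error(rootstrap_support(ml, list()), "at least one")
})

test_that("rootstrap equals brute-force counting on mixed 5-taxon replicates", {
  set.seed(77)
  ml <- random_rooted_tree(5)
  keys <- names(branch_bipartitions(ml))
  reps <- lapply(1:10, function(i)
    reroot_at(ml, root_placement(parse_bipartition(sample(keys, 1)), runif(1))))
  rs <- rootstrap_support(ml, reps)
  ## oracle: exhaustive tally of root bipartition keys
  tally <- table(vapply(reps, function(t) root_bipartition(t)$key, character(1)))
  for (k in keys)
    expect_equal(unname(rs$support[k]),
                 if (k %in% names(tally)) unname(tally[[k]]) / 10 else 0)
  expect_equal(sum(rs$support) + rs$unplaced_mass, 1)
})

test_that("rootstrap of an internal branch never exceeds its bootstrap frequency", {
  set.seed(78)
  ml <- random_rooted_tree(6)
  keys <- names(branch_bipartitions(ml))
  ## replicates with varying topologies: random rerootings of ml plus trees
  ## from a different topology
  reps <- c(lapply(1:30, function(i)
              reroot_at(ml, root_placement(parse_bipartition(sample(keys, 1)), 0.5))),
            lapply(1:20, function(i) {
              t2 <- random_rooted_tree(6)
              t2$tip.label <- ml$tip.label[sample(6)]
              t2
            }))
  rs <- rootstrap_support(ml, reps)
  occur <- sapply(keys, function(k)
    mean(vapply(reps, function(t) k %in% names(branch_bipartitions(t)), logical(1))))
  expect_true(all(rs$support[keys] <= occur[keys] + 1e-12))
})

test_that("rSED counts splits between root branch and true branch", {
  ## same branch -> 0
  ml <- read_tree(text = "((A:1,B:1):1,(C:1,D:1):1);", rooted = TRUE)
  expect_identical(rsed(ml, "A,B|C,D"), 0L)
  ## adjacent branch -> 1
  expect_identical(rsed(ml, "A|B,C,D"), 1L)
  expect_identical(rsed(ml, "C|A,B,D"), 1L)
  expect_error(rsed(ml, "A,C|B,D"), "not found")
})

test_that("rSED matches the graph-search oracle on random 12-taxon trees", {
  skip_if_not_installed("igraph")
  set.seed(41)
  for (i in 1:20) {
    ml <- random_rooted_tree(12)
    ut <- ape::unroot(ml)
    bb <- branch_bipartitions(ut)
    rootk <- root_bipartition(ml)$key
    k <- sample(names(bb), 1)
    expected <- oracle_rsed(ut, bb[[rootk]]$edges[1], bb[[k]]$edges[1])
    expect_identical(rsed(ml, k), as.integer(expected))
    ## symmetry: measuring from the other branch gives the same count
    ml2 <- reroot_at(ml, root_placement(parse_bipartition(k), 0.5))
    expect_identical(rsed(ml2, rootk), rsed(ml, k))
  }
})

test_that("rBED is the distance range from the root point to the true branch", {
  ## same branch: 0 to the farther end (root at 0.3 / 0.7 from the ends)
  tr <- read_tree(text = "((A:1,B:1):0.3,(C:1,D:1):0.7);", rooted = TRUE)
  expect_equal(rbed(tr, "A,B|C,D"), c(min = 0, max = 0.7))

  ## true branch of length 0.2 with its near end 0.1 from the root point
  tr2 <- read_tree(text = "((A:0.2,B:1):0.1,(C:1,D:1):0.05);", rooted = TRUE)
  expect_equal(rbed(tr2, "A|B,C,D"), c(min = 0.1, max = 0.3))

  ## all branch lengths zero
  tr0 <- tr
  tr0$edge.length[] <- 0
  expect_equal(rbed(tr0, "A|B,C,D"), c(min = 0, max = 0))

  ## missing lengths refuse
  suppressWarnings(trm <- read_tree(text = "((A,B),(C,D));", rooted = TRUE))
  expect_error(rbed(trm, "A|B,C,D"), "branch lengths")
})

test_that("rBED agrees with the igraph path oracle on random trees", {
  skip_if_not_installed("igraph")
  set.seed(43)
  for (i in 1:20) {
    ml <- random_rooted_tree(12)
    bb <- branch_bipartitions(ml)
    k <- sample(names(bb), 1)
    got <- rbed(ml, k)
    expect_gte(got["max"], got["min"])
    expected <- oracle_rbed(ml, bb[[k]]$edges[1])
    expect_equal(unname(got), expected, tolerance = 1e-10)
    ## min = 0 exactly when the root point lies on the true branch
    expect_identical(unname(got["min"]) == 0,
                     k == root_bipartition(ml)$key)
  }
})

test_that("rSED and rBED vanish when the ML root branch is the true branch", {
  set.seed(44)
  for (i in 1:10) {
    ml <- random_rooted_tree(8)
    key <- root_bipartition(ml)$key
    expect_identical(rsed(ml, key), 0L)
    expect_equal(unname(rbed(ml, key)["min"]), 0)
  }
})

test_that("rooted topology counts follow the double factorial", {
  expect_equal(count_rooted_topologies(2), 1)
  expect_equal(count_rooted_topologies(3), 3)
  expect_equal(count_rooted_topologies(4), 15)
  expect_equal(count_rooted_topologies(5), 105)
  expect_error(count_rooted_topologies(1), ">= 2")
  ## growth: each new taxon multiplies the count by 2n-3
  for (n in 4:8)
    expect_equal(count_rooted_topologies(n) / count_rooted_topologies(n - 1),
                 2 * n - 3)
})

test_that("exhaustive enumeration confirms the rooted topology counts", {
  skip_if_not_installed("phytools")
  expect_equal(enumerate_rooted_topologies(3), 3)
  expect_equal(enumerate_rooted_topologies(4), 15)
  expect_equal(enumerate_rooted_topologies(5), 105)
})

test_that("random-root probabilities display at the conventional precision", {
  expect_equal(random_root_probability(4), 6.7)
  expect_equal(random_root_probability(5), 0.95)
  expect_equal(random_root_probability(2), 100)
  expect_equal(random_root_probability(4, digits = NULL), 100 / 15)
})

test_that("binomial test against 0.33 matches direct tail summation", {
  expect_equal(binomial_exceeds_onethird(0, 10), 1)
  ## oracle: direct upper-tail sum of Binomial(100, 0.33) at 33
  direct <- sum(choose(100, 33:100) * 0.33^(33:100) * 0.67^(100 - 33:100))
  expect_equal(binomial_exceeds_onethird(33, 100), direct, tolerance = 1e-12)
  ## monotone in successes
  p <- vapply(0:100, binomial_exceeds_onethird, numeric(1), n = 100)
  expect_true(all(diff(p) <= 0))
  expect_error(binomial_exceeds_onethird(5, 4), "successes")
})
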