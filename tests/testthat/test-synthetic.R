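test_that("scenario generation is reproducible byte for byte", {
  cfg <- scenario_config(n_taxa = 5, n_loci = 3, locus_length = 50, seed = 81)
  d1 <- file.path(tempdir(), "sc1"); d2 <- file.path(tempdir(), "sc2")
  generate_scenario(cfg, out_dir = d1)
  generate_scenario(cfg, out_dir = d2)
  for (f in c("aln.fasta", "tree.rooted.nwk", "loci.partitions", "truth.tsv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  ## emitted metadata records the configured distributions and bounds
  meta <- read.delim(file.path(d1, "scenario.meta.tsv"))
  expect_true(all(c("bl_mean", "rate_range", "nonrev_strength", "seed")
                  %in% meta$field))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the emitted files round-trip through the readers", {
  cfg <- scenario_config(n_taxa = 5, n_loci = 3, locus_length = 50, seed = 82)
  d <- file.path(tempdir(), "sc3")
  sc <- generate_scenario(cfg, out_dir = d)
  tr <- read_tree(file = file.path(d, "tree.rooted.nwk"), rooted = TRUE)
  expect_identical(root_bipartition(tr)$key, sc$truth$root_bipartition)
  aln <- read_alignment(file.path(d, "aln.fasta"))
  expect_identical(aln$states[rownames(sc$aln$states), ], sc$aln$states)
  parts <- read_partitions(file.path(d, "loci.partitions"))
  expect_equal(parts$start, sc$aln$partitions$start)
  unlink(d, recursive = TRUE)
})

test_that("the nonreversibility knob at zero yields detailed balance", {
  for (seed in 83:87) {
    cfg <- scenario_config(n_taxa = 4, n_loci = 1, locus_length = 10,
                           nonrev_strength = 0, seed = seed)
    sc <- generate_scenario(cfg)
    expect_true(is_reversible(sc$model, tol = 1e-8))
  }
})

test_that("invalid configurations are refused", {
  expect_error(scenario_config(n_taxa = 1), "at least 2")
  expect_error(scenario_config(n_loci = 0), "at least 1")
  expect_error(scenario_config(n_taxa = 6, tree_shape = "balanced"),
               "power-of-2")
})

test_that("simulated root-state frequencies follow the root distribution", {
  set.seed(88)
  m <- build_model(rexp(12), root_freqs = c(0.4, 0.3, 0.2, 0.1))
  tr <- read_tree(text = "(A:0.1,B:0.1);", rooted = TRUE)
  aln <- simulate_alignment(tr, m, 100000, seed = 88)
  emp <- tabulate(attr(aln, "root_states"), 4) / 100000
  expect_lt(max(abs(emp - m$root_freqs)), 0.01)
})

test_that("zero-length branches copy the root states to every leaf", {
  set.seed(89)
  tr <- random_rooted_tree(6)
  tr$edge.length[] <- 0
  m <- build_model(rexp(12))
  aln <- simulate_alignment(tr, m, 200, seed = 89)
  for (i in seq_len(6))
    expect_identical(unname(aln$states[i, ]), attr(aln, "root_states"))
})

test_that("leaf compositions drift from the root law toward stationarity", {
  set.seed(90)
  m <- build_model(rexp(12), root_freqs = c(0.9, 0.04, 0.03, 0.03))
  ## two-taxon chain: one near leaf, one far leaf
  tr <- read_tree(text = "(near:0.01,far:8);", rooted = TRUE)
  aln <- simulate_alignment(tr, m, 50000, seed = 90)
  emp_near <- tabulate(aln$states["near", ], 4) / 50000
  emp_far <- tabulate(aln$states["far", ], 4) / 50000
  d_near <- sum(abs(emp_near - m$root_freqs))
  d_far <- sum(abs(emp_far - m$root_freqs))
  expect_lt(d_near, d_far)
  expect_lt(sum(abs(emp_far - m$pi)), d_far)
})

test_that("locus subsampling nests, counts, and preserves identity", {
  cfg <- scenario_config(n_taxa = 4, n_loci = 40, locus_length = 10, seed = 91)
  sc <- generate_scenario(cfg)
  subs <- subsample_loci(sc$aln, fractions = c(1, 0.5, 0.1, 0.025), seed = 4)
  ## counts: ceiling(fraction * L), at least 1
  expect_equal(vapply(subs, function(a) nrow(a$partitions), integer(1)),
               c(40L, 20L, 4L, 1L), ignore_attr = TRUE)
  ## fraction 1 is the identity
  expect_identical(subs[[1]]$states, sc$aln$states)
  ## nesting: smaller fractions select subsets of larger ones
  l1 <- subs[[2]]$partitions$locus
  l2 <- subs[[3]]$partitions$locus
  l3 <- subs[[4]]$partitions$locus
  expect_true(all(l3 %in% l2) && all(l2 %in% l1))
  expect_error(subsample_loci(sc$aln, fractions = 0), "fractions")
})

test_that("parsimony-informative sites match a brute-force column scan", {
  ## fixed examples
  aln <- toy_aln(c(w = "aaca", x = "aacc", y = "acga", z = "acgc"))
  ## col1 all a (no); col2 a,a,c,c (yes); col3 c,c,g,g (yes); col4 a,c,a,c (yes)
  expect_equal(count_parsimony_informative(aln), 3)
  expect_equal(count_parsimony_informative(toy_aln(c(a = "aaaa", b = "aaaa",
                                                     c = "aaaa"))), 0)
  ## random alignments against an independent per-column tally
  set.seed(92)
  for (i in 1:5) {
    chars <- matrix(sample(c("a", "c", "g", "t", "-"), 200, TRUE), 5,
                    dimnames = list(letters[1:5], NULL))
    aln <- aln_block(chars)
    oracle <- sum(apply(chars, 2, function(col) {
      col <- col[col != "-"]
      sum(table(col) >= 2) >= 2
    }))
    expect_equal(count_parsimony_informative(aln), oracle)
  }
})

test_that("noiseless long alignments put the inferred root on the true branch", {
  ## with strong signal the truth record scores the search at zero error
  sc <- generate_scenario(scenario_config(n_taxa = 6, n_loci = 10,
                                          locus_length = 500, seed = 93))
  res <- ml_root_search(sc$tree, sc$aln)
  expect_identical(res$placement$branch$key, sc$truth$root_bipartition)
  expect_identical(rsed(res$rooted_tree, sc$truth$root_bipartition), 0L)
  expect_equal(unname(rbed(res$rooted_tree, sc$truth$root_bipartition)["min"]), 0)
})
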