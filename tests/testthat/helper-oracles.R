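## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: exhaustive enumeration, naive summation, and
## igraph-based graph search stand in for pruning, path walking, and
## counting.

## full-enumeration log-likelihood: sum over every assignment of states to
## internal nodes, transition probabilities taken straight from exp(Qt)
exhaustive_loglik <- function(tree, aln, model) {
  K <- length(model$alphabet)
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), length(internal))))
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) transition_matrix(model, tree$edge.length[e]))
  root <- ntip + 1L
  per_site <- numeric(ncol(aln$states))
  for (s in seq_len(ncol(aln$states))) {
    tipstate <- aln$states[tree$tip.label, s]
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      assign <- integer(ntip + tree$Nnode)
      assign[internal] <- grid[g, ]
      assign[seq_len(ntip)] <- tipstate
      pr <- model$root_freqs[assign[root]]
      for (e in seq_len(nrow(tree$edge))) {
        a <- assign[tree$edge[e, 1]]; b <- assign[tree$edge[e, 2]]
        pr <- pr * (if (b == 0) 1 else P[[e]][a, b])
      }
      tot <- tot + pr
    }
    per_site[s] <- log(tot)
  }
  per_site
}

## igraph-based root error oracles: split the two target edges with
## auxiliary vertices and read distances off the augmented graph
make_igraph <- function(tree) {
  g <- igraph::graph_from_edgelist(matrix(as.character(tree$edge), ncol = 2),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  g
}

## number of internal nodes strictly between two branches of a tree
oracle_rsed <- function(tree, edge_row1, edge_row2) {
  if (edge_row1 == edge_row2) return(0L)
  g <- make_igraph(tree)
  ends1 <- as.character(tree$edge[edge_row1, ])
  ends2 <- as.character(tree$edge[edge_row2, ])
  g <- igraph::add_vertices(g, 2, name = c("aux1", "aux2"))
  g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(ends1, ends2)))
  g <- igraph::add_edges(g, c(ends1[1], "aux1", "aux1", ends1[2],
                              ends2[1], "aux2", "aux2", ends2[2]),
                         weight = 1)
  path <- igraph::shortest_paths(g, "aux1", "aux2", weights = NA)$vpath[[1]]
  length(path) - 2L
}

## (min, max) branch-length distance from the root node to a target branch
oracle_rbed <- function(tree, edge_row) {
  root <- ape::Ntip(tree) + 1L
  g <- make_igraph(tree)
  d <- igraph::distances(g, v = as.character(root),
                         to = as.character(tree$edge[edge_row, ]))
  len <- tree$edge.length[edge_row]
  rb <- which(tree$edge[, 1] == root)
  if (edge_row %in% rb) {
    c(0, max(tree$edge.length[rb]))
  } else {
    c(min(d), min(d) + len)
  }
}

## enumerate all labeled rooted binary trees on n taxa by recursive tip
## insertion into every branch (plus a new root above everything)
enumerate_rooted_trees <- function(n) {
  labs <- letters[seq_len(n)]
  trees <- list(ape::read.tree(text = sprintf("(%s:1,%s:1);", labs[1], labs[2])))
  for (k in seq(3, length.out = max(0, n - 2))) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        node <- tr$edge[e, 2]
        nxt[[length(nxt) + 1]] <- phytools::bind.tip(
          tr, labs[k], edge.length = 1, where = node,
          position = tr$edge.length[e] / 2)
      }
      ## new root above the current root, by newick surgery
      nxt[[length(nxt) + 1]] <- ape::read.tree(
        text = sprintf("(%s:1,%s:1);", labs[k],
                       sub(";$", "", ape::write.tree(tr))))
    }
    trees <- nxt
  }
  trees
}

## count the distinct rooted topologies among them
enumerate_rooted_topologies <- function(n) {
  sigs <- vapply(enumerate_rooted_trees(n), function(tr) {
    keys <- sort(names(branch_bipartitions(tr)))
    paste(c(root_bipartition(tr)$key, "::", keys), collapse = ";")
  }, character(1))
  length(unique(sigs))
}

## a random rooted binary tree with exponential branch lengths
random_rooted_tree <- function(n, bl_mean = 0.1) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / bl_mean)
  tr
}

## quick fixed 4-taxon rooted tree
tree4 <- function(lens = c(0.3, 0.1, 0.2, 0.15, 0.25, 0.12)) {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tr$edge.length <- lens
  tr
}

## small deterministic alignment over given taxa
toy_aln <- function(seqs) aln_block(do.call(rbind, strsplit(seqs, "")))
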