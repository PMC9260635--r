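#' Rootstrap support for every branch of the ML tree
#'
#' The rootstrap support of a branch is the proportion of bootstrap
#' replicate trees whose root lies on that branch, where a replicate "has
#' the root on" a branch of the ML tree exactly when its root bipartition
#' equals that branch's bipartition. Supports are computed for all branches,
#' external ones included: under a nonreversible model the root can be on
#' any branch. Replicates whose root bipartition matches no branch of the
#' ML tree (their root branch does not exist in the ML topology) contribute
#' to `unplaced_mass`, so the supports sum to at most 1.
#'
#' @param ml_tree the rooted ML tree (`phylo`).
#' @param bootstrap_trees list of rooted replicate trees over the same
#'   taxon set.
#' @return object of class `rootstrap_result`: `support` (named numeric,
#'   one entry per ML branch, keyed by bipartition), `unplaced_mass`,
#'   `unplaced_by_branch` (named counts of unmatched root bipartitions),
#'   `n_replicates`.
#' @export
rootstrap_support <- function(ml_tree, bootstrap_trees) {
  if (inherits(bootstrap_trees, "phylo")) bootstrap_trees <- list(bootstrap_trees)
  if (length(bootstrap_trees) == 0L) stop("need at least one bootstrap tree")
  taxa <- sort(ml_tree$tip.label)
  bb <- branch_bipartitions(ml_tree)
  counts <- stats::setNames(integer(length(bb)), names(bb))
  unplaced <- integer(0)
  for (bt in bootstrap_trees) {
    if (!setequal(bt$tip.label, taxa))
      stop("bootstrap tree taxon set differs from the ML tree")
    key <- root_bipartition(bt)$key
    if (key %in% names(counts)) {
      counts[key] <- counts[key] + 1L
    } else {
      unplaced[key] <- if (key %in% names(unplaced)) unplaced[key] + 1L else 1L
    }
  }
  B <- length(bootstrap_trees)
  structure(list(
    support = counts / B,
    counts = counts,
    unplaced_mass = sum(unplaced) / B,
    unplaced_by_branch = unplaced / B,
    n_replicates = B,
    ml_root_key = root_bipartition(ml_tree)$key
  ), class = "rootstrap_result")
}

#' @export
print.rootstrap_result <- function(x, ...) {
  cat("Rootstrap support over", x$n_replicates, "bootstrap replicates\n")
  sup <- sort(x$support[x$support > 0], decreasing = TRUE)
  for (k in names(sup)) {
    mark <- if (k == x$ml_root_key) " (ML root branch)" else ""
    cat(sprintf("  %5.1f%%  %s%s\n", 100 * sup[k], k, mark))
  }
  if (x$unplaced_mass > 0)
    cat(sprintf("  %5.1f%%  [root branch absent from the ML tree]\n",
                100 * x$unplaced_mass))
  invisible(x)
}

## adjacency list over node ids of a phylo
tree_adjacency <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

## breadth-first edge-count distances from a node
bfs_distances <- function(adj, from) {
  n <- length(adj)
  d <- rep(NA_integer_, n)
  d[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; queue <- c(queue, w) }
  }
  d
}

#' Root split error distance (rSED)
#'
#' The number of splits (internal nodes) strictly between the ML root
#' branch and the branch believed to contain the true root, on the unrooted
#' version of the ML topology. Zero when the true root branch is the ML
#' root branch; adjacent branches (sharing a node) are one split apart.
#'
#' @param ml_tree rooted ML tree.
#' @param true_root_branch a `bipartition` (or key string) that must be a
#'   branch of the tree.
#' @return nonnegative integer.
#' @export
rsed <- function(ml_tree, true_root_branch) {
  if (is.character(true_root_branch)) true_root_branch <- parse_bipartition(true_root_branch)
  rb <- root_bipartition(ml_tree)
  if (rb$key == true_root_branch$key) return(0L)
  ut <- if (ape::Ntip(ml_tree) > 2L) ape::unroot(ml_tree) else ml_tree
  bb <- branch_bipartitions(ut)
  e1 <- bb[[rb$key]]; e2 <- bb[[true_root_branch$key]]
  if (is.null(e2)) stop("branch not found in tree: ", true_root_branch$key)
  adj <- tree_adjacency(ut)
  ends1 <- ut$edge[e1$edges[1], ]; ends2 <- ut$edge[e2$edges[1], ]
  best <- Inf
  for (u in ends1) {
    d <- bfs_distances(adj, u)
    best <- min(best, d[ends2])
  }
  as.integer(best + 1L)
}

#' Root branch-length error distance (rBED)
#'
#' The range (minimum, maximum) of path-length distances, in substitutions
#' per site, between the inferred root position (a point on a branch) and
#' the branch believed to contain the true root. When the true root branch
#' is the ML root branch itself the minimum is 0 and the maximum is the
#' distance from the root point to the farther end of that branch;
#' otherwise the minimum is the distance to the nearer end of the true
#' branch and the maximum exceeds it by that branch's length.
#'
#' @inheritParams rsed
#' @return named numeric vector `c(min = , max = )`.
#' @export
rbed <- function(ml_tree, true_root_branch) {
  if (is.character(true_root_branch)) true_root_branch <- parse_bipartition(true_root_branch)
  if (isTRUE(attr(ml_tree, "missing_lengths")))
    stop("rBED requires branch lengths")
  rb <- root_bipartition(ml_tree)
  root <- root_node(ml_tree)
  idx <- which(ml_tree$edge[, 1] == root)
  half <- ml_tree$edge.length[idx]
  if (rb$key == true_root_branch$key)
    return(c(min = 0, max = max(half)))
  entry <- find_branch(ml_tree, true_root_branch)
  k <- entry$edges[1]
  D <- ape::dist.nodes(ml_tree)
  dmin <- min(D[root, ml_tree$edge[k, 1]], D[root, ml_tree$edge[k, 2]])
  c(min = dmin, max = dmin + entry$length)
}

#' Number of labeled rooted binary tree topologies
#'
#' The count of distinct labeled rooted binary topologies on `n` taxa, the
#' double factorial (2n-3)!!. Four taxa admit 15 rooted topologies, five
#' taxa 105.
#'
#' @param n_taxa integer >= 2.
#' @export
count_rooted_topologies <- function(n_taxa) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa != round(n_taxa) || n_taxa < 2)
    stop("n_taxa must be a single integer >= 2")
  if (n_taxa == 2) return(1)
  prod(seq(1, 2 * n_taxa - 3, by = 2))
}

#' Probability of a particular root position arising by chance
#'
#' If a rooted topology were drawn uniformly at random, any particular
#' rooted topology (hence any particular root position on it) has
#' probability `1 / count_rooted_topologies(n)`. Reported as a percentage,
#' rounded to two significant digits for display (6.7% for four taxa,
#' 0.95% for five).
#'
#' @param n_taxa integer >= 2.
#' @param digits significant digits for display rounding; `NULL` for the
#'   exact value.
#' @export
random_root_probability <- function(n_taxa, digits = 2) {
  p <- 100 / count_rooted_topologies(n_taxa)
  if (is.null(digits)) p else signif(p, digits)
}

#' One-sided exact binomial test against a success probability of 0.33
#'
#' Used to decide whether a concordance-factor-style proportion is
#' significantly greater than the one-in-three value expected when the
#' three resolutions around a branch are equally supported. The null
#' success probability is 0.33 (as conventionally quoted), not 1/3.
#'
#' @param successes number of successes.
#' @param n number of trials.
#' @return the one-sided p-value `P[X >= successes]` under
#'   `Binomial(n, 0.33)`.
#' @export
binomial_exceeds_onethird <- function(successes, n) {
  if (successes < 0 || n < 1 || successes > n)
    stop("need 0 <= successes <= n, n >= 1")
  stats::binom.test(successes, n, p = 0.33, alternative = "greater")$p.value
}
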