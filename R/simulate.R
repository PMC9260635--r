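#' Simulate an alignment along a rooted tree
#'
#' Root states are drawn from the model's root frequencies; states then
#' evolve down each branch with the transition probabilities
#' `P(t) = exp(Qt)`. Deterministic given `seed`.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param model a `nonrev_model`.
#' @param n_sites number of alignment columns, `>= 1`.
#' @param seed optional integer seed.
#' @return an `aln_block` over the tree's leaves.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = NULL) {
  if (!tree_is_rooted(tree)) stop("tree must be rooted")
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  K <- length(model$alphabet)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  states <- matrix(0L, nnode, n_sites)
  root <- root_node(tree)
  states[root, ] <- sample.int(K, n_sites, replace = TRUE, prob = model$root_freqs)
  pre <- ape::reorder.phylo(tree, "cladewise")    # parents before children
  for (e in seq_len(nrow(pre$edge))) {
    parent <- pre$edge[e, 1]; child <- pre$edge[e, 2]
    P <- transition_matrix(model, pre$edge.length[e])
    ps <- states[parent, ]
    cs <- integer(n_sites)
    for (k in seq_len(K)) {
      at <- which(ps == k)
      if (length(at))
        cs[at] <- sample.int(K, length(at), replace = TRUE, prob = P[k, ])
    }
    states[child, ] <- cs
  }
  tip_states <- states[seq_len(ntip), , drop = FALSE]
  rownames(tip_states) <- tree$tip.label
  obj <- structure(list(states = tip_states, alphabet = model$alphabet,
                        partitions = NULL), class = "aln_block")
  attr(obj, "root_states") <- states[root, ]
  obj
}
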