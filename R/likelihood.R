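#' Log-likelihood of an alignment on a rooted tree
#'
#' Felsenstein pruning with per-pattern rescaling, evaluated at the root
#' with the model's root-state frequencies. Because the model may be
#' nonreversible, the value depends on where the root is placed — the
#' property the whole rooting method rests on. Gaps and ambiguity codes are
#' treated as fully missing (conditional likelihood 1 for every state).
#'
#' @param tree rooted `phylo`; its leaves must all appear in the alignment.
#' @param aln an `aln_block`.
#' @param model a `nonrev_model` over the same alphabet.
#' @return list with `total` (log-likelihood), `per_site` (numeric vector,
#'   one entry per alignment column; sums to `total`), `per_pattern` and
#'   `weights` (the compressed view).
#' @export
rooted_log_likelihood <- function(tree, aln, model) {
  if (!tree_is_rooted(tree)) stop("tree must be rooted (degree-2 root)")
  cp <- compress_patterns(aln, taxa = tree$tip.label)
  pp <- peel_patterns(tree, cp$patterns, model)
  list(total = sum(pp * cp$weights),
       per_site = pp[cp$site_index],
       per_pattern = pp,
       weights = cp$weights)
}

## pruning over an already-compressed pattern matrix (rows in tree tip order)
peel_patterns <- function(tree, patterns, model, lengths = NULL) {
  po <- ape::reorder.phylo(tree, "postorder")
  if (is.null(lengths)) lengths <- po$edge.length
  peel_loglik_cpp(po$edge, lengths, patterns, model$Q, model$root_freqs,
                  ape::Ntip(tree) + tree$Nnode, root_node(tree))
}

## weighted total log-likelihood, the optimizer's objective
peel_total <- function(tree, patterns, weights, model, lengths = NULL) {
  sum(peel_patterns(tree, patterns, model, lengths) * weights)
}
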