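#' Read a phylogenetic tree from Newick
#'
#' Parses a Newick string or file into an \code{ape::phylo} object and
#' validates it for use with the rooting machinery: leaf labels must be
#' unique, branch lengths must be nonnegative, and (optionally) the tree
#' must carry a degree-2 root. Branch lengths absent from the Newick are set
#' to 0 with a warning, so topology-only bootstrap files remain usable for
#' rootstrap and rSED computations (which need no lengths).
#'
#' @param text Newick string (one tree). Exactly one of `text`/`file`.
#' @param file path to a Newick file containing a single tree.
#' @param rooted if `TRUE`, require a degree-2 root (a basal polytomy is an
#'   error); if `FALSE`, require an unrooted tree; if `NA` (default), accept
#'   either.
#' @return a validated `phylo` object. The attribute `"missing_lengths"` is
#'   `TRUE` when branch lengths were absent from the input.
#' @export
read_tree <- function(text = NULL, file = NULL, rooted = NA) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tr <- if (!is.null(text)) {
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  } else {
    tryCatch(ape::read.tree(file = file),
             error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  }
  if (is.null(tr)) stop("Newick parse error: no tree found in input")
  if (inherits(tr, "multiPhylo")) stop("input contains more than one tree; use read_trees()")
  validate_tree(tr, rooted = rooted)
}

#' Read a list of trees (one Newick per line)
#'
#' @inheritParams read_tree
#' @return a list of validated `phylo` objects.
#' @export
read_trees <- function(file, rooted = NA) {
  trs <- tryCatch(ape::read.tree(file = file),
                  error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(trs)) stop("no trees found in ", file)
  if (inherits(trs, "phylo")) trs <- list(trs)
  lapply(trs, validate_tree, rooted = rooted)
}

#' Write a tree (or trees) as Newick
#'
#' @param tree a `phylo` object or list of them.
#' @param file output path; when `NULL`, the Newick string(s) are returned.
#' @export
write_tree <- function(tree, file = NULL) {
  if (inherits(tree, "phylo")) tree <- list(tree)
  txt <- vapply(tree, function(t) ape::write.tree(t, digits = 15), character(1))
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

validate_tree <- function(tr, rooted = NA) {
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  missing_lengths <- FALSE
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
    missing_lengths <- TRUE
  } else if (anyNA(tr$edge.length)) {
    warning("tree has missing branch lengths; defaulting them to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
    missing_lengths <- TRUE
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (isTRUE(rooted) && !tree_is_rooted(tr))
    stop("expected a rooted tree (degree-2 root), got a basal multifurcation")
  if (isFALSE(rooted) && tree_is_rooted(tr))
    stop("expected an unrooted tree, got a degree-2 root")
  attr(tr, "missing_lengths") <- missing_lengths
  tr
}

#' Is the tree rooted (degree-2 root node)?
#' @param tree a `phylo` object.
#' @export
tree_is_rooted <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  sum(tree$edge[, 1] == root) == 2L
}

root_node <- function(tree) ape::Ntip(tree) + 1L

## tip sets below every node, one postorder pass; returns list indexed by node id
node_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

#' Construct a canonical bipartition of a taxon set
#'
#' A bipartition (split) is the pair of complementary taxon subsets induced
#' by removing a branch; it is the identity of a branch across trees. The
#' stored form is canonical: the side whose sorted, comma-joined label string
#' is lexicographically smaller is the key side, so the same object results
#' whichever side is supplied.
#'
#' @param side character vector of taxon labels on one side of the split.
#' @param universe character vector of all taxon labels in the tree.
#' @return an object of class `bipartition` with elements `side`, `other`,
#'   `key` (string `"side|other"` with each side sorted and comma-joined).
#' @export
bipartition <- function(side, universe) {
  universe <- sort(unique(universe))
  side <- sort(unique(side))
  if (!all(side %in% universe)) stop("side contains taxa not in the universe")
  other <- setdiff(universe, side)
  if (length(side) == 0L || length(other) == 0L)
    stop("both sides of a bipartition must be nonempty")
  a <- paste(side, collapse = ","); b <- paste(other, collapse = ",")
  if (b < a) { tmp <- side; side <- other; other <- tmp; tmp <- a; a <- b; b <- tmp }
  structure(list(side = side, other = other, key = paste(a, b, sep = "|")),
            class = "bipartition")
}

#' @export
print.bipartition <- function(x, ...) {
  cat("<bipartition> ", x$key, "\n", sep = "")
  invisible(x)
}

#' @export
`==.bipartition` <- function(e1, e2) e1$key == e2$key

#' Parse a bipartition key string such as `"A,B|C,D"`
#' @param key string with the two sides separated by `|`, taxa by commas.
#' @export
parse_bipartition <- function(key) {
  sides <- strsplit(key, "|", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("bipartition key must have two sides separated by '|'")
  a <- strsplit(sides[1], ",", fixed = TRUE)[[1]]
  b <- strsplit(sides[2], ",", fixed = TRUE)[[1]]
  bipartition(a, c(a, b))
}

#' All branch bipartitions of a tree
#'
#' Indexes every branch (external branches included) by its canonical
#' bipartition. In a rooted tree the two branches incident to the degree-2
#' root describe the same split of the taxa and are collapsed into a single
#' "root branch" entry whose length is the sum of the two half-branches, so
#' a rooted binary tree with n leaves yields 2n-3 distinct keys.
#'
#' @param tree a `phylo` object with at least 2 leaves.
#' @return named list keyed by bipartition key; each element has `bip`,
#'   `edges` (row indices into `tree$edge`), `length` (total branch length),
#'   `is_root_branch`.
#' @export
branch_bipartitions <- function(tree) {
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 leaves")
  universe <- sort(tree$tip.label)
  sets <- node_tip_sets(tree)
  rooted <- tree_is_rooted(tree)
  root <- root_node(tree)
  out <- list()
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2]
    bp <- bipartition(sets[[ch]], universe)
    len <- tree$edge.length[k]
    if (!is.null(out[[bp$key]])) {
      out[[bp$key]]$edges <- c(out[[bp$key]]$edges, k)
      out[[bp$key]]$length <- out[[bp$key]]$length + len
    } else {
      out[[bp$key]] <- list(bip = bp, edges = k, length = len,
                            is_root_branch = FALSE)
    }
  }
  if (rooted) {
    rb <- root_bipartition(tree)
    out[[rb$key]]$is_root_branch <- TRUE
  }
  out
}

#' The bipartition of the root branch of a rooted tree
#'
#' The split between the taxa under the root's two children: the branch of
#' the unrooted topology on which the root lies.
#'
#' @param tree a rooted `phylo`.
#' @export
root_bipartition <- function(tree) {
  if (!tree_is_rooted(tree))
    stop("tree is not rooted (no degree-2 root)")
  root <- root_node(tree)
  ch <- tree$edge[tree$edge[, 1] == root, 2]
  sets <- node_tip_sets(tree)
  bipartition(sets[[ch[1]]], sort(tree$tip.label))
}

#' Describe a root placement: a branch plus a position along it
#'
#' @param branch a `bipartition` (or key string) identifying the branch.
#' @param fraction position of the root along the branch in `[0, 1]`,
#'   measured from the end adjacent to the canonical (key) side.
#' @export
root_placement <- function(branch, fraction = 0.5) {
  if (is.character(branch)) branch <- parse_bipartition(branch)
  stopifnot(inherits(branch, "bipartition"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  structure(list(branch = branch, fraction = fraction), class = "root_placement")
}

#' @export
print.root_placement <- function(x, ...) {
  cat("<root placement> branch ", x$branch$key,
      sprintf(", fraction %.4g\n", x$fraction), sep = "")
  invisible(x)
}

#' Extract the current root placement of a rooted tree
#'
#' The branch is the root bipartition; the fraction is the root's position
#' along the (collapsed) root branch, measured from the canonical side.
#' @param tree a rooted `phylo`.
#' @export
current_root_placement <- function(tree) {
  bp <- root_bipartition(tree)
  root <- root_node(tree)
  idx <- which(tree$edge[, 1] == root)
  ch <- tree$edge[idx, 2]
  sets <- node_tip_sets(tree)
  side1 <- sort(sets[[ch[1]]])
  ## half-branch on the canonical side has length f * total
  len1 <- tree$edge.length[idx[1]]; len2 <- tree$edge.length[idx[2]]
  total <- len1 + len2
  on_canon <- identical(side1, bp$side)
  f <- if (total == 0) 0.5 else if (on_canon) len1 / total else len2 / total
  root_placement(bp, f)
}

#' Re-root a tree at a point along a branch
#'
#' Places a new degree-2 root on the branch identified by
#' `placement$branch`, splitting it at `placement$fraction` (measured from
#' the end adjacent to the canonical side). Patristic distances between
#' leaves are preserved. A fraction of 0 or 1 yields a zero-length root
#' half-branch, which is permitted.
#'
#' @param tree a `phylo` (rooted trees are unrooted first, collapsing the
#'   old degree-2 root).
#' @param placement a `root_placement`, or a `bipartition`/key string (then
#'   rooted at `fraction`).
#' @param fraction used when `placement` is not a `root_placement`.
#' @return a rooted `phylo`.
#' @export
reroot_at <- function(tree, placement, fraction = 0.5) {
  if (!inherits(placement, "root_placement"))
    placement <- root_placement(placement, fraction)
  ntip <- ape::Ntip(tree)
  if (!setequal(c(placement$branch$side, placement$branch$other), tree$tip.label))
    stop("placement refers to a different taxon set than the tree")
  if (ntip == 2L) return(reroot_two_taxon(tree, placement))
  ut <- if (tree_is_rooted(tree)) ape::unroot(tree) else tree
  bb <- branch_bipartitions(ut)
  entry <- bb[[placement$branch$key]]
  if (is.null(entry))
    stop("branch not found in tree: ", placement$branch$key)
  k <- entry$edges[1]
  child <- ut$edge[k, 2]
  len <- ut$edge.length[k]
  sets <- node_tip_sets(ut)
  child_is_canon <- identical(sort(sets[[child]]), placement$branch$side)
  f <- placement$fraction
  ## phytools position = length of the new root-to-parent half-branch
  pos <- if (child_is_canon) (1 - f) * len else f * len
  eps <- if (len > 0) min(len * 1e-8, len / 2) else 0
  pos_safe <- min(max(pos, eps), len - eps)
  rt <- phytools::reroot(ut, child, position = pos_safe)
  ## phytools can lose precision (and the endpoint clamp perturbs the two
  ## root half-branches): restore every edge length exactly from the source
  ## tree's bipartition map, and split the target branch at exactly f
  root <- root_node(rt)
  idx <- which(rt$edge[, 1] == root)
  rsets <- node_tip_sets(rt)
  for (i in seq_len(nrow(rt$edge))) {
    ch_side <- sort(rsets[[rt$edge[i, 2]]])
    key <- bipartition(ch_side, sort(rt$tip.label))$key
    rt$edge.length[i] <- if (i %in% idx && key == placement$branch$key) {
      if (identical(ch_side, placement$branch$side)) f * len else (1 - f) * len
    } else bb[[key]]$length
  }
  attr(rt, "missing_lengths") <- attr(tree, "missing_lengths")
  rt
}

reroot_two_taxon <- function(tree, placement) {
  labs <- tree$tip.label
  total <- sum(tree$edge.length)
  f <- placement$fraction
  canon_first <- placement$branch$side[1]
  other <- setdiff(labs, canon_first)
  str <- sprintf("(%s:%.12g,%s:%.12g);", canon_first, f * total,
                 other, (1 - f) * total)
  validate_tree(ape::read.tree(text = str), rooted = TRUE)
}

#' Patristic (path-length) distances between all leaf pairs
#' @param tree a `phylo` with branch lengths.
#' @return symmetric matrix with leaf labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[sort(rownames(d)), sort(colnames(d))]
}

## locate a bipartition among the branches of a tree; error when absent
find_branch <- function(tree, bip) {
  bb <- branch_bipartitions(tree)
  entry <- bb[[bip$key]]
  if (is.null(entry)) stop("branch not found in tree: ", bip$key)
  entry
}
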