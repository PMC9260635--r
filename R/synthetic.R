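## Synthetic-data generator: rooted trees, nonreversible models, and
## partitioned alignments with a recorded truth, so root-recovery and
## rootstrap experiments run end to end without any external data.

#' Configuration for a synthetic rooting scenario
#'
#' @param n_taxa number of leaves (default 8).
#' @param tree_shape `"random"` (successive random attachment of tips to a
#'   uniformly chosen branch) or `"balanced"` (requires a power of 2).
#' @param bl_mean mean of the exponential branch-length distribution, in
#'   substitutions/site (default 0.1).
#' @param rate_range log-uniform sampling range for off-diagonal rates.
#' @param nonrev_strength 0..1; 0 gives a detailed-balance (reversible)
#'   model, 1 a free nonreversible one (see [sample_model()]).
#' @param n_loci,locus_length partition structure of the alignment
#'   (default 100 loci of 500 sites).
#' @param seed integer seed; the same config and seed give identical
#'   output, byte for byte.
#' @export
scenario_config <- function(n_taxa = 8, tree_shape = c("random", "balanced"),
                            bl_mean = 0.1, rate_range = c(0.1, 10),
                            nonrev_strength = 1, n_loci = 100,
                            locus_length = 500, seed = 1) {
  tree_shape <- match.arg(tree_shape)
  if (n_taxa < 2) stop("need at least 2 taxa")
  if (n_loci < 1 || locus_length < 1) stop("need at least 1 locus of 1 site")
  if (tree_shape == "balanced" && bitwAnd(n_taxa, n_taxa - 1L) != 0)
    stop("balanced shape requires a power-of-2 taxon count")
  structure(list(n_taxa = n_taxa, tree_shape = tree_shape, bl_mean = bl_mean,
                 rate_range = rate_range, nonrev_strength = nonrev_strength,
                 n_loci = n_loci, locus_length = locus_length, seed = seed),
            class = "scenario_config")
}

## rooted random topology by successive random attachment; all branch
## lengths then redrawn i.i.d. exponential(mean)
sample_rooted_tree <- function(n_taxa, shape = "random", bl_mean = 0.1) {
  labs <- sprintf("t%d", seq_len(n_taxa))
  if (shape == "balanced") {
    tr <- ape::stree(n_taxa, type = "balanced")
    tr$tip.label <- labs
    tr$edge.length <- rep(1, nrow(tr$edge))
  } else {
    tr <- ape::read.tree(text = sprintf("(%s:1,%s:1);", labs[1], labs[2]))
    for (k in seq(3, length.out = max(0, n_taxa - 2))) {
      edge <- sample.int(nrow(tr$edge), 1)
      node <- tr$edge[edge, 2]
      tr <- phytools::bind.tip(tr, labs[k], edge.length = 1,
                               where = node,
                               position = tr$edge.length[edge] / 2)
    }
  }
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / bl_mean)
  validate_tree(tr, rooted = TRUE)
}

#' Generate a synthetic rooting scenario
#'
#' Draws a rooted tree, a substitution model of the configured
#' nonreversibility, and a partitioned alignment evolved from the root, and
#' returns them together with a truth record (true root bipartition and
#' model) for downstream scoring with [rbed()], [rsed()], and
#' [rootstrap_support()]. When `out_dir` is given, writes
#' `tree.rooted.nwk`, `aln.fasta`, `loci.partitions`, `truth.tsv`, and
#' `scenario.meta.tsv` (the sampled distributions and bounds).
#'
#' @param config a [scenario_config()].
#' @param out_dir optional output directory.
#' @return list: `tree` (rooted `phylo`), `model` (`nonrev_model`), `aln`
#'   (partitioned `aln_block`), `truth` (list: `root_bipartition` key,
#'   `fraction`, `rates`, `pi`, `root_freqs`).
#' @export
generate_scenario <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  tree <- sample_rooted_tree(config$n_taxa, config$tree_shape, config$bl_mean)
  model <- sample_model(config$nonrev_strength, config$rate_range)
  nsites <- config$n_loci * config$locus_length
  aln <- simulate_alignment(tree, model, nsites)
  parts <- data.frame(
    locus = sprintf("locus%03d", seq_len(config$n_loci)),
    start = (seq_len(config$n_loci) - 1L) * config$locus_length + 1L,
    end = seq_len(config$n_loci) * config$locus_length)
  aln <- set_partitions(aln, parts)
  pl <- current_root_placement(tree)
  truth <- list(root_bipartition = pl$branch$key, fraction = pl$fraction,
                rates = model$rates, pi = model$pi,
                root_freqs = model$root_freqs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tree(tree, file.path(out_dir, "tree.rooted.nwk"))
    write_alignment(aln, file.path(out_dir, "aln.fasta"))
    write_partitions(parts, file.path(out_dir, "loci.partitions"))
    tv <- data.frame(
      field = c("root_bipartition", "root_fraction",
                paste0("rate_", rate_names(model$alphabet)),
                paste0("pi_", model$alphabet),
                paste0("root_freq_", model$alphabet)),
      value = c(truth$root_bipartition, format(truth$fraction, digits = 12),
                format(truth$rates, digits = 12),
                format(truth$pi, digits = 12),
                format(truth$root_freqs, digits = 12)))
    utils::write.table(tv, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    meta <- data.frame(field = names(config),
                       value = vapply(config, function(v)
                         paste(format(v), collapse = ","), character(1)))
    utils::write.table(meta, file.path(out_dir, "scenario.meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(tree = tree, model = model, aln = aln, truth = truth)
}

#' Extract a subset of loci as a new alignment
#' @param aln a partitioned `aln_block`.
#' @param loci locus names or indices to keep (original order preserved).
#' @export
subset_loci <- function(aln, loci) {
  parts <- aln$partitions
  if (is.null(parts)) stop("alignment has no partition map")
  keep <- if (is.character(loci)) match(loci, parts$locus) else as.integer(loci)
  if (anyNA(keep)) stop("unknown loci requested")
  keep <- sort(keep)
  sites <- unlist(lapply(keep, function(r) parts$start[r]:parts$end[r]))
  newp <- parts[keep, , drop = FALSE]
  len <- newp$end - newp$start + 1L
  newp$end <- cumsum(len)
  newp$start <- newp$end - len + 1L
  obj <- structure(list(states = aln$states[, sites, drop = FALSE],
                        alphabet = aln$alphabet, partitions = NULL),
                   class = "aln_block")
  set_partitions(obj, newp)
}

#' Random locus subsamples at nested fractions
#'
#' Draws one random permutation of the loci and takes the first
#' `ceiling(fraction * L)` (at least one) for each requested fraction, so
#' subsamples derived from one seed nest: the 0.1% set is contained in the
#' 1% set, which is contained in the 10% set.
#'
#' @param aln a partitioned `aln_block`.
#' @param fractions numeric fractions in (0, 1] (default
#'   `c(1, 0.1, 0.01, 0.001)`).
#' @param seed integer seed.
#' @return named list of `aln_block`s, one per fraction.
#' @export
subsample_loci <- function(aln, fractions = c(1, 0.1, 0.01, 0.001), seed = 1) {
  parts <- aln$partitions
  if (is.null(parts) || nrow(parts) == 0) stop("alignment has no partition map")
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  L <- nrow(parts)
  set.seed(seed)
  perm <- sample.int(L)
  out <- lapply(fractions, function(f) {
    m <- max(1L, ceiling(f * L))
    subset_loci(aln, sort(perm[seq_len(m)]))
  })
  names(out) <- format(fractions)
  out
}

#' Number of parsimony-informative sites
#'
#' Counts alignment columns with at least two distinct states each present
#' in at least two sequences; gaps and ambiguities do not count as states.
#'
#' @param aln an `aln_block`.
#' @export
count_parsimony_informative <- function(aln) {
  K <- length(aln$alphabet)
  sum(apply(aln$states, 2, function(col) {
    tab <- tabulate(col[col > 0L], nbins = K)
    sum(tab >= 2L) >= 2L
  }))
}
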