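## Matched-pairs symmetry testing and locus filtering. Nonreversible models
## relax reversibility but still assume stationarity and homogeneity; loci
## that violate those assumptions (e.g. compositional drift between
## lineages) show asymmetric pairwise substitution-pattern counts and can
## be removed before rooting.

#' Pairwise site-pattern count matrix for two aligned sequences
#'
#' Entry (i, j) counts alignment columns where the first sequence shows
#' state i and the second state j. Columns with a gap or ambiguity in
#' either sequence are excluded, since matched-pairs tests require resolved
#' states.
#'
#' @param aln an `aln_block`.
#' @param pair two taxon labels (or indices).
#' @param sites optional site indices restricting the count (e.g. a locus).
#' @return K x K integer matrix with the alphabet as dimnames.
#' @export
pair_counts <- function(aln, pair, sites = NULL) {
  if (length(pair) != 2) stop("pair must name exactly two sequences")
  x <- aln$states[pair[1], ]; y <- aln$states[pair[2], ]
  if (!is.null(sites)) { x <- x[sites]; y <- y[sites] }
  ok <- x > 0L & y > 0L
  K <- length(aln$alphabet)
  m <- matrix(0L, K, K, dimnames = list(aln$alphabet, aln$alphabet))
  if (any(ok)) {
    tab <- table(factor(x[ok], levels = seq_len(K)),
                 factor(y[ok], levels = seq_len(K)))
    m[] <- as.integer(tab)
  }
  m
}

#' Matched-pairs test of symmetry (Bowker's test)
#'
#' Tests the hypothesis that the joint substitution-pattern matrix of a
#' sequence pair is symmetric — the condition a stationary, homogeneous
#' (possibly nonreversible) process implies for the *expected* counts.
#' The statistic is `sum_{i<j} (n_ij - n_ji)^2 / (n_ij + n_ji)` over pairs
#' with `n_ij + n_ji > 0`, with one degree of freedom per such pair, and a
#' chi-square upper-tail p-value. An all-symmetric (or empty) off-diagonal
#' gives statistic 0, df 0, and p = 1 by convention.
#'
#' @param counts K x K count matrix (see [pair_counts()]).
#' @return list `statistic`, `df`, `p_value`.
#' @export
bowker_test <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts) || nrow(counts) < 2)
    stop("counts must be a square matrix with K >= 2")
  K <- nrow(counts)
  stat <- 0; df <- 0L
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    s <- counts[i, j] + counts[j, i]
    if (s > 0) {
      stat <- stat + (counts[i, j] - counts[j, i])^2 / s
      df <- df + 1L
    }
  }
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

## proportion of differing resolved sites between two coded sequences
p_distance <- function(aln, pair, sites = NULL) {
  x <- aln$states[pair[1], ]; y <- aln$states[pair[2], ]
  if (!is.null(sites)) { x <- x[sites]; y <- y[sites] }
  ok <- x > 0L & y > 0L
  if (!any(ok)) return(NA_real_)
  mean(x[ok] != y[ok])
}

#' Symmetry-based locus filter
#'
#' Applies the matched-pairs symmetry test per locus to the sequence pair
#' with the largest p-distance within that locus — the pair with the most
#' accumulated substitutions, where assumption violations are most visible —
#' and fails the locus when the selected p-value falls below `alpha`. Set
#' `all_pairs = TRUE` to test every pair and judge by the minimum p-value
#' instead (no multiple-testing correction is applied by default; pass
#' `correct = "bonferroni"` etc. to adjust within a locus).
#'
#' @param aln a partitioned `aln_block` (see [aln_block()],
#'   [read_partitions()]). An unpartitioned alignment is treated as one
#'   locus.
#' @param alpha significance level (default 0.05).
#' @param all_pairs test all sequence pairs rather than the max-distance
#'   pair.
#' @param correct p-value adjustment method across pairs within a locus
#'   (see [stats::p.adjust()]); `"none"` by default.
#' @return data.frame: locus, pair, statistic, df, p_value, verdict
#'   (`"pass"`, `"fail"`, or `"untestable"`).
#' @export
maxsym_filter <- function(aln, alpha = 0.05, all_pairs = FALSE,
                          correct = "none") {
  parts <- aln$partitions
  if (is.null(parts))
    parts <- data.frame(locus = "all", start = 1L, end = n_sites(aln))
  taxa <- aln_taxa(aln)
  out <- list()
  for (r in seq_len(nrow(parts))) {
    sites <- parts$start[r]:parts$end[r]
    pairs <- utils::combn(taxa, 2, simplify = FALSE)
    pd <- vapply(pairs, function(p) p_distance(aln, p, sites), numeric(1))
    testable <- !is.na(pd)
    if (!any(testable)) {
      out[[r]] <- data.frame(locus = parts$locus[r], pair = NA_character_,
                             statistic = NA_real_, df = NA_integer_,
                             p_value = NA_real_, verdict = "untestable")
      next
    }
    sel <- if (all_pairs) which(testable) else which.max(pd)
    res <- lapply(sel, function(i)
      bowker_test(pair_counts(aln, pairs[[i]], sites)))
    pvals <- stats::p.adjust(vapply(res, `[[`, numeric(1), "p_value"), correct)
    worst <- which.min(pvals)
    i <- sel[worst]
    out[[r]] <- data.frame(
      locus = parts$locus[r],
      pair = paste(pairs[[i]], collapse = ":"),
      statistic = res[[worst]]$statistic,
      df = res[[worst]]$df,
      p_value = pvals[worst],
      verdict = if (pvals[worst] < alpha) "fail" else "pass")
  }
  do.call(rbind, out)
}
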