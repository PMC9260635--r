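## AU-test confidence set over candidate root placements, and site-/gene-
## wise log-likelihood diagnostics between two rooting hypotheses.

#' Per-site log-likelihoods for every candidate root placement
#'
#' Reroots the fixed topology on each of its branches, optimizes the root's
#' position along that branch under a fixed model (no per-placement model
#' refit), and records the per-site log-likelihood row. The rows form the
#' input to the AU test and to the site-/gene-wise diagnostics.
#'
#' @param tree topology with branch lengths (rooted input is unrooted
#'   first).
#' @param aln an `aln_block`.
#' @param model the fitted `nonrev_model`, held fixed across placements.
#' @return object of class `site_ll_matrix`: `ll` (placements x sites
#'   matrix, rownames are bipartition keys), `fractions` (optimized root
#'   position per branch), `locus_map` (from the alignment's partitions, if
#'   any).
#' @export
site_ll_for_all_roots <- function(tree, aln, model) {
  ut <- if (tree_is_rooted(tree) && ape::Ntip(tree) > 2L) ape::unroot(tree) else tree
  bb <- branch_bipartitions(ut)
  keys <- sort(names(bb))
  cp <- compress_patterns(aln, taxa = ut$tip.label)
  ll <- matrix(NA_real_, length(keys), n_sites(aln),
               dimnames = list(keys, NULL))
  fr <- stats::setNames(numeric(length(keys)), keys)
  for (i in seq_along(keys)) {
    view <- rooted_branch_view(ut, bb[[keys[i]]]$bip)
    f <- optimize_fraction(view, cp$patterns, cp$weights, model)$f
    len <- view$po$edge.length
    len[view$idx_canon] <- f * view$length
    len[view$idx_other] <- (1 - f) * view$length
    pp <- peel_loglik_cpp(view$po$edge, len,
                          cp$patterns[view$tip_perm, , drop = FALSE],
                          model$Q, model$root_freqs, view$nnode, view$root)
    ll[i, ] <- pp[cp$site_index]
    fr[i] <- f
  }
  structure(list(ll = ll, fractions = fr, locus_map = aln$partitions),
            class = "site_ll_matrix")
}

#' @export
print.site_ll_matrix <- function(x, ...) {
  cat("<site log-likelihood matrix> ", nrow(x$ll), " placements x ",
      ncol(x$ll), " sites\n", sep = "")
  invisible(x)
}

#' AU-test confidence set of root placements
#'
#' Approximately unbiased p-values for each candidate root placement by
#' multiscale RELL bootstrap: site log-likelihood columns are resampled at
#' several scale factors, the frequency with which each candidate attains
#' the maximum resampled likelihood is recorded per scale, and the signed
#' distance d and curvature c are estimated by weighted least squares on
#' the probit-transformed frequencies, giving `p = 1 - pnorm(d - c)`. The
#' confidence set at level `alpha` is the set of placements not rejected
#' in favor of the ML placement; it always contains the ML placement.
#'
#' @param sllm a `site_ll_matrix` (or plain candidates x sites matrix).
#' @param alpha rejection level (default 0.05).
#' @param scales relative bootstrap sample sizes (default 0.5 to 1.4 in
#'   steps of 0.1).
#' @param replicates RELL replicates per scale (default 10000).
#' @param seed integer seed; results are reproducible given it.
#' @return object of class `au_result`: `p` (named AU p-values),
#'   `confidence_set` (keys with `p >= alpha`), `ml` (key of the ML
#'   placement), `bp` (per-scale maximum frequencies), `alpha`.
#' @export
au_confidence_set <- function(sllm, alpha = 0.05,
                              scales = seq(0.5, 1.4, by = 0.1),
                              replicates = 10000, seed = 1) {
  L <- if (inherits(sllm, "site_ll_matrix")) sllm$ll else sllm
  m <- nrow(L); n <- ncol(L)
  if (m < 2) stop("need at least 2 candidate placements")
  if (n < 2) stop("need at least 2 sites")
  keys <- rownames(L)
  if (is.null(keys)) keys <- paste0("cand", seq_len(m))
  totals <- rowSums(L)
  ml <- which.max(totals)

  ## degenerate case: all candidates identical at every site
  if (max(L) - min(L) == 0 || all(apply(L, 2, function(col) max(col) - min(col)) < 1e-12)) {
    p <- stats::setNames(rep(1, m), keys)
    return(structure(list(p = p, confidence_set = keys, ml = keys[ml],
                          bp = NULL, alpha = alpha), class = "au_result"))
  }

  set.seed(seed)
  bp <- matrix(0, m, length(scales), dimnames = list(keys, NULL))
  eps <- 1e-10
  for (s in seq_along(scales)) {
    nr <- max(2L, round(scales[s] * n))
    ## resampled totals for all replicates at once: L %*% counts
    counts <- stats::rmultinom(replicates, nr, rep(1 / n, n))
    tot <- L %*% counts                       # m x replicates
    top <- apply(tot, 2, max)
    winners <- sweep(tot, 2, top, `-`) > -eps
    ## ties: split the win among tied candidates
    bp[, s] <- rowSums(sweep(winners, 2, colSums(winners), `/`)) / replicates
  }

  sigma <- 1 / sqrt(scales)                   # sqrt(n / n'), model z = d*s + c/s
  p <- stats::setNames(rep(NA_real_, m), keys)
  for (i in seq_len(m)) {
    bpi <- bp[i, ]
    if (all(bpi >= 1 - eps)) { p[i] <- 1; next }
    if (all(bpi <= eps)) { p[i] <- 0; next }
    use <- bpi > eps & bpi < 1 - eps
    if (sum(use) < 2) {
      ## nearly degenerate: fall back on the plain RELL frequency at scale 1
      p[i] <- bp[i, which.min(abs(scales - 1))]
      next
    }
    z <- stats::qnorm(1 - bpi[use])
    w <- (replicates * stats::dnorm(z)^2) / (bpi[use] * (1 - bpi[use]))
    ## z(sigma) = d / sigma + c * sigma: the signed distance dominates as
    ## replicates grow (sigma -> 0), the curvature as they shrink
    X <- cbind(1 / sigma[use], sigma[use])
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      warning("WLS failure for candidate ", keys[i], "; AU p-value is NaN")
      p[i] <- NaN
      next
    }
    d <- fit$coefficients[1]; cc <- fit$coefficients[2]
    p[i] <- 1 - stats::pnorm(d - cc)
  }
  ## the ML placement is never rejected in favor of itself
  cs <- union(keys[ml], keys[!is.na(p) & p >= alpha])
  structure(list(p = p, confidence_set = cs,
                 ml = keys[ml], bp = bp, alpha = alpha),
            class = "au_result")
}

#' @export
print.au_result <- function(x, ...) {
  cat("AU test over", length(x$p), "candidate root placements (alpha =",
      x$alpha, ")\n")
  ord <- order(x$p, decreasing = TRUE)
  for (i in ord) {
    mark <- paste0(if (names(x$p)[i] == x$ml) " ML" else "",
                   if (names(x$p)[i] %in% x$confidence_set) " *" else "")
    cat(sprintf("  p = %6.4f  %s%s\n", x$p[i], names(x$p)[i], mark))
  }
  cat("confidence set: ", length(x$confidence_set), " placement(s)\n", sep = "")
  invisible(x)
}

#' Site-wise log-likelihood differences between two rooting hypotheses
#'
#' The per-site difference in log-likelihood between two candidate root
#' placements, plus counts of sites preferring each side. Sites with zero
#' difference are counted as "equal", not split. The differences sum to the
#' total log-likelihood difference.
#'
#' @param sllm a `site_ll_matrix` with exactly two rows, or a 2 x sites
#'   matrix, or two equal-length numeric vectors via `row2`.
#' @param row2 optional second per-site vector when `sllm` is a vector.
#' @return object of class `delta_sls`: `delta` (per-site row1 - row2),
#'   `n_favor_1`, `n_favor_2`, `n_equal`, `total`.
#' @export
delta_sls <- function(sllm, row2 = NULL) {
  if (!is.null(row2)) {
    if (length(sllm) != length(row2)) stop("site vectors differ in length")
    L <- rbind(sllm, row2)
  } else {
    L <- if (inherits(sllm, "site_ll_matrix")) sllm$ll else sllm
  }
  if (nrow(L) != 2) stop("delta_sls needs exactly 2 candidate rows")
  d <- L[1, ] - L[2, ]
  structure(list(delta = d,
                 n_favor_1 = sum(d > 0), n_favor_2 = sum(d < 0),
                 n_equal = sum(d == 0), total = sum(d)),
            class = "delta_sls")
}

#' @export
print.delta_sls <- function(x, ...) {
  cat("Site-wise log-likelihood differences (hypothesis 1 - hypothesis 2)\n")
  cat(sprintf("  sites favoring 1: %d   favoring 2: %d   equal: %d\n",
              x$n_favor_1, x$n_favor_2, x$n_equal))
  cat(sprintf("  total log-likelihood difference: %.4f\n", x$total))
  invisible(x)
}

#' Gene-wise log-likelihood differences between two rooting hypotheses
#'
#' Sums the site-wise differences within each locus. Loci with the largest
#' absolute values are the ones whose removal most perturbs the preferred
#' root, which is what locus-filtering experiments act on.
#'
#' @inheritParams delta_sls
#' @param locus_map `data.frame(locus, start, end)` covering every site
#'   exactly once; defaults to the matrix's own locus map.
#' @return object of class `delta_gls`: `table` (data.frame: locus, delta,
#'   n_sites, ordered by |delta| decreasing), counts per side, `total`.
#' @export
delta_gls <- function(sllm, locus_map = NULL) {
  if (inherits(sllm, "site_ll_matrix") && is.null(locus_map))
    locus_map <- sllm$locus_map
  if (is.null(locus_map)) stop("a locus map is required")
  ds <- delta_sls(sllm)
  n <- length(ds$delta)
  covered <- integer(n)
  for (r in seq_len(nrow(locus_map)))
    covered[locus_map$start[r]:locus_map$end[r]] <-
      covered[locus_map$start[r]:locus_map$end[r]] + 1L
  if (any(covered != 1L))
    stop("locus map must cover every site exactly once")
  g <- vapply(seq_len(nrow(locus_map)), function(r)
    sum(ds$delta[locus_map$start[r]:locus_map$end[r]]), numeric(1))
  tab <- data.frame(locus = locus_map$locus, delta = g,
                    n_sites = locus_map$end - locus_map$start + 1L)
  tab <- tab[order(-abs(tab$delta)), ]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 n_favor_1 = sum(g > 0), n_favor_2 = sum(g < 0),
                 n_equal = sum(g == 0), total = sum(g)),
            class = "delta_gls")
}

#' @export
print.delta_gls <- function(x, ...) {
  cat("Gene-wise log-likelihood differences (hypothesis 1 - hypothesis 2)\n")
  cat(sprintf("  loci favoring 1: %d   favoring 2: %d   equal: %d\n",
              x$n_favor_1, x$n_favor_2, x$n_equal))
  cat(sprintf("  total: %.4f\n", x$total))
  cat("  loci with largest |delta|:\n")
  print(utils::head(x$table, 5))
  invisible(x)
}
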