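## Model fitting and ML root search on a fixed topology.

## softmax with the first logit anchored at 0
softmax0 <- function(x) {
  z <- exp(c(0, x) - max(c(0, x)))
  z / sum(z)
}

## rates from the optimizer's parameter vector: first rate anchored to 1 as
## the scale reference (the overall rate is absorbed by Q normalization)
theta_to_rates <- function(theta) exp(c(0, theta))

#' Fit a nonreversible model on a fixed rooted tree
#'
#' Maximizes the pruning log-likelihood over the K(K-1) off-diagonal rates
#' (one rate is anchored to 1 during the search, since the overall rate
#' scale is absorbed by the unit-substitution normalization of Q) by
#' bounded quasi-Newton (L-BFGS-B) on log-transformed rates. Branch lengths
#' are held fixed. Optionally the root-state frequencies are freed from the
#' stationary distribution and estimated as K-1 extra parameters.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param aln an `aln_block`.
#' @param init optional `nonrev_model` (or rate vector) to warm-start from.
#' @param free_root_freqs estimate root frequencies separately from the
#'   stationary distribution (default `FALSE`: root frequencies track pi).
#' @param control list: `maxit` (default 500), `factr` (L-BFGS-B tolerance,
#'   default 100, i.e. an absolute objective change of order 1e-6),
#'   `restarts` on non-finite likelihood (default 3), `ndeps` (finite
#'   difference step, default 1e-5).
#' @return the fitted `nonrev_model`, with attributes `logl`,
#'   `convergence`, `iterations`.
#' @export
fit_model <- function(tree, aln, init = NULL, free_root_freqs = FALSE,
                      control = list()) {
  ctrl <- utils::modifyList(list(maxit = 500, factr = 100, restarts = 3,
                                 ndeps = 1e-5), control)
  K <- length(aln$alphabet)
  nr <- K * (K - 1)
  cp <- compress_patterns(aln, taxa = tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- ape::Ntip(tree) + tree$Nnode
  root <- root_node(tree)

  init_rates <- if (is.null(init)) rep(1, nr)
    else if (inherits(init, "nonrev_model")) init$rates else init
  init_rates <- pmax(init_rates / init_rates[1], 1e-8)
  theta0 <- log(init_rates[-1])
  if (free_root_freqs) {
    rf0 <- if (inherits(init, "nonrev_model")) pmax(init$root_freqs, 1e-8) else rep(1, K)
    theta0 <- c(theta0, log(rf0[-1] / rf0[1]))
  }

  make_model <- function(theta) {
    rates <- theta_to_rates(theta[seq_len(nr - 1)])
    rf <- if (free_root_freqs) softmax0(theta[nr:(nr + K - 2)]) else NULL
    build_model(rates, root_freqs = rf, alphabet = aln$alphabet)
  }
  negll <- function(theta) {
    m <- tryCatch(make_model(theta), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    v <- -sum(peel_loglik_cpp(po$edge, po$edge.length, cp$patterns, m$Q,
                              m$root_freqs, nnode, root) * cp$weights)
    if (!is.finite(v)) 1e10 else v
  }

  fit <- NULL
  for (attempt in seq_len(ctrl$restarts + 1)) {
    fit <- tryCatch(
      stats::optim(theta0, negll, method = "L-BFGS-B",
                   lower = -15, upper = 15,
                   control = list(maxit = ctrl$maxit, factr = ctrl$factr,
                                  ndeps = rep(ctrl$ndeps, length(theta0)))),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e9) break
    theta0 <- theta0 + stats::rnorm(length(theta0), 0, 0.3)
    fit <- NULL
  }
  if (is.null(fit))
    stop("model fit failed: non-finite likelihood after restarts")
  m <- make_model(fit$par)
  attr(m, "logl") <- -fit$value
  attr(m, "convergence") <- fit$convergence
  attr(m, "iterations") <- fit$counts[["function"]]
  m
}

## Rooted view of one candidate branch: reroot once at midpoint, remember
## which postorder edges are the two root half-branches, then moving the
## root along the branch is just an edge-length update.
rooted_branch_view <- function(ut, bip) {
  rt <- reroot_at(ut, root_placement(bip, 0.5))
  po <- ape::reorder.phylo(rt, "postorder")
  root <- root_node(po)
  idx <- which(po$edge[, 1] == root)
  sets <- node_tip_sets(po)
  canon_first <- identical(sort(sets[[po$edge[idx[1], 2]]]), bip$side)
  list(tree = rt, po = po,
       idx_canon = if (canon_first) idx[1] else idx[2],
       idx_other = if (canon_first) idx[2] else idx[1],
       length = sum(po$edge.length[idx]),
       ## rerooting may renumber tips: row i of the pattern matrix (built in
       ## ut tip order) must follow the view tree's tip ids
       tip_perm = match(po$tip.label, ut$tip.label),
       nnode = ape::Ntip(po) + po$Nnode, root = root)
}

view_loglik <- function(view, f, patterns, weights, model) {
  len <- view$po$edge.length
  len[view$idx_canon] <- f * view$length
  len[view$idx_other] <- (1 - f) * view$length
  sum(peel_loglik_cpp(view$po$edge, len, patterns[view$tip_perm, , drop = FALSE],
                      model$Q, model$root_freqs,
                      view$nnode, view$root) * weights)
}

## Conditional likelihoods of the two root subtrees under a fixed model:
## moving the root along its branch then costs two K x K transition
## matrices per evaluation instead of a full peel.
view_profile <- function(view, patterns, model) {
  prof <- root_partials_cpp(view$po$edge, view$po$edge.length,
                            patterns[view$tip_perm, , drop = FALSE],
                            model$Q, view$nnode, view$root)
  prof$canon_first <- prof$child1 == view$po$edge[view$idx_canon, 2]
  prof
}

profile_loglik <- function(prof, view, f, model, weights) {
  tc <- f * view$length; to <- (1 - f) * view$length
  root_profile_loglik_cpp(prof$D1, prof$D2, prof$logscale, model$Q,
                          model$root_freqs,
                          if (prof$canon_first) tc else to,
                          if (prof$canon_first) to else tc,
                          weights)
}

## maximize the root position along one branch under a fixed model
optimize_fraction <- function(view, patterns, weights, model, tol = 1e-6) {
  prof <- view_profile(view, patterns, model)
  if (view$length == 0)
    return(list(f = 0.5,
                logl = profile_loglik(prof, view, 0.5, model, weights)[1]))
  o <- stats::optimize(function(f) profile_loglik(prof, view, f, model, weights)[1],
                       interval = c(0, 1), maximum = TRUE, tol = tol)
  end_ll <- profile_loglik(prof, view, c(0, 1), model, weights)
  if (max(end_ll) > o$objective)
    list(f = c(0, 1)[which.max(end_ll)], logl = max(end_ll))
  else list(f = o$maximum, logl = o$objective)
}

view_tree_at <- function(view, f) {
  rt <- view$tree
  po <- view$po
  ## map the po edge back to rt's edge rows (same node ids, different order)
  key_po <- paste(po$edge[, 1], po$edge[, 2])
  key_rt <- paste(rt$edge[, 1], rt$edge[, 2])
  rt$edge.length[match(key_po[view$idx_canon], key_rt)] <- f * view$length
  rt$edge.length[match(key_po[view$idx_other], key_rt)] <- (1 - f) * view$length
  rt
}

#' ML root placement search over every branch of a fixed topology
#'
#' For each branch of the (unrooted) topology the tree is rerooted on that
#' branch, the root's position along the branch is optimized by bounded
#' scalar search, and (optionally) the model is refit at that rooting; the
#' branch with the highest optimized log-likelihood wins. All other branch
#' lengths are held fixed at their input values; the candidate branch keeps
#' its total length, split between the two root half-branches. Under a
#' time-reversible model with stationary root frequencies the pulley
#' principle makes every branch tie; ties within `tie_tol` are flagged and
#' broken in favor of the first branch in canonical bipartition order.
#'
#' @param tree topology with branch lengths (rooted input is unrooted
#'   first).
#' @param aln an `aln_block` containing all leaves of `tree`.
#' @param model optional fixed `nonrev_model`; when supplied with
#'   `refit = FALSE` the search profiles only over root positions.
#' @param refit refit the model at each candidate rooting (warm-started
#'   from the full fit). Default `TRUE` when no fixed model is given.
#' @param free_root_freqs passed to [fit_model()].
#' @param tie_tol log-likelihood difference under which candidates are
#'   considered tied (default 1e-6).
#' @param control passed to [fit_model()].
#' @return object of class `root_search_result`: `placement` (the best
#'   [root_placement()]), `rooted_tree`, `table` (data.frame: branch key,
#'   optimized fraction and log-likelihood), `model` (fit at the best
#'   rooting), `site_logl` (per-site log-likelihoods at the best rooting),
#'   `logl`, `tie` flag.
#' @export
ml_root_search <- function(tree, aln, model = NULL, refit = is.null(model),
                           free_root_freqs = FALSE, tie_tol = 1e-6,
                           control = list()) {
  if (ape::Ntip(tree) < 2L) stop("need at least 2 taxa")
  ut <- if (tree_is_rooted(tree) && ape::Ntip(tree) > 2L) ape::unroot(tree) else tree
  bb <- branch_bipartitions(ut)
  keys <- sort(names(bb))
  cp <- compress_patterns(aln, taxa = ut$tip.label)

  base_model <- model
  if (is.null(base_model)) {
    start <- reroot_at(ut, root_placement(bb[[keys[1]]]$bip, 0.5))
    base_model <- fit_model(start, aln, control = control)
  }
  ## per-branch scan fits may run at a coarser tolerance than the final
  ## polish at the winning branch: the argmax only needs resolution well
  ## below the between-branch log-likelihood differences
  scan_control <- utils::modifyList(list(factr = 1e7), control)

  opt_f <- function(view, m) optimize_fraction(view, cp$patterns, cp$weights, m)

  rows <- vector("list", length(keys))
  fits <- vector("list", length(keys))
  warm <- base_model
  for (i in seq_along(keys)) {
    bip <- bb[[keys[i]]]$bip
    view <- rooted_branch_view(ut, bip)
    sol <- opt_f(view, base_model)
    m_i <- base_model
    if (refit) {
      m_i <- fit_model(view_tree_at(view, sol$f), aln, init = warm,
                       free_root_freqs = free_root_freqs,
                       control = scan_control)
      warm <- m_i
      sol <- opt_f(view, m_i)
    }
    fits[[i]] <- list(model = m_i, view = view, f = sol$f)
    rows[[i]] <- data.frame(branch = keys[i], fraction = sol$f, logl = sol$logl)
  }
  tab <- do.call(rbind, rows)
  best <- which.max(tab$logl)
  tie <- sum(tab$logl >= tab$logl[best] - tie_tol) > 1L
  if (tie) best <- which(tab$logl >= max(tab$logl) - tie_tol)[1]

  bf <- fits[[best]]
  if (refit) {
    ## polish the winning branch at full tolerance
    m_b <- fit_model(view_tree_at(bf$view, bf$f), aln, init = bf$model,
                     free_root_freqs = free_root_freqs, control = control)
    sol <- opt_f(bf$view, m_b)
    bf$model <- m_b; bf$f <- sol$f
    tab$fraction[best] <- sol$f; tab$logl[best] <- sol$logl
  }
  rooted <- view_tree_at(bf$view, bf$f)
  pp <- peel_patterns(rooted, cp$patterns[bf$view$tip_perm, , drop = FALSE],
                      bf$model)
  structure(list(
    placement = root_placement(bb[[keys[best]]]$bip, tab$fraction[best]),
    rooted_tree = rooted,
    table = tab,
    model = bf$model,
    site_logl = pp[cp$site_index],
    logl = tab$logl[best],
    tie = tie
  ), class = "root_search_result")
}

#' @export
print.root_search_result <- function(x, ...) {
  cat("ML root placement search over", nrow(x$table), "branches\n")
  cat("  best branch: ", x$placement$branch$key, "\n", sep = "")
  cat(sprintf("  split fraction: %.4f   log-likelihood: %.4f\n",
              x$placement$fraction, x$logl))
  if (x$tie) cat("  NOTE: ties within tolerance; root position not identifiable\n")
  invisible(x)
}

#' Nonparametric bootstrap of the rooting analysis
#'
#' Resamples alignment sites with replacement `B` times, reruns the ML root
#' search on the fixed topology for each replicate (model warm-started from
#' the full-data fit, root position re-optimized on every branch), and
#' summarizes the replicate root positions as rootstrap supports on the
#' full-data ML tree. Fully reproducible: replicate r uses the r-th
#' substream seed drawn once from `seed`.
#'
#' @inheritParams ml_root_search
#' @param B number of bootstrap replicates.
#' @param seed integer seed governing all resampling.
#' @param resample set `FALSE` to run identity replicates (no resampling;
#'   for checking the pipeline).
#' @param refit_replicates refit the model once per replicate at the
#'   full-data ML rooting (warm-started) before the per-branch root-position
#'   profile; `FALSE` keeps the full-data model fixed.
#' @param control optimizer control for replicate refits (`maxit` default
#'   100).
#' @return object of class `bootstrap_root_result`: `ml` (the full-data
#'   [ml_root_search()] result), `trees` (replicate rooted trees),
#'   `rootstrap` (a [rootstrap_support()] result), `n_failed`.
#' @export
bootstrap_root_analysis <- function(tree, aln, B = 100, seed = 1,
                                    model = NULL, refit = is.null(model),
                                    resample = TRUE, refit_replicates = refit,
                                    control = list(maxit = 100)) {
  if (B < 1) stop("B must be >= 1")
  ml <- ml_root_search(tree, aln, model = model, refit = refit)
  ut <- if (tree_is_rooted(tree) && ape::Ntip(tree) > 2L) ape::unroot(tree) else tree
  bb <- branch_bipartitions(ut)
  keys <- sort(names(bb))
  cp <- compress_patterns(aln, taxa = ut$tip.label)
  nsites <- n_sites(aln)
  views <- lapply(keys, function(k) rooted_branch_view(ut, bb[[k]]$bip))
  ml_rooted_view <- rooted_branch_view(ut, ml$placement$branch)

  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max - 1L, B)

  trees <- vector("list", B)
  failed <- 0L
  for (r in seq_len(B)) {
    set.seed(substreams[r])
    w <- if (resample) as.vector(stats::rmultinom(1, nsites, cp$weights / nsites))
         else cp$weights
    res <- tryCatch({
      m_r <- ml$model
      if (refit_replicates) {
        ## refit on the resampled weights via a weighted objective
        m_r <- refit_weighted(ml_rooted_view, ml$placement$fraction,
                              cp$patterns, w, ml$model, aln$alphabet, control)
      }
      best_ll <- -Inf; best_tree <- NULL
      for (i in seq_along(views)) {
        v <- views[[i]]
        sol <- optimize_fraction(v, cp$patterns, w, m_r, tol = 1e-3)
        if (is.finite(sol$logl) && sol$logl > best_ll) {
          best_ll <- sol$logl; best_tree <- view_tree_at(v, sol$f)
        }
      }
      best_tree
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else trees[[r]] <- res
  }
  trees <- Filter(Negate(is.null), trees)
  if (failed > 0)
    warning(failed, " bootstrap replicate(s) failed and were excluded")
  structure(list(ml = ml, trees = trees,
                 rootstrap = rootstrap_support(ml$rooted_tree, trees),
                 n_failed = failed),
            class = "bootstrap_root_result")
}

#' @export
print.bootstrap_root_result <- function(x, ...) {
  print(x$ml)
  print(x$rootstrap)
  if (x$n_failed > 0) cat("  failed replicates:", x$n_failed, "\n")
  invisible(x)
}

## warm-started model refit at a fixed rooting with replicate pattern weights
refit_weighted <- function(view, f, patterns, weights, init, alphabet, control) {
  ctrl <- utils::modifyList(list(maxit = 15, factr = 1e9), control)
  K <- length(alphabet)
  nr <- K * (K - 1)
  len <- view$po$edge.length
  len[view$idx_canon] <- f * view$length
  len[view$idx_other] <- (1 - f) * view$length
  patterns <- patterns[view$tip_perm, , drop = FALSE]
  init_rates <- pmax(init$rates / init$rates[1], 1e-8)
  theta0 <- log(init_rates[-1])
  negll <- function(theta) {
    m <- tryCatch(build_model(theta_to_rates(theta), alphabet = alphabet),
                  error = function(e) NULL)
    if (is.null(m)) return(1e10)
    v <- -sum(peel_loglik_cpp(view$po$edge, len, patterns, m$Q, m$root_freqs,
                              view$nnode, view$root) * weights)
    if (!is.finite(v)) 1e10 else v
  }
  fit <- stats::optim(theta0, negll, method = "L-BFGS-B", lower = -15, upper = 15,
                      control = list(maxit = ctrl$maxit, factr = ctrl$factr,
                                     ndeps = rep(1e-4, length(theta0))))
  build_model(theta_to_rates(fit$par), alphabet = alphabet)
}
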