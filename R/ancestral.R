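# Shared pruning machinery reused by marginals and stochastic mapping:
# postorder tree, per-edge transition matrices, scaled upward partials.
fit_machinery <- function(fit) {
  tree <- fit$tree
  L <- tip_partials(tree, fit$states, fit$model)
  tr <- ape::reorder.phylo(tree, "postorder")
  P <- edge_pmats_cpp(fit$Q, tr$edge.length)
  pr <- prune_cpp(tr$edge, tr$edge.length, L, fit$Q)
  if (isTRUE(pr$degenerate)) stop("zero likelihood under the fitted model")
  root <- length(tree$tip.label) + 1L
  prior <- root_prior_vec(fit$root_prior, pr$partials[root, ])
  list(tr = tr, P = P, up = pr$partials, prior = prior, root = root,
       nedge = nrow(tr$edge), k = nrow(fit$Q))
}

#' Marginal ancestral state probabilities
#'
#' Combines upward (pruning) and downward partial likelihoods to give, for
#' every node, the marginal posterior over composite states, plus its
#' projections onto observed states and hidden rate categories.
#'
#' @param fit a converged `mk_fit`.
#' @return list with matrices `composite` (nodes x composite states),
#'   `observed` and `category`; rows sum to 1. Node order is ape's: tips
#'   `1..ntip` then internal nodes from the root.
#' @export
marginal_ancestral_states <- function(fit) {
  m <- fit_machinery(fit)
  tr <- m$tr; k <- m$k
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  # w[e, ] = P_e %*% up[child(e), ], the child-subtree message at the parent
  w <- matrix(0, m$nedge, k)
  for (e in seq_len(m$nedge))
    w[e, ] <- m$P[, , e] %*% m$up[tr$edge[e, 2], ]
  byparent <- split(seq_len(m$nedge), tr$edge[, 1])
  D <- matrix(0, nnode, k)
  D[m$root, ] <- m$prior
  for (e in rev(seq_len(m$nedge))) { # preorder
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    A <- D[p, ]
    for (s in byparent[[as.character(p)]]) if (s != e) A <- A * w[s, ]
    D[ch, ] <- as.vector(crossprod(m$P[, , e], A))
    mx <- max(D[ch, ])
    if (mx > 0) D[ch, ] <- D[ch, ] / mx
  }
  post <- m$up * D
  post <- post / rowSums(post)
  colnames(post) <- fit$model$states
  project <- function(groups, names) {
    out <- sapply(seq_along(names), function(g)
      rowSums(post[, groups == g, drop = FALSE]))
    colnames(out) <- names
    out
  }
  list(composite = post,
       observed = project(fit$model$obs_of, fit$model$obs_names),
       category = project(fit$model$hidden_of, fit$model$hidden_names))
}

#' @export
#' @rdname marginal_ancestral_states
#' @param object an `mk_fit`.
#' @param ... unused.
predict.mk_fit <- function(object, ...) marginal_ancestral_states(object)

#' Plot a fitted Mk/HMM model on its tree
#'
#' Draws the tree with pies of the marginal observed-state posterior at
#' internal nodes.
#'
#' @param x an `mk_fit`.
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot.mk_fit <- function(x, ...) {
  anc <- marginal_ancestral_states(x)
  ntip <- length(x$tree$tip.label)
  ape::plot.phylo(x$tree, ...)
  ape::nodelabels(pie = anc$observed[(ntip + 1):nrow(anc$observed), , drop = FALSE],
                  cex = 0.4)
  invisible(x)
}
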