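# Observed tip states -> 1-based observed indices against a model.
# Accepts 0-based integers, state-name strings, factors; NA = ambiguous.
obs_index <- function(states, model) {
  if (is.factor(states)) states <- as.character(states)
  nm <- names(states)
  out <- if (is.numeric(states)) {
    s <- as.integer(states)
    if (any(!is.na(s) & (s < 0 | s >= model$n_obs)))
      stop("numeric states must be 0-based indices < n_obs")
    s + 1L
  } else {
    s <- match(as.character(states), model$obs_names)
    bad <- !is.na(states) & is.na(s)
    if (any(bad))
      stop("unknown state labels: ", paste(unique(states[bad]), collapse = ", "))
    s
  }
  setNames(out, nm)
}

# ntip x k partial-likelihood matrix for the composite state space; an
# observed state is compatible with every hidden category (partial 1),
# missing data with every composite state.
tip_partials <- function(tree, states, model, allow_missing = TRUE) {
  tips <- tree$tip.label
  if (is.null(names(states))) {
    if (length(states) != length(tips))
      stop("unnamed state vector must match the number of tips")
    names(states) <- tips
  }
  absent <- setdiff(tips, names(states))
  if (length(absent)) {
    if (!allow_missing)
      stop("tips without trait data: ", paste(head(absent, 5), collapse = ", "))
    states[absent] <- NA
  }
  oi <- obs_index(states, model)[tips]
  k <- length(model$states)
  L <- matrix(0, length(tips), k, dimnames = list(tips, model$states))
  for (i in seq_along(tips)) {
    if (is.na(oi[i])) L[i, ] <- 1
    else L[i, model$obs_of == oi[i]] <- 1
  }
  L
}

root_prior_vec <- function(root_prior, root_partial) {
  k <- length(root_partial)
  switch(root_prior,
    flat = rep(1 / k, k),
    fitzjohn = {
      s <- sum(root_partial)
      if (s <= 0) rep(1 / k, k) else root_partial / s
    },
    stop("unknown root prior: ", root_prior))
}

#' Log-likelihood of tip data under an Mk/HMM rate matrix
#'
#' Felsenstein pruning over the composite (observed x hidden) state space.
#' Ambiguous or missing tips contribute a partial likelihood of 1 for every
#' compatible composite state.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param states named vector of observed tip states (see [fit_mk()]).
#' @param Q composite-space rate matrix, e.g. from [rate_matrix()].
#' @param model the `mk_model` describing the state space.
#' @param root_prior `"flat"` or `"fitzjohn"`; defaults to the model's.
#' @return the log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, states, Q, model, root_prior = model$root_prior) {
  validate_tree(tree)
  L <- tip_partials(tree, states, model)
  pr <- prune_tree(tree, L, Q)
  root <- length(tree$tip.label) + 1L
  rp <- pr$partials[root, ]
  prior <- root_prior_vec(root_prior, rp)
  ll <- log(sum(prior * rp)) + pr$logscale
  if (!is.finite(ll)) -Inf else ll
}

# Shared pruning pass: postorder edges + C++ core.
prune_tree <- function(tree, tipL, Q) {
  tr <- ape::reorder.phylo(tree, "postorder")
  res <- prune_cpp(tr$edge, tr$edge.length, tipL, Q)
  if (isTRUE(res$degenerate))
    res$logscale <- -Inf
  res
}
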