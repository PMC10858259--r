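#' Fit an Mk/HMM model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over the model's free rates using
#' bounded quasi-Newton (`L-BFGS-B`) on log-parameters, with multiple random
#' restarts (hidden-rate likelihood surfaces are multimodal). Rates are in
#' events per Myr.
#'
#' Tip states may be given as a named vector over tip labels with values
#' `0/1` (0-based observed states), state names (`"M"`/`"P"` for the default
#' binary model), or `NA` for missing (all states allowed).
#'
#' @param tree rooted `phylo` with branch lengths in Myr.
#' @param states named tip-state vector (see Details).
#' @param model an [mk_model()] or [pagel_model()].
#' @param bounds length-2 numeric, box bounds on every rate (events/Myr).
#'   The default upper bound scales with the tree: 100 expected events per
#'   mean root-to-tip path. Unbounded hidden-rate fits are prone to
#'   degenerate boundary optima in which one composite state flickers
#'   infinitely fast; such fits mimic state mixtures, inflate mapped
#'   transition counts without limit and carry no biological meaning.
#' @param n_restarts number of optimizer starts (first start is a fixed
#'   heuristic, the rest are random).
#' @param seed integer seed for the random restarts (reproducible fits).
#' @param init optional numeric vector of starting rates (used as the first
#'   start instead of the heuristic).
#' @param root_prior overrides the model's root prior if given.
#' @return an object of class `mk_fit` with components `model`, `rates`,
#'   `logLik`, `k`, `AIC`, `convergence`, `restarts`, `Q`, `tree`, `states`.
#' @export
fit_mk <- function(tree, states, model = mk_model(2, 1, "ARD"),
                   bounds = NULL, n_restarts = 10, seed = NULL,
                   init = NULL, root_prior = model$root_prior) {
  validate_tree(tree)
  if (length(tree$tip.label) < 2) stop("need at least 2 tips")
  stopifnot(inherits(model, "mk_model"), n_restarts >= 1)
  if (is.null(bounds)) {
    H <- mean(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
    bounds <- c(1e-9, 100 / max(H, .Machine$double.eps))
  }
  L <- tip_partials(tree, states, model)
  oi <- obs_index(states, model)
  if (length(unique(oi[!is.na(oi)])) < 2)
    warning("fewer than 2 observed states present in the data; rates are weakly identified")
  tr <- ape::reorder.phylo(tree, "postorder")
  root <- length(tree$tip.label) + 1L
  lb <- log(bounds[1]); ub <- log(bounds[2])
  nll <- function(logr) {
    Q <- rate_matrix(model, exp(logr))
    pr <- prune_cpp(tr$edge, tr$edge.length, L, Q)
    if (isTRUE(pr$degenerate)) return(1e10)
    rp <- pr$partials[root, ]
    prior <- root_prior_vec(root_prior, rp)
    ll <- log(sum(prior * rp)) + pr$logscale
    if (!is.finite(ll)) 1e10 else -ll
  }
  # heuristic scale: one expected change per root-to-tip path
  depth <- mean(ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)])
  q0 <- min(max(1 / max(depth, .Machine$double.eps), bounds[1] * 10), bounds[2] / 10)
  # deterministic multi-scale starts first (rate surfaces for hidden-rate
  # models are multimodal and boundary-prone), then random log-uniform ones
  starts <- local_seed(seed, {
    det <- lapply(c(1, 0.1, 10), function(f) rep(q0 * f, model$n_par))
    if (!is.null(init)) det <- c(list(pmin(pmax(init, bounds[1]), bounds[2])), det)
    det <- do.call(rbind, det[seq_len(min(length(det), n_restarts))])
    n_rand <- n_restarts - nrow(det)
    rnd <- matrix(exp(runif(n_rand * model$n_par, log(q0) - 3.45, log(q0) + 3.45)),
                  nrow = max(n_rand, 0), ncol = model$n_par)
    rbind(det, rnd)
  })
  best <- NULL
  rst <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      optim(log(starts[i, ]), nll, method = "L-BFGS-B",
            lower = lb, upper = ub, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(o)) next
    rst[[i]] <- data.frame(restart = i, start_nll = nll(log(starts[i, ])),
                           final_nll = o$value, convergence = o$convergence)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("optimizer failed at every restart")
  restarts <- do.call(rbind, rst)
  rates <- setNames(exp(best$par), model$par_names)
  ll <- -best$value
  k <- model$n_par
  structure(list(
    model = model, rates = rates, logLik = ll, k = k, AIC = 2 * k - 2 * ll,
    convergence = best$convergence, converged = best$convergence == 0,
    restarts = restarts, n_restarts = n_restarts,
    Q = rate_matrix(model, rates), root_prior = root_prior,
    tree = tree, states = states, bounds = bounds, seed = seed,
    call = match.call()
  ), class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, digits = 4, ...) {
  print(x$model)
  cat(sprintf("\nlog-likelihood: %.4f   k: %d   AIC: %.4f%s\n",
              x$logLik, x$k, x$AIC,
              if (!x$converged) "   [optimizer did not report convergence]" else ""))
  cat("ML rates (events/Myr):\n")
  print(signif(x$rates, digits))
  invisible(x)
}

#' @export
summary.mk_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mk_fit")
}

#' @export
print.summary.mk_fit <- function(x, ...) {
  print(x$fit)
  cat("\nInstantaneous rate matrix Q:\n")
  print(signif(x$fit$Q, 4))
  at_lower <- x$fit$rates <= x$fit$bounds[1] * 1.0001
  if (any(at_lower))
    cat("\nRates at the lower bound:",
        paste(names(x$fit$rates)[at_lower], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mk_fit <- function(object, ...) object$rates

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = length(object$tree$tip.label),
            class = "logLik")
}

#' Fit the standard four-model grid
#'
#' Equal-rates and all-rates-different models with one or two hidden rate
#' categories (four models), ranked by AIC.
#'
#' @inheritParams fit_mk
#' @param n_hidden integer vector of hidden-category counts to try.
#' @param constraints character vector of constraints to try.
#' @param ... passed to [fit_mk()].
#' @return an object of class `mk_fit_grid`: named list of fits, the
#'   [model_select()] table, and the best fit.
#' @export
fit_mk_grid <- function(tree, states, n_hidden = c(1, 2),
                        constraints = c("ER", "ARD"), seed = NULL, ...) {
  fits <- list()
  for (h in n_hidden) for (con in constraints) {
    nm <- sprintf("%s.%dcat", con, h)
    fits[[nm]] <- fit_mk(tree, states, mk_model(2, h, con), seed = seed, ...)
  }
  tab <- model_select(fits)
  structure(list(fits = fits, table = tab,
                 best = fits[[tab$model[1]]]),
            class = "mk_fit_grid")
}

#' @export
print.mk_fit_grid <- function(x, ...) {
  cat("Mk/HMM model selection:\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("\nBest model: %s\n", x$table$model[1]))
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' @param fits a (named) list of `mk_fit` objects fitted to the same data.
#' @return data frame sorted by ascending AIC with `dAIC = AIC - min(AIC)`;
#'   ties are broken in favour of fewer parameters.
#' @export
model_select <- function(fits) {
  if (length(fits) == 0) stop("empty fit list")
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  tab <- data.frame(
    model = names(fits),
    k = vapply(fits, function(f) f$k, 0L),
    logLik = vapply(fits, function(f) f$logLik, 0),
    AIC = vapply(fits, function(f) f$AIC, 0),
    row.names = NULL
  )
  tab <- tab[order(tab$AIC, tab$k), ]
  tab$dAIC <- tab$AIC - min(tab$AIC)
  rownames(tab) <- NULL
  tab
}

#' Simulate tip data from a fitted model
#'
#' Forward-simulates complete character histories under the fitted rate
#' matrix down the fitted tree and returns the observed tip states, one
#' named vector per simulation.
#'
#' @param object an `mk_fit`.
#' @param nsim number of data sets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of named tip-state vectors (0-based observed states).
#' @export
simulate.mk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  local_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      simulate_traits(object$tree, object$model, object$rates)$states
    })
  })
}
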