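# Coerce a binary trait vector (0/1, logical, or two labels) to 0/1 named
# integer, NA preserved.
binary01 <- function(v, name = "trait") {
  nm <- names(v)
  if (is.logical(v)) v <- as.integer(v)
  if (is.factor(v)) v <- as.character(v)
  if (is.character(v)) {
    lv <- sort(unique(v[!is.na(v)]))
    if (!all(lv %in% c("0", "1"))) {
      if (length(lv) > 2) stop(name, " has more than 2 states: ",
                               paste(lv, collapse = ", "))
      v <- match(v, lv) - 1L
    } else v <- as.integer(v)
  }
  if (any(!is.na(v) & !(v %in% c(0L, 1L))))
    stop(name, " must be binary (0/1)")
  setNames(as.integer(v), nm)
}

# Shared-tip pruning for a two-trait comparison; returns tree, joint states
# and the bookkeeping of what was dropped.
pagel_data <- function(tree, x, y) {
  x <- binary01(x, "x"); y <- binary01(y, "y")
  shared <- intersect(intersect(names(x)[!is.na(x)], names(y)[!is.na(y)]),
                      tree$tip.label)
  n_dropped <- length(tree$tip.label) - length(shared)
  if (length(shared) < 4) stop("fewer than 4 tips with both traits observed")
  if (length(shared) < 20)
    warning(sprintf("only %d shared tips; correlated-evolution tests will have low power",
                    length(shared)))
  tr <- if (n_dropped > 0) drop_tips(tree, setdiff(tree$tip.label, shared)) else tree
  joint <- setNames(2L * x[tr$tip.label] + y[tr$tip.label], tr$tip.label)
  list(tree = tr, joint = joint, n_shared = length(shared), n_dropped = n_dropped)
}

#' Fit one Pagel two-trait model
#'
#' @param tree rooted `phylo`; tips lacking either trait are dropped
#'   (pairwise deletion), with counts recorded on the result.
#' @param x,y named binary trait vectors over tip labels (0/1; `NA` missing).
#' @param dependency,constraint,root_prior model structure, see
#'   [pagel_model()].
#' @param ... passed to [fit_mk()] (`n_restarts`, `seed`, `bounds`, `init`).
#' @return an `mk_fit` on the 4-state joint space.
#' @export
fit_pagel <- function(tree, x, y,
                      dependency = c("independent", "x_on_y", "y_on_x", "mutual"),
                      constraint = c("ARD", "ER"),
                      root_prior = c("flat", "fitzjohn"), ...) {
  d <- pagel_data(tree, x, y)
  model <- pagel_model(dependency, constraint, root_prior)
  fit <- fit_mk(d$tree, d$joint, model, ...)
  fit$n_shared <- d$n_shared
  fit$n_dropped <- d$n_dropped
  fit
}

#' Eight-model Pagel battery for correlated evolution
#'
#' Fits the full battery — independent evolution plus the three dependency
#' structures ("x depends on y", "y depends on x", mutual), each under
#' equal-rates and all-rates-different — ranks the eight fits by AIC, and
#' reports a dependent-vs-independent verdict together with the likelihood
#' ratio test of the nested ARD pair (mutual-dependent vs independent).
#' Dependent fits are warm-started from the corresponding independent MLE,
#' which also enforces the nesting inequality `logL_dep >= logL_indep`.
#'
#' @inheritParams fit_pagel
#' @param seed integer seed for the optimizer restarts.
#' @param n_restarts optimizer restarts per model.
#' @param delta_aic AIC margin for the "greater support" verdict.
#' @param ... passed to [fit_mk()].
#' @return object of class `pagel_battery`: `fits` (named list of 8),
#'   `table` (AIC ranking), `best`, `lr` (LR statistic, df, p for the ARD
#'   dependent-vs-independent pair), `verdict`, `n_shared`.
#' @export
fit_pagel_battery <- function(tree, x, y, seed = NULL, n_restarts = 3,
                              root_prior = c("flat", "fitzjohn"),
                              delta_aic = 2, ...) {
  root_prior <- match.arg(root_prior)
  d <- pagel_data(tree, x, y)
  deps <- c("independent", "x_on_y", "y_on_x", "mutual")
  fits <- list()
  for (con in c("ER", "ARD")) {
    indep <- fit_mk(d$tree, d$joint, pagel_model("independent", con, root_prior),
                    seed = seed, n_restarts = n_restarts, ...)
    fits[[paste0("independent.", con)]] <- indep
    for (dep in deps[-1]) {
      model <- pagel_model(dep, con, root_prior)
      init <- map_nested_rates(model, indep$model, indep$rates)
      fits[[paste0(dep, ".", con)]] <-
        fit_mk(d$tree, d$joint, model, seed = seed, n_restarts = n_restarts,
               init = init, ...)
    }
  }
  tab <- model_select(fits)
  dep_names <- names(fits)[!startsWith(names(fits), "independent")]
  best_dep <- min(tab$AIC[tab$model %in% dep_names])
  best_indep <- min(tab$AIC[!(tab$model %in% dep_names)])
  verdict <- if (best_dep <= best_indep - delta_aic) "dependent"
             else if (best_indep <= best_dep - delta_aic) "independent"
             else "similar support"
  lr <- lr_test(fits[["mutual.ARD"]], fits[["independent.ARD"]])
  structure(list(fits = fits, table = tab, best = fits[[tab$model[1]]],
                 lr = lr, verdict = verdict, delta_aic = delta_aic,
                 n_shared = d$n_shared, n_dropped = d$n_dropped),
            class = "pagel_battery")
}

# Starting rates for a dependent model at the independent MLE: every
# transition cell inherits the rate the independent model assigns there.
map_nested_rates <- function(dep_model, indep_model, indep_rates) {
  init <- numeric(dep_model$n_par)
  di <- dep_model$index_matrix; ii <- indep_model$index_matrix
  for (p in seq_len(dep_model$n_par)) {
    cell <- which(di == p)[1]
    init[p] <- indep_rates[ii[cell]]
  }
  init
}

#' Likelihood-ratio test of a nested model pair
#'
#' Companion to the AIC comparison: the dependent models nest their
#' independent counterparts, so twice the log-likelihood difference is
#' asymptotically chi-squared with `df = k_dep - k_indep`.
#'
#' @param dep,indep `mk_fit` objects on identical data, `indep` nested in
#'   `dep`.
#' @return list with `statistic` (floored at 0), `df`, `p.value`.
#' @export
lr_test <- function(dep, indep) {
  if (!identical(sort(dep$tree$tip.label), sort(indep$tree$tip.label)))
    stop("fits are not on identical data")
  if (dep$k <= indep$k) stop("models are not nested: k_dep must exceed k_indep")
  di <- dep$model$index_matrix; ii <- indep$model$index_matrix
  pairs <- unique(data.frame(d = di[di > 0], i = ii[ii > 0]))
  if (!identical(di > 0, ii > 0) || anyDuplicated(pairs$d) > 0)
    stop("models are not nested: parameter sharing is incompatible")
  stat <- max(0, 2 * (dep$logLik - indep$logLik))
  df <- dep$k - indep$k
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' @export
print.pagel_battery <- function(x, digits = 3, ...) {
  cat(sprintf("Pagel correlated-evolution battery (%d shared tips, %d dropped):\n",
              x$n_shared, x$n_dropped))
  tab <- x$table
  tab$logLik <- round(tab$logLik, digits); tab$AIC <- round(tab$AIC, digits)
  tab$dAIC <- round(tab$dAIC, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("\nVerdict (dAIC >= %g): %s evolution\n", x$delta_aic, x$verdict))
  cat(sprintf("LRT mutual.ARD vs independent.ARD: chi2 = %.3f, df = %d, p = %.4g\n",
              x$lr$statistic, x$lr$df, x$lr$p.value))
  invisible(x)
}
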