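#' Simulate a time-calibrated birth-death tree
#'
#' Exact birth-death sampler conditioned on the number of extant tips
#' (via [ape::rphylo()]), optionally rescaled to a target root age. The
#' result is ultrametric and strictly bifurcating.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param lambda,mu per-lineage birth and death rates per Myr
#'   (`lambda > mu >= 0`).
#' @param root_age if given, branch lengths are rescaled so the root sits at
#'   this age (Myr).
#' @param seed integer seed.
#' @return a `phylo`.
#' @export
simulate_tree <- function(n_tips, lambda = 0.1, mu = 0, root_age = NULL,
                          seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!(lambda > mu && mu >= 0)) stop("need lambda > mu >= 0")
  tr <- local_seed(seed, ape::rphylo(n_tips, lambda, mu, fossils = FALSE))
  if (!is.null(root_age)) {
    depth <- max(ape::node.depth.edgelength(tr)[seq_len(n_tips)])
    tr$edge.length <- tr$edge.length * root_age / depth
  }
  tr
}

#' Forward-simulate a character history on a tree
#'
#' Gillespie simulation of the continuous-time Markov chain down the tree on
#' the composite (observed x hidden) state space; tips expose the observed
#' layer only. The complete history (every event with its age) is returned
#' alongside the tip states, so recovery tests can compare inferred against
#' true gains and losses.
#'
#' @param tree a `phylo` (need not be ultrametric; ages assume it is).
#' @param model an [mk_model()] or [pagel_model()].
#' @param rates true rate values (length `model$n_par`).
#' @param root_state 1-based composite root state, or `NULL` to draw it from
#'   a flat prior over composite states.
#' @param seed integer seed.
#' @return list with `states` (named 0-based observed tip states),
#'   `composite` (named composite tip states), and `history`
#'   (a `character_history`).
#' @export
simulate_traits <- function(tree, model, rates, root_state = NULL, seed = NULL) {
  validate_tree(tree)
  Q <- rate_matrix(model, rates)
  k <- nrow(Q)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  ages <- node_ages_unchecked(tr)
  local_seed(seed, {
    ns <- integer(ntip + tr$Nnode)
    ns[root] <- if (is.null(root_state)) sample.int(k, 1L) else as.integer(root_state)
    ev <- vector("list", nrow(tr$edge))
    for (e in rev(seq_len(nrow(tr$edge)))) { # preorder
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      t_tot <- tr$edge.length[e]
      a <- ns[p]; pos <- 0; rows <- list()
      repeat {
        r <- -Q[a, a]
        if (r <= 0) break
        pos <- pos + rexp(1, r)
        if (pos >= t_tot) break
        j <- sample.int(k, 1L, prob = pmax(Q[a, ], 0))
        rows[[length(rows) + 1L]] <- data.frame(time = pos, from = a, to = j)
        a <- j
      }
      ns[ch] <- a
      if (length(rows)) {
        re <- do.call(rbind, rows)
        re$edge <- e
        re$age <- ages[p] - re$time
        ev[[e]] <- re
      }
    }
    events <- if (any(!vapply(ev, is.null, TRUE)))
      do.call(rbind, ev[!vapply(ev, is.null, TRUE)])
    else data.frame(time = numeric(0), from = integer(0), to = integer(0),
                    edge = integer(0), age = numeric(0))
    history <- structure(list(tree = tr, node_states = ns, events = events,
                              node_ages = ages, model = model,
                              map_index = NA_integer_, seed = seed),
                         class = "character_history")
    comp <- setNames(ns[seq_len(ntip)], tr$tip.label)
    states <- setNames(model$obs_of[comp] - 1L, tr$tip.label)
    list(states = states, composite = comp, history = history)
  })
}

#' Calibrated heterostyly-like simulation scenario
#'
#' Generates a full test bundle emulating the macroevolutionary conditions
#' of style-length polymorphism across angiosperms: an ultrametric
#' birth-death tree with crown age 140 Myr, and a rare binary trait evolving
#' under a two-category all-rates-different hidden-rate model. The default
#' true rates put a strong loss bias in both categories (loss/gain 100 in
#' the slow category R1 and 2.7 in the fast category R2) and are calibrated
#' so roughly 2% of tips are polymorphic, matching the rarity of the trait
#' among angiosperm genera. The root starts monomorphic in R1.
#'
#' @param n_tips number of tips (>= 200 recommended for recovery tests).
#' @param seed integer seed driving both tree and trait simulation.
#' @param root_age crown age in Myr.
#' @param rates named true rates; override to explore other regimes.
#' @return list with `tree`, `states` (0 = monomorphic, 1 = polymorphic),
#'   `history` (true history), `model`, `rates`, and `truth` (true observed-
#'   layer gain and loss counts and the polymorphic tip fraction).
#' @export
heterostyly_scenario <- function(n_tips = 2000, seed = NULL, root_age = 140,
                                 rates = NULL) {
  model <- mk_model(2, 2, "ARD")
  if (is.null(rates)) {
    rates <- c(3e-4, 3e-2,      # R1: gain M->P, loss P->M (loss/gain = 100)
               1.2e-2, 3.24e-2, # R2: gain, loss (loss/gain = 2.7)
               2.5e-3, 2.5e-3,  # R1->R2 switch (M, P)
               6e-2, 6e-2)      # R2->R1 switch (M, P)
  }
  names(rates) <- model$par_names
  tree <- simulate_tree(n_tips, lambda = 0.1, mu = 0, root_age = root_age,
                        seed = seed)
  sim <- simulate_traits(tree, model, rates, root_state = 1L,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  cnt <- count_transitions(sim$history, "observed")
  list(tree = tree, states = sim$states, history = sim$history,
       model = model, rates = rates,
       truth = list(gains = cnt["M", "P"], losses = cnt["P", "M"],
                    polymorphic_fraction = mean(sim$states == 1L)),
       seed = seed, root_age = root_age)
}

#' Simulate two binary traits under a Pagel model
#'
#' Generative twin of [fit_pagel()]: forward simulation of the 4-state joint
#' chain, returning the two tip-state vectors and the true history.
#'
#' @param tree a `phylo`.
#' @param dependency,constraint model structure, see [pagel_model()].
#' @param rates true rates (length matching the model).
#' @param root_state 1-based joint root state (default `x0.y0`).
#' @param seed integer seed.
#' @return list with named binary vectors `x` and `y`, plus `history` and
#'   `model`.
#' @export
simulate_correlated_traits <- function(tree, dependency = "independent",
                                       constraint = "ARD", rates,
                                       root_state = 1L, seed = NULL) {
  model <- pagel_model(dependency, constraint)
  sim <- simulate_traits(tree, model, rates, root_state = root_state, seed = seed)
  joint <- sim$states # 0..3
  list(x = joint %/% 2L, y = joint %% 2L, history = sim$history, model = model)
}
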