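#' Endpoint-conditioned CTMC path on a single branch
#'
#' Samples one realization of the chain over a branch of duration `t`
#' conditional on the start and end states, by uniformization (dominating
#' rate `max |Q_ii|`): the number of virtual jumps is drawn from its exact
#' conditional distribution, jump states from the discretized chain, jump
#' times as uniform order statistics; self-transitions are then discarded.
#' The sampler is exact, not approximate.
#'
#' @param Q rate matrix on the composite state space.
#' @param t branch duration (Myr), `>= 0`.
#' @param start_state,end_state 1-based composite state indices.
#' @param P optional precomputed `exp(Q t)` (saves a matrix exponential).
#' @return data.frame with columns `time` (since branch start, increasing),
#'   `from`, `to`; zero rows if no state change occurs.
#' @export
simulate_branch_conditional <- function(Q, t, start_state, end_state, P = NULL) {
  if (t < 0) stop("t must be >= 0")
  empty <- data.frame(time = numeric(0), from = integer(0), to = integer(0))
  omega <- max(-diag(Q))
  if (t == 0 || omega <= 0) {
    if (start_state != end_state)
      stop("impossible endpoint pair: zero transition probability")
    return(empty)
  }
  if (is.null(P)) P <- edge_pmats_cpp(Q, t)[, , 1]
  pab <- P[start_state, end_state]
  if (pab <= 0) stop("impossible endpoint pair: zero transition probability")
  ev <- sample_bridge_cpp(Q, t, start_state, end_state, pab)
  if (nrow(ev) == 0) return(empty)
  data.frame(time = ev[, 1], from = as.integer(ev[, 2]), to = as.integer(ev[, 3]))
}

#' Stochastic character mapping
#'
#' Samples complete character histories conditional on the tip data and the
#' fitted model: node states are drawn jointly by a downward pass (each node
#' conditional on its sampled parent and its subtree partial likelihoods),
#' then each branch path is filled in by exact endpoint-conditioned
#' uniformization sampling.
#'
#' @param fit a converged `mk_fit`.
#' @param n_maps number of maps (the study default is 100).
#' @param seed integer master seed; map `i` uses substream `seed + i`.
#' @return an object of class `simmap_list`: a list of `character_history`
#'   objects, each with `node_states`, an `events` table (edge, time, age,
#'   from, to) and provenance (`map_index`, `seed`).
#' @export
simmap <- function(fit, n_maps = 100, seed = NULL) {
  stopifnot(n_maps >= 1)
  m <- fit_machinery(fit)
  tr <- m$tr
  ntip <- length(tr$tip.label)
  ages <- node_ages_unchecked(tr)
  root_w <- m$prior * m$up[m$root, ]
  maps <- lapply(seq_len(n_maps), function(im) {
    local_seed(if (is.null(seed)) NULL else seed + im, {
      smp <- sample_one_map_cpp(fit$Q, tr$edge, tr$edge.length, m$P,
                                m$up, m$prior, m$root)
      ev <- smp$events # columns: edge, time (from branch start), from, to
      events <- data.frame(time = ev[, 2], from = as.integer(ev[, 3]),
                           to = as.integer(ev[, 4]), edge = as.integer(ev[, 1]))
      events$age <- ages[tr$edge[events$edge, 1]] - events$time
      structure(list(tree = tr, node_states = as.integer(smp$node_states),
                     events = events, node_ages = ages, model = fit$model,
                     map_index = im, seed = seed),
                class = "character_history")
    })
  })
  structure(maps, class = "simmap_list", fit = fit)
}

# Ages from depths without the ultrametricity gate (mapping itself does not
# need it; event dating does and checks separately). Floating-point noise
# near the present is snapped to age 0 so tip tallies are exact.
node_ages_unchecked <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  a <- max(d[seq_along(tree$tip.label)]) - d
  a[abs(a) < 1e-8 * max(a, 1)] <- 0
  a
}

#' @export
print.character_history <- function(x, ...) {
  cat(sprintf("Character history (map %s): %d events on %d edges\n",
              x$map_index, nrow(x$events), nrow(x$tree$edge)))
  invisible(x)
}

#' @export
print.simmap_list <- function(x, ...) {
  cat(sprintf("%d stochastic character maps; mean events per map: %.2f\n",
              length(x), mean(vapply(x, function(h) nrow(h$events), 0))))
  invisible(x)
}

# Project a composite state to a layer index vector.
layer_of <- function(model, layer) {
  switch(layer,
    composite = list(idx = seq_along(model$states), names = model$states),
    observed = list(idx = model$obs_of, names = model$obs_names),
    category = list(idx = model$hidden_of, names = model$hidden_names),
    stop("unknown layer: ", layer))
}

#' Count state transitions in a character history
#'
#' Projects each event onto the requested layer: an event that changes only
#' the hidden category contributes nothing to observed-layer counts and vice
#' versa. For the binary style-length character, observed-layer `M -> P`
#' counts are gains and `P -> M` losses.
#'
#' @param history a `character_history`.
#' @param layer `"observed"`, `"category"` or `"composite"`.
#' @return square integer matrix of counts per ordered (from, to) pair.
#' @export
count_transitions <- function(history, layer = c("observed", "category", "composite")) {
  layer <- match.arg(layer)
  pr <- layer_of(history$model, layer)
  n <- length(pr$names)
  out <- matrix(0L, n, n, dimnames = list(from = pr$names, to = pr$names))
  ev <- history$events
  if (nrow(ev)) {
    f <- pr$idx[ev$from]; t <- pr$idx[ev$to]
    keep <- f != t
    if (any(keep))
      for (i in which(keep)) out[f[i], t[i]] <- out[f[i], t[i]] + 1L
  }
  out
}

#' Ages of events of a given transition type
#'
#' @param histories a `simmap_list` or single `character_history`.
#' @param from,to state labels (or 1-based indices) in the given layer.
#' @param layer projection layer, as in [count_transitions()].
#' @param tol ultrametricity tolerance for dating (ages are only meaningful
#'   on an ultrametric tree).
#' @return data.frame with columns `map` and `age` (Myr before present);
#'   zero rows, with a warning, if no such events occur.
#' @export
event_ages <- function(histories, from, to,
                       layer = c("observed", "category", "composite"),
                       tol = 1e-3) {
  layer <- match.arg(layer)
  if (inherits(histories, "character_history")) histories <- list(histories)
  node_ages(histories[[1]]$tree, tol) # gate: errors if not ultrametric
  pr <- layer_of(histories[[1]]$model, layer)
  fi <- if (is.character(from)) match(from, pr$names) else as.integer(from)
  ti <- if (is.character(to)) match(to, pr$names) else as.integer(to)
  if (is.na(fi) || is.na(ti)) stop("unknown state label for this layer")
  out <- do.call(rbind, lapply(histories, function(h) {
    ev <- h$events
    if (!nrow(ev)) return(NULL)
    keep <- pr$idx[ev$from] == fi & pr$idx[ev$to] == ti
    if (!any(keep)) return(NULL)
    data.frame(map = h$map_index, age = ev$age[keep])
  }))
  if (is.null(out)) {
    warning(sprintf("no %s -> %s events in any map", pr$names[fi], pr$names[ti]))
    out <- data.frame(map = integer(0), age = numeric(0))
  }
  out
}

#' Mode of an event-age distribution
#'
#' Argmax of a Gaussian kernel density estimate on a fixed grid over
#' `[0, upper]` (Silverman's rule by default).
#'
#' @param ages numeric vector of event ages (Myr), length >= 2.
#' @param bw bandwidth rule or value, passed to [stats::density()].
#' @param n grid size.
#' @param upper upper grid limit; defaults to `max(ages)`.
#' @return the mode age (scalar).
#' @export
density_mode <- function(ages, bw = "nrd0", n = 512, upper = NULL) {
  if (length(ages) < 2) stop("need at least 2 ages")
  if (diff(range(ages)) == 0) return(ages[1])
  if (is.null(upper)) upper <- max(ages)
  d <- density(ages, bw = bw, n = n, from = 0, to = upper)
  d$x[which.max(d$y)]
}

#' Lineages through time by state
#'
#' Step function of the number of contemporaneous lineages in each state of
#' the chosen layer, under one mapped history. Counts change only at nodes
#' and mapped events; at the present they equal the tip-state tallies, and
#' at every age they sum to the total number of live lineages.
#'
#' @param history a `character_history` on an ultrametric tree.
#' @param layer projection layer.
#' @return data.frame `(age, state, n)` evaluated at every breakpoint age,
#'   sorted from the root (oldest) to the present.
#' @export
ltt_by_state <- function(history, layer = c("observed", "category", "composite")) {
  layer <- match.arg(layer)
  pr <- layer_of(history$model, layer)
  tr <- history$tree
  ages <- history$node_ages
  ns <- history$node_states
  ev <- history$events
  # per-edge piecewise segments (age_top, age_bot, composite state)
  segs <- vector("list", nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    ee <- ev[ev$edge == e, , drop = FALSE]
    ee <- ee[order(ee$time), , drop = FALSE]
    bounds <- c(ages[p], ee$age, ages[ch])
    states <- c(ns[p], ee$to)
    segs[[e]] <- data.frame(top = bounds[-length(bounds)], bot = bounds[-1],
                            state = states)
  }
  segs <- do.call(rbind, segs)
  breaks <- sort(unique(c(0, ages, ev$age)), decreasing = TRUE)
  root <- length(tr$tip.label) + 1L
  rows <- lapply(breaks, function(a) {
    if (a >= max(ages)) {
      n <- integer(length(pr$names))
      n[pr$idx[ns[root]]] <- 1L
      return(data.frame(age = a, state = pr$names, n = n))
    }
    cover <- segs$top > a & segs$bot <= a
    cnt <- tabulate(pr$idx[segs$state[cover]], nbins = length(pr$names))
    data.frame(age = a, state = pr$names, n = cnt)
  })
  do.call(rbind, rows)
}

#' Summarize transition counts across stochastic maps
#'
#' @param histories a `simmap_list` (>= 2 maps).
#' @param layer projection layer.
#' @return object of class `mapping_summary`: a table of per-transition-type
#'   mean, median and 2.5/97.5 percentile counts (linear-interpolation
#'   percentiles) across maps, plus `n_maps`.
#' @export
summarize_maps <- function(histories, layer = c("observed", "category", "composite")) {
  layer <- match.arg(layer)
  if (length(histories) < 2) stop("need at least 2 maps")
  pr <- layer_of(histories[[1]]$model, layer)
  n <- length(pr$names)
  counts <- t(vapply(histories, function(h) as.vector(count_transitions(h, layer)),
                     numeric(n * n)))
  pairs <- expand.grid(from = pr$names, to = pr$names, stringsAsFactors = FALSE)
  keep <- pairs$from != pairs$to
  tab <- data.frame(
    from = pairs$from[keep], to = pairs$to[keep],
    mean = colMeans(counts[, keep, drop = FALSE]),
    median = apply(counts[, keep, drop = FALSE], 2, stats::median),
    lo = apply(counts[, keep, drop = FALSE], 2, quantile, 0.025),
    hi = apply(counts[, keep, drop = FALSE], 2, quantile, 0.975),
    row.names = NULL
  )
  structure(list(table = tab, n_maps = length(histories), layer = layer,
                 counts = counts[, keep, drop = FALSE]),
            class = "mapping_summary")
}

#' @export
print.mapping_summary <- function(x, digits = 2, ...) {
  cat(sprintf("Transition counts over %d stochastic maps (%s layer):\n",
              x$n_maps, x$layer))
  tab <- x$table
  tab$mean <- round(tab$mean, digits); tab$lo <- round(tab$lo, digits)
  tab$hi <- round(tab$hi, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot lineages-through-time curves by state
#'
#' @param ltt output of [ltt_by_state()].
#' @param log use a logarithmic lineage axis.
#' @param ... passed to [plot()].
#' @export
plot_ltt <- function(ltt, log = TRUE, ...) {
  states <- unique(ltt$state)
  cols <- seq_along(states)
  ymax <- max(ltt$n)
  plot(NA, xlim = rev(range(ltt$age)), ylim = c(if (log) 1 else 0, ymax),
       xlab = "age (Myr before present)", ylab = "lineages",
       log = if (log) "y" else "", ...)
  for (i in seq_along(states)) {
    d <- ltt[ltt$state == states[i] & (!log | ltt$n > 0), ]
    lines(d$age, pmax(d$n, if (log) 1 else 0), type = "s", col = cols[i])
  }
  legend("topleft", legend = states, col = cols, lty = 1, bty = "n")
  invisible(NULL)
}
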