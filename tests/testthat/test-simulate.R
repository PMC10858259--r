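test_that("simulated trees meet the scenario contract", {
  tr <- simulate_tree(2, lambda = 1, seed = 1)
  d <- ape::node.depth.edgelength(tr)
  expect_equal(d[1], d[2], tolerance = 1e-12) # a cherry with equal tip paths
  tr <- simulate_tree(500, lambda = 0.2, mu = 0, root_age = 140, seed = 2)
  expect_equal(tr$Nnode, 499L) # strictly bifurcating
  expect_equal(tree_depth(tr), 140, tolerance = 1e-9)
  expect_error(simulate_tree(1), ">= 2")
  expect_error(simulate_tree(10, lambda = 0.1, mu = 0.2), "lambda > mu")
})

test_that("pure-birth trees accumulate lineages at rate lambda", {
  # Yule property: log lineage count grows ~ linearly at slope lambda
  set.seed(3)
  lam <- 0.15
  slopes <- replicate(8, {
    tr <- simulate_tree(400, lambda = lam, seed = sample.int(1e6, 1))
    bt <- sort(ape::branching.times(tr), decreasing = TRUE)
    n <- seq_along(bt) + 1 # lineage count after each branching event
    unname(coef(lm(log(n) ~ I(bt[1] - bt)))[2])
  })
  expect_equal(mean(slopes), lam, tolerance = 0.15)
})

test_that("forward trait simulation is self-consistent with its history", {
  set.seed(4)
  tree <- simulate_tree(100, root_age = 100, seed = 4)
  m <- mk_model(2, 2, "ARD")
  rates <- c(0.01, 0.03, 0.05, 0.08, 0.01, 0.01, 0.02, 0.02)
  sim <- simulate_traits(tree, m, rates, root_state = 1L, seed = 5)
  h <- sim$history
  # tip states re-derivable from the history's node states
  ntip <- length(h$tree$tip.label)
  expect_equal(unname(sim$composite), h$node_states[seq_len(ntip)],
               ignore_attr = TRUE)
  expect_equal(unname(sim$states), m$obs_of[unname(sim$composite)] - 1L)
  # every branch path starts at the parent state and ends at the child state
  for (e in unique(h$events$edge)) {
    ev <- h$events[h$events$edge == e, ]
    ev <- ev[order(ev$time), ]
    expect_equal(ev$from[1], h$node_states[h$tree$edge[e, 1]])
    expect_equal(ev$to[nrow(ev)], h$node_states[h$tree$edge[e, 2]])
    if (nrow(ev) > 1) expect_true(all(ev$from[-1] == ev$to[-nrow(ev)]))
  }
  # zero rates: every tip inherits the root state
  sim0 <- simulate_traits(tree, m, rep(1e-300, 8), root_state = 1L, seed = 6)
  expect_true(all(sim0$states == 0))
  expect_equal(nrow(sim0$history$events), 0)
  # reproducibility
  sim2 <- simulate_traits(tree, m, rates, root_state = 1L, seed = 5)
  expect_identical(sim$states, sim2$states)
  expect_identical(sim$history$events, sim2$history$events)
})

test_that("long-branch simulation reaches the stationary distribution", {
  # star tree with very long branches: tip states approach equal frequencies
  set.seed(7)
  n <- 600
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(500, n)
  m <- mk_model(2, 1, "ER")
  sim <- simulate_traits(tr, m, 0.05, root_state = 1L, seed = 8)
  expect_lt(abs(mean(sim$states) - 0.5), 3.5 * sqrt(0.25 / n))
})

test_that("the heterostyly scenario matches its calibration targets", {
  set.seed(9)
  frac <- vapply(1:6, function(s)
    heterostyly_scenario(1000, seed = s)$truth$polymorphic_fraction, 0)
  # rare derived state, in the calibrated band
  expect_true(all(frac >= 0.005 & frac <= 0.06))
  sc <- heterostyly_scenario(500, seed = 10)
  expect_equal(tree_depth(sc$tree), 140, tolerance = 1e-9)
  # gains+losses must be at least the parsimony score of the tip data
  if (requireNamespace("phangorn", quietly = TRUE)) {
    pd <- phangorn::phyDat(as.matrix(data.frame(row.names = names(sc$states),
                                                s = as.character(sc$states))),
                           type = "USER", levels = c("0", "1"))
    score <- phangorn::parsimony(sc$tree, pd)
    expect_gte(sc$truth$gains + sc$truth$losses, score)
  }
  # slow-regime limit: R1-only rates produce almost no events
  quiet <- heterostyly_scenario(300, seed = 11,
                                rates = c(3e-4, 3e-2, 3e-4, 3e-2, 1e-300,
                                          1e-300, 1e-300, 1e-300))
  expect_lt(nrow(quiet$history$events), 12)
})

test_that("correlated-trait simulation honours the dependency structure", {
  set.seed(12)
  tree <- simulate_tree(200, root_age = 100, seed = 12)
  m <- pagel_model("mutual", "ARD")
  # forbid entering x1.y1: rates into the joint state ~ 0
  rates <- setNames(rep(0.05, 8), m$par_names)
  rates["q.x.0->1|y1"] <- 1e-300
  rates["q.y.0->1|x1"] <- 1e-300
  sim <- simulate_correlated_traits(tree, "mutual", "ARD", rates, seed = 13)
  expect_equal(sum(sim$x == 1 & sim$y == 1), 0L)
  # independent spec with zero rates: both traits constant
  r0 <- rep(1e-300, 4)
  sim0 <- simulate_correlated_traits(tree, "independent", "ARD", r0, seed = 14)
  expect_true(all(sim0$x == 0) && all(sim0$y == 0))
})
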