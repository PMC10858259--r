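test_that("endpoint-conditioned branch sampler obeys structural invariants", {
  m <- mk_model(2, 1, "ER")
  Q <- rate_matrix(m, 0.5)
  # zero-rate chain: empty path, and unequal endpoints are impossible
  Q0 <- rate_matrix(m, 1e-300) * 0
  expect_equal(nrow(simulate_branch_conditional(Q0, 1, 1, 1)), 0)
  expect_error(simulate_branch_conditional(Q0, 1, 1, 2), "impossible")
  set.seed(1)
  for (rep in 1:200) {
    path <- simulate_branch_conditional(Q, 2, 1, 2)
    expect_true(nrow(path) %% 2 == 1) # parity: unequal endpoints, binary chain
    if (nrow(path) > 1) expect_true(all(diff(path$time) > 0))
    expect_equal(path$from[1], 1)
    expect_equal(path$to[nrow(path)], 2)
  }
  for (rep in 1:100) {
    path <- simulate_branch_conditional(Q, 2, 1, 1)
    expect_true(nrow(path) %% 2 == 0)
  }
})

test_that("probability of an event-free bridge matches the closed form", {
  q <- 0.7; t <- 1.2
  m <- mk_model(2, 1, "ER")
  Q <- rate_matrix(m, q)
  p00 <- 0.5 * (1 + exp(-2 * q * t))
  p_zero <- exp(-q * t) / p00 # P(no events | start = end = 0)
  set.seed(2)
  n <- 20000
  zeros <- sum(vapply(seq_len(n),
                      function(i) nrow(simulate_branch_conditional(Q, t, 1, 1)) == 0,
                      TRUE))
  se <- sqrt(p_zero * (1 - p_zero) / n)
  expect_lt(abs(zeros / n - p_zero), 3.5 * se)
})

test_that("conditional sampler agrees with unconditioned forward simulation", {
  m <- mk_model(2, 1, "ARD")
  Q <- rate_matrix(m, c(0.4, 0.9))
  t <- 1.5
  set.seed(3)
  n <- 20000
  fwd <- t(vapply(seq_len(n), function(i) forward_branch_oracle(Q, t, 1), c(0, 0)))
  for (b in 1:2) {
    sel <- fwd[fwd[, "end"] == b, "n"]
    cond <- vapply(seq_len(length(sel)),
                   function(i) nrow(simulate_branch_conditional(Q, t, 1, b)),
                   0)
    se <- sqrt(var(sel) / length(sel) + var(cond) / length(cond))
    expect_lt(abs(mean(sel) - mean(cond)), 3.5 * se)
  }
})

test_that("transition counting projects composite events correctly", {
  m <- mk_model(2, 2, "ARD")
  tr <- read_newick("(A:1,B:1);")
  # states: 1 = M.R1, 2 = P.R1, 3 = M.R2, 4 = P.R2
  h <- structure(list(
    tree = ape::reorder.phylo(tr, "postorder"),
    node_states = c(2L, 4L, 1L),
    events = data.frame(time = c(0.3, 0.6, 0.5), from = c(1L, 2L, 1L),
                        to = c(2L, 4L, 3L), edge = c(1L, 1L, 2L),
                        age = c(0.7, 0.4, 0.5)),
    node_ages = c(0, 0, 1), model = m, map_index = 1L, seed = NULL),
    class = "character_history")
  obs <- count_transitions(h, "observed")
  expect_equal(obs["M", "P"], 1L) # gain (R1: M -> P)
  expect_equal(obs["P", "M"], 0L)
  cat <- count_transitions(h, "category")
  expect_equal(cat["R1", "R2"], 2L) # P.R1 -> P.R2 and M.R1 -> M.R2
  comp <- count_transitions(h, "composite")
  expect_equal(sum(obs), sum(comp) - sum(cat)) # dual changes are forbidden
  # empty history: all zeros
  h0 <- h; h0$events <- h$events[0, ]
  expect_true(all(count_transitions(h0, "observed") == 0L))
})

test_that("maps condition correctly on the data and the fitted model", {
  set.seed(8)
  tree <- simulate_tree(100, root_age = 100, seed = 8)
  m <- mk_model(2, 1, "ER")
  sim <- simulate_traits(tree, m, 0.01, root_state = 1L, seed = 9)
  fit <- fit_mk(tree, sim$states, m, n_restarts = 2, seed = 10)
  maps <- simmap(fit, n_maps = 20, seed = 11)
  expect_length(maps, 20)
  for (h in maps[1:5]) {
    ntip <- length(h$tree$tip.label)
    # sampled tip states match the observed data
    obs <- sim$states[h$tree$tip.label]
    expect_equal(unname(h$node_states[seq_len(ntip)] - 1L), unname(obs))
    # branch paths are consistent with sampled node states
    if (nrow(h$events)) {
      for (e in unique(h$events$edge)) {
        ev <- h$events[h$events$edge == e, ]
        ev <- ev[order(ev$time), ]
        expect_equal(ev$from[1], h$node_states[h$tree$edge[e, 1]])
        expect_equal(ev$to[nrow(ev)], h$node_states[h$tree$edge[e, 2]])
      }
    }
  }
  # reproducibility under the master seed
  maps2 <- simmap(fit, n_maps = 20, seed = 11)
  expect_identical(maps[[7]]$events, maps2[[7]]$events)
})

test_that("sampled node states reproduce the marginal posteriors", {
  set.seed(12)
  tr <- read_newick("((A:1,B:1.5):1,(C:0.8,D:1):1.2);")
  tr$edge.length <- tr$edge.length * 2
  m <- mk_model(2, 1, "ARD")
  fit <- list(tree = tr, states = c(A = 0, B = 1, C = 0, D = 1),
              model = m, Q = rate_matrix(m, c(0.3, 0.5)), root_prior = "flat",
              rates = c(0.3, 0.5))
  class(fit) <- "mk_fit"
  anc <- marginal_ancestral_states(fit)
  maps <- simmap(fit, n_maps = 4000, seed = 13)
  root <- 5
  freq <- mean(vapply(maps, function(h) h$node_states[root] == 1L, TRUE))
  p <- anc$composite[root, 1]
  expect_lt(abs(freq - p), 3.5 * sqrt(p * (1 - p) / 4000))
})

test_that("event ages are bounded by the branch and the tree", {
  set.seed(14)
  sc <- heterostyly_scenario(300, seed = 14)
  ages <- sc$history$node_ages
  ev <- sc$history$events
  expect_true(all(ev$age > 0 & ev$age < max(ages)))
  for (i in seq_len(nrow(ev))) {
    e <- ev$edge[i]
    expect_lt(ev$age[i], ages[sc$history$tree$edge[e, 1]])
    expect_gte(ev$age[i], ages[sc$history$tree$edge[e, 2]])
  }
  ga <- event_ages(sc$history, "M", "P", "observed")
  expect_equal(nrow(ga), sc$truth$gains)
  # dual transitions are forbidden by the model, so none can be found
  expect_warning(event_ages(sc$history, "M.R1", "P.R2", "composite"),
                 "no .* events")
})

test_that("density mode finds the dominant component of a mixture", {
  expect_equal(density_mode(c(5, 5, 5)), 5)
  expect_error(density_mode(numeric(0)), "at least 2")
  set.seed(15)
  x <- c(rnorm(8000, 5, 1), rnorm(2000, 50, 2))
  x <- x[x > 0]
  expect_lt(abs(density_mode(x, upper = 60) - 5), 0.5)
})

test_that("LTT curves conserve the total lineage count", {
  set.seed(16)
  sc <- heterostyly_scenario(150, seed = 16)
  ltt <- ltt_by_state(sc$history, "observed")
  ages <- unique(ltt$age)
  tot <- vapply(ages, function(a) sum(ltt$n[ltt$age == a]), 0L)
  # at the present the states tally the tips; the root carries one lineage
  expect_equal(tot[ages == 0], 150L)
  expect_equal(tot[which.max(ages)], 1L)
  plain_ltt <- vapply(ages, function(a)
    if (a >= max(sc$history$node_ages)) 1L
    else sum(sc$history$node_ages[sc$history$tree$edge[, 1]] > a &
             sc$history$node_ages[sc$history$tree$edge[, 2]] <= a), 0L)
  expect_equal(tot, plain_ltt)
  # present-day tallies match the tip states
  now <- ltt[ltt$age == 0, ]
  expect_equal(now$n[now$state == "P"], sum(sc$states == 1))
})

test_that("constant-state history yields the plain LTT in that state", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  m <- mk_model(2, 1, "ER")
  h <- structure(list(tree = ape::reorder.phylo(tr, "postorder"),
                      node_states = rep(1L, 5),
                      events = data.frame(time = numeric(0), from = integer(0),
                                          to = integer(0), edge = integer(0),
                                          age = numeric(0)),
                      node_ages = c(0, 0, 0, 2, 1), model = m,
                      map_index = 1L, seed = NULL),
                 class = "character_history")
  ltt <- ltt_by_state(h, "observed")
  expect_true(all(ltt$n[ltt$state == "P"] == 0))
  mono <- ltt[ltt$state == "M", ]
  expect_equal(mono$n[order(mono$age, decreasing = TRUE)], c(1, 2, 3))
})

test_that("map summaries use linear-interpolation percentiles", {
  tr <- read_newick("(A:1,B:1);")
  m <- mk_model(2, 1, "ER")
  mk_hist <- function(gains, im) {
    ev <- if (gains > 0)
      data.frame(time = seq_len(gains) / (gains + 1), from = 1L, to = 2L,
                 edge = 1L, age = 1 - seq_len(gains) / (gains + 1))
    else data.frame(time = numeric(0), from = integer(0), to = integer(0),
                    edge = integer(0), age = numeric(0))
    structure(list(tree = ape::reorder.phylo(tr, "postorder"),
                   node_states = c(2L, 1L, 1L), events = ev,
                   node_ages = c(0, 0, 1), model = m, map_index = im,
                   seed = NULL), class = "character_history")
  }
  # NB: alternating M->P events would be impossible mid-branch; counts only
  maps <- structure(list(mk_hist(1, 1), mk_hist(2, 2), mk_hist(3, 3)),
                    class = "simmap_list")
  sm <- summarize_maps(maps, "observed")
  row <- sm$table[sm$table$from == "M" & sm$table$to == "P", ]
  expect_equal(row$mean, 2)
  expect_equal(row$lo, 1.05)
  expect_equal(row$hi, 2.95)
  # a type absent from every map: mean 0, CI [0, 0]
  row2 <- sm$table[sm$table$from == "P" & sm$table$to == "M", ]
  expect_equal(c(row2$mean, row2$lo, row2$hi), c(0, 0, 0))
  expect_error(summarize_maps(maps[1], "observed"), "at least 2")
})
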