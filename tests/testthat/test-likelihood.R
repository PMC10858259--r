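test_that("two-tip likelihood matches the closed-form enumeration", {
  tr <- read_newick("(A:1,B:1);")
  m <- mk_model(2, 1, "ER")
  Q <- rate_matrix(m, 0.5)
  p <- 0.5 * (1 + exp(-1)); q <- 1 - p
  expect_equal(mk_loglik(tr, c(A = 0, B = 0), Q, m),
               log(0.5 * p^2 + 0.5 * q^2), tolerance = 1e-10)
  # no transitions possible at rate zero
  Q0 <- rate_matrix(m, 1e-300)
  expect_equal(mk_loglik(tr, c(A = 0, B = 0), Q0, m), log(0.5), tolerance = 1e-9)
})

test_that("pruning equals brute-force enumeration on small random trees", {
  set.seed(202)
  for (rep in 1:25) {
    tr <- random_small_tree(6)
    cs <- random_model_case()
    states <- random_states(tr, cs$n_obs)
    ll <- mk_loglik(tr, states, cs$Q, cs$model, root_prior = "flat")
    bf <- brute_force_loglik(tr, states, cs$Q, cs$model)
    expect_equal(ll, bf, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to child order and to splitting a branch", {
  m <- mk_model(2, 1, "ARD")
  Q <- rate_matrix(m, c(0.2, 0.6))
  s <- c(A = 0, B = 1, C = 0)
  t1 <- read_newick("(A:1,(B:2,C:3):1);")
  t2 <- read_newick("((C:3,B:2):1,A:1);")
  expect_equal(mk_loglik(t1, s, Q, m), mk_loglik(t2, s, Q, m), tolerance = 1e-12)
  # splitting an edge with a degree-2 node leaves the likelihood unchanged
  t3 <- read_newick("(A:1,(B:2,C:3):1);")
  t4 <- t3
  # insert a node halfway along the internal edge
  t4$edge <- rbind(c(4L, 1L), c(4L, 6L), c(6L, 5L), c(5L, 2L), c(5L, 3L))
  t4$edge.length <- c(1, 0.4, 0.6, 2, 3)
  t4$Nnode <- 3L
  expect_equal(mk_loglik(t3, s, Q, m), mk_loglik(t4, s, Q, m), tolerance = 1e-12)
})

test_that("a one-category HMM reduces to the plain Mk likelihood", {
  set.seed(31)
  tr <- random_small_tree(6)
  states <- random_states(tr, 2, p_na = 0)
  q <- c(0.15, 0.45)
  mk1 <- mk_model(2, 1, "ARD")
  ll1 <- mk_loglik(tr, states, rate_matrix(mk1, q), mk1)
  # two identical categories with zero switch rates: same likelihood
  mk2 <- mk_model(2, 2, "ARD")
  ll2 <- mk_loglik(tr, states, rate_matrix(mk2, c(q, q, rep(1e-300, 4))), mk2)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("missing tips and the ambiguity flag behave as documented", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  m <- mk_model(2, 1, "ER")
  Q <- rate_matrix(m, 0.3)
  # an all-missing tip integrates out: equals likelihood on the pruned tree
  ll_na <- mk_loglik(tr, c(A = 0, B = 0, C = NA), Q, m)
  ll_drop <- mk_loglik(drop_tips(tr, "C"), c(A = 0, B = 0), Q, m)
  expect_equal(ll_na, ll_drop, tolerance = 1e-12)
  # unnamed vectors must match tip count
  expect_error(mk_loglik(tr, c(0, 1), Q, m), "match the number of tips")
})

test_that("polytomies are handled as hard multifurcations", {
  tr <- read_newick("(A:1,B:1,C:1,D:1);")
  m <- mk_model(2, 1, "ER")
  Q <- rate_matrix(m, 0.4)
  s <- c(A = 0, B = 0, C = 1, D = 1)
  # star tree: tips independent given the root state
  P <- transition_probability(Q, 1)
  manual <- log(0.5 * P[1, 1]^2 * P[1, 2]^2 + 0.5 * P[2, 1]^2 * P[2, 2]^2)
  expect_equal(mk_loglik(tr, s, Q, m), manual, tolerance = 1e-12)
})

test_that("pruning likelihood agrees with an external implementation", {
  skip_if_not_installed("phytools")
  set.seed(77)
  tr <- ape::rtree(12)
  s <- setNames(sample(0:1, 12, replace = TRUE), tr$tip.label)
  m <- mk_model(2, 1, "ARD")
  Q <- rate_matrix(m, c(0.3, 0.8))
  x <- setNames(factor(s, levels = 0:1), names(s))
  ext <- phytools::fitMk(tr, x, fixedQ = Q, pi = "equal")
  expect_equal(mk_loglik(tr, s, Q, m), as.numeric(ext$logLik), tolerance = 1e-6)
})

test_that("marginal ancestral states match brute-force posteriors", {
  set.seed(404)
  for (rep in 1:5) {
    tr <- random_small_tree(4)
    cs <- random_model_case()
    states <- random_states(tr, cs$n_obs, p_na = 0)
    fit <- list(tree = tr, states = states, model = cs$model, Q = cs$Q,
                root_prior = "flat")
    class(fit) <- "mk_fit"
    anc <- marginal_ancestral_states(fit)
    bf <- brute_force_marginals(tr, states, cs$Q, cs$model)
    expect_equal(unname(anc$composite), unname(bf), tolerance = 1e-10)
    expect_lt(max(abs(rowSums(anc$composite) - 1)), 1e-9)
    # observed-state marginal is the hidden-category sum
    expect_equal(rowSums(anc$composite[, cs$model$obs_of == 1, drop = FALSE]),
                 unname(anc$observed[, 1]), tolerance = 1e-12)
  }
})

test_that("near-zero rates pin the root to the shared tip state", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  m <- mk_model(2, 1, "ER")
  fit <- list(tree = tr, states = c(A = 0, B = 0, C = 0),
              model = m, Q = rate_matrix(m, 1e-12), root_prior = "flat")
  class(fit) <- "mk_fit"
  anc <- marginal_ancestral_states(fit)
  root <- 4
  expect_equal(unname(anc$observed[root, ]), c(1, 0), tolerance = 1e-6)
})
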