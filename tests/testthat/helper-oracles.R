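# Independent oracles used across the suite. Deliberately implemented with
# different machinery than the package: matrix exponentials via Matrix::expm,
# likelihoods by exhaustive enumeration, expectations by numerical
# integration.

expm_oracle <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

# Tip partial-likelihood expansion, restated from the model definition:
# observed state compatible with every hidden category; NA with everything.
tip_partials_oracle <- function(tree, states, model) {
  k <- length(model$states)
  L <- matrix(0, length(tree$tip.label), k)
  s <- states[tree$tip.label]
  for (i in seq_along(tree$tip.label)) {
    if (is.na(s[i])) L[i, ] <- 1 else L[i, model$obs_of == (s[i] + 1L)] <- 1
  }
  L
}

# Brute-force likelihood: sum over every assignment of composite states to
# internal nodes of prior x product of branch transition probabilities,
# with tip ambiguity folded in analytically.
brute_force_loglik <- function(tree, states, Q, model, root_prior = "flat") {
  tr <- ape::reorder.phylo(tree, "postorder")
  k <- nrow(Q)
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  tipL <- tip_partials_oracle(tr, states, model)
  P <- lapply(seq_len(nrow(tr$edge)), function(e) expm_oracle(Q * tr$edge.length[e]))
  internals <- (ntip + 1L):nnode
  asn <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  if (root_prior != "flat") stop("oracle supports flat prior only")
  tot <- 0
  for (r in seq_len(nrow(asn))) {
    st <- integer(nnode)
    st[internals] <- asn[r, ]
    pr <- 1 / k
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      pr <- pr * if (ch <= ntip) sum(P[[e]][st[p], ] * tipL[ch, ])
                 else P[[e]][st[p], st[ch]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# Brute-force marginal posterior at every node (flat root prior).
brute_force_marginals <- function(tree, states, Q, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  k <- nrow(Q)
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  tipL <- tip_partials_oracle(tr, states, model)
  P <- lapply(seq_len(nrow(tr$edge)), function(e) expm_oracle(Q * tr$edge.length[e]))
  internals <- (ntip + 1L):nnode
  asn <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  post <- matrix(0, nnode, k)
  for (r in seq_len(nrow(asn))) {
    st <- integer(nnode)
    st[internals] <- asn[r, ]
    pr <- 1 / k
    tipw <- matrix(0, ntip, k)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      if (ch <= ntip) {
        w <- P[[e]][st[p], ] * tipL[ch, ]
        tipw[ch, ] <- w
        pr <- pr * sum(w)
      } else pr <- pr * P[[e]][st[p], st[ch]]
    }
    for (nd in internals) post[nd, st[nd]] <- post[nd, st[nd]] + pr
    for (tp in seq_len(ntip)) {
      s <- sum(tipw[tp, ])
      if (s > 0) post[tp, ] <- post[tp, ] + pr * tipw[tp, ] / s
    }
  }
  post / rowSums(post)
}

# Expected number of (real) state changes on a branch of length t,
# conditional on the endpoints, by numerical integration of
# q_ij P_ai(tau) P_jb(t - tau) / P_ab(t).
expected_events_conditional <- function(Q, t, a, b) {
  pab <- expm_oracle(Q * t)[a, b]
  k <- nrow(Q)
  tot <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j && Q[i, j] > 0) {
    f <- Vectorize(function(tau)
      expm_oracle(Q * tau)[a, i] * Q[i, j] * expm_oracle(Q * (t - tau))[j, b])
    tot <- tot + stats::integrate(f, 0, t, rel.tol = 1e-9)$value
  }
  tot / pab
}

# Unconditioned forward CTMC path on one branch: (end state, n events).
forward_branch_oracle <- function(Q, t, start) {
  a <- start; pos <- 0; n <- 0
  repeat {
    r <- -Q[a, a]
    if (r <= 0) break
    pos <- pos + rexp(1, r)
    if (pos >= t) break
    p <- pmax(Q[a, ], 0)
    a <- sample.int(nrow(Q), 1, prob = p)
    n <- n + 1
  }
  c(end = a, n = n)
}

# Small random tree with up to `max_tips` tips (>= 2), random edge lengths.
random_small_tree <- function(max_tips = 6) {
  n <- sample(2:max_tips, 1)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 2)
  tr
}

# Random model + rates from the families exercised in the analyses.
random_model_case <- function() {
  pick <- sample(3, 1)
  model <- switch(pick,
                  mk_model(2, 1, sample(c("ER", "ARD"), 1)),
                  mk_model(2, 2, sample(c("ER", "ARD"), 1)),
                  pagel_model(sample(c("independent", "x_on_y", "mutual"), 1),
                              sample(c("ER", "ARD"), 1)))
  rates <- runif(model$n_par, 0.05, 1.5)
  list(model = model, rates = rates, Q = rate_matrix(model, rates),
       n_obs = model$n_obs)
}

# Named random binary tip states (0-based observed states, some NA).
random_states <- function(tree, n_obs, p_na = 0.1) {
  s <- sample(0:(n_obs - 1), length(tree$tip.label), replace = TRUE)
  s[runif(length(s)) < p_na] <- NA
  stats::setNames(s, tree$tip.label)
}
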