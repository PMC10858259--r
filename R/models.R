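#' Specify an Mk model with optional hidden rate categories
#'
#' Builds the parameter-sharing structure of a continuous-time Markov model
#' on the composite state space observed x hidden. Composite state
#' `s = (h - 1) * n_obs + o` pairs observed state `o` (1-based) with hidden
#' rate category `h`; for the binary style-length character the composite
#' states are `M.R1, P.R1, M.R2, P.R2`. Dual transitions (simultaneous
#' change of observed state and category) are forbidden.
#'
#' Free-parameter counts for a binary character: 1 category ER = 1, ARD = 2;
#' 2 categories ER = 4 (one observed-transition rate per category plus one
#' switch rate per direction, shared across observed states), ARD = 8
#' (four observed-state rates plus four switch rates, one per observed state
#' and direction).
#'
#' @param n_obs number of observed states (2 for presence/absence).
#' @param n_hidden number of hidden rate categories (1 = plain Mk).
#' @param constraint `"ER"` (equal rates; symmetric for a binary trait) or
#'   `"ARD"` (all rates different).
#' @param root_prior `"flat"` over composite states, or `"fitzjohn"`
#'   (likelihood-weighted).
#' @param obs_names,hidden_names optional state labels.
#' @return an object of class `mk_model`: the integer index matrix (0 =
#'   forbidden), parameter names and count, and the composite state labels.
#' @export
mk_model <- function(n_obs = 2, n_hidden = 1,
                     constraint = c("ARD", "ER"),
                     root_prior = c("flat", "fitzjohn"),
                     obs_names = NULL, hidden_names = NULL) {
  constraint <- match.arg(toupper(constraint[1]), c("ARD", "ER"))
  root_prior <- match.arg(root_prior)
  if (n_obs < 2) stop("n_obs must be >= 2")
  if (n_hidden < 1) stop("n_hidden must be >= 1")
  if (is.null(obs_names))
    obs_names <- if (n_obs == 2) c("M", "P") else paste0("s", seq_len(n_obs) - 1)
  if (is.null(hidden_names)) hidden_names <- paste0("R", seq_len(n_hidden))
  k <- n_obs * n_hidden
  states <- as.vector(outer(obs_names, hidden_names,
                            function(o, h) if (n_hidden > 1) paste(o, h, sep = ".") else o))
  idx <- matrix(0L, k, k, dimnames = list(states, states))
  pnames <- character(0)
  new_par <- function(nm) {
    pnames[[length(pnames) + 1L]] <<- nm
    length(pnames)
  }
  comp <- function(o, h) (h - 1L) * n_obs + o
  # observed-state transitions within each hidden category
  for (h in seq_len(n_hidden)) {
    if (constraint == "ER") {
      p <- new_par(sprintf("q.obs%s", if (n_hidden > 1) paste0(".", hidden_names[h]) else ""))
      for (o1 in seq_len(n_obs)) for (o2 in seq_len(n_obs)) if (o1 != o2)
        idx[comp(o1, h), comp(o2, h)] <- p
    } else {
      for (o1 in seq_len(n_obs)) for (o2 in seq_len(n_obs)) if (o1 != o2) {
        nm <- sprintf("q.%s->%s%s", obs_names[o1], obs_names[o2],
                      if (n_hidden > 1) paste0(".", hidden_names[h]) else "")
        idx[comp(o1, h), comp(o2, h)] <- new_par(nm)
      }
    }
  }
  # hidden-category switches (observed state held fixed)
  if (n_hidden > 1) {
    for (h1 in seq_len(n_hidden)) for (h2 in seq_len(n_hidden)) if (h1 != h2) {
      if (constraint == "ER") {
        p <- new_par(sprintf("q.%s->%s", hidden_names[h1], hidden_names[h2]))
        for (o in seq_len(n_obs)) idx[comp(o, h1), comp(o, h2)] <- p
      } else {
        for (o in seq_len(n_obs)) {
          nm <- sprintf("q.%s->%s.%s", hidden_names[h1], hidden_names[h2], obs_names[o])
          idx[comp(o, h1), comp(o, h2)] <- new_par(nm)
        }
      }
    }
  }
  structure(list(
    n_obs = n_obs, n_hidden = n_hidden, constraint = constraint,
    root_prior = root_prior, index_matrix = idx, n_par = length(pnames),
    par_names = unlist(pnames), states = states,
    obs_names = obs_names, hidden_names = hidden_names,
    obs_of = rep(seq_len(n_obs), n_hidden),
    hidden_of = rep(seq_len(n_hidden), each = n_obs),
    kind = "mk_hmm"
  ), class = "mk_model")
}

#' Specify a Pagel two-trait model
#'
#' Four-state chain over the joint states of two binary traits x and y,
#' ordered `(x0.y0, x0.y1, x1.y0, x1.y1)`. Simultaneous change of both
#' traits is forbidden. "x depends on y" means x's transition rates differ
#' with y's current state while y's rates are y-only, and vice versa; the
#' `"ER"` option equates forward and backward rates within each trait and
#' conditioning state.
#'
#' Free parameters: independent ER = 2, ARD = 4; one-way dependence ER = 3,
#' ARD = 6; mutual ER = 4, ARD = 8.
#'
#' @param dependency one of `"independent"`, `"x_on_y"`, `"y_on_x"`,
#'   `"mutual"`.
#' @param constraint `"ER"` or `"ARD"`.
#' @param root_prior as in [mk_model()].
#' @param trait_names length-2 character, names for x and y.
#' @return an `mk_model` usable by the same likelihood machinery, with the
#'   Pagel metadata stored in `$pagel`.
#' @export
pagel_model <- function(dependency = c("independent", "x_on_y", "y_on_x", "mutual"),
                        constraint = c("ARD", "ER"),
                        root_prior = c("flat", "fitzjohn"),
                        trait_names = c("x", "y")) {
  dependency <- match.arg(dependency)
  constraint <- match.arg(toupper(constraint[1]), c("ARD", "ER"))
  root_prior <- match.arg(root_prior)
  states <- c("x0.y0", "x0.y1", "x1.y0", "x1.y1")
  xs <- c(0L, 0L, 1L, 1L); ys <- c(0L, 1L, 0L, 1L)
  idx <- matrix(0L, 4, 4, dimnames = list(states, states))
  pnames <- list()
  key2par <- new.env(parent = emptyenv())
  par_of <- function(key, nm) {
    if (!is.null(key2par[[key]])) return(key2par[[key]])
    pnames[[length(pnames) + 1L]] <<- nm
    key2par[[key]] <- length(pnames)
    length(pnames)
  }
  x_dep <- dependency %in% c("x_on_y", "mutual")
  y_dep <- dependency %in% c("y_on_x", "mutual")
  for (i in 1:4) for (j in 1:4) {
    dx <- xs[i] != xs[j]; dy <- ys[i] != ys[j]
    if (dx + dy != 1L) next
    if (dx) {
      cond <- if (x_dep) paste0("|y", ys[i]) else ""
      dir <- if (constraint == "ARD") paste0(xs[i], xs[j]) else "sym"
      key <- paste0("x", dir, cond)
      nm <- sprintf("q.%s%s%s", trait_names[1],
                    if (constraint == "ARD") sprintf(".%d->%d", xs[i], xs[j]) else "",
                    cond)
      idx[i, j] <- par_of(key, nm)
    } else {
      cond <- if (y_dep) paste0("|x", xs[i]) else ""
      dir <- if (constraint == "ARD") paste0(ys[i], ys[j]) else "sym"
      key <- paste0("y", dir, cond)
      nm <- sprintf("q.%s%s%s", trait_names[2],
                    if (constraint == "ARD") sprintf(".%d->%d", ys[i], ys[j]) else "",
                    cond)
      idx[i, j] <- par_of(key, nm)
    }
  }
  m <- structure(list(
    n_obs = 4L, n_hidden = 1L, constraint = constraint,
    root_prior = root_prior, index_matrix = idx, n_par = length(pnames),
    par_names = unlist(pnames), states = states,
    obs_names = states, hidden_names = "R1",
    obs_of = 1:4, hidden_of = rep(1L, 4),
    kind = "pagel",
    pagel = list(dependency = dependency, trait_names = trait_names,
                 x_of = xs, y_of = ys)
  ), class = "mk_model")
  m
}

#' Build the instantaneous rate matrix from a model and parameter values
#'
#' @param model an `mk_model`.
#' @param rates numeric vector of length `model$n_par` (events per Myr).
#' @return the k x k rate matrix Q (rows sum to zero).
#' @export
rate_matrix <- function(model, rates) {
  stopifnot(inherits(model, "mk_model"))
  if (length(rates) != model$n_par)
    stop(sprintf("expected %d rates, got %d", model$n_par, length(rates)))
  if (any(rates < 0)) stop("rates must be >= 0")
  idx <- model$index_matrix
  Q <- matrix(0, nrow(idx), ncol(idx), dimnames = dimnames(idx))
  nz <- idx > 0L
  Q[nz] <- rates[idx[nz]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' @export
print.mk_model <- function(x, ...) {
  if (x$kind == "pagel") {
    cat(sprintf("Pagel two-trait model (%s, %s): %d states, %d free parameters\n",
                x$pagel$dependency, x$constraint, length(x$states), x$n_par))
  } else {
    cat(sprintf("Mk%s model (%s): %d observed state(s) x %d rate categor%s, %d free parameters\n",
                if (x$n_hidden > 1) "/HMM" else "", x$constraint, x$n_obs,
                x$n_hidden, if (x$n_hidden > 1) "ies" else "y", x$n_par))
  }
  cat("Parameter-sharing index matrix (0 = forbidden):\n")
  print(x$index_matrix)
  invisible(x)
}

#' Transition probability matrix over a branch
#'
#' Computes `exp(Q t)` by dense Pade scaling-and-squaring (state spaces here
#' are at most 8 x 8).
#'
#' @param Q rate matrix (rows sum to 0).
#' @param t branch duration in Myr, `t >= 0`.
#' @return stochastic matrix of the same dimension.
#' @export
transition_probability <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  P <- edge_pmats_cpp(Q, t)[, , 1]
  dimnames(P) <- dimnames(Q)
  P
}
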