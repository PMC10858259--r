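#' Read a phylogeny from a Newick string or file
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is
#' the standard `phylo` object used throughout the package. Trees must be
#' rooted with branch lengths (in Myr) on every non-root edge; polytomies
#' are accepted and treated as hard multifurcations.
#'
#' @param text Newick string (use `file` for a path instead).
#' @param file path to a Newick file.
#' @return an object of class `phylo`.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tr <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file = file),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w)))
  if (is.null(tr)) stop("Newick parse error: malformed tree string")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree, got several")
  validate_tree(tr)
  tr
}

#' Write a phylogeny to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# Contract checks shared by every entry point that accepts a tree.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a `phylo` object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must all be present and >= 0")
  invisible(tree)
}

#' Node ages of an ultrametric tree
#'
#' Ages are measured in time before present: tips at 0, the root at the tree
#' depth. The tree must be ultrametric within a relative tolerance
#' (published megatrees carry rounding noise, hence the default 1e-3).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tol relative ultrametricity tolerance (fraction of tree depth).
#' @return numeric vector of ages indexed by node id (tips first, as in
#'   `tree$edge`), named by tip label for tips.
#' @export
node_ages <- function(tree, tol = 1e-3) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  depth <- numeric(nnode) # distance from root
  tr <- ape::reorder.phylo(tree, "cladewise") # parents precede children
  for (i in seq_len(nrow(tr$edge))) {
    depth[tr$edge[i, 2]] <- depth[tr$edge[i, 1]] + tr$edge.length[i]
  }
  h <- max(depth[seq_len(ntip)])
  dev <- max(abs(depth[seq_len(ntip)] - h))
  if (h > 0 && dev > tol * h)
    stop(sprintf("tree not ultrametric: max root-to-tip deviation %.6g (%.3g%% of depth %.6g)",
                 dev, 100 * dev / h, h))
  ages <- h - depth
  ages[seq_len(ntip)] <- 0
  names(ages) <- c(tree$tip.label, rep("", tree$Nnode))
  ages
}

#' Depth (root age) of an ultrametric tree
#' @inheritParams node_ages
#' @return root age in Myr.
#' @export
tree_depth <- function(tree, tol = 1e-3) {
  unname(node_ages(tree, tol)[length(tree$tip.label) + 1L])
}

#' Drop tips from a tree
#'
#' Removes the given tips, suppressing resulting degree-2 nodes (their
#' branch lengths are summed), so pairwise path lengths among retained tips
#' are preserved exactly. Wraps [ape::drop.tip()].
#'
#' @param tree a `phylo` object.
#' @param labels character vector of tip labels to remove (may be empty).
#' @return the pruned `phylo`.
#' @export
drop_tips <- function(tree, labels) {
  validate_tree(tree)
  if (length(labels) == 0) return(tree)
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown))
    stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  if (length(labels) >= length(tree$tip.label))
    stop("cannot drop all tips")
  ape::drop.tip(tree, labels, collapse.singles = TRUE)
}

#' Keep one randomly chosen tip per group
#'
#' Used to reduce a species-level tree to one exemplar per genus. Selection
#' is a deterministic function of the tree, the mapping and the seed.
#'
#' @param tree a `phylo` object.
#' @param group_of named character vector mapping tip label to group label,
#'   or a two-column data frame (tip, group).
#' @param seed integer seed controlling the random choice within groups.
#' @return pruned `phylo` with exactly one tip per group.
#' @export
subsample_one_per_group <- function(tree, group_of, seed) {
  validate_tree(tree)
  if (is.data.frame(group_of)) {
    group_of <- setNames(as.character(group_of[[2]]), as.character(group_of[[1]]))
  }
  missing_map <- setdiff(tree$tip.label, names(group_of))
  if (length(missing_map))
    stop("tips without a group: ", paste(head(missing_map, 5), collapse = ", "))
  groups <- group_of[tree$tip.label]
  keep <- local_seed(seed, {
    unlist(lapply(split(tree$tip.label, groups), function(tips) {
      if (length(tips) == 1L) tips else sample(tips, 1L)
    }), use.names = FALSE)
  })
  to_drop <- setdiff(tree$tip.label, keep)
  if (length(to_drop) == 0) return(tree)
  drop_tips(tree, to_drop)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}
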