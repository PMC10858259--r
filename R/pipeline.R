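# Config handling: a YAML path or a plain named list. Seeds are mandatory
# (no wall-clock seeding) so every run is exactly reproducible.
load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$seed)) stop("config error: `seed` is mandatory")
  config
}

config_tree <- function(config) {
  tr <- config$tree
  if (inherits(tr, "phylo")) return(validate_tree(tr))
  if (is.character(tr)) {
    if (!file.exists(tr)) stop("tree file not found: ", tr)
    return(read_newick(file = tr))
  }
  stop("config error: `tree` must be a phylo or a Newick path")
}

config_trait <- function(x, what = "traits") {
  if (is.character(x) && length(x) == 1 && file.exists(x)) return(read_trait_csv(x))
  if (!is.null(names(x))) return(x)
  stop("config error: `", what, "` must be a named vector or a CSV path")
}

#' Run the full style-length polymorphism macroevolution analysis
#'
#' Orchestrates the complete single-trait workflow: load tree and binary
#' trait, match labels (unmatched rows are reported, tips without data are
#' treated as ambiguous), fit the four-model Mk/HMM grid, select by AIC,
#' sample stochastic character maps under the best model, and summarize
#' gains/losses, event ages (with density modes) and lineages-through-time
#' curves. Identical config + seed gives identical output.
#'
#' @param config named list or YAML path. Fields: `tree` (Newick path or
#'   `phylo`), `traits` (CSV path or named 0/1 vector), `seed` (mandatory),
#'   and optionally `n_maps` (default 100), `n_restarts` (default 5),
#'   `root_prior`, `n_hidden`, `constraints`, `out_dir`.
#' @return object of class `polymorphism_analysis`: the model-selection
#'   table, best fit, mapping summaries (observed and category layers), age
#'   summaries per transition type, LTT curves for the first map, and the
#'   echoed config.
#' @export
run_polymorphism_analysis <- function(config) {
  config <- load_config(config)
  tree <- config_tree(config)
  traits <- config_trait(config$traits)
  n_maps <- config$n_maps %||% 100
  n_restarts <- config$n_restarts %||% 5
  unmatched <- setdiff(names(traits), tree$tip.label)
  missing_tips <- setdiff(tree$tip.label, names(traits))
  traits <- traits[intersect(names(traits), tree$tip.label)]
  grid <- fit_mk_grid(tree, traits,
                      n_hidden = config$n_hidden %||% c(1, 2),
                      constraints = config$constraints %||% c("ER", "ARD"),
                      seed = config$seed, n_restarts = n_restarts,
                      root_prior = config$root_prior %||% "flat")
  best <- grid$best
  maps <- simmap(best, n_maps = n_maps, seed = config$seed)
  obs_sum <- summarize_maps(maps, "observed")
  cat_sum <- if (best$model$n_hidden > 1) summarize_maps(maps, "category") else NULL
  age_summary <- function(from, to) {
    ag <- tryCatch(suppressWarnings(event_ages(maps, from, to, "observed")),
                   error = function(e) NULL)
    if (is.null(ag) || nrow(ag) == 0)
      return(list(n = 0L, oldest = NA, youngest = NA, mode = NA,
                  single_map = list(n = 0L, oldest = NA, youngest = NA)))
    one <- ag[ag$map == ag$map[1], ]
    list(n = nrow(ag), oldest = max(ag$age), youngest = min(ag$age),
         mode = if (nrow(ag) >= 2) density_mode(ag$age) else ag$age[1],
         single_map = list(n = nrow(one), oldest = max(one$age),
                           youngest = min(one$age)))
  }
  ages <- list(gains = age_summary("M", "P"), losses = age_summary("P", "M"))
  ltt <- ltt_by_state(maps[[1]], "observed")
  bundle <- structure(list(
    table = grid$table, fits = grid$fits, best = best, maps = maps,
    summary_observed = obs_sum, summary_category = cat_sum, ages = ages,
    ltt = ltt, unmatched_rows = unmatched, tips_without_data = missing_tips,
    config = config
  ), class = "polymorphism_analysis")
  if (!is.null(config$out_dir)) write_polymorphism_bundle(bundle, config$out_dir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_polymorphism_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(bundle$table, file.path(dir, "model_selection.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(bundle$summary_observed$table, file.path(dir, "transition_counts.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(bundle$ltt, file.path(dir, "ltt_by_state.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    seed = bundle$config$seed,
    best_model = bundle$table$model[1],
    rates = as.list(bundle$best$rates),
    logLik = bundle$best$logLik, k = bundle$best$k, AIC = bundle$best$AIC,
    ages = bundle$ages,
    unmatched_rows = bundle$unmatched_rows,
    tips_without_data = length(bundle$tips_without_data)
  ), file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run correlated-evolution batteries against a set of second traits
#'
#' For each named comparison trait, prunes to the shared tip set and runs
#' the eight-model Pagel battery of [fit_pagel_battery()].
#'
#' @param config named list or YAML path with fields `tree`, `x` (the focal
#'   binary trait), `comparisons` (named list of traits or CSV paths),
#'   `seed` (mandatory), and optionally `n_restarts`, `delta_aic`,
#'   `out_dir`.
#' @return object of class `correlation_analysis`: per-comparison batteries
#'   and a verdict table.
#' @export
run_correlation_analysis <- function(config) {
  config <- load_config(config)
  tree <- config_tree(config)
  x <- config_trait(config$x, "x")
  comparisons <- config$comparisons
  if (is.null(names(comparisons))) stop("config error: `comparisons` must be named")
  batteries <- lapply(names(comparisons), function(nm) {
    y <- config_trait(comparisons[[nm]], nm)
    fit_pagel_battery(tree, x, y, seed = config$seed,
                      n_restarts = config$n_restarts %||% 3,
                      delta_aic = config$delta_aic %||% 2)
  })
  names(batteries) <- names(comparisons)
  verdicts <- data.frame(
    comparison = names(batteries),
    best_model = vapply(batteries, function(b) b$table$model[1], ""),
    verdict = vapply(batteries, function(b) b$verdict, ""),
    lr_stat = vapply(batteries, function(b) b$lr$statistic, 0),
    lr_p = vapply(batteries, function(b) b$lr$p.value, 0),
    n_shared = vapply(batteries, function(b) b$n_shared, 0L),
    row.names = NULL
  )
  bundle <- structure(list(batteries = batteries, verdicts = verdicts,
                           config = config),
                      class = "correlation_analysis")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(verdicts, file.path(config$out_dir, "pagel_verdicts.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      lapply(batteries, function(b) list(table = b$table, verdict = b$verdict,
                                         lr = b$lr)),
      file.path(config$out_dir, "pagel_batteries.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' Human-readable report of an analysis bundle
#'
#' Every number printed is also present in the serialized artifacts when an
#' `out_dir` was configured.
#'
#' @param bundle a `polymorphism_analysis` or `correlation_analysis`.
#' @return the bundle, invisibly.
#' @export
report <- function(bundle) {
  if (inherits(bundle, "polymorphism_analysis")) {
    cat("== Style-length polymorphism macroevolution ==\n")
    cat(sprintf("seed: %s; maps: %d\n", bundle$config$seed, length(bundle$maps)))
    if (length(bundle$unmatched_rows))
      cat(sprintf("trait rows not in tree: %d\n", length(bundle$unmatched_rows)))
    if (length(bundle$tips_without_data))
      cat(sprintf("tips without trait data (treated as ambiguous): %d\n",
                  length(bundle$tips_without_data)))
    cat("\nModel selection (AIC):\n")
    print(bundle$table, row.names = FALSE)
    cat("\nBest-model rates (events/Myr):\n")
    print(signif(bundle$best$rates, 4))
    cat("\n")
    print(bundle$summary_observed)
    if (!is.null(bundle$summary_category)) { cat("\n"); print(bundle$summary_category) }
    g <- bundle$ages$gains; l <- bundle$ages$losses
    if (g$n > 0)
      cat(sprintf("\nGain ages: oldest %.2f, youngest %.2f, mode %.2f Myr (pooled over maps)\n",
                  g$oldest, g$youngest, g$mode))
    if (l$n > 0)
      cat(sprintf("Loss ages: oldest %.2f, youngest %.2f, mode %.2f Myr (pooled over maps)\n",
                  l$oldest, l$youngest, l$mode))
  } else if (inherits(bundle, "correlation_analysis")) {
    cat("== Correlated evolution (Pagel batteries) ==\n")
    if (nrow(bundle$verdicts) == 0) cat("no comparisons configured\n")
    else print(bundle$verdicts, row.names = FALSE)
  } else stop("unknown bundle type")
  invisible(bundle)
}

#' @export
print.polymorphism_analysis <- function(x, ...) report(x)

#' @export
print.correlation_analysis <- function(x, ...) report(x)
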