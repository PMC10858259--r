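# Binary coding rules for floral traits and pollination systems. All
# thresholds are strict on the state-1 side (">" / "more than"); exact
# boundary cases go to state 0. Every function is a pure function of its
# inputs and the threshold, so tables are re-derivable from the metadata.

#' Code organ fusion as a binary trait
#'
#' Perianth or filament fusion is scored unfused (0) or fused (1) against a
#' threshold fraction of organ length (default 5%).
#'
#' @param percent_fused numeric in \[0, 100\], percent of organ length fused.
#' @param kind which fusion trait (`"perianth"`, `"filament"`,
#'   `"filament_to_perianth"`); recorded, does not change the rule.
#' @param threshold percent threshold; state 1 iff strictly greater.
#' @return integer 0/1 (NA in, NA out).
#' @export
code_fusion <- function(percent_fused,
                        kind = c("perianth", "filament", "filament_to_perianth"),
                        threshold = 5) {
  kind <- match.arg(kind)
  if (any(!is.na(percent_fused) & (percent_fused < 0 | percent_fused > 100)))
    stop("percent_fused must be in [0, 100]")
  as.integer(percent_fused > threshold)
}

#' Code perianth symmetry
#'
#' Actinomorphic (radial) is state 0, zygomorphic (bilateral) state 1.
#' Labels are case-folded; anything else is an error.
#'
#' @param class character vector of symmetry classes.
#' @return integer 0/1.
#' @export
code_symmetry <- function(class) {
  cl <- tolower(trimws(as.character(class)))
  out <- ifelse(is.na(cl), NA_integer_,
                ifelse(cl == "actinomorphic", 0L,
                       ifelse(cl == "zygomorphic", 1L, NA_integer_)))
  bad <- !is.na(cl) & is.na(out)
  if (any(bad)) stop("unknown symmetry class: ", paste(unique(class[bad]), collapse = ", "))
  out
}

#' Code stamen number
#'
#' Few (state 0) versus many (state 1), threshold strictly greater than 10.
#'
#' @param n non-negative integer counts.
#' @param threshold count threshold; state 1 iff strictly greater.
#' @return integer 0/1.
#' @export
code_stamens <- function(n, threshold = 10) {
  if (any(!is.na(n) & n < 0)) stop("stamen count must be >= 0")
  as.integer(n > threshold)
}

#' Code carpel number
#'
#' Few (state 0) versus many (state 1), threshold strictly greater than 5.
#'
#' @inheritParams code_stamens
#' @export
code_carpels <- function(n, threshold = 5) {
  if (any(!is.na(n) & n < 0)) stop("carpel count must be >= 0")
  as.integer(n > threshold)
}

# Controlled vocabulary of pollinator functional types: taxonomic group and
# tongue class. Long-tongued: birds, long-tongued bees (Apidae,
# Megachilidae), long-tongued flies (Bombyliidae, Nemestrinidae),
# butterflies and moths; every other animal is short-tongued.
pollinator_vocab <- function() {
  data.frame(
    type = c("apidae", "megachilidae", "halictidae", "andrenidae",
             "colletidae", "bombyliidae", "nemestrinidae", "syrphidae",
             "muscidae", "butterfly", "moth", "beetle", "wasp", "ant",
             "thrips", "bird", "bat", "rodent", "lizard", "wind", "water"),
    group = c(rep("insect", 15), "bird", rep("other_vertebrate", 3),
              rep("abiotic", 2)),
    tongue = c("long", "long", "short", "short", "short", "long", "long",
               "short", "short", "long", "long", "short", "short", "short",
               "short", "long", "short", "short", "short", NA, NA),
    stringsAsFactors = FALSE
  )
}

# Synonym folding into the controlled vocabulary; unknown terms error.
normalize_type <- function(type) {
  syn <- c(nemestridae = "nemestrinidae", lepidoptera_butterfly = "butterfly",
           lepidoptera_moth = "moth", hummingbird = "bird", sunbird = "bird")
  t0 <- tolower(trimws(as.character(type)))
  t0 <- ifelse(t0 %in% names(syn), unname(syn[t0]), t0)
  vocab <- pollinator_vocab()
  bad <- !is.na(t0) & !(t0 %in% vocab$type)
  if (any(bad))
    stop("unknown pollinator functional type: ",
         paste(unique(type[bad]), collapse = ", "))
  t0
}

#' Tongue class of a pollinator functional type
#'
#' @param functional_type character vector of vocabulary terms (bee / fly
#'   families, `"butterfly"`, `"moth"`, `"bird"`, other animals). Abiotic
#'   vectors (`"wind"`, `"water"`) are rejected here; they are handled by
#'   the pollination-system contrasts.
#' @return character `"long"` or `"short"`.
#' @export
code_tongue <- function(functional_type) {
  t0 <- normalize_type(functional_type)
  vocab <- pollinator_vocab()
  i <- match(t0, vocab$type)
  if (any(vocab$group[i] == "abiotic", na.rm = TRUE))
    stop("abiotic vectors have no tongue class: ",
         paste(unique(functional_type[vocab$group[i] == "abiotic"]), collapse = ", "))
  vocab$tongue[i]
}

#' Generalism of a pollination system
#'
#' A system is generalist when no single pollinator functional type accounts
#' for more than 66% of visits (strict).
#'
#' @param visit_fractions named numeric vector of visit fractions by
#'   functional type (need not sum to 1; must not be all zero).
#' @param threshold specialist iff some fraction strictly exceeds this.
#' @return `"generalist"` or `"specialist"`.
#' @export
code_generalism <- function(visit_fractions, threshold = 0.66) {
  if (any(visit_fractions < 0)) stop("fractions must be >= 0")
  if (all(visit_fractions == 0)) stop("all-zero visit fractions")
  if (max(visit_fractions) > threshold) "specialist" else "generalist"
}

#' Code species for one of the six pollination-system contrasts
#'
#' From species-level pollination records (functional type and visit
#' fraction), derives the binary state for a named contrast. Species not
#' scorable for the contrast (e.g. wind-pollinated species in the
#' insect-vs-bird contrast) come back `NA`; exclusion counts are attached as
#' the `"excluded"` attribute. State 0 is the first-named side of each
#' contrast, state 1 the second.
#'
#' @param records data.frame with columns `species`, `type` (vocabulary
#'   term) and `fraction` (visit fraction; one row per species x type).
#' @param pair one of `"biotic_vs_abiotic"`, `"insect_vs_vertebrate"`,
#'   `"insect_vs_bird"`, `"generalist_vs_specialist"`,
#'   `"long_vs_short_tongued_animals"`, `"long_vs_short_tongued_insects"`.
#' @param generalism_threshold passed to [code_generalism()].
#' @return named integer vector (species -> 0/1/NA).
#' @export
build_system_pair <- function(records,
                              pair = c("biotic_vs_abiotic", "insect_vs_vertebrate",
                                       "insect_vs_bird", "generalist_vs_specialist",
                                       "long_vs_short_tongued_animals",
                                       "long_vs_short_tongued_insects"),
                              generalism_threshold = 0.66) {
  pair <- match.arg(pair)
  stopifnot(all(c("species", "type", "fraction") %in% names(records)))
  records$type <- normalize_type(records$type)
  vocab <- pollinator_vocab()
  records <- merge(records, vocab, by = "type", sort = FALSE)
  per_species <- split(records, records$species)
  out <- vapply(per_species, function(r) {
    dom <- r[which.max(r$fraction), ] # dominant functional type
    switch(pair,
      biotic_vs_abiotic = as.integer(dom$group == "abiotic"),
      insect_vs_vertebrate = {
        g <- dom$group
        if (g == "insect") 0L
        else if (g %in% c("bird", "other_vertebrate")) 1L
        else NA_integer_
      },
      insect_vs_bird = {
        g <- dom$group
        if (g == "insect") 0L else if (g == "bird") 1L else NA_integer_
      },
      generalist_vs_specialist = {
        if (all(r$group == "abiotic")) NA_integer_
        else as.integer(code_generalism(setNames(r$fraction, r$type),
                                        generalism_threshold) == "specialist")
      },
      long_vs_short_tongued_animals = {
        if (dom$group == "abiotic") NA_integer_
        else as.integer(dom$tongue == "short")
      },
      long_vs_short_tongued_insects = {
        ins <- r[r$group == "insect", ]
        if (dom$group != "insect" || nrow(ins) == 0) NA_integer_
        else as.integer(ins$tongue[which.max(ins$fraction)] == "short")
      })
  }, integer(1))
  excluded <- sum(is.na(out))
  structure(out, excluded = excluded)
}

#' Collapse a species-level trait table to genus level
#'
#' When a genus has several species, one is chosen at random
#' (seed-reproducible). A `polymorphic` column, if present, is aggregated as
#' "any qualifying report in the genus" instead; rows flagged `doubtful` are
#' excluded from that aggregation by default.
#'
#' @param species_table data.frame with columns `species`, `genus`, optional
#'   `polymorphic` and `doubtful`, plus any number of trait columns.
#' @param seed integer seed for the per-genus species choice.
#' @param exclude_doubtful drop doubtful polymorphism reports (default).
#' @return data.frame with one row per genus; metadata (`seed`,
#'   `rule_version`) in attributes.
#' @export
genus_table <- function(species_table, seed, exclude_doubtful = TRUE) {
  stopifnot(all(c("species", "genus") %in% names(species_table)))
  tab <- species_table
  rows <- local_seed(seed, {
    unlist(lapply(split(seq_len(nrow(tab)), tab$genus), function(i) {
      if (length(i) == 1L) i else sample(i, 1L)
    }), use.names = FALSE)
  })
  out <- tab[rows, setdiff(names(tab), c("polymorphic", "doubtful")), drop = FALSE]
  if ("polymorphic" %in% names(tab)) {
    p <- tab$polymorphic
    if (exclude_doubtful && "doubtful" %in% names(tab))
      p[tab$doubtful %in% c(TRUE, 1L)] <- NA
    agg <- tapply(p, tab$genus, function(v)
      if (all(is.na(v))) NA_integer_ else as.integer(any(v == 1L, na.rm = TRUE)))
    out$polymorphic <- as.integer(agg[out$genus])
  }
  rownames(out) <- NULL
  structure(out, seed = seed, rule_version = "1",
            exclude_doubtful = exclude_doubtful)
}

#' Read a taxon-state trait CSV
#'
#' Two columns, `taxon` and `state` (0/1 or state labels); returns the named
#' vector used by [fit_mk()].
#'
#' @param file CSV path.
#' @return named vector of states.
#' @export
read_trait_csv <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("trait CSV needs two columns: taxon, state")
  setNames(d[[2]], d[[1]])
}
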