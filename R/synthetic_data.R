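#' Default taxonomy stub for synthetic collections
#'
#' Builds the genome metadata for a simulated collection: a four-order clade
#' hierarchy (NC, NS, NT, NP) with seven NP subclades plus outgroup genomes.
#' The deep-sediment subclades (theta, delta, iota) carry the
#' `marine_sediment` habitat flag; the pelagic deep subclades (alpha, gamma)
#' carry `deep_ocean` and `pelagic`; remaining clades and the outgroup are
#' flagged `terrestrial`.
#'
#' @param n_per_order Named integer vector of genomes per non-NP order.
#' @param np_subclades Named integer vector: genomes per NP subclade.
#' @param n_outgroup Number of outgroup genomes.
#' @return A metadata tibble (see [read_metadata()]).
#' @export
synthetic_taxonomy <- function(n_per_order = c(NC = 4, NS = 5, NT = 4),
                               np_subclades = c(alpha = 2, gamma = 2,
                                                delta = 2, epsilon = 2,
                                                eta = 2, theta = 2, iota = 2),
                               n_outgroup = 3) {
  sediment <- c("theta", "delta", "iota")
  pelagic_deep <- c("alpha", "gamma")
  rows <- list()
  for (ord in names(n_per_order)) {
    for (i in seq_len(n_per_order[[ord]])) {
      rows[[length(rows) + 1]] <- tibble(
        genome_id = sprintf("%s_g%02d", ord, i), order = ord, subclade = "",
        habitat_flags = list("terrestrial"))
    }
  }
  for (sc in names(np_subclades)) {
    flags <- if (sc %in% sediment) c("marine_sediment", "deep_ocean")
             else if (sc %in% pelagic_deep) c("deep_ocean", "pelagic")
             else "pelagic"
    for (i in seq_len(np_subclades[[sc]])) {
      rows[[length(rows) + 1]] <- tibble(
        genome_id = sprintf("NP_%s_g%02d", sc, i), order = "NP",
        subclade = sc, habitat_flags = list(flags))
    }
  }
  for (i in seq_len(n_outgroup)) {
    rows[[length(rows) + 1]] <- tibble(
      genome_id = sprintf("OUT_g%02d", i), order = "OUTGROUP", subclade = "",
      habitat_flags = list("terrestrial"))
  }
  meta <- bind_rows(rows)
  meta$completeness <- NA_real_
  meta$contamination <- NA_real_
  validate_metadata(meta)
  meta
}

#' Blueprint for a synthetic genome collection with planted family structure
#'
#' Describes the ground-truth protein-family structure planted into a
#' simulated collection: core families spanning every non-outgroup genome,
#' order-specific and subclade-specific families, families restricted to the
#' deep-sediment subclades, families shared by the pelagic deep subclades,
#' singletons, and optional contaminants. Identity levels are *pairwise*
#' targets between family members, as measured by the package's own aligner.
#'
#' @param taxonomy Metadata tibble (default [synthetic_taxonomy()]).
#' @param n_core Families present in every non-outgroup genome.
#' @param n_order_specific Named vector: families restricted to each order.
#' @param n_subclade_specific Named vector: families restricted to single NP
#'   subclades.
#' @param n_sediment_specific Families spanning >= 2 of the sediment
#'   subclades and absent everywhere else.
#' @param n_deep_shared Families spanning both pelagic deep subclades and
#'   absent from all other genomes.
#' @param n_singletons Families with a single member in one random genome.
#' @param family_length_range Ancestor length range (residues).
#' @param within_family_identity Target pairwise identity between members of
#'   one family, in (0, 1].
#' @param cross_family_max_identity Maximum tolerated identity between
#'   ancestors of different families (rejection-sampled when `separable`).
#' @param dropout_prob Probability that a designated genome loses a family
#'   (genome incompleteness).
#' @param contaminant_rate Expected contaminant families per genome; each
#'   contaminant family is placed in a single genome.
#' @param sediment_subclades,deep_subclades NP subclades treated as
#'   deep-sediment and pelagic-deep when planting habitat-linked families.
#' @param separable Enforce the identity margin
#'   `within_family_identity - cross_family_max_identity >= 0.15` and
#'   rejection-sample ancestors against `cross_family_max_identity`.
#' @param seed Integer seed; generation is byte-deterministic given the
#'   blueprint.
#' @return An object of class `synthetic_blueprint`.
#' @export
synthetic_blueprint <- function(taxonomy = synthetic_taxonomy(),
                                n_core = 40,
                                n_order_specific = c(NC = 5, NS = 5,
                                                     NT = 5, NP = 5),
                                n_subclade_specific = c(alpha = 2, gamma = 2,
                                                        delta = 2, epsilon = 2,
                                                        eta = 2, theta = 3,
                                                        iota = 2),
                                n_sediment_specific = 8,
                                n_deep_shared = 5,
                                n_singletons = 30,
                                family_length_range = c(80, 200),
                                within_family_identity = 0.60,
                                cross_family_max_identity = 0.20,
                                dropout_prob = 0.10,
                                contaminant_rate = 0,
                                sediment_subclades = c("theta", "delta", "iota"),
                                deep_subclades = c("alpha", "gamma"),
                                separable = TRUE,
                                seed = 1L) {
  validate_metadata(taxonomy)
  # tolerate YAML-style lists for the count maps and ranges
  n_order_specific <- unlist(n_order_specific)
  n_subclade_specific <- unlist(n_subclade_specific)
  family_length_range <- unlist(family_length_range)
  sediment_subclades <- unlist(sediment_subclades)
  deep_subclades <- unlist(deep_subclades)
  counts <- c(n_core, n_order_specific, n_subclade_specific,
              n_sediment_specific, n_deep_shared, n_singletons)
  if (any(counts < 0)) abort("all family counts must be >= 0")
  stopifnot(within_family_identity > 0, within_family_identity <= 1,
            cross_family_max_identity >= 0,
            dropout_prob >= 0, dropout_prob < 1,
            contaminant_rate >= 0,
            length(family_length_range) == 2,
            family_length_range[1] >= 10,
            family_length_range[2] >= family_length_range[1])
  if (separable &&
      within_family_identity - cross_family_max_identity < 0.15) {
    abort(paste0("separable mode requires within_family_identity - ",
                 "cross_family_max_identity >= 0.15 (got ",
                 within_family_identity - cross_family_max_identity, ")"))
  }
  bad_order <- setdiff(names(n_order_specific), unique(taxonomy$order))
  if (length(bad_order)) abort(paste0("order not in taxonomy: ", bad_order[1]))
  subclades <- setdiff(unique(taxonomy$subclade), "")
  bad_sc <- setdiff(names(n_subclade_specific), subclades)
  if (length(bad_sc)) abort(paste0("subclade not in taxonomy: ", bad_sc[1]))
  structure(list(
    taxonomy = taxonomy, n_core = n_core,
    n_order_specific = n_order_specific,
    n_subclade_specific = n_subclade_specific,
    n_sediment_specific = n_sediment_specific,
    n_deep_shared = n_deep_shared, n_singletons = n_singletons,
    family_length_range = as.integer(family_length_range),
    within_family_identity = within_family_identity,
    cross_family_max_identity = cross_family_max_identity,
    dropout_prob = dropout_prob, contaminant_rate = contaminant_rate,
    sediment_subclades = sediment_subclades, deep_subclades = deep_subclades,
    separable = separable, seed = as.integer(seed)
  ), class = "synthetic_blueprint")
}

# Per-copy substitution rate d such that two independent copies of an
# ancestor have expected pairwise identity t:
#   (1-d)^2 + d^2/19 = t  (mutations go to one of the 19 other residues)
mutation_rate_for_identity <- function(t) {
  stopifnot(t > 0, t <= 1)
  (19 / 20) * (1 - sqrt(1 - (20 / 19) * (1 - t)))
}

mutate_protein <- function(residues, rate) {
  chars <- strsplit(residues, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(aa_letters, ch), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

random_protein <- function(len) {
  paste(sample(aa_letters, len, replace = TRUE), collapse = "")
}

#' Simulate one protein family at a target pairwise identity
#'
#' Draws a random ancestor and derives `n_copies` independent descendants by
#' point substitution so that the expected pairwise identity between any two
#' copies equals `target_identity`.
#'
#' @param n_copies Number of family members.
#' @param length Ancestor length (residues).
#' @param target_identity Expected pairwise identity between members.
#' @param seed Integer seed.
#' @return Tibble of records (`seq_id`, `description`, `residues`,
#'   `genome_id`), one per copy.
#' @export
simulate_family <- function(n_copies, length, target_identity, seed = 1L) {
  d <- mutation_rate_for_identity(target_identity)
  withr::with_seed(seed, {
    anc <- random_protein(length)
    tibble(
      seq_id = sprintf("fam_p%02d", seq_len(n_copies)),
      description = "",
      residues = vapply(seq_len(n_copies), function(i) mutate_protein(anc, d),
                        character(1)),
      genome_id = sprintf("g%02d", seq_len(n_copies))
    )
  })
}

# Family plan: which genomes each truth family is designated to occupy.
plan_families <- function(bp) {
  meta <- bp$taxonomy
  non_out <- meta$genome_id[meta$order != "OUTGROUP"]
  plan <- list()
  add <- function(category, genomes) {
    plan[[length(plan) + 1]] <<- list(category = category, genomes = genomes)
  }
  for (i in seq_len(bp$n_core)) add("core", non_out)
  for (ord in names(bp$n_order_specific)) {
    g <- meta$genome_id[meta$order == ord]
    for (i in seq_len(bp$n_order_specific[[ord]])) {
      add(paste0("order_specific:", ord), g)
    }
  }
  for (sc in names(bp$n_subclade_specific)) {
    g <- meta$genome_id[meta$subclade == sc]
    for (i in seq_len(bp$n_subclade_specific[[sc]])) {
      add(paste0("subclade_specific:", sc), g)
    }
  }
  for (i in seq_len(bp$n_sediment_specific)) {
    k <- sample(2:length(bp$sediment_subclades), 1)
    clades <- sort(sample(bp$sediment_subclades, k))
    add("sediment_specific", meta$genome_id[meta$subclade %in% clades])
  }
  for (i in seq_len(bp$n_deep_shared)) {
    add("deep_shared", meta$genome_id[meta$subclade %in% bp$deep_subclades])
  }
  for (i in seq_len(bp$n_singletons)) {
    add("singleton", sample(meta$genome_id, 1))
  }
  n_contam <- round(bp$contaminant_rate * nrow(meta))
  for (i in seq_len(n_contam)) {
    add("contaminant", sample(meta$genome_id, 1))
  }
  plan
}

draw_ancestors <- function(bp, n, scoring) {
  lens <- sample(seq(bp$family_length_range[1], bp$family_length_range[2]),
                 n, replace = TRUE)
  ancestors <- character(n)
  accepted <- NULL
  for (i in seq_len(n)) {
    for (try in seq_len(50)) {
      cand <- random_protein(lens[i])
      if (!bp$separable || i == 1) break
      st <- align_stats(accepted, cand, scoring)
      if (max(st$identity_short) <= bp$cross_family_max_identity) break
      if (try == 50) abort("could not draw a separable ancestor in 50 tries")
    }
    ancestors[i] <- cand
    if (bp$separable) accepted <- c(accepted, cand)
  }
  ancestors
}

#' Generate a synthetic genome collection with planted family truth
#'
#' Simulates per-genome proteomes according to a [synthetic_blueprint()]:
#' for each planted family an ancestor sequence is drawn (rejection-sampled
#' against `cross_family_max_identity` in separable mode) and per-genome
#' copies are derived by point substitutions targeting the within-family
#' pairwise identity; each designated genome carries the family unless it is
#' dropped with `dropout_prob`. Deterministic given the blueprint seed.
#'
#' @param blueprint A [synthetic_blueprint()].
#' @param scoring Aligner scoring used for ancestor rejection sampling.
#' @return A list of class `synthetic_collection` with elements
#'   `records` (all proteins, one tibble), `metadata` (genome table with
#'   realised completeness/contamination), and `truth` (tibble `family_id`,
#'   `category`, `seq_id`, `genome_id`: every generated protein appears in
#'   exactly one truth family).
#' @export
generate_collection <- function(blueprint, scoring = align_scoring()) {
  stopifnot(inherits(blueprint, "synthetic_blueprint"))
  bp <- blueprint
  meta <- bp$taxonomy
  d <- mutation_rate_for_identity(bp$within_family_identity)
  withr::with_seed(bp$seed, {
    plan <- plan_families(bp)
    ancestors <- draw_ancestors(bp, length(plan), scoring)
    counter <- stats::setNames(integer(nrow(meta)), meta$genome_id)
    rows <- vector("list", length(plan))
    for (i in seq_along(plan)) {
      fam <- plan[[i]]
      fam_id <- sprintf("T%04d", i)
      members <- list()
      for (g in fam$genomes) {
        if (bp$dropout_prob > 0 && runif(1) < bp$dropout_prob) next
        counter[g] <- counter[g] + 1L
        members[[length(members) + 1]] <- tibble(
          family_id = fam_id, category = fam$category,
          seq_id = sprintf("%s_p%04d", g, counter[g]),
          genome_id = g,
          residues = mutate_protein(ancestors[i], d)
        )
      }
      rows[[i]] <- bind_rows(members)
    }
    truth_full <- bind_rows(rows)
  })
  records <- tibble(seq_id = truth_full$seq_id, description = "",
                    residues = truth_full$residues,
                    genome_id = truth_full$genome_id)
  truth <- truth_full[, c("family_id", "category", "seq_id", "genome_id")]
  meta <- realised_quality(meta, plan_designated(bp), truth)
  structure(list(records = records, metadata = meta, truth = truth,
                 blueprint = bp),
            class = "synthetic_collection")
}

# designated (family, genome) pairs, re-derived deterministically
plan_designated <- function(bp) {
  withr::with_seed(bp$seed, plan_families(bp))
}

realised_quality <- function(meta, plan, truth) {
  categories <- vapply(plan, `[[`, character(1), "category")
  designated <- table(factor(unlist(lapply(
    plan[categories != "contaminant"], `[[`, "genomes")),
    levels = meta$genome_id))
  kept <- table(factor(truth$genome_id[truth$category != "contaminant"],
                       levels = meta$genome_id))
  contam <- table(factor(truth$genome_id[truth$category == "contaminant"],
                         levels = meta$genome_id))
  designated <- as.numeric(designated)
  meta$completeness <- ifelse(designated > 0,
                              round(100 * as.numeric(kept) /
                                      pmax(1, designated), 1),
                              NA_real_)
  meta$contamination <- round(100 * as.numeric(contam) /
                                pmax(1, designated), 1)
  meta
}

#' Write a synthetic collection to disk
#'
#' Emits one protein FASTA per genome, the metadata TSV and the truth TSV.
#'
#' @param collection A `synthetic_collection`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "synthetic_collection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in collection$metadata$genome_id) {
    recs <- collection$records[collection$records$genome_id == g, ]
    write_fasta(recs, file.path(dir, paste0(g, ".faa")))
  }
  write_metadata(collection$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(collection$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Substitute nucleotides at a fixed per-site rate
#'
#' Each position is replaced with probability `rate` by one of the three
#' other bases (substitution-only; length preserved). Uses the current RNG
#' state.
#'
#' @param residues Nucleotide sequence (character scalar, `ACGT`).
#' @param rate Per-site substitution probability in `[0, 1)`.
#' @return Mutated sequence.
#' @export
substitute_nucleotides <- function(residues, rate) {
  if (rate < 0 || rate >= 1) abort("substitution rate must be in [0, 1)")
  chars <- strsplit(residues, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(nt_letters, ch), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Generate a pair of nucleotide genomes at a set substitution rate
#'
#' Draws a random genome and derives the second by i.i.d. substitutions at
#' `substitution_rate`; lengths are equal (substitution-only model). Used to
#' validate ANI estimation against a known divergence.
#'
#' @param length_bp Genome length (>= 10 kb so divergence statistics are
#'   stable).
#' @param substitution_rate Per-site substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Tibble of two nucleotide records (`genome_id` `"gA"`, `"gB"`).
#' @export
generate_genome_pair <- function(length_bp, substitution_rate, seed = 1L) {
  if (substitution_rate < 0 || substitution_rate >= 1) {
    abort("substitution rate must be in [0, 1)")
  }
  if (length_bp < 10000) abort("length_bp must be >= 10 kb")
  withr::with_seed(seed, {
    a <- paste(sample(nt_letters, length_bp, replace = TRUE), collapse = "")
    b <- substitute_nucleotides(a, substitution_rate)
  })
  tibble(seq_id = c("gA_c1", "gB_c1"), description = "",
         residues = c(a, b), genome_id = c("gA", "gB"))
}
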