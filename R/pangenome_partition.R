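#' Build the family-by-genome presence/absence (copy count) matrix
#'
#' @param families A `protein_families` object from [cluster_proteins()], or
#'   a member tibble with columns `family_id`, `genome_id` (e.g. a truth
#'   table).
#' @param metadata Genome metadata tibble ([read_metadata()]); every member
#'   genome must appear in it, and its row order fixes the column order.
#' @return An object of class `pa_matrix`: integer copy-count matrix
#'   (families x genomes, `counts[f, g]` = members of family `f` from genome
#'   `g`; presence is `count >= 1`) with the metadata attached.
#' @export
build_matrix <- function(families, metadata) {
  members <- if (inherits(families, "protein_families")) families$members
             else families
  stopifnot(all(c("family_id", "genome_id") %in% names(members)))
  validate_metadata(metadata)
  unknown <- setdiff(unique(members$genome_id), metadata$genome_id)
  if (length(unknown) > 0) {
    abort(paste0("member genome absent from metadata: ", unknown[1]))
  }
  fam_ids <- sort(unique(members$family_id))
  if (length(fam_ids) == 0) {
    counts <- matrix(integer(0), nrow = 0, ncol = nrow(metadata),
                     dimnames = list(character(0), metadata$genome_id))
  } else {
    counts <- table(factor(members$family_id, levels = fam_ids),
                    factor(members$genome_id, levels = metadata$genome_id))
    counts <- matrix(as.integer(counts), nrow = length(fam_ids),
                     dimnames = list(fam_ids, metadata$genome_id))
  }
  structure(list(counts = counts, metadata = metadata), class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat("<pa_matrix> ", nrow(x$counts), " families x ", ncol(x$counts),
      " genomes (", sum(x$counts > 0), " presences)\n", sep = "")
  invisible(x)
}

# Resolve a clade specification to genome ids. Accepted forms:
#   "ALL", "OUTGROUP", "order:NP", "subclade:theta", "genome:<id>"
resolve_clade <- function(matrix, clade) {
  meta <- matrix$metadata
  if (clade == "ALL") return(meta$genome_id)
  if (clade == "OUTGROUP") return(meta$genome_id[meta$order == "OUTGROUP"])
  parts <- strsplit(clade, ":", fixed = TRUE)[[1]]
  if (length(parts) == 2) {
    ids <- switch(parts[1],
      order = meta$genome_id[meta$order == parts[2]],
      subclade = meta$genome_id[meta$subclade == parts[2]],
      genome = intersect(parts[2], meta$genome_id),
      character(0))
    if (length(ids) > 0) return(ids)
  }
  abort(paste0("unknown clade: ", clade))
}

#' Clade-quantified query atoms and combinators
#'
#' Build expression trees over the presence/absence matrix that formalise
#' statements such as "present in at least one genome of each of the four
#' major lineages" or "to the exclusion of all the other genomes". Atoms:
#' `present_in(clade, min_genomes)` (at least `min_genomes` genomes of the
#' clade carry the family), `present_fraction(clade, min_fraction, strict)`
#' (fraction of the clade's genomes carrying the family, `>` when `strict`,
#' `>=` otherwise) and `absent_in(clade)`. Combine with `query_and()`,
#' `query_or()` and `query_not()`. Clades are written `"ALL"`, `"OUTGROUP"`,
#' `"order:NP"`, `"subclade:theta"` or `"genome:<id>"`.
#'
#' @param clade Clade specification string.
#' @param min_genomes Minimum number of presence genomes.
#' @param min_fraction Presence-fraction threshold.
#' @param strict Use strict `>` for the fraction rule.
#' @param ... Sub-queries to combine.
#' @param q Query to negate.
#' @return A `clade_query` object; evaluate with [evaluate_query()].
#' @name clade_query
NULL

#' @rdname clade_query
#' @export
present_in <- function(clade, min_genomes = 1L) {
  stopifnot(min_genomes >= 1)
  structure(list(op = "present_in", clade = clade,
                 min_genomes = as.integer(min_genomes)),
            class = "clade_query")
}

#' @rdname clade_query
#' @export
present_fraction <- function(clade, min_fraction, strict = TRUE) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  structure(list(op = "present_fraction", clade = clade,
                 min_fraction = min_fraction, strict = isTRUE(strict)),
            class = "clade_query")
}

#' @rdname clade_query
#' @export
absent_in <- function(clade) {
  structure(list(op = "absent_in", clade = clade), class = "clade_query")
}

#' @rdname clade_query
#' @export
query_and <- function(...) {
  structure(list(op = "and", args = list(...)), class = "clade_query")
}

#' @rdname clade_query
#' @export
query_or <- function(...) {
  structure(list(op = "or", args = list(...)), class = "clade_query")
}

#' @rdname clade_query
#' @export
query_not <- function(q) {
  structure(list(op = "not", args = list(q)), class = "clade_query")
}

#' Evaluate a clade query against a presence/absence matrix
#'
#' Exact set semantics: atoms select family ids by presence counts over the
#' resolved genome set; `query_and`/`query_or` intersect/unite; `query_not`
#' complements within the set of non-empty families.
#'
#' @param matrix A `pa_matrix`.
#' @param q A `clade_query`.
#' @return Character vector of family ids (sorted).
#' @export
evaluate_query <- function(matrix, q) {
  stopifnot(inherits(matrix, "pa_matrix"), inherits(q, "clade_query"))
  sort(eval_query_rec(matrix, q))
}

eval_query_rec <- function(matrix, q) {
  pres <- matrix$counts > 0
  all_fams <- rownames(pres)
  switch(q$op,
    present_in = {
      g <- resolve_clade(matrix, q$clade)
      all_fams[rowSums(pres[, g, drop = FALSE]) >= q$min_genomes]
    },
    present_fraction = {
      g <- resolve_clade(matrix, q$clade)
      frac <- rowSums(pres[, g, drop = FALSE]) / length(g)
      if (q$strict) all_fams[frac > q$min_fraction]
      else all_fams[frac >= q$min_fraction]
    },
    absent_in = {
      g <- resolve_clade(matrix, q$clade)
      all_fams[rowSums(pres[, g, drop = FALSE]) == 0]
    },
    and = Reduce(intersect, lapply(q$args, eval_query_rec, matrix = matrix)),
    or = Reduce(union, lapply(q$args, eval_query_rec, matrix = matrix)),
    not = setdiff(all_fams[rowSums(pres) > 0],
                  eval_query_rec(matrix, q$args[[1]])),
    abort(paste0("unknown query op: ", q$op))
  )
}

#' Standard clade-aware pangenome partitions
#'
#' Evaluates the named family partitions used for clade-aware pangenome
#' analysis of an AOA-style collection:
#'
#' * `shared2` — present in >= 2 genomes;
#' * `core_aoa` — >= 1 genome of each of the four orders (NC, NS, NT, NP);
#' * `aoa_specific` — core and absent from every outgroup genome;
#' * `conserved_core` — specific and present in > 50% of the genomes of
#'   each order;
#' * `np_specific` — present in >= 2 genomes, all of them NP;
#' * `np_all_subclades` — NP-specific and present in every NP subclade;
#' * `sediment_specific` — >= 1 genome in each of >= 2 sediment subclades
#'   and absent from every genome outside the sediment subclades;
#' * `deep_ocean_shared` — >= 1 genome in each of >= 2 deep subclades and
#'   absent from all non-deep NP subclades (presence outside NP is not
#'   constrained);
#' * `sediment_ns_shared` — >= 1 sediment-subclade genome and >= 1 NS genome,
#'   absent from all other genomes.
#'
#' @param matrix A `pa_matrix` whose metadata provides orders, NP subclades
#'   and the outgroup.
#' @param sediment_clades NP subclades counted as deep-sediment clades.
#' @param deep_clades NP subclades counted as deep-ocean clades (must be
#'   supplied by the analyst; the package never infers them).
#' @param min_sediment_clades Number of sediment subclades a family must span.
#' @param min_deep_clades Number of deep subclades a family must span.
#' @param conserved_fraction Per-order presence fraction (strict `>`) for the
#'   conserved core.
#' @return An object of class `partition_report`: tibble with `set`,
#'   `n_families` and a `families` list-column, plus the parameters as
#'   attributes.
#' @export
standard_partitions <- function(matrix,
                                sediment_clades = c("theta", "delta", "iota"),
                                deep_clades = c("alpha", "gamma"),
                                min_sediment_clades = 2L,
                                min_deep_clades = 2L,
                                conserved_fraction = 0.5) {
  stopifnot(inherits(matrix, "pa_matrix"))
  meta <- matrix$metadata
  orders <- c("NC", "NS", "NT", "NP")
  missing_ord <- setdiff(orders, unique(meta$order))
  if (length(missing_ord) > 0) {
    abort(paste0("taxonomy missing order: ", missing_ord[1]))
  }
  pres <- matrix$counts > 0
  fams <- rownames(pres)
  genomes_of <- function(sel) meta$genome_id[sel]
  n_pres <- function(g) rowSums(pres[, g, drop = FALSE])

  n_genomes <- rowSums(pres)
  shared2 <- n_pres(meta$genome_id) >= 2

  in_order <- lapply(orders, function(o) n_pres(genomes_of(meta$order == o)))
  names(in_order) <- orders
  core <- Reduce(`&`, lapply(in_order, function(x) x >= 1))
  out_g <- genomes_of(meta$order == "OUTGROUP")
  aoa_specific <- core &
    (length(out_g) == 0 | n_pres(out_g) == 0)
  conserved <- aoa_specific
  for (o in orders) {
    g <- genomes_of(meta$order == o)
    conserved <- conserved & (in_order[[o]] / length(g) > conserved_fraction)
  }

  np_g <- genomes_of(meta$order == "NP")
  non_np_g <- setdiff(meta$genome_id, np_g)
  np_specific <- n_pres(np_g) >= 2 & n_pres(non_np_g) == 0
  subclades <- setdiff(unique(meta$subclade), "")
  in_sc <- vapply(subclades, function(sc) {
    n_pres(genomes_of(meta$subclade == sc)) >= 1
  }, logical(length(fams)))
  if (is.null(dim(in_sc))) in_sc <- matrix(in_sc, nrow = length(fams),
                                           dimnames = list(fams, subclades))
  np_all_subclades <- np_specific & rowSums(in_sc) == length(subclades)

  sed_g <- genomes_of(meta$subclade %in% sediment_clades)
  n_sed_clades <- rowSums(in_sc[, intersect(sediment_clades, subclades),
                                drop = FALSE])
  sediment_specific <- n_sed_clades >= min_sediment_clades &
    n_pres(setdiff(meta$genome_id, sed_g)) == 0

  deep_in_tax <- intersect(deep_clades, subclades)
  n_deep_clades <- rowSums(in_sc[, deep_in_tax, drop = FALSE])
  non_deep_np <- genomes_of(meta$order == "NP" &
                              !(meta$subclade %in% deep_clades))
  deep_ocean_shared <- n_deep_clades >= min_deep_clades &
    n_pres(non_deep_np) == 0

  ns_g <- genomes_of(meta$order == "NS")
  other_g <- setdiff(meta$genome_id, c(sed_g, ns_g))
  sediment_ns_shared <- n_pres(sed_g) >= 1 & n_pres(ns_g) >= 1 &
    n_pres(other_g) == 0

  sets <- list(shared2 = shared2, core_aoa = core,
               aoa_specific = aoa_specific, conserved_core = conserved,
               np_specific = np_specific, np_all_subclades = np_all_subclades,
               sediment_specific = sediment_specific,
               deep_ocean_shared = deep_ocean_shared,
               sediment_ns_shared = sediment_ns_shared)
  report <- tibble(
    set = names(sets),
    n_families = vapply(sets, sum, integer(1)),
    families = lapply(sets, function(sel) fams[sel])
  )
  # nesting invariants, asserted on every call
  stopifnot(all(conserved <= aoa_specific), all(aoa_specific <= core),
            all(sediment_specific <= np_specific),
            all(np_all_subclades <= np_specific))
  structure(report, class = c("partition_report", class(report)),
            sediment_clades = sediment_clades, deep_clades = deep_clades,
            min_sediment_clades = min_sediment_clades,
            min_deep_clades = min_deep_clades,
            conserved_fraction = conserved_fraction)
}

#' @export
print.partition_report <- function(x, ...) {
  cat("<partition_report>\n")
  print(tibble(set = x$set, n_families = x$n_families))
  invisible(x)
}

#' Propagate per-protein annotations to families
#'
#' A family is annotated when at least one member carries a label; the family
#' label set is the union of its member labels.
#'
#' @param families A `protein_families` object (or member tibble with
#'   `family_id`, `seq_id`).
#' @param labels Annotation tibble (`protein_id`, `label`), e.g. from
#'   [read_annotations()]. Unlabeled proteins are allowed.
#' @param report Optional `partition_report`; when given, the annotated
#'   fraction of each family set is returned as well.
#' @return A tibble `family_id`, `labels` (list-column), `annotated`; with
#'   `report`, a list with elements `families` and `set_fractions`.
#' @export
propagate_annotations <- function(families, labels, report = NULL) {
  members <- if (inherits(families, "protein_families")) families$members
             else families
  lab <- labels[!is.na(labels$label), ]
  joined <- left_join(members[, c("family_id", "seq_id")],
                      lab, by = c(seq_id = "protein_id"),
                      relationship = "many-to-many")
  fam_tbl <- joined |>
    group_by(.data$family_id) |>
    summarise(labels = list(sort(unique(.data$label[!is.na(.data$label)]))),
              .groups = "drop") |>
    mutate(annotated = vapply(.data$labels, length, integer(1)) > 0)
  if (is.null(report)) return(fam_tbl)
  fractions <- tibble(
    set = report$set,
    n_families = report$n_families,
    n_annotated = vapply(report$families, function(f) {
      sum(fam_tbl$annotated[fam_tbl$family_id %in% f])
    }, integer(1))
  )
  fractions$annotated_fraction <- ifelse(
    fractions$n_families > 0,
    fractions$n_annotated / fractions$n_families, NA_real_)
  list(families = fam_tbl, set_fractions = fractions)
}

#' Order families for presence/absence display
#'
#' Orders families from the most widespread to the most uncommon: first by
#' the number of lineages (orders) with at least one presence (descending),
#' then by the number of genomes (descending), then by family id.
#'
#' @param matrix A `pa_matrix`.
#' @return Character vector of family ids in display order.
#' @export
order_families_for_display <- function(matrix) {
  stopifnot(inherits(matrix, "pa_matrix"), nrow(matrix$counts) > 0)
  meta <- matrix$metadata
  pres <- matrix$counts > 0
  orders <- unique(meta$order[meta$order != "OUTGROUP"])
  n_lineages <- Reduce(`+`, lapply(orders, function(o) {
    rowSums(pres[, meta$genome_id[meta$order == o], drop = FALSE]) >= 1
  }))
  n_genomes <- rowSums(pres)
  rownames(pres)[order(-n_lineages, -n_genomes, rownames(pres))]
}

#' Export a presence/absence matrix
#'
#' Writes the dense family-by-genome TSV and, optionally, a sparse triplet
#' file (`family_id`, `genome_id`, `count`).
#'
#' @param matrix A `pa_matrix`.
#' @param path Output TSV path.
#' @param triplet_path Optional sparse triplet TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, triplet_path = NULL) {
  tbl <- as_tibble(matrix$counts, rownames = "family_id")
  readr::write_tsv(tbl, path)
  if (!is.null(triplet_path)) {
    idx <- which(matrix$counts > 0, arr.ind = TRUE)
    trip <- tibble(family_id = rownames(matrix$counts)[idx[, 1]],
                   genome_id = colnames(matrix$counts)[idx[, 2]],
                   count = matrix$counts[idx])
    readr::write_tsv(arrange(trip, .data$family_id, .data$genome_id),
                     triplet_path)
  }
  invisible(path)
}
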