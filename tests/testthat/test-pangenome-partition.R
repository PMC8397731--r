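make_truth_matrix <- function(seed = 1, ...) {
  col <- generate_collection(tiny_blueprint(seed = seed, ...))
  list(matrix = build_matrix(col$truth, col$metadata), col = col)
}

test_that("matrix counts reproduce truth membership", {
  tm <- make_truth_matrix(seed = 2)
  pa <- tm$matrix
  truth <- tm$col$truth
  expect_equal(sum(pa$counts), nrow(truth))
  # per-family genome sets equal truth membership
  for (f in sample(rownames(pa$counts), 5)) {
    expect_setequal(colnames(pa$counts)[pa$counts[f, ] > 0],
                    unique(truth$genome_id[truth$family_id == f]))
  }
  # column sums equal per-genome protein totals
  expect_equal(unname(colSums(pa$counts)),
               as.vector(table(factor(truth$genome_id,
                                      levels = pa$metadata$genome_id))))
})

test_that("an empty family set gives an empty matrix", {
  pa <- build_matrix(tibble::tibble(family_id = character(),
                                    genome_id = character()),
                     tiny_taxonomy())
  expect_equal(nrow(pa$counts), 0)
})

test_that("members from unknown genomes are rejected", {
  expect_error(
    build_matrix(tibble::tibble(family_id = "F1", genome_id = "nope"),
                 tiny_taxonomy()),
    "absent from metadata")
})

test_that("query atoms follow exact set semantics", {
  tm <- make_truth_matrix(seed = 4)
  pa <- tm$matrix
  truth <- tm$col$truth
  all_fams <- sort(unique(truth$family_id))
  expect_equal(evaluate_query(pa, present_in("ALL", 1)), all_fams)
  expect_equal(evaluate_query(pa, query_and(present_in("ALL", 1),
                                            absent_in("ALL"))),
               character(0))
  # core query: present in each of the four orders
  q_core <- query_and(present_in("order:NC"), present_in("order:NS"),
                      present_in("order:NT"), present_in("order:NP"))
  core_truth <- sort(unique(truth$family_id[truth$category == "core"]))
  expect_equal(evaluate_query(pa, q_core), core_truth)
  # unknown clade errors
  expect_error(evaluate_query(pa, present_in("order:XX")), "unknown clade")
})

test_that("AND distributes over intersection and NOT complements", {
  pa <- random_pa_matrix(99)
  a <- present_in("order:NP", 2)
  b <- present_fraction("order:NC", 0.5, strict = TRUE)
  expect_setequal(evaluate_query(pa, query_and(a, b)),
                  intersect(evaluate_query(pa, a), evaluate_query(pa, b)))
  expect_setequal(evaluate_query(pa, query_or(a, b)),
                  union(evaluate_query(pa, a), evaluate_query(pa, b)))
  nonempty <- rownames(pa$counts)[rowSums(pa$counts > 0) > 0]
  expect_setequal(evaluate_query(pa, query_not(a)),
                  setdiff(nonempty, evaluate_query(pa, a)))
})

test_that("strict and non-strict presence fractions differ at the boundary", {
  meta <- tiny_taxonomy()
  nc <- meta$genome_id[meta$order == "NC"]  # two genomes
  members <- tibble::tibble(family_id = c("F1", "F2", "F2"),
                            genome_id = c(nc[1], nc[1], nc[2]))
  pa <- build_matrix(members, meta)
  expect_equal(evaluate_query(pa, present_fraction("order:NC", 0.5,
                                                   strict = TRUE)), "F2")
  expect_setequal(evaluate_query(pa, present_fraction("order:NC", 0.5,
                                                      strict = FALSE)),
                  c("F1", "F2"))
})

test_that("standard partitions recover planted categories exactly", {
  tm <- make_truth_matrix(seed = 6)
  rep <- standard_partitions(tm$matrix)
  truth <- tm$col$truth
  cat_n <- function(p) length(unique(truth$family_id[grepl(p, truth$category)]))
  counts <- stats::setNames(rep$n_families, rep$set)
  bp <- tm$col$blueprint
  expect_equal(counts[["core_aoa"]], bp$n_core)
  expect_equal(counts[["aoa_specific"]], bp$n_core)
  expect_equal(counts[["conserved_core"]], bp$n_core)
  # subclade-specific families only reach the >=2-genome rule when their
  # subclade holds at least two genomes
  sc_sizes <- table(tm$col$metadata$subclade)
  sc_big <- sum(bp$n_subclade_specific[
    names(bp$n_subclade_specific) %in% names(sc_sizes)[sc_sizes >= 2]])
  expect_equal(counts[["np_specific"]],
               unname(bp$n_order_specific["NP"] + sc_big +
                        bp$n_sediment_specific + bp$n_deep_shared))
  expect_equal(counts[["np_all_subclades"]],
               unname(bp$n_order_specific["NP"]))
  expect_equal(counts[["sediment_specific"]], bp$n_sediment_specific)
  expect_equal(counts[["deep_ocean_shared"]], bp$n_deep_shared)
  expect_equal(counts[["sediment_ns_shared"]], 0L)
  expect_equal(cat_n("^sediment_specific"), bp$n_sediment_specific)
})

test_that("a family in every genome is core but not lineage-specific", {
  meta <- tiny_taxonomy()
  members <- tidyr::crossing(family_id = c("F1", "F2"),
                             genome_id = meta$genome_id)
  pa <- build_matrix(members, meta)
  rep <- standard_partitions(pa)
  counts <- stats::setNames(rep$n_families, rep$set)
  expect_equal(counts[["core_aoa"]], 2L)
  expect_equal(counts[["aoa_specific"]], 0L)   # present in the outgroup
  expect_equal(counts[["np_specific"]], 0L)
  expect_equal(counts[["sediment_specific"]], 0L)
})

test_that("partition nesting invariants hold on random matrices", {
  for (seed in 1:10) {
    pa <- random_pa_matrix(seed)
    rep <- standard_partitions(pa)
    sets <- stats::setNames(rep$families, rep$set)
    expect_true(all(sets$conserved_core %in% sets$aoa_specific))
    expect_true(all(sets$aoa_specific %in% sets$core_aoa))
    expect_true(all(sets$sediment_specific %in% sets$np_specific))
    expect_true(all(sets$np_all_subclades %in% sets$np_specific))
  }
})

test_that("annotations propagate to families as label unions", {
  tm <- make_truth_matrix(seed = 8)
  truth <- tm$col$truth
  fams <- unique(truth$family_id)
  # label one protein in each of the first 4 families, two labels for one
  first <- truth[!duplicated(truth$family_id), ][1:4, ]
  labels <- tibble::tibble(
    protein_id = c(first$seq_id, first$seq_id[1]),
    label = c("kinase", "transporter", "kinase", "oxidoreductase", "lyase"))
  ann <- propagate_annotations(truth, labels)
  expect_equal(sum(ann$annotated), 4)
  expect_setequal(ann$labels[ann$family_id == first$family_id[1]][[1]],
                  c("kinase", "lyase"))
  # no labels at all -> nothing annotated
  none <- propagate_annotations(
    truth, tibble::tibble(protein_id = character(), label = character()))
  expect_equal(sum(none$annotated), 0)
  # fraction per partition set
  rep <- standard_partitions(tm$matrix)
  both <- propagate_annotations(truth, labels, report = rep)
  fr <- both$set_fractions
  expect_true(all(fr$annotated_fraction <= 1, na.rm = TRUE))
  # fully labeled -> 100%
  full <- propagate_annotations(
    truth, tibble::tibble(protein_id = truth$seq_id, label = "x"))
  expect_true(all(full$annotated))
})

test_that("display order sorts by lineage spread, then genomes, then id", {
  pa <- random_pa_matrix(123)
  got <- order_families_for_display(pa)
  # independent sort by the stated keys
  meta <- pa$metadata
  pres <- pa$counts > 0
  orders <- unique(meta$order[meta$order != "OUTGROUP"])
  n_lin <- rowSums(vapply(orders, function(o) {
    rowSums(pres[, meta$genome_id[meta$order == o], drop = FALSE]) >= 1
  }, numeric(nrow(pres))))
  key <- data.frame(f = rownames(pres), lin = n_lin, g = rowSums(pres))
  want <- key[order(-key$lin, -key$g, key$f), "f"]
  expect_equal(got, want)
  # families spanning every lineage sort before single-lineage families
  pos <- match(rownames(pres), got)
  all4 <- n_lin == length(orders)
  one <- n_lin == 1
  if (any(all4) && any(one)) expect_lt(max(pos[all4]), min(pos[one]))
})

test_that("matrix exports are faithful", {
  tm <- make_truth_matrix(seed = 10)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  trip <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(tm$matrix, tsv, trip)
  dense <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(dense), nrow(tm$matrix$counts))
  triples <- readr::read_tsv(trip, show_col_types = FALSE)
  expect_equal(sum(triples$count), sum(tm$matrix$counts))
})
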