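test_that("identical copies cluster together, unrelated sequences apart", {
  set.seed(30)
  same <- paste(sample(c("A", "C", "D", "E", "F", "G"), 120, TRUE),
                collapse = "")
  other <- simulate_family(1, 120, 1, seed = 31)$residues
  recs <- tibble::tibble(
    seq_id = c("c1", "c2", "c3", "u1"),
    residues = c(same, same, same, other),
    genome_id = c("g1", "g2", "g3", "g4"))
  fams <- cluster_proteins(recs)
  expect_equal(nrow(fams$families), 2)
  expect_setequal(fams$families$n_members, c(3, 1))
})

test_that("clustering is a partition with a valid threshold certificate", {
  recs <- random_record_set(77)
  fams <- cluster_proteins(recs)
  # partition: every sequence in exactly one family
  expect_setequal(fams$members$seq_id, recs$seq_id)
  expect_equal(sum(fams$families$n_members), nrow(recs))
  # representative is the longest member (ties by seq_id)
  lens <- stats::setNames(nchar(recs$residues), recs$seq_id)
  for (f in fams$families$family_id) {
    m <- fams$members[fams$members$family_id == f, ]
    rep_id <- m$seq_id[m$is_representative]
    expect_equal(lens[[rep_id]], max(lens[m$seq_id]))
  }
  # certificate: re-aligning members to representatives reproduces the
  # stored statistics and satisfies the thresholds
  reps <- stats::setNames(recs$residues[match(
    fams$families$representative_id, recs$seq_id)],
    fams$families$family_id)
  seqs <- stats::setNames(recs$residues, recs$seq_id)
  nonrep <- fams$members[!fams$members$is_representative, ]
  for (i in seq_len(nrow(nonrep))) {
    r <- global_align(reps[[nonrep$family_id[i]]], seqs[[nonrep$seq_id[i]]])
    expect_equal(r$identity_short, nonrep$identity_to_rep[i])
    expect_equal(r$cov_long, nonrep$cov_long[i])
    expect_equal(r$cov_short, nonrep$cov_short[i])
    expect_gte(r$identity_short, 0.35)
    expect_gte(r$cov_long, 0.70)
    expect_gte(r$cov_short, 0.70)
  }
})

test_that("prefiltered, exhaustive and oracle clustering agree", {
  for (seed in c(301, 302)) {
    recs <- random_record_set(seed)
    pre <- cluster_proteins(recs)
    exh <- cluster_proteins(recs, clustering_params(exhaustive = TRUE))
    orc <- brute_force_cluster_oracle(recs)
    expect_identical(pre$members, exh$members)
    expect_identical(pre$members, orc$members)
  }
})

test_that("single records and sub-threshold pairs stay singletons", {
  one <- simulate_family(1, 80, 1, seed = 41)
  expect_equal(nrow(brute_force_cluster_oracle(one)$families), 1)
  pair <- simulate_family(2, 200, 0.25, seed = 42)
  orc <- brute_force_cluster_oracle(pair)
  expect_equal(nrow(orc$families), 2)
})

test_that("raising the identity threshold never merges families", {
  recs <- random_record_set(55)
  n_prev <- 0
  for (thr in c(0.35, 0.5, 0.65, 0.8)) {
    fams <- cluster_proteins(recs, clustering_params(min_identity = thr))
    expect_gte(nrow(fams$families), n_prev)
    n_prev <- nrow(fams$families)
  }
})

test_that("duplicate sequence ids are rejected", {
  recs <- tibble::tibble(seq_id = c("a", "a"),
                         residues = c("ACDEACDE", "ACDEACDE"),
                         genome_id = c("g1", "g2"))
  expect_error(cluster_proteins(recs), "duplicate")
})

test_that("family TSV and clstr exports carry every member", {
  recs <- random_record_set(66, n_families = 5)
  fams <- cluster_proteins(recs)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_families_tsv(fams, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(recs))
  clstr <- withr::local_tempfile(fileext = ".clstr")
  write_clstr(fams, recs, clstr)
  lines <- readLines(clstr)
  expect_equal(sum(grepl("^>Cluster", lines)), nrow(fams$families))
  expect_equal(sum(!grepl("^>", lines)), nrow(recs))
})
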