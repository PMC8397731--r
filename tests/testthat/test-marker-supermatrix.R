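test_that("markers are the widespread, predominantly single-copy families", {
  meta <- tiny_taxonomy()
  n <- nrow(meta)
  # F1: universal single copy; F2: universal but multicopy everywhere;
  # F3: misses one genome; F4: universal with one multicopy genome
  members <- dplyr::bind_rows(
    tibble::tibble(family_id = "F1", genome_id = meta$genome_id),
    tibble::tibble(family_id = "F2",
                   genome_id = rep(meta$genome_id, 2)),
    tibble::tibble(family_id = "F3", genome_id = meta$genome_id[-1]),
    tibble::tibble(family_id = "F4",
                   genome_id = c(meta$genome_id, meta$genome_id[1])))
  pa <- build_matrix(members, meta)
  got <- select_markers(pa, marker_params(min_genomes = n,
                                          max_multicopy_fraction = 0.05))
  expect_equal(got$family_id, "F1")
  # tolerate the single multicopy genome at a 10% allowance
  got2 <- select_markers(pa, marker_params(min_genomes = n,
                                           max_multicopy_fraction = 0.10))
  expect_setequal(got2$family_id, c("F1", "F4"))
  # relaxing widespreadness admits F3
  got3 <- select_markers(pa, marker_params(min_genomes = n - 1,
                                           max_multicopy_fraction = 0.05))
  expect_setequal(got3$family_id, c("F1", "F3"))
  expect_error(select_markers(pa, marker_params(min_genomes = n + 1)),
               "exceeds")
})

test_that("planted universal single-copy families are selected exactly", {
  col <- generate_collection(tiny_blueprint(n_core = 6, seed = 17))
  pa <- build_matrix(col$truth, col$metadata)
  n_non_out <- sum(col$metadata$order != "OUTGROUP")
  got <- select_markers(pa, marker_params(min_genomes = n_non_out))
  core <- unique(col$truth$family_id[col$truth$category == "core"])
  expect_setequal(got$family_id, core)
})

test_that("gap-heavy columns are trimmed with a strict rule", {
  # 4 rows x 4 columns with gap fractions 0, 0.25, 0.5, 0.75 at trim 0.5
  aln <- c(g1 = "AC-D", g2 = "AC--", g3 = "A-E-", g4 = "ACE-")
  sm <- build_supermatrix(list(M1 = aln), names(aln),
                          marker_params(min_genomes = 1,
                                        trim_gap_fraction = 0.5))
  expect_equal(sm$width, 3L)  # the 0.75 column goes, the 0.5 column stays
  expect_equal(unname(sm$sequences["g1"]), "AC-")
  expect_equal(unname(sm$sequences["g4"]), "ACE")
})

test_that("supermatrix concatenates blocks and pads missing genomes", {
  aln1 <- c(g1 = "ACDEF", g2 = "ACDEF", g3 = "ACDEF")
  aln2 <- c(g1 = "MKLVWYP", g2 = "MKLVWYP")  # g3 misses marker 2
  sm <- build_supermatrix(list(M1 = aln1, M2 = aln2), c("g1", "g2", "g3"),
                          marker_params(min_genomes = 1))
  expect_equal(sm$width, 12L)
  expect_equal(unname(nchar(sm$sequences)), rep(12L, 3))
  expect_equal(substr(sm$sequences[["g3"]], 6, 12), strrep("-", 7))
  expect_equal(sm$partitions$start, c(1L, 6L))
  expect_equal(sm$partitions$end, c(5L, 12L))
})

test_that("supermatrix invariants hold on generated marker sets", {
  col <- generate_collection(tiny_blueprint(seed = 19))
  fams <- build_matrix(col$truth, col$metadata)
  markers <- select_markers(
    fams, marker_params(min_genomes = sum(col$metadata$order != "OUTGROUP")))
  alns <- family_alignments(col$records, col$truth, markers$family_id)
  sm <- build_supermatrix(alns, col$metadata$genome_id,
                          marker_params(min_genomes = 1))
  # uniform row length and width additivity
  expect_true(all(nchar(sm$sequences) == sm$width))
  expect_equal(sum(sm$partitions$end - sm$partitions$start + 1), sm$width)
  # partitions tile [1, width] without overlap
  expect_equal(sm$partitions$start,
               c(1L, head(sm$partitions$end, -1) + 1L))
  # trimming is a column subset: substitution-only families have no gaps,
  # so every marker block equals the raw member sequence
  seqs <- stats::setNames(col$records$residues, col$records$seq_id)
  m1 <- markers$family_id[1]
  p1 <- sm$partitions[sm$partitions$marker == m1, ]
  member <- col$truth[col$truth$family_id == m1, ][1, ]
  expect_equal(substr(sm$sequences[[member$genome_id]], p1$start, p1$end),
               unname(seqs[member$seq_id]))
})

test_that("paralog resolution keeps the longest copy or drops the genome", {
  recs <- tibble::tibble(
    seq_id = c("p1", "p2", "p3"),
    residues = c("ACDEF", "ACD", "ACDEF"),
    genome_id = c("g1", "g1", "g2"))
  members <- tibble::tibble(family_id = "F1", seq_id = recs$seq_id,
                            genome_id = recs$genome_id)
  keep <- family_alignments(recs, members, "F1", "keep_longest")
  expect_equal(keep$F1[["g1"]], "ACDEF")
  drop <- family_alignments(recs, members, "F1", "drop_genome")
  expect_equal(names(drop$F1), "g2")
})

test_that("ragged and duplicate-genome alignments are rejected", {
  expect_error(build_supermatrix(list(M1 = c(g1 = "ACDE", g2 = "ACD")),
                                 c("g1", "g2"),
                                 marker_params(min_genomes = 1)),
               "ragged")
  expect_error(build_supermatrix(list(M1 = c(g1 = "ACDE", g1 = "ACDE")),
                                 c("g1"), marker_params(min_genomes = 1)),
               "duplicate")
})

test_that("supermatrix writers emit consistent FASTA/PHYLIP/partitions", {
  aln <- list(M1 = c(g1 = "ACDEF", g2 = "ACDEF"),
              M2 = c(g1 = "MKL", g2 = "MKL"))
  sm <- build_supermatrix(aln, c("g1", "g2"), marker_params(min_genomes = 1))
  fa <- withr::local_tempfile(fileext = ".fasta")
  phy <- withr::local_tempfile(fileext = ".phy")
  parts <- withr::local_tempfile(fileext = ".txt")
  write_supermatrix_fasta(sm, fa)
  write_supermatrix_phylip(sm, phy)
  write_partitions(sm, parts)
  back <- read_fasta(fa, "protein", permissive = TRUE)
  expect_equal(gsub("-", "X", back$residues),
               gsub("-", "X", unname(sm$sequences)))
  expect_equal(readLines(phy)[1], "2 8")
  expect_equal(readLines(parts),
               c("MARKER_M1 = 1-5", "MARKER_M2 = 6-8"))
})
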