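test_that("FASTA parsing uppercases, wraps, and attributes genomes", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "acde", "fghik",
               ">p2 genome=other", "mklv"), fa)
  recs <- read_fasta(fa, "protein")
  expect_equal(nrow(recs), 2)
  expect_equal(recs$residues, c("ACDEFGHIK", "MKLV"))
  # file stem is the default genome; a genome= token overrides it
  stem <- sub("\\.fasta$", "", basename(fa))
  expect_equal(recs$genome_id, c(stem, "other"))
})

test_that("empty FASTA gives an empty record table", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), fa)
  recs <- read_fasta(fa, "protein")
  expect_equal(nrow(recs), 0)
  expect_named(recs, c("seq_id", "description", "residues", "genome_id"))
})

test_that("write/read round-trip is the identity on id, residues, genome", {
  recs <- tibble::tibble(
    seq_id = c("a1", "b2", "c3"),
    description = c("", "something", ""),
    residues = c(strrep("ACDEFGHIKL", 20), "MKLVWY", "PQRST"),
    genome_id = c("gX", "gY", "gX"))
  fa <- withr::local_tempfile(fileext = ".faa")
  write_fasta(recs, fa, width = 60)
  expect_true(all(nchar(readLines(fa)) <= 70))
  back <- read_fasta(fa, "protein")
  expect_equal(back$seq_id, recs$seq_id)
  expect_equal(back$residues, recs$residues)
  expect_equal(back$genome_id, recs$genome_id)
  # idempotence: a second round trip is identical
  fa2 <- withr::local_tempfile(fileext = ".faa")
  write_fasta(back, fa2, width = 60)
  expect_identical(read_fasta(fa2, "protein"), back)
})

test_that("zero records produce an empty file", {
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(tibble::tibble(seq_id = character(), residues = character()),
              fa)
  expect_equal(file.size(fa), 0)
})

test_that("illegal residues error unless permissive maps them", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1", "ACDJ"), fa)  # J is not a standard residue
  expect_error(read_fasta(fa, "protein"), "illegal")
  expect_equal(read_fasta(fa, "protein", permissive = TRUE)$residues, "ACDX")
  fn <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">c1", "ACGTRY"), fn)  # ambiguity codes
  expect_error(read_fasta(fn, "nucleotide"), "illegal")
  expect_equal(read_fasta(fn, "nucleotide", permissive = TRUE)$residues,
               "ACGTNN")
})

test_that("metadata parsing enforces the genome invariants", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "genome_id\torder\tsubclade\thabitat_flags\tcompleteness\tcontamination",
    "NPMR_NP_delta_1\tNP\tdelta\tmarine_sediment\t86.2\t5.4",
    "NC_g1\tNC\t\tterrestrial\t\t",
    "OUT_g1\tOUTGROUP\t\t\t90\t1"), tsv)
  meta <- read_metadata(tsv)
  expect_equal(nrow(meta), 3)
  expect_equal(meta$habitat_flags[[1]], "marine_sediment")
  expect_true(is.na(meta$completeness[2]))

  bad_sub <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "genome_id\torder\tsubclade\thabitat_flags\tcompleteness\tcontamination",
    "g1\tNP\t\t\t\t"), bad_sub)
  expect_error(read_metadata(bad_sub), "subclade")

  bad_ord <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "genome_id\torder\tsubclade\thabitat_flags\tcompleteness\tcontamination",
    "g1\tNX\t\t\t\t"), bad_ord)
  expect_error(read_metadata(bad_ord), "order")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "genome_id\torder\tsubclade\thabitat_flags\tcompleteness\tcontamination",
    "g1\tNC\t\t\t\t", "g1\tNS\t\t\t\t"), dup)
  expect_error(read_metadata(dup), "duplicate")
})

test_that("metadata round-trips through write_metadata", {
  meta <- tiny_taxonomy()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(meta, tsv)
  back <- read_metadata(tsv)
  expect_equal(back$genome_id, meta$genome_id)
  expect_equal(back$order, meta$order)
  expect_equal(back$habitat_flags, meta$habitat_flags)
})
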