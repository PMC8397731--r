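#' Read sequences from a FASTA file into a tidy record table
#'
#' Parses a protein or nucleotide FASTA file into a tibble with one row per
#' record. Residues are uppercased. The genome a record belongs to is taken
#' from a `genome=<id>` token in the header if present, otherwise from the
#' `genome_id` argument, otherwise from the file name stem — the convention
#' for collections stored as one proteome/assembly file per genome.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` (20 amino acids plus `X`) or `"nucleotide"`
#'   (`ACGT` plus `N`).
#' @param genome_id Optional genome identifier overriding the file-stem
#'   default (a `genome=` header token still wins).
#' @param permissive If `TRUE`, residues outside the alphabet are mapped to
#'   `X` (protein) or `N` (nucleotide) instead of raising an error.
#' @return A tibble with columns `seq_id`, `description`, `residues`,
#'   `genome_id`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 genome=g1", "acdef", ">p2", "MKLV"), fa)
#' read_fasta(fa, "protein")
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide"),
                       genome_id = NULL, permissive = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ",
                                     conditionMessage(e)))
  )
  stem <- sub("\\.(fa|fasta|faa|fna|fas)(\\.gz)?$", "", basename(path),
              ignore.case = TRUE)
  default_genome <- genome_id %||% stem
  if (length(set) == 0) {
    return(tibble(seq_id = character(), description = character(),
                  residues = character(), genome_id = character()))
  }
  headers <- names(set)
  seq_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (any(seq_id == "")) {
    abort(paste0("malformed FASTA header (empty id) at record ",
                 which(seq_id == "")[1], " of ", path))
  }
  gtok <- regmatches(description, regexpr("genome=\\S+", description))
  has_tok <- grepl("genome=\\S+", description)
  gid <- rep(default_genome, length(seq_id))
  gid[has_tok] <- sub("^genome=", "",
                      regmatches(description, regexpr("genome=\\S+", description)))
  residues <- toupper(as.character(set))
  residues <- vapply(seq_along(residues), function(i) {
    normalize_residues(residues[[i]], alphabet, permissive, seq_id[[i]])
  }, character(1))
  if (anyDuplicated(seq_id)) {
    abort(paste0("duplicate seq_id in ", path, ": ",
                 seq_id[duplicated(seq_id)][1]))
  }
  tibble(seq_id = seq_id, description = description,
         residues = unname(residues), genome_id = gid)
}

protein_alphabet <- "ACDEFGHIKLMNPQRSTVWYX"
nucleotide_alphabet <- "ACGTN"

normalize_residues <- function(res, alphabet, permissive, seq_id) {
  if (is.na(res) || nchar(res) == 0) {
    abort(paste0("empty sequence for record '", seq_id, "'"))
  }
  allowed <- if (alphabet == "protein") protein_alphabet else nucleotide_alphabet
  bad <- gsub(paste0("[", allowed, "]"), "", res)
  if (nchar(bad) > 0) {
    if (!permissive) {
      abort(paste0("illegal ", alphabet, " residue '",
                   substr(bad, 1, 1), "' in record '", seq_id,
                   "' (use permissive = TRUE to mask)"))
    }
    sub_char <- if (alphabet == "protein") "X" else "N"
    res <- gsub(paste0("[^", allowed, "]"), sub_char, res)
  }
  res
}

#' Write sequence records to FASTA
#'
#' Deterministic writer: records are emitted in table order, one header per
#' record (`>seq_id genome=<genome_id> <description>`), sequence lines wrapped
#' at `width` characters. `write_fasta()` followed by [read_fasta()] restores
#' `seq_id`, `residues` and `genome_id` exactly.
#'
#' @param records Tibble with columns `seq_id` and `residues`; optional
#'   `genome_id` and `description`.
#' @param path Output path.
#' @param width Maximum sequence line width (>= 1).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), width >= 1)
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (anyDuplicated(records$seq_id)) abort("duplicate seq_id in records")
  desc <- if ("description" %in% names(records)) records$description else ""
  desc <- ifelse(is.na(desc), "", desc)
  # strip any stale genome= token; re-emit from the genome_id column
  desc <- trimws(gsub("genome=\\S+\\s*", "", desc))
  if ("genome_id" %in% names(records)) {
    desc <- trimws(paste0("genome=", records$genome_id, " ", desc))
  }
  headers <- trimws(paste(records$seq_id, desc))
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

.valid_orders <- c("NC", "NS", "NT", "NP", "OUTGROUP")

#' Read a genome metadata table
#'
#' Reads the tab-separated genome metadata table used throughout the package:
#' one row per genome with its order (one of `NC`, `NS`, `NT`, `NP`,
#' `OUTGROUP`), NP subclade (non-empty exactly when order is `NP`),
#' semicolon-separated habitat flags, and optional completeness /
#' contamination percentages.
#'
#' @param path Path to a TSV with columns `genome_id`, `order`, `subclade`,
#'   `habitat_flags`, `completeness`, `contamination`.
#' @return A tibble with `habitat_flags` as a list-column of character
#'   vectors; missing completeness/contamination become `NA`.
#' @export
read_metadata <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    genome_id = readr::col_character(),
    order = readr::col_character(),
    subclade = readr::col_character(),
    habitat_flags = readr::col_character(),
    completeness = readr::col_double(),
    contamination = readr::col_double()
  ), na = c("", "NA"))
  required <- c("genome_id", "order", "subclade", "habitat_flags",
                "completeness", "contamination")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl$subclade <- ifelse(is.na(tbl$subclade), "", tbl$subclade)
  tbl$habitat_flags <- strsplit(ifelse(is.na(tbl$habitat_flags), "",
                                       tbl$habitat_flags), ";", fixed = TRUE)
  validate_metadata(tbl)
  tbl
}

validate_metadata <- function(meta) {
  if (anyDuplicated(meta$genome_id)) {
    abort(paste0("duplicate genome_id: ",
                 meta$genome_id[duplicated(meta$genome_id)][1]))
  }
  bad_order <- setdiff(unique(meta$order), .valid_orders)
  if (length(bad_order) > 0) {
    abort(paste0("unknown order label: ", bad_order[1]))
  }
  np_empty <- meta$order == "NP" & meta$subclade == ""
  if (any(np_empty)) {
    abort(paste0("NP genome with empty subclade: ",
                 meta$genome_id[np_empty][1]))
  }
  non_np <- meta$order != "NP" & meta$subclade != ""
  if (any(non_np)) {
    abort(paste0("non-NP genome with subclade set: ",
                 meta$genome_id[non_np][1]))
  }
  bad_comp <- !is.na(meta$completeness) &
    (meta$completeness < 0 | meta$completeness > 100)
  if (any(bad_comp)) abort("completeness outside [0, 100]")
  bad_cont <- !is.na(meta$contamination) & meta$contamination < 0
  if (any(bad_cont)) abort("negative contamination")
  invisible(meta)
}

#' Write a genome metadata table
#'
#' Inverse of [read_metadata()]: habitat flag list-columns are collapsed with
#' semicolons.
#'
#' @param meta Metadata tibble as returned by [read_metadata()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- meta
  out$habitat_flags <- vapply(meta$habitat_flags, paste, character(1),
                              collapse = ";")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a per-protein annotation table
#'
#' @param path TSV with columns `protein_id`, `label`.
#' @return Tibble with those columns; proteins may carry several labels
#'   (several rows).
#' @export
read_annotations <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    label = readr::col_character()
  ))
  if (!all(c("protein_id", "label") %in% names(tbl))) {
    abort("annotation table needs columns protein_id, label")
  }
  tbl
}

#' Read one proteome/assembly FASTA per genome from a directory
#'
#' @param dir Directory containing FASTA files (one per genome; the file stem
#'   is the genome id unless headers carry `genome=` tokens).
#' @param alphabet Passed to [read_fasta()].
#' @param permissive Passed to [read_fasta()].
#' @return One tibble of records for the whole collection.
#' @export
read_fasta_dir <- function(dir, alphabet = "protein", permissive = FALSE) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta|faa|fna|fas)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (length(files) == 0) abort(paste0("no FASTA files under ", dir))
  recs <- purrr::map(files, read_fasta, alphabet = alphabet,
                     permissive = permissive)
  out <- bind_rows(recs)
  if (anyDuplicated(out$seq_id)) {
    abort(paste0("duplicate seq_id across files: ",
                 out$seq_id[duplicated(out$seq_id)][1]))
  }
  out
}
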