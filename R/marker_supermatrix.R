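#' Parameters for single-copy marker selection and supermatrix assembly
#'
#' @param min_genomes Minimum number of genomes a marker family must be
#'   present in (the widespreadness rule, e.g. 70 of 85 genomes).
#' @param max_multicopy_fraction Maximum fraction of a family's presence
#'   genomes that may carry >= 2 copies.
#' @param paralog_resolution How to resolve multi-copy genomes when
#'   extracting marker alignments: `"keep_longest"` (ties: smallest seq_id)
#'   or `"drop_genome"`.
#' @param trim_gap_fraction Columns with gap fraction strictly greater than
#'   this are removed before concatenation.
#' @return An object of class `marker_params`.
#' @export
marker_params <- function(min_genomes, max_multicopy_fraction = 0.05,
                          paralog_resolution = c("keep_longest",
                                                 "drop_genome"),
                          trim_gap_fraction = 0.5) {
  paralog_resolution <- match.arg(paralog_resolution)
  stopifnot(min_genomes >= 1, max_multicopy_fraction >= 0,
            max_multicopy_fraction <= 1,
            trim_gap_fraction >= 0, trim_gap_fraction <= 1)
  structure(list(min_genomes = as.integer(min_genomes),
                 max_multicopy_fraction = max_multicopy_fraction,
                 paralog_resolution = paralog_resolution,
                 trim_gap_fraction = trim_gap_fraction),
            class = "marker_params")
}

#' Select widespread, predominantly single-copy marker families
#'
#' Markers are families present in at least `min_genomes` genomes and
#' multi-copy (count >= 2) in at most `max_multicopy_fraction` of their
#' presence genomes. Returned in deterministic order: descending presence
#' genome count, then family id.
#'
#' @param matrix A `pa_matrix`.
#' @param params A [marker_params()] object.
#' @return Tibble `family_id`, `n_genomes`, `n_multicopy`, in marker order.
#' @export
select_markers <- function(matrix, params) {
  stopifnot(inherits(matrix, "pa_matrix"), inherits(params, "marker_params"))
  if (params$min_genomes > ncol(matrix$counts)) {
    abort("min_genomes exceeds the number of genomes")
  }
  n_genomes <- rowSums(matrix$counts > 0)
  n_multi <- rowSums(matrix$counts >= 2)
  ok <- n_genomes >= params$min_genomes &
    n_multi <= params$max_multicopy_fraction * n_genomes
  out <- tibble(family_id = rownames(matrix$counts)[ok],
                n_genomes = n_genomes[ok], n_multicopy = n_multi[ok])
  arrange(out, desc(.data$n_genomes), .data$family_id)
}

#' Extract per-marker alignments from clustered families
#'
#' Collects the member sequences of each marker family keyed by genome and
#' applies paralog resolution when a genome contributes several copies.
#' Sequences must already be aligned (equal length within a family) — e.g.
#' externally aligned marker FASTA, or synthetic families generated under a
#' substitution-only model.
#'
#' @param records Record tibble with `seq_id`, `residues`.
#' @param families A `protein_families` object (or member tibble).
#' @param marker_ids Family ids to extract (e.g. from [select_markers()]).
#' @param paralog_resolution `"keep_longest"` or `"drop_genome"`.
#' @return Named list: `family_id` -> named character vector
#'   (genome_id -> aligned sequence).
#' @export
family_alignments <- function(records, families, marker_ids,
                              paralog_resolution = "keep_longest") {
  members <- if (inherits(families, "protein_families")) families$members
             else families
  seqs <- stats::setNames(records$residues, records$seq_id)
  out <- lapply(marker_ids, function(f) {
    m <- members[members$family_id == f, ]
    m$len <- nchar(seqs[m$seq_id])
    m <- m[order(m$genome_id, -m$len, m$seq_id), ]
    dup <- duplicated(m$genome_id)
    if (any(dup)) {
      if (paralog_resolution == "drop_genome") {
        m <- m[!(m$genome_id %in% m$genome_id[dup]), ]
      } else {
        m <- m[!dup, ]   # rows sorted longest-first, smallest seq_id first
      }
    }
    stats::setNames(unname(seqs[m$seq_id]), m$genome_id)
  })
  stats::setNames(out, marker_ids)
}

trim_alignment <- function(aln_matrix, trim_gap_fraction) {
  gap_frac <- colMeans(aln_matrix == "-")
  aln_matrix[, gap_frac <= trim_gap_fraction, drop = FALSE]
}

#' Assemble a trimmed, concatenated marker supermatrix
#'
#' Per marker, alignment columns whose gap fraction is strictly greater than
#' `trim_gap_fraction` are removed; the trimmed blocks are concatenated in
#' the given marker order, padding genomes that miss a marker with gap
#' characters, and 1-based inclusive partition coordinates are recorded.
#'
#' @param alignments Named list of marker alignments: `family_id` -> named
#'   character vector (genome_id -> aligned sequence, equal lengths, at most
#'   one sequence per genome).
#' @param genomes Character vector of genome ids forming the rows.
#' @param params A [marker_params()] object (only `trim_gap_fraction` used).
#' @return An object of class `supermatrix`: list with `sequences` (named
#'   character vector, one row string per genome, all of equal length),
#'   `partitions` (tibble `marker`, `start`, `end`) and `width`.
#' @export
build_supermatrix <- function(alignments, genomes, params) {
  stopifnot(length(alignments) > 0, length(genomes) > 0,
            inherits(params, "marker_params"))
  rows <- stats::setNames(rep("", length(genomes)), genomes)
  parts <- vector("list", length(alignments))
  pos <- 0L
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    marker <- names(alignments)[i]
    if (anyDuplicated(names(aln))) {
      abort(paste0("duplicate genome in marker ", marker))
    }
    widths <- nchar(aln)
    if (length(unique(widths)) != 1) {
      abort(paste0("ragged alignment for marker ", marker))
    }
    unknown <- setdiff(names(aln), genomes)
    if (length(unknown) > 0) {
      abort(paste0("marker ", marker, " has sequence for unknown genome ",
                   unknown[1]))
    }
    mat <- do.call(rbind, strsplit(unname(aln), ""))
    rownames(mat) <- names(aln)
    mat <- trim_alignment(mat, params$trim_gap_fraction)
    w <- ncol(mat)
    block <- stats::setNames(strrep("-", w), NULL)
    block_rows <- rep(strrep("-", w), length(genomes))
    names(block_rows) <- genomes
    if (w > 0 && nrow(mat) > 0) {
      block_rows[rownames(mat)] <- apply(mat, 1, paste, collapse = "")
    }
    rows <- paste0(rows, block_rows)
    names(rows) <- genomes
    parts[[i]] <- tibble(marker = marker, start = pos + 1L,
                         end = pos + as.integer(w))
    pos <- pos + as.integer(w)
  }
  partitions <- bind_rows(parts)
  partitions <- partitions[partitions$end >= partitions$start, ]
  width <- pos
  stopifnot(all(nchar(rows) == width))
  structure(list(sequences = rows, partitions = partitions,
                 width = as.integer(width)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", length(x$sequences), " genomes x ", x$width,
      " sites (", nrow(x$partitions), " markers)\n", sep = "")
  invisible(x)
}

#' Write a supermatrix as FASTA
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_supermatrix_fasta <- function(sm, path) {
  write_fasta(tibble(seq_id = names(sm$sequences),
                     residues = unname(sm$sequences)),
              path)
}

#' Write a supermatrix as relaxed PHYLIP
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_supermatrix_phylip <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(sm$sequences), sm$width), con)
  writeLines(paste(names(sm$sequences), unname(sm$sequences)), con)
  invisible(path)
}

#' Write RAxML-style partition coordinates
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(sm, path) {
  writeLines(sprintf("MARKER_%s = %d-%d", sm$partitions$marker,
                     sm$partitions$start, sm$partitions$end), path)
  invisible(path)
}
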