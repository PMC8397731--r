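#' Per-assembly contig statistics
#'
#' Computes the standard MAG assembly statistics: contig count, total size,
#' longest contig, N50 (length of the contig at which the cumulative sum of
#' descending-sorted lengths first reaches half the assembly size) and GC%
#' over unambiguous bases (Ns excluded from numerator and denominator).
#'
#' @param records Nucleotide records: tibble with `residues`, or a character
#'   vector of contig sequences.
#' @return One-row tibble: `n_contigs`, `total_bp`, `longest_bp`, `n50_bp`,
#'   `gc_percent`.
#' @examples
#' contig_stats(c(strrep("ATGC", 25)))
#' @export
contig_stats <- function(records) {
  seqs <- assembly_seqs(records)
  if (length(seqs) == 0) abort("empty assembly")
  lens <- nchar(seqs)
  if (any(lens == 0)) abort("empty contig")
  gc <- sum(nchar(gsub("[^GCgc]", "", seqs)))
  at <- sum(nchar(gsub("[^ATat]", "", seqs)))
  tibble(
    n_contigs = length(seqs),
    total_bp = sum(lens),
    longest_bp = max(lens),
    n50_bp = n50(lens),
    gc_percent = if (gc + at == 0) NA_real_ else 100 * gc / (gc + at)
  )
}

#' N50 of a set of contig lengths
#'
#' @param lengths Positive integer vector of contig lengths.
#' @return The N50 length.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Summarise a MAG statistics table
#'
#' Column-wise mean, sample SD (n-1), min and max for the numeric columns of
#' a MAG statistics table, plus counts of rows above user-chosen thresholds.
#'
#' @param table Tibble with one row per MAG; numeric stat columns (e.g.
#'   `genome_size_bp`, `gc_percent`, `completeness`, `contamination`).
#' @param count_thresholds Named numeric vector: column -> threshold; rows
#'   with value above the threshold are counted.
#' @param strict Use strict `>` for threshold counting (default); `FALSE`
#'   uses `>=`.
#' @return List of class `mag_summary`: `stats` (tibble `column`, `mean`,
#'   `sd`, `min`, `max`, `n`) and `counts` (tibble `column`, `threshold`,
#'   `n_above`).
#' @export
summarize_mag_table <- function(table, count_thresholds = NULL,
                                strict = TRUE) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  if (length(num_cols) == 0) abort("no numeric columns to summarise")
  stats_tbl <- bind_rows(lapply(num_cols, function(cn) {
    x <- table[[cn]]
    x <- x[!is.na(x)]
    tibble(column = cn, mean = mean(x),
           sd = if (length(x) > 1) stats::sd(x) else 0,
           min = min(x), max = max(x), n = length(x))
  }))
  counts <- NULL
  if (!is.null(count_thresholds)) {
    bad <- setdiff(names(count_thresholds), num_cols)
    if (length(bad) > 0) abort(paste0("non-numeric column: ", bad[1]))
    counts <- bind_rows(lapply(names(count_thresholds), function(cn) {
      thr <- count_thresholds[[cn]]
      x <- table[[cn]]
      n_above <- if (strict) sum(x > thr, na.rm = TRUE)
                 else sum(x >= thr, na.rm = TRUE)
      tibble(column = cn, threshold = thr, n_above = n_above)
    }))
  }
  structure(list(stats = stats_tbl, counts = counts), class = "mag_summary")
}

#' @export
print.mag_summary <- function(x, ...) {
  cat("<mag_summary>\n")
  print(x$stats)
  if (!is.null(x$counts)) print(x$counts)
  invisible(x)
}

#' MAG quality tier thresholds
#'
#' Defaults encode the tiering used for deep-sediment MAG sets: high quality
#' means completeness strictly above 80% with contamination at ~5% or below
#' (operationalised as <= 5.5 so that bins reported at 5.3-5.4% qualify),
#' very high quality additionally requires completeness strictly above 90%.
#'
#' @param hq_min_completeness High-quality completeness bound (strict `>`).
#' @param hq_max_contamination Maximum contamination for high/very-high tiers.
#' @param vq_min_completeness Very-high-quality completeness bound (strict
#'   `>`).
#' @return An object of class `quality_thresholds`.
#' @export
quality_thresholds <- function(hq_min_completeness = 80,
                               hq_max_contamination = 5.5,
                               vq_min_completeness = 90) {
  stopifnot(vq_min_completeness >= hq_min_completeness)
  structure(list(hq_min_completeness = hq_min_completeness,
                 hq_max_contamination = hq_max_contamination,
                 vq_min_completeness = vq_min_completeness),
            class = "quality_thresholds")
}

#' Classify MAG quality from completeness and contamination
#'
#' Tiers: `very_high` (completeness > 90, contamination <= 5.5 by default),
#' `high` (completeness > 80, contamination <= 5.5), `medium` (completeness
#' >= 50), else `low`. Vectorised.
#'
#' @param completeness Completeness percentages in `[0, 100]`.
#' @param contamination Contamination percentages (>= 0).
#' @param thresholds A [quality_thresholds()] object.
#' @return Factor with levels `very_high`, `high`, `medium`, `low`.
#' @examples
#' classify_quality(c(99.5, 76.2, 80), c(2.9, 6.3, 0))
#' @export
classify_quality <- function(completeness, contamination,
                             thresholds = quality_thresholds()) {
  if (any(completeness < 0 | completeness > 100, na.rm = TRUE)) {
    abort("completeness outside [0, 100]")
  }
  if (any(contamination < 0, na.rm = TRUE)) abort("negative contamination")
  t <- thresholds
  tier <- ifelse(
    completeness > t$vq_min_completeness &
      contamination <= t$hq_max_contamination, "very_high",
    ifelse(completeness > t$hq_min_completeness &
             contamination <= t$hq_max_contamination, "high",
           ifelse(completeness >= 50, "medium", "low")))
  factor(tier, levels = c("very_high", "high", "medium", "low"))
}

#' Published statistics table for the 11 deep-sediment MAGs
#'
#' Loads the statistics table for the 11 deep marine sediment-derived AOA
#' MAGs (contig counts, genome size, longest contig, N50, GC%, completeness,
#' contamination) shipped with the package as plain TSV, for worked examples
#' and summary checks.
#'
#' @return Tibble with one row per MAG.
#' @export
sediment_mag_table <- function() {
  path <- system.file("extdata", "deep_sediment_mags.tsv",
                      package = "sedipan", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    genome_bin = readr::col_character(),
    clade = readr::col_character(),
    .default = readr::col_double()
  ))
}
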