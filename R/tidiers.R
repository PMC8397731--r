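#' Tidy a protein family clustering
#'
#' @param x A `protein_families` object.
#' @param ... Unused.
#' @return The member tibble (one row per sequence).
#' @exportS3Method generics::tidy
tidy.protein_families <- function(x, ...) x$members

#' One-row clustering summary
#'
#' @param x A `protein_families` object.
#' @param ... Unused.
#' @return Tibble: `n_sequences`, `n_families`, `n_singleton_families`,
#'   `largest_family`, `min_identity`, `min_cov_long`, `min_cov_short`.
#' @exportS3Method generics::glance
glance.protein_families <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$members),
    n_families = nrow(x$families),
    n_singleton_families = sum(x$families$n_members == 1),
    largest_family = max(x$families$n_members),
    min_identity = x$params$min_identity,
    min_cov_long = x$params$min_cov_long,
    min_cov_short = x$params$min_cov_short
  )
}

#' Tidy a presence/absence matrix into long form
#'
#' @param x A `pa_matrix`.
#' @param ... Unused.
#' @return Long tibble: `family_id`, `genome_id`, `count`, `present`.
#' @exportS3Method generics::tidy
tidy.pa_matrix <- function(x, ...) {
  as_tibble(x$counts, rownames = "family_id") |>
    tidyr::pivot_longer(-"family_id", names_to = "genome_id",
                        values_to = "count") |>
    mutate(present = .data$count >= 1)
}

#' One-row presence/absence matrix summary
#'
#' @param x A `pa_matrix`.
#' @param ... Unused.
#' @return Tibble: `n_families`, `n_genomes`, `n_presences`,
#'   `n_shared_families` (families in >= 2 genomes).
#' @exportS3Method generics::glance
glance.pa_matrix <- function(x, ...) {
  pres <- x$counts > 0
  tibble(n_families = nrow(pres), n_genomes = ncol(pres),
         n_presences = sum(pres),
         n_shared_families = sum(rowSums(pres) >= 2))
}

#' Tidy a partition report
#'
#' @param x A `partition_report`.
#' @param ... Unused.
#' @return Tibble `set`, `n_families` (family id lists dropped).
#' @exportS3Method generics::tidy
tidy.partition_report <- function(x, ...) {
  tibble(set = x$set, n_families = x$n_families)
}

#' Tidy a supermatrix into its partition table
#'
#' @param x A `supermatrix`.
#' @param ... Unused.
#' @return Tibble `marker`, `start`, `end`, `width`.
#' @exportS3Method generics::tidy
tidy.supermatrix <- function(x, ...) {
  mutate(x$partitions, width = .data$end - .data$start + 1L)
}

#' One-row supermatrix summary
#'
#' @param x A `supermatrix`.
#' @param ... Unused.
#' @return Tibble: `n_genomes`, `n_markers`, `width`, `gap_fraction`.
#' @exportS3Method generics::glance
glance.supermatrix <- function(x, ...) {
  gaps <- sum(vapply(x$sequences, function(s) {
    nchar(gsub("[^-]", "", s))
  }, numeric(1)))
  tibble(n_genomes = length(x$sequences), n_markers = nrow(x$partitions),
         width = x$width,
         gap_fraction = gaps / (x$width * length(x$sequences)))
}

#' Tidy an ANI matrix into pair rows
#'
#' @param x An `ani_matrix`.
#' @param ... Unused.
#' @return Tibble `genome_a`, `genome_b`, `ani` for all unordered pairs.
#' @exportS3Method generics::tidy
tidy.ani_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(genome_a = rownames(m)[idx[, 1]], genome_b = colnames(m)[idx[, 2]],
         ani = m[idx])
}

#' Tidy a MAG summary
#'
#' @param x A `mag_summary`.
#' @param ... Unused.
#' @return The per-column stats tibble.
#' @exportS3Method generics::tidy
tidy.mag_summary <- function(x, ...) x$stats
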