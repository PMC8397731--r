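#' Plot a presence/absence matrix as a tile map
#'
#' Families are ordered from the most widespread to the most uncommon (see
#' [order_families_for_display()]); genomes keep their metadata order, which
#' groups clades together.
#'
#' @param object A `pa_matrix`.
#' @param max_families Cap on the number of families drawn (most widespread
#'   first) to keep the device responsive.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pa_matrix <- function(object, max_families = 2000, ...) {
  fam_order <- order_families_for_display(object)
  fam_order <- head(fam_order, max_families)
  long <- tidy(object) |>
    filter(.data$family_id %in% fam_order, .data$present) |>
    mutate(family_id = factor(.data$family_id, levels = fam_order),
           genome_id = factor(.data$genome_id,
                              levels = object$metadata$genome_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$family_id,
                                     y = .data$genome_id)) +
    ggplot2::geom_tile(fill = "grey20") +
    ggplot2::labs(x = "protein family (widespread to uncommon)",
                  y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot partition set sizes
#'
#' @param object A `partition_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.partition_report <- function(object, ...) {
  tbl <- tidy(object)
  tbl$set <- factor(tbl$set, levels = rev(tbl$set))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$n_families, y = .data$set)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "families", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ANI matrix as a heatmap
#'
#' @param object An `ani_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ani_matrix <- function(object, ...) {
  m <- unclass(object)
  long <- as_tibble(m, rownames = "genome_a") |>
    tidyr::pivot_longer(-"genome_a", names_to = "genome_b",
                        values_to = "ani")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genome_a, y = .data$genome_b,
                                     fill = .data$ani)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(70, min(long$ani,
                                                         na.rm = TRUE)), 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ANI %") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the family size distribution of a clustering
#'
#' @param families A `protein_families` object.
#' @return A ggplot object.
#' @export
plot_family_sizes <- function(families) {
  stopifnot(inherits(families, "protein_families"))
  ggplot2::ggplot(families$families,
                  ggplot2::aes(x = .data$n_members)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::scale_x_continuous(trans = "log10") +
    ggplot2::labs(x = "family size (members)", y = "families") +
    ggplot2::theme_minimal()
}
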