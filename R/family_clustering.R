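#' Parameters for greedy protein family clustering
#'
#' Defaults reproduce the common pangenome setting for distant homology:
#' >= 35% identity over the shorter sequence and >= 70% aligned-span coverage
#' of both sequences against the family representative.
#'
#' @param min_identity Minimum identity (shorter-sequence denominator).
#' @param min_cov_long Minimum aligned-span coverage of the longer sequence.
#' @param min_cov_short Minimum aligned-span coverage of the shorter sequence.
#' @param word_size k-mer length for the candidate prefilter: a sequence is
#'   aligned against representatives sharing at least one word, plus any
#'   representative whose residue-composition match bound still allows the
#'   identity threshold (so the prefilter can never skip a qualifying
#'   representative).
#' @param exhaustive If `TRUE`, skip the prefilter and align against every
#'   representative.
#' @param scoring An [align_scoring()] scheme.
#' @return An object of class `clustering_params`.
#' @export
clustering_params <- function(min_identity = 0.35, min_cov_long = 0.70,
                              min_cov_short = 0.70, word_size = 3L,
                              exhaustive = FALSE,
                              scoring = align_scoring()) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_cov_long > 0, min_cov_long <= 1,
            min_cov_short > 0, min_cov_short <= 1,
            word_size >= 1)
  structure(list(min_identity = min_identity, min_cov_long = min_cov_long,
                 min_cov_short = min_cov_short,
                 word_size = as.integer(word_size),
                 exhaustive = isTRUE(exhaustive), scoring = scoring),
            class = "clustering_params")
}

seq_words <- function(residues, k) {
  n <- nchar(residues)
  if (n < k) return(residues)
  unique(substring(residues, 1:(n - k + 1), k:n))
}

aa_composition <- function(residues) {
  chars <- strsplit(residues, "")[[1]]
  tabulate(factor(chars, levels = aa_alphabet_full),
           nbins = length(aa_alphabet_full))
}

# Upper bound on identical aligned residue pairs between the query and every
# representative, from residue compositions: matches <= sum_a min(count_a).
# Makes the prefilter sound: a representative the word index misses is still
# aligned whenever this bound leaves the identity threshold attainable.
composition_match_bound <- function(rep_comp, n_reps, q_comp) {
  bound <- numeric(n_reps)
  for (a in seq_along(q_comp)) {
    if (q_comp[a] > 0) {
      bound <- bound + pmin(rep_comp[seq_len(n_reps), a], q_comp[a])
    }
  }
  bound
}

#' Cluster proteins into families by greedy incremental clustering
#'
#' Star clustering in the style of greedy incremental tools: sequences are
#' processed in order of decreasing length (ties broken by `seq_id`); the
#' first sequence founds the first family, and each subsequent sequence is
#' aligned against the existing family representatives and joins the
#' representative with the highest identity among those meeting all three
#' thresholds (ties: longest representative, then smallest family id);
#' otherwise it founds a new family. Membership is evaluated against
#' representatives only; representatives are always the longest member. The
#' result is a partition: every input sequence belongs to exactly one family.
#'
#' @param records Tibble of protein records (`seq_id`, `residues`,
#'   `genome_id`); `seq_id` must be unique.
#' @param params A [clustering_params()] object.
#' @return An object of class `protein_families`: list with `members`
#'   (tibble `family_id`, `seq_id`, `genome_id`, `identity_to_rep`,
#'   `cov_long`, `cov_short`, `is_representative`), `families` (tibble
#'   `family_id`, `representative_id`, `n_members`, `n_genomes`) and
#'   `params`. Family ids are `F00001`, ... in founding order.
#' @examples
#' fam <- simulate_family(3, 120, 0.8, seed = 2)
#' cluster_proteins(fam)
#' @export
cluster_proteins <- function(records, params = clustering_params()) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("seq_id", "residues") %in% names(records)))
  if (anyDuplicated(records$seq_id)) {
    abort(paste0("duplicate seq_id: ",
                 records$seq_id[duplicated(records$seq_id)][1]))
  }
  if (!"genome_id" %in% names(records)) records$genome_id <- NA_character_
  ord <- order(-nchar(records$residues), records$seq_id)
  recs <- records[ord, ]
  n <- nrow(recs)
  k <- params$word_size

  rep_seqs <- character(0)        # representative residues, by family index
  rep_ids <- character(0)
  rep_comp <- matrix(0L, nrow = 64, ncol = length(aa_alphabet_full))
  rep_len <- integer(0)
  word_index <- new.env(hash = TRUE, parent = emptyenv())
  assignment <- integer(n)        # family index per input row
  id_to_rep <- numeric(n); covl <- numeric(n); covs <- numeric(n)

  for (i in seq_len(n)) {
    seq_i <- recs$residues[i]
    comp_i <- aa_composition(seq_i)
    len_i <- nchar(seq_i)
    if (params$exhaustive || length(rep_seqs) == 0) {
      cand <- seq_along(rep_seqs)
    } else {
      words <- seq_words(seq_i, k)
      hit <- logical(length(rep_seqs))
      for (w in words) {
        fams <- word_index[[w]]
        if (!is.null(fams)) hit[fams] <- TRUE
      }
      if (!all(hit)) {
        # soundness net: keep any word-missed representative whose
        # composition bound still allows identity >= min_identity
        bound <- composition_match_bound(rep_comp, length(rep_seqs), comp_i)
        feasible <- bound >= params$min_identity * pmin(rep_len, len_i)
        hit <- hit | feasible
      }
      cand <- which(hit)
    }
    best <- 0L
    if (length(cand) > 0) {
      st <- align_stats(rep_seqs[cand], seq_i, params$scoring)
      ok <- st$identity_short >= params$min_identity &
        st$cov_long >= params$min_cov_long &
        st$cov_short >= params$min_cov_short
      if (any(ok)) {
        okc <- which(ok)
        # best identity; ties -> longest representative, then smallest family
        o <- order(-st$identity_short[okc], -nchar(rep_seqs[cand[okc]]),
                   cand[okc])
        pick <- okc[o[1]]
        best <- cand[pick]
        id_to_rep[i] <- st$identity_short[pick]
        covl[i] <- st$cov_long[pick]
        covs[i] <- st$cov_short[pick]
      }
    }
    if (best == 0L) {
      fam_idx <- length(rep_seqs) + 1L
      rep_seqs[fam_idx] <- seq_i
      rep_ids[fam_idx] <- recs$seq_id[i]
      if (fam_idx > nrow(rep_comp)) {
        rep_comp <- rbind(rep_comp, matrix(0L, nrow = nrow(rep_comp),
                                           ncol = ncol(rep_comp)))
      }
      rep_comp[fam_idx, ] <- comp_i
      rep_len[fam_idx] <- len_i
      for (w in seq_words(seq_i, k)) {
        word_index[[w]] <- c(word_index[[w]], fam_idx)
      }
      assignment[i] <- fam_idx
      id_to_rep[i] <- 1; covl[i] <- 1; covs[i] <- 1
    } else {
      assignment[i] <- best
    }
  }

  members <- tibble(
    family_id = sprintf("F%05d", assignment),
    seq_id = recs$seq_id, genome_id = recs$genome_id,
    identity_to_rep = id_to_rep, cov_long = covl, cov_short = covs,
    is_representative = recs$seq_id == rep_ids[assignment]
  )
  members <- arrange(members, .data$family_id, desc(.data$is_representative),
                     .data$seq_id)
  families <- members |>
    group_by(.data$family_id) |>
    summarise(representative_id = .data$seq_id[.data$is_representative][1],
              n_members = n(),
              n_genomes = dplyr::n_distinct(.data$genome_id),
              .groups = "drop")
  structure(list(members = members, families = families, params = params),
            class = "protein_families")
}

#' @export
print.protein_families <- function(x, ...) {
  cat("<protein_families> ", nrow(x$families), " families, ",
      nrow(x$members), " sequences\n", sep = "")
  cat("  thresholds: identity >= ", x$params$min_identity,
      ", coverage >= ", x$params$min_cov_long, "/", x$params$min_cov_short,
      " (long/short)\n", sep = "")
  invisible(x)
}

#' Brute-force greedy clustering oracle
#'
#' Reference implementation of the same greedy scheme as
#' [cluster_proteins()], written independently with plain loops, all-vs-all
#' alignment of each sequence against every representative, and no k-mer
#' prefilter. Guarded to small inputs; used to certify the production path.
#'
#' @param records Protein record tibble (<= 500 rows).
#' @param params A [clustering_params()] object (`word_size`/`exhaustive`
#'   ignored).
#' @return A `protein_families` object.
#' @export
brute_force_cluster_oracle <- function(records, params = clustering_params()) {
  if (nrow(records) > 500) abort("oracle is guarded to <= 500 records")
  if (anyDuplicated(records$seq_id)) abort("duplicate seq_id")
  if (!"genome_id" %in% names(records)) records$genome_id <- NA_character_
  recs <- records[order(-nchar(records$residues), records$seq_id), ]
  fam_of <- integer(nrow(recs))
  reps <- integer(0)              # row index of each family representative
  stats <- list()
  for (i in seq_len(nrow(recs))) {
    best_fam <- 0L; best <- NULL
    for (f in seq_along(reps)) {
      st <- global_align(recs$residues[reps[f]], recs$residues[i],
                         scoring = params$scoring)
      meets <- st$identity_short >= params$min_identity &&
        st$cov_long >= params$min_cov_long &&
        st$cov_short >= params$min_cov_short
      if (!meets) next
      better <- is.null(best) ||
        st$identity_short > best$identity_short ||
        (st$identity_short == best$identity_short &&
           nchar(recs$residues[reps[f]]) > nchar(recs$residues[reps[best_fam]]))
      if (better) { best_fam <- f; best <- st }
    }
    if (best_fam == 0L) {
      reps <- c(reps, i)
      fam_of[i] <- length(reps)
      stats[[i]] <- list(id = 1, cl = 1, cs = 1)
    } else {
      fam_of[i] <- best_fam
      stats[[i]] <- list(id = best$identity_short, cl = best$cov_long,
                         cs = best$cov_short)
    }
  }
  members <- tibble(
    family_id = sprintf("F%05d", fam_of),
    seq_id = recs$seq_id, genome_id = recs$genome_id,
    identity_to_rep = vapply(stats, `[[`, numeric(1), "id"),
    cov_long = vapply(stats, `[[`, numeric(1), "cl"),
    cov_short = vapply(stats, `[[`, numeric(1), "cs"),
    is_representative = seq_len(nrow(recs)) %in% reps
  )
  members <- arrange(members, .data$family_id, desc(.data$is_representative),
                     .data$seq_id)
  families <- members |>
    group_by(.data$family_id) |>
    summarise(representative_id = .data$seq_id[.data$is_representative][1],
              n_members = n(),
              n_genomes = dplyr::n_distinct(.data$genome_id),
              .groups = "drop")
  structure(list(members = members, families = families, params = params),
            class = "protein_families")
}

#' Write family membership as TSV
#'
#' @param families A `protein_families` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_families_tsv <- function(families, path) {
  tbl <- left_join(families$members,
                   families$families[, c("family_id", "representative_id")],
                   by = "family_id")
  readr::write_tsv(tbl[, c("family_id", "representative_id", "seq_id",
                           "genome_id", "identity_to_rep", "cov_long",
                           "cov_short")], path)
  invisible(path)
}

#' Write families in `.clstr`-style text for interoperability
#'
#' @param families A `protein_families` object.
#' @param records The record tibble that was clustered (for lengths).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(families, records, path) {
  lens <- stats::setNames(nchar(records$residues), records$seq_id)
  con <- file(path, "w")
  on.exit(close(con))
  fams <- unique(families$members$family_id)
  for (fi in seq_along(fams)) {
    writeLines(paste0(">Cluster ", fi - 1), con)
    m <- families$members[families$members$family_id == fams[fi], ]
    m <- m[order(-m$is_representative, m$seq_id), ]
    for (j in seq_len(nrow(m))) {
      tag <- if (m$is_representative[j]) "*"
             else sprintf("at %.2f%%", 100 * m$identity_to_rep[j])
      writeLines(sprintf("%d\t%daa, >%s... %s", j - 1,
                         lens[[m$seq_id[j]]], m$seq_id[j], tag), con)
    }
  }
  invisible(path)
}
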