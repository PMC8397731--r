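# Independent oracles used across the suite. Written deliberately with plain
# loops / enumeration so they share no code path with the implementation.

# Enumerate every monotone alignment path of two short sequences and score it
# with BLOSUM62 + affine gaps (run cost = open + extend * length), terminal
# gap runs free. Returns the optimal score and the set of match counts
# attained by optimal paths. Exponential: keep sequences <= 6 residues.
enum_align <- function(a, b, gap_open = 11, gap_extend = 1) {
  mat <- sedipan::align_scoring()$matrix
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- list(score = -Inf, matches = integer(0))
  score_path <- function(moves) {
    ms <- which(moves == "M")
    if (length(ms) == 0) return(list(score = 0, matches = 0L))
    core <- moves[ms[1]:ms[length(ms)]]
    i <- 0L; j <- 0L; total <- 0; matches <- 0L
    # positions consumed before the core
    pre <- moves[seq_len(ms[1] - 1)]
    i <- sum(pre == "A"); j <- sum(pre == "B")
    run <- 0; run_type <- ""
    for (mv in core) {
      if (mv == "M") {
        if (run > 0) { total <- total - gap_open - gap_extend * run; run <- 0 }
        i <- i + 1L; j <- j + 1L
        total <- total + mat[av[i], bv[j]]
        if (av[i] == bv[j]) matches <- matches + 1L
        run_type <- ""
      } else {
        if (mv == "A") i <- i + 1L else j <- j + 1L
        if (mv == run_type) run <- run + 1
        else { if (run > 0) total <- total - gap_open - gap_extend * run
               run <- 1; run_type <- mv }
      }
    }
    if (run > 0) total <- total - gap_open - gap_extend * run  # unreachable:
    # core ends on M, so no trailing run remains
    list(score = total, matches = matches)
  }
  walk <- function(i, j, moves) {
    if (i == n && j == m) {
      r <- score_path(moves)
      if (r$score > best$score) best <<- list(score = r$score,
                                              matches = r$matches)
      else if (r$score == best$score) {
        best$matches <<- unique(c(best$matches, r$matches))
      }
      return(invisible())
    }
    if (i < n && j < m) walk(i + 1, j + 1, c(moves, "M"))
    if (i < n) walk(i + 1, j, c(moves, "A"))
    if (j < m) walk(i, j + 1, c(moves, "B"))
  }
  walk(0L, 0L, character(0))
  best
}

# N50 by the literal definition: first prefix of the descending-sorted
# lengths whose sum reaches half the total.
brute_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) return(x)
  }
}

# Random mixed record set: several simulated families at identities spanning
# the clustering threshold, plus length variation to exercise coverage rules.
random_record_set <- function(seed, n_families = NULL) {
  set.seed(seed)
  if (is.null(n_families)) n_families <- sample(8:15, 1)
  dplyr::bind_rows(lapply(seq_len(n_families), function(i) {
    fam <- simulate_family(sample(1:6, 1), sample(60:150, 1),
                           stats::runif(1, 0.30, 0.90), seed = seed * 997 + i)
    fam$seq_id <- paste0("r", seed, "f", i, "_", fam$seq_id)
    fam$genome_id <- paste0("g", sample(1:8, nrow(fam), replace = TRUE))
    fam
  }))
}

# Small taxonomy / blueprint for fast unit tests: 4 orders, 7 NP subclades
# (one genome each), one outgroup genome.
tiny_taxonomy <- function() {
  synthetic_taxonomy(n_per_order = c(NC = 2, NS = 2, NT = 2),
                     np_subclades = c(alpha = 1, gamma = 1, delta = 1,
                                      epsilon = 1, eta = 1, theta = 1,
                                      iota = 1),
                     n_outgroup = 1)
}

tiny_blueprint <- function(...) {
  defaults <- list(
    taxonomy = tiny_taxonomy(), n_core = 3,
    n_order_specific = c(NC = 1, NS = 1, NT = 1, NP = 1),
    n_subclade_specific = c(theta = 1, iota = 1),
    n_sediment_specific = 2, n_deep_shared = 1, n_singletons = 3,
    family_length_range = c(60, 120), dropout_prob = 0, seed = 11
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_blueprint, args)
}

# Random presence/absence matrix over a random small taxonomy.
random_pa_matrix <- function(seed) {
  set.seed(seed)
  meta <- synthetic_taxonomy(
    n_per_order = c(NC = sample(1:3, 1), NS = sample(1:3, 1),
                    NT = sample(1:3, 1)),
    np_subclades = stats::setNames(sample(1:2, 7, replace = TRUE),
                                   c("alpha", "gamma", "delta", "epsilon",
                                     "eta", "theta", "iota")),
    n_outgroup = sample(0:2, 1))
  n_fam <- sample(20:60, 1)
  members <- dplyr::bind_rows(lapply(seq_len(n_fam), function(f) {
    g <- sample(meta$genome_id, sample(1:nrow(meta), 1))
    tibble::tibble(family_id = sprintf("F%03d", f),
                   seq_id = paste0("F", f, "_", g), genome_id = g)
  }))
  build_matrix(members, meta)
}
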