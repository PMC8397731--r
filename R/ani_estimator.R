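#' Parameters for MinHash ANI estimation
#'
#' @param k k-mer length (4-32; 16 resolves genome-scale divergence well).
#' @param sketch_size Bottom-sketch size (>= 100).
#' @param seed Integer seed for the k-mer hash; fixes the sketch.
#' @return An object of class `ani_params`.
#' @export
ani_params <- function(k = 16L, sketch_size = 5000L, seed = 1L) {
  stopifnot(k >= 4, k <= 32, sketch_size >= 100)
  structure(list(k = as.integer(k), sketch_size = as.integer(sketch_size),
                 seed = as.integer(seed)),
            class = "ani_params")
}

assembly_seqs <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("residues" %in% names(x))
    return(x$residues)
  }
  stopifnot(is.character(x))
  x
}

unambiguous_bp <- function(seqs) {
  sum(nchar(gsub("[^ACGTacgt]", "", seqs)))
}

# Mash-style Jaccard from two bottom sketches: restrict to the bottom-s of
# the union and count hashes present in both.
sketch_jaccard <- function(sa, sb, sketch_size) {
  u <- sort(unique(c(sa, sb)))
  x <- head(u, sketch_size)
  shared <- sum(x %in% sa & x %in% sb)
  if (length(x) == 0) return(NA_real_)
  shared / length(x)
}

jaccard_to_ani <- function(j, k) {
  if (is.na(j) || j <= 0) return(NA_real_)
  # invert the k-mer survival model: fraction of shared k-mers w = 2J/(1+J),
  # per-site identity = w^(1/k)
  ani <- 100 * (2 * j / (1 + j))^(1 / k)
  min(max(ani, 0), 100)
}

#' Estimate average nucleotide identity between two assemblies
#'
#' Bottom-s MinHash sketches are taken over canonical k-mers of each
#' assembly (k-mers containing ambiguous bases are skipped), the Jaccard
#' index `J` of the k-mer sets is estimated from the merged sketch, and ANI
#' is recovered by inverting the k-mer survival model:
#' `ANI% = 100 * (2J / (1 + J))^(1/k)`, clamped to `[0, 100]`. Sketch-based
#' estimates are coarse below ~85% ANI; `J = 0` gives `NA`.
#'
#' @param a,b Assemblies: character vectors of contig sequences or record
#'   tibbles with a `residues` column. Each needs at least `10 * k` bp of
#'   unambiguous sequence.
#' @param params An [ani_params()] object.
#' @return ANI percentage (0-100), or `NA` when no k-mers are shared.
#' @export
estimate_ani <- function(a, b, params = ani_params()) {
  stopifnot(inherits(params, "ani_params"))
  a <- assembly_seqs(a); b <- assembly_seqs(b)
  if (unambiguous_bp(a) < 10 * params$k || unambiguous_bp(b) < 10 * params$k) {
    abort(paste0("assembly too short: need >= ", 10 * params$k,
                 " unambiguous bp"))
  }
  sa <- sketch_minhash(a, params$k, params$sketch_size, params$seed)
  sb <- sketch_minhash(b, params$k, params$sketch_size, params$seed)
  j <- sketch_jaccard(sa, sb, params$sketch_size)
  jaccard_to_ani(j, params$k)
}

#' All-pairs ANI matrix
#'
#' @param assemblies Named list: genome_id -> assembly (character vector of
#'   contigs or record tibble). At least two assemblies.
#' @param params An [ani_params()] object.
#' @return An object of class `ani_matrix`: symmetric numeric matrix of ANI
#'   percentages with 100 on the diagonal and `NA` for incomparable pairs.
#' @export
ani_matrix <- function(assemblies, params = ani_params()) {
  stopifnot(inherits(params, "ani_params"))
  if (length(assemblies) < 2) abort("need at least two assemblies")
  ids <- names(assemblies)
  if (is.null(ids) || any(ids == "")) abort("assemblies must be named")
  sketches <- lapply(assemblies, function(x) {
    x <- assembly_seqs(x)
    if (unambiguous_bp(x) < 10 * params$k) return(NULL)
    sketch_minhash(x, params$k, params$sketch_size, params$seed)
  })
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  for (i in seq_along(ids)) {
    for (jj in seq_len(i - 1)) {
      if (is.null(sketches[[i]]) || is.null(sketches[[jj]])) {
        warn(paste0("assembly too short, ANI set to NA: ", ids[i], " vs ",
                    ids[jj]))
        next
      }
      j <- sketch_jaccard(sketches[[i]], sketches[[jj]], params$sketch_size)
      m[i, jj] <- m[jj, i] <- jaccard_to_ani(j, params$k)
    }
  }
  structure(m, class = c("ani_matrix", "matrix"))
}

#' @export
print.ani_matrix <- function(x, ...) {
  cat("<ani_matrix> ", nrow(x), " genomes\n", sep = "")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Write an ANI matrix as TSV
#' @param m An `ani_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ani_matrix <- function(m, path) {
  tbl <- as_tibble(unclass(m), rownames = "genome_id")
  readr::write_tsv(tbl, path)
  invisible(path)
}
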