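#' Read a pipeline run configuration
#'
#' Configurations are flat YAML files with optional per-stage blocks
#' (`simulate` or `inputs`, `cluster`, `partition`, `markers`, `ani`),
#' a `seed` and an `out_dir`. Defaults mirror the package's standard
#' analysis: clustering at 0.35 identity / 0.70 bidirectional coverage,
#' marker widespreadness ratio 70/85, sediment subclades theta/delta/iota.
#'
#' @param path YAML file.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

default_config <- function() {
  list(
    seed = 1L,
    cluster = list(min_identity = 0.35, min_cov_long = 0.7,
                   min_cov_short = 0.7, word_size = 3, exhaustive = FALSE),
    partition = list(sediment_clades = c("theta", "delta", "iota"),
                     deep_clades = c("alpha", "gamma")),
    markers = list(min_genomes_fraction = 70 / 85,
                   max_multicopy_fraction = 0.05,
                   paralog_resolution = "keep_longest",
                   trim_gap_fraction = 0.5),
    ani = list(enabled = FALSE, k = 16, sketch_size = 5000,
               length_bp = 50000, rates = c(0.02, 0.05))
  )
}

merge_config <- function(user, defaults = default_config()) {
  for (nm in names(defaults)) {
    if (is.null(user[[nm]])) {
      user[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (k in names(defaults[[nm]])) {
        if (is.null(user[[nm]][[k]])) user[[nm]][[k]] <- defaults[[nm]][[k]]
      }
    }
  }
  user
}

validate_config <- function(config) {
  cfg <- merge_config(as.list(config))
  if (is.null(cfg$out_dir)) abort("config needs out_dir")
  has_sim <- !is.null(cfg$simulate)
  has_inputs <- !is.null(cfg$inputs)
  if (!has_sim && !has_inputs) {
    abort("config needs either a 'simulate' blueprint block or 'inputs'")
  }
  if (has_inputs) {
    for (p in c(cfg$inputs$proteome_dir, cfg$inputs$metadata,
                cfg$inputs$assembly_dir)) {
      if (!is.null(p) && !file.exists(p)) {
        abort(paste0("input path does not exist: ", p))
      }
    }
    if (is.null(cfg$inputs$proteome_dir) || is.null(cfg$inputs$metadata)) {
      abort("inputs block needs proteome_dir and metadata")
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

run_stage <- function(name, log, expr) {
  log(paste0("stage ", name, " ..."))
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full comparative-genomics pipeline
#'
#' Executes the stages in dependency order — simulate (or load inputs),
#' cluster, matrix, partition, markers, supermatrix, optionally ANI, stats —
#' writing every stage output under `out_dir` together with a JSON run
#' manifest (parameters, per-stage counts, md5 checksums). Re-running an
#' identical configuration reproduces identical checksums.
#'
#' @param config A `run_config` from [read_run_config()], or an equivalent
#'   named list (must contain `out_dir` and either a `simulate` blueprint
#'   block or an `inputs` block with `proteome_dir` and `metadata`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the stage objects (`collection`,
#'   `families`, `matrix`, `report`, `markers`, `supermatrix`, `ani`,
#'   `quality`) and the `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- validate_config(config)
  log <- if (quiet) function(...) invisible() else function(m) message(m)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "sedipan",
                   version = as.character(utils::packageVersion("sedipan")),
                   seed = cfg$seed, parameters = cfg[c("cluster", "partition",
                                                       "markers", "ani")])
  collection <- NULL

  if (!is.null(cfg$simulate)) {
    bp_args <- cfg$simulate
    if (isTRUE(bp_args)) bp_args <- list()
    bp_args$seed <- bp_args$seed %||% cfg$seed
    bp <- run_stage("simulate", log, do.call(synthetic_blueprint, bp_args))
    collection <- run_stage("simulate", log, generate_collection(bp))
    run_stage("simulate", log,
              write_collection(collection, file.path(out, "simulated")))
    records <- collection$records
    metadata <- collection$metadata
  } else {
    records <- run_stage("load", log,
                         read_fasta_dir(cfg$inputs$proteome_dir, "protein"))
    metadata <- run_stage("load", log, read_metadata(cfg$inputs$metadata))
  }

  cl <- cfg$cluster
  params <- clustering_params(cl$min_identity, cl$min_cov_long,
                              cl$min_cov_short, cl$word_size,
                              isTRUE(cl$exhaustive))
  families <- run_stage("cluster", log, cluster_proteins(records, params))
  run_stage("cluster", log,
            write_families_tsv(families, file.path(out, "families.tsv")))
  run_stage("cluster", log,
            write_clstr(families, records, file.path(out, "families.clstr")))
  log(paste0("  ", nrow(families$families), " families from ",
             nrow(records), " proteins"))

  pa <- run_stage("matrix", log, build_matrix(families, metadata))
  run_stage("matrix", log,
            write_matrix(pa, file.path(out, "matrix.tsv"),
                         file.path(out, "matrix_triplets.tsv")))

  pt <- cfg$partition
  report <- run_stage("partition", log,
                      standard_partitions(pa,
                                          sediment_clades = pt$sediment_clades,
                                          deep_clades = pt$deep_clades))
  run_stage("partition", log, {
    readr::write_tsv(tidy(report), file.path(out, "partition_counts.tsv"))
    sets <- tidyr::unnest(
      tibble(set = report$set, family_id = report$families), "family_id")
    readr::write_tsv(sets, file.path(out, "partition_sets.tsv"))
  })
  log(paste0("  partition counts: ",
             paste(report$set, report$n_families, sep = "=",
                   collapse = ", ")))

  mk <- cfg$markers
  min_genomes <- mk[["min_genomes"]] %||%
    ceiling(mk[["min_genomes_fraction"]] * ncol(pa$counts))
  mparams <- marker_params(min_genomes, mk$max_multicopy_fraction,
                           mk$paralog_resolution, mk$trim_gap_fraction)
  markers <- run_stage("markers", log, select_markers(pa, mparams))
  run_stage("markers", log,
            readr::write_tsv(markers, file.path(out, "markers.tsv")))
  log(paste0("  ", nrow(markers), " markers at min_genomes=", min_genomes))

  sm <- NULL
  if (nrow(markers) > 0) {
    alns <- run_stage("supermatrix", log,
                      family_alignments(records, families,
                                        markers$family_id,
                                        mparams$paralog_resolution))
    sm <- run_stage("supermatrix", log,
                    build_supermatrix(alns, metadata$genome_id, mparams))
    run_stage("supermatrix", log, {
      write_supermatrix_fasta(sm, file.path(out, "supermatrix.fasta"))
      write_supermatrix_phylip(sm, file.path(out, "supermatrix.phy"))
      write_partitions(sm, file.path(out, "partitions.txt"))
    })
    log(paste0("  supermatrix: ", sm$width, " sites x ",
               length(sm$sequences), " genomes"))
  }

  ani <- NULL
  if (isTRUE(cfg$ani$enabled)) {
    ani <- run_stage("ani", log, pipeline_ani(cfg, out))
    run_stage("ani", log, write_ani_matrix(ani, file.path(out, "ani.tsv")))
  }

  quality <- run_stage("stats", log, {
    q <- metadata[, c("genome_id", "completeness", "contamination")]
    ok <- !is.na(q$completeness) & !is.na(q$contamination)
    q$quality <- NA_character_
    q$quality[ok] <- as.character(
      classify_quality(q$completeness[ok], q$contamination[ok]))
    readr::write_tsv(q, file.path(out, "mag_quality.tsv"))
    q
  })

  manifest$counts <- list(
    n_proteins = nrow(records), n_genomes = nrow(metadata),
    n_families = nrow(families$families),
    partition = as.list(stats::setNames(report$n_families, report$set)),
    n_markers = nrow(markers),
    supermatrix_width = if (is.null(sm)) NULL else sm$width)
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, "manifest.json"))
  manifest$checksums <- as.list(stats::setNames(
    unname(tools::md5sum(files)),
    sub(paste0("^", out, "/?"), "", files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(collection = collection, families = families, matrix = pa,
                 report = report, markers = markers, supermatrix = sm,
                 ani = ani, quality = quality, manifest = manifest))
}

# Simulated ANI stage: a chain of assemblies derived from one root genome at
# the configured substitution rates.
pipeline_ani <- function(cfg, out) {
  if (!is.null(cfg$inputs$assembly_dir)) {
    files <- list.files(cfg$inputs$assembly_dir, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    assemblies <- lapply(files, function(f) read_fasta(f, "nucleotide"))
    names(assemblies) <- vapply(assemblies, function(x) x$genome_id[1],
                                character(1))
  } else {
    a <- cfg$ani
    assemblies <- withr::with_seed(cfg$seed, {
      root <- paste(sample(nt_letters, a$length_bp, replace = TRUE),
                    collapse = "")
      chain <- list(g1 = root)
      cur <- root
      for (i in seq_along(a$rates)) {
        cur <- substitute_nucleotides(cur, a$rates[[i]])
        chain[[paste0("g", i + 1)]] <- cur
      }
      chain
    })
  }
  ani_matrix(assemblies, ani_params(cfg$ani$k, cfg$ani$sketch_size,
                                    cfg$seed))
}
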