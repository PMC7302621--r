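#' Pipeline configuration
#'
#' Collects every stage's parameter block. Unknown keys are rejected so
#' typos fail loudly; the effective configuration is echoed to
#' `provenance.json` in the output directory.
#'
#' @param link_rule [pham_link_rule()].
#' @param scoring [pham_scoring()].
#' @param ani [ani_params()].
#' @param sketch [sketch_params()].
#' @param taxonomy [taxonomy_config()].
#' @param motif List with `discover` (logical), `length`, `min_copies`,
#'   `max_mismatch` controlling the direct-repeat discovery stage.
#' @param ... Must be empty; present to catch misspelled arguments.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(link_rule = pham_link_rule(),
                            scoring = pham_scoring(),
                            ani = ani_params(),
                            sketch = sketch_params(),
                            taxonomy = taxonomy_config(),
                            motif = list(discover = TRUE, length = 18L,
                                         min_copies = 3L,
                                         max_mismatch = 2L), ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ",
         paste(names(extra), collapse = ", "))
  known_motif <- c("discover", "length", "min_copies", "max_mismatch")
  if (length(setdiff(names(motif), known_motif)))
    stop("unknown motif configuration keys: ",
         paste(setdiff(names(motif), known_motif), collapse = ", "))
  motif <- modifyList(list(discover = TRUE, length = 18L, min_copies = 3L,
                           max_mismatch = 2L), motif)
  structure(list(link_rule = link_rule, scoring = scoring, ani = ani,
                 sketch = sketch, taxonomy = taxonomy, motif = motif),
            class = "pipeline_config")
}

stage_hash <- function(...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(...), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

cache_valid <- function(out_dir, stage, hash, files) {
  hf <- file.path(out_dir, ".cache", paste0(stage, ".hash"))
  file.exists(hf) && identical(readLines(hf, warn = FALSE), hash) &&
    all(file.exists(file.path(out_dir, files)))
}

cache_mark <- function(out_dir, stage, hash) {
  dir.create(file.path(out_dir, ".cache"), showWarnings = FALSE)
  writeLines(hash, file.path(out_dir, ".cache", paste0(stage, ".hash")))
}

#' Run the whole comparative-genomics pipeline
#'
#' Chains the stages on a genome set: genometrics table, pham
#' construction, presence matrix (TSV + NEXUS), GCS/GCD/ANI/
#' nucleotide-distance matrices, cluster/subcluster assignment,
#' MaxGCDGap, genome network, and (optionally) intergenic direct-repeat
#' discovery. Every table is written to `out_dir` with a `#` header
#' comment naming the parameters that produced it; the effective config
#' goes to `provenance.json` and a log to `run.log`. Expensive stages
#' (phams, matrices) are cached keyed on a content hash of their inputs
#' and parameters, so reruns and parameter sweeps reuse them. A stage
#' failure aborts with the stage name in the error.
#'
#' @param input Directory of `.gbk`/`.gb`/`.fasta`/`.fa` genome files, a
#'   list of [phage_genome()] objects, or a `phage_cohort`.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param quiet Suppress console log messages.
#' @return Invisibly, a list of the in-memory stage results
#'   (`genometrics`, `phams`, `matrices`, `clusters`, `maxgcdgap`,
#'   `network`, `motifs`).
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  cat("", file = logfile)
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logfile, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genomes <- stage("read", {
    if (is.character(input)) {
      files <- sort(list.files(input, "\\.(gbk?|gb|genbank|fa|fasta)$",
                               full.names = TRUE))
      if (!length(files)) stop("no genome files found in ", input)
      as_genome_list(lapply(files, function(f)
        if (grepl("\\.(fa|fasta)$", f)) read_fasta(f) else read_genbank(f)))
    } else as_genome_list(input)
  })
  note("read ", length(genomes), " genomes")
  if (length(genomes) < 2L)
    stop("pipeline stage 'pairwise' failed: at least 2 genomes required, ",
         "got ", length(genomes), call. = FALSE)
  genome_key <- lapply(genomes, function(g)
    list(g$phage_id, g$sequence, g$genes))

  metrics <- stage("genometrics", genometrics_table(genomes))
  readr::write_tsv(select(metrics, -"regional_gc"),
                   file.path(out_dir, "genometrics.tsv"), progress = FALSE)

  h_pham <- stage_hash("phams", genome_key, config$link_rule,
                       config$scoring)
  if (cache_valid(out_dir, "phams", h_pham, "phams.tsv")) {
    note("phams: cached")
    tb <- readr::read_tsv(file.path(out_dir, "phams.tsv"),
                          show_col_types = FALSE, progress = FALSE,
                          comment = "#")
    phams <- structure(list(membership = tb[c("gene_id", "phage_id",
                                              "pham_id")],
                            representatives = NULL,
                            phage_ids = names(genomes),
                            link_rule = config$link_rule,
                            scoring = config$scoring), class = "pham_set")
  } else {
    phams <- stage("phams", build_phams(genomes, config$link_rule,
                                        config$scoring))
    write_pham_table(phams, file.path(out_dir, "phams.tsv"))
    cache_mark(out_dir, "phams", h_pham)
  }
  note("phams: ", length(unique(phams$membership$pham_id)), " phamilies")
  pres <- presence_matrix(phams, genomes)
  utils::write.table(pres, file.path(out_dir, "presence_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  write_nexus_binary(pres, file.path(out_dir, "presence.nex"))

  h_mat <- stage_hash("matrices", genome_key, config$link_rule,
                      config$scoring, config$ani, config$sketch)
  mat_files <- c("gcs.tsv", "gcd.tsv", "ani.tsv", "nd.tsv")
  if (cache_valid(out_dir, "matrices", h_mat, mat_files)) {
    note("matrices: cached")
    mats <- lapply(setNames(c("gcs", "gcd", "ani", "nd"),
                            c("gcs", "gcd", "ani", "nd")), function(m)
      structure(list(values = read_matrix_tsv(
        file.path(out_dir, paste0(m, ".tsv"))), metric = m, params = NULL),
        class = "phamnet_matrix"))
  } else {
    mats <- stage("matrices", list(
      gcs = all_pairs(genomes, "gcs", phams = phams),
      gcd = all_pairs(genomes, "gcd", phams = phams),
      ani = all_pairs(genomes, "ani", params = config$ani),
      nd = all_pairs(genomes, "nd", params = config$sketch)))
    write_matrix_tsv(mats$gcs, file.path(out_dir, "gcs.tsv"),
                     comments = param_comment("gcs", config$link_rule))
    write_matrix_tsv(mats$gcd, file.path(out_dir, "gcd.tsv"),
                     comments = param_comment("gcd", config$link_rule))
    write_matrix_tsv(mats$ani, file.path(out_dir, "ani.tsv"),
                     comments = param_comment("ani", config$ani))
    write_matrix_tsv(mats$nd, file.path(out_dir, "nd.tsv"),
                     comments = param_comment("nd", config$sketch))
    cache_mark(out_dir, "matrices", h_mat)
  }
  note("matrices: gcs/gcd/ani/nd written")
  readr::write_tsv(similarity_table(mats$gcd, mats$nd),
                   file.path(out_dir, "similarity_pairs.tsv"),
                   progress = FALSE)

  clusters <- stage("clusters", {
    ca <- assign_clusters(mats$gcs, config$taxonomy)
    assign_subclusters(ca, mats$ani, config$taxonomy)
  })
  readr::write_tsv(tidy(clusters), file.path(out_dir, "clusters.tsv"),
                   progress = FALSE)
  note("clusters: ", glance(clusters)$n_clusters, " clusters, ",
       glance(clusters)$n_singletons, " singletons")

  gaps <- stage("maxgcdgap", max_gcd_gap(mats$gcd))
  readr::write_tsv(gaps, file.path(out_dir, "maxgcdgap.tsv"),
                   progress = FALSE)

  network <- stage("network", build_network(mats$gcd, mats$nd,
                                            config$taxonomy))
  readr::write_tsv(network$edges, file.path(out_dir, "network_edges.tsv"),
                   progress = FALSE)
  readr::write_tsv(network$components,
                   file.path(out_dir, "network_components.tsv"),
                   progress = FALSE)
  note("network: ", nrow(network$edges), " edges")

  motifs <- NULL
  if (isTRUE(config$motif$discover)) {
    motifs <- stage("motifs", discover_direct_repeats(
      genomes, length = config$motif$length,
      min_copies = config$motif$min_copies,
      max_mismatch = config$motif$max_mismatch))
    readr::write_tsv(select(motifs, -"occurrences"),
                     file.path(out_dir, "motifs.tsv"), progress = FALSE)
    if (nrow(motifs)) {
      hits <- bind_rows(lapply(seq_len(nrow(motifs)), function(i) {
        h <- motifs$occurrences[[i]]
        h$model_id <- motifs$model_id[i]
        h$strand <- "+"
        h
      }))
      write_gff3(hits, file.path(out_dir, "motif_hits.gff3"))
    }
    note("motifs: ", nrow(motifs), " models")
  }

  jsonlite::write_json(
    list(package = "phamnet",
         version = as.character(utils::packageVersion("phamnet")),
         r_version = R.version.string,
         n_genomes = length(genomes),
         config = unclass_deep(config)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  note("done")
  invisible(list(genometrics = metrics, phams = phams, matrices = mats,
                 clusters = clusters, maxgcdgap = gaps, network = network,
                 motifs = motifs))
}

param_comment <- function(metric, params) {
  sprintf("metric=%s %s", metric,
          paste(names(params), unlist(params), sep = "=", collapse = " "))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
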