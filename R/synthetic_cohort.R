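#' Specification for a synthetic phage cohort
#'
#' Describes a cohort with known ground truth: clusters of genomes built
#' from shared gene-family templates, singletons with private families,
#' tunable nucleotide divergence (targeting ANI bands), optional
#' subcluster structure, and motifs planted into intergenic spacers.
#' Everything downstream of the seed is deterministic.
#'
#' @param n_clusters Number of multi-member clusters.
#' @param cluster_sizes Genomes per cluster (recycled to `n_clusters`).
#' @param n_singletons Genomes with no relatives in the cohort.
#' @param genes_per_genome Two-element range; each cluster template
#'   carries the upper bound's worth of families, and members retain each
#'   with probability `within_cluster_family_retention`.
#' @param within_cluster_family_retention Per-family retention
#'   probability inside a cluster (default 0.9).
#' @param cross_cluster_family_overlap Fraction of each template drawn
#'   from a pool shared between clusters (default 0).
#' @param substitution_rate Per-site substitution rate applied to each
#'   member's genes, scalar or per-cluster (default 0.05; rate r targets
#'   an ANI band near `100 * (1 - r)`).
#' @param subcluster_counts Subgroups per cluster (default 1 = none).
#' @param between_subcluster_rate Divergence between subgroup references
#'   (default 0.15).
#' @param intergenic_len Two-element range of spacer lengths in bp.
#' @param protein_len Two-element range of protein lengths (aa).
#' @param gc_target Genome G+C fraction target (default 0.63, the
#'   mid-range of Microbacterium phage genomes). Spacers hit the target
#'   exactly in expectation; coding regions are limited by the uniform
#'   amino-acid composition of the random proteins, so realized genome
#'   GC is compressed a few points toward 50% for extreme targets.
#' @param minus_strand_frac Fraction of genes placed on the minus strand.
#' @param planted_motifs List of motif plantings; each element a list
#'   with `consensus`, `copies`, and optionally `max_mismatch` (0),
#'   `upstream_offset` (c(20, 30)), `orientation` ("direct" or
#'   "inverted"), `genomes` (phage ids; default the first genome).
#' @param n_integrase_genomes Number of genomes given one gene with a
#'   "serine integrase" product annotation (default 0).
#' @param seed Mandatory RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_clusters = 4L, cluster_sizes = 5L,
                        n_singletons = 2L, genes_per_genome = c(10L, 14L),
                        within_cluster_family_retention = 0.9,
                        cross_cluster_family_overlap = 0,
                        substitution_rate = 0.05,
                        subcluster_counts = 1L,
                        between_subcluster_rate = 0.15,
                        intergenic_len = c(30L, 120L),
                        protein_len = c(80L, 200L),
                        gc_target = 0.63, minus_strand_frac = 0.2,
                        planted_motifs = list(),
                        n_integrase_genomes = 0L, seed) {
  if (missing(seed)) stop("cohort_spec requires an explicit seed")
  stopifnot(n_clusters >= 0, n_singletons >= 0,
            within_cluster_family_retention >= 0,
            within_cluster_family_retention <= 1,
            cross_cluster_family_overlap >= 0,
            cross_cluster_family_overlap <= 1,
            all(substitution_rate >= 0), all(substitution_rate < 1),
            gc_target > 0, gc_target < 1)
  if (within_cluster_family_retention == 0 && min(genes_per_genome) > 0 &&
      n_clusters > 0)
    stop("infeasible spec: retention 0 with a positive minimum gene count")
  structure(list(
    n_clusters = as.integer(n_clusters),
    cluster_sizes = rep_len(as.integer(cluster_sizes), n_clusters),
    n_singletons = as.integer(n_singletons),
    genes_per_genome = as.integer(genes_per_genome),
    within_cluster_family_retention = within_cluster_family_retention,
    cross_cluster_family_overlap = cross_cluster_family_overlap,
    substitution_rate = rep_len(substitution_rate, max(1L, n_clusters)),
    subcluster_counts = rep_len(as.integer(subcluster_counts),
                                max(1L, n_clusters)),
    between_subcluster_rate = between_subcluster_rate,
    intergenic_len = as.integer(intergenic_len),
    protein_len = as.integer(protein_len),
    gc_target = gc_target, minus_strand_frac = minus_strand_frac,
    planted_motifs = planted_motifs,
    n_integrase_genomes = as.integer(n_integrase_genomes),
    seed = as.integer(seed)), class = "cohort_spec")
}

# codon choice biased toward the GC target; stop codons excluded
reverse_translate <- function(protein, gc_target) {
  code <- Biostrings::getGeneticCode("11")
  by_aa <- split(names(code), unname(code))
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(aa, function(a) {
    opts <- by_aa[[a]]
    gc <- vapply(opts, function(cd)
      sum(strsplit(cd, "")[[1]] %in% c("G", "C")) / 3, double(1))
    w <- exp(-12 * abs(gc - gc_target))
    sample(opts, 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
  paste(c("ATG", codons, "TAA"), collapse = "")
}

#' Mutate a sequence at a fixed substitution rate
#'
#' Each unambiguous site is independently substituted to a uniformly
#' chosen different base with probability `rate`; `N` sites are left
#' untouched. The realized substitution count is attached as the
#' `n_substitutions` attribute.
#'
#' @param seq DNA string.
#' @param rate Substitutions per site, in `[0, 1)`.
#' @return The mutated sequence (character scalar) with attribute
#'   `n_substitutions`.
#' @export
mutate_sequence <- function(seq, rate) {
  stopifnot(rate >= 0, rate < 1)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  eligible <- chars %in% c("A", "C", "G", "T")
  hit <- which(eligible & runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    idx <- match(chars[hit], bases)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- bases[((idx - 1L + shift) %% 4L) + 1L]
  }
  out <- paste(chars, collapse = "")
  attr(out, "n_substitutions") <- length(hit)
  out
}

# assemble one genome from (family_id, cds, strand, product, spacer)
# rows; each gene is preceded by its spacer, then the trailing spacer
assemble_genome <- function(phage_id, genes, trailing_spacer, spec) {
  n <- nrow(genes)
  seq_parts <- character(2L * n + 1L)
  rows <- vector("list", n)
  pos <- 0L
  for (i in seq_len(n)) {
    sp <- genes$spacer[i]
    seq_parts[2L * i - 1L] <- sp
    pos <- pos + nchar(sp)
    cds <- genes$cds[i]
    placed <- if (genes$strand[i] == "-") revcomp(cds) else cds
    seq_parts[2L * i] <- placed
    rows[[i]] <- gene_table(
      gene_id = sprintf("%s_g%02d", phage_id, i),
      start = pos, end = pos + nchar(cds), strand = genes$strand[i],
      product = genes$product[i], translation = translate_cds(cds),
      is_trna = FALSE)
    pos <- pos + nchar(cds)
  }
  seq_parts[2L * n + 1L] <- trailing_spacer
  genome <- phage_genome(phage_id, paste(seq_parts, collapse = ""),
                         genes = bind_rows(rows),
                         host = "Microbacterium sp. synthetic")
  truth <- tibble(gene_id = vapply(rows, function(r) r$gene_id, character(1)),
                  phage_id = phage_id, family = genes$family_id)
  list(genome = genome, truth = truth)
}

#' Generate a synthetic phage cohort with ground truth
#'
#' Gene families are random proteins reverse-translated at the GC target;
#' each cluster samples a family template, members retain families with
#' the retention probability and diverge by per-site substitution;
#' singletons carry private families. Genomes are genes separated by
#' random intergenic spacers; motifs are planted into spacers on request.
#' Fully reproducible from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `phage_cohort`: list with `genomes` (named list of
#'   [phage_genome()]), `truth` (list of tibbles: `genes` with true
#'   families, `phages` with true cluster/subcluster, `motifs` with
#'   planted coordinates, `substitutions`, `integrase_genomes`), and
#'   `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_clusters = 2, cluster_sizes = 2,
#'                                       n_singletons = 0, seed = 1))
#' names(cohort$genomes)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  shared_n <- round(spec$cross_cluster_family_overlap *
                      spec$genes_per_genome[2])
  shared_pool <- NULL
  if (shared_n > 0) {
    shared_pool <- lapply(seq_len(shared_n), function(k) {
      p <- random_protein(sample_range(spec$protein_len[1], spec$protein_len[2]))
      list(family_id = sprintf("FSHARED_%02d", k),
           cds = reverse_translate(p, spec$gc_target))
    })
  }
  genomes <- list()
  truth_genes <- list()
  truth_phages <- list()
  truth_subs <- list()

  for (cl in seq_len(spec$n_clusters)) {
    K <- spec$genes_per_genome[2]
    own <- lapply(seq_len(K - shared_n), function(k) {
      p <- random_protein(sample_range(spec$protein_len[1], spec$protein_len[2]))
      list(family_id = sprintf("F%02d_%02d", cl, k),
           cds = reverse_translate(p, spec$gc_target))
    })
    template <- c(shared_pool, own)
    fam_ids <- vapply(template, `[[`, character(1), "family_id")
    template_cds <- vapply(template, `[[`, character(1), "cds")
    # intergenic spacers belong to the template too: related genomes
    # share (diverged) intergenic sequence, not independent random DNA
    template_spacers <- vapply(
      sample_range(spec$intergenic_len[1], spec$intergenic_len[2], K + 1L),
      random_dna, character(1), gc = spec$gc_target)
    strands <- sample(c("+", "-"), K, replace = TRUE,
                      prob = c(1 - spec$minus_strand_frac,
                               spec$minus_strand_frac))
    S <- spec$subcluster_counts[cl]
    sub_refs <- lapply(seq_len(S), function(s) {
      if (s == 1L)
        list(cds = template_cds, spacers = template_spacers)
      else list(
        cds = vapply(template_cds, function(x)
          as.character(mutate_sequence(x, spec$between_subcluster_rate)),
          character(1), USE.NAMES = FALSE),
        spacers = vapply(template_spacers, function(x)
          as.character(mutate_sequence(x, spec$between_subcluster_rate)),
          character(1), USE.NAMES = FALSE))
    })
    for (m in seq_len(spec$cluster_sizes[cl])) {
      pid <- sprintf("SYN_C%02dM%02d", cl, m)
      sub <- ((m - 1L) %% S) + 1L
      keep <- runif(K) < spec$within_cluster_family_retention
      if (!any(keep)) keep[1L] <- TRUE
      nsub_total <- 0L
      mut <- function(x) {
        ms <- mutate_sequence(x, spec$substitution_rate[cl])
        nsub_total <<- nsub_total + attr(ms, "n_substitutions")
        as.character(ms)
      }
      cds <- vapply(sub_refs[[sub]]$cds[keep], mut, character(1),
                    USE.NAMES = FALSE)
      spacers <- vapply(sub_refs[[sub]]$spacers[seq_len(K)][keep], mut,
                        character(1), USE.NAMES = FALSE)
      trailing <- mut(sub_refs[[sub]]$spacers[K + 1L])
      genes <- tibble(family_id = fam_ids[keep], cds = cds,
                      strand = strands[keep], spacer = spacers,
                      product = "hypothetical protein")
      built <- assemble_genome(pid, genes, trailing, spec)
      genomes[[pid]] <- built$genome
      truth_genes[[pid]] <- built$truth
      truth_phages[[pid]] <- tibble(
        phage_id = pid, cluster = sprintf("C%d", cl),
        subcluster = if (S > 1L) sprintf("C%d.%d", cl, sub)
        else NA_character_)
      truth_subs[[pid]] <- tibble(phage_id = pid,
                                  n_substitutions = nsub_total)
    }
  }
  for (s in seq_len(spec$n_singletons)) {
    pid <- sprintf("SYN_S%02d", s)
    K <- sample_range(spec$genes_per_genome[1], spec$genes_per_genome[2])
    genes <- tibble(
      family_id = sprintf("FSING%02d_%02d", s, seq_len(K)),
      cds = vapply(seq_len(K), function(k)
        reverse_translate(
          random_protein(sample_range(spec$protein_len[1], spec$protein_len[2])),
          spec$gc_target), character(1)),
      strand = sample(c("+", "-"), K, replace = TRUE,
                      prob = c(1 - spec$minus_strand_frac,
                               spec$minus_strand_frac)),
      spacer = vapply(
        sample_range(spec$intergenic_len[1], spec$intergenic_len[2], K),
        random_dna, character(1), gc = spec$gc_target),
      product = "hypothetical protein")
    trailing <- random_dna(
      sample_range(spec$intergenic_len[1], spec$intergenic_len[2]),
      spec$gc_target)
    built <- assemble_genome(pid, genes, trailing, spec)
    genomes[[pid]] <- built$genome
    truth_genes[[pid]] <- built$truth
    truth_phages[[pid]] <- tibble(phage_id = pid, cluster = "SINGLETON",
                                  subcluster = NA_character_)
    truth_subs[[pid]] <- tibble(phage_id = pid, n_substitutions = 0L)
  }

  truth_motifs <- tibble(phage_id = character(), start = integer(),
                         end = integer(), strand = character(),
                         consensus = character(), mismatches = integer(),
                         upstream_offset = integer())
  for (pm in spec$planted_motifs) {
    targets <- pm$genomes %||% names(genomes)[1]
    for (pid in targets) {
      prior <- truth_motifs[truth_motifs$phage_id == pid, , drop = FALSE]
      planted <- plant_motif(
        genomes[[pid]], consensus = pm$consensus, copies = pm$copies,
        max_mismatch = pm$max_mismatch %||% 0L,
        upstream_offset = pm$upstream_offset %||% c(20L, 30L),
        orientation = pm$orientation %||% "direct",
        exclude = prior)
      genomes[[pid]] <- planted$genome
      truth_motifs <- bind_rows(truth_motifs, planted$truth)
    }
  }

  integrase_ids <- character()
  if (spec$n_integrase_genomes > 0L) {
    integrase_ids <- sort(sample(names(genomes),
                                 min(spec$n_integrase_genomes,
                                     length(genomes))))
    for (pid in integrase_ids) {
      g <- genomes[[pid]]
      j <- sample.int(nrow(g$genes), 1L)
      g$genes$product[j] <- "serine integrase"
      genomes[[pid]] <- g
    }
  }

  structure(list(
    genomes = genomes,
    truth = list(genes = bind_rows(truth_genes),
                 phages = bind_rows(truth_phages),
                 motifs = truth_motifs,
                 substitutions = bind_rows(truth_subs),
                 integrase_genomes = integrase_ids),
    spec = spec), class = "phage_cohort")
}

#' @export
print.phage_cohort <- function(x, ...) {
  cat("<phage_cohort> ", length(x$genomes), " genomes (",
      x$spec$n_clusters, " clusters, ", x$spec$n_singletons,
      " singletons), seed ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Plant copies of a motif into intergenic spacers
#'
#' Writes `copies` instances of the consensus into distinct intergenic
#' regions that have a downstream plus-strand gene, positioned so that
#' the instance's 3' end lies `upstream_offset` bases before that gene's
#' start codon. Lowercase consensus positions are instantiated as their
#' base, `N` as a random base; each instance then receives a uniform
#' 0..`max_mismatch` count of random departures. Inverted orientation
#' writes the reverse complement. Consumes the session RNG stream (seed
#' it for reproducibility).
#'
#' @param genome A [phage_genome()].
#' @param consensus Case-encoded motif string.
#' @param copies Number of instances to plant.
#' @param max_mismatch Maximum random departures per instance.
#' @param upstream_offset Two-element range of 3'-end-to-start-codon
#'   distances in bp.
#' @param orientation `"direct"` or `"inverted"`.
#' @param exclude Optional tibble of `(start, end)` intervals (e.g. the
#'   truth of earlier plantings); regions overlapping them are not used,
#'   so successive plantings never overwrite each other.
#' @return List with the modified `genome` and a `truth` tibble of
#'   planted coordinates (`phage_id`, `start`, `end`, `strand`,
#'   `consensus`, `mismatches`, `upstream_offset`).
#' @export
plant_motif <- function(genome, consensus, copies, max_mismatch = 0L,
                        upstream_offset = c(20L, 30L),
                        orientation = c("direct", "inverted"),
                        exclude = NULL) {
  orientation <- match.arg(orientation)
  if (copies == 0L)
    return(list(genome = genome,
                truth = tibble(phage_id = character(), start = integer(),
                               end = integer(), strand = character(),
                               consensus = character(),
                               mismatches = integer(),
                               upstream_offset = integer())))
  len <- nchar(consensus)
  off_max <- max(upstream_offset)
  regions <- extract_intergenic(genome)
  regions <- regions[!is.na(regions$downstream_plus) &
                       regions$length >= off_max + len + 1L, , drop = FALSE]
  # usable only where the downstream gene abuts the region's right edge
  gene_starts <- genome$genes$start[match(regions$downstream_plus,
                                          genome$genes$gene_id)]
  regions <- regions[gene_starts == regions$end, , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude) && nrow(regions)) {
    clash <- vapply(seq_len(nrow(regions)), function(i)
      any(pmin(exclude$end, regions$end[i]) >
            pmax(exclude$start, regions$start[i])), logical(1))
    regions <- regions[!clash, , drop = FALSE]
  }
  if (nrow(regions) < copies)
    stop("insufficient intergenic spacer capacity: need ", copies,
         " regions of >= ", off_max + len + 1L, " bp, have ",
         nrow(regions))
  pick <- sort(sample.int(nrow(regions), copies))
  seq <- genome$sequence
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", copies)
  for (i in seq_along(pick)) {
    r <- regions[pick[i], ]
    offset <- sample_range(min(upstream_offset), max(upstream_offset))
    chars <- toupper(strsplit(consensus, "", fixed = TRUE)[[1]])
    chars[chars == "N"] <- sample(bases, sum(chars == "N"), replace = TRUE)
    k <- sample_range(0L, max_mismatch)
    if (k > 0L) {
      at <- sample.int(len, k)
      chars[at] <- vapply(chars[at], function(b)
        sample(setdiff(bases, b), 1L), character(1))
    }
    instance <- paste(chars, collapse = "")
    if (orientation == "inverted") instance <- revcomp(instance)
    end <- r$end - offset
    start <- end - len
    if (start < r$start) stop("internal: instance does not fit region")
    substr(seq, start + 1L, end) <- instance
    rows[[i]] <- tibble(phage_id = genome$phage_id, start = start,
                        end = end,
                        strand = if (orientation == "direct") "+" else "-",
                        consensus = consensus, mismatches = k,
                        upstream_offset = offset)
  }
  genome$sequence <- seq
  list(genome = genome, truth = bind_rows(rows))
}

#' Write a cohort to disk
#'
#' One GenBank flat file per genome, a cohort manifest TSV, truth tables
#' as TSV, and the full truth as JSON. Byte-identical for the same spec
#' and seed.
#'
#' @param cohort A `phage_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phage_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in cohort$genomes)
    write_genbank(g, file.path(dir, paste0(g$phage_id, ".gbk")))
  manifest <- genometrics_table(cohort$genomes) |>
    select(-"regional_gc")
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$truth$genes,
                   file.path(dir, "truth_families.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth$phages,
                   file.path(dir, "truth_clusters.tsv"), progress = FALSE)
  readr::write_tsv(cohort$truth$motifs,
                   file.path(dir, "truth_motifs.tsv"), progress = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
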