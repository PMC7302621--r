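#' Scoring and linkage parameters for pham construction
#'
#' Proteins are compared by Smith–Waterman local alignment (BLOSUM62, gap
#' open 11 / extend 1 by default) and linked into the same phamily when
#' the percent identity over aligned columns and the coverage of the
#' shorter protein both pass their thresholds. All parameters are
#' recorded in the resulting [pham_set][build_phams].
#'
#' @param matrix Substitution matrix name understood by
#'   `Biostrings::pairwiseAlignment()` (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return A `pham_scoring` list.
#' @export
pham_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "pham_scoring")
}

#' @param min_identity Minimum percent identity over aligned columns
#'   (default 32.5).
#' @param min_coverage Minimum aligned fraction of the shorter protein
#'   (default 0.5).
#' @rdname pham_scoring
#' @export
pham_link_rule <- function(min_identity = 32.5, min_coverage = 0.5) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 1)
  structure(list(min_identity = min_identity, min_coverage = min_coverage),
            class = "pham_link_rule")
}

#' Score one protein pair
#'
#' Local (Smith–Waterman) alignment of two amino-acid sequences. Percent
#' identity is computed over aligned columns (gaps included in the
#' denominator); coverage is the number of aligned residue pairs divided
#' by the length of the shorter protein. Symmetric under swapping the two
#' sequences and deterministic for fixed scoring parameters. `X` residues
#' are tolerated and scored by the substitution matrix.
#'
#' @param a,b Protein sequences (character scalars, 20-letter alphabet
#'   plus `X`).
#' @param scoring A [pham_scoring()].
#' @return A one-row tibble: `percent_identity`, `coverage`, `raw_score`.
#' @examples
#' score_protein_pair("MKTAYIAKQR", "MKTAYIAKQR")
#' @export
score_protein_pair <- function(a, b, scoring = pham_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop("protein sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  aligned_pairs <- Biostrings::nmatch(al) + Biostrings::nmismatch(al)
  tibble(
    percent_identity = Biostrings::pid(al, type = "PID1"),
    coverage = aligned_pairs / min(nchar(a), nchar(b)),
    raw_score = Biostrings::score(al))
}

#' Partition cohort proteins into phamilies (phams)
#'
#' Builds a graph over all non-tRNA gene products of the cohort, with an
#' edge between two proteins when the [link rule][pham_link_rule] holds
#' for their local alignment, and takes connected components
#' (single-linkage closure) as phams. Pham ids are assigned
#' deterministically by the lexicographically smallest member `gene_id`,
#' so the partition is invariant to genome and protein input order.
#' Singleton phams ("orphams") — genes with no close relative in the
#' dataset — are retained.
#'
#' @param genomes List of [phage_genome()] objects (or a `phage_cohort`).
#'   Gene ids must be unique across the cohort.
#' @param link_rule A [pham_link_rule()].
#' @param scoring A [pham_scoring()].
#' @return A `pham_set`: list with `membership` (tibble `gene_id`,
#'   `phage_id`, `pham_id`), `representatives` (longest member per pham),
#'   `phage_ids` (all genomes in the build, including gene-less ones),
#'   `link_rule`, `scoring`. Has [tidy()] and [glance()] methods.
#' @export
build_phams <- function(genomes, link_rule = pham_link_rule(),
                        scoring = pham_scoring()) {
  genomes <- as_genome_list(genomes)
  prot <- purrr::map_dfr(genomes, function(g) {
    gg <- g$genes[!g$genes$is_trna, , drop = FALSE]
    tibble(gene_id = gg$gene_id, phage_id = rep(g$phage_id, nrow(gg)),
           translation = gg$translation)
  })
  if (anyDuplicated(prot$gene_id))
    stop("gene ids must be unique across the cohort; prefix them with ",
         "the phage id")
  prot <- arrange(prot, .data$gene_id)  # canonical order
  n <- nrow(prot)
  edges <- pham_edge_list(prot, link_rule, scoring)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = prot$gene_id)
  comp <- igraph::components(g)$membership
  # deterministic pham numbering by smallest member gene id
  split_ids <- split(names(comp), comp)
  ord <- order(vapply(split_ids, min, character(1)))
  membership <- bind_rows(lapply(seq_along(ord), function(r) {
    tibble(gene_id = sort(split_ids[[ord[r]]]),
           pham_id = sprintf("PH%04d", r))
  }))
  membership <- left_join(membership,
                          prot[c("gene_id", "phage_id", "translation")],
                          by = "gene_id")
  reps <- membership |>
    mutate(len = nchar(.data$translation)) |>
    group_by(.data$pham_id) |>
    arrange(dplyr::desc(.data$len), .data$gene_id, .by_group = TRUE) |>
    summarise(representative = dplyr::first(.data$gene_id),
              n_members = n(), .groups = "drop")
  structure(
    list(membership = membership[c("gene_id", "phage_id", "pham_id")],
         representatives = reps,
         phage_ids = names(genomes),
         link_rule = link_rule, scoring = scoring),
    class = "pham_set")
}

# all-vs-all link evaluation, vectorized one-query-vs-many; identical
# sequences short-circuit to a link without alignment
pham_edge_list <- function(prot, link_rule, scoring) {
  n <- nrow(prot)
  from <- character(0); to <- character(0)
  if (n < 2L) return(tibble(from = from, to = to))
  seqs <- Biostrings::AAStringSet(prot$translation)
  lens <- nchar(prot$translation)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    same <- prot$translation[j] == prot$translation[i]
    need <- j[!same]
    hit <- j[same]
    if (length(need)) {
      al <- Biostrings::pairwiseAlignment(
        seqs[need], seqs[[i]], type = "local",
        substitutionMatrix = scoring$matrix,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
      pid <- Biostrings::pid(al, type = "PID1")
      cov <- (Biostrings::nmatch(al) + Biostrings::nmismatch(al)) /
        pmin(lens[need], lens[i])
      hit <- c(hit, need[pid >= link_rule$min_identity &
                           cov >= link_rule$min_coverage])
    }
    if (length(hit)) {
      from <- c(from, rep(prot$gene_id[i], length(hit)))
      to <- c(to, prot$gene_id[hit])
    }
  }
  tibble(from = from, to = to)
}

#' @export
print.pham_set <- function(x, ...) {
  g <- glance(x)
  cat("<pham_set> ", g$n_phams, " phams over ", g$n_genes, " genes from ",
      g$n_genomes, " genomes (", g$n_orphams, " orphams)\n", sep = "")
  cat("  link rule: identity >= ", x$link_rule$min_identity,
      "%, coverage >= ", x$link_rule$min_coverage,
      " (", x$scoring$matrix, ", gap ", x$scoring$gap_open, "/",
      x$scoring$gap_extend, ")\n", sep = "")
  invisible(x)
}

#' @describeIn build_phams Pham membership as a tibble
#'   (`gene_id`, `phage_id`, `pham_id`).
#' @param x A `pham_set`.
#' @param ... Unused.
#' @export
tidy.pham_set <- function(x, ...) x$membership

#' @describeIn build_phams One-row summary: `n_phams`, `n_orphams`,
#'   `n_genes`, `n_genomes`.
#' @export
glance.pham_set <- function(x, ...) {
  sizes <- table(x$membership$pham_id)
  tibble(n_phams = length(sizes), n_orphams = sum(sizes == 1L),
         n_genes = nrow(x$membership), n_genomes = length(x$phage_ids))
}

#' Pham presence/absence matrix
#'
#' @param phams A `pham_set` from [build_phams()].
#' @param genomes Optional list of genomes (or a `phage_cohort`) fixing
#'   row order; every genome must have been part of the pham build.
#'   Defaults to the build's genome set.
#' @return Integer 0/1 matrix, rows = phages, columns = phams; an entry
#'   is 1 iff the genome carries at least one member of the pham
#'   (in-genome paralogs still give 1).
#' @export
presence_matrix <- function(phams, genomes = NULL) {
  stopifnot(inherits(phams, "pham_set"))
  ids <- if (is.null(genomes)) phams$phage_ids
  else names(as_genome_list(genomes))
  missing <- setdiff(ids, phams$phage_ids)
  if (length(missing))
    stop("genomes absent from the pham build: ",
         paste(missing, collapse = ", "))
  pham_ids <- sort(unique(phams$membership$pham_id))
  m <- matrix(0L, nrow = length(ids), ncol = length(pham_ids),
              dimnames = list(ids, pham_ids))
  hit <- distinct(phams$membership, .data$phage_id, .data$pham_id)
  hit <- hit[hit$phage_id %in% ids, , drop = FALSE]
  m[cbind(hit$phage_id, hit$pham_id)] <- 1L
  m
}

# distinct pham set of one phage
pham_set_of <- function(phams, phage_id) {
  unique(phams$membership$pham_id[phams$membership$phage_id == phage_id])
}

#' Write the pham table as TSV
#'
#' @param phams A `pham_set`.
#' @param path Output path; columns `pham_id`, `gene_id`, `phage_id`.
#' @return `path`, invisibly.
#' @export
write_pham_table <- function(phams, path) {
  stopifnot(inherits(phams, "pham_set"))
  tb <- phams$membership[c("pham_id", "gene_id", "phage_id")]
  readr::write_tsv(arrange(tb, .data$pham_id, .data$gene_id), path,
                   progress = FALSE)
  invisible(path)
}
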