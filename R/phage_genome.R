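#' Construct a phage genome object
#'
#' A `phage_genome` bundles one genome sequence with its ordered gene
#' features and record metadata. Gene coordinates are 0-based half-open
#' internally; all human-facing output (GenBank, GFF3) is 1-based
#' inclusive.
#'
#' @param phage_id Character scalar identifying the phage.
#' @param sequence DNA string over `A`,`C`,`G`,`T`,`N` (case-insensitive).
#' @param genes Tibble of gene features with columns `gene_id`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`), `product`,
#'   `translation`, `is_trna`. Rows are sorted by `start` on construction.
#' @param termini_class One of `"circularly_permuted"`, `"cos_ext"`,
#'   `"DTR"`, `"unknown"`. Metadata only; never inferred from sequence.
#' @param termini_repeat_len Optional repeat length in bp (DTR class).
#' @param host,accession Optional record metadata.
#'
#' @return An object of class `phage_genome`.
#' @examples
#' g <- phage_genome("toy", "ATGAAATAAGGGCCC",
#'   genes = gene_table(gene_id = "toy_1", start = 0, end = 9,
#'                      strand = "+", translation = "MK"))
#' glance(g)
#' @export
phage_genome <- function(phage_id, sequence, genes = gene_table(),
                         termini_class = c("unknown", "circularly_permuted",
                                           "cos_ext", "DTR"),
                         termini_repeat_len = NA_integer_,
                         host = NA_character_, accession = NA_character_) {
  termini_class <- match.arg(termini_class)
  stopifnot(is.character(phage_id), length(phage_id) == 1L, nzchar(phage_id))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) stop("sequence length must be >= 1")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence must be over the alphabet {A,C,G,T,N}")
  genes <- validate_gene_table(genes, nchar(sequence))
  structure(
    list(phage_id = phage_id, sequence = sequence, genes = genes,
         termini_class = termini_class,
         termini_repeat_len = as.integer(termini_repeat_len),
         host = host, accession = accession),
    class = "phage_genome")
}

#' Build a gene feature table
#'
#' Convenience constructor for the gene tibble consumed by
#' [phage_genome()]. Coordinates are 0-based half-open.
#'
#' @param gene_id,start,end,strand,product,translation,is_trna Vectors,
#'   recycled to common length.
#' @return A tibble with the canonical gene columns.
#' @export
gene_table <- function(gene_id = character(), start = integer(),
                       end = integer(), strand = character(),
                       product = NA_character_, translation = NA_character_,
                       is_trna = FALSE) {
  tibble(gene_id = as.character(gene_id), start = as.integer(start),
         end = as.integer(end), strand = as.character(strand),
         product = as.character(product),
         translation = as.character(translation),
         is_trna = as.logical(is_trna))
}

validate_gene_table <- function(genes, genome_len) {
  need <- c("gene_id", "start", "end", "strand", "product", "translation",
            "is_trna")
  genes <- as_tibble(genes)
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene table is missing columns: ", paste(miss, collapse = ", "))
  genes <- genes[need]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (nrow(genes)) {
    if (any(genes$start < 0L | genes$start >= genes$end |
            genes$end > genome_len))
      stop("gene intervals must satisfy 0 <= start < end <= genome length")
    if (!all(genes$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    if (anyDuplicated(genes$gene_id))
      stop("duplicated gene_id in gene table")
    genes$translation[is.na(genes$translation)] <- ""
    bad <- !genes$is_trna & !nzchar(genes$translation)
    if (any(bad))
      stop("non-tRNA genes must carry a translation: ",
           paste(genes$gene_id[bad], collapse = ", "))
    if (any(genes$is_trna & nzchar(genes$translation)))
      stop("tRNA genes must not carry a translation")
    genes <- arrange(genes, .data$start, .data$end, .data$gene_id)
  }
  genes
}

#' @export
print.phage_genome <- function(x, ...) {
  cat("<phage_genome> ", x$phage_id, "\n", sep = "")
  cat("  length: ", nchar(x$sequence), " bp; genes: ", nrow(x$genes),
      " (", sum(x$genes$is_trna), " tRNA)\n", sep = "")
  cat("  termini: ", x$termini_class,
      if (!is.na(x$termini_repeat_len))
        paste0(" (", x$termini_repeat_len, " bp repeat)"),
      "; accession: ", x$accession, "\n", sep = "")
  invisible(x)
}

#' @describeIn phage_genome Gene features as a tibble with a `phage_id`
#'   column prepended.
#' @param x A `phage_genome`.
#' @param ... Unused.
#' @export
tidy.phage_genome <- function(x, ...) {
  dplyr::bind_cols(tibble(phage_id = rep(x$phage_id, nrow(x$genes))),
                   x$genes)
}

#' @describeIn phage_genome One-row genometrics summary (see
#'   [compute_genometrics()]).
#' @export
glance.phage_genome <- function(x, ...) compute_genometrics(x)

# normalize "one genome or a list of genomes" arguments
as_genome_list <- function(genomes) {
  if (inherits(genomes, "phage_genome")) genomes <- list(genomes)
  if (inherits(genomes, "phage_cohort")) genomes <- genomes$genomes
  stopifnot(all(vapply(genomes, inherits, TRUE, "phage_genome")))
  ids <- vapply(genomes, function(g) g$phage_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate phage ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(genomes, ids)
}
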