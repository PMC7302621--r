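#' Read an annotated phage genome from a GenBank flat file
#'
#' Parses a single-record GenBank flat file into a [phage_genome()]. Every
#' `CDS` feature becomes a gene with its `/translation` qualifier (or a
#' conceptual translation under genetic code table 11 when the qualifier
#' is absent, with a warning); `tRNA` features are flagged and carry no
#' translation. Coordinates are converted from GenBank's 1-based inclusive
#' convention to the internal 0-based half-open one; `complement(...)` and
#' `join(...)` locations are handled, a joined CDS being treated as a
#' single gene spanning its outermost coordinates.
#'
#' @param path Path to a GenBank flat file containing one record.
#' @return A [phage_genome()].
#' @seealso [read_fasta()], [write_genbank()]
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("not a GenBank flat file (no LOCUS line): ", path)
  name <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i[1]])), "\\s+")[[1]][1]
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc_line))
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  else NA_character_

  origin_i <- grep("^ORIGIN", lines)
  end_i <- grep("^//", lines)
  if (!length(origin_i) || !length(end_i) || end_i[1] <= origin_i[1])
    stop("GenBank record has no sequence (ORIGIN section missing): ", path)
  seq_lines <- lines[(origin_i[1] + 1L):(end_i[1] - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence))
    stop("GenBank record has an empty sequence: ", path)

  feats <- parse_genbank_features(lines, origin_i[1])
  host <- NA_character_
  rows <- list()
  cds_n <- 0L
  for (f in feats) {
    if (f$key == "source") {
      host <- f$qualifiers[["host"]] %||% f$qualifiers[["lab_host"]] %||%
        NA_character_
      next
    }
    if (!f$key %in% c("CDS", "tRNA")) next
    loc <- parse_genbank_location(f$location)
    is_trna <- f$key == "tRNA"
    cds_n <- cds_n + 1L
    gid <- f$qualifiers[["locus_tag"]] %||% f$qualifiers[["gene"]] %||%
      sprintf("%s_%s_%03d", name, f$key, cds_n)
    tr <- ""
    if (!is_trna) {
      tr <- f$qualifiers[["translation"]]
      if (is.null(tr) || !nzchar(tr)) {
        warning("CDS ", gid, " has no /translation; using conceptual ",
                "translation (genetic code table 11)", call. = FALSE)
        nt <- substr(sequence, loc$start + 1L, loc$end)
        if (loc$strand == "-") nt <- revcomp(nt)
        tr <- translate_cds(nt)
      }
      tr <- gsub("\\*$", "", gsub("\\s", "", tr))
    }
    rows[[length(rows) + 1L]] <- gene_table(
      gene_id = gid, start = loc$start, end = loc$end, strand = loc$strand,
      product = f$qualifiers[["product"]] %||% NA_character_,
      translation = if (is_trna) NA_character_ else tr, is_trna = is_trna)
  }
  genes <- if (length(rows)) bind_rows(rows) else gene_table()
  phage_genome(phage_id = name, sequence = sequence, genes = genes,
               host = host, accession = accession)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split the FEATURES section into (key, location, qualifiers) triples;
# feature keys sit at column 6, continuations/qualifiers at column 22
parse_genbank_features <- function(lines, origin_i) {
  fi <- grep("^FEATURES", lines)
  if (!length(fi) || fi[1] + 1L > origin_i - 1L) return(list())
  block <- lines[(fi[1] + 1L):(origin_i - 1L)]
  block <- block[nzchar(trimws(block))]
  starts <- grep("^ {5}\\S", block)
  if (!length(starts)) return(list())
  bounds <- c(starts, length(block) + 1L)
  feats <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    chunk <- block[bounds[i]:(bounds[i + 1L] - 1L)]
    head_parts <- strsplit(trimws(chunk[1]), "\\s+")[[1]]
    key <- head_parts[1]
    rest <- trimws(chunk[-1])
    qual_at <- grep("^/", rest)
    loc_extra <- if (length(qual_at)) rest[seq_len(min(qual_at) - 1L)] else rest
    location <- paste(c(head_parts[-1], loc_extra), collapse = "")
    quals <- list()
    if (length(qual_at)) {
      qlines <- rest[min(qual_at):length(rest)]
      grp <- cumsum(grepl("^/[A-Za-z_]+(=|$)", qlines))
      for (q in split(qlines, grp)) {
        first <- q[1]
        nm <- sub("^/([A-Za-z_]+).*$", "\\1", first)
        if (!grepl("=", first, fixed = TRUE)) { quals[[nm]] <- TRUE; next }
        val <- paste(c(sub("^/[A-Za-z_]+=", "", first), q[-1]), collapse = " ")
        val <- gsub("^\"|\"$", "", val)
        if (nm == "translation") val <- gsub("\\s", "", val)
        quals[[nm]] <- val
      }
    }
    feats[[i]] <- list(key = key, location = location, qualifiers = quals)
  }
  feats
}

parse_genbank_location <- function(loc) {
  strand <- if (grepl("complement", loc, fixed = TRUE)) "-" else "+"
  nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (!length(nums)) stop("unparseable feature location: ", loc)
  list(start = min(nums) - 1L, end = max(nums), strand = strand)
}

#' Write a phage genome as a GenBank flat file
#'
#' Emits a minimal but standard-conforming single-record flat file (LOCUS,
#' FEATURES with `source`/`CDS`/`tRNA`, ORIGIN) that [read_genbank()]
#' round-trips losslessly. Coordinates are written 1-based inclusive, with
#' `complement(...)` for minus-strand genes. Output is byte-deterministic:
#' no timestamps.
#'
#' @param genome A [phage_genome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  stopifnot(inherits(genome, "phage_genome"))
  L <- nchar(genome$sequence)
  out <- c(
    sprintf("LOCUS       %-17s %d bp    DNA     linear   PHG", genome$phage_id, L),
    sprintf("DEFINITION  %s, complete genome.", genome$phage_id),
    sprintf("ACCESSION   %s",
            if (is.na(genome$accession)) genome$phage_id else genome$accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L))
  if (!is.na(genome$host))
    out <- c(out, wrap_qualifier("host", genome$host))
  g <- genome$genes
  for (i in seq_len(nrow(g))) {
    loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
    if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    key <- if (g$is_trna[i]) "tRNA" else "CDS"
    out <- c(out, sprintf("     %-15s %s", key, loc),
             wrap_qualifier("locus_tag", g$gene_id[i]))
    if (!is.na(g$product[i]))
      out <- c(out, wrap_qualifier("product", g$product[i]))
    if (!g$is_trna[i])
      out <- c(out, wrap_qualifier("translation", g$translation[i]))
  }
  out <- c(out, "ORIGIN", format_origin(genome$sequence), "//")
  writeLines(out, path)
  invisible(path)
}

wrap_qualifier <- function(name, value) {
  text <- sprintf("/%s=\"%s\"", name, value)
  pieces <- substring(text, seq(1L, nchar(text), 58L),
                      pmin(seq(58L, nchar(text) + 57L, 58L), nchar(text)))
  paste0(strrep(" ", 21L), pieces)
}

format_origin <- function(sequence) {
  s <- tolower(sequence)
  starts <- seq(1L, nchar(s), 60L)
  vapply(starts, function(p) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    sprintf("%9d %s", p, paste(groups, collapse = " "))
  }, character(1))
}

#' Read a phage genome from FASTA, optionally with a gene table
#'
#' @param path Single-record FASTA file. Multi-record files are rejected;
#'   supply one file per genome.
#' @param gene_table Optional path to a tab-separated table with columns
#'   `gene_id`, `start`, `end` (1-based inclusive, GenBank convention),
#'   `strand`, `translation` and optionally `product`, `is_trna`. Without
#'   it the genome has no gene features and only sequence-level operations
#'   are valid.
#' @param phage_id Optional id; defaults to the FASTA header word.
#' @return A [phage_genome()].
#' @export
read_fasta <- function(path, gene_table = NULL, phage_id = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("multi-record FASTA: supply one file per genome (got ",
         length(ss), " records in ", path, ")")
  id <- phage_id %||% strsplit(names(ss)[1], "\\s+")[[1]][1]
  genes <- phamnet::gene_table()
  if (!is.null(gene_table)) {
    tb <- readr::read_tsv(gene_table, show_col_types = FALSE,
                          progress = FALSE)
    if (!"product" %in% names(tb)) tb$product <- NA_character_
    if (!"is_trna" %in% names(tb)) tb$is_trna <- FALSE
    if (!"translation" %in% names(tb)) tb$translation <- NA_character_
    genes <- gene_table(gene_id = tb$gene_id, start = tb$start - 1L,
                        end = tb$end, strand = tb$strand,
                        product = tb$product, translation = tb$translation,
                        is_trna = tb$is_trna)
  }
  phage_genome(phage_id = id, sequence = as.character(ss[[1]]),
               genes = genes)
}

#' Per-genome genometrics
#'
#' Computes the summary statistics reported per genome in phage cohort
#' tables: length, G+C%, CDS and tRNA counts, and coding density (the
#' fraction of the genome covered by the union of gene intervals). G+C% is
#' `100 * (G + C) / (A + C + G + T)` — ambiguous `N` bases are excluded
#' from numerator and denominator — rounded half away from zero to one
#' decimal. Optional `regions` get their own regional G+C values (clipped
#' to the genome).
#'
#' @param genome A [phage_genome()].
#' @param regions Optional two-column matrix/data frame of 0-based
#'   half-open `(start, end)` regions.
#' @return A one-row tibble: `phage_id`, `length_bp`, `gc_percent`,
#'   `cds_count`, `trna_count`, `coding_density`, and a `regional_gc`
#'   list-column holding a tibble `(start, end, gc_percent)`.
#' @examples
#' g <- phage_genome("toy", "ATGC")
#' compute_genometrics(g)$gc_percent  # 50.0
#' @export
compute_genometrics <- function(genome, regions = NULL) {
  stopifnot(inherits(genome, "phage_genome"))
  L <- nchar(genome$sequence)
  reg <- tibble(start = integer(), end = integer(), gc_percent = double())
  if (!is.null(regions)) {
    regions <- as.data.frame(regions)
    reg <- tibble(
      start = pmax(0L, as.integer(regions[[1]])),
      end = pmin(L, as.integer(regions[[2]])))
    reg$gc_percent <- vapply(seq_len(nrow(reg)), function(i)
      gc_percent_of(substr(genome$sequence, reg$start[i] + 1L, reg$end[i])),
      double(1))
  }
  cover <- 0
  if (nrow(genome$genes)) {
    ir <- IRanges::reduce(IRanges::IRanges(genome$genes$start + 1L,
                                           genome$genes$end))
    cover <- sum(IRanges::width(ir))
  }
  tibble(
    phage_id = genome$phage_id,
    length_bp = L,
    gc_percent = gc_percent_of(genome$sequence),
    cds_count = sum(!genome$genes$is_trna),
    trna_count = sum(genome$genes$is_trna),
    coding_density = cover / L,
    regional_gc = list(reg))
}

gc_percent_of <- function(seq) {
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  denom <- sum(f[c("A", "C", "G", "T")])
  if (denom == 0) stop("GC content undefined: no unambiguous bases")
  round_half_up(100 * sum(f[c("G", "C")]) / denom, 1)
}

#' Genometrics for a set of genomes
#'
#' @param genomes A list of [phage_genome()] objects or a `phage_cohort`.
#' @return A tibble with one row per genome (see [compute_genometrics()]).
#' @export
genometrics_table <- function(genomes) {
  purrr::map_dfr(as_genome_list(genomes), compute_genometrics)
}

#' Write / read a labeled symmetric matrix as TSV
#'
#' Tab-separated with a leading `phage_id` header cell, values to three
#' decimals; the write/read pair round-trips losslessly at that precision.
#' Lines starting with `#` carry provenance comments and are skipped on
#' read.
#'
#' @param m A [pairwise matrix][all_pairs] (`phamnet_matrix`) or a plain
#'   labeled square matrix.
#' @param path File path.
#' @param comments Optional character vector written as `# `-prefixed
#'   header lines.
#' @return `path` invisibly (write); a labeled matrix (read).
#' @export
write_matrix_tsv <- function(m, path, comments = NULL) {
  vals <- if (inherits(m, "phamnet_matrix")) m$values else as.matrix(m)
  labels <- rownames(vals)
  if (is.null(labels) || anyDuplicated(labels))
    stop("matrix labels must be present and unique")
  lines <- c(
    if (length(comments)) paste0("# ", comments),
    paste(c("phage_id", labels), collapse = "\t"),
    vapply(seq_along(labels), function(i)
      paste(c(labels[i], sprintf("%.3f", vals[i, ])), collapse = "\t"),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  labels <- parts[[1]][-1]
  vals <- t(vapply(parts[-1], function(p) as.numeric(p[-1]),
                   double(length(labels))))
  rownames(vals) <- vapply(parts[-1], `[[`, character(1), 1L)
  colnames(vals) <- labels
  vals
}

#' Write a binary pham presence/absence matrix as NEXUS
#'
#' Emits a NEXUS file with TAXA and CHARACTERS blocks over the symbol set
#' `01`, the input to split-network software: each genome (taxon) is coded
#' by the presence or absence of a member of each pham (character).
#'
#' @param presence Binary matrix, rows = phages, columns = phams (as from
#'   [presence_matrix()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nexus_binary <- function(presence, path) {
  m <- as.matrix(presence)
  if (!all(m %in% c(0, 1))) stop("presence matrix must be binary (0/1)")
  taxa <- rownames(m)
  if (is.null(taxa)) stop("presence matrix must have row names")
  lines <- c(
    "#NEXUS", "",
    "BEGIN TAXA;",
    sprintf("    DIMENSIONS NTAX=%d;", nrow(m)),
    "    TAXLABELS",
    paste0("        ", taxa),
    "    ;", "END;", "",
    "BEGIN CHARACTERS;",
    sprintf("    DIMENSIONS NCHAR=%d;", ncol(m)),
    "    FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
    "    MATRIX",
    vapply(seq_len(nrow(m)), function(i)
      sprintf("        %-20s %s", taxa[i], paste(m[i, ], collapse = "")),
      character(1)),
    "    ;", "END;")
  writeLines(lines, path)
  invisible(path)
}
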