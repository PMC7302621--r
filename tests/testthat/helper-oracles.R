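# independent oracles and small fixture builders, deliberately naive and
# kept separate from the package's own code paths

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

random_protein_seq <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

# brute-force sliding Hamming scan (N in consensus is a wildcard; N in
# the sequence mismatches everything else)
brute_hamming_scan <- function(seq, consensus, max_mm) {
  s <- strsplit(toupper(seq), "")[[1]]
  cc <- strsplit(toupper(consensus), "")[[1]]
  L <- length(cc)
  n <- length(s)
  if (n < L) return(data.frame(start = integer(), mismatches = integer()))
  mm <- integer(n - L + 1L)
  for (j in seq_len(L)) {
    if (cc[j] == "N") next
    col <- s[j:(n - L + j)]
    mm <- mm + as.integer(col != cc[j])
  }
  hit <- which(mm <= max_mm)
  data.frame(start = hit - 1L, mismatches = mm[hit])
}

# exact canonical-k-mer Jaccard / Mash distance oracle (pure R)
canonical_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  unique(pmin(kmers, vapply(kmers, rc, character(1), USE.NAMES = FALSE)))
}

exact_mash_distance <- function(a, b, k) {
  ka <- canonical_kmers(a, k)
  kb <- canonical_kmers(b, k)
  j <- length(intersect(ka, kb)) / length(union(ka, kb))
  if (j <= 0) return(1.0)
  min(1, -(1 / k) * log(2 * j / (1 + j)))
}

# affine-gap Smith-Waterman score by plain dynamic programming
sw_score_oracle <- function(a, b, gap_open = 11, gap_extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                      Iy[i, j - 1] - gap_extend)
      M[i, j] <- max(0,
                     max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                         Iy[i - 1, j - 1]) + sub[av[i - 1], bv[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# a pham_set built directly from stated per-phage pham sets, bypassing
# alignment entirely (for formula-level oracles)
fake_pham_set <- function(sets) {
  membership <- dplyr::bind_rows(lapply(names(sets), function(p) {
    tibble::tibble(
      gene_id = paste0(p, "_g", seq_along(sets[[p]])),
      phage_id = p, pham_id = as.character(sets[[p]]))
  }))
  structure(list(membership = membership, representatives = NULL,
                 phage_ids = names(sets),
                 link_rule = phamnet::pham_link_rule(),
                 scoring = phamnet::pham_scoring()),
            class = "pham_set")
}

# labeled symmetric matrix wrapped as the package's matrix type
fake_matrix <- function(values, metric) {
  structure(list(values = values, metric = metric, params = NULL),
            class = "phamnet_matrix")
}

sym_matrix <- function(labels, fill, metric, self) {
  n <- length(labels)
  m <- matrix(fill, n, n, dimnames = list(labels, labels))
  diag(m) <- self
  m
}

# tiny annotated genome: genes given as (start, end, strand) triples
toy_genome <- function(id, seq, genes = NULL) {
  gt <- phamnet::gene_table()
  if (!is.null(genes)) {
    gt <- phamnet::gene_table(
      gene_id = sprintf("%s_g%02d", id, seq_len(nrow(genes))),
      start = genes[[1]], end = genes[[2]], strand = genes[[3]],
      product = "hypothetical protein",
      translation = strrep("M", 5))
  }
  phamnet::phage_genome(id, seq, genes = gt)
}
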