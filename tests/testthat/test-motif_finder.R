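test_that("intergenic extraction is the complement of the gene-interval union", {
  g <- toy_genome("toy", rand_dna(300),
                  data.frame(start = c(9, 149), end = c(120, 270),
                             strand = c("+", "-")))
  reg <- extract_intergenic(g)
  expect_equal(reg$start, c(0L, 120L, 270L))
  expect_equal(reg$end, c(9L, 149L, 300L))
  # fully tiled genome has no intergenic space
  tiled <- toy_genome("tiled", rand_dna(100),
                      data.frame(start = 0, end = 100, strand = "+"))
  expect_equal(nrow(extract_intergenic(tiled)), 0)
  # min_len drops short gaps
  expect_equal(nrow(extract_intergenic(g, min_len = 50)), 0)
  # downstream genes resolved per strand
  expect_equal(reg$downstream_plus[1], "toy_g01")
  expect_equal(reg$downstream_minus[3], "toy_g02")
  expect_true(is.na(reg$downstream_minus[1]))
})

test_that("a gene-less genome is one whole intergenic region", {
  g <- phage_genome("bare", rand_dna(500))
  reg <- extract_intergenic(g)
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$start, reg$end), c(0L, 500L))
})

test_that("scan_motif at zero mismatches equals exact substring search", {
  set.seed(31)
  s <- rand_dna(5000)
  g <- phage_genome("x", s)
  motif <- substr(s, 2001, 2013)
  hits <- scan_motif(g, motif, 0, search_space = "whole", strands = "fwd")
  exact <- as.integer(gregexpr(motif, s, fixed = TRUE)[[1]]) - 1L
  # gregexpr misses overlapping repeats; check containment both ways on
  # the brute-force oracle instead
  oracle <- brute_hamming_scan(s, motif, 0)
  expect_equal(hits$start, oracle$start)
  expect_true(all(exact %in% hits$start))
  expect_true(all(hits$mismatches == 0))
})

test_that("scan_motif equals the brute-force Hamming oracle, both strands", {
  set.seed(32)
  for (i in 1:3) {
    s <- rand_dna(5000)
    g <- phage_genome("x", s)
    consensus <- rand_dna(18)
    mm <- i - 1
    hits <- scan_motif(g, consensus, mm, search_space = "whole")
    fwd <- brute_hamming_scan(s, consensus, mm)
    rev <- brute_hamming_scan(s, rc(consensus), mm)
    expect_equal(hits$start[hits$strand == "+"], fwd$start)
    expect_equal(hits$mismatches[hits$strand == "+"], fwd$mismatches)
    expect_equal(hits$start[hits$strand == "-"], rev$start)
  }
})

test_that("N in a consensus is a wildcard and bad characters are rejected", {
  g <- phage_genome("x", "TTTTGATCAACCGGTTTT")
  hits <- scan_motif(g, "GATCNNCC", 0, search_space = "whole",
                     strands = "fwd")
  expect_equal(hits$start, 4L)
  expect_error(scan_motif(g, "GATC!ACC", 0), "IUPAC")
  expect_error(scan_motif(g, "GAT", 0), ">= 4")
})

test_that("planted 13-bp SAS-like motifs are recovered at exactly the planted count", {
  set.seed(33)
  motif <- "GGGAAAGGACCCC"
  s <- rand_dna(5000)
  starts <- seq(200, 4700, length.out = 10)
  chars <- strsplit(s, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in starts) {
    inst <- strsplit(motif, "")[[1]]
    k <- sample(0:1, 1)
    if (k) {
      at <- sample(13, 1)
      inst[at] <- sample(setdiff(bases, inst[at]), 1)
    }
    chars[p:(p + 12)] <- inst
  }
  g <- phage_genome("x", paste(chars, collapse = ""))
  hits <- scan_motif(g, motif, 1, search_space = "whole", strands = "fwd")
  expect_equal(nrow(hits), 10)
  expect_equal(hits$start, as.integer(starts) - 1L)
})

test_that("reverse-complementing the genome mirrors hits across strands", {
  set.seed(34)
  s <- rand_dna(2000)
  consensus <- rand_dna(12)
  g <- phage_genome("x", s)
  grc <- phage_genome("xrc", rc(s))
  h <- scan_motif(g, consensus, 2, search_space = "whole")
  hrc <- scan_motif(grc, consensus, 2, search_space = "whole")
  L <- nchar(s)
  mapped <- sort(L - h$end[h$strand == "+"])
  expect_equal(sort(hrc$start[hrc$strand == "-"]), mapped)
  expect_equal(nrow(h), nrow(hrc))
})

test_that("intergenic search space restricts hits to intergenic windows", {
  set.seed(35)
  # motif sits inside the gene body: whole finds it, intergenic does not
  s <- paste0(rand_dna(50), "GGGAAAGGACCCC", rand_dna(50))
  g <- phage_genome("x", s, genes = gene_table(
    gene_id = "g1", start = 40, end = 80, strand = "+", translation = "M"))
  expect_equal(nrow(scan_motif(g, "GGGAAAGGACCCC", 0,
                               search_space = "whole")), 1)
  expect_equal(nrow(scan_motif(g, "GGGAAAGGACCCC", 0,
                               search_space = "intergenic")), 0)
})

test_that("direct-repeat discovery recovers a planted 12-copy motif as one model", {
  spec <- cohort_spec(
    n_clusters = 1, cluster_sizes = 1, n_singletons = 0,
    genes_per_genome = c(14, 16), minus_strand_frac = 0,
    intergenic_len = c(60, 140),
    planted_motifs = list(list(consensus = "TAGACTCTAGGTGTAAGC",
                               copies = 12, max_mismatch = 2)),
    seed = 11)
  co <- generate_cohort(spec)
  g <- co$genomes[[1]]
  mods <- discover_direct_repeats(g, length = 18, min_copies = 3,
                                  max_mismatch = 2)
  expect_equal(nrow(mods), 1)
  expect_equal(mods$n_occurrences, 12)
  expect_equal(toupper(mods$consensus), "TAGACTCTAGGTGTAAGC")
  expect_setequal(mods$occurrences[[1]]$start, co$truth$motifs$start)
})

test_that("rescanning a discovered consensus recovers at least its occurrences", {
  spec <- cohort_spec(
    n_clusters = 1, cluster_sizes = 1, n_singletons = 0,
    genes_per_genome = c(14, 16), minus_strand_frac = 0,
    intergenic_len = c(60, 140),
    planted_motifs = list(list(consensus = "TAGACTCTAGGTGTAAGC",
                               copies = 10, max_mismatch = 2)),
    seed = 21)
  g <- generate_cohort(spec)$genomes[[1]]
  mods <- discover_direct_repeats(g, length = 18, min_copies = 3,
                                  max_mismatch = 2)
  for (i in seq_len(nrow(mods))) {
    hits <- scan_motif(g, mods$consensus[i], mods$max_mismatch[i],
                       search_space = "intergenic", strands = "fwd")
    expect_true(all(mods$occurrences[[i]]$start %in% hits$start))
  }
})

test_that("two distinct planted motifs give two uncontaminated models", {
  spec <- cohort_spec(
    n_clusters = 1, cluster_sizes = 1, n_singletons = 0,
    genes_per_genome = c(20, 24), minus_strand_frac = 0,
    intergenic_len = c(80, 160),
    planted_motifs = list(
      list(consensus = "TAGACTCTAGGTGTAAGC", copies = 6, max_mismatch = 1),
      list(consensus = "CCGTTACGGAATCCGGTA", copies = 6, max_mismatch = 1)),
    seed = 31)
  co <- generate_cohort(spec)
  g <- co$genomes[[1]]
  mods <- discover_direct_repeats(g, length = 18, min_copies = 3,
                                  max_mismatch = 2)
  expect_equal(nrow(mods), 2)
  # planted departures can erode single columns below the lowercase
  # threshold, so compare case-folded consensi with N as a wildcard
  matches_planted <- function(consensus, planted) {
    a <- strsplit(toupper(consensus), "")[[1]]
    b <- strsplit(planted, "")[[1]]
    length(a) == length(b) && all(a == b | a == "N")
  }
  truth <- co$truth$motifs
  for (planted_consensus in unique(truth$consensus)) {
    i <- which(vapply(mods$consensus, matches_planted, logical(1),
                      planted = planted_consensus))
    expect_length(i, 1)
    expect_setequal(mods$occurrences[[i]]$start,
                    truth$start[truth$consensus == planted_consensus])
  }
})

test_that("discovery reports nothing on unplanted random sequence", {
  set.seed(36)
  for (i in 1:3) {
    g <- phage_genome(paste0("neg", i), rand_dna(5000))
    mods <- discover_direct_repeats(g, length = 18, min_copies = 5,
                                    max_mismatch = 1,
                                    search_space = "whole")
    expect_equal(nrow(mods), 0)
  }
})

test_that("inverted repeats are detected by arm complementarity", {
  g1 <- phage_genome("ir", paste0(strrep("T", 20), "GATCAACCAGGGTTGATC",
                                  strrep("A", 20)))
  h1 <- find_inverted_repeats(g1, search_space = "whole")
  expect_equal(h1$start, 20L)
  expect_equal(h1$mismatches, 0L)
  g2 <- phage_genome("ir2", paste0("CGCG", strrep("A", 8), "TT",
                                   strrep("T", 8), "CGCG"))
  h2 <- find_inverted_repeats(g2, search_space = "whole")
  expect_true(4L %in% h2$start)
})

test_that("inverted-repeat scan equals a brute-force oracle on random sequence", {
  set.seed(37)
  s <- rand_dna(10000)
  g <- phage_genome("x", s)
  arm <- 6L; spacer <- 2L; mm <- 1L
  h <- find_inverted_repeats(g, arm = arm, spacer = spacer,
                             max_mismatch = mm, search_space = "whole")
  w <- 2L * arm + spacer
  chars <- strsplit(s, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  oracle <- integer(0)
  for (p in 1:(10000 - w + 1)) {
    left <- chars[p:(p + arm - 1)]
    right <- chars[(p + w - 1):(p + arm + spacer)]
    if (sum(left != comp[right]) <= mm) oracle <- c(oracle, p - 1L)
  }
  expect_equal(h$start, oracle)
})

test_that("consensus case-encoding follows the conservation thresholds", {
  expect_equal(build_consensus(rep("ACGT", 4)), "ACGT")
  # column with 9/12 'A' -> lowercase at partial_frac 0.75
  occ <- c(rep("A", 9), rep("C", 3))
  expect_equal(build_consensus(paste0(occ, "G")), "aG")
  # 6/12 -> below 0.75 -> N
  occ2 <- c(rep("G", 6), rep("A", 3), rep("C", 3))
  expect_equal(build_consensus(paste0(occ2, "T")), "NT")
  # tie broken alphabetically
  expect_equal(build_consensus(c("A", "A", "C", "C"), partial_frac = 0.5),
               "a")
  expect_error(build_consensus(c("AC", "ACG")), "equal lengths")
})

test_that("upstream distance counts exclusive bases to the next start codon", {
  # forward: motif half-open end 100, gene start 121 -> 21
  g <- phage_genome("x", rand_dna(400), genes = gene_table(
    gene_id = c("fwd", "rev"), start = c(121, 20), end = c(200, 50),
    strand = c("+", "-"), translation = "M"))
  hits <- tibble::tibble(phage_id = "x", start = 87L, end = 100L,
                         strand = "+", mismatches = 0L)
  ann <- annotate_upstream_distance(hits, g)
  expect_equal(ann$upstream_distance, 21L)
  expect_equal(ann$upstream_gene, "fwd")
  # reverse: motif start 60, minus gene end 50 -> 10 on the bottom strand
  hits_rev <- tibble::tibble(phage_id = "x", start = 60L, end = 73L,
                             strand = "-", mismatches = 0L)
  ann_rev <- annotate_upstream_distance(hits_rev, g)
  expect_equal(ann_rev$upstream_distance, 10L)
  expect_equal(ann_rev$upstream_gene, "rev")
  # beyond the window: no annotation
  far <- tibble::tibble(phage_id = "x", start = 300L, end = 313L,
                        strand = "-", mismatches = 0L)
  expect_true(is.na(annotate_upstream_distance(far, g,
                                               window = 100)$upstream_distance))
})

test_that("planted upstream offsets are reproduced by the annotator", {
  spec <- cohort_spec(
    n_clusters = 1, cluster_sizes = 1, n_singletons = 0,
    genes_per_genome = c(14, 16), minus_strand_frac = 0,
    intergenic_len = c(60, 140),
    planted_motifs = list(list(consensus = "GGGAAAGGACCCC", copies = 8,
                               max_mismatch = 1,
                               upstream_offset = c(21, 30))),
    seed = 41)
  co <- generate_cohort(spec)
  g <- co$genomes[[1]]
  hits <- scan_motif(g, "GGGAAAGGACCCC", 1, search_space = "intergenic",
                     strands = "fwd")
  ann <- annotate_upstream_distance(hits, g)
  truth <- co$truth$motifs
  m <- merge(ann, truth, by = "start")
  expect_equal(nrow(m), 8)
  expect_equal(m$upstream_distance, m$upstream_offset)
  expect_true(all(m$upstream_distance >= 21 & m$upstream_distance <= 30))
})

test_that("GFF3 output is valid and 1-based", {
  hits <- tibble::tibble(phage_id = "x", start = 10L, end = 28L,
                         strand = "+", mismatches = 1L,
                         upstream_distance = 25L, model_id = "DR01")
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(hits, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], "##gff-version 3")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(fields[4], "11")
  expect_equal(fields[5], "28")
  expect_match(fields[9], "mismatches=1")
  expect_match(fields[9], "upstream_distance=25")
  expect_match(fields[9], "model_id=DR01")
})
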