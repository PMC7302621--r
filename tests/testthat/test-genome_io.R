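genbank_fixture <- function(path) {
  # 300-bp record, one forward CDS 10..120, one complement CDS 150..270,
  # one tRNA 280..295; translations are stated in the record
  seq <- strrep("ACGTTGCAAC", 30)
  fwd_nt <- substr(seq, 10, 120)
  lines <- c(
    "LOCUS       TESTPHAGE         300 bp    DNA     linear   PHG",
    "DEFINITION  Test phage, complete genome.",
    "ACCESSION   TP000001",
    "FEATURES             Location/Qualifiers",
    "     source          1..300",
    "                     /host=\"Microbacterium foliorum\"",
    "     CDS             10..120",
    "                     /locus_tag=\"TP_01\"",
    "                     /product=\"terminase\"",
    "                     /translation=\"MKLVVNNNAAAPPPQQQRRRSSSTTTVVVWWWYYYMK\"",
    "     CDS             complement(150..270)",
    "                     /locus_tag=\"TP_02\"",
    "                     /product=\"portal protein\"",
    "                     /translation=\"MAAAPPPQQQRRRSSSTTTVVVWWWYYYKLMNPQRSTVWX\"",
    "     tRNA            280..295",
    "                     /product=\"tRNA-Ala\"",
    "ORIGIN")
  starts <- seq(1, 300, 60)
  ori <- vapply(starts, function(p) {
    chunk <- tolower(substr(seq, p, min(p + 59, 300)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", p, paste(groups, collapse = " "))
  }, character(1))
  writeLines(c(lines, ori, "//"), path)
  path
}

test_that("GenBank CDS coordinates convert from 1-based inclusive to 0-based half-open", {
  tf <- withr::local_tempfile(fileext = ".gbk")
  genbank_fixture(tf)
  g <- read_genbank(tf)
  expect_s3_class(g, "phage_genome")
  expect_equal(nchar(g$sequence), 300)
  expect_equal(g$accession, "TP000001")
  expect_equal(g$host, "Microbacterium foliorum")
  expect_equal(nrow(g$genes), 3)
  cds <- g$genes[!g$genes$is_trna, ]
  expect_equal(cds$start, c(9L, 149L))
  expect_equal(cds$end, c(120L, 270L))
  expect_equal(cds$strand, c("+", "-"))
  expect_equal(sum(g$genes$is_trna), 1)
  expect_equal(cds$product, c("terminase", "portal protein"))
})

test_that("GenBank records without sequence are rejected; empty feature tables are fine", {
  tf <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       X  10 bp", "FEATURES", "//"), tf)
  expect_error(read_genbank(tf), "sequence")

  tf2 <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       EMPTY  12 bp    DNA",
               "ORIGIN", "        1 acgtacgtacgt", "//"), tf2)
  g <- read_genbank(tf2)
  expect_equal(nrow(g$genes), 0)
  expect_equal(g$sequence, "ACGTACGTACGT")
})

test_that("CDS without /translation falls back to conceptual translation with a warning", {
  tf <- withr::local_tempfile(fileext = ".gbk")
  # ATG AAA TGC TAA -> MKC
  writeLines(c("LOCUS       CONC  18 bp    DNA",
               "FEATURES             Location/Qualifiers",
               "     CDS             4..15",
               "                     /locus_tag=\"c1\"",
               "ORIGIN",
               "        1 cccatgaaat gctaaccc", "//"), tf)
  expect_warning(g <- read_genbank(tf), "conceptual")
  expect_equal(g$genes$translation, "MKC")
})

test_that("write_genbank/read_genbank round-trips features, strands and translations", {
  co <- fixture_cohort()
  g1 <- co$genomes[[1]]
  tf <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g1, tf)
  g2 <- read_genbank(tf)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(
    g1$genes[c("gene_id", "start", "end", "strand", "translation",
               "is_trna")],
    g2$genes[c("gene_id", "start", "end", "strand", "translation",
               "is_trna")])
})

test_that("genometrics: GC is computed over unambiguous bases and rounded half away from zero", {
  expect_equal(compute_genometrics(phage_genome("x", "GGCC"))$gc_percent, 100)
  expect_equal(compute_genometrics(phage_genome("x", "ATGC"))$gc_percent, 50)
  # N excluded from numerator and denominator
  expect_equal(compute_genometrics(phage_genome("x", "GGCCNNNN"))$gc_percent,
               100)
  # 205 GC / 400 unambiguous = 51.25% -> 51.3 half away from zero
  seqv <- paste0(strrep("G", 205), strrep("A", 195))
  expect_equal(compute_genometrics(phage_genome("x", seqv))$gc_percent, 51.3)
  expect_error(compute_genometrics(phage_genome("x", "NNNN")), "undefined")
})

test_that("genometrics counts CDS vs tRNA and measures coding density as interval union", {
  g <- phage_genome("x", strrep("A", 100), genes = gene_table(
    gene_id = c("a", "b", "t"), start = c(0, 30, 80), end = c(40, 60, 90),
    strand = "+", translation = c("MK", "MK", NA), is_trna = c(FALSE, FALSE, TRUE)))
  m <- compute_genometrics(g)
  expect_equal(m$cds_count, 2)
  expect_equal(m$trna_count, 1)
  # union of [0,40) [30,60) [80,90) = 70 bp
  expect_equal(m$coding_density, 0.7)
})

test_that("genometrics of a concatenation is the base-count-weighted mean", {
  set.seed(42)
  for (i in 1:5) {
    a <- rand_dna(sample(200:500, 1))
    b <- rand_dna(sample(200:500, 1))
    ma <- compute_genometrics(phage_genome("a", a))
    mb <- compute_genometrics(phage_genome("b", b))
    mab <- compute_genometrics(phage_genome("ab", paste0(a, b)))
    expect_equal(mab$length_bp, ma$length_bp + mb$length_bp)
    expected_gc <- (ma$gc_percent * ma$length_bp +
                      mb$gc_percent * mb$length_bp) / mab$length_bp
    expect_equal(mab$gc_percent, expected_gc, tolerance = 0.1)
  }
})

test_that("regional GC is computed per requested region, clipped to the genome", {
  g <- phage_genome("x", paste0(strrep("G", 50), strrep("A", 50)))
  m <- compute_genometrics(g, regions = rbind(c(0, 50), c(50, 100),
                                              c(90, 200)))
  reg <- m$regional_gc[[1]]
  expect_equal(reg$gc_percent, c(100, 0, 0))
  expect_equal(reg$end[3], 100)
})

test_that("matrix TSV round-trips losslessly at 3 decimals with n+1 lines", {
  labels <- sprintf("P%02d", 1:6)
  m <- sym_matrix(labels, 0, "gcs", 100)
  m[upper.tri(m)] <- round(runif(15) * 100, 3)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, tf, comments = "metric=gcs")
  lines <- readLines(tf)
  expect_equal(length(lines), 6 + 1 + 1)  # comment + header + n rows
  back <- read_matrix_tsv(tf)
  expect_identical(rownames(back), labels)
  expect_equal(back, m)
  dimnames(m) <- list(rep("dup", 6), rep("dup", 6))
  expect_error(write_matrix_tsv(m, tf), "unique")
})

test_that("NEXUS export writes a standard binary characters block", {
  pres <- matrix(c(1, 0, 1, 0, 1, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("phageA", "phageB"), NULL))
  tf <- withr::local_tempfile(fileext = ".nex")
  write_nexus_binary(pres, tf)
  txt <- readLines(tf)
  expect_equal(txt[1], "#NEXUS")
  expect_true(any(grepl("NTAX=2", txt)))
  expect_true(any(grepl("NCHAR=3", txt)))
  parsed <- ape::read.nexus.data(tf)
  expect_equal(names(parsed), c("phageA", "phageB"))
  expect_equal(paste(parsed$phageA, collapse = ""), "101")
  expect_error(write_nexus_binary(matrix(2, 1, 1,
                                         dimnames = list("a", NULL)), tf),
               "binary")
})

test_that("NEXUS nchar matches the pham count of a synthetic cohort", {
  pres <- presence_matrix(fixture_phams())
  tf <- withr::local_tempfile(fileext = ".nex")
  write_nexus_binary(pres, tf)
  n_phams <- glance(fixture_phams())$n_phams
  expect_true(any(grepl(sprintf("NCHAR=%d", n_phams), readLines(tf))))
})

test_that("FASTA reader handles bare sequences, gene tables, and rejects bad input", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">toy some description", rand_dna(1000)), tf)
  g <- read_fasta(tf)
  expect_equal(g$phage_id, "toy")
  expect_equal(nrow(g$genes), 0)
  expect_equal(nchar(g$sequence), 1000)

  gt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tstart\tend\tstrand\ttranslation",
               "g1\t11\t100\t+\tMAAA", "g2\t151\t220\t-\tMCCC",
               "g3\t301\t400\t+\tMGGG"), gt)
  g2 <- read_fasta(tf, gene_table = gt)
  expect_equal(nrow(g2$genes), 3)
  expect_equal(g2$genes$start, c(10L, 150L, 300L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tstart\tend\tstrand\ttranslation",
               "g1\t1\t2000\t+\tM"), bad)
  expect_error(read_fasta(tf, gene_table = bad), "genome length")

  multi <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), multi)
  expect_error(read_fasta(multi), "one file per genome")
})

test_that("gene table invariants are enforced", {
  expect_error(phage_genome("x", "ACGT", genes = gene_table(
    gene_id = "g", start = 2, end = 2, strand = "+", translation = "M")),
    "start < end")
  expect_error(phage_genome("x", "ACGT", genes = gene_table(
    gene_id = "g", start = 0, end = 3, strand = "+",
    translation = NA_character_)), "translation")
  expect_error(phage_genome("x", "ACGT", genes = gene_table(
    gene_id = "g", start = 0, end = 3, strand = "+", translation = "M",
    is_trna = TRUE)), "tRNA")
})
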