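# shared internal helpers

# round half away from zero (tables print 51.4-style values; R's round()
# would go half-to-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A",
              R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
              B = "V", D = "H", H = "D", V = "B", N = "N", X = "X")

# reverse complement preserving IUPAC degeneracy and case
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  up <- toupper(chars)
  comp <- unname(DNA_COMP[up])
  comp[is.na(comp)] <- "N"
  low <- chars != up
  comp[low] <- tolower(comp[low])
  paste(rev(comp), collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# uniform integer draws from [lo, hi]; immune to sample()'s scalar
# expansion when lo == hi
sample_range <- function(lo, hi, n = 1L) {
  v <- seq.int(lo, hi)
  v[sample.int(length(v), n, replace = TRUE)]
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# translate a CDS (bacterial/plastid code, table 11); trailing stop dropped,
# internal stops and unresolvable codons reported as X
translate_cds <- function(nt) {
  nt <- toupper(nt)
  n <- (nchar(nt) %/% 3L) * 3L
  if (n < 3L) return("")
  code <- Biostrings::getGeneticCode("11")
  codons <- substring(nt, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  aa[aa == "*"] <- "X"
  paste(aa, collapse = "")
}
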