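#' Gene-content similarity and dissimilarity
#'
#' Gene-content similarity (GCS) between two phages is the number of
#' phams present in both, divided by the number of distinct phams in each
#' phage, the two fractions averaged and expressed as a percent:
#' `GCS = 100 * ((|A n B| / |A|) + (|A n B| / |B|)) / 2`. Gene-content
#' dissimilarity is its complement on the unit scale,
#' `GCD = 1 - GCS / 100`.
#'
#' @param a,b Phage ids present in the pham build.
#' @param phams A `pham_set` from [build_phams()].
#' @return A percent in `[0, 100]` (GCS) or fraction in `[0, 1]` (GCD).
#' @examples
#' \dontrun{
#' gene_content_similarity("TeddyBear", "Golden", phams)
#' }
#' @export
gene_content_similarity <- function(a, b, phams) {
  pa <- pham_set_of(phams, a)
  pb <- pham_set_of(phams, b)
  gcs_from_sets(pa, pb, a, b)
}

gcs_from_sets <- function(pa, pb, a = "a", b = "b") {
  if (!length(pa)) stop("GCS undefined: phage ", a, " has no genes")
  if (!length(pb)) stop("GCS undefined: phage ", b, " has no genes")
  shared <- length(intersect(pa, pb))
  100 * (shared / length(pa) + shared / length(pb)) / 2
}

#' @rdname gene_content_similarity
#' @export
gene_content_dissimilarity <- function(a, b, phams) {
  1 - gene_content_similarity(a, b, phams) / 100
}

#' Parameters for fragment-based ANI
#'
#' Average nucleotide identity is computed by the classic reciprocal
#' fragment method: the query is chopped into non-overlapping fragments
#' (default 1,020 bp; a trailing fragment is kept if at least 100 bp),
#' each fragment is locally aligned to the subject genome (both strands,
#' best kept), fragments passing the identity and coverage filters are
#' retained, and ANI in that direction is the mean identity of retained
#' fragments. The reported value is the symmetrized mean of the two
#' directions.
#'
#' @param fragment_length,step Fragment size and tiling step in bp.
#' @param min_identity Fragment identity filter (fraction, default 0.3).
#' @param min_coverage Fragment coverage filter (fraction of the fragment
#'   aligned, default 0.7).
#' @return An `ani_params` list.
#' @export
ani_params <- function(fragment_length = 1020L, step = 1020L,
                       min_identity = 0.3, min_coverage = 0.7) {
  stopifnot(fragment_length >= 100, step >= 1,
            min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  structure(list(fragment_length = as.integer(fragment_length),
                 step = as.integer(step), min_identity = min_identity,
                 min_coverage = min_coverage), class = "ani_params")
}

#' Average nucleotide identity of two genomes
#'
#' @param a,b [phage_genome()] objects.
#' @param params An [ani_params()].
#' @return Percent identity in `[0, 100]`; 0 when no fragment passes the
#'   filters in either direction.
#' @export
ani <- function(a, b, params = ani_params()) {
  stopifnot(inherits(a, "phage_genome"), inherits(b, "phage_genome"))
  (ani_directed(a$sequence, b$sequence, params) +
     ani_directed(b$sequence, a$sequence, params)) / 2
}

ani_directed <- function(qseq, sseq, params) {
  if (!nchar(qseq) || !nchar(sseq)) stop("empty sequence")
  L <- nchar(qseq)
  starts <- seq(1L, L, by = params$step)
  ends <- pmin(starts + params$fragment_length - 1L, L)
  keep <- (ends - starts + 1L) >= min(100L, L)
  starts <- starts[keep]; ends <- ends[keep]
  frags <- Biostrings::DNAStringSet(substring(qseq, starts, ends))
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = FALSE, type = "DNA")
  subj <- Biostrings::DNAString(sseq)
  subj_rc <- Biostrings::reverseComplement(subj)
  best <- lapply(list(subj, subj_rc), function(s) {
    al <- Biostrings::pairwiseAlignment(
      frags, s, type = "local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    list(score = Biostrings::score(al),
         identity = Biostrings::pid(al, type = "PID1") / 100,
         aligned = Biostrings::nmatch(al) + Biostrings::nmismatch(al))
  })
  use_rc <- best[[2]]$score > best[[1]]$score
  identity <- ifelse(use_rc, best[[2]]$identity, best[[1]]$identity)
  aligned <- ifelse(use_rc, best[[2]]$aligned, best[[1]]$aligned)
  coverage <- aligned / (ends - starts + 1L)
  ok <- identity >= params$min_identity & coverage >= params$min_coverage
  if (!any(ok)) return(0)
  100 * mean(identity[ok])
}

#' Parameters for MinHash nucleotide distance
#'
#' @param k K-mer size (default 21; canonical k-mers).
#' @param sketch_size Bottom-sketch size (default 1000). `0` keeps every
#'   distinct k-mer hash, giving the exact Jaccard index.
#' @param seed Hash seed; fixed so sketches are deterministic.
#' @return A `sketch_params` list.
#' @export
sketch_params <- function(k = 21L, sketch_size = 1000L, seed = 42L) {
  stopifnot(k >= 1, k <= 32, sketch_size >= 0)
  structure(list(k = as.integer(k), sketch_size = as.integer(sketch_size),
                 seed = as.integer(seed)), class = "sketch_params")
}

genome_sketch <- function(seq, params) {
  if (nchar(seq) < params$k)
    stop("sequence shorter than k = ", params$k)
  .kmer_sketch_cpp(seq, params$k, params$sketch_size, params$seed)
}

# Mash-style distance from two bottom sketches (sorted distinct hashes)
sketch_distance <- function(sa, sb, params) {
  if (params$sketch_size == 0L) {
    j <- length(intersect(sa, sb)) / length(union(sa, sb))
  } else {
    merged <- sort(unique(c(sa, sb)))
    x <- head(merged, params$sketch_size)
    j <- sum(x %in% sa & x %in% sb) / length(x)
  }
  if (j <= 0) return(1.0)
  min(1.0, -(1 / params$k) * log(2 * j / (1 + j)))
}

#' MinHash nucleotide distance between two genomes
#'
#' Bottom-sketch MinHash estimate of the Jaccard index `j` over canonical
#' k-mers, transformed to an evolutionary distance
#' `d = -(1/k) * log(2j / (1 + j))` (the Mash distance); `j = 0` maps to
#' the cap `d = 1`. Deterministic for a fixed hash seed.
#'
#' @param a,b [phage_genome()] objects (sequences must be at least `k`
#'   long).
#' @param params A [sketch_params()].
#' @return A distance fraction in `[0, 1]`.
#' @export
nucleotide_distance <- function(a, b, params = sketch_params()) {
  stopifnot(inherits(a, "phage_genome"), inherits(b, "phage_genome"))
  sketch_distance(genome_sketch(a$sequence, params),
                  genome_sketch(b$sequence, params), params)
}

metric_self_value <- function(metric) {
  switch(metric, gcs = 100, gcd = 0, ani = 100, nd = 0,
         stop("unknown metric: ", metric))
}

#' All-vs-all pairwise genome comparison matrix
#'
#' Computes the upper triangle of the chosen metric for every genome pair,
#' mirrors it, and sets the diagonal to the metric's analytic self-value
#' (GCS 100, GCD 0, ANI 100, nucleotide distance 0); self-comparisons are
#' never computed. Label order follows input order.
#'
#' @param genomes List of [phage_genome()] objects or a `phage_cohort`
#'   (at least 2 genomes, unique ids).
#' @param metric One of `"gcs"`, `"gcd"`, `"ani"`, `"nd"`.
#' @param phams A `pham_set`; required for `"gcs"`/`"gcd"`.
#' @param params [ani_params()] or [sketch_params()] for the sequence
#'   metrics.
#' @return A `phamnet_matrix`: list with `values` (labeled symmetric
#'   matrix), `metric`, `params`. Has [tidy()] and [autoplot()] methods.
#' @export
all_pairs <- function(genomes, metric = c("gcs", "gcd", "ani", "nd"),
                      phams = NULL, params = NULL) {
  metric <- match.arg(metric)
  genomes <- as_genome_list(genomes)
  ids <- names(genomes)
  n <- length(ids)
  if (n < 2L) stop("all_pairs requires at least 2 genomes")
  vals <- matrix(metric_self_value(metric), n, n,
                 dimnames = list(ids, ids))
  if (metric %in% c("gcs", "gcd")) {
    if (is.null(phams)) stop("metric '", metric, "' requires a pham_set")
    sets <- lapply(ids, pham_set_of, phams = phams)
    pairfun <- function(i, j) {
      g <- gcs_from_sets(sets[[i]], sets[[j]], ids[i], ids[j])
      if (metric == "gcs") g else 1 - g / 100
    }
  } else if (metric == "ani") {
    if (is.null(params)) params <- ani_params()
    pairfun <- function(i, j) ani(genomes[[i]], genomes[[j]], params)
  } else {
    if (is.null(params)) params <- sketch_params()
    sketches <- lapply(genomes, function(g) genome_sketch(g$sequence, params))
    pairfun <- function(i, j) sketch_distance(sketches[[i]], sketches[[j]],
                                              params)
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- pairfun(i, j)
      vals[i, j] <- v
      vals[j, i] <- v
    }
  }
  structure(list(values = vals, metric = metric, params = params),
            class = "phamnet_matrix")
}

#' @export
print.phamnet_matrix <- function(x, ...) {
  cat("<phamnet_matrix> metric: ", x$metric, "; ",
      nrow(x$values), " x ", ncol(x$values), " phages\n", sep = "")
  print(utils::head(round(x$values, 3), 6))
  invisible(x)
}

#' @export
as.matrix.phamnet_matrix <- function(x, ...) x$values

#' @describeIn all_pairs Long-form upper triangle as a tibble
#'   (`phage_a`, `phage_b`, `value`).
#' @param x A `phamnet_matrix`.
#' @param ... Unused.
#' @export
tidy.phamnet_matrix <- function(x, ...) {
  ids <- rownames(x$values)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(phage_a = ids[idx[, 1]], phage_b = ids[idx[, 2]],
         value = x$values[idx]) |>
    rename(!!x$metric := "value") |>
    arrange(.data$phage_a, .data$phage_b)
}

#' Long-form gene-content dissimilarity vs nucleotide distance table
#'
#' Joins a GCD and a nucleotide-distance matrix into the per-pair table
#' behind genomic similarity plots and network construction.
#'
#' @param gcd,nd `phamnet_matrix` objects sharing labels, with metrics
#'   `"gcd"` and `"nd"`.
#' @return Tibble with `phage_a`, `phage_b`, `gcd`,
#'   `nucleotide_distance`.
#' @export
similarity_table <- function(gcd, nd) {
  stopifnot(inherits(gcd, "phamnet_matrix"), inherits(nd, "phamnet_matrix"))
  if (!identical(rownames(gcd$values), rownames(nd$values)))
    stop("gcd and nd matrices must share labels in the same order")
  tg <- tidy(gcd)
  tn <- tidy(nd)
  left_join(tg, tn, by = c("phage_a", "phage_b")) |>
    rename(nucleotide_distance = "nd")
}
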