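#' Extract intergenic regions
#'
#' Maximal intervals of the genome not covered by any gene (the union of
#' gene intervals subtracted from `[0, L)`), with the nearest downstream
#' gene resolved per strand: on the plus strand the next gene starting at
#' or after the region's end, on the minus strand the next gene whose
#' start codon (at its right edge) lies at or before the region's start.
#' A genome without gene features yields the whole sequence as one
#' region.
#'
#' @param genome A [phage_genome()].
#' @param min_len Regions shorter than this are dropped (bp, default 1).
#' @return Tibble: `phage_id`, `start`, `end` (0-based half-open),
#'   `length`, `downstream_plus`, `downstream_minus` (gene ids or `NA`).
#' @export
extract_intergenic <- function(genome, min_len = 1L) {
  stopifnot(inherits(genome, "phage_genome"))
  L <- nchar(genome$sequence)
  g <- genome$genes
  if (nrow(g)) {
    covered <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, L), covered)
    start <- IRanges::start(gaps) - 1L
    end <- IRanges::end(gaps)
  } else {
    start <- 0L
    end <- L
  }
  keep <- (end - start) >= min_len
  start <- start[keep]; end <- end[keep]
  plus <- g[g$strand == "+", , drop = FALSE]
  minus <- g[g$strand == "-", , drop = FALSE]
  down_plus <- vapply(end, function(e) {
    cand <- plus$gene_id[plus$start >= e]
    if (length(cand)) plus$gene_id[plus$start >= e][which.min(plus$start[plus$start >= e])] else NA_character_
  }, character(1))
  down_minus <- vapply(start, function(s) {
    sel <- minus$end <= s
    if (any(sel)) minus$gene_id[sel][which.max(minus$end[sel])] else NA_character_
  }, character(1))
  tibble(phage_id = genome$phage_id, start = start, end = end,
         length = end - start,
         downstream_plus = down_plus, downstream_minus = down_minus)
}

# regions to scan and their concatenation with non-matching separators
search_text <- function(genome, search_space) {
  regions <- if (search_space == "whole") {
    tibble(start = 0L, end = nchar(genome$sequence))
  } else {
    extract_intergenic(genome)[c("start", "end")]
  }
  if (!nrow(regions))
    return(list(text = "", regions = regions, offsets = integer()))
  pieces <- substring(genome$sequence, regions$start + 1L, regions$end)
  offsets <- cumsum(c(0L, nchar(pieces) + 1L))[seq_len(nrow(regions))]
  list(text = paste(pieces, collapse = "X"), regions = regions,
       offsets = offsets)
}

# map 0-based hit starts in the concatenated text back to genome coords;
# separators can never be matched, so each hit lies inside one region
map_hits_back <- function(starts, width, st) {
  region_idx <- findInterval(starts, st$offsets)
  genome_start <- st$regions$start[region_idx] +
    (starts - st$offsets[region_idx])
  tibble(start = genome_start, end = genome_start + width)
}

#' Scan a genome for a degenerate consensus motif
#'
#' Sliding Hamming scan: every window whose distance to the (case-folded)
#' consensus is at most `max_mismatch` is reported, overlapping hits
#' included. `N` and other IUPAC degeneracy codes in the consensus match
#' their base sets; matching is substitution-only (no indels).
#' Reverse-strand hits are found by scanning with the reverse complement
#' of the consensus and are reported with the window's reverse complement
#' as `matched_seq`.
#'
#' @param genome A [phage_genome()].
#' @param consensus Motif string (length >= 4, IUPAC alphabet; case
#'   ignored for matching).
#' @param max_mismatch Maximum Hamming departures (default 0, exact
#'   search).
#' @param search_space `"whole"` (default) or `"intergenic"`.
#' @param strands `"both"` (default) or `"fwd"`.
#' @return Tibble of hits: `phage_id`, `start`, `end` (0-based
#'   half-open), `strand`, `mismatches`, `matched_seq`.
#' @examples
#' g <- phage_genome("toy", "AAGGGAAAGGACCCCTT")
#' scan_motif(g, "GGGAAAGGACCCC")
#' @export
scan_motif <- function(genome, consensus, max_mismatch = 0L,
                       search_space = c("whole", "intergenic"),
                       strands = c("both", "fwd")) {
  stopifnot(inherits(genome, "phage_genome"))
  search_space <- match.arg(search_space)
  strands <- match.arg(strands)
  consensus <- as.character(consensus)
  if (nchar(consensus) < 4L) stop("consensus length must be >= 4")
  if (grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", consensus))
    stop("non-IUPAC character in consensus")
  st <- search_text(genome, search_space)
  w <- nchar(consensus)
  out <- list()
  fwd <- .hamming_scan_cpp(st$text, consensus, as.integer(max_mismatch))
  if (length(fwd$start)) {
    hits <- map_hits_back(fwd$start, w, st)
    hits$strand <- "+"
    hits$mismatches <- fwd$mismatches
    out[["+"]] <- hits
  }
  if (strands == "both") {
    rc <- .hamming_scan_cpp(st$text, revcomp(consensus),
                            as.integer(max_mismatch))
    if (length(rc$start)) {
      hits <- map_hits_back(rc$start, w, st)
      hits$strand <- "-"
      hits$mismatches <- rc$mismatches
      out[["-"]] <- hits
    }
  }
  hits <- if (length(out)) bind_rows(out) else
    tibble(start = integer(), end = integer(), strand = character(),
           mismatches = integer())
  hits$phage_id <- rep(genome$phage_id, nrow(hits))
  hits$matched_seq <- if (nrow(hits))
    substring(genome$sequence, hits$start + 1L, hits$end)
  else character()
  flip <- hits$strand == "-"
  hits$matched_seq[flip] <- vapply(hits$matched_seq[flip], revcomp,
                                   character(1), USE.NAMES = FALSE)
  arrange(hits[c("phage_id", "start", "end", "strand", "mismatches",
                 "matched_seq")], .data$start, .data$strand)
}

#' Discover repeated degenerate motifs (direct repeats)
#'
#' Greedy seed-and-refine discovery over the chosen search space of one
#' or more genomes. Every L-mer of the search space is a candidate seed
#' (processed in genome, then coordinate order, so discovery is
#' deterministic with no randomization); all windows within
#' `max_mismatch` of the seed are gathered; if at least `min_copies`
#' windows match, a case-encoded consensus is built and rescanned,
#' iterating to a fixed point (at most 10 rounds). Maximal non-duplicate
#' models are reported sorted by copy number. Matching is forward-strand
#' only ("direct" repeats).
#'
#' @param genomes A [phage_genome()], list of them, or `phage_cohort`.
#' @param length Motif length L in bp (>= 8).
#' @param min_copies Minimum occurrences for a model (>= 3).
#' @param max_mismatch Allowed departures per occurrence.
#' @param search_space `"intergenic"` (default) or `"whole"`.
#' @param full_frac,partial_frac Consensus conservation thresholds (see
#'   [build_consensus()]).
#' @return Tibble of models: `model_id`, `consensus` (case-encoded),
#'   `length`, `n_occurrences`, `max_mismatch`, `occurrences`
#'   (list-column of hit tibbles).
#' @export
discover_direct_repeats <- function(genomes, length = 18L, min_copies = 3L,
                                    max_mismatch = 2L,
                                    search_space = c("intergenic", "whole"),
                                    full_frac = 1.0, partial_frac = 0.75) {
  stopifnot(length >= 8L, min_copies >= 3L)
  search_space <- match.arg(search_space)
  genomes <- as_genome_list(genomes)
  sts <- lapply(genomes, search_text, search_space = search_space)
  scan_all <- function(consensus, mm) {
    bind_rows(lapply(names(genomes), function(id) {
      st <- sts[[id]]
      if (!nzchar(st$text)) return(NULL)
      h <- .hamming_scan_cpp(st$text, consensus, as.integer(mm))
      if (!length(h$start)) return(NULL)
      hits <- map_hits_back(h$start, nchar(consensus), st)
      hits$mismatches <- h$mismatches
      hits$phage_id <- id
      hits$matched_seq <- substring(genomes[[id]]$sequence,
                                    hits$start + 1L, hits$end)
      hits[c("phage_id", "start", "end", "mismatches", "matched_seq")]
    }))
  }
  hit_key <- function(hits) sort(paste(hits$phage_id, hits$start))
  models <- list()
  accepted_keys <- list()
  covered <- character()  # phage_id:start pairs already in a model
  seen_seeds <- new.env(hash = TRUE)
  # one concatenated text over all genomes (input order, X separators);
  # the C++ pre-screen counts, for every seed, how many windows it
  # matches, so only seeds that can reach min_copies are refined
  texts <- vapply(names(genomes), function(id) sts[[id]]$text,
                  character(1))
  gtext <- paste(texts, collapse = "X")
  gofs <- cumsum(c(0L, nchar(texts) + 1L))[seq_along(texts)]
  counts <- .seed_count_cpp(gtext, as.integer(length),
                            as.integer(max_mismatch))
  for (p in which(counts >= min_copies)) {
    seed <- substr(gtext, p, p + length - 1L)
    if (!is.null(seen_seeds[[seed]])) next
    seen_seeds[[seed]] <- TRUE
    gi <- findInterval(p - 1L, gofs)
    id <- names(genomes)[gi]
    st <- sts[[id]]
    local_p <- p - gofs[gi]
    region_idx <- findInterval(local_p - 1L, st$offsets)
    gstart <- st$regions$start[region_idx] +
      (local_p - 1L - st$offsets[region_idx])
    if (paste(id, gstart) %in% covered) next
    {
      hits <- scan_all(seed, max_mismatch)
      if (nrow(hits) < min_copies) next
      consensus <- seed
      for (round in seq_len(10L)) {
        new_cons <- build_consensus(hits$matched_seq, full_frac, partial_frac)
        new_hits <- scan_all(new_cons, max_mismatch)
        if (nrow(new_hits) < min_copies) break
        if (identical(hit_key(new_hits), hit_key(hits)) &&
            toupper(new_cons) == toupper(consensus)) {
          consensus <- new_cons
          hits <- new_hits
          break
        }
        consensus <- new_cons
        hits <- new_hits
      }
      if (nrow(hits) < min_copies) next
      key <- hit_key(hits)
      dup <- FALSE
      for (k in seq_along(accepted_keys)) {
        if (all(key %in% accepted_keys[[k]])) { dup <- TRUE; break }
        if (all(accepted_keys[[k]] %in% key)) {
          # new model is maximal; replace the contained one
          models[[k]] <- list(consensus = consensus, hits = hits)
          accepted_keys[[k]] <- key
          dup <- TRUE
          break
        }
      }
      if (!dup) {
        models[[length(models) + 1L]] <- list(consensus = consensus,
                                              hits = hits)
        accepted_keys[[length(accepted_keys) + 1L]] <- key
      }
      covered <- union(covered, paste(hits$phage_id, hits$start))
    }
  }
  if (!base::length(models))
    return(tibble(model_id = character(), consensus = character(),
                  length = integer(), n_occurrences = integer(),
                  max_mismatch = integer(), occurrences = list()))
  # keep maximal models: phase-shifted rediscoveries of one repeat reach
  # their own fixed points (random flank columns encoded as N), so rank
  # candidates by total column conservation — the sum over columns of
  # the majority-base frequency, which the true phase maximizes because
  # a shift trades a conserved column for a random one — then by copy
  # number, and drop models whose occurrence windows mostly overlap an
  # already-selected model's
  conservation <- vapply(models, function(m) {
    mat <- do.call(rbind, strsplit(toupper(m$hits$matched_seq), "",
                                   fixed = TRUE))
    sum(apply(mat, 2, function(col) max(table(col)) / base::length(col)))
  }, double(1))
  copies <- vapply(models, function(m) nrow(m$hits), integer(1))
  ord <- order(-conservation, -copies,
               vapply(models, `[[`, character(1), "consensus"))
  selected <- list()
  sel_occ <- tibble(phage_id = character(), start = integer(),
                    end = integer())
  for (k in ord) {
    hits <- models[[k]]$hits
    overlapping <- vapply(seq_len(nrow(hits)), function(i) {
      same <- sel_occ[sel_occ$phage_id == hits$phage_id[i], , drop = FALSE]
      any(pmin(same$end, hits$end[i]) - pmax(same$start, hits$start[i]) >=
            (hits$end[i] - hits$start[i]) / 2)
    }, logical(1))
    if (mean(overlapping) > 0.5) next
    selected[[base::length(selected) + 1L]] <- models[[k]]
    sel_occ <- bind_rows(sel_occ, hits[c("phage_id", "start", "end")])
  }
  bind_rows(lapply(seq_along(selected), function(r) {
    m <- selected[[r]]
    tibble(model_id = sprintf("DR%02d", r), consensus = m$consensus,
           length = nchar(m$consensus), n_occurrences = nrow(m$hits),
           max_mismatch = as.integer(max_mismatch),
           occurrences = list(arrange(m$hits, .data$phage_id, .data$start)))
  }))
}

#' Find inverted repeats
#'
#' Scans for windows of the form `arm + spacer + reverse-complement(arm)`
#' with at most `max_mismatch` mismatching arm columns in total (the
#' spacer is unconstrained). The defaults, arm 8 and spacer 2, describe
#' an 18-bp element such as `GATCAACC-NN-GGTTGATC`.
#'
#' @param genome A [phage_genome()].
#' @param arm Arm length in bp (>= 4).
#' @param spacer Spacer length in bp (>= 0).
#' @param max_mismatch Total allowed arm mismatches.
#' @param search_space `"intergenic"` (default) or `"whole"`.
#' @return Tibble of hits: `phage_id`, `start`, `end`, `strand` (always
#'   `"+"`; an inverted repeat reads equivalently on both strands),
#'   `mismatches`, `matched_seq`.
#' @export
find_inverted_repeats <- function(genome, arm = 8L, spacer = 2L,
                                  max_mismatch = 0L,
                                  search_space = c("intergenic", "whole")) {
  stopifnot(inherits(genome, "phage_genome"), arm >= 4L, spacer >= 0L)
  search_space <- match.arg(search_space)
  st <- search_text(genome, search_space)
  w <- 2L * arm + spacer
  if (!nzchar(st$text))
    return(tibble(phage_id = character(), start = integer(),
                  end = integer(), strand = character(),
                  mismatches = integer(), matched_seq = character()))
  h <- .inverted_scan_cpp(st$text, as.integer(arm), as.integer(spacer),
                          as.integer(max_mismatch))
  hits <- map_hits_back(h$start, w, st)
  hits$mismatches <- h$mismatches
  tibble(phage_id = genome$phage_id, start = hits$start, end = hits$end,
         strand = "+", mismatches = hits$mismatches,
         matched_seq = substring(genome$sequence, hits$start + 1L,
                                 hits$end))
}

#' Build a case-encoded consensus
#'
#' Per column of the aligned occurrences: the majority base (ties broken
#' alphabetically) is written uppercase when its frequency reaches
#' `full_frac` (complete conservation), lowercase when it reaches
#' `partial_frac`, and `N` otherwise. The defaults encode the convention
#' "uppercase = conserved in all occurrences, lowercase = conserved in at
#' least three quarters".
#'
#' @param occurrences Character vector of equal-length aligned sequences
#'   (>= 2).
#' @param full_frac,partial_frac Conservation thresholds (fractions).
#' @return Case-encoded consensus string over `{ACGTacgtN}`.
#' @examples
#' build_consensus(c("ACGT", "ACGA", "ACTA", "ACTA"))
#' @export
build_consensus <- function(occurrences, full_frac = 1.0,
                            partial_frac = 0.75) {
  stopifnot(length(occurrences) >= 2L)
  w <- unique(nchar(occurrences))
  if (length(w) != 1L) stop("occurrences must have equal lengths")
  mat <- do.call(rbind, strsplit(toupper(occurrences), "", fixed = TRUE))
  n <- nrow(mat)
  cols <- vapply(seq_len(w), function(j) {
    counts <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    best <- names(counts)[which.max(counts)]  # alphabetical tie-break
    f <- max(counts) / n
    if (f >= full_frac) best
    else if (f >= partial_frac) tolower(best)
    else "N"
  }, character(1))
  paste(cols, collapse = "")
}

#' Annotate motif hits with upstream distance to a start codon
#'
#' For each hit, the number of bases between the motif's 3'-most position
#' and the first base of the start codon of the nearest downstream gene
#' on the hit's strand (both endpoints exclusive; reverse-strand
#' distances are measured on the reverse complement). Hits with no gene
#' start within `window` bp get `NA`.
#'
#' @param hits Hit tibble from [scan_motif()] or
#'   [find_inverted_repeats()].
#' @param genome The annotated [phage_genome()] the hits refer to.
#' @param window Maximum annotated distance in bp (default 500).
#' @return `hits` with `upstream_distance` and `upstream_gene` columns.
#' @export
annotate_upstream_distance <- function(hits, genome, window = 500L) {
  stopifnot(inherits(genome, "phage_genome"))
  g <- genome$genes
  plus <- g[g$strand == "+", , drop = FALSE]
  minus <- g[g$strand == "-", , drop = FALSE]
  n <- nrow(hits)
  dist <- rep(NA_integer_, n)
  gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (hits$strand[i] == "-") {
      sel <- minus$end <= hits$start[i]
      if (any(sel)) {
        j <- which(sel)[which.max(minus$end[sel])]
        d <- hits$start[i] - minus$end[j]
        if (d <= window) { dist[i] <- d; gene[i] <- minus$gene_id[j] }
      }
    } else {
      sel <- plus$start >= hits$end[i]
      if (any(sel)) {
        j <- which(sel)[which.min(plus$start[sel])]
        d <- plus$start[j] - hits$end[i]
        if (d <= window) { dist[i] <- d; gene[i] <- plus$gene_id[j] }
      }
    }
  }
  hits$upstream_distance <- dist
  hits$upstream_gene <- gene
  hits
}

#' Write motif hits as GFF3
#'
#' One `sequence_motif` feature per hit, 1-based inclusive coordinates,
#' with `mismatches`, `upstream_distance` and `model_id` attributes when
#' present.
#'
#' @param hits Hit tibble (columns `phage_id`, `start`, `end`, `strand`,
#'   `mismatches`; optionally `upstream_distance`, `model_id`).
#' @param path Output path.
#' @param type GFF3 feature type (default `"sequence_motif"`).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(hits, path, type = "sequence_motif") {
  attr_of <- function(i) {
    a <- sprintf("ID=hit%d;mismatches=%d", i, hits$mismatches[i])
    if ("upstream_distance" %in% names(hits) &&
        !is.na(hits$upstream_distance[i]))
      a <- paste0(a, ";upstream_distance=", hits$upstream_distance[i])
    if ("model_id" %in% names(hits))
      a <- paste0(a, ";model_id=", hits$model_id[i])
    a
  }
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(hits)), function(i)
               paste(hits$phage_id[i], "phamnet", type,
                     hits$start[i] + 1L, hits$end[i], ".",
                     hits$strand[i], ".", attr_of(i), sep = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
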