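#' Taxonomy thresholds
#'
#' @param cluster_gcs_min Minimum shared gene content (percent) for two
#'   phages to join the same cluster; threshold inclusive (default 35, "35
#'   percent or more of their genes").
#' @param subcluster_ani_min ANI threshold (percent) for subcluster
#'   linkage within a cluster (default 75; inclusive).
#' @param network_gcd_max,network_nd_max Strict upper bounds on
#'   gene-content dissimilarity and nucleotide distance for a network
#'   edge (defaults 0.89 and 0.42; both conditions required, both
#'   strict).
#' @return A `taxonomy_config` list.
#' @export
taxonomy_config <- function(cluster_gcs_min = 35, subcluster_ani_min = 75,
                            network_gcd_max = 0.89, network_nd_max = 0.42) {
  stopifnot(cluster_gcs_min >= 0, cluster_gcs_min <= 100,
            subcluster_ani_min >= 0, subcluster_ani_min <= 100,
            network_gcd_max >= 0, network_gcd_max <= 1,
            network_nd_max >= 0, network_nd_max <= 1)
  structure(list(cluster_gcs_min = cluster_gcs_min,
                 subcluster_ani_min = subcluster_ani_min,
                 network_gcd_max = network_gcd_max,
                 network_nd_max = network_nd_max),
            class = "taxonomy_config")
}

components_at <- function(values, threshold, above = TRUE, strict = FALSE) {
  ids <- rownames(values)
  adj <- if (above) {
    if (strict) values > threshold else values >= threshold
  } else {
    if (strict) values < threshold else values <= threshold
  }
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  split(ids, comp[ids])
}

#' Assign phages to clusters and singletons
#'
#' Phages sharing at least `cluster_gcs_min` percent gene content are
#' linked; clusters are the connected components of that graph
#' (single-linkage, so one member's pairwise link suffices to join a
#' cluster). Components of size 1 are labeled `SINGLETON`. Multi-member
#' clusters are named `C1`, `C2`, ... by decreasing size, ties broken by
#' the lexicographically smallest member, so labels are invariant to
#' input order. An optional `label_map` renames them (EA/EB-style).
#'
#' @param gcs A GCS `phamnet_matrix` from [all_pairs()].
#' @param config A [taxonomy_config()].
#' @param label_map Optional named character vector mapping default
#'   labels (`C1`, ...) to display labels.
#' @return A `cluster_assignment`: list with `assignments` (tibble
#'   `phage_id`, `cluster`, `subcluster`) and `config`. Has [tidy()] and
#'   [glance()] methods.
#' @export
assign_clusters <- function(gcs, config = taxonomy_config(),
                            label_map = NULL) {
  stopifnot(inherits(gcs, "phamnet_matrix"))
  comps <- components_at(gcs$values, config$cluster_gcs_min, above = TRUE)
  comps <- lapply(comps, sort)
  multi <- comps[lengths(comps) >= 2L]
  ord <- order(-lengths(multi),
               vapply(multi, `[[`, character(1), 1L))
  multi <- multi[ord]
  tb <- bind_rows(c(
    lapply(seq_along(multi), function(r)
      tibble(phage_id = multi[[r]], cluster = sprintf("C%d", r))),
    unname(lapply(comps[lengths(comps) == 1L], function(m)
      tibble(phage_id = m, cluster = "SINGLETON")))))
  if (!is.null(label_map)) {
    hit <- tb$cluster %in% names(label_map)
    tb$cluster[hit] <- unname(label_map[tb$cluster[hit]])
  }
  tb$subcluster <- NA_character_
  tb <- arrange(tb, .data$cluster, .data$phage_id)
  structure(list(assignments = tb, config = config),
            class = "cluster_assignment")
}

#' Subdivide clusters by average nucleotide identity
#'
#' Within each multi-member cluster, phages are linked when their ANI is
#' at least `subcluster_ani_min`; the connected components, when there is
#' more than one, become subclusters numbered by decreasing size
#' (`C1.1`, `C1.2`, ...). A cluster whose ANI graph is a single component
#' keeps `NA` subcluster labels.
#'
#' @param assignment A `cluster_assignment` from [assign_clusters()].
#' @param ani An ANI `phamnet_matrix` covering the assigned phages.
#' @param config A [taxonomy_config()]; defaults to the assignment's.
#' @return The updated `cluster_assignment`.
#' @export
assign_subclusters <- function(assignment, ani, config = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(ani, "phamnet_matrix"))
  config <- config %||% assignment$config
  tb <- assignment$assignments
  for (cl in setdiff(unique(tb$cluster), "SINGLETON")) {
    members <- tb$phage_id[tb$cluster == cl]
    if (length(members) < 2L) next
    if (!all(members %in% rownames(ani$values)))
      stop("ANI matrix does not cover cluster ", cl)
    sub <- ani$values[members, members, drop = FALSE]
    comps <- components_at(sub, config$subcluster_ani_min, above = TRUE)
    if (length(comps) < 2L) next
    comps <- lapply(comps, sort)
    ord <- order(-lengths(comps), vapply(comps, `[[`, character(1), 1L))
    for (r in seq_along(ord)) {
      m <- comps[[ord[r]]]
      tb$subcluster[tb$phage_id %in% m] <- sprintf("%s.%d", cl, r)
    }
  }
  assignment$assignments <- tb
  assignment$config <- config
  assignment
}

#' @export
print.cluster_assignment <- function(x, ...) {
  g <- glance(x)
  cat("<cluster_assignment> ", g$n_clusters, " clusters, ",
      g$n_singletons, " singletons over ", g$n_phages, " phages\n",
      sep = "")
  invisible(x)
}

#' @describeIn assign_clusters Assignments as a tibble
#'   (`phage_id`, `cluster`, `subcluster`).
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @export
tidy.cluster_assignment <- function(x, ...) x$assignments

#' @describeIn assign_clusters One-row summary: `n_phages`,
#'   `n_clusters`, `n_singletons`, `n_subclustered`.
#' @export
glance.cluster_assignment <- function(x, ...) {
  tb <- x$assignments
  tibble(n_phages = nrow(tb),
         n_clusters = length(setdiff(unique(tb$cluster), "SINGLETON")),
         n_singletons = sum(tb$cluster == "SINGLETON"),
         n_subclustered = length(unique(stats::na.omit(tb$subcluster))))
}

#' MaxGCDGap: gene-content isolation of each phage
#'
#' For one phage, sort its gene-content dissimilarities to all other
#' phages, prepend a sentinel 0 (the self-comparison), and take the
#' largest gap between consecutive values. A large MaxGCDGap marks a
#' phage that is genetically isolated from its nearest sampled
#' relatives; no trailing sentinel at 1 is added.
#'
#' @param gcd A GCD `phamnet_matrix` (at least 2 phages).
#' @param phage_id Optional subset of phages; default all.
#' @return Tibble with `phage_id`, `max_gcd_gap`.
#' @examples
#' \dontrun{max_gcd_gap(gcd_matrix)}
#' @export
max_gcd_gap <- function(gcd, phage_id = NULL) {
  stopifnot(inherits(gcd, "phamnet_matrix"))
  ids <- rownames(gcd$values)
  if (length(ids) < 2L) stop("MaxGCDGap requires at least 2 phages")
  phage_id <- phage_id %||% ids
  stopifnot(all(phage_id %in% ids))
  gaps <- vapply(phage_id, function(p) {
    d <- sort(gcd$values[p, setdiff(ids, p)])
    max(diff(c(0, d)))
  }, double(1))
  tibble(phage_id = phage_id, max_gcd_gap = unname(gaps))
}

#' Build the genome network
#'
#' Retains every phage pair with "intra-cluster" distances — gene-content
#' dissimilarity strictly below `network_gcd_max` AND nucleotide distance
#' strictly below `network_nd_max` — as an edge, and reports the
#' connected components. Components group phages irrespective of their
#' formal cluster labels.
#'
#' @param gcd,nd `phamnet_matrix` objects sharing labels.
#' @param config A [taxonomy_config()].
#' @return A `genome_network`: list with `edges` (tibble `phage_a`,
#'   `phage_b`, `gcd`, `nucleotide_distance`), `components` (tibble
#'   `phage_id`, `component`), `config`.
#' @export
build_network <- function(gcd, nd, config = taxonomy_config()) {
  stopifnot(inherits(gcd, "phamnet_matrix"), inherits(nd, "phamnet_matrix"))
  if (!identical(rownames(gcd$values), rownames(nd$values)))
    stop("gcd and nd matrices must share labels in the same order")
  pairs <- similarity_table(gcd, nd)
  edges <- filter(pairs, .data$gcd < config$network_gcd_max,
                  .data$nucleotide_distance < config$network_nd_max)
  g <- igraph::graph_from_data_frame(
    edges[c("phage_a", "phage_b")], directed = FALSE,
    vertices = rownames(gcd$values))
  comp <- igraph::components(g)$membership
  # stable component numbering by smallest member id
  comp_split <- split(names(comp), comp)
  ord <- order(vapply(comp_split, min, character(1)))
  components <- bind_rows(lapply(seq_along(ord), function(r)
    tibble(phage_id = sort(comp_split[[ord[r]]]), component = r)))
  structure(list(edges = edges, components = components, config = config),
            class = "genome_network")
}

#' @export
print.genome_network <- function(x, ...) {
  cat("<genome_network> ", nrow(x$edges), " edges, ",
      max(x$components$component), " components over ",
      nrow(x$components), " phages\n", sep = "")
  cat("  thresholds: gcd < ", x$config$network_gcd_max, ", nd < ",
      x$config$network_nd_max, " (strict)\n", sep = "")
  invisible(x)
}

#' @describeIn build_network Edge list as a tibble.
#' @param x A `genome_network`.
#' @param ... Unused.
#' @export
tidy.genome_network <- function(x, ...) x$edges

#' @describeIn build_network One-row summary: `n_phages`, `n_edges`,
#'   `n_components`.
#' @export
glance.genome_network <- function(x, ...) {
  tibble(n_phages = nrow(x$components), n_edges = nrow(x$edges),
         n_components = max(x$components$component))
}

#' Heatmap leaf order for a pairwise matrix
#'
#' Row distances under the maximum (Chebyshev) metric, agglomerated by
#' single linkage; returns the dendrogram leaf order, which places the
#' members of well-separated blocks contiguously.
#'
#' @param m A `phamnet_matrix` or labeled square matrix.
#' @return Character vector of labels in leaf order.
#' @export
order_heatmap <- function(m) {
  vals <- if (inherits(m, "phamnet_matrix")) m$values else as.matrix(m)
  if (nrow(vals) < 2L) return(rownames(vals))
  hc <- hclust(dist(vals, method = "maximum"), method = "single")
  rownames(vals)[hc$order]
}

#' Flag bioinformatic temperate-lifestyle markers
#'
#' Scans gene product annotations for integrase / repressor keywords
#' (case-insensitive: "integrase", "immunity repressor", "repressor").
#' This reports the presence of temperate markers only — it is explicitly
#' NOT a lifestyle call, since marker-free genomes can still be temperate
#' and vice versa.
#'
#' @param genomes A [phage_genome()], a list of them, or a
#'   `phage_cohort`.
#' @return Tibble with one row per genome: `phage_id`, `marker_present`,
#'   `n_marker_genes`, `marker_genes` (list-column of gene ids), `note`
#'   (`"temperate-marker present"` or `"no markers"`).
#' @export
flag_lifestyle_markers <- function(genomes) {
  genomes <- as_genome_list(genomes)
  pattern <- "integrase|immunity repressor|\\brepressor\\b"
  purrr::map_dfr(genomes, function(g) {
    prod <- g$genes$product
    hit <- !is.na(prod) & grepl(pattern, prod, ignore.case = TRUE)
    tibble(phage_id = g$phage_id,
           marker_present = any(hit),
           n_marker_genes = sum(hit),
           marker_genes = list(g$genes$gene_id[hit]),
           note = if (any(hit)) "temperate-marker present" else "no markers")
  })
}
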