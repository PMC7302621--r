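# shared cohort fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# 3 clusters x 4 genomes + 2 singletons; defaults otherwise
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- phamnet::generate_cohort(
      phamnet::cohort_spec(n_clusters = 3, cluster_sizes = 4,
                           n_singletons = 2, seed = 101))
  .fixtures$cohort
}

fixture_phams <- function() {
  if (is.null(.fixtures$phams))
    .fixtures$phams <- phamnet::build_phams(fixture_cohort())
  .fixtures$phams
}

fixture_gcs <- function() {
  if (is.null(.fixtures$gcs))
    .fixtures$gcs <- phamnet::all_pairs(fixture_cohort(), "gcs",
                                        phams = fixture_phams())
  .fixtures$gcs
}
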