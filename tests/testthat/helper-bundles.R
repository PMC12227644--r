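# memoized simulated bundles shared across test files
.bundle_cache <- new.env(parent = emptyenv())

small_bundle <- function() {
  if (is.null(.bundle_cache$small)) {
    .bundle_cache$small <- simulate_cohort(
      sim_params(seed = 101L, n_genes = 30L, n_fusions = 200L))
  }
  .bundle_cache$small
}

small_annotated <- function() {
  if (is.null(.bundle_cache$small_ann)) {
    b <- small_bundle()
    .bundle_cache$small_ann <- annotate_fusions(
      b$calls, b$genes, b$seq_store, b$domain_table, topology = b$topology)
  }
  .bundle_cache$small_ann
}

big_bundle <- function() {
  if (is.null(.bundle_cache$big)) {
    .bundle_cache$big <- simulate_cohort(
      sim_params(seed = 202L, n_genes = 60L, n_fusions = 1000L))
  }
  .bundle_cache$big
}

big_annotated <- function() {
  if (is.null(.bundle_cache$big_ann)) {
    b <- big_bundle()
    .bundle_cache$big_ann <- annotate_fusions(
      b$calls, b$genes, b$seq_store, b$domain_table, topology = b$topology)
  }
  .bundle_cache$big_ann
}
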