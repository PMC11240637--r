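## shared fixtures: built once per test run, deterministic

fx_regional <- fallow_deer_fixture("regional", seed = 11)
fx_global <- fallow_deer_fixture("global_192", seed = 11)
fx_new138 <- fallow_deer_fixture("new_collection_138", seed = 11)

run_haplotyping <- function(fx) {
  positioned <- map_sequences(fx$sequences, fx$reference)
  res <- assign_haplotypes(positioned, fx$registry, fx$reference)
  list(
    positioned = positioned,
    assignments = res$assignments,
    registry = res$registry,
    pop_table = haplotype_frequencies(res$assignments, fx$metadata)
  )
}

hap_regional <- run_haplotyping(fx_regional)
hap_global <- run_haplotyping(fx_global)

## independent brute-force oracle: mean pairwise difference counts from an
## explicit enumeration of individual pairs (never the matrix algebra of
## the implementation)
oracle_fst <- function(labels_a, labels_b, diffs) {
  pair_mean <- function(x, y, within) {
    tot <- 0; np <- 0
    for (i in seq_along(x)) {
      for (j in seq_along(y)) {
        if (within && j <= i) next
        tot <- tot + diffs[x[i], y[j]]
        np <- np + 1
      }
    }
    if (np == 0) 0 else tot / np
  }
  hw <- mean(c(pair_mean(labels_a, labels_a, TRUE),
               pair_mean(labels_b, labels_b, TRUE)))
  hb <- pair_mean(labels_a, labels_b, FALSE)
  if (hb == 0) 0 else 1 - hw / hb
}

oracle_gst_uncorrected <- function(labels_a, labels_b) {
  haps <- sort(unique(c(labels_a, labels_b)))
  pa <- sapply(haps, function(h) mean(labels_a == h))
  pb <- sapply(haps, function(h) mean(labels_b == h))
  hs <- mean(c(1 - sum(pa^2), 1 - sum(pb^2)))
  ht <- 1 - sum(((pa + pb) / 2)^2)
  if (ht == 0) 0 else (ht - hs) / ht
}
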